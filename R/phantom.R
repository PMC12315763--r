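#' Specify a layered head phantom
#'
#' The phantom emulates the anatomy the pipeline targets: an ellipsoidal
#' brain (WM core, GM rind) surrounded by a CSF gap, a three-layer skull
#' (dark inner cortical table, bright diploe whose intensity encodes marrow
#' fat and hence is the BMD-linked parameter, dark outer table) and a scalp
#' whose voxel intensities are drawn from a two-component muscle/fat mixture
#' with mixing weight `fat_fraction`. The inferior quarter of the head is
#' optionally left open (no CSF/skull/scalp) to mimic the defaced /
#' truncated lower portions of real brain scans.
#'
#' Layer membership is defined by the exact Euclidean distance (mm) of each
#' voxel center from the brain mask, so the nominal layer thicknesses hold
#' in every direction, for ellipsoids and under rotation.
#'
#' @param shape grid dimensions (default 128^3).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param brain_radii ellipsoid semi-axes of the brain in mm.
#' @param csf_gap_mm,inner_table_mm,diploe_mm,outer_table_mm,scalp_mm layer
#'   thicknesses in mm.
#' @param diploe_intensity mean T1 intensity of the diploe (bright marrow;
#'   higher values emulate lower bone mineral density).
#' @param fat_fraction scalp fat mixing weight in \[0,1\].
#' @param tissue_means named intensities for gm, wm, csf, cortical_bone,
#'   muscle, fat, background.
#' @param noise_sd additive noise standard deviation (intensity units);
#'   the default 20 gives SNR (WM mean / sd) of 20.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param bias_amplitude fractional amplitude of a smooth multiplicative
#'   bias field (0 disables it).
#' @param rotation Euler angles (degrees) rotating the anatomy about the
#'   x, y, z axes.
#' @param open_inferior leave the inferior quarter of the head open.
#' @param seed integer seed controlling anatomy (scalp mixture assignment)
#'   and, unless overridden, noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         spacing = c(1, 1, 1),
                         brain_radii = c(40, 46, 38),
                         csf_gap_mm = 2,
                         inner_table_mm = 2,
                         diploe_mm = 3,
                         outer_table_mm = 2,
                         scalp_mm = 6,
                         diploe_intensity = 450,
                         fat_fraction = 0.3,
                         tissue_means = c(gm = 280, wm = 400, csf = 80,
                                          cortical_bone = 130, muscle = 300,
                                          fat = 600, background = 10),
                         noise_sd = 20,
                         noise_model = c("gaussian", "rician"),
                         bias_amplitude = 0,
                         rotation = c(0, 0, 0),
                         open_inferior = TRUE,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               brain_radii = as.numeric(brain_radii),
               csf_gap_mm = csf_gap_mm, inner_table_mm = inner_table_mm,
               diploe_mm = diploe_mm, outer_table_mm = outer_table_mm,
               scalp_mm = scalp_mm, diploe_intensity = diploe_intensity,
               fat_fraction = fat_fraction, tissue_means = tissue_means,
               noise_sd = noise_sd, noise_model = noise_model,
               bias_amplitude = bias_amplitude,
               rotation = as.numeric(rotation),
               open_inferior = isTRUE(open_inferior),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  th <- c(spec$csf_gap_mm, spec$inner_table_mm, spec$diploe_mm,
          spec$outer_table_mm, spec$scalp_mm)
  if (any(th <= 0))
    stop("phantom_spec: all layer thicknesses must be > 0", call. = FALSE)
  if (spec$fat_fraction < 0 || spec$fat_fraction > 1)
    stop("phantom_spec: fat_fraction must be in [0,1]", call. = FALSE)
  tm <- spec$tissue_means
  if (tm[["cortical_bone"]] >= spec$diploe_intensity)
    stop("phantom_spec: cortical bone mean must be below diploe intensity",
         call. = FALSE)
  if (tm[["cortical_bone"]] >= tm[["wm"]])
    stop("phantom_spec: cortical bone mean must be below WM mean",
         call. = FALSE)
  half_extent <- (spec$shape - 1) * spec$spacing / 2
  total <- max(spec$brain_radii) + sum(th)
  if (total >= min(half_extent))
    stop("phantom_spec: layers exceed the grid (need < ",
         round(min(half_extent), 1), " mm, got ", total, " mm)",
         call. = FALSE)
  invisible(spec)
}

#' Phantom presets
#'
#' @param preset one of `"default"`, `"thin-skull"`, `"obese"`,
#'   `"osteoporotic"`.
#' @param ... overrides passed on to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(preset = c("default", "thin-skull", "obese",
                                      "osteoporotic"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "default" = list(),
    "thin-skull" = list(inner_table_mm = 1.2, diploe_mm = 1.6,
                        outer_table_mm = 1.2),
    "obese" = list(scalp_mm = 12, fat_fraction = 0.6),
    # low bone mineral density: fattier marrow, hence brighter diploe
    "osteoporotic" = list(diploe_intensity = 560, diploe_mm = 3.5))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# sub-tissue codes used in phantom truth
PHANTOM_TISSUES <- c(background = 0L, gm = 1L, wm = 2L, csf = 3L,
                     inner_table = 4L, diploe = 5L, outer_table = 6L,
                     muscle = 7L, fat = 8L)

#' Generate a layered head phantom
#'
#' @param spec a [phantom_spec()].
#' @param kind segmentation kind to emit: `"label"` (ground-truth classes)
#'   or `"probability"` (binary classes smoothed by a 1 mm Gaussian and
#'   renormalized).
#' @param noise_seed optional separate seed for the noise/bias realization
#'   (anatomy stays governed by `spec$seed`); used by [make_retest_pair()].
#' @return list with `t1` ([volume_grid]), `seg` ([tissue_segmentation])
#'   and `truth` (list: per-voxel `labels` 1..6, sub-tissue `tissue` codes,
#'   `skull_thickness_mm`, `scalp_thickness_mm`, `diploe_intensity`,
#'   `fat_fraction`, `center` (mm), `rim_z` (lowest skull slice, 1-based),
#'   `skull_thickness_map`, `scalp_thickness_map`).
#' @export
generate_phantom <- function(spec, kind = c("label", "probability"),
                             noise_seed = NULL) {
  kind <- match.arg(kind)
  validate_phantom_spec(spec)
  dims <- spec$shape
  sp <- spec$spacing
  center <- (dims - 1) * sp / 2
  g <- voxel_center_grids(dims, sp)
  px <- g$x - center[1]; py <- g$y - center[2]; pz <- g$z - center[3]
  R <- rotation_matrix(spec$rotation)
  # anatomy coordinates: rotate world offsets back into the ellipsoid frame
  qx <- R[1, 1] * px + R[2, 1] * py + R[3, 1] * pz
  qy <- R[1, 2] * px + R[2, 2] * py + R[3, 2] * pz
  qz <- R[1, 3] * px + R[2, 3] * py + R[3, 3] * pz
  rb <- spec$brain_radii
  brain <- (qx / rb[1])^2 + (qy / rb[2])^2 + (qz / rb[3])^2 <= 1
  if (!any(brain))
    stop("generate_phantom: brain ellipsoid does not cover any voxel",
         call. = FALSE)
  wm <- (qx / (0.72 * rb[1]))^2 + (qy / (0.72 * rb[2]))^2 +
        (qz / (0.72 * rb[3]))^2 <= 1

  d <- edt_distance(brain, sp)
  b0 <- spec$csf_gap_mm
  b1 <- b0 + spec$inner_table_mm
  b2 <- b1 + spec$diploe_mm
  b3 <- b2 + spec$outer_table_mm
  b4 <- b3 + spec$scalp_mm

  tissue <- array(PHANTOM_TISSUES[["background"]], dims)
  tissue[brain & !wm] <- PHANTOM_TISSUES[["gm"]]
  tissue[wm] <- PHANTOM_TISSUES[["wm"]]
  tissue[!brain & d <= b0] <- PHANTOM_TISSUES[["csf"]]
  tissue[d > b0 & d <= b1] <- PHANTOM_TISSUES[["inner_table"]]
  tissue[d > b1 & d <= b2] <- PHANTOM_TISSUES[["diploe"]]
  tissue[d > b2 & d <= b3] <- PHANTOM_TISSUES[["outer_table"]]
  scalp <- d > b3 & d <= b4

  set.seed(spec$seed)
  fat_draw <- array(stats::runif(prod(dims)) < spec$fat_fraction, dims)
  tissue[scalp & fat_draw] <- PHANTOM_TISSUES[["fat"]]
  tissue[scalp & !fat_draw] <- PHANTOM_TISSUES[["muscle"]]

  if (spec$open_inferior) {
    open_reg <- qz < -0.5 * rb[3] & !brain
    tissue[open_reg] <- PHANTOM_TISSUES[["background"]]
  }

  # six-class labels: GM=1 WM=2 CSF=3 skull=4 head=5 background=6
  labels <- array(6L, dims)
  labels[tissue == PHANTOM_TISSUES[["gm"]]] <- 1L
  labels[tissue == PHANTOM_TISSUES[["wm"]]] <- 2L
  labels[tissue == PHANTOM_TISSUES[["csf"]]] <- 3L
  labels[tissue %in% PHANTOM_TISSUES[c("inner_table", "diploe",
                                       "outer_table")]] <- 4L
  labels[tissue %in% PHANTOM_TISSUES[c("muscle", "fat")]] <- 5L

  tm <- spec$tissue_means
  t1 <- array(tm[["background"]], dims)
  t1[labels == 1L] <- tm[["gm"]]
  t1[labels == 2L] <- tm[["wm"]]
  t1[labels == 3L] <- tm[["csf"]]
  t1[tissue == PHANTOM_TISSUES[["inner_table"]]] <- tm[["cortical_bone"]]
  t1[tissue == PHANTOM_TISSUES[["outer_table"]]] <- tm[["cortical_bone"]]
  t1[tissue == PHANTOM_TISSUES[["diploe"]]] <- spec$diploe_intensity
  t1[tissue == PHANTOM_TISSUES[["muscle"]]] <- tm[["muscle"]]
  t1[tissue == PHANTOM_TISSUES[["fat"]]] <- tm[["fat"]]

  set.seed(if (is.null(noise_seed)) spec$seed else as.integer(noise_seed))
  if (spec$bias_amplitude > 0) {
    t1 <- t1 * (1 + spec$bias_amplitude * bias_field(dims, sp))
  }
  if (spec$noise_sd > 0) {
    n <- prod(dims)
    if (spec$noise_model == "gaussian") {
      t1 <- t1 + array(stats::rnorm(n, 0, spec$noise_sd), dims)
    } else {
      n1 <- array(stats::rnorm(n, 0, spec$noise_sd), dims)
      n2 <- array(stats::rnorm(n, 0, spec$noise_sd), dims)
      t1 <- sqrt((t1 + n1)^2 + n2^2)
    }
  }

  seg <- if (kind == "label") {
    labels_to_segmentation(labels, sp)
  } else {
    maps <- lapply(1:6, function(i) {
      gaussian_smooth(array(as.numeric(labels == i), dims), 1, sp)
    })
    tot <- Reduce(`+`, maps)
    maps <- lapply(maps, function(m) m / tot)
    tissue_segmentation(maps, kind = "probability", spacing = sp)
  }

  skull_mask <- labels == 4L
  skull_total <- spec$inner_table_mm + spec$diploe_mm + spec$outer_table_mm
  skull_thickness_map <- array(NA_real_, dims)
  skull_thickness_map[skull_mask] <- skull_total
  scalp_thickness_map <- array(NA_real_, dims)
  scalp_thickness_map[labels == 5L] <- spec$scalp_mm
  rim_z <- if (any(skull_mask)) {
    min(which(apply(skull_mask, 3, any)))
  } else NA_integer_

  truth <- list(labels = labels, tissue = tissue,
                skull_thickness_mm = skull_total,
                scalp_thickness_mm = spec$scalp_mm,
                diploe_intensity = spec$diploe_intensity,
                fat_fraction = spec$fat_fraction,
                center = center, rim_z = rim_z,
                skull_thickness_map = skull_thickness_map,
                scalp_thickness_map = scalp_thickness_map)
  list(t1 = volume_grid(t1, sp), seg = seg, truth = truth)
}

# zero-mean smooth low-order polynomial on [-1,1]^3, max |value| = 1,
# random coefficients from the current RNG stream
bias_field <- function(dims, spacing) {
  g <- voxel_center_grids(dims, spacing)
  ext <- (dims - 1) * spacing
  x <- 2 * g$x / ext[1] - 1
  y <- 2 * g$y / ext[2] - 1
  z <- 2 * g$z / ext[3] - 1
  co <- stats::rnorm(9)
  p <- co[1] * x + co[2] * y + co[3] * z + co[4] * x * y + co[5] * x * z +
    co[6] * y * z + co[7] * x^2 + co[8] * y^2 + co[9] * z^2
  p <- p - mean(p)
  p / max(abs(p))
}

#' Plant the marrow misclassification the correction step repairs
#'
#' Unified segmentation often assigns the bright bone marrow of the diploe
#' to the soft head tissue class instead of the skull. This planter
#' relabels a random connected subset of diploe voxels from skull to head,
#' producing a corrupted segmentation with a known defect mask.
#'
#' @param seg phantom [tissue_segmentation].
#' @param truth phantom truth list (provides the diploe location).
#' @param fraction fraction of diploe voxels to corrupt, in \[0,1\].
#' @param seed integer seed.
#' @return list `seg` (corrupted segmentation) and `planted_mask` (logical
#'   volume of exactly the relabelled voxels).
#' @export
plant_marrow_misclassification <- function(seg, truth, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("plant_marrow_misclassification: fraction must be in [0,1]",
         call. = FALSE)
  dims <- dim(seg$maps[[1]])
  diploe <- truth$tissue == PHANTOM_TISSUES[["diploe"]]
  n_diploe <- sum(diploe)
  if (n_diploe == 0)
    stop("plant_marrow_misclassification: phantom has no diploe layer",
         call. = FALSE)
  target <- round(fraction * n_diploe)
  planted <- array(FALSE, dims)
  if (target > 0) {
    set.seed(as.integer(seed))
    prio <- stats::runif(prod(dims))
    start <- which(diploe)[sample.int(n_diploe, 1)]
    planted <- array(cpp_region_grow(as.logical(diploe), as.integer(dims),
                                     prio, as.integer(start),
                                     as.integer(target)), dims)
  }
  if (any(planted)) {
    sk <- seg$maps[["skull"]]
    hd <- seg$maps[["head"]]
    moved <- sk[planted]
    sk[planted] <- if (seg$kind == "label") 0 else 0
    hd[planted] <- if (seg$kind == "label") 1 else hd[planted] + moved
    seg$maps[["skull"]] <- sk
    seg$maps[["head"]] <- hd
  }
  list(seg = validate_segmentation(seg), planted_mask = planted)
}

#' Generate a retest pair: same anatomy, independent noise
#'
#' Emulates two acquisitions of the same head within a short interval:
#' identical geometry and tissue means, independent noise (and bias)
#' realizations.
#'
#' @param spec a [phantom_spec()].
#' @param seeds two distinct integer seeds for the noise realizations.
#' @param kind segmentation kind, as in [generate_phantom()].
#' @return list of two `generate_phantom()` results.
#' @export
make_retest_pair <- function(spec, seeds, kind = "label") {
  if (length(seeds) != 2L || seeds[1] == seeds[2])
    stop("make_retest_pair: two distinct seeds required", call. = FALSE)
  list(generate_phantom(spec, kind = kind, noise_seed = seeds[1]),
       generate_phantom(spec, kind = kind, noise_seed = seeds[2]))
}
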