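# Calvarial sector atlas. The reference manual CT-based atlas is not
# distributable, so regions are defined procedurally as angular sectors
# about the head center, preserving the regional-extraction architecture
# (and the occipital default) while remaining fully reproducible. A real
# atlas volume can be substituted wherever a `calvarial_atlas` is accepted.

ATLAS_REGIONS <- c(none = 0L, frontal = 1L, parietal_l = 2L,
                   parietal_r = 3L, occipital = 4L, temporal_l = 5L,
                   temporal_r = 6L, sphenoid = 7L)

# sector bounds (documented constants, degrees):
#   elevation theta = atan2(z, sqrt(x^2+y^2)); azimuth a = atan2(x, y)
#   (0 deg = anterior, +/-180 = posterior, sign of x = right/left)
#   occipital: |a| >= 135 (posterior band, all elevations)
#   superior (theta >= 10): frontal |a| < 45; parietal 45 <= |a| < 135
#   inferior (theta < 10): sphenoid |a| < 45; temporal 45 <= |a| < 135
ATLAS_ELEVATION_SPLIT_DEG <- 10
ATLAS_AZIMUTH_FRONT_DEG <- 45
ATLAS_AZIMUTH_BACK_DEG <- 135

sector_labels_from_offsets <- function(dx, dy, dz) {
  elev <- atan2(dz, sqrt(dx^2 + dy^2)) * 180 / pi
  azim <- abs(atan2(dx, dy) * 180 / pi)
  lab <- array(0L, dim(dx))
  sup <- elev >= ATLAS_ELEVATION_SPLIT_DEG
  left <- dx < 0
  occ <- azim >= ATLAS_AZIMUTH_BACK_DEG
  fro <- azim < ATLAS_AZIMUTH_FRONT_DEG
  lat <- !occ & !fro
  lab[occ] <- ATLAS_REGIONS[["occipital"]]
  lab[fro & sup] <- ATLAS_REGIONS[["frontal"]]
  lab[fro & !sup] <- ATLAS_REGIONS[["sphenoid"]]
  lab[lat & sup & left] <- ATLAS_REGIONS[["parietal_l"]]
  lab[lat & sup & !left] <- ATLAS_REGIONS[["parietal_r"]]
  lab[lat & !sup & left] <- ATLAS_REGIONS[["temporal_l"]]
  lab[lat & !sup & !left] <- ATLAS_REGIONS[["temporal_r"]]
  lab
}

new_calvarial_atlas <- function(labels, bone_mask, spacing, affine,
                                center) {
  structure(list(labels = labels, bone_mask = bone_mask,
                 names = ATLAS_REGIONS, spacing = spacing, affine = affine,
                 center = center),
            class = "calvarial_atlas")
}

#' @export
print.calvarial_atlas <- function(x, ...) {
  cat("<calvarial_atlas> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", sum(x$bone_mask), " bone-mask voxels\n", sep = "")
  invisible(x)
}

#' Build the procedural calvarial sector atlas on a template geometry
#'
#' Partitions the template skull shell into 7 angular sectors relative to
#' the head center: frontal (anterior-superior), left/right parietal
#' (lateral-superior), occipital (posterior), left/right temporal
#' (lateral-inferior) and sphenoid (anterior-inferior). The defacing-safe
#' bone mask covers the frontal, parietal and occipital sectors only; the
#' thin and defacing-prone temporal and sphenoid regions are excluded.
#'
#' Sector labels are assigned densely over the grid (every voxel gets the
#' label of its sector), which makes nearest-neighbor mapping to individual
#' grids robust; the bone mask is restricted to the template skull shell.
#'
#' @param template_spec a [phantom_spec()] describing the template
#'   geometry, or a [tissue_segmentation] whose skull class defines the
#'   shell (the head center is then the skull centroid).
#' @return a `calvarial_atlas`: integer `labels` volume, logical
#'   `bone_mask`, region `names` table.
#' @export
build_template_atlas <- function(template_spec) {
  if (inherits(template_spec, "phantom_spec")) {
    ph <- generate_phantom(template_spec, kind = "label")
    seg <- ph$seg
  } else if (inherits(template_spec, "tissue_segmentation")) {
    seg <- template_spec
  } else {
    stop("build_template_atlas: need a phantom_spec or tissue_segmentation",
         call. = FALSE)
  }
  labels6 <- seg_labels(seg)
  skull <- labels6 == 4L
  if (!any(skull))
    stop("build_template_atlas: template skull shell is empty",
         call. = FALSE)
  dims <- dim(labels6)
  sp <- seg$spacing
  g <- voxel_center_grids(dims, sp, seg$affine)
  idx <- which(skull)
  center <- c(mean(g$x[idx]), mean(g$y[idx]), mean(g$z[idx]))
  lab <- sector_labels_from_offsets(g$x - center[1], g$y - center[2],
                                    g$z - center[3])
  bone_mask <- skull & (lab %in% 1:4)
  new_calvarial_atlas(lab, bone_mask, sp, seg$affine, center)
}

#' Map a calvarial atlas into an individual grid
#'
#' Nearest-neighbor resampling of labels and bone mask through the linear
#' template-to-individual transform (the affine from the segmentation
#' step); no nonlinear warping.
#'
#' @param atlas a `calvarial_atlas` in template space.
#' @param affine_template_to_individual 4x4 world-to-world transform
#'   (template mm to individual mm).
#' @param target_dims,target_spacing,target_affine geometry of the
#'   individual grid (affine defaults to a diagonal from spacing).
#' @return a `calvarial_atlas` on the individual grid.
#' @export
map_atlas_to_individual <- function(atlas, affine_template_to_individual,
                                    target_dims, target_spacing,
                                    target_affine = NULL) {
  A <- as.matrix(affine_template_to_individual)
  if (!all(dim(A) == c(4, 4)) || abs(det(A[1:3, 1:3])) < 1e-12)
    stop("map_atlas_to_individual: transform must be an invertible 4x4 ",
         "affine", call. = FALSE)
  if (is.null(target_affine)) target_affine <- diag(c(target_spacing, 1))
  dims_t <- dim(atlas$labels)
  # individual voxel -> individual world -> template world -> template voxel
  M <- solve(atlas$affine) %*% solve(A) %*% target_affine
  i <- seq_len(target_dims[1]) - 1
  j <- seq_len(target_dims[2]) - 1
  k <- seq_len(target_dims[3]) - 1
  n <- prod(target_dims)
  vox <- cbind(rep(i, times = target_dims[2] * target_dims[3]),
               rep(rep(j, each = target_dims[1]), times = target_dims[3]),
               rep(k, each = target_dims[1] * target_dims[2]))
  src <- round(t(M %*% rbind(t(vox), 1))[, 1:3, drop = FALSE])
  inside <- src[, 1] >= 0 & src[, 1] < dims_t[1] &
            src[, 2] >= 0 & src[, 2] < dims_t[2] &
            src[, 3] >= 0 & src[, 3] < dims_t[3]
  lin <- src[, 3] * dims_t[1] * dims_t[2] + src[, 2] * dims_t[1] +
    src[, 1] + 1
  labels <- integer(n)
  labels[inside] <- atlas$labels[lin[inside]]
  mask <- logical(n)
  mask[inside] <- atlas$bone_mask[lin[inside]]
  center_w <- (A %*% c(atlas$center, 1))[1:3]
  new_calvarial_atlas(array(labels, target_dims), array(mask, target_dims),
                      target_spacing, target_affine, center_w)
}

#' Aggregate a voxel measure by atlas region
#'
#' @param measure_map numeric volume of the measure (or a `thickness_map`,
#'   whose excluded voxels are dropped).
#' @param atlas individual-space `calvarial_atlas`.
#' @param skull_mask logical volume restricting aggregation (usually the
#'   corrected skull class; for head measures, the included scalp voxels).
#' @param use_bone_mask intersect with the atlas bone mask for the regions
#'   it covers and the global row (default TRUE).
#' @return data.frame (`region_table`): region, label, mean_value,
#'   n_voxels, in_mask; plus a `global` row aggregated over
#'   `skull_mask` (intersected with the bone mask when `use_bone_mask`).
#' @export
regional_aggregate <- function(measure_map, atlas, skull_mask,
                               use_bone_mask = TRUE) {
  if (inherits(measure_map, "thickness_map")) {
    skull_mask <- skull_mask & !measure_map$excluded_mask
    measure_map <- measure_map$values
  }
  lab <- atlas$labels
  rows <- lapply(1:7, function(r) {
    in_mask <- r %in% 1:4
    m <- skull_mask & lab == r
    if (use_bone_mask && in_mask) m <- m & atlas$bone_mask
    vals <- measure_map[m]
    vals <- vals[is.finite(vals)]
    data.frame(region = names(ATLAS_REGIONS)[ATLAS_REGIONS == r],
               label = r,
               mean_value = if (length(vals)) mean(vals) else NA_real_,
               n_voxels = length(vals),
               in_mask = in_mask)
  })
  gm <- skull_mask
  if (use_bone_mask) gm <- gm & atlas$bone_mask
  gvals <- measure_map[gm]
  gvals <- gvals[is.finite(gvals)]
  rows <- c(rows, list(data.frame(
    region = "global", label = NA_integer_,
    mean_value = if (length(gvals)) mean(gvals) else NA_real_,
    n_voxels = length(gvals), in_mask = TRUE)))
  do.call(rbind, rows)
}
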