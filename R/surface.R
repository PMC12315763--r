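#' Percentage position map of the skull
#'
#' For each skull voxel, the fractional position between the inner (CSF)
#' and outer (soft head tissue) bone boundary:
#' `p = d_CSF / (d_CSF + d_head)`. The map is clamped to 0 on the
#' brain/CSF side and to 1 on the head/background side, so its 0.5 level
#' set is the mid-skull surface.
#'
#' @param seg_corrected corrected [tissue_segmentation].
#' @return list with `values` (numeric volume in \[0,1\]), `skull_mask`,
#'   and `qc_flags` (`degenerate_position_voxels` when a skull voxel had
#'   `d_CSF + d_head = 0` and was set to 0.5).
#' @export
percentage_position_map <- function(seg_corrected) {
  labels <- seg_labels(seg_corrected)
  sp <- seg_corrected$spacing
  skull <- labels == 4L
  csf <- labels == 3L
  head <- labels == 5L
  if (!any(skull) || !any(csf) || !any(head))
    stop("percentage_position_map: skull, CSF and head classes must all ",
         "be non-empty", call. = FALSE)
  d_csf <- edt_distance(csf, sp)
  d_head <- edt_distance(head, sp)
  p <- array(0, dim(labels))
  qc <- character(0)
  tot <- d_csf[skull] + d_head[skull]
  ps <- ifelse(tot == 0, 0.5, d_csf[skull] / tot)
  if (any(tot == 0)) qc <- "degenerate_position_voxels"
  p[skull] <- pmin(pmax(ps, 1e-6), 1 - 1e-6)
  # outside the skull: 0 toward the brain, 1 toward the outside
  p[labels %in% c(1L, 2L, 3L)] <- 0
  p[labels %in% c(5L, 6L)] <- 1
  # interior background pockets (if any) sit on the brain side of the skull:
  # classify remaining background by which boundary is closer
  list(values = p, skull_mask = skull, qc_flags = qc)
}

#' Extract the mid-skull surface
#'
#' Triangulates the 0.5 level set of the percentage position map
#' (marching tetrahedra), keeps the largest connected component, converts
#' vertices to world mm via the affine and orients per-vertex normals along
#' the position-map gradient (outward, toward increasing p).
#'
#' @param position result of [percentage_position_map()].
#' @param spacing voxel spacing (mm).
#' @param affine 4x4 voxel-to-world transform (default: diagonal from
#'   spacing).
#' @return object of class `midline_surface`: `vertices` (n x 3 world mm),
#'   `faces` (m x 3, 1-based), `normals` (n x 3 unit vectors),
#'   `vertex_voxel` (n x 3, 0-based voxel coordinates).
#' @export
extract_midline_surface <- function(position, spacing, affine = NULL) {
  p <- position$values
  dims <- dim(p)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!any(p > 0.5) || !any(p < 0.5))
    stop("extract_midline_surface: position map has no 0.5 crossing",
         call. = FALSE)
  mt <- cpp_marching_tetrahedra(as.numeric(p), as.integer(dims), 0.5)
  verts <- mt$vertices
  faces <- mt$faces
  if (nrow(faces) == 0)
    stop("extract_midline_surface: empty level-set mesh", call. = FALSE)

  keep <- largest_surface_component(nrow(verts), faces)
  vmap <- integer(nrow(verts))
  vmap[keep] <- seq_along(keep)
  fkeep <- faces[rowSums(matrix(vmap[faces], ncol = 3) > 0) == 3, ,
                 drop = FALSE]
  faces <- matrix(vmap[fkeep], ncol = 3)
  verts <- verts[keep, , drop = FALSE]

  # normals from the position-map gradient (voxel space -> world)
  grad <- numeric_gradient_at(p, verts, spacing)
  world <- t(affine %*% rbind(t(verts), 1))[, 1:3, drop = FALSE]
  # map gradient direction through the affine rotation part (ignoring
  # scale differences; normalized afterwards)
  Rm <- affine[1:3, 1:3] %*% diag(1 / spacing)
  nrm <- grad %*% t(Rm)
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len

  structure(list(vertices = world, faces = faces, normals = nrm,
                 vertex_voxel = verts, spacing = spacing, affine = affine),
            class = "midline_surface")
}

#' @export
print.midline_surface <- function(x, ...) {
  cat("<midline_surface> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

# largest vertex-connected component of a triangle mesh (union-find)
largest_surface_component <- function(n_vertices, faces) {
  parent <- seq_len(n_vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(faces))) {
    a <- find(faces[r, 1]); b <- find(faces[r, 2]); c <- find(faces[r, 3])
    parent[b] <- a
    parent[c] <- a
  }
  roots <- vapply(seq_len(n_vertices), find, 0L)
  tab <- tabulate(roots)
  which(roots == which.max(tab))
}

# central-difference gradient of a volume, trilinearly sampled at 0-based
# voxel coordinates; returns n x 3 (per-axis, voxel units scaled to mm)
numeric_gradient_at <- function(vol, pts, spacing) {
  dims <- dim(vol)
  n <- nrow(pts)
  grad <- matrix(0, n, 3)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 0.5
    hi <- cpp_trilinear(as.numeric(vol), as.integer(dims),
                        sweep(pts, 2, e, `+`))
    lo <- cpp_trilinear(as.numeric(vol), as.integer(dims),
                        sweep(pts, 2, e, `-`))
    hi[is.na(hi)] <- 0.5
    lo[is.na(lo)] <- 0.5
    grad[, ax] <- (hi - lo) / spacing[ax]
  }
  grad
}

#' Sample intensity profiles along surface normals
#'
#' For each vertex, takes `n_samples` trilinear T1 samples at equidistant
#' offsets spanning `[-t/2, +t/2]` along the vertex normal, where `t` is
#' the local bone thickness (sampled from the thickness map at the nearest
#' skull voxel).
#'
#' @param surface a [extract_midline_surface()] result.
#' @param t1 T1 [volume_grid].
#' @param thickness a bone `thickness_map`.
#' @param n_samples odd integer >= 3 (default 7).
#' @return list: `profiles` (n_vertices x n_samples matrix), `offsets_mm`
#'   (n_vertices x n_samples), `thickness_mm` (per vertex), `valid`
#'   (per-vertex logical; invalid = any sample fell outside the volume),
#'   `qc_flags`.
#' @export
sample_normal_profiles <- function(surface, t1, thickness, n_samples = 7L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L || n_samples %% 2L == 0L)
    stop("sample_normal_profiles: n_samples must be odd and >= 3",
         call. = FALSE)
  dims <- dim(t1$data)
  sp <- t1$spacing
  # per-vertex thickness from the nearest skull voxel
  dn <- edt_distance(thickness$domain_mask, sp, return_nearest = TRUE)
  vox <- round(surface$vertex_voxel) + 1
  vox[, 1] <- pmin(pmax(vox[, 1], 1), dims[1])
  vox[, 2] <- pmin(pmax(vox[, 2], 1), dims[2])
  vox[, 3] <- pmin(pmax(vox[, 3], 1), dims[3])
  lin <- (vox[, 3] - 1) * dims[1] * dims[2] + (vox[, 2] - 1) * dims[1] +
    vox[, 1]
  tvert <- thickness$values[dn$nearest[lin]]
  tvert[!is.finite(tvert)] <- 0

  inv <- solve(t1$affine)
  frac <- seq(-0.5, 0.5, length.out = n_samples)
  nv <- nrow(surface$vertices)
  profiles <- matrix(NA_real_, nv, n_samples)
  offsets <- outer(tvert, frac)
  for (j in seq_len(n_samples)) {
    pts_world <- surface$vertices + surface$normals * offsets[, j]
    pts_vox <- t(inv %*% rbind(t(pts_world), 1))[, 1:3, drop = FALSE]
    profiles[, j] <- cpp_trilinear(as.numeric(t1$data), as.integer(dims),
                                   pts_vox)
  }
  valid <- rowSums(is.na(profiles)) == 0
  qc <- if (!all(valid)) "profiles_outside_volume" else character(0)
  list(profiles = profiles, offsets_mm = offsets, thickness_mm = tvert,
       valid = valid, qc_flags = qc)
}

#' Separate cortical and marrow intensity along a normal profile
#'
#' The cortical bone intensity is the local minimum of the profile; the
#' marrow intensity is the distance-weighted average with triangular
#' weights `w(o) = max(0, 1 - |o|/(t/2))` that peak on the midline and
#' vanish at the bone edges, so the dark cortical plates are annihilated
#' and the bright diploe dominates.
#'
#' @param profile numeric vector of intensity samples (NAs allowed).
#' @param offsets offsets (mm) of the samples along the normal, spanning
#'   `[-t/2, +t/2]`.
#' @return list `cortical_intensity`, `marrow_intensity` (both `NA` with a
#'   flag when fewer than 3 valid samples remain).
#' @export
cortical_marrow_split <- function(profile, offsets) {
  ok <- is.finite(profile)
  if (sum(ok) < 3L)
    return(list(cortical_intensity = NA_real_, marrow_intensity = NA_real_,
                flagged = TRUE))
  prof <- profile[ok]
  off <- offsets[ok]
  half <- max(abs(off))
  w <- if (half == 0) rep(1, length(off)) else pmax(0, 1 - abs(off) / half)
  if (sum(w) == 0) w <- rep(1, length(off))
  list(cortical_intensity = min(prof),
       marrow_intensity = sum(w * prof) / sum(w),
       flagged = FALSE)
}

# vectorized split over a profile matrix; returns per-vertex cortical and
# marrow intensities
split_profiles <- function(profiles, offsets) {
  nv <- nrow(profiles)
  cortical <- rep(NA_real_, nv)
  marrow <- rep(NA_real_, nv)
  half <- apply(abs(offsets), 1, max)
  w <- 1 - abs(offsets) / ifelse(half == 0, Inf, half)
  w[w < 0] <- 0
  w[half == 0, ] <- 1
  dim(w) <- dim(profiles)
  ok <- is.finite(profiles)
  w[!ok] <- 0
  profz <- profiles
  profz[!ok] <- 0
  nvalid <- rowSums(ok)
  cortical <- suppressWarnings(apply(ifelse(ok, profiles, Inf), 1, min))
  cortical[!is.finite(cortical)] <- NA_real_
  wsum <- rowSums(w)
  marrow <- ifelse(wsum > 0, rowSums(w * profz) / wsum, NA_real_)
  bad <- nvalid < 3
  cortical[bad] <- NA_real_
  marrow[bad] <- NA_real_
  list(cortical_intensity = cortical, marrow_intensity = marrow,
       flagged = bad)
}
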