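#' Euclidean distance from domain voxels to a target class
#'
#' Exact anisotropy-aware Euclidean distance transform: for every voxel of
#' the grid, the distance in mm from its center to the nearest target-class
#' voxel center. Values outside `mask_domain` are `NA`.
#'
#' @param mask_domain logical volume on which distances are requested.
#' @param mask_target logical volume of the target class (non-empty).
#' @param spacing voxel spacing in mm.
#' @return numeric volume of distances (mm), `NA` outside the domain.
#' @export
edt_to_class <- function(mask_domain, mask_target, spacing) {
  if (!any(mask_target))
    stop("edt_to_class: target class is empty", call. = FALSE)
  d <- edt_distance(mask_target, spacing)
  d[!mask_domain] <- NA_real_
  d
}

new_thickness_map <- function(values, excluded, domain) {
  structure(list(values = values, excluded_mask = excluded,
                 domain_mask = domain),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  inc <- x$domain_mask & !x$excluded_mask
  cat("<thickness_map> ", sum(x$domain_mask), " domain voxels, ",
      sum(x$excluded_mask), " excluded\n", sep = "")
  if (any(inc))
    cat("  mean included thickness ", round(mean(x$values[inc]), 2),
        " mm\n", sep = "")
  invisible(x)
}

#' Voxelwise skull bone thickness
#'
#' Bone thickness at each skull voxel is the sum of the shortest distances
#' to the CSF and to the soft head tissue, minus the mean voxel spacing.
#' The subtraction removes the center-to-center discretization bias: for an
#' axis-aligned slab of n voxels at spacing h the raw distance sum is
#' (n+1)h at every slab voxel, so the corrected value is exactly n*h.
#'
#' @param seg_corrected corrected [tissue_segmentation] (probability maps
#'   are argmax-hardened first).
#' @return a `thickness_map` over the skull class, values in mm; no
#'   exclusions are applied for bone.
#' @export
bone_thickness_map <- function(seg_corrected) {
  labels <- seg_labels(seg_corrected)
  sp <- seg_corrected$spacing
  skull <- labels == 4L
  csf <- labels == 3L
  head <- labels == 5L
  if (!any(skull) || !any(csf) || !any(head))
    stop("bone_thickness_map: skull, CSF and head classes must all be ",
         "non-empty", call. = FALSE)
  hbar <- mean(sp)
  d_csf <- edt_distance(csf, sp)
  d_head <- edt_distance(head, sp)
  values <- array(NA_real_, dim(labels))
  values[skull] <- pmax(d_csf[skull] + d_head[skull] - hbar, 0)
  new_thickness_map(values, array(FALSE, dim(labels)), skull)
}

#' Voxelwise soft head tissue thickness
#'
#' Head (scalp) thickness at each soft-head voxel is the sum of the
#' shortest distances to the skull and to the background, minus the mean
#' voxel spacing (same slab-exact correction as bone). Two exclusion rules
#' are applied: voxels more than `max_skull_distance_mm` (30 mm) from the
#' skull, and voxels inferior to the lowest axial slice of the reference
#' bone mask (defaulting to the skull class itself) — the lower portions of
#' head scans are unreliable due to defacing and field-of-view truncation.
#'
#' @param seg_corrected corrected [tissue_segmentation].
#' @param max_skull_distance_mm exclusion radius from the skull (default 30).
#' @param lower_cut_mask optional logical volume (e.g. an individual-space
#'   bone mask); voxels on axial slices below its lowest occupied slice are
#'   excluded. `NULL` uses the skull class.
#' @return a `thickness_map` over the head class with `excluded_mask` set.
#' @export
head_thickness_map <- function(seg_corrected, max_skull_distance_mm = 30,
                               lower_cut_mask = NULL) {
  labels <- seg_labels(seg_corrected)
  sp <- seg_corrected$spacing
  head <- labels == 5L
  skull <- labels == 4L
  bg <- labels == 6L
  if (!any(head) || !any(skull) || !any(bg))
    stop("head_thickness_map: head, skull and background classes must all ",
         "be non-empty", call. = FALSE)
  hbar <- mean(sp)
  d_skull <- edt_distance(skull, sp)
  d_bg <- edt_distance(bg, sp)
  values <- array(NA_real_, dim(labels))
  values[head] <- pmax(d_skull[head] + d_bg[head] - hbar, 0)

  excluded <- array(FALSE, dim(labels))
  excluded[head & d_skull > max_skull_distance_mm] <- TRUE
  ref <- if (is.null(lower_cut_mask)) skull else lower_cut_mask
  if (any(ref)) {
    z_floor <- min(which(apply(ref, 3, any)))
    if (z_floor > 1) excluded[, , seq_len(z_floor - 1)] <- TRUE
  }
  excluded <- excluded & head
  values[excluded] <- NA_real_
  new_thickness_map(values, excluded, head)
}
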