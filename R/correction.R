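#' Correct the skull segment of a tissue segmentation
#'
#' Unified segmentation frequently assigns the bright bone marrow of the
#' diploe to the soft head tissue class, which both biases the skull
#' intensity (the marrow signal is lost) and underestimates bone thickness.
#' This step repairs the skull class with morphological operations:
#'
#' 1. *Reclaim*: head-labelled voxels that fall inside the morphological
#'    closing of the skull mask (Euclidean ball, `close_radius_mm`) and do
#'    not belong to an outer head component (a 6-connected head component
#'    touching the background class) are relabelled skull. With the
#'    intensity guard active, a voxel is only reclaimed if its T1 intensity
#'    exceeds the 5th percentile of current skull-class intensities — the
#'    targeted misclassification is *bright* marrow.
#' 2. *Fill*: head/background cavities fully enclosed by skull (6-connected
#'    components not reaching the grid boundary whose entire outer contact
#'    is skull) are filled as skull.
#' 3. *Prune*: 26-connected skull islands smaller than `min_island_mm3`
#'    are relabelled to the majority 6-neighbor class.
#'
#' Brain classes (GM, WM, CSF) are never modified and every voxel keeps
#' exactly one label, so total voxel count is conserved. The operation is
#' idempotent on its own output.
#'
#' Probability segmentations are hardened by argmax before correction; the
#' result is always a label segmentation.
#'
#' @param seg a [tissue_segmentation].
#' @param t1 the co-registered T1 [volume_grid] (used by the intensity
#'   guard).
#' @param close_radius_mm closing radius in mm (default 3).
#' @param min_island_mm3 minimum skull component volume in mm^3 kept
#'   (default 100, i.e. 100 voxels at 1 mm isotropic).
#' @param intensity_guard require reclaimed voxels to be brighter than the
#'   cortical-bone intensity estimate (default `TRUE`).
#' @return list with `seg` (corrected label [tissue_segmentation]) and
#'   `report`: counts `n_reclaimed`, `n_filled`, `n_removed` and the
#'   logical `changed_mask`.
#' @export
correct_skull_segment <- function(seg, t1, close_radius_mm = 3,
                                  min_island_mm3 = 100,
                                  intensity_guard = TRUE) {
  stopifnot(inherits(seg, "tissue_segmentation"),
            inherits(t1, "volume_grid"))
  dims <- dim(seg$maps[[1]])
  if (!identical(dims, dim(t1$data)))
    stop("correct_skull_segment: T1 and segmentation grids differ",
         call. = FALSE)
  sp <- seg$spacing
  labels <- seg_labels(seg)
  if (!any(labels == 4L))
    stop("correct_skull_segment: skull class is empty; nothing to correct",
         call. = FALSE)
  labels0 <- labels

  skull <- labels == 4L
  head <- labels == 5L
  bg <- labels == 6L

  # (a) reclaim marrow mislabelled as head inside the skull closing
  closed <- morph_close(skull, close_radius_mm, sp)
  comp <- connected_components(head, connectivity = 6L)
  # outer head components (scalp): components whose voxels lie mostly
  # outside the skull closing. The component-level majority vote is robust
  # both to scalp patches that dip into the closing and to marrow patches
  # whose cut face is exposed at the truncated inferior scan boundary.
  n_comp <- length(comp$sizes)
  inner_head <- head
  if (n_comp > 0) {
    inside_counts <- tabulate(comp$labels[closed], nbins = n_comp)
    outer_ids <- which(inside_counts / comp$sizes <= 0.5)
    inner_head <- head & !(comp$labels %in% outer_ids)
  }
  candidates <- inner_head & closed
  if (intensity_guard && any(candidates)) {
    bone_floor <- stats::quantile(t1$data[skull], 0.05, names = FALSE)
    candidates <- candidates & (t1$data > bone_floor)
  }
  labels[candidates] <- 4L
  n_reclaimed <- sum(candidates)

  # (b) fill head/background cavities fully enclosed by skull
  skull <- labels == 4L
  cavity_space <- labels == 5L | labels == 6L
  comp <- connected_components(cavity_space, connectivity = 6L)
  filled <- array(FALSE, dims)
  if (max(comp$labels) > 0) {
    border <- array(FALSE, dims)
    border[c(1, dims[1]), , ] <- TRUE
    border[, c(1, dims[2]), ] <- TRUE
    border[, , c(1, dims[3])] <- TRUE
    touches_border <- unique(comp$labels[border & cavity_space])
    # components whose neighborhood contains any non-skull, non-self voxel
    # are not enclosed by skull
    near_nonskull <- adjacent_to(!cavity_space & !skull, dims)
    open_ids <- unique(c(touches_border, comp$labels[cavity_space & near_nonskull]))
    open_ids <- open_ids[open_ids > 0]
    enclosed <- cavity_space & !(comp$labels %in% open_ids)
    filled <- enclosed
    labels[filled] <- 4L
  }
  n_filled <- sum(filled)

  # (c) prune small skull islands
  skull <- labels == 4L
  vox_mm3 <- prod(sp)
  min_vox <- max(1, round(min_island_mm3 / vox_mm3))
  comp <- connected_components(skull, connectivity = 26L)
  small <- which(comp$sizes < min_vox)
  n_removed <- 0L
  if (length(small)) {
    remove_mask <- array(comp$labels %in% small, dims)
    n_removed <- sum(remove_mask)
    labels <- relabel_to_majority_neighbor(labels, remove_mask, dims)
  }

  changed <- labels != labels0
  seg_out <- labels_to_segmentation(labels, sp, seg$affine)
  seg_out$qc_flags <- seg$qc_flags
  list(seg = seg_out,
       report = list(n_reclaimed = n_reclaimed, n_filled = n_filled,
                     n_removed = n_removed, changed_mask = changed))
}

# voxels 6-adjacent to `mask` (including mask voxels themselves shifted out)
adjacent_to <- function(mask, dims) {
  out <- array(FALSE, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  out[-nx, , ] <- out[-nx, , ] | mask[-1, , ]
  out[-1, , ]  <- out[-1, , ]  | mask[-nx, , ]
  out[, -ny, ] <- out[, -ny, ] | mask[, -1, ]
  out[, -1, ]  <- out[, -1, ]  | mask[, -ny, ]
  out[, , -nz] <- out[, , -nz] | mask[, , -1]
  out[, , -1]  <- out[, , -1]  | mask[, , -nz]
  out
}

# relabel voxels in remove_mask to the majority 6-neighbor class outside the
# mask (head class if no outside neighbor exists)
relabel_to_majority_neighbor <- function(labels, remove_mask, dims) {
  idx <- which(remove_mask)
  if (!length(idx)) return(labels)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- c(1, -1, nx, -nx, nx * ny, -nx * ny)
  coords <- arrayInd(idx, dims)
  votes <- matrix(0L, length(idx), 6)
  for (k in seq_along(offs)) {
    nb <- idx + offs[k]
    ok <- switch(k,
      coords[, 1] < nx, coords[, 1] > 1,
      coords[, 2] < ny, coords[, 2] > 1,
      coords[, 3] < nz, coords[, 3] > 1)
    ok <- ok & !remove_mask[pmax(pmin(nb, length(labels)), 1)]
    nbl <- labels[pmax(pmin(nb, length(labels)), 1)]
    for (cl in 1:6) {
      votes[, cl] <- votes[, cl] + as.integer(ok & nbl == cl)
    }
  }
  votes[, 4] <- 0L # never vote the class being removed back in
  new_lab <- max.col(votes, ties.method = "first")
  no_votes <- rowSums(votes) == 0
  new_lab[no_votes] <- 5L
  labels[idx] <- as.integer(new_lab)
  labels
}
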