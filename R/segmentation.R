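#' Six-class tissue segmentation
#'
#' Bundles six co-registered tissue maps in the fixed order grey matter,
#' white matter, CSF, skull (hard head tissue), soft head tissue and
#' background — the class order produced by unified segmentation (c1..c6).
#' Maps are either probabilities in \[0,1\] or disjoint binary labels.
#'
#' @param maps list of six [volume_grid]s (or plain arrays sharing one grid)
#'   in the order GM, WM, CSF, skull, head, background.
#' @param kind `"probability"` or `"label"`.
#' @param spacing,affine grid geometry used when `maps` are plain arrays.
#' @return object of class `tissue_segmentation` with fields `maps` (list of
#'   six arrays), `spacing`, `affine`, `kind`, `qc_flags`.
#' @export
tissue_segmentation <- function(maps, kind = c("probability", "label"),
                                spacing = c(1, 1, 1), affine = NULL) {
  kind <- match.arg(kind)
  if (length(maps) != 6L)
    stop("tissue_segmentation: exactly six maps required (GM, WM, CSF, ",
         "skull, head, background)", call. = FALSE)
  if (inherits(maps[[1]], "volume_grid")) {
    ref <- maps[[1]]
    for (m in maps[-1]) {
      if (!same_grid(ref, m))
        stop("tissue_segmentation: maps are not on an identical grid",
             call. = FALSE)
    }
    spacing <- ref$spacing
    affine <- ref$affine
    maps <- lapply(maps, function(m) m$data)
  } else {
    if (is.null(affine)) affine <- diag(c(spacing, 1))
    shp <- dim(maps[[1]])
    for (m in maps[-1]) {
      if (!identical(dim(m), shp))
        stop("tissue_segmentation: maps are not on an identical grid",
             call. = FALSE)
    }
  }
  names(maps) <- tissue_class_names()
  seg <- structure(list(maps = maps, spacing = as.numeric(spacing),
                        affine = affine, kind = kind,
                        qc_flags = character(0)),
                   class = "tissue_segmentation")
  validate_segmentation(seg)
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat("<tissue_segmentation> ", x$kind, " kind, ",
      paste(dim(x$maps[[1]]), collapse = " x "), " voxels\n", sep = "")
  counts <- if (x$kind == "label") vapply(x$maps, sum, 0)
            else vapply(x$maps, function(m) sum(m > 0.5), 0)
  cat("  voxels/class:", paste(names(x$maps), round(counts), sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

tissue_class_names <- function() {
  c("gm", "wm", "csf", "skull", "head", "background")
}

validate_segmentation <- function(seg, sum_tol = 0.05, frac_tol = 0.01) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  if (seg$kind == "probability") {
    clipped <- FALSE
    for (i in seq_along(seg$maps)) {
      m <- seg$maps[[i]]
      if (any(m < 0) || any(m > 1)) {
        seg$maps[[i]] <- pmin(pmax(m, 0), 1)
        clipped <- TRUE
      }
    }
    if (clipped)
      seg$qc_flags <- union(seg$qc_flags, "probabilities_clipped")
    s <- Reduce(`+`, seg$maps)
    bad <- mean(abs(s - 1) > sum_tol)
    if (bad > frac_tol)
      stop(sprintf(paste0("tissue_segmentation: probability maps sum outside ",
                          "1 +/- %.2f on %.1f%% of voxels"),
                   sum_tol, 100 * bad), call. = FALSE)
  } else {
    s <- Reduce(`+`, lapply(seg$maps, function(m) m != 0))
    if (any(s != 1))
      stop("tissue_segmentation: label maps must be disjoint binary masks ",
           "covering the grid", call. = FALSE)
  }
  seg
}

#' Load a six-map segmentation from NIfTI files
#'
#' @param paths character vector of six NIfTI paths in c1..c6 order
#'   (GM, WM, CSF, skull, head, background).
#' @param kind `"probability"` or `"label"`.
#' @return a [tissue_segmentation]; probability maps outside \[0,1\] are
#'   clipped with a `probabilities_clipped` QC flag.
#' @export
load_segmentation <- function(paths, kind = c("probability", "label")) {
  kind <- match.arg(kind)
  if (length(paths) != 6L)
    stop("load_segmentation: six paths required", call. = FALSE)
  vols <- lapply(paths, load_volume)
  tissue_segmentation(vols, kind = kind)
}

#' Convert a segmentation to hard labels
#'
#' Probability maps are hardened by voxelwise argmax with ties broken by the
#' fixed class order GM > WM > CSF > skull > head > background (the argmax
#' picks the first of the tied classes in that order).
#'
#' @param seg a [tissue_segmentation].
#' @return integer 3-D array of class codes 1..6 in the order GM, WM, CSF,
#'   skull, head, background.
#' @export
seg_labels <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  dims <- dim(seg$maps[[1]])
  if (seg$kind == "label") {
    lab <- array(0L, dims)
    for (i in 6:1) lab[seg$maps[[i]] != 0] <- i
    return(lab)
  }
  best <- seg$maps[[1]]
  lab <- array(1L, dims)
  for (i in 2:6) {
    better <- seg$maps[[i]] > best
    lab[better] <- i
    best[better] <- seg$maps[[i]][better]
  }
  lab
}

# label array (1..6) -> label-kind tissue_segmentation
labels_to_segmentation <- function(labels, spacing, affine = NULL) {
  maps <- lapply(1:6, function(i) array(as.numeric(labels == i), dim(labels)))
  tissue_segmentation(maps, kind = "label", spacing = spacing,
                      affine = affine)
}
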