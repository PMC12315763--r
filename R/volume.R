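#' Construct a 3-D volume grid
#'
#' A `volume_grid` is the carrier of the T1 image and every derived map:
#' a 3-D scalar array together with its voxel spacing (mm) and a 4x4
#' voxel-to-world affine (mm, RAS convention, 0-based voxel indices).
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3, mm per voxel along each axis. Ignored if
#'   `affine` is given (spacing is then derived from the affine columns).
#' @param affine numeric 4x4 voxel-to-world transform. Defaults to a diagonal
#'   affine built from `spacing` with the origin at voxel (0,0,0).
#' @return object of class `volume_grid` with fields `data`, `spacing`,
#'   `affine`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3-D array", call. = FALSE)
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("volume_grid: spacing must be three strictly positive numbers",
           call. = FALSE)
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("volume_grid: affine must be 4x4", call. = FALSE)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  v <- structure(list(data = data, spacing = spacing, affine = affine),
                 class = "volume_grid")
  validate_volume_grid(v)
  v
}

validate_volume_grid <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  if (any(v$spacing <= 0))
    stop("volume_grid: spacing components must be strictly positive",
         call. = FALSE)
  d <- det(v$affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("volume_grid: affine is not invertible", call. = FALSE)
  colnorm <- sqrt(colSums(v$affine[1:3, 1:3]^2))
  if (any(abs(colnorm - v$spacing) / v$spacing > 1e-6))
    stop("volume_grid: spacing does not match affine column norms",
         call. = FALSE)
  invisible(v)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  rng <- range(x$data, finite = TRUE)
  cat("  intensity range [", signif(rng[1], 5), ", ", signif(rng[2], 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

# voxel (0-based index triplets, n x 3) -> world mm
voxel_to_world <- function(v, idx) {
  idx <- rbind(t(as.matrix(idx)), 1)
  t((v$affine %*% idx)[1:3, , drop = FALSE])
}

# world mm (n x 3) -> 0-based voxel coordinates (continuous)
world_to_voxel <- function(v, xyz) {
  xyz <- rbind(t(as.matrix(xyz)), 1)
  t((solve(v$affine) %*% xyz)[1:3, , drop = FALSE])
}

# array of world coordinates of every voxel center along one axis; used by
# the phantom and atlas geometry code. Returns list(x, y, z) of 3-D arrays.
voxel_center_grids <- function(dims, spacing, affine = NULL) {
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  i <- seq_len(dims[1]) - 1
  j <- seq_len(dims[2]) - 1
  k <- seq_len(dims[3]) - 1
  # affine assumed axis-aligned for geometry synthesis
  list(
    x = array(rep(affine[1, 1] * i + affine[1, 4], times = dims[2] * dims[3]),
              dim = dims),
    y = array(rep(rep(affine[2, 2] * j + affine[2, 4], each = dims[1]),
                  times = dims[3]), dim = dims),
    z = array(rep(affine[3, 3] * k + affine[3, 4], each = dims[1] * dims[2]),
              dim = dims)
  )
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}
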