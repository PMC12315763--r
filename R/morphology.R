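# Binary morphology built on the exact Euclidean distance transform:
# dilation/erosion by a Euclidean ball of radius r mm are thresholded
# distance maps, which keeps every operator resolution-independent.

edt_distance <- function(mask, spacing, return_nearest = FALSE) {
  dims <- dim(mask)
  res <- cpp_edt(as.logical(mask), as.integer(dims), as.numeric(spacing))
  d <- array(res$dist, dims)
  if (!return_nearest) return(d)
  list(dist = d, nearest = array(res$nearest, dims))
}

morph_dilate <- function(mask, radius_mm, spacing) {
  if (!any(mask)) return(mask)
  edt_distance(mask, spacing) <= radius_mm + 1e-9
}

morph_erode <- function(mask, radius_mm, spacing) {
  if (all(mask)) return(mask)
  if (!any(mask)) return(mask)
  edt_distance(!mask, spacing) > radius_mm + 1e-9
}

morph_close <- function(mask, radius_mm, spacing) {
  morph_erode(morph_dilate(mask, radius_mm, spacing), radius_mm, spacing)
}

morph_open <- function(mask, radius_mm, spacing) {
  morph_dilate(morph_erode(mask, radius_mm, spacing), radius_mm, spacing)
}

connected_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  res <- cpp_label_components(as.logical(mask), as.integer(dims),
                              as.integer(connectivity))
  list(labels = array(res$labels, dims), sizes = res$sizes)
}

# separable Gaussian smoothing, sigma in mm (per axis after division by
# spacing); kernel truncated at 3 sigma
gaussian_smooth <- function(vol, sigma_mm, spacing) {
  dims <- dim(vol)
  out <- as.numeric(vol)
  for (ax in 0:2) {
    sig_vox <- sigma_mm / spacing[ax + 1]
    if (sig_vox < 1e-8) next
    half <- max(1L, ceiling(3 * sig_vox))
    k <- exp(-0.5 * ((-half:half) / sig_vox)^2)
    k <- k / sum(k)
    out <- cpp_convolve_axis(out, as.integer(dims), k, ax)
  }
  array(out, dims)
}
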