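# Shared fixtures, memoized across test files (helpers are sourced once per
# run). All fixtures are generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small closed noise-free phantom: fast, exact geometry
small_spec <- function(...) {
  do.call(phantom_spec, utils::modifyList(
    list(shape = c(72, 72, 72), brain_radii = c(18, 20, 16), scalp_mm = 5,
         noise_sd = 0, open_inferior = FALSE),
    list(...)))
}

small_phantom <- function() fixture("small_phantom",
                                    generate_phantom(small_spec()))

# realistic open phantom with noise, used by correction/measures tests
noisy_spec <- function(...) {
  phantom_spec(shape = c(96, 96, 96), brain_radii = c(26, 30, 24),
               noise_sd = 20, ...)
}

noisy_phantom <- function() fixture("noisy_phantom",
                                    generate_phantom(noisy_spec()))

# axis-aligned slab segmentation: along `axis`, layers
# [gm 1][wm 1][csf n_csf][skull n][head n_head][background rest]
# with full cross-sections, so distances are exactly axial.
slab_segmentation <- function(n, h, axis = 3L, n_csf = 3L, n_head = 6L,
                              n_cross = 10L) {
  n_axis <- 2L + n_csf + n + n_head + 3L
  dims <- rep(n_cross, 3L)
  dims[axis] <- n_axis
  idx_axis <- slice.index(array(0, dims), axis)
  labels <- array(6L, dims)
  labels[idx_axis == 1L] <- 1L
  labels[idx_axis == 2L] <- 2L
  labels[idx_axis > 2L & idx_axis <= 2L + n_csf] <- 3L
  sk <- idx_axis > 2L + n_csf & idx_axis <= 2L + n_csf + n
  labels[sk] <- 4L
  hd <- idx_axis > 2L + n_csf + n & idx_axis <= 2L + n_csf + n + n_head
  labels[hd] <- 5L
  calvaria:::labels_to_segmentation(labels, rep(h, 3))
}

# brute-force nearest-neighbor distance oracle (mm), independent of the
# package's distance transform
brute_force_edt <- function(target, spacing, chunk = 2048L) {
  dims <- dim(target)
  ti <- which(target, arr.ind = TRUE)
  co <- which(array(TRUE, dims), arr.ind = TRUE)
  n <- nrow(co)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- 0
    for (ax in 1:3) {
      d2 <- d2 + outer(co[s:e, ax], ti[, ax], function(a, b)
        (spacing[ax] * (a - b))^2)
    }
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  array(out, dims)
}

# explicit two-way ANOVA mean squares by double loop (ICC oracle)
anova_mean_squares_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

icc_a1_oracle <- function(x) {
  ms <- anova_mean_squares_oracle(x)
  n <- nrow(x); k <- ncol(x)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# Holm step-down oracle: explicit ordering + running-max arithmetic
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin((m - seq_len(m) + 1) * p[o], 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

euler_characteristic <- function(surface) {
  V <- nrow(surface$vertices)
  Fc <- nrow(surface$faces)
  e <- rbind(surface$faces[, 1:2], surface$faces[, 2:3],
             surface$faces[, c(1, 3)])
  E <- nrow(unique(t(apply(e, 1, sort))))
  V - E + Fc
}
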