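test_that("noise-free phantom is piecewise constant at the tissue means", {
  ph <- small_phantom()
  tm <- small_spec()$tissue_means
  lab <- ph$truth$labels
  tis <- ph$truth$tissue
  expect_true(all(ph$t1$data[lab == 2L] == tm[["wm"]]))
  expect_true(all(ph$t1$data[lab == 3L] == tm[["csf"]]))
  expect_true(all(ph$t1$data[tis == 5L] == small_spec()$diploe_intensity))
  expect_true(all(ph$t1$data[tis %in% c(4L, 6L)] == tm[["cortical_bone"]]))
  scalp_vals <- unique(ph$t1$data[lab == 5L])
  expect_setequal(scalp_vals, c(tm[["muscle"]], tm[["fat"]]))
})

test_that("phantoms are deterministic given the seed", {
  spec <- phantom_spec(shape = c(48, 48, 48), brain_radii = c(12, 13, 11),
                       scalp_mm = 3, csf_gap_mm = 1.5, inner_table_mm = 1.5,
                       diploe_mm = 2, outer_table_mm = 1.5, noise_sd = 15,
                       seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$seg$maps, b$seg$maps)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("truth records the summed skull layer thickness", {
  expect_equal(small_phantom()$truth$skull_thickness_mm, 2 + 3 + 2)
  sp <- phantom_spec(inner_table_mm = 1.5, diploe_mm = 2.5,
                     outer_table_mm = 1)
  expect_equal(generate_phantom(
    phantom_spec(shape = c(48, 48, 48), brain_radii = c(11, 12, 10),
                 scalp_mm = 3, inner_table_mm = 1.5, diploe_mm = 2.5,
                 outer_table_mm = 1, noise_sd = 0)
  )$truth$skull_thickness_mm, 5)
})

test_that("layers that do not fit the grid raise a geometry error", {
  expect_error(phantom_spec(shape = c(48, 48, 48),
                            brain_radii = c(30, 30, 30)),
               "exceed the grid")
  expect_error(phantom_spec(fat_fraction = 1.3), "fat_fraction")
  expect_error(phantom_spec(diploe_intensity = 100), "diploe")
})

test_that("diploe voxels touch only skull-layer voxels (nesting)", {
  ph <- small_phantom()
  tis <- ph$truth$tissue
  dip <- tis == 5L
  dims <- dim(tis)
  ok <- TRUE
  sh <- function(a, d, ax) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dims[ax]
    idx[[ax]] <- if (d > 0) c(2:n, n) else c(1, 1:(n - 1))
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) for (d in c(-1, 1)) {
    nb <- sh(tis, d, ax)
    ok <- ok && all(nb[dip] %in% c(4L, 5L, 6L))
  }
  expect_true(ok)
})

test_that("mean scalp intensity increases with fat fraction", {
  base <- phantom_spec(shape = c(56, 56, 56), brain_radii = c(13, 14, 12),
                       scalp_mm = 4, noise_sd = 0)
  means <- vapply(c(0.1, 0.3, 0.5, 0.7), function(ff) {
    s <- base; s$fat_fraction <- ff
    ph <- generate_phantom(s)
    mean(ph$t1$data[ph$truth$labels == 5L])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("probability phantoms validate and harden back to the truth", {
  ph <- generate_phantom(small_spec(), kind = "probability")
  expect_identical(ph$seg$kind, "probability")
  lab <- seg_labels(ph$seg)
  agree <- mean(lab == ph$truth$labels)
  expect_gt(agree, 0.95)  # smoothing only blurs thin boundaries
})

test_that("planted marrow misclassification has the requested size", {
  ph <- small_phantom()
  n_dip <- sum(ph$truth$tissue == 5L)

  pl0 <- plant_marrow_misclassification(ph$seg, ph$truth, 0, seed = 3)
  expect_identical(pl0$seg$maps, ph$seg$maps)
  expect_equal(sum(pl0$planted_mask), 0)

  pl1 <- plant_marrow_misclassification(ph$seg, ph$truth, 1, seed = 3)
  expect_equal(sum(pl1$planted_mask), n_dip)
  expect_true(all(seg_labels(pl1$seg)[pl1$planted_mask] == 5L))

  pl <- plant_marrow_misclassification(ph$seg, ph$truth, 0.3, seed = 3)
  expect_lt(abs(sum(pl$planted_mask) - 0.3 * n_dip), 0.02 * 0.3 * n_dip + 1)
  pl_b <- plant_marrow_misclassification(ph$seg, ph$truth, 0.3, seed = 3)
  expect_identical(pl$planted_mask, pl_b$planted_mask)

  expect_error(plant_marrow_misclassification(ph$seg, ph$truth, 1.2),
               "fraction")
})

test_that("retest pairs share anatomy and have independent noise", {
  spec <- phantom_spec(shape = c(64, 64, 64), brain_radii = c(15, 16, 14),
                       scalp_mm = 4, noise_sd = 0)
  pair <- make_retest_pair(spec, seeds = c(101, 202))
  expect_identical(pair[[1]]$t1$data, pair[[2]]$t1$data)
  expect_identical(pair[[1]]$truth$labels, pair[[2]]$truth$labels)

  spec$noise_sd <- 10
  pair <- make_retest_pair(spec, seeds = c(101, 202))
  dd <- pair[[1]]$t1$data - pair[[2]]$t1$data
  expect_gt(length(dd), 1e5)
  expect_lt(abs(mean(dd)), 0.15)
  expect_lt(abs(sd(dd) - sqrt(2) * 10), 0.2)
  expect_identical(pair[[1]]$truth$labels, pair[[2]]$truth$labels)

  expect_error(make_retest_pair(spec, seeds = c(5, 5)), "distinct")
})
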