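test_that("wm_reference recovers the planted WM intensity", {
  ph <- small_phantom()
  expect_equal(wm_reference(ph$t1, ph$seg)$wm_intensity, 400)

  phn <- generate_phantom(small_spec(noise_sd = 10))
  expect_lt(abs(wm_reference(phn$t1, phn$seg)$wm_intensity - 400), 1)

  lab <- seg_labels(ph$seg)
  lab[lab == 2L] <- 1L
  seg <- calvaria:::labels_to_segmentation(lab, ph$seg$spacing)
  expect_error(wm_reference(ph$t1, seg), "WM voxels")
})

test_that("bone intensity is WM-normalized and scale invariant", {
  ph <- small_phantom()
  atlas <- build_template_atlas(ph$seg)
  wm <- wm_reference(ph$t1, ph$seg)

  # skull intensities equal to the reference give exactly 1
  t1c <- ph$t1
  t1c$data[seg_labels(ph$seg) == 4L] <- wm$wm_intensity
  tab <- bone_intensity(t1c, ph$seg, atlas, wm)
  expect_equal(tab$mean_intensity[tab$region == "global"], 1)

  tab1 <- bone_intensity(ph$t1, ph$seg, atlas, wm)
  t1s <- ph$t1; t1s$data <- t1s$data * 3.7
  wms <- wm_reference(t1s, ph$seg)
  tab2 <- bone_intensity(t1s, ph$seg, atlas, wms)
  expect_equal(tab2$mean_intensity, tab1$mean_intensity, tolerance = 1e-12)
})

test_that("proxy BMD is the negated occipital intensity, monotone in marrow", {
  expect_equal(proxy_bmd(0.8), -0.8)
  expect_true(is.na(proxy_bmd(NA_real_)))

  vals <- vapply(c(550, 500, 450, 400, 350), function(di) {
    ph <- generate_phantom(small_spec(diploe_intensity = di))
    atlas <- build_template_atlas(ph$seg)
    wm <- wm_reference(ph$t1, ph$seg)
    tab <- bone_intensity(ph$t1, ph$seg, atlas, wm)
    proxy_bmd(tab$mean_intensity[tab$region == "occipital"])
  }, 0)
  expect_true(all(diff(vals) > 0))  # decreasing marrow -> increasing proxy
})

test_that("the head GMM recovers planted mixtures", {
  dims <- c(40, 40, 40)
  n <- prod(dims)
  lab <- array(5L, dims)
  lab[1, 1, 1:6] <- 1:6  # token voxels so all classes exist
  seg <- calvaria:::labels_to_segmentation(lab, c(1, 1, 1))

  set.seed(31)
  x <- rnorm(n, 300, 25)
  t1 <- volume_grid(array(x, dims))
  fit1 <- fit_head_gmm(t1, seg, K = 1L, seed = 2)
  expect_lt(abs(fit1$means - 300) / 300, 0.01)

  x2 <- ifelse(runif(n) < 0.3, rnorm(n, 100, 20), rnorm(n, 500, 40))
  t12 <- volume_grid(array(x2, dims))
  fit2 <- fit_head_gmm(t12, seg, K = 2L, seed = 2)
  expect_lt(abs(fit2$weights[1] - 0.3), 0.02)
  expect_lt(abs(fit2$weights[2] - 0.7), 0.02)
  expect_lt(abs(fit2$means[1] - 100), 5)
  expect_lt(abs(fit2$means[2] - 500), 5)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)

  fit2b <- fit_head_gmm(t12, seg, K = 2L, seed = 2)
  expect_identical(fit2, fit2b)

  # far more components than structure: collapse path refits with K-1
  xs <- rnorm(n, 300, 1e-3)
  fits <- fit_head_gmm(volume_grid(array(xs, dims)), seg, K = 4L, seed = 2)
  expect_true(fits$K < 4L || all(fits$weights >= 1e-4))
})

test_that("IAP is the weighted Gaussian-peak composite over WM", {
  wm <- list(wm_intensity = 400)
  fit <- list(K = 1L, means = 300, sds = 10, weights = 1)
  expect_equal(iap(fit, wm), 0.75)
  fit2 <- list(K = 2L, means = c(200, 600), sds = c(10, 10),
               weights = c(0.25, 0.75))
  expect_equal(iap(fit2, wm), 1.25)
})

test_that("TAP recovers planted scalp thickness in the occipital sector", {
  ph <- small_phantom()
  atlas <- build_template_atlas(ph$seg)
  ht <- head_thickness_map(ph$seg)
  res <- tap(ht, ph$seg, atlas)
  expect_false(res$flagged)
  expect_lt(abs(res$tap_mm - 5), 0.5)

  # occipital scalp thickened by 4 mm: TAP exceeds the frontal mean by ~4
  lab <- seg_labels(ph$seg)
  d <- calvaria:::edt_distance(lab == 5L | lab == 4L, ph$seg$spacing)
  grow <- lab == 6L & d <= 4 & atlas$labels == 4L
  lab2 <- lab; lab2[grow] <- 5L
  seg2 <- calvaria:::labels_to_segmentation(lab2, ph$seg$spacing)
  ht2 <- head_thickness_map(seg2)
  occ <- tap(ht2, seg2, atlas)$tap_mm
  fro <- tap(ht2, seg2, atlas,
             region = calvaria:::ATLAS_REGIONS[["frontal"]])$tap_mm
  expect_lt(abs((occ - fro) - 4), 1)

  # all scalp voxels far from the skull: flagged missing
  res0 <- tap(new_env <- local({
    x <- ht
    x$excluded_mask <- x$domain_mask
    x
  }), ph$seg, atlas)
  expect_true(res0$flagged)
  expect_true(is.na(res0$tap_mm))
})

test_that("compute_all is finite, deterministic and retest stable", {
  ph <- small_phantom()
  hm1 <- compute_all(ph$t1, ph$seg, seed = 4)
  expect_true(all(is.finite(c(hm1$proxy_bmd, hm1$bone_thickness_mm,
                              hm1$iap, hm1$tap_mm))))
  hm2 <- compute_all(ph$t1, ph$seg, seed = 4)
  s1 <- attr(hm1, "surface"); s2 <- attr(hm2, "surface")
  attr(hm1, "surface") <- NULL; attr(hm2, "surface") <- NULL
  expect_identical(hm1, hm2)
  expect_identical(s1$marrow_intensity, s2$marrow_intensity)

  pair <- make_retest_pair(small_spec(noise_sd = 15), seeds = c(31, 32))
  a <- compute_all(pair[[1]]$t1, pair[[1]]$seg, with_surface = FALSE)
  b <- compute_all(pair[[2]]$t1, pair[[2]]$seg, with_surface = FALSE)
  expect_lt(abs(a$bone_thickness_mm - b$bone_thickness_mm), 0.5)
})

test_that("marrow minus cortical intensity tracks diploe brightness", {
  seps <- vapply(c(250, 300, 350, 400, 450), function(di) {
    ph <- generate_phantom(small_spec(diploe_intensity = di))
    hm <- compute_all(ph$t1, ph$seg)
    s <- attr(hm, "surface")
    mean(s$marrow_intensity, na.rm = TRUE) -
      mean(s$cortical_intensity, na.rm = TRUE)
  }, 0)
  expect_equal(cor(seps, 1:5, method = "spearman"), 1)
})
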