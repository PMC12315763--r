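sphere_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 64), brain_radii = c(17, 17, 17),
               scalp_mm = 4, noise_sd = 0, open_inferior = FALSE, ...)
}
sphere_phantom <- function() fixture("sphere_phantom",
                                     generate_phantom(sphere_spec()))

test_that("position map matches the analytic slab fractions", {
  seg <- slab_segmentation(5, 1.0)  # skull slices 6..10 (1-based)
  pos <- percentage_position_map(seg)
  p <- pos$values
  for (i in 1:5)
    expect_equal(unique(p[, , 5 + i][pos$skull_mask[, , 5 + i]]), i / 6,
                 tolerance = 1e-12)
  expect_true(all(p[pos$skull_mask] > 0 & p[pos$skull_mask] < 1))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("midline surface bisects a slab to sub-voxel accuracy", {
  seg <- slab_segmentation(5, 1.0)
  pos <- percentage_position_map(seg)
  surf <- extract_midline_surface(pos, seg$spacing)
  # analytic midplane: skull occupies 0-based slices 5..9 -> midplane z = 7
  expect_true(all(abs(surf$vertex_voxel[, 3] - 7) <= 0.5))
})

test_that("midline surface of a spherical shell sits at the mid radius", {
  ph <- sphere_phantom()
  pos <- percentage_position_map(ph$seg)
  surf <- extract_midline_surface(pos, ph$seg$spacing)
  r <- sqrt(rowSums(sweep(surf$vertices, 2, ph$truth$center)^2))
  expect_lt(abs(mean(r) - (17 + 2 + 3.5)), 0.6)
  expect_equal(euler_characteristic(surf), 2)
  expect_equal(sqrt(rowSums(surf$normals^2)), rep(1, nrow(surf$normals)),
               tolerance = 1e-6)
  # outward orientation: normals point away from the center
  dirs <- sweep(surf$vertices, 2, ph$truth$center)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_gt(mean(rowSums(dirs * surf$normals) > 0), 0.99)
})

test_that("a position map without a 0.5 crossing is rejected", {
  pos <- list(values = array(0.9, c(8, 8, 8)),
              skull_mask = array(TRUE, c(8, 8, 8)))
  expect_error(extract_midline_surface(pos, c(1, 1, 1)), "crossing")
})

test_that("normal profiles see bright marrow between dark tables", {
  ph <- sphere_phantom()
  pos <- percentage_position_map(ph$seg)
  surf <- extract_midline_surface(pos, ph$seg$spacing)
  bt <- bone_thickness_map(ph$seg)
  prof <- sample_normal_profiles(surf, ph$t1, bt, n_samples = 7L)
  expect_true(all(prof$valid))
  mid <- prof$profiles[, 4]
  ends <- pmax(prof$profiles[, 1], prof$profiles[, 7])
  expect_gt(mean(mid > ends), 0.95)

  # constant volume -> constant profiles
  flat <- volume_grid(array(42, dim(ph$t1$data)), ph$t1$spacing)
  proff <- sample_normal_profiles(surf, flat, bt, n_samples = 5L)
  expect_true(all(abs(proff$profiles - 42) < 1e-9))

  expect_error(sample_normal_profiles(surf, ph$t1, bt, n_samples = 1L),
               "odd")
  expect_error(sample_normal_profiles(surf, ph$t1, bt, n_samples = 4L),
               "odd")
})

test_that("cortical/marrow split uses min and triangular weights", {
  s <- cortical_marrow_split(c(150, 450, 150), c(-2, 0, 2))
  expect_equal(s$cortical_intensity, 150)
  expect_equal(s$marrow_intensity, 450)

  s <- cortical_marrow_split(rep(7.5, 5), seq(-2, 2, 1))
  expect_equal(s$cortical_intensity, 7.5)
  expect_equal(s$marrow_intensity, 7.5)

  s <- cortical_marrow_split(c(100, 300, 500, 300, 100), seq(-2, 2, 1))
  expect_equal(s$cortical_intensity, 100)
  expect_equal(s$marrow_intensity, 400)  # weights (0,.5,1,.5,0)

  s <- cortical_marrow_split(c(1, NA, 2), c(-1, 0, 1))
  expect_true(s$flagged)
  expect_true(is.na(s$marrow_intensity))

  # vectorized path agrees with the scalar splitter
  set.seed(3)
  profs <- matrix(runif(40, 100, 600), 8, 5)
  offs <- matrix(rep(seq(-2, 2, 1), each = 8), 8, 5)
  vec <- calvaria:::split_profiles(profs, offs)
  for (i in 1:8) {
    sc <- cortical_marrow_split(profs[i, ], offs[i, ])
    expect_equal(vec$cortical_intensity[i], sc$cortical_intensity)
    expect_equal(vec$marrow_intensity[i], sc$marrow_intensity)
  }
})

test_that("surface-mean thickness agrees with voxel-mean bone thickness", {
  ph <- sphere_phantom()
  pos <- percentage_position_map(ph$seg)
  surf <- extract_midline_surface(pos, ph$seg$spacing)
  bt <- bone_thickness_map(ph$seg)
  prof <- sample_normal_profiles(surf, ph$t1, bt)
  vox_mean <- mean(bt$values[bt$domain_mask])
  expect_lt(abs(mean(prof$thickness_mm) - vox_mean) / vox_mean, 0.10)
})
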