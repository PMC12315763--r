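test_that("the sector atlas partitions the shell with the posterior pole occipital", {
  ph <- small_phantom()
  atlas <- build_template_atlas(ph$seg)
  skull <- seg_labels(ph$seg) == 4L
  expect_true(all(atlas$labels[skull] %in% 1:7))

  # posterior pole: y minimal, z mid
  sk_idx <- which(skull, arr.ind = TRUE)
  post <- sk_idx[which.min(sk_idx[, 2]), , drop = FALSE]
  expect_equal(atlas$labels[post], calvaria:::ATLAS_REGIONS[["occipital"]])

  # bone mask excludes temporal/sphenoid and lives on the shell
  expect_false(any(atlas$bone_mask & (atlas$labels %in% 5:7)))
  expect_true(all(skull[atlas$bone_mask]))
})

test_that("atlas mapping honors identity, translation and rotation", {
  ph <- small_phantom()
  atlas <- build_template_atlas(ph$seg)
  dims <- dim(atlas$labels)

  ident <- map_atlas_to_individual(atlas, diag(4), dims, atlas$spacing)
  expect_identical(ident$labels, atlas$labels)

  tr <- diag(4); tr[1, 4] <- atlas$spacing[1]  # one voxel along +x
  shifted <- map_atlas_to_individual(atlas, tr, dims, atlas$spacing)
  expect_identical(shifted$labels[2:dims[1], , ],
                   atlas$labels[1:(dims[1] - 1), , ])

  rot <- diag(4)
  cen <- c(atlas$center, 1)
  R <- calvaria:::rotation_matrix(c(0, 0, 10))
  rot[1:3, 1:3] <- R
  rot[1:3, 4] <- cen[1:3] - R %*% cen[1:3]
  rotated <- map_atlas_to_individual(atlas, rot, dims, atlas$spacing)
  skull <- seg_labels(ph$seg) == 4L
  h0 <- tabulate(atlas$labels[skull], 7)
  h1 <- tabulate(rotated$labels[skull], 7)
  expect_true(all(abs(h1 - h0) / h0 < 0.05))

  expect_error(map_atlas_to_individual(atlas, matrix(0, 4, 4), dims,
                                       atlas$spacing), "invertible")
})

test_that("regional aggregation is exact for constants and decomposes", {
  ph <- small_phantom()
  atlas <- build_template_atlas(ph$seg)
  skull <- seg_labels(ph$seg) == 4L

  const <- array(3.25, dim(skull))
  tab <- regional_aggregate(const, atlas, skull)
  expect_true(all(abs(tab$mean_value[tab$n_voxels > 0] - 3.25) < 1e-12))

  vals <- array(rnorm(length(skull)), dim(skull))
  tab <- regional_aggregate(vals, atlas, skull)
  reg <- tab[tab$region != "global" & tab$in_mask & tab$n_voxels > 0, ]
  glob <- tab[tab$region == "global", ]
  expect_equal(sum(reg$mean_value * reg$n_voxels) / sum(reg$n_voxels),
               glob$mean_value, tolerance = 1e-9)
  expect_equal(sum(reg$n_voxels), glob$n_voxels)

  # empty regions are reported, not errors
  tiny <- array(FALSE, dim(skull))
  tab0 <- regional_aggregate(const, atlas, tiny)
  expect_true(all(tab0$n_voxels == 0))
  expect_true(all(is.na(tab0$mean_value)))
})

test_that("a planted occipital thickness difference is recovered", {
  ph <- fixture("boosted_phantom", {
    # sphere: regional baselines are equal by symmetry
    spec <- small_spec(brain_radii = c(17, 17, 17))
    p <- generate_phantom(spec)
    # extend the skull outward by 2 mm over a posterior wedge that
    # strictly contains the occipital sector, so the sector mean is not
    # diluted by edge effects at the wedge boundary
    atl <- build_template_atlas(p$seg)
    lab <- seg_labels(p$seg)
    g <- calvaria:::voxel_center_grids(dim(lab), spec$spacing)
    azim <- abs(atan2(g$x - atl$center[1], g$y - atl$center[2]) * 180 / pi)
    d <- calvaria:::edt_distance(lab == 4L, spec$spacing)
    grow <- lab == 5L & d <= 2 & azim >= 120
    lab[grow] <- 4L
    list(seg = calvaria:::labels_to_segmentation(lab, spec$spacing),
         atlas = atl)
  })
  bt <- bone_thickness_map(ph$seg)
  tab <- regional_aggregate(bt, ph$atlas, seg_labels(ph$seg) == 4L)
  occ <- tab$mean_value[tab$region == "occipital"]
  fro <- tab$mean_value[tab$region == "frontal"]
  expect_lt(abs((occ - fro) - 2), 0.5)
})
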