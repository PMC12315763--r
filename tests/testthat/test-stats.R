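test_that("ICC(A,1) matches the explicit ANOVA oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, mean = 10, sd = 2), n, k) +
      rnorm(n)  # subject effects
    res <- icc_absolute_agreement(x)
    expect_equal(res$icc, icc_a1_oracle(x), tolerance = 1e-10)
    ms <- anova_mean_squares_oracle(x)
    expect_equal(res$msr, ms$msr, tolerance = 1e-10)
    expect_equal(res$msc, ms$msc, tolerance = 1e-10)
    expect_equal(res$mse, ms$mse, tolerance = 1e-10)
  }
})

test_that("ICC boundary behavior: perfect agreement, noise, degeneracy", {
  x <- cbind(1:10, 1:10)
  res <- icc_absolute_agreement(x)
  expect_equal(res$icc, 1.0)
  expect_lt(res$p_value, 1e-6)

  set.seed(5)
  y <- cbind(rnorm(40, sd = 0.01), rnorm(40, sd = 100))
  expect_lt(abs(icc_absolute_agreement(y)$icc), 0.15)

  z <- matrix(5, 6, 2)  # zero between-subject variance
  res0 <- icc_absolute_agreement(z)
  expect_equal(res0$icc, 0)
  expect_true(res0$flagged)

  expect_error(icc_absolute_agreement(matrix(1:4, 2, 2)), "subjects")

  # rows with missing cells are dropped and reported
  xm <- cbind(c(1:8, NA), c(1:8 + 0.1, 2))
  resm <- icc_absolute_agreement(xm)
  expect_equal(resm$n_dropped, 1)
  expect_equal(resm$n, 8)
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(23)
  x <- matrix(rnorm(30), 10, 3) + rnorm(10, sd = 2)
  base <- icc_absolute_agreement(x)$icc
  expect_equal(icc_absolute_agreement(x + 100)$icc, base,
               tolerance = 1e-10)
  expect_equal(icc_absolute_agreement(x * 3.5)$icc, base,
               tolerance = 1e-10)
})

test_that("spearman_holm produces correct correlations and adjustment", {
  set.seed(9)
  d <- data.frame(a = 1:20)
  d$b <- d$a^2            # strictly increasing
  d$c <- -d$a             # strictly decreasing
  d$n1 <- rnorm(20)
  d$n2 <- rnorm(20)
  d$const <- 1
  panel <- spearman_holm(d, list(c("a", "b"), c("a", "c"), c("n1", "n2"),
                                 c("a", "const")))
  expect_equal(panel$rho[1], 1.0)
  expect_equal(panel$rho[2], -1.0)
  expect_true(panel$flagged[4])
  expect_true(is.na(panel$rho[4]))

  ok <- !is.na(panel$p_raw)
  expect_equal(panel$p_holm[ok], holm_oracle(panel$p_raw[ok]),
               tolerance = 1e-12)
  expect_true(all(panel$p_holm[ok] >= panel$p_raw[ok]))
  expect_true(all(panel$p_holm[ok] <= 1))

  # step-down arithmetic on a known raw-p vector
  expect_equal(holm_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "holm"),
               holm_oracle(c(0.01, 0.02, 0.04)))
})

test_that("holm ordering is preserved on random panels", {
  set.seed(41)
  for (rep in 1:10) {
    p <- runif(sample(3:8, 1))
    adj <- holm_oracle(p)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_equal(stats::p.adjust(p, "holm"), adj, tolerance = 1e-12)
  }
})

test_that("noise-free retest gives perfect reliability", {
  spec <- phantom_spec(shape = c(64, 64, 64), brain_radii = c(15, 16, 14),
                       scalp_mm = 4, noise_sd = 0)
  res <- retest_reliability_experiment(spec, n_subjects = 10, seed = 3,
                                       corruption_fraction = 0)
  expect_equal(res$n_failed, 0)
  expect_true(all(res$icc_table$icc == 1))
})

test_that("zero between-subject variance flags degenerate reliability", {
  spec <- phantom_spec(shape = c(64, 64, 64), brain_radii = c(15, 16, 14),
                       scalp_mm = 4, noise_sd = 0)
  res <- retest_reliability_experiment(spec, n_subjects = 10, seed = 3,
                                       vary_subjects = FALSE,
                                       corruption_fraction = 0)
  # identical anatomy and no noise: the deterministic measures are equal
  # across subjects -> zero between-subject variance, flagged, ICC 0
  # (IAP keeps residual between-subject variance from the EM subsample
  # draw, so it is legitimately unflagged)
  det_rows <- res$icc_table$measure != "iap"
  expect_true(all(res$icc_table$flagged[det_rows]))
  expect_true(all(res$icc_table$icc[det_rows] == 0))
})
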