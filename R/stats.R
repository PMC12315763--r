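#' Intraclass correlation, two-way model, absolute agreement, single rater
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an n x k ratings
#' table (subjects x sessions):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the F-based p-value (`F = MSR/MSE` on `(n-1, (n-1)(k-1))` df) and
#' the 95% confidence interval of McGraw & Wong. Rows containing missing
#' values are dropped (count reported).
#'
#' @param table numeric matrix or data.frame, subjects in rows, raters or
#'   sessions in columns (n >= 3, k >= 2).
#' @param conf_level confidence level (default 0.95).
#' @return list: `icc`, `p_value`, `ci_low`, `ci_high`, `n`, `k`,
#'   `n_dropped`, `flagged` (TRUE with `icc = 0` when the between-subject
#'   variance is exactly zero), and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_absolute_agreement <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L || k < 2L)
    stop("icc_absolute_agreement: need >= 3 complete subjects and >= 2 ",
         "raters", call. = FALSE)
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (ssr <= .Machine$double.eps * max(1, sst)) {
    return(list(icc = 0, p_value = 1, ci_low = NA_real_, ci_high = NA_real_,
                n = n, k = k, n_dropped = n_dropped, flagged = TRUE,
                msr = msr, msc = msc, mse = mse))
  }

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom <= 0) 0 else (msr - mse) / denom

  # F test of H0: ICC = 0
  fval <- if (mse > 0) msr / mse else Inf
  p <- stats::pf(fval, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  # McGraw & Wong (1996) confidence bounds for ICC(A,1)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (mse > 0 && is.finite(a) && is.finite(b)) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    ci_low <- ci_high <- icc
  }
  list(icc = icc, p_value = p, ci_low = ci_low, ci_high = ci_high,
       n = n, k = k, n_dropped = n_dropped, flagged = FALSE,
       msr = msr, msc = msc, mse = mse)
}

#' Spearman correlations with Holm correction
#'
#' Rank correlation (average ranks for ties) for each requested variable
#' pair, with Holm step-down adjustment of the p-values across the panel.
#' P-values use the exact permutation distribution for n <= 10 without
#' ties and the t approximation otherwise.
#'
#' @param measure_table data.frame or matrix, subjects x variables.
#' @param target_pairs list of length-2 character vectors (or a 2-column
#'   matrix) naming variable pairs.
#' @return data.frame (`correlation_panel`): var1, var2, rho, p_raw,
#'   p_holm, n, flagged (constant variable or insufficient pairs).
#' @export
spearman_holm <- function(measure_table, target_pairs) {
  m <- as.data.frame(measure_table)
  if (is.matrix(target_pairs)) {
    target_pairs <- lapply(seq_len(nrow(target_pairs)),
                           function(i) target_pairs[i, ])
  }
  rows <- lapply(target_pairs, function(pr) {
    v1 <- m[[pr[1]]]
    v2 <- m[[pr[2]]]
    ok <- is.finite(v1) & is.finite(v2)
    n <- sum(ok)
    if (n < 4L)
      return(data.frame(var1 = pr[1], var2 = pr[2], rho = NA_real_,
                        p_raw = NA_real_, n = n, flagged = TRUE))
    x <- v1[ok]; y <- v2[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(var1 = pr[1], var2 = pr[2], rho = NA_real_,
                        p_raw = NA_real_, n = n, flagged = TRUE))
    has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = (n <= 10L && !has_ties)))
    data.frame(var1 = pr[1], var2 = pr[2],
               rho = unname(ct$estimate), p_raw = ct$p.value, n = n,
               flagged = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel$p_holm <- NA_real_
  ok <- !is.na(panel$p_raw)
  panel$p_holm[ok] <- stats::p.adjust(panel$p_raw[ok], method = "holm")
  panel[, c("var1", "var2", "rho", "p_raw", "p_holm", "n", "flagged")]
}

#' Simulated retest-reliability experiment
#'
#' The reliability design of a two-session retest study, run on phantoms:
#' `n_subjects` heads with randomized geometry and intensity parameters
#' are each generated twice with independent noise realizations
#' ([make_retest_pair()]); the full pipeline runs on every image and the
#' per-measure ICC(A,1) across subjects quantifies retest reliability.
#'
#' @param spec base [phantom_spec()]; per-subject parameters are drawn
#'   around it.
#' @param n_subjects number of simulated subjects (>= 10).
#' @param seed integer seed controlling all randomization.
#' @param vary_subjects randomize per-subject anatomy (default TRUE;
#'   FALSE exercises the zero-between-subject-variance path).
#' @param corruption_fraction fraction of diploe voxels planted as
#'   head-class per session with a session-specific seed (default 0.3).
#'   This emulates the session-varying segmentation errors of real
#'   processing, so the correction stage contributes to (and limits)
#'   retest reliability; 0 reuses the ground-truth classes in both
#'   sessions, making the thickness measures trivially identical.
#' @param protocol_shift_sd sd of a per-session additive intensity offset
#'   (a protocol/scanner nuisance; default 0).
#' @param with_surface run the surface stage inside [compute_all()]
#'   (default FALSE; the headline measures do not need it).
#' @return list: `icc_table` (data.frame measure/icc/ci/p/flagged),
#'   `measures` (long data.frame of per-subject sessions), `n_failed`.
#' @export
retest_reliability_experiment <- function(spec, n_subjects = 20L, seed = 7L,
                                          vary_subjects = TRUE,
                                          corruption_fraction = 0.3,
                                          protocol_shift_sd = 0,
                                          with_surface = FALSE) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 10L)
    stop("retest_reliability_experiment: n_subjects must be >= 10",
         call. = FALSE)
  set.seed(as.integer(seed))
  # per-subject anatomy varies multiplicatively around the base spec so
  # the population scales with any grid size
  geo_scale <- if (vary_subjects) stats::runif(n_subjects, 0.9, 1.1)
               else rep(1, n_subjects)
  unit <- rep(1, n_subjects)
  diploe_mm <- spec$diploe_mm *
    (if (vary_subjects) stats::runif(n_subjects, 0.7, 1.3) else unit)
  table_mm <- spec$inner_table_mm *
    (if (vary_subjects) stats::runif(n_subjects, 0.75, 1.25) else unit)
  diploe_int <- if (vary_subjects) stats::runif(n_subjects, 350, 550)
                else rep(spec$diploe_intensity, n_subjects)
  scalp_mm <- spec$scalp_mm *
    (if (vary_subjects) stats::runif(n_subjects, 0.7, 1.3) else unit)
  fat_fr <- if (vary_subjects) stats::runif(n_subjects, 0.15, 0.45)
            else rep(spec$fat_fraction, n_subjects)
  anat_seed <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  noise_seed <- matrix(sample.int(.Machine$integer.max %/% 2,
                                  2 * n_subjects), ncol = 2)
  shift <- matrix(stats::rnorm(2 * n_subjects, 0, protocol_shift_sd),
                  ncol = 2)

  measure_names <- c("proxy_bmd", "bone_thickness_mm", "iap", "tap_mm")
  vals <- array(NA_real_, c(n_subjects, 2, length(measure_names)),
                dimnames = list(NULL, NULL, measure_names))
  n_failed <- 0L
  failures <- character(0)
  for (i in seq_len(n_subjects)) {
    spec_i <- spec
    spec_i$brain_radii <- spec$brain_radii * geo_scale[i]
    spec_i$diploe_mm <- diploe_mm[i]
    spec_i$inner_table_mm <- table_mm[i]
    spec_i$outer_table_mm <- table_mm[i]
    spec_i$diploe_intensity <- diploe_int[i]
    spec_i$scalp_mm <- scalp_mm[i]
    spec_i$fat_fraction <- fat_fr[i]
    spec_i$seed <- anat_seed[i]
    res <- try({
      validate_phantom_spec(spec_i)
      pair <- make_retest_pair(spec_i, noise_seed[i, ])
      for (s in 1:2) {
        t1 <- pair[[s]]$t1
        if (protocol_shift_sd > 0)
          t1$data <- t1$data + shift[i, s]
        seg_s <- pair[[s]]$seg
        if (corruption_fraction > 0) {
          seg_s <- plant_marrow_misclassification(
            seg_s, pair[[s]]$truth, corruption_fraction,
            seed = noise_seed[i, s])$seg
        }
        hm <- compute_all(t1, seg_s, seed = 1L,
                          with_surface = with_surface)
        vals[i, s, ] <- c(hm$proxy_bmd, hm$bone_thickness_mm, hm$iap,
                          hm$tap_mm)
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      n_failed <- n_failed + 1L
      failures <- c(failures,
                    paste0("subject ", i, ": ",
                           conditionMessage(attr(res, "condition"))))
      vals[i, , ] <- NA_real_
    }
  }

  icc_rows <- lapply(measure_names, function(mn) {
    tab <- vals[, , mn]
    if (sum(stats::complete.cases(tab)) < 3L)
      return(data.frame(measure = mn, icc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_, n = 0L,
                        flagged = TRUE))
    res <- icc_absolute_agreement(tab)
    data.frame(measure = mn, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high, p_value = res$p_value,
               n = res$n, flagged = res$flagged)
  })
  long <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    do.call(rbind, lapply(1:2, function(s) {
      data.frame(subject = i, session = s,
                 measure = measure_names, value = vals[i, s, ])
    }))
  }))
  list(icc_table = do.call(rbind, icc_rows), measures = long,
       n_failed = n_failed, failures = failures)
}
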