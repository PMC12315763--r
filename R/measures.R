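#' White-matter reference intensity
#'
#' The normalizing reference for all intensity measures: the median T1
#' intensity over high-confidence WM voxels (probability > 0.9, or the WM
#' label). The median is robust to partial volume and residual bias.
#'
#' @param t1 T1 [volume_grid].
#' @param seg a [tissue_segmentation].
#' @param min_voxels minimum number of qualifying WM voxels (default 100).
#' @return list with `wm_intensity`.
#' @export
wm_reference <- function(t1, seg, min_voxels = 100L) {
  wm <- if (seg$kind == "probability") seg$maps[["wm"]] > 0.9
        else seg$maps[["wm"]] != 0
  n <- sum(wm)
  if (n < min_voxels)
    stop("wm_reference: only ", n, " high-confidence WM voxels (need >= ",
         min_voxels, ")", call. = FALSE)
  w <- stats::median(t1$data[wm])
  if (!is.finite(w) || w <= 0)
    stop("wm_reference: non-positive WM reference intensity", call. = FALSE)
  list(wm_intensity = w)
}

#' WM-normalized skull intensity, global and per region
#'
#' Mean T1 intensity over corrected skull voxels, divided by the WM
#' reference; aggregated globally and per calvarial atlas region within the
#' bone mask.
#'
#' @param t1 T1 [volume_grid].
#' @param seg_corrected corrected [tissue_segmentation].
#' @param atlas individual-space `calvarial_atlas`.
#' @param wm [wm_reference()] result.
#' @return `region_table` data.frame of normalized mean intensities (see
#'   [regional_aggregate()]).
#' @export
bone_intensity <- function(t1, seg_corrected, atlas, wm) {
  labels <- seg_labels(seg_corrected)
  skull <- labels == 4L
  if (!any(skull))
    stop("bone_intensity: corrected skull class is empty", call. = FALSE)
  tab <- regional_aggregate(t1$data / wm$wm_intensity, atlas, skull)
  names(tab)[names(tab) == "mean_value"] <- "mean_intensity"
  tab
}

#' Proxy bone mineral density
#'
#' The negated WM-normalized occipital skull intensity. Higher marrow fat
#' (lower BMD) brightens the diploe on T1, so the proxy is defined as any
#' strictly decreasing transform of normalized intensity; negation is used
#' as the simplest such transform, keeping units interpretable. The proxy
#' is a relative measure — it is not calibrated to DXA units.
#'
#' @param occipital_bone_intensity WM-normalized occipital mean intensity.
#' @return proxy BMD (dimensionless), `NA` if the occipital value is
#'   undefined.
#' @export
proxy_bmd <- function(occipital_bone_intensity) {
  if (!is.finite(occipital_bone_intensity)) return(NA_real_)
  -occipital_bone_intensity
}

#' Fit a 1-D Gaussian mixture to head-class intensities
#'
#' EM fit of a K-component univariate Gaussian mixture to soft-head-class
#' voxel intensities, mirroring the per-class Gaussian intensity model of
#' unified segmentation. Deterministic given `seed` (used for
#' subsampling); components are returned sorted by mean. A component whose
#' weight collapses below 1e-4 triggers a refit with K-1 components and a
#' QC flag.
#'
#' @param t1 T1 [volume_grid].
#' @param seg a [tissue_segmentation].
#' @param K number of components (default 4, the usual soft-head count).
#' @param seed integer seed.
#' @param max_voxels subsample cap for EM (default 200000).
#' @return list of class `gaussian_mixture_fit`: `K`, `means`, `sds`,
#'   `weights`, `loglik`, `qc_flags`.
#' @export
fit_head_gmm <- function(t1, seg, K = 4L, seed = 1L, max_voxels = 200000L) {
  head <- if (seg$kind == "probability") seg$maps[["head"]] > 0.5
          else seg$maps[["head"]] != 0
  x <- t1$data[head]
  if (length(x) < 1000L)
    stop("fit_head_gmm: head class has ", length(x),
         " voxels (need >= 1000)", call. = FALSE)
  set.seed(as.integer(seed))
  if (length(x) > max_voxels) x <- x[sample.int(length(x), max_voxels)]
  fit <- gmm_em_1d(x, K)
  qc <- character(0)
  while (any(fit$weights < 1e-4) && fit$K > 1L) {
    qc <- union(qc, "gmm_component_collapsed")
    fit <- gmm_em_1d(x, fit$K - 1L)
  }
  fit$qc_flags <- qc
  class(fit) <- "gaussian_mixture_fit"
  fit
}

# univariate EM on histogram-binned data (the standard speed-up for
# intensity mixtures: responsibilities are computed per bin midpoint with
# the bin count as case weight); deterministic quantile initialization
gmm_em_1d <- function(x, K, max_iter = 500L, tol = 1e-10, n_bins = 1024L) {
  K <- as.integer(K)
  if (K == 1L) {
    mu <- mean(x); s <- stats::sd(x)
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    return(list(K = 1L, means = mu, sds = s, weights = 1, loglik = ll))
  }
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  mid <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  keep <- cnt > 0
  mid <- mid[keep]
  cnt <- as.numeric(cnt[keep])
  n <- sum(cnt)
  m_bins <- length(mid)

  qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  mu <- as.numeric(qs)
  s <- rep(stats::sd(x) / K + 1e-6, K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) {
      log(w[k]) + stats::dnorm(mid, mu[k], s[k], log = TRUE)
    }, numeric(m_bins))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(cnt * lse)
    r <- exp(logd - lse) * cnt
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * mid) / nk
    s <- sqrt(colSums(r * (mid - rep(mu, each = m_bins))^2) / nk)
    s <- pmax(s, 1e-6)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(K = K, means = mu[ord], sds = s[ord], weights = w[ord], loglik = ll)
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("<gaussian_mixture_fit> K =", x$K, "\n")
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights))
  invisible(x)
}

#' Intensity-based adiposity proxy (IAP)
#'
#' The weight-averaged Gaussian peak intensity of the soft head class,
#' normalized by the WM reference: subjects with more subcutaneous fat
#' carry a larger share of bright (fat) voxels, raising the composite.
#'
#' @param fit a [fit_head_gmm()] result.
#' @param wm a [wm_reference()] result.
#' @return IAP (dimensionless).
#' @export
iap <- function(fit, wm) {
  sum(fit$weights * fit$means) / wm$wm_intensity
}

#' Thickness-based adiposity proxy (TAP)
#'
#' Mean included soft-head-tissue thickness over scalp voxels whose
#' nearest skull voxel lies in the occipital atlas sector (soft tissue is
#' not itself in the atlas; the region is propagated from the nearest
#' bone).
#'
#' @param head_thickness a `thickness_map` from [head_thickness_map()]
#'   (exclusions applied).
#' @param seg_corrected corrected [tissue_segmentation].
#' @param atlas individual-space `calvarial_atlas`.
#' @param region target region label (default occipital, 4).
#' @return list `tap_mm` (mm; `NA` with `flagged = TRUE` when no voxel
#'   qualifies), `n_voxels`, `flagged`.
#' @export
tap <- function(head_thickness, seg_corrected, atlas,
                region = ATLAS_REGIONS[["occipital"]]) {
  labels <- seg_labels(seg_corrected)
  skull <- labels == 4L
  sp <- seg_corrected$spacing
  dn <- edt_distance(skull, sp, return_nearest = TRUE)
  included <- head_thickness$domain_mask & !head_thickness$excluded_mask
  idx <- which(included)
  if (!length(idx))
    return(list(tap_mm = NA_real_, n_voxels = 0L, flagged = TRUE))
  nearest_lab <- atlas$labels[dn$nearest[idx]]
  sel <- idx[nearest_lab == region]
  if (!length(sel))
    return(list(tap_mm = NA_real_, n_voxels = 0L, flagged = TRUE))
  list(tap_mm = mean(head_thickness$values[sel]), n_voxels = length(sel),
       flagged = FALSE)
}

#' Head measures record
#'
#' @param proxy_bmd,bone_thickness_mm,iap,tap_mm the four headline
#'   measures (occipital region).
#' @param region_table per-region data.frame.
#' @param qc_flags character vector of warning codes.
#' @return object of class `head_measures`.
#' @export
head_measures <- function(proxy_bmd, bone_thickness_mm, iap, tap_mm,
                          region_table = NULL, qc_flags = character(0)) {
  if (is.finite(bone_thickness_mm) && bone_thickness_mm < 0)
    stop("head_measures: bone thickness must be >= 0", call. = FALSE)
  if (is.finite(tap_mm) && tap_mm < 0)
    stop("head_measures: TAP must be >= 0", call. = FALSE)
  structure(list(proxy_bmd = proxy_bmd,
                 bone_thickness_mm = bone_thickness_mm,
                 iap = iap, tap_mm = tap_mm,
                 region_table = region_table, qc_flags = qc_flags),
            class = "head_measures")
}

#' @export
print.head_measures <- function(x, ...) {
  cat("<head_measures>\n")
  cat(sprintf("  proxy BMD          %8.4f (dimensionless)\n", x$proxy_bmd))
  cat(sprintf("  bone thickness     %8.2f mm\n", x$bone_thickness_mm))
  cat(sprintf("  IAP                %8.4f (WM-normalized)\n", x$iap))
  cat(sprintf("  TAP                %8.2f mm\n", x$tap_mm))
  if (length(x$qc_flags))
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a head-measures record to CSV or JSON
#'
#' @param measures a [head_measures()].
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_measures <- function(measures, path,
                           format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  scalars <- list(proxy_bmd = measures$proxy_bmd,
                  bone_thickness_mm = measures$bone_thickness_mm,
                  iap = measures$iap, tap_mm = measures$tap_mm)
  if (format == "json") {
    out <- c(scalars,
             list(qc_flags = measures$qc_flags,
                  region_table = measures$region_table))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    sc <- data.frame(region = "summary", label = NA_integer_,
                     measure = names(scalars),
                     value = as.numeric(unlist(scalars)),
                     n_voxels = NA_integer_)
    rt <- measures$region_table
    if (!is.null(rt) && nrow(rt)) {
      mcols <- setdiff(names(rt), c("region", "label", "n_voxels",
                                    "in_mask"))
      long <- do.call(rbind, lapply(mcols, function(mc) {
        data.frame(region = rt$region, label = rt$label, measure = mc,
                   value = rt[[mc]], n_voxels = rt$n_voxels)
      }))
      sc <- rbind(sc, long)
    }
    utils::write.csv(sc, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a head-measures record
#'
#' @param path file written by [write_measures()].
#' @return a [head_measures()] (region table only for JSON).
#' @export
read_measures <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    head_measures(num_or_na(x$proxy_bmd), num_or_na(x$bone_thickness_mm),
                  num_or_na(x$iap), num_or_na(x$tap_mm),
                  region_table = x$region_table,
                  qc_flags = as.character(unlist(x$qc_flags)))
  } else {
    d <- utils::read.csv(path)
    sc <- d[d$region == "summary", ]
    val <- function(nm) num_or_na(sc$value[sc$measure == nm])
    head_measures(val("proxy_bmd"), val("bone_thickness_mm"), val("iap"),
                  val("tap_mm"), region_table = d[d$region != "summary", ])
  }
}

num_or_na <- function(x) {
  if (is.null(x) || !length(x) || !is.finite(as.numeric(x[1]))) NA_real_
  else as.numeric(x[1])
}

#' Run the full measure-extraction pipeline
#'
#' correction -> thickness -> surface -> atlas -> measures. The headline
#' values (proxy BMD, bone thickness, IAP, TAP) are read from the
#' occipital sector, the region selected as the most BMD-relevant; the
#' full per-region table is attached.
#'
#' @param t1 T1 [volume_grid].
#' @param seg a [tissue_segmentation] (c1..c6 order).
#' @param atlas optional `calvarial_atlas` already on the individual grid;
#'   `NULL` builds the procedural sector atlas on the subject's own
#'   corrected skull.
#' @param close_radius_mm,min_island_mm3 correction parameters.
#' @param gmm_k head-class mixture size (default 4).
#' @param seed seed for the (subsampled) GMM fit.
#' @param iap_floor QC floor: IAP below this raises a
#'   `possible_fat_suppression` flag (default 0.5).
#' @param with_surface also extract the midline surface and
#'   cortical/marrow intensities (default TRUE).
#' @return a [head_measures()]; when `with_surface`, the surface and the
#'   per-vertex cortical/marrow values are attached as attribute
#'   `"surface"`.
#' @export
compute_all <- function(t1, seg, atlas = NULL, close_radius_mm = 3,
                        min_island_mm3 = 100, gmm_k = 4L, seed = 1L,
                        iap_floor = 0.5, with_surface = TRUE) {
  qc <- character(0)
  corr <- correct_skull_segment(seg, t1, close_radius_mm = close_radius_mm,
                                min_island_mm3 = min_island_mm3)
  segc <- corr$seg
  if (is.null(atlas)) atlas <- build_template_atlas(segc)

  if (max(seg$spacing) / min(seg$spacing) > 1.2)
    qc <- c(qc, "anisotropic_voxels")

  wm <- wm_reference(t1, segc)
  bone_tab <- bone_intensity(t1, segc, atlas, wm)
  occ_int <- bone_tab$mean_intensity[bone_tab$region == "occipital"]
  pbmd <- proxy_bmd(occ_int)
  if (!is.finite(pbmd)) qc <- c(qc, "occipital_intensity_missing")

  bone_thk <- bone_thickness_map(segc)
  thk_tab <- regional_aggregate(bone_thk, atlas, seg_labels(segc) == 4L)
  names(thk_tab)[names(thk_tab) == "mean_value"] <- "mean_thickness_mm"
  occ_thk <- thk_tab$mean_thickness_mm[thk_tab$region == "occipital"]

  head_thk <- head_thickness_map(segc, lower_cut_mask = atlas$bone_mask)
  tap_res <- tap(head_thk, segc, atlas)
  if (tap_res$flagged) qc <- c(qc, "tap_missing")

  gmm <- fit_head_gmm(t1, segc, K = gmm_k, seed = seed)
  qc <- c(qc, gmm$qc_flags)
  iap_val <- iap(gmm, wm)
  if (is.finite(iap_val) && iap_val < iap_floor)
    qc <- c(qc, "possible_fat_suppression")

  region_table <- merge(
    bone_tab[, c("region", "label", "mean_intensity", "n_voxels",
                 "in_mask")],
    thk_tab[, c("region", "mean_thickness_mm")],
    by = "region", sort = FALSE)

  surf_attr <- NULL
  if (with_surface) {
    pos <- percentage_position_map(segc)
    qc <- c(qc, pos$qc_flags)
    surf <- extract_midline_surface(pos, segc$spacing, segc$affine)
    prof <- sample_normal_profiles(surf, t1, bone_thk)
    qc <- c(qc, prof$qc_flags)
    sp_split <- split_profiles(prof$profiles, prof$offsets_mm)
    surf_attr <- list(surface = surf,
                      thickness_mm = prof$thickness_mm,
                      cortical_intensity = sp_split$cortical_intensity,
                      marrow_intensity = sp_split$marrow_intensity)
  }

  hm <- head_measures(proxy_bmd = pbmd,
                      bone_thickness_mm = occ_thk,
                      iap = iap_val,
                      tap_mm = tap_res$tap_mm,
                      region_table = region_table,
                      qc_flags = unique(qc))
  if (!is.null(surf_attr)) attr(hm, "surface") <- surf_attr
  hm
}
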