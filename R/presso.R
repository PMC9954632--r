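## MR-PRESSO: simulation-based residual-sum-of-squares framework with a
## global heterogeneity test, a per-variant outlier test and a distortion
## test.  The observed statistic uses leave-one-out IVW predictions, so a
## variant never contributes to its own expected outcome beta; the null
## distribution is built by parametric simulation from the observed
## summary statistics.

.pressoCore <- function(gx, gy, sy) {
  w <- 1 / sy^2
  num <- sum(w * gx * gy)
  den <- sum(w * gx^2)
  theta_loo <- (num - w * gx * gy) / (den - w * gx^2)
  res <- w * (gy - theta_loo * gx)^2
  list(theta_loo = theta_loo, residuals = res, rss = sum(res))
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed statistic is the weighted residual sum of squares
#' `sum_j w_j (gy_j - theta_{-j} gx_j)^2` with `w_j = 1/se_outcome_j^2`
#' and `theta_{-j}` the IVW estimate excluding variant j.  The null
#' sample redraws, for each replicate, exposure betas from
#' `N(gx_j, se_exposure_j^2)` and outcome betas from
#' `N(theta_{-j} gx_j, se_outcome_j^2)`, and recomputes the statistic
#' identically (including the replicate's own leave-one-out estimates).
#' The p-value carries the +1 finite-sample correction, so it is never
#' exactly zero.
#'
#' @param h harmonized instruments, J >= 4.
#' @param n_sim number of null replicates (>= 1000).
#' @param seed integer seed (mandatory; fixed seed gives bit-identical
#'   results).
#' @return list with `rss_observed`, `p_global`, `rss_sim` (length
#'   `n_sim`), `residuals_observed` (named per-variant terms),
#'   `residuals_sim` (J x n_sim matrix), `n_sim`, `seed`.
#' @export
pressoGlobal <- function(h, n_sim = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  d <- .harmData(h)
  J <- nrow(d)
  if (J < 4L) stop("insufficient instruments for MR-PRESSO (J = ", J, " < 4)")
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  obs <- .pressoCore(d$beta_exposure, d$beta_outcome, d$se_outcome)
  names(obs$residuals) <- d$rsid

  set.seed(as.integer(seed))
  gxs <- matrix(stats::rnorm(J * n_sim, d$beta_exposure, d$se_exposure),
                nrow = J)
  gys <- matrix(stats::rnorm(J * n_sim, obs$theta_loo * d$beta_exposure,
                             d$se_outcome), nrow = J)
  w <- 1 / d$se_outcome^2
  nums <- colSums(w * gxs * gys)
  dens <- colSums(w * gxs^2)
  theta_loo_s <- (rep(nums, each = J) - w * gxs * gys) /
                 (rep(dens, each = J) - w * gxs^2)
  res_sim <- w * (gys - theta_loo_s * gxs)^2
  rss_sim <- colSums(res_sim)
  p_global <- (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1)
  list(rss_observed = obs$rss, p_global = p_global, rss_sim = rss_sim,
       residuals_observed = obs$residuals, residuals_sim = res_sim,
       n_sim = as.integer(n_sim), seed = as.integer(seed))
}

#' MR-PRESSO per-variant outlier test
#'
#' Each variant's observed squared weighted residual is compared against
#' its own simulated null distribution from the global test; raw
#' p-values carry the +1 correction and are Bonferroni-multiplied by J
#' (capped at 1).  Variants with adjusted p below `alpha` are flagged.
#'
#' @param h harmonized instruments (same set the global test used).
#' @param n_sim,seed simulation settings; must match the global run.
#' @param alpha outlier significance threshold (default 0.05).
#' @param global optionally, the result of [pressoGlobal()] with the same
#'   settings, to avoid recomputation.
#' @return list with `outliers` (character, possibly empty) and
#'   `per_variant_p` (named, Bonferroni-adjusted).
#' @export
pressoOutliers <- function(h, n_sim = 1000, seed, alpha = 0.05,
                           global = NULL) {
  if (is.null(global)) global <- pressoGlobal(h, n_sim = n_sim, seed = seed)
  J <- length(global$residuals_observed)
  exceed <- rowSums(global$residuals_sim >= global$residuals_observed)
  raw <- (1 + exceed) / (global$n_sim + 1)
  adj <- pmin(1, raw * J)
  names(adj) <- names(global$residuals_observed)
  list(outliers = names(adj)[adj < alpha], per_variant_p = adj)
}

#' MR-PRESSO distortion test
#'
#' Compares the random-effects IVW estimate with all instruments
#' (`theta_all`) against the estimate with the flagged outliers removed
#' (`theta_no_outliers`).  The distortion coefficient is
#' `(theta_no_outliers - theta_all) / |theta_no_outliers|`; its null
#' distribution is built by removing the same number of variants chosen
#' uniformly at random and recomputing the coefficient, and the p-value
#' is the two-sided exceedance fraction with the +1 correction.
#'
#' @param h harmonized instruments.
#' @param outlier_rsids non-empty subset of the instrument rsids,
#'   strictly smaller than the full set.
#' @param n_sim number of random-subset replicates.
#' @param seed integer seed.
#' @return list with `theta_all`, `theta_no_outliers` (both
#'   [MREstimate-class]), `distortion_coefficient` and `p_distortion`.
#' @export
pressoDistortion <- function(h, outlier_rsids, n_sim = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  d <- .harmData(h)
  J <- nrow(d)
  k <- length(outlier_rsids)
  if (k == 0L)
    stop("not applicable: no outliers were flagged")
  if (!all(outlier_rsids %in% d$rsid))
    stop("unknown outlier rsid(s)")
  if (J - k < 2L)
    stop("too few instruments remain after outlier removal")
  theta_all <- mrIVW(d, model = "random")$estimate
  keep <- !(d$rsid %in% outlier_rsids)
  theta_no <- mrIVW(d[keep, , drop = FALSE], model = "random")$estimate
  d_obs <- (theta_no@theta - theta_all@theta) / abs(theta_no@theta)

  set.seed(as.integer(seed))
  d_null <- vapply(seq_len(n_sim), function(r) {
    drop <- sample.int(J, k)
    th <- mrIVW(d[-drop, , drop = FALSE], model = "random")$estimate@theta
    (th - theta_all@theta) / abs(th)
  }, numeric(1))
  p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  list(theta_all = theta_all, theta_no_outliers = theta_no,
       distortion_coefficient = d_obs, p_distortion = p)
}

#' Run the full MR-PRESSO suite
#'
#' Global test, outlier test, and (when outliers are flagged and enough
#' instruments remain) the distortion test, sharing one simulation
#' stream so the whole result is bit-reproducible for a fixed seed.
#'
#' @param h harmonized instruments, J >= 4.
#' @param n_sim simulation replicates (default 1000).
#' @param seed integer seed (mandatory).
#' @param alpha outlier-test significance threshold.
#' @return a [PressoResult-class].
#' @export
mrPresso <- function(h, n_sim = 1000, seed, alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  d <- .harmData(h)
  glob <- pressoGlobal(d, n_sim = n_sim, seed = seed)
  out <- pressoOutliers(d, global = glob, alpha = alpha)
  theta_all <- mrIVW(d, model = "random")$estimate
  k <- length(out$outliers)
  if (k > 0L && nrow(d) - k >= 2L) {
    dist <- pressoDistortion(d, out$outliers, n_sim = n_sim, seed = seed)
    theta_no <- dist$theta_no_outliers
    dc <- dist$distortion_coefficient
    pd <- dist$p_distortion
  } else {
    theta_no <- NULL
    dc <- NA_real_
    pd <- NA_real_
  }
  new("PressoResult", rssObserved = glob$rss_observed,
      pGlobal = glob$p_global, outliers = out$outliers,
      perVariantP = out$per_variant_p, thetaAll = theta_all,
      thetaNoOutliers = theta_no, distortionCoefficient = dc,
      pDistortion = pd, nSim = as.integer(n_sim), seed = as.integer(seed))
}
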