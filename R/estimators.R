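## Causal-effect estimators for two-sample MR on harmonized instruments.
##
## All estimators take either an MRHarmonized object or a plain
## data.frame with the harmonized columns (beta_exposure, se_exposure,
## beta_outcome, se_outcome, rsid); the latter keeps simulation loops
## cheap.  Estimates are causal log odds ratios per 1 SD of the exposure,
## with 95% CIs at theta +/- 1.96 se and two-sided normal p-values.

.Z95 <- 1.96

.harmData <- function(h) {
  d <- if (is(h, "MRHarmonized")) h@data else as.data.frame(h)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("harmonized data lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$rsid)) d$rsid <- paste0("v", seq_len(nrow(d)))
  if (any(d$se_exposure <= 0) || any(d$se_outcome <= 0))
    stop("standard errors must be positive")
  d
}

.ivwCore <- function(gx, gy, sy) {
  w <- 1 / sy^2
  den <- sum(w * gx^2)
  theta <- sum(w * gx * gy) / den
  q <- sum(w * (gy - theta * gx)^2)
  list(theta = theta, se_fixed = 1 / sqrt(den), q = q)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-variant causal estimate: the variant-outcome beta divided by
#' the variant-exposure beta, with the first-order delta-method standard
#' error `se_outcome / |beta_exposure|`.
#'
#' @param inst a single harmonized instrument (one-row `data.frame`,
#'   list, or an [MRHarmonized-class] with exactly one variant).
#' @return an [MREstimate-class] with method `"wald"`.
#' @examples
#' waldRatio(data.frame(beta_exposure = 0.1, se_exposure = 0.004,
#'                      beta_outcome = 0.02, se_outcome = 0.01))
#' @export
waldRatio <- function(inst) {
  d <- .harmData(if (is.list(inst) && !is.data.frame(inst) &&
                     !is(inst, "MRHarmonized")) as.data.frame(inst) else inst)
  if (nrow(d) != 1L) stop("waldRatio expects exactly one instrument")
  if (d$beta_exposure == 0)
    stop("undefined ratio: beta_exposure is zero")
  theta <- d$beta_outcome / d$beta_exposure
  se <- d$se_outcome / abs(d$beta_exposure)
  .newEstimate("wald", theta, se, 1L, z = .Z95)
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2` -- equivalently a fixed-effect
#' meta-analysis of the per-variant Wald ratios.  Cochran's Q against
#' this fit (J-1 df) measures heterogeneity; under the multiplicative
#' random-effects model the standard error is inflated by
#' `max(1, sqrt(Q/(J-1)))` while the point estimate is unchanged.
#'
#' @param h harmonized instruments ([MRHarmonized-class] or
#'   `data.frame`), J >= 2.
#' @param model `"fixed"` or `"random"` (multiplicative).
#' @return list with `estimate` ([MREstimate-class]) and `diagnostics`
#'   ([PleiotropyDiagnostics-class]; Egger fields are `NA`).
#' @export
mrIVW <- function(h, model = c("fixed", "random")) {
  model <- match.arg(model)
  d <- .harmData(h)
  J <- nrow(d)
  if (J < 2L)
    stop("insufficient instruments (J = ", J,
         "): use waldRatio() for a single variant")
  core <- .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)
  qdf <- J - 1L
  se <- if (model == "random")
    core$se_fixed * max(1, sqrt(core$q / qdf)) else core$se_fixed
  est <- .newEstimate(paste0("ivw_", model), core$theta, se, J, z = .Z95)
  diag <- new("PleiotropyDiagnostics",
              qStatistic = core$q, qDf = as.numeric(qdf),
              qPvalue = max(stats::pchisq(core$q, qdf, lower.tail = FALSE),
                            .Machine$double.xmin),
              eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
              eggerInterceptCILower = NA_real_,
              eggerInterceptCIUpper = NA_real_, eggerInterceptP = NA_real_,
              i2GX = NA_real_, nomeReliable = NA)
  list(estimate = est, diagnostics = diag)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept (weights `1/se_outcome^2`), after re-orienting every
#' instrument so its exposure beta is positive.  The slope is a causal
#' estimate robust to directional pleiotropy under the InSIDE
#' assumption; the intercept estimates the average directional
#' pleiotropic effect, and its test against zero is the Egger pleiotropy
#' test.  Residual Q is on J-2 df; under `model = "random"` both
#' standard errors are inflated by `max(1, sqrt(Q/(J-2)))`.  The I2GX
#' statistic (from the weighted dispersion of the oriented exposure
#' betas) flags violation of the NO-Measurement-Error assumption;
#' inference is marked unreliable below 0.90.
#'
#' @param h harmonized instruments, J >= 3.
#' @param model `"fixed"` or `"random"` (multiplicative).
#' @param distribution `"normal"` (default, matching normal-theory CIs)
#'   or `"t"` for t-distribution p-values/CIs on J-2 df.
#' @return list with `estimate` (slope, [MREstimate-class]),
#'   `diagnostics` ([PleiotropyDiagnostics-class] including the intercept
#'   test and I2GX), and `intercept` (named vector: estimate, se, lower,
#'   upper, p).
#' @export
mrEgger <- function(h, model = c("fixed", "random"),
                    distribution = c("normal", "t")) {
  model <- match.arg(model)
  distribution <- match.arg(distribution)
  d <- .harmData(h)
  J <- nrow(d)
  if (J < 3L) stop("insufficient instruments for MR-Egger (J = ", J, " < 3)")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  gx <- d$beta_exposure * flip
  gy <- d$beta_outcome * flip
  sy <- d$se_outcome
  sx <- d$se_exposure
  if (max(gx) - min(gx) < .Machine$double.eps * max(abs(gx)))
    stop("collinear instruments: all exposure betas equal, slope undefined")

  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * gx); swx2 <- sum(w * gx^2)
  swy <- sum(w * gy); swxy <- sum(w * gx * gy)
  det <- sw * swx2 - swx^2
  intercept <- (swx2 * swy - swx * swxy) / det
  slope     <- (sw * swxy - swx * swy) / det
  qres <- sum(w * (gy - intercept - slope * gx)^2)
  qdf <- J - 2L
  scale <- if (model == "random") max(1, sqrt(qres / qdf)) else 1
  se_slope <- sqrt(sw / det) * scale
  se_int   <- sqrt(swx2 / det) * scale

  crit <- if (distribution == "t") stats::qt(0.975, qdf) else .Z95
  pfun <- if (distribution == "t")
    function(z) 2 * stats::pt(-abs(z), qdf)
  else
    function(z) 2 * stats::pnorm(-abs(z))

  est <- new("MREstimate", method = "egger_slope", theta = slope,
             se = se_slope, ciLower = slope - crit * se_slope,
             ciUpper = slope + crit * se_slope, pvalue = pfun(slope / se_slope),
             oddsRatio = exp(slope), orCILower = exp(slope - crit * se_slope),
             orCIUpper = exp(slope + crit * se_slope),
             nVariants = as.integer(J))

  wx <- 1 / sx^2
  gbar <- sum(wx * gx) / sum(wx)
  qgx <- sum(wx * (gx - gbar)^2)
  i2 <- if (qgx > 0) max(0, (qgx - (J - 1)) / qgx) else 0

  diag <- new("PleiotropyDiagnostics",
              qStatistic = qres, qDf = as.numeric(qdf),
              qPvalue = max(stats::pchisq(qres, qdf, lower.tail = FALSE),
                            .Machine$double.xmin),
              eggerIntercept = intercept, eggerInterceptSE = se_int,
              eggerInterceptCILower = intercept - crit * se_int,
              eggerInterceptCIUpper = intercept + crit * se_int,
              eggerInterceptP = pfun(intercept / se_int),
              i2GX = i2, nomeReliable = i2 >= 0.90)
  list(estimate = est, diagnostics = diag,
       intercept = c(estimate = intercept, se = se_int,
                     lower = intercept - crit * se_int,
                     upper = intercept + crit * se_int,
                     p = pfun(intercept / se_int)))
}

.weightedMedianPoint <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  n <- length(r)
  if (0.5 >= p[n]) return(r[n])
  stats::approx(p, r, xout = 0.5)$y
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted
#' ascending with inverse-variance weights `(se_outcome/|beta_exposure|)^-2`
#' normalized to sum 1, and the estimate is the linear interpolation of
#' the ratio at cumulative weight 0.5 (midpoint convention).  Consistent
#' when instruments carrying at least half the weight are valid.  The
#' standard error is the standard deviation of the estimate over
#' `n_boot` parametric resamples drawing both betas from their sampling
#' distributions.
#'
#' @param h harmonized instruments, J >= 3.
#' @param n_boot number of parametric bootstrap resamples (>= 100).
#' @param seed integer seed for the bootstrap stream (mandatory).
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
weightedMedian <- function(h, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  d <- .harmData(h)
  J <- nrow(d)
  if (J < 3L)
    stop("insufficient instruments for the weighted median (J = ", J, " < 3)")
  if (n_boot < 100) stop("n_boot must be at least 100")
  ratios <- d$beta_outcome / d$beta_exposure
  weights <- (d$se_outcome / abs(d$beta_exposure))^-2
  point <- .weightedMedianPoint(ratios, weights)

  set.seed(as.integer(seed))
  gx <- matrix(stats::rnorm(J * n_boot, d$beta_exposure, d$se_exposure),
               nrow = J)
  gy <- matrix(stats::rnorm(J * n_boot, d$beta_outcome, d$se_outcome),
               nrow = J)
  boots <- vapply(seq_len(n_boot), function(b) {
    .weightedMedianPoint(gy[, b] / gx[, b],
                         (d$se_outcome / abs(gx[, b]))^-2)
  }, numeric(1))
  se <- stats::sd(boots)
  .newEstimate("weighted_median", point, se, J, z = .Z95)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect J times, each time omitting one
#' instrument, with the same estimator settings as the primary analysis
#' (IVW with the chosen effects model).  The variant whose omission
#' moves the estimate furthest toward the null is reported as most
#' influential.
#'
#' @param h harmonized instruments, J >= 3.
#' @param model IVW effects model, `"fixed"` or `"random"`.
#' @return list with `results` (a `data.frame`: `excluded_rsid`, `theta`,
#'   `se`, `ciLower`, `ciUpper`, `pvalue`, `oddsRatio`, `nVariants`) and
#'   `mostInfluential` (the rsid minimizing `|theta|` on omission).
#' @export
leaveOneOut <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- .harmData(h)
  J <- nrow(d)
  if (J < 3L) stop("insufficient instruments for leave-one-out (J < 3)")
  rows <- lapply(seq_len(J), function(j) {
    fit <- mrIVW(d[-j, , drop = FALSE], model = model)$estimate
    data.frame(excluded_rsid = d$rsid[j], theta = fit@theta, se = fit@se,
               ciLower = fit@ciLower, ciUpper = fit@ciUpper,
               pvalue = fit@pvalue, oddsRatio = fit@oddsRatio,
               nVariants = fit@nVariants, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  list(results = res,
       mostInfluential = res$excluded_rsid[which.min(abs(res$theta))])
}

#' Plot-ready scatter and funnel tables
#'
#' Assembles the per-variant scatter data (exposure beta vs outcome beta
#' with both standard errors), the fitted lines of the supplied
#' estimators (IVW and median lines pass through the origin; the Egger
#' line carries its intercept), and the funnel data (per-variant Wald
#' ratio against its precision).
#'
#' @param h harmonized instruments (non-empty).
#' @param fits named list of [MREstimate-class] objects.
#' @param diagnostics optional [PleiotropyDiagnostics-class] supplying
#'   the Egger intercept for the `egger_slope` line.
#' @return list of three `data.frame`s: `scatter`, `lines`, `funnel`.
#' @export
funnelScatterData <- function(h, fits = list(), diagnostics = NULL) {
  d <- .harmData(h)
  if (!nrow(d)) stop("no instruments")
  scatter <- data.frame(rsid = d$rsid,
                        beta_exposure = d$beta_exposure,
                        beta_outcome = d$beta_outcome,
                        se_exposure = d$se_exposure,
                        se_outcome = d$se_outcome,
                        stringsAsFactors = FALSE)
  lines <- if (length(fits)) do.call(rbind, lapply(fits, function(f) {
    icpt <- if (f@method == "egger_slope" && !is.null(diagnostics))
      diagnostics@eggerIntercept else 0
    data.frame(method = f@method, slope = f@theta, intercept = icpt,
               stringsAsFactors = FALSE)
  })) else data.frame(method = character(), slope = numeric(),
                      intercept = numeric(), stringsAsFactors = FALSE)
  rownames(lines) <- NULL
  wald_theta <- d$beta_outcome / d$beta_exposure
  wald_se <- d$se_outcome / abs(d$beta_exposure)
  funnel <- data.frame(rsid = d$rsid, theta = wald_theta,
                       precision = 1 / wald_se, stringsAsFactors = FALSE)
  list(scatter = scatter, lines = lines, funnel = funnel)
}
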