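## Toy anthropometric cohort for body-shape principal components.
##
## Six traits -- height, weight, BMI, waist circumference (WC), hip
## circumference (HC), waist-to-hip ratio (WHR) -- are generated as
## correlated lognormals.  The default correlation target is built from
## a 4-trait base (log height, weight, WC, HC) with BMI and WHR derived
## through their defining ratios (log BMI = log W - 2 log H(m),
## log WHR = log WC - log HC) plus a few percent of independent
## measurement noise, which keeps the 6x6 matrix full-rank and the
## simulated BMI/WHR ratio-consistent up to that noise.

.ANTHRO_TRAITS <- c("height", "weight", "bmi", "wc", "hc", "whr")

## log-scale meanlog / sdlog targets for an adult female population
.ANTHRO_MEANLOG <- c(height = log(162), weight = log(68), bmi = log(25.9),
                     wc = log(83), hc = log(100), whr = log(0.83))

#' Default anthropometric correlation target
#'
#' The 6x6 log-scale correlation matrix used by
#' [simulateAnthropometrics()], derived from a base covariance over
#' height, weight, WC and HC calibrated to adult female anthropometry,
#' with BMI and WHR induced by their defining ratios and `noise_frac`
#' of each trait's SD added as independent measurement noise.
#'
#' @param noise_frac measurement-noise SD as a fraction of each trait's
#'   SD (default 0.05); must be positive to keep the matrix full-rank.
#' @return positive-definite 6x6 correlation matrix with attribute
#'   `"sdlog"` (the implied log-scale trait SDs).
#' @export
defaultAnthroCorr <- function(noise_frac = 0.05) {
  base_sd <- c(height = 0.040, weight = 0.150, wc = 0.080, hc = 0.070)
  base_cor <- matrix(c(
    1.00, 0.45, 0.15, 0.25,
    0.45, 1.00, 0.85, 0.85,
    0.15, 0.85, 1.00, 0.82,
    0.25, 0.85, 0.82, 1.00), 4, 4,
    dimnames = list(names(base_sd), names(base_sd)))
  base_cov <- base_cor * tcrossprod(base_sd)
  ## rows: height, weight, bmi = W - 2H, wc, hc, whr = WC - HC
  A <- rbind(height = c(1, 0, 0, 0),
             weight = c(0, 1, 0, 0),
             bmi    = c(-2, 1, 0, 0),
             wc     = c(0, 0, 1, 0),
             hc     = c(0, 0, 0, 1),
             whr    = c(0, 0, 1, -1))
  cov6 <- A %*% base_cov %*% t(A)
  cov6 <- cov6 + diag((noise_frac^2) * diag(cov6))
  corr <- stats::cov2cor(cov6)
  dimnames(corr) <- list(.ANTHRO_TRAITS, .ANTHRO_TRAITS)
  attr(corr, "sdlog") <- sqrt(diag(cov6))
  corr
}

#' Simulate an anthropometric cohort and its body-shape PCs
#'
#' Draws multivariate-normal log traits with the target correlation,
#' transforms them to natural units, and runs a PCA on the six
#' standardized traits.  With the default calibrated correlation the
#' qualitative body-shape pattern holds: PC1 (general adiposity) loads
#' with a common sign on all traits with height's loading smallest in
#' magnitude; PC2 contrasts height against WHR; variance explained is
#' ordered PC1 > PC2 > PC3 with PC1 around two thirds.
#'
#' @param n_subjects cohort size.
#' @param correlation 6x6 positive-definite correlation target
#'   (default [defaultAnthroCorr()]).
#' @param seed integer seed.
#' @param sdlog optional log-scale SDs per trait (default: the ones
#'   implied by the default correlation construction).
#' @return an [AnthroCohort-class].
#' @export
simulateAnthropometrics <- function(n_subjects, correlation = defaultAnthroCorr(),
                                    seed, sdlog = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.matrix(correlation), nrow(correlation) == 6L,
            ncol(correlation) == 6L)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix is not positive definite")
  if (is.null(sdlog)) {
    sdlog <- attr(correlation, "sdlog")
    if (is.null(sdlog)) sdlog <- attr(defaultAnthroCorr(), "sdlog")
  }
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_subjects * 6), n_subjects, 6) %*%
    chol(correlation)
  traits <- exp(sweep(sweep(z, 2, sdlog, "*"), 2, .ANTHRO_MEANLOG, "+"))
  colnames(traits) <- .ANTHRO_TRAITS
  pca <- stats::prcomp(traits, center = TRUE, scale. = TRUE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  new("AnthroCohort", traits = traits, loadings = pca$rotation,
      varExplained = ve,
      correlationTarget = matrix(as.numeric(correlation), 6, 6,
                                 dimnames = dimnames(correlation)))
}
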