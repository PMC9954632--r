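#' @import methods
NULL

.PANEL_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")

.HARM_COLS <- c("rsid", "effect_allele", "other_allele",
                "beta_exposure", "se_exposure", "beta_outcome", "se_outcome",
                "eaf_exposure", "eaf_outcome", "action", "proxy_rsid")

#' Panel of variant-trait association summary statistics
#'
#' An `MRPanel` holds per-variant GWAS summary statistics for one trait
#' (an exposure such as a body-shape principal component, or an outcome
#' such as breast cancer risk).  Each row is one variant association:
#' identifier, alleles, effect-allele frequency, beta, standard error,
#' p-value and optional sample size.  Exposure betas are interpreted in
#' SD units of the trait; outcome betas as log odds ratios.
#'
#' @slot exposureName label for the trait (e.g. `"PC1"`).
#' @slot data `data.frame` with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot genomeBuild genome build label (informational only; matching is
#'   by rsid and alleles, never by coordinates).
#' @slot rejected per-row rejection log from [readSummaryStats()]:
#'   columns `row`, `rsid`, `reason`.
#'
#' @seealso [MRPanel()] for the validating constructor.
#' @export
setClass("MRPanel",
  representation(
    exposureName = "character",
    data         = "data.frame",
    genomeBuild  = "character",
    rejected     = "data.frame"
  )
)

setValidity("MRPanel", function(object) {
  d <- object@data
  msgs <- character()
  if (!all(.PANEL_COLS %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(.PANEL_COLS, names(d)), collapse = ", ")))
  if (nrow(d) == 0L)
    msgs <- c(msgs, "panel is empty")
  if (anyDuplicated(d$rsid))
    msgs <- c(msgs, paste0("duplicate rsid: ",
                           paste(unique(d$rsid[duplicated(d$rsid)]), collapse = ", ")))
  if (any(!nzchar(d$rsid)))
    msgs <- c(msgs, "empty rsid")
  if (any(!is.finite(d$se) | d$se <= 0))
    msgs <- c(msgs, "non-positive se")
  if (any(d$effect_allele == d$other_allele))
    msgs <- c(msgs, "effect_allele equals other_allele")
  bad_eaf <- !is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)
  if (any(bad_eaf))
    msgs <- c(msgs, "eaf outside [0,1]")
  bad_p <- !is.na(d$pval) & (d$pval <= 0 | d$pval > 1)
  if (any(bad_p))
    msgs <- c(msgs, "pval outside (0,1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Harmonized two-sample instrument set
#'
#' Pairs of exposure and outcome associations aligned to a common effect
#' allele, ready for Mendelian randomization estimation.  The `action`
#' column records how each variant was aligned (`direct`, `sign_flipped`,
#' `strand_flipped`, `proxy_substituted`); `dropped` records every variant
#' excluded during harmonization together with the reason, so that
#' kept + dropped always accounts for the full input panel.
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot data `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, `action`, `proxy_rsid`.
#' @slot dropped `data.frame` with columns `rsid`, `reason`.
#' @export
setClass("MRHarmonized",
  representation(
    exposureName = "character",
    outcomeName  = "character",
    data         = "data.frame",
    dropped      = "data.frame"
  )
)

setValidity("MRHarmonized", function(object) {
  d <- object@data
  if (!all(.HARM_COLS %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(.HARM_COLS, names(d)), collapse = ", ")))
  msgs <- character()
  if (nrow(d)) {
    if (any(!is.finite(d$se_exposure) | d$se_exposure <= 0))
      msgs <- c(msgs, "non-positive se_exposure")
    if (any(!is.finite(d$se_outcome) | d$se_outcome <= 0))
      msgs <- c(msgs, "non-positive se_outcome")
    if (anyDuplicated(d$rsid))
      msgs <- c(msgs, "duplicate rsid")
    if (!all(d$action %in% c("direct", "sign_flipped", "strand_flipped",
                             "proxy_substituted")))
      msgs <- c(msgs, "unknown action")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Causal-effect estimate from a Mendelian randomization estimator
#'
#' Holds the causal log odds ratio per 1 SD of the exposure with its
#' standard error, 95% confidence bounds and two-sided normal p-value,
#' plus the exponentiated (odds ratio) scale used for reporting.
#'
#' @slot method one of `"wald"`, `"ivw_fixed"`, `"ivw_random"`,
#'   `"egger_slope"`, `"egger_intercept"`, `"weighted_median"`.
#' @slot theta causal log-OR per 1 SD increase of the exposure.
#' @slot se standard error of `theta`.
#' @slot ciLower,ciUpper 95% bounds, `theta +/- 1.96 se`.
#' @slot pvalue two-sided normal p-value.
#' @slot oddsRatio,orCILower,orCIUpper exponentiated scale.
#' @slot nVariants number of instruments used.
#' @export
setClass("MREstimate",
  representation(
    method    = "character",
    theta     = "numeric",
    se        = "numeric",
    ciLower   = "numeric",
    ciUpper   = "numeric",
    pvalue    = "numeric",
    oddsRatio = "numeric",
    orCILower = "numeric",
    orCIUpper = "numeric",
    nVariants = "integer"
  )
)

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (object@nVariants < 1L) msgs <- c(msgs, "nVariants < 1")
  if (is.finite(object@se) && object@se > 0) {
    if (!(object@ciLower < object@theta && object@theta < object@ciUpper))
      msgs <- c(msgs, "CI does not bracket theta")
  }
  if (abs(object@oddsRatio - exp(object@theta)) >
      1e-8 * max(1, abs(object@oddsRatio)))
    msgs <- c(msgs, "oddsRatio != exp(theta)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Heterogeneity and pleiotropy diagnostics
#'
#' Cochran's Q against the IVW (or Egger) fit, the MR-Egger intercept
#' test for directional pleiotropy, and the I2GX statistic quantifying
#' how close the NO-Measurement-Error (NOME) assumption is to holding
#' (values below 0.90 flag MR-Egger inference as unreliable).
#'
#' @slot qStatistic Cochran's Q (>= 0).
#' @slot qDf residual degrees of freedom (J-1 for IVW, J-2 for Egger).
#' @slot qPvalue chi-square upper-tail p-value.
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptCILower,eggerInterceptCIUpper,eggerInterceptP
#'   Egger intercept summary (NA when the diagnostics come from IVW).
#' @slot i2GX I2GX in [0,1]; NA when not computed.
#' @slot nomeReliable `TRUE` when `i2GX >= 0.90`.
#' @export
setClass("PleiotropyDiagnostics",
  representation(
    qStatistic            = "numeric",
    qDf                   = "numeric",
    qPvalue               = "numeric",
    eggerIntercept        = "numeric",
    eggerInterceptSE      = "numeric",
    eggerInterceptCILower = "numeric",
    eggerInterceptCIUpper = "numeric",
    eggerInterceptP       = "numeric",
    i2GX                  = "numeric",
    nomeReliable          = "logical"
  )
)

setValidity("PleiotropyDiagnostics", function(object) {
  msgs <- character()
  if (is.finite(object@qStatistic) && object@qStatistic < 0)
    msgs <- c(msgs, "qStatistic < 0")
  if (is.finite(object@qPvalue) &&
      (object@qPvalue <= 0 || object@qPvalue > 1))
    msgs <- c(msgs, "qPvalue outside (0,1]")
  if (is.finite(object@i2GX) && (object@i2GX < 0 || object@i2GX > 1))
    msgs <- c(msgs, "i2GX outside [0,1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setClassUnion("MREstimateOrNULL", c("MREstimate", "NULL"))

#' MR-PRESSO result
#'
#' Result of the MR-PRESSO global residual-sum-of-squares test, the
#' per-variant outlier test (Bonferroni-adjusted simulation p-values)
#' and, when outliers were flagged, the distortion test comparing the
#' random-effects IVW estimate with and without the outliers.
#'
#' @slot rssObserved observed leave-one-out weighted residual sum of squares.
#' @slot pGlobal simulation p-value of the global test (+1 corrected).
#' @slot outliers rsids flagged at the outlier-test alpha (possibly empty).
#' @slot perVariantP named vector of Bonferroni-adjusted outlier p-values.
#' @slot thetaAll,thetaNoOutliers random-effects IVW estimates with all
#'   instruments and with outliers removed (`NULL` when no outliers).
#' @slot distortionCoefficient signed fractional change
#'   `(theta_no_outliers - theta_all) / |theta_no_outliers|` (NA when no
#'   outliers).
#' @slot pDistortion two-sided simulation p-value of the distortion test.
#' @slot nSim number of simulation replicates used.
#' @slot seed seed used for the simulation streams.
#' @export
setClass("PressoResult",
  representation(
    rssObserved           = "numeric",
    pGlobal               = "numeric",
    outliers              = "character",
    perVariantP           = "numeric",
    thetaAll              = "MREstimateOrNULL",
    thetaNoOutliers       = "MREstimateOrNULL",
    distortionCoefficient = "numeric",
    pDistortion           = "numeric",
    nSim                  = "integer",
    seed                  = "integer"
  )
)

setValidity("PressoResult", function(object) {
  msgs <- character()
  if (is.finite(object@pGlobal) &&
      (object@pGlobal < 0 || object@pGlobal > 1))
    msgs <- c(msgs, "pGlobal outside [0,1]")
  if (is.finite(object@pDistortion) &&
      (object@pDistortion < 0 || object@pDistortion > 1))
    msgs <- c(msgs, "pDistortion outside [0,1]")
  if (!all(object@outliers %in% names(object@perVariantP)))
    msgs <- c(msgs, "outliers not a subset of tested rsids")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Synthetic anthropometric cohort with body-shape principal components
#'
#' A simulated cohort of six anthropometric traits (height, weight, BMI,
#' waist circumference, hip circumference, waist-to-hip ratio) with a
#' stated target correlation structure, together with the PCA of the six
#' standardized traits: loadings and variance-explained fractions.
#'
#' @slot traits numeric matrix, subjects x 6 traits, natural units.
#' @slot loadings 6 x 6 PCA loading matrix (columns PC1..PC6).
#' @slot varExplained length-6 vector of variance-explained fractions.
#' @slot correlationTarget the 6 x 6 correlation matrix the generator
#'   targeted (on the log-trait scale).
#' @export
setClass("AnthroCohort",
  representation(
    traits            = "matrix",
    loadings          = "matrix",
    varExplained      = "numeric",
    correlationTarget = "matrix"
  )
)

setValidity("AnthroCohort", function(object) {
  msgs <- character()
  if (ncol(object@traits) != 6L) msgs <- c(msgs, "expected 6 traits")
  if (length(object@varExplained) != 6L ||
      abs(sum(object@varExplained) - 1) > 1e-6)
    msgs <- c(msgs, "varExplained must be 6 fractions summing to 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---- constructors -------------------------------------------------------

#' Construct a validated summary-statistics panel
#'
#' @param data `data.frame` with at least `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; optional `chrom`, `pos`, `eaf`, `pval`,
#'   `n` are filled with `NA` when absent.  Alleles are uppercased.
#' @param exposureName trait label.
#' @param genomeBuild genome build label.
#' @param rejected optional rejection log (`row`, `rsid`, `reason`).
#' @return an [MRPanel-class] object.
#' @examples
#' MRPanel(data.frame(rsid = "rs1", effect_allele = "a", other_allele = "g",
#'                    beta = 0.1, se = 0.01), "PC1")
#' @export
MRPanel <- function(data, exposureName = "exposure", genomeBuild = "unknown",
                    rejected = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "))
  for (col in setdiff(.PANEL_COLS, names(data)))
    data[[col]] <- if (col %in% c("rsid", "chrom")) NA_character_ else NA_real_
  data <- data[, .PANEL_COLS]
  data$rsid          <- as.character(data$rsid)
  data$chrom         <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele  <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])
  rownames(data) <- NULL
  if (is.null(rejected))
    rejected <- data.frame(row = integer(), rsid = character(),
                           reason = character(), stringsAsFactors = FALSE)
  new("MRPanel", exposureName = exposureName, data = data,
      genomeBuild = genomeBuild, rejected = rejected)
}

.newEstimate <- function(method, theta, se, n, z = 1.96) {
  ci <- theta + c(-1, 1) * z * se
  p  <- 2 * stats::pnorm(-abs(theta / se))
  new("MREstimate", method = method, theta = theta, se = se,
      ciLower = ci[1], ciUpper = ci[2], pvalue = p,
      oddsRatio = exp(theta), orCILower = exp(ci[1]), orCIUpper = exp(ci[2]),
      nVariants = as.integer(n))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "MRPanel", function(object) {
  cat("MRPanel '", object@exposureName, "': ", nrow(object@data),
      " variant(s), build ", object@genomeBuild, "\n", sep = "")
  if (nrow(object@rejected))
    cat("  ", nrow(object@rejected), " row(s) rejected on read\n", sep = "")
  print(utils::head(object@data, 5))
  if (nrow(object@data) > 5) cat("  ...\n")
})

setMethod("show", "MRHarmonized", function(object) {
  cat("MRHarmonized: ", object@exposureName, " -> ", object@outcomeName,
      "\n  ", nrow(object@data), " instrument(s) kept, ",
      nrow(object@dropped), " dropped\n", sep = "")
  if (nrow(object@data)) {
    tab <- table(object@data$action)
    cat("  actions:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf(
    "MREstimate [%s] OR per 1 SD = %.3f (95%% CI %.3f-%.3f), p = %.3g, J = %d\n",
    object@method, object@oddsRatio, object@orCILower, object@orCIUpper,
    object@pvalue, object@nVariants))
})

setMethod("show", "PleiotropyDiagnostics", function(object) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              object@qStatistic, as.integer(object@qDf), object@qPvalue))
  if (is.finite(object@eggerIntercept))
    cat(sprintf("Egger intercept = %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
                object@eggerIntercept, object@eggerInterceptCILower,
                object@eggerInterceptCIUpper, object@eggerInterceptP))
  if (is.finite(object@i2GX))
    cat(sprintf("I2GX = %.3f (%s)\n", object@i2GX,
                if (isTRUE(object@nomeReliable)) "NOME plausible"
                else "MR-Egger unreliable"))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: RSS = %.4f, global p = %.4g (n_sim = %d)\n",
              object@rssObserved, object@pGlobal, object@nSim))
  if (length(object@outliers))
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  if (is.finite(object@distortionCoefficient))
    cat(sprintf("  distortion coefficient = %.4f, p = %.4g\n",
                object@distortionCoefficient, object@pDistortion))
})

setMethod("show", "AnthroCohort", function(object) {
  cat("AnthroCohort:", nrow(object@traits), "subjects x",
      ncol(object@traits), "traits\n")
  cat("  variance explained:",
      paste(sprintf("PC%d=%.1f%%", 1:3, 100 * object@varExplained[1:3]),
            collapse = ", "), "\n")
})
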