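## Synthetic two-sample GWAS summary statistics with known ground truth.
##
## The generator emulates the study design this package targets: an
## exposure GWAS of a body-shape principal component (betas in SD units,
## GIANT-scale standard errors) and a disease outcome GWAS (betas as log
## odds ratios, BCAC-scale standard errors), linked by true instrument
## strengths, a configurable pleiotropy regime, planted outliers, and
## allele-presentation quirks (coding swaps, strand flips, palindromes)
## so every harmonization path is exercised.

.PLEIO_MODES <- c("none", "balanced", "directional", "inside_violating")

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is calibrated for:
#' 30 instruments (the PC1 panel size), a true causal log-OR per SD of
#' `log(0.89)`, instrument strengths of 0.03-0.10 SD per allele oriented
#' to the trait-increasing allele, exposure standard errors on the scale
#' of a ~170k-sample GWAS and outcome standard errors on the scale of a
#' ~247k case-control GWAS, and 5% palindromic / 5% strand-flipped /
#' 30% allele-swapped presentation.
#'
#' @param n_variants number of instruments J (>= 1).
#' @param theta_true causal log-OR per 1 SD of the exposure.
#' @param gamma_range interval for true instrument strengths (SD/allele).
#' @param se_exposure_scale,se_outcome_scale per-variant standard-error
#'   scales (the SE at minor-allele frequency 0.25; SEs scale with
#'   `1/sqrt(2 maf (1-maf))`).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct
#'   effects), `"directional"` (nonzero mean), or `"inside_violating"`
#'   (direct effects correlated with instrument strength).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the direct
#'   (pleiotropic) effects on the outcome, log-OR units.
#' @param pleiotropy_frac fraction of instruments carrying pleiotropy
#'   (default 1; 0.4 gives the "40% invalid instruments" regime).
#' @param n_outliers number of planted outliers.
#' @param outlier_shift outlier displacement in units of the variant's
#'   outcome SE.
#' @param maf_range effect-allele minor-frequency interval, within
#'   (0, 0.5].
#' @param palindromic_rate,strand_flip_rate,allele_swap_rate rates at
#'   which variants are made palindromic, presented on the opposite
#'   strand in the outcome file, or presented with swapped effect/other
#'   alleles in the outcome file.
#' @param seed integer seed (mandatory).
#' @return validated list of class `"simConfig"`.
#' @export
simConfig <- function(n_variants = 30, theta_true = log(0.89),
                      gamma_range = c(0.03, 0.10),
                      se_exposure_scale = 0.004, se_outcome_scale = 0.008,
                      pleiotropy_mode = "none", pleiotropy_mean = 0.03,
                      pleiotropy_sd = 0.01, pleiotropy_frac = 1,
                      n_outliers = 0, outlier_shift = 10,
                      maf_range = c(0.05, 0.5),
                      palindromic_rate = 0.05, strand_flip_rate = 0.05,
                      allele_swap_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_variants = as.integer(n_variants), theta_true = theta_true,
              gamma_range = gamma_range,
              se_exposure_scale = se_exposure_scale,
              se_outcome_scale = se_outcome_scale,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              pleiotropy_frac = pleiotropy_frac,
              n_outliers = as.integer(n_outliers),
              outlier_shift = outlier_shift, maf_range = maf_range,
              palindromic_rate = palindromic_rate,
              strand_flip_rate = strand_flip_rate,
              allele_swap_rate = allele_swap_rate, seed = as.integer(seed))
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1")
  if (cfg$se_exposure_scale <= 0 || cfg$se_outcome_scale <= 0)
    stop("standard-error scales must be positive")
  if (!(cfg$pleiotropy_mode %in% .PLEIO_MODES))
    stop("pleiotropy_mode must be one of: ",
         paste(.PLEIO_MODES, collapse = ", "))
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    stop("maf_range must lie within (0, 0.5]")
  if (length(cfg$gamma_range) != 2L || diff(cfg$gamma_range) < 0)
    stop("gamma_range must be an increasing interval")
  for (r in c("palindromic_rate", "strand_flip_rate", "allele_swap_rate",
              "pleiotropy_frac"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0,1]")
  if (cfg$n_outliers < 0 || cfg$n_outliers > cfg$n_variants)
    stop("n_outliers must be between 0 and n_variants")
  class(cfg) <- "simConfig"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the [simConfig()] arguments.
#' @return a validated `"simConfig"`.
#' @export
readSimConfig <- function(path) {
  do.call(simConfig, yaml::read_yaml(path))
}

.NONPAL_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a two-sample summary-statistics study with known truth
#'
#' True instrument strengths are drawn uniformly from `gamma_range`
#' (oriented to the trait-increasing allele); direct pleiotropic effects
#' follow the configured mode; true outcome effects are
#' `theta_true * gamma + alpha`; observed betas add independent normal
#' noise at per-variant standard errors scaled by allele frequency; and
#' planted outliers displace the observed outcome beta by
#' `outlier_shift` outcome SEs.  The outcome file re-presents each
#' variant with configurable allele swaps and strand flips, so panels
#' must be harmonized before estimation.
#'
#' @param config a [simConfig()].
#' @return list with `exposure` and `outcome` ([MRPanel-class]) and
#'   `truth` (every latent quantity: `gamma`, `alpha`, `Gamma`,
#'   `theta_true`, `maf`, per-variant SEs, outlier/pleiotropy/swap/strand
#'   indicators, and the config).
#' @export
simulateTwoSample <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  J <- config$n_variants
  rsid <- sprintf("rs%04d", seq_len(J))
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  sefac <- sqrt(0.375 / (2 * maf * (1 - maf)))
  se_x <- config$se_exposure_scale * sefac
  se_y <- config$se_outcome_scale * sefac

  gamma <- stats::runif(J, config$gamma_range[1], config$gamma_range[2])
  alpha <- rep(0, J)
  pleio_set <- integer()
  if (config$pleiotropy_mode != "none" && config$pleiotropy_frac > 0) {
    n_pleio <- max(1L, round(config$pleiotropy_frac * J))
    pleio_set <- sort(sample.int(J, n_pleio))
    a <- switch(config$pleiotropy_mode,
      balanced = stats::rnorm(n_pleio, 0, config$pleiotropy_sd),
      directional = stats::rnorm(n_pleio, config$pleiotropy_mean,
                                 config$pleiotropy_sd),
      inside_violating = {
        z <- scale(gamma[pleio_set])[, 1]
        if (any(!is.finite(z))) z <- rep(0, n_pleio)
        config$pleiotropy_mean + config$pleiotropy_sd *
          (sqrt(0.5) * z + sqrt(0.5) * stats::rnorm(n_pleio))
      })
    alpha[pleio_set] <- a
  }
  Gamma <- config$theta_true * gamma + alpha

  beta_x <- stats::rnorm(J, gamma, se_x)
  beta_y <- stats::rnorm(J, Gamma, se_y)
  outlier_set <- integer()
  if (config$n_outliers > 0L) {
    outlier_set <- sort(sample.int(J, config$n_outliers))
    beta_y[outlier_set] <- beta_y[outlier_set] +
      config$outlier_shift * se_y[outlier_set]
  }

  ## allele presentation
  is_pal <- stats::runif(J) < config$palindromic_rate
  pick <- function(pool) pool[sample.int(nrow(pool), J, replace = TRUE), ,
                              drop = FALSE]
  np <- pick(.NONPAL_PAIRS); pp <- pick(.PAL_PAIRS)
  ea <- ifelse(is_pal, pp[, 1], np[, 1])
  oa <- ifelse(is_pal, pp[, 2], np[, 2])
  eaf_minor <- stats::runif(J) < 0.5
  eaf_x <- ifelse(eaf_minor, maf, 1 - maf)
  eaf_y <- pmin(1 - 1e-4, pmax(1e-4, eaf_x + stats::rnorm(J, 0, 0.005)))

  swap   <- stats::runif(J) < config$allele_swap_rate
  strand <- !is_pal & (stats::runif(J) < config$strand_flip_rate)
  o_ea <- ea; o_oa <- oa
  beta_y_pres <- beta_y; eaf_y_pres <- eaf_y
  o_ea[swap] <- oa[swap]; o_oa[swap] <- ea[swap]
  beta_y_pres[swap] <- -beta_y_pres[swap]
  eaf_y_pres[swap] <- 1 - eaf_y_pres[swap]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  o_ea[strand] <- comp[o_ea[strand]]
  o_oa[strand] <- comp[o_oa[strand]]

  pv <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)),
                            .Machine$double.xmin)
  exposure <- MRPanel(data.frame(
    rsid = rsid, chrom = as.character(sample.int(22, J, replace = TRUE)),
    pos = seq_len(J) * 1e5, effect_allele = ea, other_allele = oa,
    eaf = eaf_x, beta = beta_x, se = se_x, pval = pv(beta_x, se_x),
    n = 170000, stringsAsFactors = FALSE),
    exposureName = "exposure", genomeBuild = "GRCh37")
  outcome <- MRPanel(data.frame(
    rsid = rsid, chrom = exposure@data$chrom, pos = exposure@data$pos,
    effect_allele = o_ea, other_allele = o_oa, eaf = eaf_y_pres,
    beta = beta_y_pres, se = se_y, pval = pv(beta_y_pres, se_y),
    n = 247173, stringsAsFactors = FALSE),
    exposureName = "outcome", genomeBuild = "GRCh37")

  truth <- list(theta_true = config$theta_true, gamma = gamma, alpha = alpha,
                Gamma = Gamma, maf = maf, se_exposure = se_x,
                se_outcome = se_y, beta_exposure_obs = beta_x,
                beta_outcome_obs = beta_y, rsid = rsid,
                outliers = rsid[outlier_set],
                pleiotropic = rsid[pleio_set],
                palindromic = rsid[is_pal], swapped = rsid[swap],
                strand_flipped = rsid[strand], config = config)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a block-structured LD matrix
#'
#' Squared correlations are drawn uniformly from `r2_range` within each
#' block and are exactly zero between blocks; the matrix is symmetric
#' with unit diagonal.
#'
#' @param n_variants number of variants.
#' @param blocks partition of the variants: either an integer vector of
#'   block labels (length `n_variants`) or a list of index vectors; the
#'   default puts every variant in its own block (identity matrix).
#' @param r2_range within-block r-squared interval.
#' @param seed integer seed.
#' @param rsids optional variant names (default `rs0001...`).
#' @return symmetric LD matrix with rsid dimnames.
#' @export
simulateLDPanel <- function(n_variants, blocks = seq_len(n_variants),
                            r2_range = c(0.3, 0.95), seed, rsids = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.list(blocks)) {
    lab <- integer(n_variants)
    for (b in seq_along(blocks)) lab[blocks[[b]]] <- b
    if (any(lab == 0L) ||
        length(unlist(blocks)) != n_variants ||
        anyDuplicated(unlist(blocks)))
      stop("blocks must partition the variants")
    blocks <- lab
  }
  if (length(blocks) != n_variants)
    stop("blocks must partition the variants")
  if (is.null(rsids)) rsids <- sprintf("rs%04d", seq_len(n_variants))
  set.seed(as.integer(seed))
  m <- diag(1, n_variants)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) > 1L) {
      for (i in seq_along(idx)[-1]) for (j in seq_len(i - 1)) {
        r2 <- stats::runif(1, r2_range[1], r2_range[2])
        m[idx[i], idx[j]] <- r2
        m[idx[j], idx[i]] <- r2
      }
    }
  }
  dimnames(m) <- list(rsids, rsids)
  m
}
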