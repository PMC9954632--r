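# Shared fixtures: all synthetic, built in code.

# Minimal harmonized instrument table straight from beta/se vectors.
makeHarm <- function(gx, gy, sx, sy, rsid = sprintf("v%02d", seq_along(gx))) {
  data.frame(rsid = rsid,
             beta_exposure = gx, se_exposure = sx,
             beta_outcome = gy, se_outcome = sy,
             stringsAsFactors = FALSE)
}

# Harmonized instruments drawn under the generator's study conditions,
# built from the truth record (harmonization itself is tested separately).
simHarm <- function(seed, ...) {
  sim <- simulateTwoSample(simConfig(seed = seed, ...))
  t <- sim$truth
  makeHarm(t$beta_exposure_obs, t$beta_outcome_obs,
           t$se_exposure, t$se_outcome, rsid = t$rsid)
}

# Independent weighted-least-squares oracles via stats::lm (QR path,
# not the package's normal-equations code).
lmIVW <- function(d) {
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = d,
                   weights = 1 / d$se_outcome^2)
  s <- summary(fit)$sigma
  list(theta = unname(stats::coef(fit)[1]),
       se_fixed = sqrt(stats::vcov(fit)[1, 1]) / s)
}

lmEgger <- function(d) {
  flip <- ifelse(d$beta_exposure < 0, -1, 1)
  gx <- d$beta_exposure * flip
  gy <- d$beta_outcome * flip
  fit <- stats::lm(gy ~ gx, weights = 1 / d$se_outcome^2)
  s <- summary(fit)$sigma
  co <- stats::coef(fit)
  ses <- sqrt(diag(stats::vcov(fit))) / s
  list(intercept = unname(co[1]), slope = unname(co[2]),
       se_intercept = unname(ses[1]), se_slope = unname(ses[2]),
       q = sum(stats::resid(fit)^2 / d$se_outcome^2))
}

# A small well-formed panel for IO tests.
toyPanel <- function(n = 3) {
  MRPanel(data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.1, 0.4, length.out = n),
    beta = seq(0.05, 0.15, length.out = n),
    se = rep(0.01, n),
    pval = rep(1e-8, n), n = 1e5, stringsAsFactors = FALSE), "PC1")
}
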