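test_that("Wald ratio arithmetic and error handling", {
  e <- waldRatio(makeHarm(0.1, 0.02, 0.004, 0.01))
  expect_equal(theta(e), 0.2)
  expect_equal(stdError(e), 0.1)
  expect_equal(confint(e), c(lower = 0.2 - 1.96 * 0.1,
                             upper = 0.2 + 1.96 * 0.1))

  e0 <- waldRatio(makeHarm(0.15, 0, 0.004, 0.01))
  expect_equal(theta(e0), 0)
  expect_equal(oddsRatio(e0), 1)

  en <- waldRatio(makeHarm(-0.15, 0.03, 0.004, 0.006))
  expect_equal(theta(en), -0.2)
  expect_equal(stdError(en), 0.04)

  expect_error(waldRatio(makeHarm(0, 0.02, 0.004, 0.01)), "undefined ratio")
})

test_that("IVW on proportional data is exact with zero heterogeneity", {
  gx <- c(0.05, 0.08, 0.1)
  d <- makeHarm(gx, 0.2 * gx, 0.004, 0.01)
  f <- mrIVW(d, "fixed")
  r <- mrIVW(d, "random")
  expect_equal(theta(f$estimate), 0.2, tolerance = 1e-12)
  expect_equal(f$diagnostics@qStatistic, 0, tolerance = 1e-20)
  expect_equal(stdError(f$estimate), stdError(r$estimate))
  expect_equal(theta(f$estimate), theta(r$estimate))
})

test_that("IVW matches a grid-search weighted-least-squares oracle at J=2", {
  d <- makeHarm(c(0.1, 0.2), c(0.01, 0.06), 0.004, c(0.01, 0.01))
  est <- theta(mrIVW(d, "fixed")$estimate)
  # brute-force minimization of the weighted residual sum over a fine grid
  grid <- seq(-1, 1, by = 1e-5)
  rss <- vapply(grid, function(th)
    sum((d$beta_outcome - th * d$beta_exposure)^2 / d$se_outcome^2),
    numeric(1))
  expect_equal(est, grid[which.min(rss)], tolerance = 1e-4)
  expect_error(mrIVW(makeHarm(0.1, 0.02, 0.004, 0.01)), "waldRatio")
})

test_that("single-instrument IVW formulas reduce to the Wald ratio", {
  gx <- 0.08; gy <- 0.02; sy <- 0.012
  w <- mrIVW(makeHarm(c(gx, gx), c(gy, gy), 0.004, c(sy, sy) * sqrt(2)),
             "fixed")$estimate
  wald <- waldRatio(makeHarm(gx, gy, 0.004, sy))
  # duplicating one instrument at sqrt(2)-inflated SE reproduces it exactly
  expect_equal(theta(w), theta(wald), tolerance = 1e-12)
  expect_equal(stdError(w), stdError(wald), tolerance = 1e-12)
})

test_that("IVW is invariant to flipping any instrument's coded allele", {
  set.seed(31)
  d <- simHarm(31)
  base <- theta(mrIVW(d, "fixed")$estimate)
  for (j in c(1, 5, 12)) {
    d2 <- d
    d2$beta_exposure[j] <- -d2$beta_exposure[j]
    d2$beta_outcome[j] <- -d2$beta_outcome[j]
    expect_equal(theta(mrIVW(d2, "fixed")$estimate), base, tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact affine data and flags collinearity", {
  gx <- c(0.03, 0.05, 0.08, 0.1)
  d <- makeHarm(gx, 0.05 + 0.2 * gx, 0.004, 0.01)
  fit <- mrEgger(d, "fixed")
  expect_equal(theta(fit$estimate), 0.2, tolerance = 1e-10)
  expect_equal(unname(fit$intercept["estimate"]), 0.05, tolerance = 1e-10)
  expect_equal(fit$diagnostics@qStatistic, 0, tolerance = 1e-16)

  expect_error(mrEgger(makeHarm(rep(0.1, 4), rnorm(4), 0.004, 0.01)),
               "collinear")
  expect_error(mrEgger(makeHarm(c(0.1, 0.2), c(0.01, 0.02), 0.004, 0.01)),
               "insufficient")
})

test_that("I2GX approaches 1 for widely spread exposure betas", {
  d <- makeHarm(seq(0.5, 5, length.out = 10), rnorm(10), 0.001, 0.01)
  fit <- mrEgger(d)
  expect_gt(i2GX(fit$diagnostics), 0.999)
  expect_true(fit$diagnostics@nomeReliable)
})

test_that("IVW and Egger agree with lm oracles on random inputs", {
  set.seed(99)
  for (rep in 1:20) {
    J <- sample(3:40, 1)
    d <- makeHarm(runif(J, -0.2, 0.3), rnorm(J, 0, 0.05),
                  runif(J, 0.002, 0.01), runif(J, 0.005, 0.03))
    iv <- mrIVW(d, "fixed")
    or <- lmIVW(d)
    expect_equal(theta(iv$estimate), or$theta, tolerance = 1e-10)
    expect_equal(stdError(iv$estimate), or$se_fixed, tolerance = 1e-10)

    eg <- mrEgger(d, "fixed")
    oe <- lmEgger(d)
    expect_equal(theta(eg$estimate), oe$slope, tolerance = 1e-10)
    expect_equal(unname(eg$intercept["estimate"]), oe$intercept,
                 tolerance = 1e-10)
    expect_equal(stdError(eg$estimate), oe$se_slope, tolerance = 1e-10)
    expect_equal(unname(eg$intercept["se"]), oe$se_intercept,
                 tolerance = 1e-10)
    expect_equal(eg$diagnostics@qStatistic, oe$q, tolerance = 1e-8)

    # multiplicative random effects: same point estimate, scaled SE
    ivr <- mrIVW(d, "random")
    expect_equal(theta(ivr$estimate), theta(iv$estimate))
    scale <- max(1, sqrt(iv$diagnostics@qStatistic / (J - 1)))
    expect_equal(stdError(ivr$estimate), stdError(iv$estimate) * scale,
                 tolerance = 1e-12)
  }
})

test_that("Cochran's Q p-value is uniform under the null", {
  set.seed(123)
  nrep <- 1000; J <- 30
  pvals <- replicate(nrep, {
    gx <- runif(J, 0.03, 0.1)
    sy <- rep(0.008, J)
    d <- makeHarm(rnorm(J, gx, 0.004), rnorm(J, 0, sy), 0.004, sy)
    mrIVW(d, "fixed")$diagnostics@qPvalue
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("weighted median point estimator matches its definition", {
  # degenerate: all ratios equal
  gx <- c(0.05, 0.1, 0.2)
  wm <- weightedMedian(makeHarm(gx, 0.3 * gx, 0.004,
                                c(0.01, 0.02, 0.005)),
                       n_boot = 100, seed = 1)
  expect_equal(theta(wm), 0.3, tolerance = 1e-12)

  # equal weights, middle element at p = 0.5
  d <- makeHarm(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.09), 0.004, 0.01)
  wm2 <- weightedMedian(d, n_boot = 100, seed = 1)
  expect_equal(theta(wm2), 0.2, tolerance = 1e-12)

  # unequal weights vs an independent interpolated-quantile oracle
  d5 <- makeHarm(c(0.05, 0.08, 0.1, 0.12, 0.2),
                 c(0.012, 0.004, 0.031, 0.011, 0.05),
                 0.004, c(0.01, 0.02, 0.008, 0.015, 0.03))
  ratios <- d5$beta_outcome / d5$beta_exposure
  weights <- (d5$se_outcome / abs(d5$beta_exposure))^-2
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  S <- cumsum(w)
  p <- S - w / 2
  k <- max(which(p < 0.5))
  oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
  wm5 <- weightedMedian(d5, n_boot = 100, seed = 1)
  expect_equal(theta(wm5), oracle, tolerance = 1e-12)

  expect_error(weightedMedian(d5, n_boot = 50, seed = 1), "at least 100")
  expect_error(weightedMedian(d5[1:2, ], n_boot = 100, seed = 1),
               "insufficient")
  expect_error(weightedMedian(d5, n_boot = 100), "seed")
  # same seed, same bootstrap SE
  expect_equal(stdError(weightedMedian(d5, n_boot = 200, seed = 7)),
               stdError(weightedMedian(d5, n_boot = 200, seed = 7)))
})

test_that("leave-one-out flags the planted influential variant", {
  gx <- seq(0.04, 0.1, length.out = 8)
  d <- makeHarm(gx, -0.12 * gx, 0.004, 0.008)
  # homogeneous data: all J estimates identical
  loo <- leaveOneOut(d, model = "fixed")
  expect_equal(nrow(loo$results), 8)
  expect_equal(var(loo$results$theta), 0, tolerance = 1e-20)

  # planted extreme variant drives the estimate
  d$beta_outcome[3] <- d$beta_outcome[3] + 0.1
  full <- theta(mrIVW(d, "random")$estimate)
  loo2 <- leaveOneOut(d, model = "random")
  # exhaustive recomputation oracle
  manual <- vapply(seq_len(8), function(j)
    theta(mrIVW(d[-j, ], "random")$estimate), numeric(1))
  expect_equal(loo2$results$theta, manual, tolerance = 1e-12)
  expect_equal(which.max(abs(manual - full)), 3L)
  expect_equal(loo2$mostInfluential, d$rsid[which.min(abs(manual))])
})

test_that("plot-data tables have the stated structure", {
  d <- simHarm(17, n_variants = 12)
  iv <- mrIVW(d, "random")
  eg <- mrEgger(d, "random")
  fs <- funnelScatterData(d, list(ivw_random = iv$estimate,
                                  egger_slope = eg$estimate),
                          eg$diagnostics)
  expect_equal(nrow(fs$scatter), 12)
  expect_equal(nrow(fs$funnel), 12)
  expect_equal(fs$lines$intercept[fs$lines$method == "ivw_random"], 0)
  expect_equal(fs$lines$intercept[fs$lines$method == "egger_slope"],
               eg$diagnostics@eggerIntercept)
  expect_equal(fs$funnel$theta, d$beta_outcome / d$beta_exposure)
})

test_that("funnel asymmetry is centered on zero under balanced pleiotropy", {
  set.seed(77)
  slopes <- replicate(200, {
    J <- 30
    gx <- runif(J, 0.03, 0.1)
    alpha <- rnorm(J, 0, 0.01)
    sy <- rep(0.008, J)
    d <- makeHarm(rnorm(J, gx, 0.004), rnorm(J, -0.12 * gx + alpha, sy),
                  0.004, sy)
    fs <- funnelScatterData(d)
    unname(coef(lm(fs$funnel$theta ~ fs$funnel$precision))[2])
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})
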