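mkVar <- function(rsid, ea, oa, beta, se = 0.01, eaf = NA_real_) {
  list(rsid = rsid, effect_allele = ea, other_allele = oa,
       beta = beta, se = se, eaf = eaf)
}

test_that("allele coding differences are resolved pairwise", {
  # swapped coding: sign flip
  r <- harmonizePair(mkVar("rs1", "A", "G", 0.10, eaf = 0.3),
                     mkVar("rs1", "G", "A", 0.05, eaf = 0.7))
  expect_true(r$kept)
  expect_equal(r$row$beta_outcome, -0.05)
  expect_equal(r$row$action, "sign_flipped")
  expect_equal(r$row$eaf_outcome, 0.3)

  # opposite strand, same orientation
  r <- harmonizePair(mkVar("rs2", "C", "T", 0.10),
                     mkVar("rs2", "G", "A", 0.03))
  expect_true(r$kept)
  expect_equal(r$row$beta_outcome, 0.03)
  expect_equal(r$row$action, "strand_flipped")

  # opposite strand and swapped
  r <- harmonizePair(mkVar("rs3", "C", "T", 0.10, eaf = 0.2),
                     mkVar("rs3", "A", "G", 0.03, eaf = 0.8))
  expect_equal(r$row$beta_outcome, -0.03)
  expect_equal(r$row$action, "sign_flipped")

  # incompatible alleles: typed drop, no error
  r <- harmonizePair(mkVar("rs4", "A", "G", 0.1),
                     mkVar("rs4", "A", "C", 0.1))
  expect_false(r$kept)
  expect_equal(r$reason, "incompatible alleles")
})

test_that("palindromic variants are frequency-resolved or dropped", {
  # maximal ambiguity at eaf 0.5
  r <- harmonizePair(mkVar("rs1", "A", "T", 0.1, eaf = 0.50),
                     mkVar("rs1", "A", "T", 0.05, eaf = 0.10))
  expect_false(r$kept)
  expect_equal(r$reason, "ambiguous palindrome")

  # missing frequency drops too (conservative rule)
  r <- harmonizePair(mkVar("rs1", "A", "T", 0.1, eaf = 0.1),
                     mkVar("rs1", "A", "T", 0.05, eaf = NA))
  expect_false(r$kept)

  # concordant frequencies: kept as-is
  r <- harmonizePair(mkVar("rs1", "A", "T", 0.1, eaf = 0.1),
                     mkVar("rs1", "A", "T", 0.05, eaf = 0.12))
  expect_true(r$kept)
  expect_equal(r$row$beta_outcome, 0.05)
  expect_equal(r$row$action, "direct")

  # discordant frequencies imply a strand error: flipped
  r <- harmonizePair(mkVar("rs1", "A", "T", 0.1, eaf = 0.1),
                     mkVar("rs1", "A", "T", 0.05, eaf = 0.88))
  expect_true(r$kept)
  expect_equal(r$row$beta_outcome, -0.05)
  expect_equal(r$row$action, "sign_flipped")

  # window covering [0,1] drops every palindrome
  r <- harmonizePair(mkVar("rs1", "A", "T", 0.1, eaf = 0.1),
                     mkVar("rs1", "A", "T", 0.05, eaf = 0.12),
                     palindrome_window = c(0, 1))
  expect_false(r$kept)
})

test_that("harmonization is involution-safe", {
  sim <- simulateTwoSample(simConfig(seed = 11, palindromic_rate = 0.2,
                                     strand_flip_rate = 0.2))
  h1 <- harmonizePanels(sim$exposure, sim$outcome)
  d <- instruments(h1)
  for (i in seq_len(nrow(d))) {
    again <- harmonizePair(
      mkVar(d$rsid[i], d$effect_allele[i], d$other_allele[i],
            d$beta_exposure[i], d$se_exposure[i], d$eaf_exposure[i]),
      mkVar(d$rsid[i], d$effect_allele[i], d$other_allele[i],
            d$beta_outcome[i], d$se_outcome[i], d$eaf_outcome[i]))
    expect_true(again$kept)
    expect_equal(again$row$beta_outcome, d$beta_outcome[i])
    expect_equal(again$row$action, "direct")
  }
})

test_that("harmonization is invariant to the outcome file's allele coding", {
  for (seed in c(3, 7, 21)) {
    sim <- simulateTwoSample(simConfig(seed = seed, palindromic_rate = 0.1,
                                       strand_flip_rate = 0.1))
    flipped <- sim$outcome
    od <- instruments(flipped)
    tmp <- od$effect_allele
    od$effect_allele <- od$other_allele
    od$other_allele <- tmp
    od$beta <- -od$beta
    od$eaf <- 1 - od$eaf
    flipped <- MRPanel(od, exposureName = "outcome")

    h1 <- instruments(harmonizePanels(sim$exposure, sim$outcome))
    h2 <- instruments(harmonizePanels(sim$exposure, flipped))
    expect_equal(h1$rsid, h2$rsid)
    num <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome",
             "eaf_outcome")
    expect_equal(h1[num], h2[num], tolerance = 1e-12)
    expect_equal(h1$effect_allele, h2$effect_allele)
  }
})

test_that("LD pruning is greedy in p-value order and order-invariant", {
  # independent variants all kept
  p3 <- toyPanel(3)
  ld <- diag(1, 3); dimnames(ld) <- list(p3@data$rsid, p3@data$rsid)
  expect_equal(nrow(instruments(ldPrune(p3, ld))), 3)

  # dominance: stronger p wins within a correlated pair
  d <- data.frame(rsid = c("v1", "v2"), effect_allele = "A",
                  other_allele = "G", beta = 0.1, se = 0.01,
                  pval = c(1e-10, 1e-9), stringsAsFactors = FALSE)
  panel <- MRPanel(d)
  ld2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
                dimnames = list(c("v1", "v2"), c("v1", "v2")))
  pruned <- ldPrune(panel, ld2, r2_max = 0.01)
  expect_equal(instruments(pruned)$rsid, "v1")
  expect_equal(attr(pruned, "removed"), "v2")

  # brute-force check on a block-structured panel
  set.seed(5)
  J <- 20
  ld20 <- simulateLDPanel(J, blocks = rep(1:5, each = 4),
                          r2_range = c(0.0, 0.9), seed = 9)
  dd <- data.frame(rsid = rownames(ld20), effect_allele = "A",
                   other_allele = "G", beta = 0.1, se = 0.01,
                   pval = runif(J, 1e-12, 1e-6), stringsAsFactors = FALSE)
  panel20 <- MRPanel(dd)
  kept <- instruments(ldPrune(panel20, ld20, r2_max = 0.05))$rsid
  for (a in kept) for (b in kept)
    if (a != b) expect_lte(ld20[a, b], 0.05)
  # maximality: every removed variant conflicts with a kept one
  for (r in setdiff(dd$rsid, kept))
    expect_true(any(ld20[r, kept] > 0.05))

  # row order does not matter
  shuf <- MRPanel(dd[sample(J), ])
  expect_equal(instruments(ldPrune(shuf, ld20, r2_max = 0.05))$rsid, kept)

  # unknown rsid errors by name
  dd2 <- rbind(dd, data.frame(rsid = "rs_missing", effect_allele = "A",
                              other_allele = "G", beta = 0.1, se = 0.01,
                              pval = 1e-8))
  expect_error(ldPrune(MRPanel(dd2), ld20, 0.05), "rs_missing")
})

test_that("proxy search respects the r2 threshold and tie-breaks", {
  out <- MRPanel(data.frame(
    rsid = c("p1", "p2"), effect_allele = "A", other_allele = "G",
    beta = c(0.02, 0.03), se = 0.01, pval = c(0.01, 0.001),
    stringsAsFactors = FALSE), "outcome")
  ids <- c("target", "p1", "p2")
  ld <- diag(1, 3); dimnames(ld) <- list(ids, ids)

  ld["target", "p1"] <- ld["p1", "target"] <- 0.95
  expect_equal(findProxy("target", ld, out, 0.8)$rsid, "p1")

  ld["target", "p1"] <- ld["p1", "target"] <- 0.79
  expect_null(findProxy("target", ld, out, 0.8))

  # tie on r2: smaller outcome p-value wins
  ld["target", "p1"] <- ld["p1", "target"] <- 0.9
  ld["target", "p2"] <- ld["p2", "target"] <- 0.9
  expect_equal(findProxy("target", ld, out, 0.8)$rsid, "p2")

  expect_error(findProxy("absent", ld, out), "absent")
})

test_that("panel harmonization substitutes proxies and logs missing data", {
  sim <- simulateTwoSample(simConfig(n_variants = 6, seed = 2,
                                     palindromic_rate = 0,
                                     strand_flip_rate = 0))
  od <- instruments(sim$outcome)
  missing_rsid <- od$rsid[1]
  od_extra <- od
  od_extra$rsid[1] <- "rsPROXY"   # the missing instrument's stand-in
  outcome <- MRPanel(od_extra, exposureName = "outcome")

  ids <- c(missing_rsid, od_extra$rsid)
  ld <- diag(1, length(ids)); dimnames(ld) <- list(ids, ids)
  ld[missing_rsid, "rsPROXY"] <- ld["rsPROXY", missing_rsid] <- 0.92

  h <- harmonizePanels(sim$exposure, outcome, ld = ld)
  d <- instruments(h)
  expect_true(missing_rsid %in% d$rsid)
  row <- d[d$rsid == missing_rsid, ]
  expect_equal(row$action, "proxy_substituted")
  expect_equal(row$proxy_rsid, "rsPROXY")
  # exposure side stays that of the original instrument
  e <- instruments(sim$exposure)
  expect_equal(row$beta_exposure, e$beta[e$rsid == missing_rsid])

  # without LD: dropped and counted
  h2 <- harmonizePanels(sim$exposure, outcome)
  expect_true(missing_rsid %in% dropLog(h2)$rsid)
  expect_equal(dropLog(h2)$reason[dropLog(h2)$rsid == missing_rsid],
               "no outcome data")
  expect_equal(nrow(instruments(h2)) + nrow(dropLog(h2)), 6)
})
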