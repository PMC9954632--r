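---
title: "Methods: two-sample MR for body-shape phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for body-shape phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeMR)
```

## The problem and the model

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from two independent GWAS. Here the exposure is a
composite body-shape phenotype — a principal component of six
anthropometric traits (height, weight, BMI, waist circumference, hip
circumference, waist-to-hip ratio) — measured in SD units, and the
outcome is a disease (log odds ratio scale). For each instrument $j$ we
observe $\hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2)$ (variant–exposure)
and $\hat\Gamma_j \sim N(\Gamma_j, \sigma_{Yj}^2)$ (variant–outcome).
Under the IV assumptions (relevance, no confounding, exclusion
restriction) and a linear structural model,
$\Gamma_j = \theta\,\gamma_j + \alpha_j$, where $\theta$ is the causal
log-OR per 1 SD and $\alpha_j$ is variant $j$'s direct (pleiotropic)
effect, zero for a valid instrument.

The estimators:

* **Wald ratio** $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$, first-order
  delta-method SE $\sigma_{Yj}/|\hat\gamma_j|$. The second-order term is
  deliberately omitted: the instruments this design selects are
  genome-wide significant, so $|\hat\gamma_j|/\sigma_{Xj} \gtrsim 5.5$
  and the correction is negligible.
* **IVW**: weighted regression of $\hat\Gamma$ on $\hat\gamma$ through
  the origin with weights $\sigma_{Yj}^{-2}$; Cochran's
  $Q=\sum_j \sigma_{Yj}^{-2}(\hat\Gamma_j-\hat\theta\hat\gamma_j)^2$ on
  $J-1$ df. The random-effects flavour is *multiplicative* with a scale
  floor of 1 — the SE is multiplied by $\max(1,\sqrt{Q/(J-1)})$ and the
  point estimate is unchanged. An additive random-effects model is not
  implemented; the multiplicative convention matches the standard
  summary-data MR toolchain this package is meant to be comparable
  with.
* **MR-Egger**: WLS with intercept after re-orienting every instrument
  to $\hat\gamma_j > 0$ (flipping both betas, which leaves $\alpha_j$'s
  orientation intact). The intercept estimates the mean directional
  pleiotropy; the slope is consistent under InSIDE. $I^2_{GX} =
  \max(0, (Q_{GX}-(J-1))/Q_{GX})$, with $Q_{GX}$ the
  $\sigma_{Xj}^{-2}$-weighted dispersion of the oriented
  $\hat\gamma_j$, quantifies regression-dilution risk (NOME); results
  are annotated unreliable below 0.90 but still reported.
* **Weighted median**: ratios sorted ascending with normalized weights
  $(\sigma_{Yj}/|\hat\gamma_j|)^{-2}$, midpoint cumulative positions
  $p_j = S_{j-1} + w_j/2$, linear interpolation at $p=0.5$ (clamped to
  the extreme ratios outside $[p_1, p_J]$). SE by parametric bootstrap:
  both betas redrawn from their sampling distributions, default 1000
  resamples, seed mandatory.
* **MR-PRESSO**: observed statistic
  $\mathrm{RSS}=\sum_j \sigma_{Yj}^{-2}(\hat\Gamma_j -
  \hat\theta_{-j}\hat\gamma_j)^2$ with $\hat\theta_{-j}$ the IVW
  estimate excluding $j$; the null sample redraws both betas
  ($\hat\Gamma^*_j$ centred on $\hat\theta_{-j}\hat\gamma_j$) and
  recomputes RSS identically, including the replicate's own
  leave-one-out estimates. Per-variant outlier p-values are
  Bonferroni-multiplied by $J$; the distortion test compares the
  random-effects IVW with and without flagged outliers against random
  same-size removals.

All p-values are two-sided normal by default (a t-option on $J-2$ df is
exposed for Egger but off, matching the normal-theory CI presentation
this design reports); all CIs are $\theta \pm 1.96\,\mathrm{se}$, with
the literal constant 1.96, exponentiated for OR-per-1-SD reporting.

## Harmonization rules

Matching is by rsid and alleles, never by genomic coordinates. For a
non-palindromic pair: identical coding is kept as-is; swapped coding
flips the outcome beta's sign and complements its frequency; a pure
strand complement relabels only; strand complement plus swap does both
(recorded as `sign_flipped` — the action enum keeps the *net* effect on
the beta). Palindromic (A/T, C/G) variants are aligned by effect-allele
frequency; they are dropped as ambiguous when either study's frequency
is missing or falls inside the configurable window (default 0.42–0.58,
a common compromise between retention and strand-error risk; a window
of [0, 1] reproduces "drop all palindromes"). Harmonization never
raises an error on a data row: every variant ends either in the kept
set or in the drop log with a typed reason, and the two always sum to
the input panel.

LD pruning is greedy in ascending exposure p-value order (ties by rsid):
a variant is kept iff its $r^2$ with every already-kept variant is at
most the threshold (default 0.01). The source design names only the
threshold; greedy p-value ordering is the declared convention because it
matches standard clumping and is deterministic and order-invariant.

Proxy substitution (default $r^2 \ge 0.8$) recovers instruments absent
from the outcome GWAS: the proxy's outcome beta and SE are adopted
unchanged while the exposure association stays the original
instrument's. Because the LD input carries $r^2$ only (no signed $D'$ or
haplotype information), no allele alignment between proxy and original
is attempted; users supplying proxies across strands should pre-align
them. Instruments with no outcome data and no proxy are dropped and
counted.

## What the generator emulates — and what it does not

`simulateTwoSample()` encodes the default study conditions: $J = 30$
instruments (a PC1-sized panel), true causal OR per SD of 0.89
($\theta=\log 0.89$), instrument strengths uniform on 0.03–0.10 SD per
allele oriented to the trait-increasing allele, standard errors scaled
by $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$ from a scale of 0.004
(exposure, a ~170k-sample GWAS) and 0.008 (outcome, a ~247k
case-control GWAS), minor-allele frequencies uniform on 0.05–0.5, and a
presentation layer with 5% palindromic variants, 5% strand flips and
30% allele-coding swaps so every harmonization path is exercised.
Pleiotropy modes: `none`, `balanced` (zero-mean $\alpha_j$),
`directional` (mean 0.03 by default, the magnitude of Egger intercepts
this design is powered for), and `inside_violating` ($\alpha_j$
correlated ~0.7 with $\gamma_j$); `pleiotropy_frac` restricts pleiotropy
to a subset (0.4 gives the "40% invalid instruments" regime). Outliers
are planted by displacing the observed outcome beta by a multiple
(default 10) of its SE.

The generator does **not** emulate: genotype-level sampling (LD is an
input, not computed), winner's-curse selection of instruments, sample
overlap between the two GWAS, correlated outcome GWASs sharing
controls, or non-normal summary-statistic errors. Passing calibration
tests therefore demonstrates correctness of the estimators under the
stated sampling model, not robustness to those real-data features.

`simulateAnthropometrics()` builds the six traits as correlated
lognormals. The default correlation target is constructed from a
4-trait base (log height, weight, WC, HC, calibrated to adult female
anthropometry) with log BMI and log WHR induced by their defining
ratios plus 5% independent measurement noise — which keeps the 6×6
matrix full-rank positive definite and the simulated BMI/WHR
ratio-consistent up to that noise. Its PCA reproduces the qualitative
body-shape pattern (PC1 common-signed with height loading least, PC2
contrasting height against WHR, PC1 > PC2 > PC3); the PC1
variance-explained band declared for testing is 0.55–0.75, around the
~64% reported for this trait set in the literature. This is a
qualitative emulation: the originating cohort's covariance structure is
not published, so no numeric reproduction is attempted.

## Numerical choices

* Chi-square p-values are floored at the smallest positive double so a
  gigantic Q never yields an invalid $p = 0$.
* All simulation p-values carry the $+1$ finite-sample correction,
  $(1+\#\{\text{sim}\ge\text{obs}\})/(n_{\mathrm{sim}}+1)$, so they are
  never exactly zero and downstream $\log p$ stays finite.
* MR-PRESSO's default $n_{\mathrm{sim}} = 1000$ (configurable); the
  observed RSS is simulation-free, so it is invariant to
  $n_{\mathrm{sim}}$ and the whole result is bit-reproducible for a
  fixed seed.
* Egger collinearity (all $\hat\gamma_j$ equal) and a zero exposure
  beta in the Wald ratio are hard errors; estimator preconditions
  ($J \ge 2$ for IVW, 3 for Egger/median/leave-one-out, 4 for
  MR-PRESSO) fail with messages that direct the caller to the
  applicable method.
* Weighted-median ties in the cumulative positions cannot occur with
  positive weights; interpolation uses the strictly increasing
  midpoint grid.
* The pipeline derives one seed per analysis cell from the plan seed
  (`seed + 1000 i + j`), keeping reruns byte-identical while keeping
  cells independent.

## Design decisions taken where the design was open

* **Headline model per cell**: fixed-effects IVW is the primary
  estimator, but when the Cochran-Q p-value is below 0.05 the
  random-effects estimate is flagged as the headline, mirroring the
  reporting convention of heterogeneity-aware MR studies. Both are
  always computed; the rule is total (every cell is flagged one way or
  the other).
* **Distortion "ρ"**: the distortion result reports the signed
  coefficient $(\theta_{\setminus\mathrm{out}} - \theta_{\mathrm{all}})
  / |\theta_{\setminus\mathrm{out}}|$ *and* its simulation p-value
  separately, because published summaries are ambiguous about which of
  the two a "ρ distortion" denotes; either reading is recoverable from
  the result object.
* **Instrument counts are reported, not arbitrated**: loaders and
  ledgers count what they keep and drop; discrepancies between nominal
  and effective panel sizes (e.g. a variant lost for lack of outcome
  data) surface in the harmonization ledger rather than being silently
  reconciled.
* **Partial-failure tolerance**: sub-type outcome GWASs can have too
  few cases for some estimators; a cell-level failure (e.g. Egger with
  $J<3$) is recorded in that cell while the rest of the grid completes.
* **No multiple-testing correction across cells**: the grid reports
  two-sided p < 0.05 per cell, stated explicitly in the report header,
  matching the reporting convention of the design this package
  implements.

## Problem sizes used in the test suite

Calibration tests run at the study conditions: $J=30$, 1000 replicates
for IVW bias/coverage and Egger intercept recovery, 500 for the
weighted-median robustness comparison, 2000 for type-I error, 200
replicates at $n_{\mathrm{sim}}=1000$ for MR-PRESSO detection and null
calibration, and 100 random instances ($J \in 3..50$) for the
weighted-least-squares oracle equivalence. These sizes give Monte-Carlo
standard errors comfortably below the asserted tolerances while keeping
the whole suite at a few minutes on one CPU.

## Known limitations

* Proxy substitution cannot sign-align across strands from $r^2$-only
  LD input (see above).
* The weighted-median bootstrap redraws exposure betas around the
  *observed* values, the standard parametric approximation; at very
  weak instrument strength its SE can be optimistic.
* $I^2_{GX}$ is computed from the re-oriented exposure betas; with
  near-zero strengths the orientation step itself contributes a small
  upward bias to $Q_{GX}$, which is immaterial for genome-wide
  significant instruments.
* MR-PRESSO's outlier test inherits the conservativeness of Bonferroni;
  with many moderate outliers the global test can reject while no
  single variant is flagged.
* The pipeline treats outcome GWASs as independent; shared controls
  across sub-type analyses induce cross-cell correlation the report
  does not model.
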