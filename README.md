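# shapeMR

Two-sample Mendelian randomization (MR) for composite body-shape
phenotypes. The package targets a recurring study design in cancer and
cardiometabolic epidemiology: an exposure described by principal
components of anthropometric traits (height, weight, BMI, waist and hip
circumference, waist-to-hip ratio), instrumented by GWAS-significant
variants, tested against a disease outcome (e.g. breast cancer risk and
its hormone-receptor sub-types) using only published summary statistics
from two non-overlapping GWAS.

It provides, end to end:

* **Summary-statistics IO** — tab-separated files (gzip accepted) with a
  column-synonym dialect so GIANT-style and BCAC-style headers both load
  without editing; per-row validation with a total rejection log.
* **Instrument preparation** — allele harmonization onto a shared effect
  allele (sign flips, strand complements, frequency-resolved
  palindromes), greedy LD pruning in p-value order (default r² ≤ 0.01),
  and proxy substitution for instruments missing from the outcome GWAS
  (default r² ≥ 0.8).
* **Estimation** — per-variant Wald ratios; inverse-variance weighted
  (IVW) estimates under fixed and multiplicative random effects;
  MR-Egger with its intercept test and the I²GX/NOME diagnostic; the
  weighted-median estimator with a parametric bootstrap.
* **Outlier and influence diagnostics** — Cochran's Q, MR-PRESSO
  (global, per-variant outlier and distortion tests), leave-one-out.
* **A synthetic-data generator** with full ground truth, so calibration
  (bias, CI coverage, type-I error, outlier detection rates) is testable
  without any data download.
* **A pipeline** that runs an exposures × outcomes grid and emits a
  forest-style results table, a structured JSON report, and a
  STROBE-MR-style reporting checklist.

## The model

For variant *j*, let γ̂ⱼ (SE σ_Xj) be its association with the exposure
in SD units and Γ̂ⱼ (SE σ_Yj) its log odds ratio for the outcome. Under
the IV assumptions the per-variant Wald ratio θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ estimates the
causal log-OR per 1 SD of exposure, with first-order SE σ_Yj/|γ̂ⱼ|. The
fixed-effects IVW estimate combines them as a weighted regression
through the origin:

θ̂ = Σⱼ γ̂ⱼΓ̂ⱼσ_Yj⁻² / Σⱼ γ̂ⱼ²σ_Yj⁻² ,  se(θ̂) = (Σⱼ γ̂ⱼ²σ_Yj⁻²)^(−1/2)

Cochran's Q = Σⱼ σ_Yj⁻²(Γ̂ⱼ − θ̂γ̂ⱼ)² on J−1 df measures heterogeneity;
under the multiplicative random-effects model the SE is inflated by
max(1, √(Q/(J−1))). MR-Egger adds an intercept β₀ (the average
directional pleiotropic effect); the weighted median is consistent when
valid instruments carry at least half the weight; MR-PRESSO compares
leave-one-out weighted residual sums of squares against a parametric
simulation to find outliers. All confidence intervals are θ ± 1.96·se
on the log-OR scale, exponentiated for reporting as OR per 1 SD.

## Worked example

```r
library(shapeMR)

# A synthetic study under the package's default conditions: 30 instruments,
# true OR per 1 SD = 0.89, balanced pleiotropy inducing heterogeneity.
sim <- simulateTwoSample(simConfig(seed = 42, pleiotropy_mode = "balanced",
                                   pleiotropy_sd = 0.01))
h <- harmonizePanels(sim$exposure, sim$outcome)
h
#> MRHarmonized: exposure -> outcome
#>   29 instrument(s) kept, 1 dropped
#>   actions: direct=20, sign_flipped=8, strand_flipped=1

mrIVW(h, "random")$estimate
#> MREstimate [ivw_random] OR per 1 SD = 0.903 (95% CI 0.848-0.962), p = 0.0016, J = 29

eg <- mrEgger(h, "random")
eg$diagnostics
#> Cochran's Q = 72.616 on 27 df, p = 4.71e-06
#> Egger intercept = 0.0025 (95% CI -0.0128-0.0178), p = 0.752
#> I2GX = 0.969 (NOME plausible)

weightedMedian(h, seed = 1)
#> MREstimate [weighted_median] OR per 1 SD = 0.894 (95% CI 0.839-0.953), p = 0.000536, J = 29

mrPresso(h, seed = 1)
#> MR-PRESSO: RSS = 78.3111, global p = 0.000999 (n_sim = 1000)
#>   outliers: rs0008, rs0024
#>   distortion coefficient = 0.2888, p = 0.01898
```

Reading: one of 30 variants was dropped during harmonization (an
ambiguous palindrome); the random-effects IVW estimates a 9.7% lower
odds per SD of the exposure (true value: 11%), with strong heterogeneity
across instruments (Q p < 10⁻⁵) but no directional pleiotropy (Egger
intercept p = 0.75, I²GX above the 0.90 reliability bar); the weighted
median agrees; MR-PRESSO attributes the heterogeneity mainly to two
variants whose removal does shift the estimate (distortion p ≈ 0.02).

The same analysis runs over a grid via `analysisPlan()`/`runPlan()`,
from a YAML config via `loadPlan()`, or from the shell through the thin
wrapper in `inst/scripts/mr_pipeline.R` (subcommands `simulate`,
`analyze`, `report`).

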