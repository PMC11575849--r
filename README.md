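# benthoforce

Analysis of the hydraulic forces experienced by fixed fish bodies in a
laboratory flow channel, for researchers in fish biomechanics and movement
ecology. A benthic fish body (preserved round goby, 3D-printed replica, or
a rubber ball) is held on a 0.10 m fixation stick at four
position × substrate treatments — Column Smooth (CS), Column Rough (CR),
Bottom Rough (BR), Bottom Smooth (BS) — in 0.95 m/s flow, while a
three-axis sensor records torque X/Y and force Z at 1000 Hz for 60 s. The
package implements the full analysis chain:

* **Force processing** — moment-arm conversion `F = M / r`, and the per-run
  summary `F_3D = sqrt(F_X² + F_Y² + F_Z²)` on the channel means
  (mean-then-norm), plus a signal-to-noise ratio defined as mean/s.d. of
  the instantaneous 3D force magnitude.
* **Morphometry** — fineness ratio `TL / sqrt(HW · BD)` (1.00 for a
  sphere, ≈ 5.2 for the study fish), Reynolds number `ϱUL/μ`, quartile
  fin-spread and body-arch classes, sex ratio.
* **Treatment statistics** — Shapiro–Wilk screen; Kruskal–Wallis with rank
  eta-squared effect size `(H − k + 1)/(n − k)`; Dunn's pairwise z tests
  with Bonferroni correction; an inverse-Gaussian log-link GLM of per-run
  `F_3D` on sex, wet weight, lengths and shape classes.
* **Spectral comparison** — Welch PSDs (256-sample Hann windows, the
  3.90625 Hz grid on which the published peak frequencies lie), median
  curves per treatment, top-5 peak tables.
* **CNN classification** — smoothing-kernel augmentation (widths 5/15/25),
  10× decimation, six 10 s segments per run, leakage-free balanced 3-fold
  cross-validation, and a four-block residual 1D convolutional network
  (vectorised base R with analytic backprop) evaluated by per-class
  accuracy `Ac_a = Cpred_a / (Cpred_a + Fpred_b + Fpred_c + Fpred_d)` and
  F1.
* **Synthetic flume experiment** — a seeded generator calibrated to the
  published treatment means, s.d.s, SNRs and spectral peak sets, so the
  whole pipeline is testable without the (unpublished) raw recordings.

## Worked example

Simulate the study-scale experiment (112 fish × 4 treatments) at run level
and run the statistical battery:

```r
library(benthoforce)
tab <- simulate_run_table(cohort_config(seed = 1), signal_config(seed = 2))
aggregate_treatments(tab, "F3D_N")
#>   object_class treatment   mean     sd   n
#>      preserved        CS 0.0702 0.0229 112
#>      preserved        CR 0.0813 0.0254 112
#>      preserved        BR 0.0733 0.0226 112
#>      preserved        BS 0.0733 0.0233 112
treatment_stats(tab)
#> Shapiro-Wilk: W = 0.959, p = 9.09e-10
#> Kruskal-Wallis: H = 13.36 (df = 3), p = 0.00392, eta^2 = 0.023
#> Dunn pairwise (Bonferroni):
#>   pair group1 group2      z    p_raw p_adjusted
#>  BR-BS     BR     BS  0.214 0.830819    1.00000
#>  BR-CR     BR     CR -2.300 0.021472    0.12883
#>  BR-CS     BR     CS  1.235 0.216659    1.00000
#>  BS-CR     BS     CR -2.513 0.011963    0.07178
#>  BS-CS     BS     CS  1.022 0.306871    1.00000
#>  CR-CS     CR     CS  3.535 0.000408    0.00245
```

The treatment means sit at their calibrated targets (column-rough highest
at ~0.077 N, column-smooth lowest at ~0.068 N), the force data are
non-normal (Shapiro–Wilk p << 0.05), the omnibus test detects a treatment
effect of small size, and the only Bonferroni-significant pair is CR vs
CS — the column-position substrate contrast. The morphometric GLM on the
same table recovers the planted shape effects:

```r
fit_invgauss_glm(tab)
#> Inverse-Gaussian log-link GLM
#>   n = 448, null deviance = 629.01, residual deviance = 537.16
#>                         Estimate Std. Error t value Pr(>|t|)
#> factor(FinSpreadClass)4  0.24097    0.04114    5.86  9.3e-09 ***
#> Arch_deg                 0.01278    0.00284    4.50  8.7e-06 ***
#> ...
```

Fin spread (class 4 vs 1: +0.24 on the log scale, planted 0.28) and body
arching (+0.0128 per degree, planted 0.010) emerge as significant force
predictors, as in the flume study.

For full-series work, `generate_experiment()` produces 60 s sensor records
(`summarize_experiment()`, `psd_by_treatment()`, `build_dataset()` +
`cross_validate()` consume them), and `run_pipeline()` drives all stages
from one config; `inst/scripts/benthoforce.R` is a command-line wrapper.

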