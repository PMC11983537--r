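# mrpath

Two-sample Mendelian randomization (MR) and two-step MR mediation analysis
over GWAS summary statistics, in tidy R.

## What problem this solves

Observational associations between modifiable exposures (education, sleep,
adiposity, diet) and immune-mediated kidney diseases such as IgA nephropathy
are prone to confounding and reverse causation. Two-sample MR sidesteps both
by using genetic variants as instruments: per-variant effect estimates on an
exposure come from one GWAS, effects on the outcome from another, and the
ratio identifies the causal effect under the instrumental-variable
assumptions. Two-step MR additionally decomposes an exposure's total effect
into the part running through a candidate mediator and the rest.

`mrpath` is for analysts who have summary-statistics tables (not
individual-level genotypes) and want the full pipeline as composable,
tested functions: instrument selection, allele harmonization, the standard
estimator battery with sensitivity diagnostics, multivariable MR, and the
mediation arithmetic — plus a summary-statistic simulator so every stage
can be exercised and calibrated without downloading anything.

## The statistics at the core

For harmonized variant *j* with exposure effect β<sub>Xj</sub> (SE
se<sub>Xj</sub>) and outcome effect β<sub>Yj</sub> (SE se<sub>Yj</sub>):

- **Wald ratio** r<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>, first-order
  SE se<sub>Yj</sub>/|β<sub>Xj</sub>|.
- **IVW**: with weights w<sub>j</sub> = β<sub>Xj</sub>²/se<sub>Yj</sub>²,
  b = Σw<sub>j</sub>r<sub>j</sub>/Σw<sub>j</sub>, fixed-effect SE
  (Σw<sub>j</sub>)<sup>−1/2</sup>; Cochran's Q = Σw<sub>j</sub>(r<sub>j</sub> − b)²,
  and when Q rejects (p < 0.05) the SE is inflated by √(Q/(n−1))
  (multiplicative random effects, floored at 1).
- **MR-Egger**: weighted regression of β<sub>Yj</sub> on β<sub>Xj</sub>
  *with* intercept after orienting β<sub>Xj</sub> ≥ 0; a non-zero intercept
  indicates directional horizontal pleiotropy.
- **Weighted median**: the interpolated 50th percentile of the
  weight-ordered ratios; SE by seeded parametric bootstrap.
- **MR-PRESSO**: leave-one-out residual sum of squares with a simulated
  null for the global test, per-variant outlier tests (Bonferroni), and a
  distortion test comparing raw and outlier-corrected IVW estimates.
- **MVMR**: weighted multiple regression of β<sub>Yj</sub> on several
  exposure-effect columns without intercept — each coefficient is a direct
  effect conditional on the other exposures.
- **Mediation**: with α (exposure→mediator, IVW), β₁ (mediator→outcome
  adjusted for the exposure, MVMR) and total effect β (IVW), the indirect
  effect is α·β₁ with delta-method SE √(α²se<sub>β₁</sub>² + β₁²se<sub>α</sub>²),
  and the proportion mediated is 100·α·β₁/β with a bootstrap CI.

Instrument selection applies, in order: exposure p < 5×10⁻⁸; MAF > 0.01;
greedy LD clumping (r² 0.001, 10,000 kb); exclusion of variants associated
with the outcome at p < 0.001; exclusion of weak instruments with per-SNP
F = R²(n−k−1)/(k(1−R²)) < 10. All thresholds are configurable.

## Worked example

The package bundles the published path-coefficient estimates for the
educational-attainment → IgA-nephropathy pathway (three mediators) and
reruns the mediation arithmetic:

```r
library(mrpath)
mediation_table(ea_igan_estimates(), n_boot = 1000, seed = 4)
```

```
             mediator indirect ci_low ci_high p_value proportion proportion_low proportion_high
1            insomnia  -0.0987 -0.175 -0.0227 0.01090      12.52           1.09            24.0
2     body mass index  -0.0871 -0.145 -0.0297 0.00296      11.06           2.51            19.6
3 waist circumference  -0.0783 -0.132 -0.0243 0.00451       9.93           1.79            18.1
```

Reading the first row: genetically higher educational attainment lowers
insomnia (α = −0.195), insomnia raises IgA-nephropathy risk after adjusting
for education (β₁ = 0.506), so −0.099 of the −0.788 total log-odds effect —
about 12.5% — runs through insomnia, with a delta-method 95% CI excluding
zero (p ≈ 0.011).

The same machinery runs end to end on simulated GWAS tables:

```r
st <- simulate_study(sim_config(seed = 42))   # truth: 12.5% mediated
res <- two_step_mediation(st$exposure, st$mediator, st$outcome,
                          thresholds = instrument_thresholds(p_outcome = 0),
                          seed = 7, mediator_label = "bmi")
res
#> Mediation through bmi
#>   alpha = -0.188, beta1 = 0.499, total = -0.784
#>   indirect = -0.094 (95% CI -0.104, -0.083), p = 5.55e-70
#>   proportion mediated = 11.97% (95% CI 10.62%, 13.33%)
```

(`p_outcome = 0` switches off the outcome-association screen, which is
counterproductive when the simulated outcome GWAS is as well powered as the
exposure GWAS — see the vignette.)

`run_pair()`, `run_bidirectional()` and `run_mediation_screen()` orchestrate
multi-study analyses from a single `run_config()` (or a YAML file) and write
results, harmonization audits, plot data and a JSON run log; `plot_mr_scatter()`,
`plot_mr_funnel()`, `plot_mr_loo()` and `plot_mr_forest()` draw the standard
figures.

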