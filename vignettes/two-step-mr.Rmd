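---
title: "Two-sample MR and two-step mediation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

`mrpath` implements a complete two-sample Mendelian randomization (MR)
pipeline over GWAS summary statistics: instrument selection, allele
harmonization, univariable estimators with sensitivity diagnostics,
MR-PRESSO outlier handling, multivariable MR (MVMR), and two-step
product-of-coefficients mediation. This vignette is the package's account of
the underlying models, the parameters that matter, the simulator used for
validation, and the design decisions taken where the methodology left room.

## The causal model and its assumptions

Each genetic variant used as an instrument is assumed to be (i) robustly
associated with the exposure, (ii) independent of exposure–outcome
confounders, and (iii) associated with the outcome only through the exposure
(no horizontal pleiotropy). Under these assumptions the per-variant Wald
ratio $r_j = \beta_{Yj}/\beta_{Xj}$ estimates the causal effect, and the
inverse-variance-weighted (IVW) combination

$$\hat b = \frac{\sum_j w_j r_j}{\sum_j w_j},
\qquad w_j = \frac{\beta_{Xj}^2}{\mathrm{se}_{Yj}^2}$$

is algebraically identical to weighted least squares of $\beta_{Yj}$ on
$\beta_{Xj}$ through the origin (a property the test suite verifies
numerically). The first-order ratio SE $\mathrm{se}_{Yj}/|\beta_{Xj}|$
ignores exposure-side noise — the usual "no measurement error" (NOME)
approximation. Its practical consequences are discussed under limitations.

MR-Egger relaxes assumption (iii) to the InSIDE condition (instrument
strength independent of direct effects) by adding an intercept; the
intercept estimates the average directional pleiotropy and its test
(p < 0.05) is the package's pleiotropy alarm. The weighted median is
consistent when at least half the total weight comes from valid
instruments. MR-PRESSO attacks the same problem variant by variant: the
observed leave-one-out residual sum of squares is compared with a
simulated null, individual variants with extreme residual contributions are
flagged (Bonferroni-adjusted, 0.05), and a distortion test quantifies how
much the flagged variants moved the IVW estimate.

Two-step mediation composes three of these estimates. Step 1 estimates the
exposure→mediator effect $\alpha$ by univariable IVW. Step 2 estimates the
mediator's *direct* effect on the outcome $\beta_1$ by MVMR with the
exposure as a covariable exposure — weighted multiple regression of outcome
effects on both effect columns, no intercept. With the total effect $\beta$
from univariable IVW, the indirect effect is $\alpha\beta_1$, its SE is the
first-order delta method $\sqrt{\alpha^2\mathrm{se}_{\beta_1}^2 +
\beta_1^2\mathrm{se}_\alpha^2}$ (no cross term: the estimates come from
different GWAS and are treated as independent — an approximation, since
$\alpha$ and $\beta$ share exposure instruments), and the proportion
mediated is $100\,\alpha\beta_1/\beta$. A mediator is *admitted* when both
$\alpha$ and $\beta_1$ are significant at 0.05.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `p_exposure` | 5×10⁻⁸ | p-value | genome-wide significance |
| `maf_min` | 0.01 | frequency | excludes rare, unstable instruments |
| `r2_max`, `window_kb` | 0.001, 10,000 | LD r², kb | near-independence of instruments |
| `p_outcome` | 0.001 | p-value | outcome-association exclusion (see below) |
| `f_min` | 10 | F statistic | conventional weak-instrument bound |
| `palindrome_band` | 0.08 | frequency half-width | drops palindromic SNPs with MAF > 0.42 |
| `n_boot` | 1000 | iterations | weighted-median SE, proportion CI |
| `n_sim` | 1000 | replicates | MR-PRESSO empirical null |

Notes on the less standard choices:

- **Outcome-association exclusion at p < 0.001.** This cut-off is far more
  permissive than genome-wide significance and is applied exactly as
  configured. It deserves care: the filter conditions on the outcome, so
  when the outcome GWAS is comparably powered to the exposure GWAS and the
  true causal effect is strong, *valid* instruments are outcome-associated
  below any such threshold and the filter removes exactly the variants one
  wants to keep. It is harmless in the typical setting where the binary
  outcome GWAS has far fewer effective cases than the exposure GWAS has
  samples. The package's simulation studies therefore run with
  `p_outcome = 0` (filter off); real-data configurations should choose the
  threshold in light of the outcome GWAS's power.
- **Palindromic band checked in both studies.** "Intermediate allele
  frequency" is read symmetrically as eaf ∈ (0.42, 0.58) — MAF above 0.42 —
  and a palindromic variant is dropped when *either* study falls in the
  band; this is the conservative reading, since a confident strand call
  needs both frequencies away from 0.5. Outside the band, orientation is
  inferred from whether the two frequencies lie on the same side of 0.5.
- **Per-SNP F with k = 1.** $F = R^2(n-k-1)/(k(1-R^2))$ with
  $R^2_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\beta_j^2$, the
  standardized-trait approximation ($R^2$ is not otherwise identifiable
  from summary statistics). An aggregate F over the retained set is also
  computed and logged.
- **Matching is rsID-keyed.** No chrom:pos fallback, no liftover, no
  reference-panel strand inference; indels and multi-allelic records are
  rejected at read time.

## Numerical and inferential choices

- Two-sided **normal** p-values throughout (not t): summary statistics come
  from large samples. No multiple-testing correction across exposures.
- **Multiplicative random effects** for IVW, floored at 1, selected
  automatically when Cochran's Q has p < 0.05; the floor guarantees the
  random-effects SE never undercuts the fixed-effect SE.
- The same multiplicative overdispersion (floored at 1) scales MR-Egger and
  MVMR coefficient covariances, for internal consistency.
- MR-Egger orients every variant so $\beta_{Xj} \ge 0$ before regression;
  the intercept is only interpretable in that orientation.
- MR-PRESSO empirical p-values carry the +1 correction (floor
  $1/(n_\mathrm{sim}+1)$); the per-variant outlier p is the plain simulated
  fraction, Bonferroni-multiplied by the number of instruments.
- Greedy clumping breaks p-value ties by lexicographic variant id, making
  the result independent of input row order. Without LD information,
  clumping is a warning no-op rather than a silent one.
- The **proportion-mediated CI** is, by default, the normal approximation
  `point ± 1.96 · sd(bootstrap draws)` rather than the percentile interval:
  published mediation tables of this design report intervals numerically
  symmetric about the estimate, which a percentile bootstrap would not
  generally produce. `type = "percentile"` is available. Bootstrap draws of
  the total effect with $|\beta^*| < 10^{-6}$ are rejected and redrawn (the
  ratio of normals has no finite moments); more than 50% rejections abort
  with an instability error.
- Degenerate inputs error with typed conditions (`mrpath_error_*`) rather
  than propagating NaN: zero exposure effects in ratios, constant exposure
  effects in Egger, collinear MVMR columns, all-variant outlier sets.

## The worked example and the total-effect ambiguity

`ea_igan_estimates()` bundles published path coefficients for the
educational attainment (EA) → IgA nephropathy pathway: per-mediator
$\alpha$ (EA→mediator, IVW) and $\beta_1$ (mediator→IgAN, EA-adjusted MVMR)
with SEs. Feeding them through `mediation_table()` reproduces the published
indirect effects (−0.099, −0.087, −0.078), delta-method CIs and z-test
p-values.

The bundled total effect is $\beta = -0.788$: the three published mediation
proportions (12.522%, 11.056%, 9.933%) are arithmetically consistent with
that value to four decimals, whereas the published headline odds ratio
0.433 implies $\log(0.433) = -0.837$. The two candidates presumably differ
in the instrument set behind the mediation-stage total effect; the package
reports which value it uses and makes no attempt to reconcile them. Its SE
(0.132) is derived from the headline OR's confidence interval. Published
p-values were evidently computed from unrounded internals: from the rounded
inputs the third z-test p is 0.0045 against a printed 0.004, so regression
tests compare p-values to one unit in the last printed digit while effects
and CI bounds match at three decimals exactly.

## What the simulator emulates

`simulate_study()` generates summary statistics directly — no
individual-level genotypes — under a linear structural model with two
instrument classes:

- exposure instruments with effects $\gamma_j \sim N(0, \texttt{gamma\_sd})$:
  marginal effects $\gamma_j$ on the exposure, $\alpha\gamma_j$ on the
  mediator, $(\tau + \alpha\beta_1)\gamma_j + \pi_j$ on the outcome;
- mediator instruments with effects $\delta_j$: zero on the exposure,
  $\delta_j$ on the mediator, $\beta_1\delta_j + \pi_j$ on the outcome.

Mediator-specific instruments are what identify the MVMR direct effect —
with shared instruments only, the two effect columns are proportional in
truth and $\beta_1$ is not estimable. Observed effects add noise with the
standardized-GWAS standard error $(2n\,\mathrm{maf}(1-\mathrm{maf}))^{-1/2}$;
binary-outcome effects are treated directly on the log-odds scale with the
same approximation (a simplification — no case/control imbalance is
modelled). Horizontal pleiotropy $\pi_j$ can be `none`, `balanced`
(zero-mean), `directional` (non-zero mean *along each instrument's
trait-increasing allele* — with symmetric instrument effects an unsigned
constant mean would cancel and be indistinguishable from balanced), or
`inside` ($\pi_j$ correlated with instrument strength, violating InSIDE).
LD can be injected block-diagonally with constant within-block r², feeding
the clumping tests; alleles avoid palindromic pairs unless requested.

Defaults are the package's reference study conditions: 100 + 100
instruments, all three GWAS at n = 100,000, $\alpha = -0.2$,
$\beta_1 = 0.5$, $\tau = -0.7$, hence a total effect of −0.8 and a true
proportion mediated of 12.5%; `gamma_sd = 0.05` puts selected-instrument
per-SNP F statistics in the tens-to-hundreds range, matching the span
reported for well-powered exposure GWAS (roughly 27–808).

What the simulator does **not** emulate: realistic allele-frequency
spectra, population stratification, sample overlap between the three GWAS,
LD beyond constant blocks, and case/control imbalance in the outcome. Tests
passing on simulated data therefore validate the estimators and the
pipeline's plumbing under clean sampling assumptions, not robustness to
those real-data complications.

## Validation suite problem sizes

The test suite exercises the arithmetic against independent oracles
(weighted `lm()` fits, brute-force interpolation) on ≤10-SNP fixtures at
10⁻¹⁰ relative tolerance, and the pipeline statistically: mean proportion
recovery over 200 simulated studies at the reference conditions; null
calibration of the Egger-intercept and MR-PRESSO global tests over 200
seeds (MR-PRESSO at 300 simulated replicates per call, which resolves a
0.05-level rejection comfortably); and planted-outlier detection over 100
seeds. These sizes keep the full suite in the minutes range on one core
while leaving Monte-Carlo error well below the tolerances being asserted.

## Known limitations

- **Finite-sample attenuation of the two-step estimate.** Instruments are
  selected at p < 5×10⁻⁸ in the same GWAS used for estimation, as in
  standard two-sample practice. The resulting winner's curse, together with
  the NOME approximation, attenuates each stage by 1–2% relative at the
  reference instrument strengths. The attenuations of $\hat\alpha$ and
  $\hat\beta$ (same instruments, same denominators) largely cancel in the
  proportion mediated; the residual downward bias — about 0.25 percentage
  points on a true 12.5% — comes from the MVMR mediator column and is
  visible in the recovery suite. Consistency improves with instrument
  strength; no winner's-curse correction is applied.
- The pipeline assumes biallelic, rsID-keyed SNPs; no proxy-variant search
  when an instrument is missing from the outcome GWAS (it is dropped and
  logged).
- No Steiger directionality filtering, mode-based estimators, robust IVW
  variants, MVMR-Egger, or conditional F diagnostics; `mvmr_fit()` notes
  the latter's absence in `cond_note`.
- Mediators are analysed one at a time; no joint multi-mediator
  decomposition.
- Bidirectional analyses flag, not resolve, reverse causation; note that in
  the reverse direction the outcome-association filter is what removes the
  forward-causal instruments, so running it with that filter disabled will
  manufacture a spurious reverse signal from any strong forward effect.
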