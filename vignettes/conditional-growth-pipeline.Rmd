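---
title: "Conditional growth modeling of infant anthropometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional growth modeling of infant anthropometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Length and weight are strongly correlated within an infant, so asking
whether "growth" predicts later neurodevelopment is ill-posed unless
linear growth is disentangled from weight gain. Conditional growth
modeling does this by sequential residualisation: the *conditional
length* at an age is the residual of the current length-for-age z-score
regressed on all previous lengths and weights, and the *conditional
relative weight* is the residual of the current weight z-score regressed
on the current length plus all previous sizes. Each variable captures
growth in one interval, net of everything earlier, and is by
construction uncorrelated with its regressors — so all of them can enter
one multivariable model without collinearity. Birth length and weight
z-scores act as the conditional variables at birth, having no earlier
measurements to condition on.

The outcome is parent-reported neurodevelopmental delay from the Ages &
Stages Questionnaires, third edition (ASQ-3): five domains of six items
each ("yes" = 10, "sometimes" = 5, "not yet" = 0; domain scores 0–60),
with a domain cutoff two standard deviations below the reference-sample
mean and *delay* defined as any domain at or below its cutoff.
Associations are estimated per sex with quasi-Poisson regression —
a log-link Poisson-family GLM on the binary delay indicator, whose
exponentiated coefficients are relative risks, with Pearson-dispersion
scaled standard errors.

`condgrowth` implements this pipeline end to end, plus a seeded
synthetic-cohort generator, because the motivating cohort data
(a national Japanese birth cohort followed through 12 months) are not
publicly available. Everything the package claims is therefore
demonstrated either on published summary counts or on synthetic cohorts
whose generating truth is known.

## Stages and their parameters

### Target ages and the checkup timeline

Checkups happen around — not at — 4, 7 and 10 months. Raw lengths and
weights are aligned to target ages (defaults 122, 213, 304 days, using
one month = 30.4375 days) by linear interpolation between the two
observations flanking the target, or linear extrapolation from the
nearest two when the target lies outside the observed range
(`measurement_at_age()`, `build_timeline()`). Interpolation is on raw
cm/g before z-scoring: over the short spans actually used (a checkup is
at most a few weeks from its target) linearity is an excellent
approximation, and the affine-exactness of the rule is testable.

A value is produced only when the nearest observation lies within an
admissibility *window* of the target. For cohort processing the default
window is **45 days** — half the smallest gap between targets — so each
target value is reconstructed only from its own checkup (plus birth for
the 4-month target). We chose this deliberately: with a permissive
window, a child who skipped the 4-month checkup would receive a 4-month
value interpolated between birth and the 7-month visit, a span over
which infant growth is strongly nonlinear; the resulting values are
biased by more than a z-score unit and, worse, per-age availability
stops matching checkup attendance, which is how checkup-based cohorts
define data availability and their model subsamples. The standalone
`measurement_at_age()` helper keeps a permissive 92-day default for
ad-hoc use; both are configuration knobs, not claims about any
particular cohort.

### Growth reference and LMS transforms

Z-scores use the LMS parameterisation: `z = ((x/M)^L − 1)/(L·S)`, with
the log-form limit used when `|L| < 1e-7` so the transform is continuous
in `L` at zero. The inverse transform (`lms_inverse()`) round-trips to
`1e-10` and drives the simulator. Birth z-scores are additionally
stratified by the mother's parity and the child's completed gestational
week (the floor of gestational age), as national newborn standards are;
later ages use sex and age only.

National growth standards are not redistributable, so the package ships
a *synthetic* reference (`synthetic_lms_reference()`): smooth,
decelerating median curves emulating Japanese infant growth (birth
≈ 49 cm / 3.0 kg to ≈ 74 cm / 9.3 kg at 12 months), tabulated daily so
that the nearest-row lookup (tolerance ±15 days, falling back to linear
interpolation of L, M, S between flanking rows) is exact at any
simulated checkup age. Users with access to a real reference supply it
as CSV in the same schema (`read_lms_reference()`).

### Conditional variables

`build_conditional_set()` fits the residualisation chain on the
complete-case sample of a model variant, separately per sex (the
analysis is sex-stratified throughout), using ordinary least squares
with an intercept. Variants encode which timepoints are available:
variant 0 (birth + 4 m) feeds the 6-month models; variants 1
(birth/4/7/10 m), 2 (birth/4/7 m) and 3 (birth/4/10 m) feed the
12-month models. In variant 3 the 10-month conditionals condition on
birth and 4 months only — the 7-month timepoint is absent by definition
of that subsample.

Two decisions the source method leaves open:

* **Standardisation.** All conditional variables — including the birth
  z-scores — are centred and scaled to unit variance within the
  estimation sample and sex stratum, so each relative risk is per 1 SD
  and comparable across variables and variants.
* **Stratified estimation.** Residualisations are fitted within sex,
  matching the stratified outcome models, rather than pooled.

Orthogonality of each conditional variable to its regressors (and hence
to all earlier variables in its chain) holds to numerical precision and
is asserted at `1e-8`; the residuals agree with an independent
normal-equations solver to `1e-9` on small samples. Note the two birth
variables are correlated with *each other* — they are raw sizes, not
residuals — which is expected and harmless since both enter every model.

### ASQ-3 scoring and cutoffs

Domains with any missing item are treated as absent by default; the
instrument manual's proration (mean of answered items × 6) is available
behind `prorate = TRUE` but is not the default, since the motivating
analysis does not describe using it. Cutoffs are derived per outcome age
and domain, pooled across sexes, as mean − 2·SD with the n−1 sample SD
(immaterial at reference sizes in the tens of thousands) and no flooring
at zero. The delay flag uses at-or-below semantics, and the any-domain
flag requires at least one scored domain. In the pipeline, cutoffs are
derived from all children with questionnaire data *before* eligibility
exclusions, emulating the use of the full available population as the
normative reference.

### Risk models

`fit_rr_model()` is `stats::glm()` with `quasipoisson(link = "log")`,
convergence tolerance `1e-10`, at most 100 IRLS iterations, complete
cases only. The dispersion is the Pearson chi-square over residual
degrees of freedom; confidence intervals are Wald, `exp(β ± 1.96·SE)`.
Point estimates equal Poisson maximum likelihood exactly; with a single
binary regressor the fitted relative risk equals the closed-form ratio
of outcome proportions. Maternal age enters linearly in years; the
categorical covariates are dummy-coded against junior-high education,
low income, non-smoking and no speech stimulation. No multiple-testing
adjustment is applied, matching the source analysis.

### Balance diagnostics

`balance_table()` compares children with and without complete
anthropometry: phi (2×2) and Cramér's V (r×c) from the uncorrected
Pearson chi-square for categorical variables, and the point-biserial r
from a pooled-variance Student's t for numeric ones, each on
per-variable denominators after excluding missing values. Values are
reported rounded half-up to two decimals, the convention of the
published table these diagnostics reproduce. The published group counts
themselves are embedded (`published_balance_summaries()`) so the
routines can be validated exactly against printed effect sizes.

## The synthetic-cohort generator

`simulate_cohort()` draws, in a fixed documented order from one seed:

1. **Demographics and covariates** with marginals matching the published
   complete-data column: 51 % boys, gestational age ~ N(39.5, 1.1)
   truncated to [37, 42), 51.7 % multipara, 14.5 % smoking, the
   education/income/speech splits, maternal age ~ N(31.4, 4.9).
2. **Latent growth**: an 8-dimensional multivariate normal over
   (length, weight) × (birth, 4, 7, 10 m) z-scores. The default
   correlation is the Kronecker product of an AR(1) across timepoints
   (ρ = 0.7) and a length–weight block (ρ = 0.6) — positive definite by
   construction. The source study does not report its correlation
   structure; these are plausible values for infant anthropometry, fixed
   once.
3. **Raw measurements** via the inverse LMS transform: birth values from
   the parity × gestational-week stratum; checkup values at jittered
   ages (±10 days) with the latent z linearly interpolated between the
   knot ages. Measurements are rounded to 0.1 cm / 1 g.
4. **Delay indicators** on the log-risk scale:
   `log p = log(baseline) + Σ βᵥ·zᵥ` over the *true* conditional
   variables, which are computed analytically from the configured
   correlation matrix (population residualisation). Generating on the
   log-risk — not logit — scale makes the configured relative risk the
   exact estimand of the quasi-Poisson model, so parameter recovery is
   an unbiased test. Configurations whose effects push any probability
   above 1 are rejected with an error naming the offending stratum.
   Default baselines: 8.9 % / 8.5 % (boys/girls, 6 m) and
   16.9 % / 12.6 % (12 m); default effects give protective birth weight
   (RR 0.92) and 4-month conditional length (RR 0.86) per SD.
5. **ASQ items**, sampled backwards from the drawn indicator:
   non-delayed children draw every domain score from {45, …, 60};
   delayed children get one to three domains (weighted by the published
   domain mix) forced into {0, …, 15}. Items realising each score are
   deterministic (yes-first composition). The scored any-domain flag
   then equals the drawn indicator whenever every derived cutoff falls
   in (15, 45) — which holds for per-domain low-score rates between
   roughly 1 % and 12 %, comfortably containing the defaults. Outside
   that band (extreme user configurations) the guarantee degrades
   gracefully and the discrepancy is detectable by the packaged
   consistency test.
6. **Missingness**, applied last and missing-at-random given covariates:
   checkup attendance combines a shared child-level propensity
   (SD 1.2) with multipara and smoking effects (log-odds 0.45 / 0.35),
   intercept-calibrated to the marginal availability rates of the
   motivating cohort (83.9 / 36.7 / 57.9 %); questionnaire-level ASQ
   missingness 13.9 % / 18.2 %; small covariate-specific rates. This
   reproduces the published selection structure — missing-data children
   skew multiparous, smoking and less educated — for bias exercises.

What the generator does **not** emulate: regional/center structure,
joint covariate distributions beyond the stated marginals, covariate
effects on delay (covariates are genuinely null, so adjusted and
unadjusted estimands coincide), item-level response heterogeneity, and
real growth-reference misspecification. Passing tests therefore
demonstrate the *pipeline's* correctness and calibration under the
assumed data-generating structure, not robustness to violations of it.

## Problem sizes and numerical choices

The packaged checks use: simulation-recovery and null-calibration runs
at n = 50,000 children × 20 seeds each (the recovered 95 % CI must
contain the configured RR in ≥ 18 of 20, and likewise contain 1 under
the null); latent-correlation convergence at n = 100,000 (Frobenius
distance < 0.05); oracle comparisons on ≤ 50-row samples at `1e-9`;
LMS round-trips at `1e-10`; orthogonality at `1e-8`. Model degeneracies
are surfaced, not silently absorbed: rank-deficient designs, too-small
samples and empty strata raise estimation errors; a perfect-fit
residualisation warns and returns unstandardised (zero) residuals; an
empty covariate level is dropped with a warning.

## Known limitations

* The synthetic LMS reference is an emulation; absolute z-scores from it
  are not comparable to any national standard.
* The two-point alignment of checkup data is linear in raw measurements;
  over spans much longer than the 45-day window this would be biased,
  which is exactly why the window excludes such spans.
* Quasi-Poisson Wald intervals are the only CI construction offered;
  log-binomial and sandwich alternatives are out of scope.
* With all covariate effects null in the generator, confounding-related
  behaviour of the adjusted models is not exercised.
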