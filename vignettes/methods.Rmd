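---
title: "Blood pressure and the brain-age gap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood pressure and the brain-age gap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brainageBP implements a longitudinal analysis linking blood pressure (BP) to
brain health measured as the brain-age gap (BrainAGE): the difference, in
years, between a machine-estimated brain age and chronological age, where a
positive gap means an older-appearing brain.  Because the cohort data this
kind of study uses are not publicly distributable, the package pairs the
analysis machinery with a synthetic cohort generator whose defaults encode
the study conditions, so every stage is testable end to end.

## The synthetic cohort

`sim_config()` describes a two-cohort community sample: a middle-aged (MA)
cohort aged 44–46 at baseline and an older (OA) cohort aged 60–64, followed
for up to four assessment waves roughly four years apart (about 12 years of
follow-up).  Baseline ages are uniform within each cohort's range; visit
times are the planned 4-year interval plus Gaussian jitter (SD 0.35 years),
so "total years in study" varies realistically around 12.

**Attrition.** Dropout is monotone and completely at random: a subject seen
at wave $w$ is never seen again with a per-wave hazard.  The default hazards
$(0, 0.26, 0.5676)$ produce 2-, 3- and 4-visit proportions of about
26/42/32%, matching the scan-count mix of the emulated study, and an
expected 3.06 visits per subject (about 2,100 scans at $n = 686$).
Informative dropout is deliberately out of scope.

**Blood pressure.** The generator parameterizes each subject's trajectory on
the (MAP, pulse pressure) scale rather than (SBP, DBP):

$$\mathrm{SBP} = \mathrm{MAP} + \tfrac{2}{3}\,\mathrm{PP}, \qquad
  \mathrm{DBP} = \mathrm{MAP} - \tfrac{1}{3}\,\mathrm{PP},$$

so the defining identity $\mathrm{MAP} = \tfrac13\,\mathrm{SBP} +
\tfrac23\,\mathrm{DBP}$ holds exactly at every visit.  Each subject draws a
baseline MAP and PP from cohort- and sex-specific normal distributions
(cohort means reconstructed from the emulated study's summary table, with
the male–female gaps applied within cohort) and an annual slope from
$N(0.8, 0.92^2)$ mmHg/yr for MAP and $N(0.915, 1.758^2)$ for PP.  The PP
slope mean is chosen so the implied SBP slope mean is exactly
$0.8 + \tfrac23 \times 0.915 = 1.41$ mmHg/yr.  This is a deliberate design
choice: the three published annual slopes (MAP 0.8, SBP 1.41, DBP 0.61)
are mutually inconsistent with the MAP identity (they imply a MAP slope of
0.877), so the generator reproduces the MAP and SBP slopes exactly — the two
that drive the calibration checks — and accepts an implied DBP slope of
0.495 mmHg/yr.  Each visit yields two readings per measure, equal to the
true value plus independent $N(0, 3^2)$ mmHg reading noise; the within-visit
correlation of duplicate readings is not documented for the emulated study,
so the reading-noise SD is a free configuration parameter.

**Covariates.** Education, BMI, physical activity, depression and alcohol
intake are drawn from normal distributions matching the published marginal
summaries; smoking, diabetes, APOE ε4 and anti-hypertensive medication are
Bernoulli with the published prevalences (medication is time-varying:
cohort-specific baseline probability, then a 5%/wave initiation hazard, and
monotone once started).  Covariates are generated independently except for
BP's dependence on cohort and sex, because only marginal summaries are
published; this means covariate–covariate confounding present in real data
is not emulated, and adjusted models mainly test the machinery rather than
deconfounding.

**Outcome.** `simulate_brainage_outcome()` generates the per-visit gap from
the base generating model

$$y_{ij} = \beta_{\mathrm{MAP}}(\mathrm{MAP}_{ij} - 90) + \beta_t\, t_{ij}
 + \beta_{\mathrm{OA}}\, \mathbb{1}[\mathrm{OA}]
 + \beta_{F}\, \mathbb{1}[\mathrm{female}] + \beta_0 + u_i + e_{ij},$$

with $u_i \sim N(0, 3.633^2)$, $e_{ij} \sim N(0, 1.590^2)$ and the default
fixed effects $(0.019, 0.035, -0.402, -0.837, 0.073)$ — the published
base-model values, used here as generating truth.  The measured (not latent)
MAP enters the outcome, mirroring an analysis in which the fitted exposure is
the same measured variable.

**Features.** `simulate_features()` stands in for voxel-based gray-matter
images: features are a linear mixing of a small latent space whose first
axis is a latent brain age (chronological age plus a configurable BP effect
per mmHg of MAP over 90 and a sex offset), plus an additive scanner offset
for scans after the changepoint wave (one scanner label per wave, default
changepoint at wave 2) and iid noise.  No spatial structure, tissue
segmentation or registration is emulated; passing tests therefore
demonstrate recovery of a linear latent age signal under a batch effect,
not performance on real morphometry.

**Randomness.** Every generator stage (design, visit layout, medication, BP,
features, outcome) derives its own named RNG stream from the single seed, so
adding a stage never shifts another stage's draws and identical
(config, seed) pairs give bit-identical tables.

## Blood-pressure measures and eligibility

Visit-level SBP/DBP are the mean of the two readings; MAP is
$\tfrac13$ SBP $+ \tfrac23$ DBP.  Classification follows the emulated
study's strict wording: hypertensive iff SBP > 140 or DBP > 90 mmHg or on
anti-hypertensive medication; optimal BP iff SBP < 115 and DBP < 75 mmHg.
Model exposures are centered at the minimum-cardiovascular-risk thresholds
(90 MAP / 114 SBP / 74 DBP), so coefficients read "per mmHg above
threshold".

`apply_eligibility()` applies, in order: fewer than two usable scans; a
neurological flag or MMSE < 25 (strictly) at any visit; baseline MAP beyond
3 SD of the mean; missing key baseline covariates.  The outlier mean/SD are
computed within age cohort by default — the cohorts differ in mean BP, so a
pooled SD would flag low-BP middle-aged and high-BP older subjects
asymmetrically — with a pooled option retained.  Baseline (first-visit)
values are used because the emulated study does not state whether any-wave
values entered the rule.  Note the arithmetic bound on z-scores: in a sample
of $n$ values the largest attainable $|z|$ is $(n-1)/\sqrt{n}$, so a 3-SD
rule can only ever fire for $n \ge 11$.

Missing covariates are completed by `em_impute()`: a multivariate-normal
working model fit by expectation-maximization, with missing cells replaced
by conditional means given the row's observed cells.  Observed cells are
never altered; binary columns are imputed on the MVN model and thresholded
at 0.5, a documented simplification of the original proprietary routine.
Convergence is declared on the relative change of the MVN parameters
(tolerance $10^{-6}$, default cap 100 iterations) because the observed-data
log-likelihood — which is tracked and must be non-decreasing — is undefined
for exactly collinear columns.

## The brain-age engine

The estimation pipeline mirrors the established BrainAGE framework:

1. **Volume preprocessing** (optional, for image input): separable Gaussian
   smoothing at 4-mm FWHM ($\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per
   axis in voxel units, kernel truncated at $4\sigma$ and renormalized at
   the edges so constants are preserved) followed by block-mean resampling
   to 4-mm resolution.  The target resolution must be an integer multiple of
   the source voxel size; this keeps resampling an exact block average and
   avoids interpolation-scheme ambiguity.
2. **Scanner orthogonalization**: each feature is replaced by its residual
   from a regression on scanner indicators plus intercept, removing additive
   scanner/protocol batch effects; residuals are exactly uncorrelated with
   every scanner dummy and the operation is idempotent.
3. **PCA reduction** on training scans only (centered, unscaled).  The
   retained dimension defaults to the smallest $k$ explaining 95% of
   training variance, capped at $n-2$; the original pipeline's
   dimensionality is unpublished, so $k$ is configurable.
4. **Relevance vector regression** of age on the reduced scores.

### Relevance vector regression

RVR is sparse Bayesian regression over a kernel basis (bias plus one kernel
function per training point; linear kernel on PCA scores by default, RBF and
polynomial available).  Weights have independent $N(0, \alpha_i^{-1})$
priors and observations $N(\Phi w, \beta^{-1})$ noise; hyperparameters are
optimized by type-II maximum likelihood with the classic fixed-point
updates

$$\alpha_i \leftarrow \gamma_i / \mu_i^2, \qquad
  \beta \leftarrow \frac{n - \sum_i \gamma_i}{\lVert y - \Phi\mu \rVert^2},
  \qquad \gamma_i = 1 - \alpha_i \Sigma_{ii},$$

where $(\mu, \Sigma)$ are the posterior mean and covariance of the weights.
Basis functions with $\alpha_i > 10^{12}$ are pruned (the bias column never
is); iteration stops when $\max_i |\Delta \log \alpha_i| < 10^{-6}$ or after
1000 iterations, and the marginal log-likelihood trace is recorded with
every model.  With a single shared fixed $\alpha$ the posterior mean is the
ridge-regression solution with penalty $\lambda = \alpha/\beta$, which the
test suite uses as a closed-form oracle.

Two numerical choices deserve note.  First, the marginal likelihood's
quadratic term is evaluated in the algebraically equivalent form
$\beta\lVert y - \Phi\mu\rVert^2 + \mu^\top A\,\mu$, which avoids
catastrophic cancellation at large $\beta$.  Second, when the surviving
basis can interpolate the responses (small folds, noiseless signal) the
marginal likelihood is flat in $\beta$ along a ridge and the fixed-point
update stalls at an arbitrary noise level; the fit therefore finishes with a
tie-break that escalates $\beta$ tenfold at a time, re-converging the
$\alpha$'s each step, for as long as the marginal likelihood does not
decrease *and* the residual sum of squares still improves.  A genuine noise
level rejects the first escalation; a noiseless fit walks to the
interpolating end (capped at $\beta = 10^{14}$, where the degenerate
self-pruning regime begins).  If no kernel basis function survives pruning
the model falls back to bias-only with a warning.

### Cross-validation and bias correction

`estimate_brainage_loso()` refits the PCA basis and the RVR model once per
held-out **subject** — not per scan — so all of a subject's repeated scans
are predicted by a model they never influenced; scan-level folds would leak
within-subject information.  The fold audit (zero self-inclusions) is
recorded on the result.

The raw gap (estimated minus chronological age) is then regressed on age
over the full estimation sample and the residual is the final BrainAGE, so
the score is exactly uncorrelated with age by construction.  Whether such a
correction should regress the gap or the estimated age is immaterial (both
zero the correlation); fitting on the full sample rather than training folds
only is the default, with the alternative selectable.  `brainage_diagnostics()`
reports the pre-correction mean absolute deviation and the post-correction
age correlation.

## Association models

`fit_lmm()` fits random-intercept mixed models with `lmerTest::lmer`.  Age
is decomposed into time in study (within-person change, years from
baseline) and cohort (between-cohort contrast), following the emulated
analysis; sex completes the base model, and the adjusted model adds
education, diabetes, BMI, smoking, depression, physical activity, alcohol
intake, APOE ε4 and the time-varying medication term.  Estimation is by
maximum likelihood by default so nested-model likelihood comparisons
(`lrt_lmm()`) are valid; REML is available.  Inference is Wald: 95%
confidence intervals from the normal approximation, p-values from t
statistics with Satterthwaite denominator degrees of freedom, which hold
the nominal test size in this design (verified by a 500-replicate null
simulation in the acceptance suite).  Stratified analyses reuse the same
specification on a subset; fixed-effect terms that are constant within the
stratum (typically the grouping variable) are dropped with a message.
Non-convergence and singular random-effect fits are flagged on the returned
object, never silent.

Reporting helpers convert coefficients to days of brain ageing per mmHg
(`coef_to_days()`, 365.25 days/year — the value that reproduces all three
published conversions after 3-significant-figure rounding), and reproduce
group comparisons from summary statistics alone: Welch's unequal-variance
t-test with Welch–Satterthwaite degrees of freedom (the variant that matches
the published table's statistics; pooled-variance is retained as an option)
and Pearson's chi-square without continuity correction.

## Problem sizes and what the tests show

The package's own experiments are sized for a desk run: parameter-recovery
and null-size simulations use the full study design (686 subjects, about
2,100 visits) with 200 and 500 replicates respectively; generator
calibration uses one 686-subject cohort; the LOSO demonstrations use
cohorts of about 60–120 subjects with 30–60 features, where the engine's
refits take seconds.  These sizes are stated here as the package's choices
so results are reproducible as printed.

Passing tests demonstrate: exact arithmetic of the BP rules; statistical
calibration of the generator (slopes, prevalences, variance components);
correctness of the RVR solution against closed forms and an independent
implementation; leakage-free cross-validation; exact residualization
properties; and unbiased recovery of the generating mixed-model
coefficients at the study size.  They do not demonstrate anything about
real neuroimaging data: the feature model is linear and low-rank, dropout
is non-informative, covariates are mutually independent, and the published
coefficient values themselves are not reproducible without the original
cohort.

## Known limitations

* The generator's DBP slope is implied (0.495 mmHg/yr), not the published
  0.61, because the three published slopes cannot hold simultaneously with
  the MAP identity.
* Binary covariates are imputed under an MVN working model and thresholded;
  no multiple imputation with pooling.
* The published post-correction BrainAGE–age correlation is slightly
  nonzero (−0.037), suggesting the original correction was fitted on a
  different sample than it was evaluated on; this package's correction is
  exactly zeroing by construction and does not emulate that discrepancy.
* RVR hyperparameter optimization is a fixed-point scheme with a documented
  tie-break, not a guaranteed global optimizer; `alpha` pruning and `beta`
  caps are configurable.
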