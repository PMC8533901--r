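---
title: "EEG-vigilance, personality, and the vigicor pipeline: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-vigilance, personality, and the vigicor pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicor)
```

`vigicor` studies how resting-state brain arousal relates to personality.
This vignette is the package's own account of the science it implements:
the staging model and its assumptions, the summary metrics, the inference
stack, the synthetic cohort generator and its calibration, and the design
decisions taken where the published record leaves the procedure open.

## The staging model

Brain arousal during eyes-closed rest is operationalised as an ordinal
EEG-vigilance stage per one-second segment: 0 (active wakefulness), A1/A2/A3
(relaxed wakefulness with occipital, intermediate, and anteriorised alpha),
B1 and B2/3 (drowsiness), C (sleep onset), numerically coded 7 down to 1.
The classifier consumes, per segment, the alpha and delta+theta current
densities of four regions of interest (occipital, parietal, temporal,
frontal), an EOG slow-eye-movement flag, and a spindle/K-complex
graph-element flag. Segment duration is fixed at 1 s; segment indices are
0-based, so a segment covers the half-open interval `[t, t+1)` seconds.

The rule cascade in `classify_segment()` is, first match wins:

1. artifact segments receive no stage (missing, never interpolated);
2. a graph element forces **C**;
3. **A-candidacy**: some ROI has alpha at or above the individual threshold
   `theta_A` *and* at least `a_ratio` (default 2) times its own delta+theta.
   Among candidates, occipital alpha strictly greatest gives **A1**;
   frontal alpha at or above occipital gives **A3** (a frontal–occipital
   tie is deliberately resolved to A3, the lower-arousal label, to keep
   severity monotone); otherwise **A2**;
4. mean delta+theta at or above `dt_dominance_factor` (default 2) times
   mean alpha gives **B2/3**;
5. otherwise **B1** when slow eye movements are present, when residual
   alpha still reaches `theta_A`, when mean delta+theta exceeds mean alpha,
   or when a drowsiness stage (B1, B2/3, C) was assigned within the
   preceding `b1_context_window` (default 60 s); otherwise **0**.

Rule 5 is the package's own reconstruction — the 0-versus-B1 rule is not
printed in the public description of the staging method. Its four clauses
were chosen so that the cascade is *provably monotone*: increasing a
segment's delta+theta (alpha held fixed) can only turn clauses on, never
off, so the label can never move towards higher arousal. A plain
"0 unless drowsiness context" rule fails this property and also
misclassifies degraded A-segments. Only direct drowsiness evidence
(clauses other than the context clause itself) refreshes the context
window; without that restriction a single drowsiness episode would lock
all subsequent desynchronised wakefulness into B1.

The **adaptive threshold** (`compute_adaptive_threshold()`) is
`threshold_scale` (default 0.25) times the mean occipital alpha over the
top decile (`threshold_quantile = 0.9`) of artifact-free segments. The
published procedure defers to the staging tool's manual; this top-decile
stand-in tracks the individual's alpha amplitude, is homogeneous of degree
one (so classification is invariant to a common rescaling of all densities)
and is configurable. A recording containing essentially no A-stage alpha
has an ill-defined threshold and can mis-stage 0 as B1; this mirrors the
practice of excluding low-voltage-alpha EEGs from such analyses and is a
known limitation, not silently corrected.

Recordings with at least 15 % artifact segments (boundary inclusive) fail
QC (`qc_artifact_filter()`), reproducing the cohort-level exclusion rule.

## Summary metrics

`summarize_vigilance()` reduces a stage sequence to three variables, all
computed over artifact-free segments only:

* **mean vigilance** — the arithmetic mean of the numeric codes, in [1, 7];
* **slope index** — the OLS slope of per-minute mean vigilance against the
  block midpoint, expressed in *stages per 10 minutes*. Minute blocks need
  at least 30 usable seconds (robustness to artifacts without imputation);
  at least two usable blocks are required. The per-10-min unit was chosen
  so that typical 20-minute recordings land in the range reported for
  large cohorts (roughly −4 to +1);
* **stability score** — an ordinal 1–14 index. The cited rubric is not
  printed anywhere public, so the package ships a reconstruction
  (`stability_rubric()`, a plain TSV under `inst/extdata/`): a first-match
  table over *cumulative* stage burdens — proportion of segments at or
  below C; at or below B2/3; at or below B1; below A1 — with one earliness
  row (first C within 10 minutes). Because every condition is monotone in
  cumulative burdens, deepening any segment or moving sleep onset earlier
  can never increase the score. The rubric preserves the ordinal intent
  (depth × earliness of decline) and the 1–14 range; numeric equality with
  the proprietary implementation is explicitly *not* claimed, and the
  table can be replaced wholesale via the `rubric` argument.

`moving_average_course()` provides the centred 61-s moving average used in
group time-course figures (each point averages the data point ± 30 s).

## Association statistics

`association_matrix()` correlates each trait (5 dimensions or 30 facets)
with each metric by Spearman correlation (Pearson on mean ranks),
two-sided p-values from the t approximation on `n − 2` degrees of freedom
(standard at cohort sample sizes; the type-I error of this approximation is
verified by simulation in the test suite, and an exact enumeration path is
available behind `exact = TRUE` for untied samples up to n = 9), and
Benjamini–Hochberg FDR
adjustment *within the full scope* (15 or 90 tests), matching the
convention of correcting across all tested associations. Covariate
adjustment (`partial_spearman()`) ranks x, y *and* the covariates, then
residualises the ranked x and y on the ranked covariates with an intercept
and correlates the residuals on `n − 2 − k` degrees of freedom. Ranking the
covariates keeps the procedure fully nonparametric; daytime is coded by its
slot hour and sex as a 0/1 indicator. Whether the original analysis used
exactly this form of adjustment is unknown, which is why adjusted
coefficients are treated as directional, not as reproduction targets.

## Correlation Bayes factors

Evidence for a nonzero correlation uses the stretched symmetric beta prior
`(ρ+1)/2 ~ Beta(1/κ, 1/κ)` with the conventional moderate width κ = 1/3
(about 80 % prior mass between −0.5 and 0.5; `stretched_beta_mass()`
computes 0.793):

$$BF_{10} = \frac{\int_{-1}^{1} f(r \mid \rho, n)\,\pi_\kappa(\rho)\,d\rho}{f(r \mid 0, n)}$$

with `f` the *exact* sampling density of the sample correlation under a
bivariate normal population, evaluated in log space via its rapidly
converging Gauss-hypergeometric form (`r_sampling_density()`); at ρ = 0 the
closed Beta form is used. The integral uses adaptive quadrature at relative
tolerance 1e-8. A Fisher-z approximation is available behind
`method = "fisher_z"` purely as a cross-check; an independent Savage–Dickey
grid estimate agrees with the quadrature within 1 % in the test suite.

Two approximation notes. First, published tables report *Spearman*
coefficients fed into a Pearson-model Bayes factor; we do the same,
computing BF from the reported coefficient and n under the bivariate-normal
model. Second, reported coefficients are rounded to three decimals, and
`d log BF / dr ≈ n·r`, so reproduction of published Bayes factors is only
meaningful to within a few percent; the package's acceptance checks use a
±5 % band for this reason.

## Structured permutation null

To judge a whole set of 15 (or 90) dependent p-values, the null must
preserve the correlation structure *within* the trait domain and within the
vigilance domain while destroying cross-domain association. `block_permute()`
applies one shared row permutation to the entire vigilance block, which
preserves within-block correlation matrices exactly (matrix equality, not
approximation — permuting either block is equivalent by symmetry).
`permutation_pvalue_sets()` repeats this B times, collecting each set of
cross-domain Spearman p-values sorted ascending, with the same mean-rank tie
policy as the observed analysis so observed and null are comparable.
`qq_envelope()` summarises the null per rank on the −log10 scale (mean =
the qq diagonal; 5th/95th percentiles = the grey band; the mean is taken on
the −log10 scale, matching the plotted diagonal) and flags observed values
above the 95th percentile. `exceedance_summaries()` reports the fraction of
null sets with at least k p-values below α and with a minimum below a
stated p₀. The full B × m sorted matrix is stored rather than a streaming
percentile sketch: even at the reference scale of one million sets of 15 it
is ~120 MB, well within a desk machine, and it keeps the percentile code
exact. The default B = 10⁴ is a desk-scale choice; the envelope is
configurable to 10⁶. Exceedance fractions published for the real cohort
depend on that cohort's within-domain correlation matrices and are
therefore *not* reproducible from synthetic data; the package instead
verifies the closed-form independent-domain value (1 − 0.95¹⁵ ≈ 0.537) and
the directional effect of within-domain correlation.

## Power analysis

`correlation_power()` mirrors the standard correlation power calculator:
critical r from the two-sided t criterion on `n − 2` df, then the Fisher-z
normal approximation with the `r/(2(n−1))` bias term, summing both
rejection tails so that power → α as r → 0. `detectable_r()` inverts it by
root-finding on (0, 0.999) at tolerance 1e-6. At N = 468 and α = 0.05 this
reproduces the detectable-effect triplet 0.052 / 0.091 / 0.129 for 20/50/80 %
power, and 0.173 at 80 % power under Bonferroni α = 0.05/15 — recomputed,
not hard-coded, in both the test suite and `scripts/acceptance.R`.

## The synthetic cohort generator

Cohort data of this kind are access-restricted, so the generator emulates
the *statistical structure* the analysis assumes, at the study's scale
(defaults: 468 subjects, 1200 one-second segments):

* **Traits.** Dimension T-scores are multivariate normal on the latent
  scale (extraversion–openness correlation 0.48, the dominant observed
  intercorrelation; other entries modest norm-sample values), affinely
  mapped to mean 50 / SD 10. Integer rounding is off by default to
  preserve rank statistics. Each of the six facets per dimension loads on
  its parent latent score (default loading 0.7). Sex, age (40–79) and the
  three assessment slots (8:30, 11:00, 13:30) are drawn independently.
* **Decline propensity.** A latent standard-normal `d` carries the effects:
  requested trait and covariate effect sizes are mapped to latent
  correlations through a Gaussian-copula-style linear model
  (`solve(S, c)` against the joint predictor correlation matrix), with an
  explicit error when the implied multiple correlation approaches 1.
  Signs follow the study's directions: higher openness/extraversion,
  younger age and later daytime mean steeper decline.
* **Stage courses.** A time-inhomogeneous Markov chain over codes 7..1
  with single-step moves: per-second downward hazard
  `p_down_base · exp(scale · squash(d)) · (1 + drift · minutes)`, squashed
  through `1.5·tanh(d/1.5)` so the hazard is bounded yet strictly monotone
  in `d` (no rank ties among extreme decliners); recovery 0.002/s from
  drowsiness stages and 2e-4/s into stage 0; recordings start in A1 (95 %)
  or 0 (5 %), and post-task active wakefulness decays at ≥ 0.01/s —
  emulating the arithmetic-task activation before recording onset.
  Artifacts are injected at 2 %/s, a typical post-ICA residual rate.
* **Features.** Per-stage template means for the eight density channels
  plus flags, with Gaussian noise of SD `feature_noise` × mean (default
  0.2) truncated at zero. Noise-free templates satisfy the staging rules
  exactly, giving the round-trip oracle used throughout the tests.

**Calibration.** The chain's defaults were fixed once against the
descriptive ranges reported for a large adult cohort: mean vigilance
centred near 5 with SD ≈ 1, slope index centred near −1.4 with SD ≈ 1.1,
and fewer than 1 % of subjects outside the reported Min–Max bands of either
metric (the test suite checks ≥ 99 % inside at n = 5000). A 7-state
single-step chain is intrinsically noisy, so the Spearman correlation
between the latent propensity and the realised slope index is attenuated
(≈ 0.64 under the defaults). Because the scientific meaning of an "effect
size" here is the *realised* trait–metric correlation, the generator
de-attenuates: requested effects are divided by the frozen calibration
constant `slope_attenuation = 0.636`, measured by large-scale simulation
under the default chain (and re-measurable for custom dynamics via
`estimate_slope_attenuation()`). The package verifies the result
end-to-end: over 200 replicate cohorts at n = 468 with a requested −0.17,
the mean recovered Spearman correlation is within ±0.02 of the target and
its SD matches the theoretical `1/sqrt(n−3)` ≈ 0.046.

**What passing tests do and do not show.** The generator reproduces the
correlation structure, effect sizes, time-course shape and summary ranges
of real cohort data, so green tests demonstrate that the *pipeline* is
correct and calibrated. They do not validate the staging rules against real
multichannel EEG (no waveforms are synthesised, no source inversion is
performed), nor do they reproduce cohort-specific published coefficients,
which depend on restricted data. The chain is a generative stand-in for
arousal dynamics, not a claim about their mechanism.

## Numerical choices and problem sizes

* Quadrature: `integrate()` at rel.tol 1e-8; hypergeometric series summed
  in log space to a 1e-17 relative term bound.
* Root-finding: `uniroot()` at tol 1e-9.
* Ranks: mean ranks for ties everywhere (observed and permutation null).
* Degenerate inputs: constant vectors make Spearman undefined (error);
  variables fully absorbed by covariates return a null partial correlation
  with a warning; `|rho| = 1` yields the degenerate p = 0 with a warning;
  all-artifact recordings yield all-missing sequences and fail QC.
* Test-suite problem sizes (chosen as routine desk-scale checks): 10⁶
  Monte-Carlo draws for the sampling-density KS comparison; 2×10⁵
  replicates for the power rejection-rate oracle; 200 cohorts at n = 468
  for parameter recovery; B = 10³/10⁴ permutation sets for the null
  calibration; 2×10⁴ null simulations for the type-I check.

## Known limitations

* The adaptive threshold, the 0/B1 rule and the stability rubric are
  documented reconstructions of procedures whose exact published forms are
  not public; fidelity to the proprietary implementations is not claimed.
* Alpha-poor recordings (no discernible A-stage alpha) have an ill-defined
  adaptive threshold; such EEGs are excluded in practice.
* Bayes factors assume the bivariate-normal sampling model for a Spearman
  coefficient, as in the original analyses; a rank-likelihood Bayes factor
  is out of scope.
* The covariate-adjusted analysis is one reasonable nonparametric
  adjustment among several; adjusted published values are therefore treated
  as directional only.
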