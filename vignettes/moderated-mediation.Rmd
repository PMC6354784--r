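---
title: "Moderated multilevel mediation for psychophysics trial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated multilevel mediation for psychophysics trial data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

In a typical psychophysics session a participant receives brief painful
(laser, mJ) or non-painful tactile (von Frey, mN) stimuli at three
calibrated intensities, rates each stimulus on a 0--100 numerical rating
scale (NRS), and responds as fast as possible with a modality judgement
(reaction time, ms). Stimulus intensity drives both perception (ratings)
and behavior (speed). The interesting question is *how* these effects are
transmitted:

* **perception-behavior model** — do ratings mediate the effect of
  intensity on reaction times?
* **behavior-perception model** — do motor responses mediate the effect of
  intensity on ratings?

Both are *moderated* mediations: every path may differ between the pain
and touch modalities, and the whole analysis is run separately for chronic
pain patients and healthy controls, followed by a subject-level
permutation test of the group difference in the proportion mediated.

`psymediate` implements this pipeline end to end, together with a
synthetic trial generator that reproduces the paradigm's structure, so
every stage can be exercised, calibrated and power-analysed without access
to raw data.

## The model

For one group, with centered intensity $x \in \{-1, 0, 1\}$, moderator
$w$ (modality; touch $= 0$, pain $= 1$ under the default reference
coding), mediator $M$ and outcome $Y$ (both z-scored within group ×
modality), two linear mixed models are fitted by REML with `lme4`:

$$M_{it} = \alpha_0 + \alpha_X x + \alpha_W w + \alpha_{XW} x w
          + u_{0i} + u_{1i} x + \varepsilon_{it}$$
$$Y_{it} = \gamma_0 + \gamma_X x + \gamma_W w + \gamma_M M + \gamma_{XW} x w
          + \gamma_{MW} M w + v_{0i} + v_{1i} x + \eta_{it}$$

The moderated paths at modality $w$ are
$a(w) = \alpha_X + \alpha_{XW} w$, $b(w) = \gamma_M + \gamma_{MW} w$ and
$c'(w) = \gamma_X + \gamma_{XW} w$, giving

$$\mathrm{ME}(w) = a(w)\,b(w), \qquad \mathrm{DE}(w) = c'(w), \qquad
\mathrm{TE}(w) = \mathrm{ME}(w) + \mathrm{DE}(w),$$

and the proportion mediated $\mathrm{ME}/\mathrm{TE}$. Because the outcome
model contains no $x{\times}M$ interaction, the additive decomposition
holds *exactly for every parameter draw*, not just in expectation — the
package asserts this identity draw-wise.

Inference is quasi-Bayesian Monte Carlo: `n_sims` (default 1000) draws of
each model's fixed effects from $\mathcal N(\hat\beta, \widehat{\mathrm{Cov}}
(\hat\beta))$, drawn independently for the two models (they are fitted
separately, so no cross-model covariance exists), propagated through the
formulas above. Confidence intervals are percentile intervals of the
draws; an effect is "significant" when its 95% interval excludes zero.
Modality contrasts subtract the pain and touch draws and examine the
difference distribution; two-sided $p = 2\min(\#\{d>0\}, \#\{d<0\})/n$,
with zero draws split evenly and a floor of $2/n_\text{sims}$ reported as
an inequality, never as 0.

```{r example}
library(psymediate)
cfg <- trial_config()                      # the full 22 + 22 paradigm
trials <- generate_trials(cfg, seed = 1)
pp <- preprocess_trials(trials)
fit <- mediate_trials(pp$table, "behavior_perception", group = "patient",
                      n_sims = 1000, seed = 2)
summary(fit)
modality_difference_p(fit$estimate, "prop")
```

## Preprocessing rules

`exclude_trials()` applies, in order: (1) drop misidentified-modality
trials; (2) drop zero-rated trials; (3) per subject, drop trials whose RT
lies more than 2 sample SDs from the subject's mean RT, with mean and SD
computed over the survivors of (1)–(2) in a single pass (no re-trimming).
A trial is counted under the first rule that catches it, so the report's
four counts partition the input exactly. Two deliberately exposed options
resolve ambiguities in the verbal description of such rules:

* `rt_outlier_pool`: the RT mean/SD is computed per subject *and
  modality* by default, because RT distributions differ strongly by
  modality and pooling would shift exclusions onto the slower modality;
  `"all"` pools them.
* `strata` in `zscore_by_stratum()`: z-scoring defaults to group ×
  modality strata; passing `"modality"` pools the groups.

The exclusion step is guarded by a processing-stage flag in the table's
metadata: running it twice would re-trim an already trimmed distribution
and remove extra trials, so a second call is an error.

Stratum means and SDs are stored in the table metadata; `backtransform()`
multiplies standardized effects by the outcome's stratum SD to express
them as NRS points or milliseconds per one-level intensity increase.

One consequence worth knowing: trimming RT tails is a (mild) selection on
the mediator when RT mediates, and attenuates the estimated mediation
effect by roughly 10–20% relative to untrimmed data. That is a property
of the published procedure itself, not of this implementation. The
package's calibration and recovery experiments therefore exclude the
trimming step, so that the generating value is exactly the estimand (see
below); the bundled reproduction script runs the complete pipeline,
trimming included.

## The synthetic generator

`trial_config()` parameterizes the paradigm: 22 subjects per group, 4
blocks of 54 pseudorandomized trials (9 per modality × intensity cell,
i.e. 108 pain and 108 touch trials per subject), block sequences with at
most two consecutive trials of the same intensity and three of the same
modality, a small misidentification rate (3%), occasional zero ratings
(1%), and per-subject calibrated stimulus magnitudes drawn around the
published group means (e.g. pain 479/525/571 mJ in patients, capped at
600 mJ).

The mediation structure lives on standardized latent scales: per trial,
$M = a x + u_{0i} + u_{1i} x + \varepsilon$ and
$Y = c' x + b M + v_{0i} + v_{1i} x + \eta$, with path coefficients per
group × modality. Observables are single affine maps of the latents:
ratings $= 50 + 15 \cdot \text{latent}$ clipped to $[0, 100]$, reaction
times $= 500 - 100 \cdot \text{latent}$ ms floored at 100 ms (the sign
convention makes a larger standardized behavior latent a *faster*
response, so path signs carry over to the z-scored RT analysis with the
expected negative sign in milliseconds). Default residual and
random-effect SDs (0.93/0.90 residual, 0.3 intercept, 0.1 slope) put the
latent SDs near 1, so configured paths are approximately the standardized
paths the analysis estimates; `latent_sds()` gives the exact conversion.
Defaults keep clipping below 0.1% of draws, preserving the linear-model
assumptions.

Three design choices deserve justification:

* **Default paths are back-computed from published group estimates**
  (patients: behavior-perception ME 0.067/DE 0.08 for pain, ME 0.007/DE
  0.32 for touch; controls: 0.05/0.11 and −0.005/0.34; a-paths from the
  corresponding total intensity→behavior effects). These imply proportions
  mediated of about 46%/2% (patients) and 31%/−1.5% (controls) — the
  structure the pipeline is meant to detect.
* **Rating anchors are calibration targets, not realized separations.**
  The calibration aims at ratings 30/50/70, but the published standardized
  effects (total effects of 0.15–0.35 SD per level) are mathematically
  incompatible with 20-point mean separations on a bounded 0–100 scale at
  plausible rating SDs. The generator therefore centers ratings at the
  middle anchor and lets the configured paths determine the separation,
  as they do in real data; `calibrate_intensities()` models the
  calibration step itself.
* **Block sequences** are sampled by a constrained left-to-right sampler
  with dead-end restarts (`"greedy"`, default): it satisfies both
  run-length constraints exactly, is deterministic given the seed, and is
  about three orders of magnitude faster than rejection-sampling whole
  permutations, whose acceptance rate for a 54-trial block is ~0.1%.
  `method = "rejection"` (exactly uniform over valid sequences) remains
  available and tested; trial order never enters any analysis stage, so
  the sampler choice cannot affect results.

`direction = "behavior_mediates"` (default) routes the mediator latent to
RT and the outcome latent to ratings; `"perception_mediates"` swaps them;
`"none"` forces $b = 0$. Residual SDs of zero are allowed so that the
fully degenerate noiseless configuration (every rating exactly 50, every
RT exactly 500 ms) can be used to test the observable maps.

What the generator does *not* emulate: habituation or sensitization over
blocks, skin-site rotation, inter-stimulus timing, response-box latency,
and any non-Gaussian features of real rating distributions (discreteness,
end-point clumping). Passing tests therefore demonstrate correctness of
the *pipeline* under its assumed model, not robustness of the method to
real-data pathologies.

## Group comparison by permutation

`permutation_test()` relabels subjects (all trials of a subject move
together, group sizes preserved), recomputes both groups' mediations and
the patients-minus-controls difference in proportion mediated, and reports
$p = (\#\text{qualifying} + 1)/(n_\text{perm} + 1)$. Defaults:

* **Sidedness** `"two_sided_abs"` ($|d_\text{perm}| \ge |d_\text{obs}|$):
  a literal "exceeds the observed difference" reading
  (`"one_sided_exceed"`) is selectable, but effects in either direction
  are of interest, so two-sided is the default.
* **+1 correction**: the observed statistic joins the null set, standard
  Monte-Carlo practice that makes $p = 0$ impossible.
* **Inner Monte-Carlo budget** defaults to 200 draws inside permutations
  (vs 1000 for headline estimates): the proportion-mediated point is a
  draw median and stabilizes quickly, and the permutation loop re-fits
  four mixed models per permutation.
* **Fit memoization**: the mixed-model fits depend only on the relabeling,
  so for small designs (at most `memoize_fits_below = 256` distinct
  relabelings) they are cached per relabeling. Parameter draws are fresh
  per permutation by default (`inner_seed_policy = "per_permutation"`),
  which breaks ties continuously; `"per_relabeling"` derives the draw
  seed from the relabeling itself, making the statistic a deterministic
  function of the relabeling — that is what exact enumeration
  (`method = "exact"`) uses.

## Repeated-measures ANOVA and correlations

`mixed_anova()` computes the classical univariate mixed between-within
decomposition on subject-level cell means via `stats::aov` with an
`Error(subject/(modality*intensity))` stratum: group is tested against
subjects-within-groups, each within effect against its own
subject-by-effect stratum. Uncorrected univariate tests are the default;
`gg = TRUE` adds Greenhouse–Geisser-corrected p values. Subjects with any
empty cell are dropped listwise. Degenerate all-constant data report
$F = 0$, $p = 1$ rather than 0/0. `pearson_correlations()` wraps the
textbook $t$ transform with $n - 2$ df for per-subject covariate checks
(e.g. medication load vs averaged ratings).

## Numerical choices

* **Proportion-mediated point estimate** is the *median* of the per-draw
  ratios; draws with $|\mathrm{TE}| < 10^{-12}$ are excluded (counted, and
  a modality-difference p on proportions with more than 20% exclusions
  carries a warning flag). The ratio distribution is heavy-tailed, so the
  mean is unstable; the median matches the bracketed interval summaries
  such proportions are reported with.
* **Seeds**: one master seed expands to per-stage child seeds via
  `derive_seeds()` (seed the RNG with the master, draw the children below
  $2^{31}$), so the whole pipeline is reproducible from one integer; all
  internal seeding is local and restores the caller's RNG state.
* **Covariance checks**: parameter draws reject a non-PSD covariance
  (beyond a $10^{-8}$ relative eigenvalue tolerance) instead of silently
  repairing it.
* **Non-convergence**: an `lmer` convergence failure triggers one fallback
  refit without the random intensity slope; singular (zero-variance) fits
  are accepted — they are the legitimate boundary case in which the model
  collapses to OLS, and the package's tests pin that limit against a
  hand-built GLS solution.
* **Moderator coding** defaults to reference (touch 0, pain 1); ±0.5
  effect coding is available, and per-modality effects are invariant to
  the choice (tested to $10^{-8}$).

## Validation experiments and their problem sizes

The test suite runs several simulation experiments; sizes were chosen to
give informative Monte-Carlo precision at desk-scale runtimes:

* **Interval calibration**: 400 datasets at the full paradigm scale
  (22+22 subjects × 216 trials), moderate paths ($a = 0.4$, $b = 0.35$,
  $c' = 0.15$), 500 draws each; the 95% ME interval should cover the true
  standardized ME in 95% ± 3% of runs. These runs use centering and
  z-scoring but no trial exclusion: exclusion (RT trimming) slightly
  shifts the estimand, and this experiment isolates the calibration of
  the Monte-Carlo intervals.
* **Type-I error**: 400 datasets with $b = 0$; the ME interval should
  exclude zero in about 5% of runs.
* **Permutation-null calibration**: 200 replicates of two identically
  generated groups (3+3 subjects, pooled-modality z-scoring so the
  processed data are label-independent); permutation p values should be
  uniform (Kolmogorov–Smirnov at α = 0.01).
* **Exactness**: for 3+3 subjects the Monte-Carlo permutation p at
  $10^4$ draws is compared with full enumeration of all 20 relabelings.
* **Parameter recovery**: 100 paradigm-scale replicates with patient
  proportions mediated set to 0.46 (pain) and 0.02 (touch); the estimated
  proportion intervals should cover the set values in ≥ 90% of replicates
  and the modality contrast should be detected in the majority.
  Misidentified and zero-rated trials are excluded as in the full pipeline
  (they are missing at random); RT trimming is skipped because selecting
  on the mediator shifts the estimand away from the set values by several
  percent — enough to matter when the question is recovery of what was
  set.

## Known limitations

* The mediation effect uses fixed-effect paths only; random a/b-path
  mediation (subject-varying indirect effects) is out of scope.
* No sensitivity analysis for sequential ignorability: as in any
  single-mediator design, unmeasured mediator-outcome confounding is
  untestable from these data.
* The permutation test re-fits mixed models per permutation; at the full
  paradigm scale 1000 permutations take tens of minutes on one core. The
  bundled reproduction script uses 99 permutations per contrast, which
  resolves p at 0.01 — enough to reproduce "all p > 0.05" style
  conclusions.
* `fit_lmm` fits Gaussian models with subject random intercepts and
  intensity slopes; crossed or nested-deeper random structures and
  non-Gaussian outcomes are not supported.
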