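# psymediate

Moderated multilevel mediation for trial-level psychophysics data.

## The problem

In paradigms that deliver brief painful (laser, mJ) and non-painful
tactile (von Frey, mN) stimuli at three calibrated intensities, each trial
yields a perceptual rating (0–100 NRS) and a speeded motor response
(reaction time, ms). Stimulus intensity drives both. Two mediation
questions follow:

* **perception-behavior model** — how much of the intensity effect on
  reaction times is transmitted through perception (ratings)?
* **behavior-perception model** — how much of the intensity effect on
  ratings is transmitted through motor responses?

Both are *moderated* mediations (every path may differ between pain and
touch), run separately for chronic pain patients and healthy controls,
with a subject-level permutation test for group differences.

## The model

With centered intensity $x \in \{-1,0,1\}$, modality code $w$, z-scored
mediator $M$ and outcome $Y$, two linear mixed models (REML, per-subject
random intercepts and intensity slopes) are fitted per group:

$$M = \alpha_0 + \alpha_X x + \alpha_W w + \alpha_{XW} xw + u_{0i} + u_{1i}x + \varepsilon$$
$$Y = \gamma_0 + \gamma_X x + \gamma_W w + \gamma_M M + \gamma_{XW} xw + \gamma_{MW} Mw + v_{0i} + v_{1i}x + \eta$$

At modality $w$: $a(w) = \alpha_X + \alpha_{XW}w$,
$b(w) = \gamma_M + \gamma_{MW}w$, $c'(w) = \gamma_X + \gamma_{XW}w$, and

$$\mathrm{ME}(w) = a(w)b(w),\quad \mathrm{DE}(w) = c'(w),\quad
\mathrm{TE} = \mathrm{ME} + \mathrm{DE},\quad
\text{prop. mediated} = \mathrm{ME}/\mathrm{TE}.$$

Inference is quasi-Bayesian Monte Carlo: draws from
$\mathcal N(\hat\beta, \widehat{\mathrm{Cov}}(\hat\beta))$ of each model's
fixed effects are pushed through these formulas; 95% percentile intervals,
modality contrasts by subtracting the pain and touch draws, and
back-transformation to original units (ms, NRS points) via the stored
z-score stratum SDs. Group contrasts use subject-level permutation of
group labels with the full mediation re-run per permutation.

The package also ships the supporting statistics (trial exclusion rules,
mixed between-within repeated-measures ANOVA, Pearson correlation checks)
and a synthetic trial generator reproducing the paradigm (22 + 22
subjects, 4 blocks × 54 pseudorandomized trials, calibrated magnitudes,
misidentification and zero-rating rates), so the entire pipeline runs and
can be power-analysed with no external data.

## Worked example

```r
library(psymediate)
cfg <- trial_config()                      # the 22 + 22 paradigm defaults
trials <- generate_trials(cfg, seed = 402)
pp <- preprocess_trials(trials)            # exclusion, centering, z-scores
pp$report
fit <- mediate_trials(pp$table, "behavior_perception", group = "patient",
                      n_sims = 1000, seed = 7)
fit
modality_difference_p(fit$estimate, "prop")$p_label
```

```
Trial exclusion report
  input trials       9504
  misidentified       286
  zero ratings        107
  RT outliers (2SD)   381  (pool: modality)
  retained           8730  (91.9%)
Moderated multilevel mediation (behavior-perception model, group: patient)
Moderated mediation estimate (1000 Monte-Carlo draws, 95% CIs)
  mediator: z_rt   outcome: z_rating 
  pain  ME=  0.066 [  0.042;   0.091] DE=  0.106 [  0.052;   0.161] TE=  0.172 [  0.109;   0.226] PROP=  0.383 [  0.246;   0.574]
  touch ME=  0.006 [  0.001;   0.014] DE=  0.383 [  0.324;   0.434] TE=  0.389 [  0.334;   0.441] PROP=  0.015 [  0.002;   0.038]
Effects in original units (NRS points per one intensity level)
  pain  ME=    1.00 [    0.64;     1.38]  DE=    1.61 [    0.79;     2.45]
  touch ME=    0.10 [    0.01;     0.22]  DE=    5.72 [    4.84;     6.49]
[1] "< 0.002"
```

Reading: in this synthetic patient group, motor responses mediate a
substantial share of the intensity effect on perception for pain
(ME = 0.066 z per intensity level, ≈ 1 NRS point; proportion mediated
38% [25; 57]) but almost none for touch (1.5% [0.2; 3.8]), and the
modality difference is significant (p < 0.002) — the qualitative pattern
the generator's default effect structure encodes. `permutation_test()`
then compares the proportion mediated between patients and controls;
`mixed_anova(cell_means(pp$table), "rating")` gives the supporting
repeated-measures ANOVA.

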