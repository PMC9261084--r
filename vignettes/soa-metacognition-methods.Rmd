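---
title: "Models and methods: sense-of-agency, metacognition and clinical classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sense-of-agency, metacognition and clinical classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soameta)
```

## The task and its measures

`soameta` analyses behaviour from an embodied sense-of-agency (SoA)
experiment. On each trial the participant makes a single finger movement
while watching a virtual hand; the displayed movement is either identical to
the real one or carries a sensorimotor alteration in one of two aspects — a
temporal delay of 100, 200 or 300 ms, or a spatial angular deviation of 6,
10 or 14 degrees. The participant answers a yes/no question ("was the
movement identical to mine?") and rates confidence on a continuous slider
from −3 to 3. A session has 240 trials in five 48-trial blocks: 25%
unaltered, and 30 trials for each aspect × magnitude cell. Because the two
aspects have incommensurable physical units, all analyses use a common
ordinal magnitude coding 0–3 (0 = unaltered); the single pool of unaltered
trials serves as level 0 for both aspects.

Four families of statistics are computed per participant and compared
between a psychosis group and a control group:

* **Detection**: hit rate H (answering "identical" on unaltered trials),
  false-alarm rate FA (answering "identical" on altered trials, pooled over
  aspects and magnitudes), sensitivity $d' = z(H) - z(FA)$ and criterion
  $c = -\tfrac{1}{2}\left(z(H) + z(FA)\right)$, where $z$ is the
  standard-normal quantile. Under this signal = unaltered convention a
  negative $c$ is a bias toward claiming agency.
* **Metacognition**: Goodman–Kruskal $\gamma$ between trial confidence and
  judgment accuracy: over all trial pairs, $\gamma = (C - D)/(C + D)$ with
  $C$ the concordant and $D$ the discordant pairs, pairs tied on either
  variable excluded.
* **Classification**: a leave-$p$-out nearest-centroid classifier on the
  two-dimensional vector of per-aspect psychometric slopes (least-squares
  slope of the self-attribution proportion on magnitude level 0–3), with a
  label-permutation null and a two-sample Kolmogorov–Smirnov comparison.
* **Trial-level models**: BIC-compared mixed-effects ladders for the binary
  agency judgment (logistic) and for confidence (linear), plus Pearson
  correlations between the participant-level measures and clinical scales
  (PANSS for patients, SPQ-B for controls).

## The synthetic observer and cohort

Every stage is testable without access to the original data through a
generative model of the task (`build_cohort()`). The observer is
equal-variance Gaussian signal detection: on a trial at level $\ell$ of
aspect $a$, latent evidence $x \sim N(\delta_{a\ell}, 1)$ with
$\delta_{a0} = 0$, and the participant answers "identical" when $x <
\kappa$. Confidence is a gain-scaled evidence margin with additive read-out
noise, clipped to the slider:

$$\text{conf} = \mathrm{clip}\left(g\,|x - \kappa| + b + \varepsilon,\ -3,\ 3\right),
\qquad \varepsilon \sim N(0, \sigma_\text{meta}).$$

Participants are drawn from group-level distributions:

* per-aspect discriminability increments (three per aspect, drawn
  independently for the temporal and spatial aspects, clamped at zero and
  cumulated so $\delta_1 \le \delta_2 \le \delta_3$ within each aspect);
* a decision criterion $\kappa \sim N(\kappa_\mu, \kappa_\sigma)$ shared by
  both aspects;
* a confidence gain $g \sim N(g_\mu, g_\sigma)$ — the participant's
  metacognitive efficiency, allowed to straddle zero in the patient group
  (a negative gain produces confidence that anti-tracks the evidence);
* trial missingness at a group rate (1.9% controls, 8.4% patients),
  with a reason drawn uniformly from {no movement, camera malfunction, no
  response}; such trials lose response and confidence and are flagged for
  the pre-registered exclusion step;
* clinical scores from truncated-normal marginals (integer-rounded), with
  one structural coupling: in the patient group, PANSS Positive decreases
  with the participant's standardized confidence gain, so worse
  metacognitive efficiency (hence lower realized $\gamma$) predicts more
  positive symptoms.

Aspect-specific sensitivity is the generator's main axis of individual
variation. It was chosen deliberately: criterion scatter moves the pooled
$d'$ one-for-one while producing correlated, weakly discriminative slope
scatter, whereas independent per-aspect increments dilute into pooled $d'$
by $1/\sqrt{2}$ but drive the classifier's two-dimensional slope spread in
full. This is what lets one parameter set satisfy both the group-mean
statistics and a realistic (~90%, not ~99%) classifier accuracy.

### Calibration

The default parameters ship in
`inst/extdata/default_generative_params.json`, produced by
`scripts/calibrate.R` — a staged coarse grid search, not hand-tuned
constants. The stages: (A) per group, a grid over the criterion mean and a
common scale on the discriminability increments, scored against mean $d'$
(1.8 control / 0.76 psychosis, weighted double) and criterion (−0.43 /
−0.73); (S) a small grid over the between-subject spreads, keeping the one
whose full-cohort classifier accuracy sits nearest the middle of the
0.80–0.95 band; (B) the control confidence gain that yields mean $\gamma =
0.26$ at $\sigma_\text{meta} = 1$, and for patients the
$(g_\sigma, \sigma_\text{meta})$ pair maximizing the correlation between
gain and realized $\gamma$ (the channel the clinical coupling uses) with
$g_\mu = 0$ keeping mean $\gamma$ near zero; (C) a PANSS-Positive coupling
at 85% of the scale's SD. `calibration_targets()` records the benchmark
values; the pipeline summary flags whether a run reproduces them.

### What the generator does and does not emulate

It reproduces the design (trial counts, blocks, magnitudes, 25% unaltered),
group differences in sensitivity, bias, psychometric slopes and
confidence–accuracy coupling, group-specific missingness, and one clinical
coupling. It does **not** model learning or block-order effects, reaction
times, kinematics, aspect asymmetries at the population level, or any
clinical structure beyond the single coupling. Tests passing on this cohort
therefore show that the analysis code recovers known structure of this
kind; they do not certify behaviour on real data with features the
generator lacks (sequential dependencies, non-Gaussian evidence,
scale-use idiosyncrasies in confidence).

One consequence of the observer model is worth stating plainly: type-2
information is bounded by type-1 evidence. At the patient group's $d'
\approx 0.76$ the latent evidence carries little information about
accuracy, so even a noiseless read-out yields a small $\gamma$, and
between-patient $\gamma$ variance is compressed. The shipped
$\gamma$–PANSS-Positive coupling is therefore calibrated to the attainable
maximum of this mechanism (analytic target near $r = -0.3$) rather than to
a larger value; the recovery test compares the realized correlation to the
coupling's own large-sample target.

## Analysis conventions and numerical choices

* **Extreme-rate correction**: the log-linear rule $(\text{count} + 0.5) /
  (n + 1)$ is applied to H and FA for *every* participant, not only those
  at the boundary, avoiding conditional bias. `dprime_criterion()` refuses
  rates at exactly 0 or 1.
* **Undefined $\gamma$**: when accuracy has no contrast or confidence is
  constant across informative pairs, $C + D = 0$ and $\gamma$ does not
  exist. `gk_gamma()` signals a classed error
  (`soameta_undefined_gamma`); `gamma_summary()` converts it to `NA` with a
  warning and group tests drop such participants.
* **Welch tests** with Welch–Satterthwaite degrees of freedom and pooled-SD
  Cohen's d are used for group comparisons; one-sample t-tests check each
  group's $\gamma$ against zero.
* **Classifier**: per iteration, the same fraction of each group is left
  out; centroids are the means of the *retained* participants'
  (temporal, spatial) slope vectors computed from their full retained
  trials; each left-out participant is assigned to the nearer centroid in
  Euclidean distance. Trial subsampling (`n_trials_sampled`) applies to the
  left-out participants only — the use case is classifying a new individual
  from few trials against established group norms — with
  `subsample_retained = TRUE` available for the alternative reading. A
  subsample draw that leaves any aspect × level cell empty is rejected and
  retried (at most 100 times). Exact centroid ties (measure-zero with
  continuous proportions) deterministically go to the control group with a
  warning. Two independent seeded RNG streams drive participant selection
  and trial sampling, so grid cells with the same seed share leave-out
  sequences. The "first block" trial pool is block 1 (the first 48
  presented trials).
* **Model ladders**: magnitude enters as centred ordinal level (0–3 − 1.5);
  group as a centred contrast (control +1/2, psychosis −1/2), so the
  magnitude term is the cross-group average slope, the group term the
  control-minus-psychosis difference, and the interaction the slope
  difference — the coding under which the benchmark sign pattern (all three
  negative) is coherent. Aspect is a centred ±1/2 contrast, 0 on unaltered
  trials, so aspect effects are identified from altered trials only. The
  agency ladder is logistic (`lme4::glmer`, `nAGQ = 0` by default — the
  fast penalized-likelihood approximation, adequate for selection and sign
  work; set `nAGQ = 1` for Laplace) with diagonal per-participant random
  intercept, magnitude and aspect slopes. The aspect random slope is
  included in *all* candidates because the generator's individual
  aspect-specific sensitivity otherwise masquerades as a spurious fixed
  aspect effect in a 14,000-trial fit. The confidence ladder is linear
  (maximum likelihood for BIC comparability) with an orthogonal quadratic
  polynomial in magnitude — confidence is high when the movement is clearly
  one's own *or* clearly altered — accuracy coded correct = 1, and
  per-participant random intercept + magnitude slope; the winner is
  refitted through `lmerTest` for Satterthwaite p-values. ΔBIC grades:
  2–6 positive, 6–10 strong, >10 very strong. Non-convergent candidates are
  recorded and the ladder continues; singular random-effect fits are
  flagged, not discarded.
* **Correlations**: Pearson r per measure × scale cell, two-sided p,
  uncorrected (a Holm-adjusted column is provided alongside); cells with
  fewer than three complete pairs or a constant vector yield `NA`.
* **Determinism**: `build_cohort()`, `run_classifier()`,
  `permutation_null()` and `run_pipeline()` are bit-reproducible given
  their seeds; the pipeline derives all stage seeds from one master seed.

## Problem sizes used by the test suite

The shipped tests run the analyses at sizes chosen to exercise the
study-scale behaviour while keeping a full run in the minutes range on one
CPU: the calibrated-cohort checks use the default 30-per-group cohort with
2,000 classifier and null iterations (10,000 remains the documented
production setting and is a single argument away); the robustness grid uses
{240, 120, 48, 24} trials × {0.2, 0.5, 0.8} leave-out at 400 iterations;
model-selection and sign-recovery checks use 100 cohorts of 15 participants
per group, which preserves the trial-level effects that drive selection;
CI-coverage checks simulate directly from the logistic mixed model with 24
participants. Monte-Carlo tolerances in the tests are set to the
corresponding sampling error.

## Known limitations

* Wald intervals from mixed logistic fits under-cover with very few
  clusters (≈80% at 10 participants in our checks, ≈92% at 24); the
  coverage test documents and works at the larger size. Satterthwaite
  corrections apply only to the linear ladder.
* $\gamma$ inherits first-order performance: group differences in $\gamma$
  partly reflect the $d'$ difference, and the patient group's $\gamma$
  spread is mechanically compressed (see above). Measures that equate
  first-order performance (meta-d′) are out of scope here because the task
  does not equate difficulty.
* The unaltered-trial pool is shared by both aspects in per-aspect
  analyses; per-aspect statistics are therefore not independent between
  aspects.
* The classifier is deliberately minimal (two slopes, nearest centroid):
  it is the study's instrument, not a tuned machine-learning model, and no
  probability calibration is attempted.
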