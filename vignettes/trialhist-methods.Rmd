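---
title: "Models and methods in trialhist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in trialhist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialhist)
```

`trialhist` analyzes two-alternative odor-cued spatial choice
experiments: on every trial a mouse enters a central odor port, waits
for a valve to open (~144 ms after entry), samples a binary mixture of
two odors, waits for a go signal (~434 ms after the valve), and reports
the dominant odor by moving to the left or right reward port. Although
only the current stimulus is task-relevant, both behavior and neural
activity carry traces of the previous trial. The package provides the
statistical machinery to quantify those traces and a generator that
produces sessions with known ground truth, so every analysis can be
validated by parameter recovery rather than by eye.

## The behavioral model

Choice is modeled with a logistic function, `p(left) = 1/(1+e^-eta)`.
All models share the stimulus kernel

`eta0 = b0 + bOdorL*xOdorL + bOdorR*xOdorR`,

with `xOdor = max(0, (f - 0.5)/0.5)` for the fraction `f` of the
corresponding odor, so each regressor ranges over [0, 1] and at most one
is positive per trial. The raw `(f - 0.5)/0.5` formula is negative for
the non-dominant side; clamping at 0 keeps the two terms separately
interpretable as left- and right-odor influences, and a mouse that
follows the stimulus has `bOdorL > 0` and `bOdorR < 0` (both terms act
on the *left*-choice log-odds — a sign convention worth internalizing
before reading fitted tables).

The extended models add, for each lag `n`, a choice term
(left = +1, right = -1, none = 0) and side-specific outcome terms
(+1 rewarded / -1 unrewarded at that side, 0 otherwise). Two exclusion
rules, both with a 1.5-s budget, define the analyzable data: a trial
with no reward-port entry within 1.5 s of odor-port exit contributes no
response, and a predecessor counts as "no choice" (all lag regressors 0)
if it was itself excluded or if the next trial was not initiated within
1.5 s of reward-port exit. Lags never cross session boundaries; the
first trials of a session code their unavailable lags as 0.

Fitting is maximum likelihood by iteratively reweighted least squares
(`stats::glm.fit`, binomial family, coefficient tolerance 1e-10, at most
100 iterations) with Wald 95% confidence intervals. Perfect or
quasi-perfect separation is detected (fitted probabilities pinned to
0/1, or |coefficient| > 25) and flagged rather than silently diverging;
rank-deficient designs error with the names of the collinear columns.
One coefficient vector is normally fitted per mouse across its sessions;
any subset can be fitted by passing the subsetted table.

### Cross-validated model comparison

Models of different complexity are compared by their ability to
*generate* choices that match the data, not by in-sample likelihood: for
one session, a random half of its included trials (stratified by odor
mixture, which stabilizes accuracy at ~450-trial sessions) is held out;
both models are fitted on all remaining trials of that mouse; each
fitted model then draws Bernoulli choices on the held-out trials, and
accuracy is the percentage matching the actual choices. Fifty redraws
are averaged per session, and a one-tailed paired t test across sessions
asks whether the richer model improves accuracy. Sampling (rather than
thresholding at 0.5) is the default because the comparison is between
generative models; a deterministic mode exists for sensitivity checks.
Because simulated-choice accuracy is capped by the intrinsic
stochasticity of the fitted probabilities, improvements are a few
percentage points even for clearly better models — the paired test, not
the magnitude, carries the inference.

### Inactivation sessions

Muscimol sets (saline-pre, muscimol, saline-post) are pooled and fitted
with `eta0 + bMuscimol*xMuscimol`; positive values are a leftward
(ipsilateral, for left-hemisphere infusion) influence. The reduced model
`eta0 + bChoice1*xChoice1`, fitted separately per condition, asks
whether inactivation weakens the dependence on the previous choice; the
across-set comparison uses a one-tailed Mann-Whitney U test.

A caveat the package's own simulations exposed: because the reduced
model omits outcome terms, any generative win-stay *outcome* coupling
loads onto `bChoice1` (on ~75%-rewarded sessions roughly half the
outcome coefficient). The muscimol-vs-saline contrast is unaffected —
the load is common to both conditions — but absolute reduced-model
coefficients should not be read as pure choice-history effects, and the
"scale bChoice1 to zero implies the fitted CI covers zero" identity only
holds for generators without outcome terms.

## ROC preference

A unit's selectivity between two trial groups is
`preference = 2*(ROC_area - 0.5)`, where ROC_area is the probability
that a randomly drawn epoch firing rate from the positively oriented
group (contralateral choices, or rewarded trials) exceeds one from the
other group, ties counting 1/2 — the Mann-Whitney U normalized by
`na*nb`. It is computed from mid-ranks in the algebraic form
`(2U - na*nb)/(na*nb)`, which makes the antisymmetry
`pref(A,B) = -pref(B,A)` exact in floating point and guarantees
invariance under any strictly increasing transform of the rates. The
default epoch is the pre-stimulus window, odor-port entry to 100 ms
after valve open, before stimulus information can reach the recorded
structure; epochs are half-open `[start, end)`, so a spike exactly at
the boundary belongs to the later interval.

Significance uses a Monte Carlo permutation test: rates are reassigned
to the two groups (sizes preserved) 1000 times. The published
description of the test counts permuted preferences "exceeding" the
observed one — one-sided as written — yet both preference signs are
reported as significant, so the consistent reading, and the default
here, is two-sided on |preference| with the add-one correction
`(k+1)/(n_perm+1)`; a one-sided mode is available by flag. Units with
fewer than 4 trials in either group, or below 2 spikes/s in both groups
(assessed as the mean rate within the analysis epoch; the published rule
does not state its interval), are excluded. Because pooled mid-ranks are
permutation-invariant, each permuted preference is computed from a
random rank subset, making the test O(n) per permutation.

Population summaries report per-lag fractions of significantly
positive/negative units, a chi-square test on the sign counts, a
Kruskal-Wallis test (with pairwise Wilcoxon post-hocs) on preference
magnitudes across lags, and the lag-0/lag-1 preference correlation. The
port-vs-direction control computes choice preference separately during
the outbound movement (odor-port exit to reward-port entry) and the
return movement (reward-port exit to the next odor-port entry — the
published description gives no exact bounds, and this is the widest
unambiguous window): the two movements are in opposite physical
directions, so matching preference signs mark a unit as coding the
chosen port, inverted signs as coding movement direction.

## Sliding-window encoding regression

Firing rate in 100-ms bins stepped every 10 ms, aligned to valve open,
odor-port exit, or reward-port entry (the left-panel alignment of the
figure narrative is configurable between valve open and port entry;
valve open is the default), is regressed per bin on four
hemisphere-referenced regressors: previous and current choice
(contralateral = +1) and previous and current outcome (rewarded = +1),
no-choice trials coding 0. Per-bin OLS with t-based 95% CIs; a
coefficient is significant when its CI excludes zero. Bins are centered
on their timestamps, and neighboring bins share 90% of their data, so
per-bin significance inherits that correlation; no multiplicity
correction is applied, matching the published display convention, and
the package's own specificity checks therefore evaluate false-positive
rates only at independent (100-ms) spacing. The design matrix is shared
across bins, so one QR factorization fits all bins, and a
rank-deficient design (e.g., every previous choice identical) marks the
aliased coefficients undefined everywhere rather than failing bin by
bin.

## Choice linkage

For each unit with a significant previous-choice preference, the
question is whether its pre-stimulus rate predicts the upcoming choice
when the stimulus is ambiguous (40-60% left odor). Rates are normalized
to the unit's maximum across trials *separately within each
previous-choice condition* — the maximum is taken over all trials of the
condition, not only ambiguous ones, the more stable of the two readings
of the published description — and each ambiguous trial contributes a
point (normalized rate, indicator of choosing the unit's preferred
port). The statistic is the least-squares slope through the raw points;
significance is a two-sided permutation test shuffling the indicators
(1000 repeats, add-one corrected). A logistic fit of the same points is
available and agrees in sign classification on essentially all units.

Per-condition normalization removes the *scale* difference between
previous-choice conditions but not the full confound: if a unit's rate
and the animal's choice both depend on the previous choice, slopes bias
positive even without any trial-by-trial coupling (the calibration
suite measures ~14% positive classifications in such a regime). This is
the "indirect pathway" caveat of the original analysis, which addressed
it by showing positive slopes within mice whose behavior lacked
previous-choice dependence. Consequently the package's null calibration
uses a generator in which the indicator is genuinely independent of the
rate (no behavioral history dependence), and users should interpret
population slope counts with the same care.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
task's stated statistics: sessions of 451 +/- 115 trials; seven mixtures
95/5, 80/20, 60/40, 50/50, 40/60, 20/80, 5/95 drawn pseudo-randomly;
valve delay 144 +/- 64 ms; go delay 434 +/- 68 ms; reward delay 41 +/-
32 ms. Delays are truncated normals floored at 10 ms (the task reports
only mean +/- SD; a floor keeps event times ordered). Quantities the
task description leaves open were chosen once, for realism, and are
documented here: go-to-exit reaction 250 +/- 50 ms; movement duration
350 +/- 80 ms; drinking 1.0 +/- 0.2 s; inter-trial interval (reward-port
exit to next entry) 0.5 +/- 0.2 s, placing normal re-initiation inside
the 1.5-s history-validity window so that history effects are actually
expressed; no-choice trials at 2% (existence reported, frequency not).
A lapse parameter (default 0) lets recovery tests probe robustness;
analyses never assume it.

Choices are drawn sequentially from the extended model itself, with
history regressors computed from the already-simulated past by the same
coding rules the fitting code uses, so generator truth is the oracle for
every behavioral test. Because the next choice needs the previous
*outcome*, outcomes are assigned as choices are drawn (dominant-odor
rule; 50/50 trials rewarded with probability 0.5); the standalone
outcome-assignment operation applies the identical rule to an existing
table. Spike trains are inhomogeneous Poisson processes: a baseline rate
plus event-anchored windowed modulations of amplitude x (-1/0/+1 neural
coding), floored at zero, sampled exactly as per-segment Poisson counts
with uniform placement within segments. Inactivation sets modify the
muscimol session's generative parameters only: `b0 + delta_bias` and
`bChoice1 * choice1_scale`.

For the choice-linkage analysis, coupled units add a per-trial standard
normal latent `z` to both the pre-stimulus rate (`rate_gain * z`) and
the left-choice log-odds (`choice_gain * z`) — the simplest mechanism
that produces genuine trial-by-trial linkage. The default gains
(5 spikes/s and 1.2 log-odds per latent SD) represent a strongly coupled
unit, detectable on a single ~300-trial session about 9 times in 10;
weaker coupling (e.g., 4 and 0.8) grades detection down to roughly
two-thirds, toward the mixed regime real populations show.

### What a green test does and does not establish

The generator emulates the statistical structure the analyses assume:
event-locked rate modulations, Poisson spiking, logistic choice with
within-session history. It does not emulate slow nonstationarity
(drift, satiety), bursting or refractory spike-train structure,
correlated noise across simultaneously recorded units, learning, or
body-position confounds. Green recovery tests establish that the
estimators are correct and calibrated under the stated model — not that
the model is true of any particular dataset.

## Numerical and design choices

- Seeds: every stochastic operation takes an explicit seed; composite
  simulators derive per-part sub-seeds deterministically (multiplicative
  congruential step, kept below 2^31), so one seed reproduces a whole
  cohort byte-for-byte. RNG state is restored after every seeded call.
- Epochs and bins are half-open; times are double-precision seconds from
  session start; 0-based trial indices within session.
- Wald CIs throughout (the published methods state only "95% confidence
  intervals"); t-based for per-bin OLS.
- Permutation p-values use the add-one correction, so the smallest
  attainable p at 1000 permutations is 1/1001.
- Interchange formats are headered CSV (choice tokens `L`/`R`/`none`)
  and JSON configs with an explicit seed and rejection of unknown keys;
  all readers/writers are lossless round-trips on valid data.
- The packaged demo pipeline (`inst/extdata/demo_config.json`) uses a
  deliberately small cohort (2 mice x 3 sessions x ~150 trials, 3 units
  per session, reduced permutation and CV counts) so the end-to-end run
  finishes in seconds while exercising every stage; its outputs are
  bit-reproducible from the config alone.

## Known limitations

- Wald intervals undercover slightly in small samples or near
  separation; the recovery suite validates coverage at the
  ~5000-trials-per-mouse scale, not for single short sessions.
- The no-multiplicity convention for per-bin significance is inherited
  from the display convention it reproduces; treat per-bin traces as
  descriptive.
- Reduced-model `bChoice1` absorbs omitted outcome effects (see above).
- The movement-direction control assumes the return movement is
  uncontaminated by the next trial's preparation; with very short
  inter-trial intervals the two are not separable.
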