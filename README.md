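# trialhist

Analyses of how recent trial history shapes choice behavior and
single-neuron activity in two-alternative odor-cued spatial choice
tasks, with a ground-truth synthetic-session generator so that every
stage is testable without external recordings.

## Who this is for

Systems/behavioral neuroscientists analyzing head-fixed or freely moving
two-alternative forced-choice experiments in which an animal samples a
binary odor mixture at a central port and reports the dominant odor at a
left or right reward port, with simultaneous extracellular unit
recordings and (optionally) reversible pharmacological inactivation
sessions.

## What it computes

**History-dependent choice models.** The probability of a left choice is
modeled as `p = 1 / (1 + exp(-eta))` with

```
eta = b0 + bOdorL * xOdorL + bOdorR * xOdorR
      + sum_n ( bChoice_n * xChoice_n
              + bOutcomeL_n * xOutcomeL_n
              + bOutcomeR_n * xOutcomeR_n )      (extended models)
      [ + bMuscimol * xMuscimol ]                (inactivation model)
```

where `xOdor* = max(0, (f - 0.5) / 0.5)` codes the strength of the
dominant odor, `xChoice_n` codes the choice `n` trials back
(left = +1, right = -1, no choice = 0) and the outcome regressors code
rewarded (+1) / unrewarded (-1) choices at the named side. Trials
without a reward-port entry within 1.5 s of odor-port exit are excluded;
predecessors that were excluded or were not followed by re-initiation
within 1.5 s count as "no choice". Models are compared by
cross-validated simulated-choice accuracy (random 50% test splits of a
session, both models trained on the animal's remaining trials, 50
repeats, one-tailed paired t test across sessions).

**ROC preference index.** For a unit and any trial grouping (choice or
outcome, current trial or 1-2 back), `preference = 2 * (ROC_area - 0.5)`
in [-1, 1], where ROC_area is the probability that a random firing rate
from the positively oriented group (contralateral / rewarded) exceeds
one from the other group (ties 1/2) -- the normalized Mann-Whitney U.
Significance by Monte Carlo permutation (1000 group reassignments,
two-sided on |preference|, add-one corrected); units with < 4 trials in
either group or < 2 spikes/s in both groups are excluded. The default
epoch is the pre-stimulus window (odor-port entry to 100 ms after odor
valve open).

**Sliding-window encoding regression.** Per 100-ms bin stepped every
10 ms, OLS of firing rate on previous/current choice and outcome in
hemisphere-referenced -1/0/+1 coding, with t-based 95% CIs and per-bin
significance, plus population time-courses (mean coefficients and
fraction of significant units).

**Choice linkage.** For units selective for the previous choice: on
ambiguous trials (40-60% left odor), the least-squares slope of the
preferred-port indicator on the max-normalized pre-stimulus rate, with
a two-sided permutation test; population counts of positive/negative
slopes per mouse.

**Inactivation contrasts.** `bMuscimol` on pooled saline/muscimol
session sets, reduced-model `bChoice_1` compared between conditions
(one-tailed Mann-Whitney U), and movement latency/duration contrasts.

## Worked example

```r
library(trialhist)

cfg <- task_config()                      # 451 +/- 115 trials/session,
                                          # 7 mixtures, task delays
bp  <- behavior_params(beta_choice = 0.7) # win-stay generator
np  <- neuron_params(baseline_rate = 10, modulation = list(
  list(regressor = "prev_choice", amplitude = 5,
       event = "odor_port_entry", start = -0.05, end = 0.35)))

m <- simulate_mouse(cfg, bp, n_sessions = 4,
                    neurons_per_session = list(np), seed = 7)

fit_choice_model(m$trials, "extended1")
#> <logistic_fit 'extended1' | n = 1676 | logLik = -774.01>
#>               estimate      lo      hi
#> (Intercept)    -0.0636 -0.2620  0.1348
#> x_odor_L        2.9391  2.4587  3.4194
#> x_odor_R       -2.7151 -3.1908 -2.2395
#> x_choice_1      0.7344  0.5879  0.8810
#> x_outcome_L_1   0.2830  0.0820  0.4840
#> x_outcome_R_1  -0.3720 -0.5665 -0.1776
```

The fitted coefficients recover the generating values: a positive
`x_choice_1` is the tendency to repeat the previous choice, and the
outcome terms (positive for left, negative for right) are the extra pull
toward the previously rewarded side. The odor terms show the expected
strong, symmetric stimulus control.

```r
sp <- m$spikes[[1]]
tr <- m$trials[m$trials$session_id == sp$session_id, ]
unit_preference(sp, tr, variable = "choice", lag = 1, seed = 1)
#>      unit_id mouse_id session_id variable lag preference     p_value included
#> 1 m1_s01_u01       m1     m1_s01   choice   1  0.7566335 0.000999001     TRUE
#>   n_pos n_neg mean_rate_pos mean_rate_neg
#> 1   145   118      13.97541      4.643295
```

The unit prefers contralateral previous choices (preference 0.76 of a
possible 1; permutation p = 0.001): its pre-stimulus rate carries the
previous trial's choice, the signature this package is built to detect
and link to upcoming behavior.

## Command line

```sh
Rscript -e 'trialhist::run_cli()' simulate --config cfg.json --out out/
Rscript -e 'trialhist::run_cli()' behavior fit --trials out/trials.csv --out out/
Rscript -e 'trialhist::run_cli()' run --config inst/extdata/demo_config.json --out demo/
```

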