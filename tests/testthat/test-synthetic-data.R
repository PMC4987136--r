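test_that("trial events honor configured delays, ordering and determinism", {
  cfg <- task_config(valve_delay_sd_s = 0, go_delay_sd_s = 0,
                     reward_delay_sd_s = 0)
  tr <- simulate_trial_events(cfg, 50, seed = 1)
  expect_equal(tr$valve_open - tr$odor_port_entry, rep(0.144, 50))
  expect_equal(tr$go - tr$valve_open, rep(0.434, 50))

  one <- simulate_trial_events(task_config(), 1, seed = 2)
  expect_equal(nrow(one), 1L)
  ev <- unlist(one[1, c("odor_port_entry", "valve_open", "go",
                        "odor_port_exit", "reward_port_entry",
                        "reward_port_exit")])
  expect_true(all(diff(ev) > 0))

  a <- simulate_trial_events(task_config(), 100, seed = 7)
  b <- simulate_trial_events(task_config(), 100, seed = 7)
  expect_identical(a, b)

  expect_error(task_config(valve_delay_mean_s = -1), "positive")
  expect_error(task_config(odor_set = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("event ordering holds on every completed trial of random sessions", {
  for (s in 1:5) {
    ses <- simulate_session(quick_cfg(), behavior_params(), n_trials = 120,
                            seed = 100 + s)
    tr <- ses$trials
    done <- tr$choice != "none"
    ev <- as.matrix(tr[done, c("odor_port_entry", "valve_open", "go",
                               "odor_port_exit", "reward_port_entry",
                               "reward_port_exit")])
    expect_true(all(apply(ev, 1, function(r) all(diff(r) > 0))))
  }
})

test_that("choice marginals match the generative logistic", {
  # no influences at all: long-run left fraction 1/2
  null_bp <- behavior_params(beta0 = 0, beta_odor_L = 0, beta_odor_R = 0,
                             beta_choice = 0, beta_outcome_L = 0,
                             beta_outcome_R = 0)
  tr <- simulate_trial_events(quick_cfg(), 10000, seed = 3)
  tr <- simulate_choices(tr, null_bp, no_choice_rate = 0, seed = 4)
  p <- mean(tr$choice == "left")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))

  # odor-only model on 95/5 trials: p(left) = plogis(4 * 0.9)
  bp <- behavior_params(beta0 = 0, beta_odor_L = 4, beta_odor_R = -4,
                        beta_choice = 0, beta_outcome_L = 0,
                        beta_outcome_R = 0)
  cfg95 <- quick_cfg(odor_set = 0.95)
  tr <- simulate_choices(simulate_trial_events(cfg95, 10000, seed = 5),
                         bp, no_choice_rate = 0, seed = 6)
  expect_lt(abs(mean(tr$choice == "left") - plogis(3.6)), 0.01)

  # overwhelming stay term: repeats almost surely
  bp_stay <- behavior_params(beta0 = 0, beta_odor_L = 0, beta_odor_R = 0,
                             beta_choice = 10, beta_outcome_L = 0,
                             beta_outcome_R = 0)
  tr <- simulate_choices(simulate_trial_events(quick_cfg(), 3000, seed = 8),
                         bp_stay, no_choice_rate = 0, seed = 9)
  stay <- tr$choice[-1] == tr$choice[-nrow(tr)]
  expect_gt(mean(stay), 0.99)
})

test_that("outcomes follow the dominant-odor rule", {
  tr <- manual_trials(c("left", "right", "left"),
                      fractions = c(0.80, 0.80, 0.95))
  out <- assign_outcomes(tr, seed = 1)
  expect_equal(out$rewarded, c(1L, 0L, 1L))

  tr5050 <- manual_trials(rep("left", 5), fractions = rep(0.5, 5))
  # chance reward at 50/50, checked in aggregate
  big <- do.call(rbind, replicate(2000, tr5050, simplify = FALSE))
  big$session_id <- rep(seq_len(2000), each = 5)
  out <- assign_outcomes(big, seed = 2)
  expect_lt(abs(mean(out$rewarded) - 0.5), 3 * sqrt(0.25 / 10000))

  bad <- tr; bad$odor_left_fraction[2] <- NA
  expect_error(assign_outcomes(bad, seed = 1), "odor fraction")
})

test_that("spike trains are Poisson with the configured rate structure", {
  tr <- manual_trials(rep(c("left", "right"), 25))
  t_end <- 100
  np <- neuron_params(baseline_rate = 20)
  sp <- simulate_spike_train(tr, np, t_end = t_end, seed = 10)
  expect_lt(abs(length(sp$spike_times) - 2000), 4 * sqrt(2000))

  # dispersion of disjoint-window counts ~ 1
  counts <- vapply(1:200, function(i) {
    length(simulate_spike_train(tr, neuron_params(baseline_rate = 15),
                                t_end = 10, seed = 1000 + i)$spike_times)
  }, numeric(1))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)

  # prev-choice modulation: rate difference in-window = 2 * amplitude
  np <- neuron_params(baseline_rate = 20, modulation = list(
    list(regressor = "prev_choice", amplitude = 5,
         event = "odor_port_entry", start = 0, end = 0.244)))
  tr2 <- manual_trials(rep(c("left", "right"), 150))
  sp2 <- simulate_spike_train(tr2, np, recorded_side = "left", seed = 11)
  rates <- epoch_rate(sp2, tr2, epoch_spec("w", "odor_port_entry",
                                           "odor_port_entry",
                                           end_offset_s = 0.244))
  regs <- code_regressors(tr2, "left")
  d <- mean(rates[regs$x_choice_prev == 1]) -
    mean(rates[regs$x_choice_prev == -1])
  expect_lt(abs(d - 10), 2.5)

  # rate floored at zero: suppressed (x = +1) windows are silent while
  # enhanced (x = -1) windows fire at 1 - 5 * (-1) = 6 spikes/s
  np0 <- neuron_params(baseline_rate = 1, modulation = list(
    list(regressor = "prev_choice", amplitude = -5,
         event = "odor_port_entry", start = 0, end = 0.244)))
  sp0 <- simulate_spike_train(tr2, np0, recorded_side = "left", seed = 12)
  r0 <- epoch_rate(sp0, tr2, epoch_spec("w", "odor_port_entry",
                                        "odor_port_entry",
                                        end_offset_s = 0.244))
  expect_true(all(r0[regs$x_choice_prev == 1] == 0))
  expect_gt(mean(r0[regs$x_choice_prev == -1]), 3)
})

test_that("sessions are reproducible byte-for-byte under a fixed seed", {
  np <- neuron_params(baseline_rate = 8, modulation = list(
    list(regressor = "prev_choice", amplitude = 3,
         event = "odor_port_entry", start = -0.05, end = 0.35)))
  a <- simulate_session(quick_cfg(), behavior_params(), list(np),
                        n_trials = 80, seed = 42)
  b <- simulate_session(quick_cfg(), behavior_params(), list(np),
                        n_trials = 80, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("inactivation sets implement the bias and choice1 manipulations", {
  cfg <- quick_cfg(n_trials_mean = 2000)
  s <- simulate_inactivation_set(cfg, behavior_params(), delta_bias = 1,
                                 choice1_scale = 1, seed = 13)
  left_frac <- function(tr) mean(tr$choice[tr$choice != "none"] == "left")
  expect_gt(left_frac(s$muscimol$trials), left_frac(s$saline_pre$trials))
  expect_gt(left_frac(s$muscimol$trials), left_frac(s$saline_post$trials))

  # per-mixture monotonicity under a large bias
  mus <- s$muscimol$trials; sal <- rbind(s$saline_pre$trials,
                                         s$saline_post$trials)
  for (f in unique(mus$odor_left_fraction)) {
    pm <- left_frac(mus[mus$odor_left_fraction == f, ])
    ps <- left_frac(sal[sal$odor_left_fraction == f, ])
    expect_gt(pm, ps)
  }

  # choice1_scale = 0 removes previous-choice dependence (generator
  # without outcome terms: the reduced model has no outcome regressors,
  # so generative win-stay outcome coupling would load onto x_choice_1)
  bp_nohist <- behavior_params(beta_outcome_L = 0, beta_outcome_R = 0)
  s0 <- simulate_inactivation_set(cfg, bp_nohist, delta_bias = 0,
                                  choice1_scale = 0, seed = 14)
  f <- fit_reduced_choice1(s0$trials, "muscimol")
  expect_true(f$ci95["x_choice_1", "lo"] < 0 &&
                f$ci95["x_choice_1", "hi"] > 0)
  expect_error(simulate_inactivation_set(cfg, behavior_params(),
                                         choice1_scale = 2),
               "choice1_scale")
})
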