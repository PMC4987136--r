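test_that("design codings follow the trial-history rules", {
  # previous trial rewarded left
  tr <- manual_trials(c("left", "right"), fractions = c(0.80, 0.50))
  d <- build_design(tr, "extended1")
  expect_equal(unname(d$X[2, c("x_choice_1", "x_outcome_L_1",
                               "x_outcome_R_1")]), c(1, 1, 0))
  # previous trial: no choice
  tr2 <- manual_trials(c("none", "left"))
  d2 <- build_design(tr2, "extended1")
  expect_equal(unname(d2$X[2, c("x_choice_1", "x_outcome_L_1",
                                "x_outcome_R_1")]), c(0, 0, 0))
  expect_false(d2$included[1])
  # odor regressors from the mixture fraction
  tr3 <- manual_trials("left", fractions = 0.80)
  d3 <- build_design(tr3, "simple")
  expect_equal(unname(d3$X[1, c("x_odor_L", "x_odor_R")]), c(0.6, 0))
  # unrewarded right one back
  tr4 <- manual_trials(c("right", "left"), fractions = c(0.80, 0.50))
  d4 <- build_design(tr4, "extended1")
  expect_equal(unname(d4$X[2, c("x_choice_1", "x_outcome_L_1",
                                "x_outcome_R_1")]), c(-1, 0, -1))
  # late re-initiation voids the predecessor
  tr5 <- manual_trials(c("left", "left"), spacing = 5)
  d5 <- build_design(tr5, "extended1")
  expect_equal(unname(d5$X[2, "x_choice_1"]), 0)
  # unsorted input rejected
  tr6 <- tr4[2:1, ]
  expect_error(build_design(tr6, "simple"), "unsorted")
})

test_that("design invariants hold on random simulated sessions", {
  for (s in 1:5) {
    ses <- simulate_session(quick_cfg(), behavior_params(), n_trials = 150,
                            seed = 200 + s)
    d <- build_design(ses$trials, "extended2")
    X <- d$X
    for (g in 1:2) {
      xc <- X[, sprintf("x_choice_%d", g)]
      xl <- X[, sprintf("x_outcome_L_%d", g)]
      xr <- X[, sprintf("x_outcome_R_%d", g)]
      expect_true(all(xc %in% c(-1, 0, 1)))
      expect_true(all(xl %in% c(-1, 0, 1)))
      expect_true(all(xc[xl != 0] == 1))
      expect_true(all(xc[xr != 0] == -1))
    }
    expect_true(all(X[, "x_odor_L"] >= 0 & X[, "x_odor_L"] <= 1))
    expect_true(all(X[, "x_odor_L"] * X[, "x_odor_R"] == 0))
  }
})

test_that("maximum-likelihood fit recovers, flags and errors correctly", {
  # null recovery: every CI covers 0
  null_bp <- behavior_params(beta0 = 0, beta_odor_L = 0, beta_odor_R = 0,
                             beta_choice = 0, beta_outcome_L = 0,
                             beta_outcome_R = 0)
  tr <- simulate_choices(simulate_trial_events(quick_cfg(), 5000, seed = 20),
                         null_bp, no_choice_rate = 0, seed = 21)
  f <- fit_choice_model(tr, "extended1")
  expect_true(all(f$ci95[, "lo"] < 0 & f$ci95[, "hi"] > 0))

  # recovery of non-null truth within CI
  bp <- behavior_params(beta0 = 0, beta_odor_L = 3, beta_odor_R = -3,
                        beta_choice = 0.5, beta_outcome_L = 0,
                        beta_outcome_R = 0)
  tr <- simulate_choices(simulate_trial_events(quick_cfg(), 20000, seed = 22),
                         bp, no_choice_rate = 0, seed = 23)
  f <- fit_choice_model(tr, "extended1")
  truth <- c(0, 3, -3, 0.5, 0, 0)
  expect_true(all(f$ci95[, "lo"] <= truth & truth <= f$ci95[, "hi"]))
  expect_true(f$converged)

  # nesting: extended1 log-likelihood >= simple on identical trials
  f_s <- fit_choice_model(tr, "simple")
  expect_gte(f$log_likelihood, f_s$log_likelihood - 1e-8)

  # degenerate responses flag separation
  all_left <- manual_trials(rep("left", 30))
  expect_true(fit_choice_model(all_left, "simple")$separation)

  # singular design names the offending column
  const_odor <- manual_trials(rep(c("left", "right"), 20),
                              fractions = rep(0.95, 40))
  expect_error(fit_choice_model(const_odor, "simple"), "x_odor_R")
})

test_that("cross-validated comparison finds history signal iff present", {
  cfg <- quick_cfg(n_trials_mean = 300)
  bp <- behavior_params(beta_choice = 1, beta_outcome_L = 0.3,
                        beta_outcome_R = -0.3)
  m <- simulate_mouse(cfg, bp, n_sessions = 4, seed = 30)
  cmp <- compare_models_cv(m$trials, "simple_vs_ext1", n_repeats = 20,
                           seed = 31)
  expect_gt(cmp$mean_improvement, 0)
  expect_lt(cmp$p_value, 0.05)
  expect_named(cmp$per_session, c("session_id", "mean_improvement"))
})

test_that("inactivation fits report the muscimol influence with its sign", {
  cfg <- quick_cfg(n_trials_mean = 450)
  s <- simulate_inactivation_set(cfg, behavior_params(), delta_bias = 1,
                                 choice1_scale = 1, seed = 40)
  f <- fit_inactivation(s$trials)
  expect_gt(coef(f)["x_muscimol"], 0)
  expect_gt(f$ci95["x_muscimol", "lo"], 0)

  # swapping condition labels flips the sign
  sw <- s$trials
  sw$condition <- ifelse(sw$condition == "muscimol", "saline", "muscimol")
  # keep exactly one muscimol session by relabeling only one saline session
  sw$condition[sw$session_id %in% unique(s$trials$session_id[
    s$trials$condition == "muscimol"])] <- "saline"
  sw$condition[sw$session_id == unique(s$trials$session_id[
    s$trials$condition == "saline"])[1]] <- "muscimol"
  f_sw <- fit_inactivation(sw)
  expect_lt(coef(f_sw)["x_muscimol"], 0)

  miss <- s$trials; miss$condition <- NA_character_
  expect_error(fit_inactivation(miss), "condition")
  expect_error(compare_choice1_conditions(list(s$trials)), ">= 2")
})

test_that("movement metrics subtract event times and compare groups", {
  tr <- manual_trials(c("left", "right", "left"))
  mm <- movement_metrics(tr, by_prev_choice = FALSE, by_condition = FALSE)
  expect_equal(mm$metrics$movement_s, rep(0.35, 3))
  expect_equal(mm$metrics$latency_s, rep(0.25, 3))

  bad <- tr
  bad$reward_port_entry[2] <- bad$odor_port_exit[2] - 0.1
  expect_error(movement_metrics(bad), "negative duration")

  # injected condition effect on movement duration is detected
  cfg_mus <- quick_cfg(n_trials_mean = 300,
                       movement_duration_mean_s = 0.45)
  ses_m <- simulate_session(cfg_mus, behavior_params(), n_trials = 300,
                            condition = "muscimol", seed = 50)
  ses_s <- simulate_session(quick_cfg(), behavior_params(), n_trials = 300,
                            session_id = "s2", condition = "saline",
                            seed = 51)
  mm <- movement_metrics(rbind(ses_m$trials, ses_s$trials),
                         by_prev_choice = FALSE)
  row <- mm$by_condition[mm$by_condition$metric == "movement_s", ]
  expect_gt(row$diff_muscimol_minus_saline, 0.05)
  expect_lt(row$p_value, 0.001)
})

test_that("conditional psychometrics shift with the previous trial", {
  bp <- behavior_params(beta_choice = 1.2, beta_outcome_L = 0,
                        beta_outcome_R = 0)
  m <- simulate_mouse(quick_cfg(n_trials_mean = 500), bp, n_sessions = 4,
                      seed = 60)
  uncond <- psychometric_conditional(m$trials, "none")
  prev_l <- psychometric_conditional(m$trials, "prev_left_rew")
  mid <- c(0.4, 0.5, 0.6)
  pu <- uncond$points$p_left[uncond$points$odor_left_fraction %in% mid]
  pl <- prev_l$points$p_left[prev_l$points$odor_left_fraction %in% mid]
  expect_true(all(pl > pu))
  expect_s3_class(uncond$fit, "logistic_fit")

  # conditioning on nothing reproduces the pooled curve
  expect_equal(uncond$points$p_left,
               psychometric_conditional(m$trials, "none")$points$p_left)
})
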