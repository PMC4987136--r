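test_that("epoch rates use the half-open count/duration convention", {
  tr <- manual_trials("left")
  a <- tr$odor_port_entry[1]; b <- tr$valve_open[1] + 0.1
  sp <- spike_train("u1", spike_times = c(a, a + 0.1, a + 0.2, b, b + 0.5))
  r <- epoch_rate(sp, tr)
  # spike exactly at the epoch end is excluded: 3 spikes / 0.244 s
  expect_equal(r, 3 / 0.244)
  sp0 <- spike_train("u0", spike_times = numeric(0))
  expect_equal(epoch_rate(sp0, tr), 0)
  # missing event: trial excluded with a warning
  tr$valve_open <- NA_real_
  expect_warning(r2 <- epoch_rate(sp, tr), "excluded")
  expect_true(is.na(r2))
})

test_that("roc preference matches hand-computable cases", {
  expect_equal(roc_preference(c(10, 11, 12), c(1, 2, 3)), 1)
  expect_equal(roc_preference(c(5, 5, 5), c(5, 5, 5)), 0)
  # exhaustive pairs: P(pos > neg) = 1/4 -> preference -0.5
  expect_equal(roc_preference(c(1, 3), c(2, 4)), -0.5)
  expect_error(roc_preference(numeric(0), 1:3), "non-empty")
})

test_that("roc preference properties: antisymmetry, rank-sum identity, monotone invariance", {
  set.seed(77)
  for (i in 1:50) {
    na <- sample(4:20, 1); nb <- sample(4:20, 1)
    a <- sample(0:8, na, replace = TRUE) + sample(c(0, 0.5), na, TRUE)
    b <- sample(0:8, nb, replace = TRUE)
    p <- roc_preference(a, b)
    expect_equal(p, -roc_preference(b, a), tolerance = 1e-14)
    expect_equal(p, 2 * (roc_bruteforce(a, b) - 0.5), tolerance = 1e-12)
    # strictly increasing transform leaves ranks, hence preference, fixed
    expect_equal(roc_preference(exp(a / 4), exp(b / 4)), p,
                 tolerance = 1e-12)
    wt <- suppressWarnings(wilcox.test(a, b))
    expect_equal(p, 2 * (unname(wt$statistic) / (na * nb) - 0.5),
                 tolerance = 1e-12)
  }
})

test_that("permutation test applies inclusion rules and extreme-case bounds", {
  # fully separated groups: no permutation can exceed the observed value
  res <- preference_permutation(11:20, 1:10, n_perm = 1000, seed = 1)
  expect_true(res$included)
  expect_lte(res$p_value, 2 / 1001)

  # fewer than four trials in one group: excluded
  res3 <- preference_permutation(c(5, 6, 7), c(1, 2, 3, 4), seed = 1)
  expect_false(res3$included)
  expect_true(is.na(res3$p_value))

  # both groups below 2 spikes/s: excluded
  low <- preference_permutation(rep(0.5, 6), rep(1.0, 6), seed = 1)
  expect_false(low$included)
  # one group above threshold suffices
  hi <- preference_permutation(rep(0.5, 6), rep(3.0, 6), seed = 1)
  expect_true(hi$included)
})

test_that("unit preference separates lagged groupings with correct sign", {
  np <- neuron_params(baseline_rate = 6, modulation = list(
    list(regressor = "prev_choice", amplitude = 5,
         event = "odor_port_entry", start = -0.05, end = 0.35)))
  ses <- simulate_session(quick_cfg(n_trials_mean = 250),
                          behavior_params(), list(np), n_trials = 250,
                          seed = 70)
  sp <- ses$spikes[[1]]
  p1 <- unit_preference(sp, ses$trials, "choice", 1, n_perm = 500, seed = 71)
  expect_true(p1$included)
  expect_gt(p1$preference, 0.3)   # modulation favors contra (+1) trials
  expect_lt(p1$p_value, 0.01)
  p2 <- unit_preference(sp, ses$trials, "choice", 2, n_perm = 500, seed = 72)
  expect_lt(abs(p2$preference), abs(p1$preference))
})

test_that("population summary aggregates lags, signs and correlations", {
  mk <- function(lag, pref, p) {
    data.frame(unit_id = sprintf("u%02d", seq_along(pref)), mouse_id = "m1",
               session_id = "s1", variable = "choice", lag = lag,
               preference = pref, p_value = p, included = TRUE,
               n_pos = 10, n_neg = 10, mean_rate_pos = 5, mean_rate_neg = 5)
  }
  set.seed(1)
  res <- rbind(mk(0, runif(40, -0.2, 0.2), runif(40, 0.2, 1)),
               mk(1, c(runif(30, 0.3, 0.9), runif(10, -0.5, -0.2)),
                  c(rep(0.001, 30), rep(0.2, 10))))
  pop <- population_preference(res)
  f1 <- pop$per_lag$frac_significant[pop$per_lag$lag == 1]
  f0 <- pop$per_lag$frac_significant[pop$per_lag$lag == 0]
  expect_gt(f1, f0)
  expect_equal(pop$sign_test$n_positive[pop$sign_test$lag == 1], 30)
  expect_lt(pop$kruskal$p.value, 0.01)

  # identical preference vectors at two lags correlate perfectly
  res2 <- rbind(mk(0, seq(-0.5, 0.5, length.out = 20), rep(0.01, 20)),
                mk(1, seq(-0.5, 0.5, length.out = 20), rep(0.01, 20)))
  pop2 <- population_preference(res2)
  expect_equal(pop2$lag01_correlation$r, 1, tolerance = 1e-12)

  expect_warning(population_preference(mk(1, 0.5, 0.01)[0, ]), "excluded")
})

test_that("movement-direction check separates port and direction coding", {
  tr <- manual_trials(rep(c("left", "right"), 30))
  n <- nrow(tr)
  burst <- function(a, b, rate) a + seq(0.001, b - a - 0.001,
                                        by = 1 / rate)
  nxt <- c(tr$odor_port_entry[-1], NA)
  mk_spikes <- function(rate_out, rate_ret) {
    st <- unlist(lapply(seq_len(n), function(i) {
      s <- c()
      if (rate_out[i] > 0)
        s <- c(s, burst(tr$odor_port_exit[i], tr$reward_port_entry[i],
                        rate_out[i]))
      if (!is.na(nxt[i]) && rate_ret[i] > 0)
        s <- c(s, burst(tr$reward_port_exit[i], nxt[i], rate_ret[i]))
      s
    }))
    spike_train("u", spike_times = sort(st), recorded_side = "left")
  }
  left <- tr$choice == "left"
  # port-coding unit: fires for left choices during both movements
  port_unit <- mk_spikes(ifelse(left, 40, 4), ifelse(left, 40, 4))
  chk <- movement_direction_check(port_unit, tr, n_perm = 200, seed = 1)
  expect_equal(chk$classification, "port_preserving")
  # direction-coding unit: fires for leftward movements (outbound on left
  # choices, return on right choices)
  dir_unit <- mk_spikes(ifelse(left, 40, 4), ifelse(left, 4, 40))
  chk2 <- movement_direction_check(dir_unit, tr, n_perm = 200, seed = 2)
  expect_equal(chk2$classification, "direction_preserving")

  pop <- population_movement_direction(rbind(chk, chk, chk2))
  expect_equal(pop$fraction_port_preserving, 2 / 3)
})

test_that("psth recovers flat rates and degenerate cases", {
  tr <- manual_trials(rep("left", 60))
  np <- neuron_params(baseline_rate = 20)
  sp <- simulate_spike_train(tr, np, seed = 80)
  ps <- compute_psth(sp, tr, "valve_open", window = c(-0.2, 0.3))
  expect_lt(abs(mean(ps$rate) - 20), 2)
  expect_true(all(ps$sem >= 0))

  sp0 <- spike_train("u0", spike_times = numeric(0))
  ps0 <- compute_psth(sp0, tr, "valve_open", window = c(-0.2, 0.3))
  expect_true(all(ps0$rate == 0))

  # sigma = 0: raw binned histogram (values multiples of 1/bin)
  ps_raw <- compute_psth(sp, tr, "valve_open", window = c(-0.1, 0.1),
                         smoothing_sigma_s = 0)
  expect_true(all(abs(ps_raw$rate * 0.001 * 60 -
                        round(ps_raw$rate * 0.001 * 60)) < 1e-9))
})
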