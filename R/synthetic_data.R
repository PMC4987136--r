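#' Task configuration for the synthetic session generator
#'
#' Bundles the timing and stimulus statistics of the odor-cued spatial
#' choice task: seven binary odor mixtures presented pseudo-randomly, a
#' short delay from odor-port entry to valve opening, a longer delay to
#' the go signal, and a brief delay from reward-port entry to reward
#' delivery. Defaults reproduce the task statistics the analyses assume
#' (sessions of about 451 +/- 115 trials; valve delay 144 +/- 64 ms; go
#' delay 434 +/- 68 ms; reward delay 41 +/- 32 ms). Delays are drawn from
#' normals truncated below at 10 ms.
#'
#' @param odor_set numeric vector of left-odor fractions in `[0, 1]`.
#' @param n_trials_mean,n_trials_sd mean and SD of the per-session trial
#'   count (drawn once per session, floored at 50).
#' @param valve_delay_mean_s,valve_delay_sd_s odor-port entry to valve
#'   open, seconds.
#' @param go_delay_mean_s,go_delay_sd_s valve open to go signal, seconds.
#' @param reward_delay_mean_s,reward_delay_sd_s reward-port entry to
#'   water-valve opening, seconds.
#' @param reaction_mean_s,reaction_sd_s go signal to odor-port exit.
#' @param movement_duration_mean_s,movement_duration_sd_s odor-port exit
#'   to reward-port entry.
#' @param drink_mean_s,drink_sd_s reward-port entry to reward-port exit.
#' @param inter_trial_mean_s,inter_trial_sd_s reward-port exit to the next
#'   odor-port entry. The task does not constrain this interval; the
#'   default (0.5 s) keeps re-initiation within the 1.5-s window that the
#'   behavioral models use to define a valid trial history.
#' @param no_choice_rate fraction of trials on which the mouse fails to
#'   report a choice (default 2%).
#' @param seed integer; fixed seed implies bit-identical output.
#' @return an object of class `task_config` (a validated list).
#' @export
task_config <- function(odor_set = c(0.95, 0.80, 0.60, 0.50, 0.40, 0.20, 0.05),
                        n_trials_mean = 451, n_trials_sd = 115,
                        valve_delay_mean_s = 0.144, valve_delay_sd_s = 0.064,
                        go_delay_mean_s = 0.434, go_delay_sd_s = 0.068,
                        reward_delay_mean_s = 0.041, reward_delay_sd_s = 0.032,
                        reaction_mean_s = 0.25, reaction_sd_s = 0.05,
                        movement_duration_mean_s = 0.35,
                        movement_duration_sd_s = 0.08,
                        drink_mean_s = 1.0, drink_sd_s = 0.2,
                        inter_trial_mean_s = 0.5, inter_trial_sd_s = 0.2,
                        no_choice_rate = 0.02,
                        seed = NULL) {
  if (any(odor_set < 0 | odor_set > 1)) {
    stopf("odor fractions must lie in [0, 1]")
  }
  means <- c(valve_delay_mean_s, go_delay_mean_s, reward_delay_mean_s,
             reaction_mean_s, movement_duration_mean_s, drink_mean_s,
             inter_trial_mean_s)
  if (any(means <= 0)) stopf("all delay means must be positive")
  if (no_choice_rate < 0 || no_choice_rate >= 1) {
    stopf("no_choice_rate must be in [0, 1)")
  }
  structure(list(
    odor_set = odor_set,
    n_trials_mean = n_trials_mean, n_trials_sd = n_trials_sd,
    valve_delay_mean_s = valve_delay_mean_s,
    valve_delay_sd_s = valve_delay_sd_s,
    go_delay_mean_s = go_delay_mean_s, go_delay_sd_s = go_delay_sd_s,
    reward_delay_mean_s = reward_delay_mean_s,
    reward_delay_sd_s = reward_delay_sd_s,
    reaction_mean_s = reaction_mean_s, reaction_sd_s = reaction_sd_s,
    movement_duration_mean_s = movement_duration_mean_s,
    movement_duration_sd_s = movement_duration_sd_s,
    drink_mean_s = drink_mean_s, drink_sd_s = drink_sd_s,
    inter_trial_mean_s = inter_trial_mean_s,
    inter_trial_sd_s = inter_trial_sd_s,
    no_choice_rate = no_choice_rate,
    seed = seed
  ), class = "task_config")
}

#' Ground-truth behavioral parameters
#'
#' Coefficients of the generative extended logistic choice model. The
#' linear predictor for the probability of a left choice is
#' `beta0 + beta_odor_L * x_odor_L + beta_odor_R * x_odor_R +
#' sum_n (beta_choice[n] * x_choice_n + beta_outcome_L[n] * x_outcome_L_n
#' + beta_outcome_R[n] * x_outcome_R_n) + beta_muscimol * x_muscimol`,
#' using the codings described in [build_design()].
#'
#' @param beta0 overall left/right choice bias.
#' @param beta_odor_L,beta_odor_R influence of the left- and
#'   right-dominant odor strength (each regressor in `[0, 1]`). Both act
#'   on the left-choice log-odds, so an odor-following mouse has
#'   `beta_odor_L > 0` and `beta_odor_R < 0`.
#' @param beta_choice numeric vector, influence of the choice `n` trials
#'   back (positive = stay).
#' @param beta_outcome_L,beta_outcome_R numeric vectors, influence of the
#'   outcome of previous left / right choices; must match
#'   `length(beta_choice)`.
#' @param beta_muscimol additive bias on muscimol sessions (positive =
#'   leftward/ipsilateral for a left-hemisphere infusion).
#' @param lapse_rate probability in `[0, 0.5)` that a choice is replaced
#'   by a fair coin flip.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(beta0 = 0,
                            beta_odor_L = 3, beta_odor_R = -3,
                            beta_choice = 0.7,
                            beta_outcome_L = 0.3,
                            beta_outcome_R = -0.3,
                            beta_muscimol = 0,
                            lapse_rate = 0) {
  nl <- length(beta_choice)
  if (length(beta_outcome_L) != nl || length(beta_outcome_R) != nl) {
    stopf("beta_choice, beta_outcome_L, beta_outcome_R must share length")
  }
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stopf("lapse_rate must be in [0, 0.5)")
  }
  structure(list(beta0 = beta0,
                 beta_odor_L = beta_odor_L, beta_odor_R = beta_odor_R,
                 beta_choice = as.numeric(beta_choice),
                 beta_outcome_L = as.numeric(beta_outcome_L),
                 beta_outcome_R = as.numeric(beta_outcome_R),
                 beta_muscimol = beta_muscimol,
                 lapse_rate = lapse_rate),
            class = "behavior_params")
}

#' Ground-truth parameters of one simulated unit
#'
#' A simulated neuron fires as an inhomogeneous Poisson process whose
#' rate is a session-wide baseline plus event-locked modulations. Each
#' modulation adds `amplitude * x` spikes/s inside a window anchored to a
#' named trial event, where `x` is the -1/0/+1 coding of the named
#' regressor for that trial (contralateral choice = +1, rewarded = +1, no
#' choice = 0; see [code_regressors()]). The summed rate is floored at 0.
#'
#' @param baseline_rate spikes/s, non-negative.
#' @param modulation list of terms, each a list with fields `regressor`
#'   (one of `"prev_choice"`, `"prev_outcome"`, `"cur_choice"`,
#'   `"cur_outcome"`), `amplitude` (spikes/s), `event` (a trial event
#'   column name), `start`, `end` (seconds relative to the event).
#' @param noise_model only `"poisson"` is implemented.
#' @param seed integer seed for spike generation.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(baseline_rate = 10,
                          modulation = list(),
                          noise_model = "poisson",
                          seed = NULL) {
  if (baseline_rate < 0) stopf("baseline_rate must be >= 0")
  if (!identical(noise_model, "poisson")) {
    stopf("unsupported noise_model '%s'", noise_model)
  }
  valid_reg <- c("prev_choice", "prev_outcome", "cur_choice", "cur_outcome")
  for (m in modulation) {
    if (!all(c("regressor", "amplitude", "event", "start", "end") %in%
             names(m))) {
      stopf("each modulation term needs regressor/amplitude/event/start/end")
    }
    if (!m$regressor %in% valid_reg) {
      stopf("unknown modulation regressor '%s'", m$regressor)
    }
    if (m$end <= m$start) stopf("modulation window must have end > start")
  }
  structure(list(baseline_rate = baseline_rate, modulation = modulation,
                 noise_model = noise_model, seed = seed),
            class = "neuron_params")
}

event_cols <- function() {
  c("odor_port_entry", "valve_open", "go", "odor_port_exit",
    "reward_port_entry", "reward_port_exit")
}

#' Simulate task event times for one session
#'
#' Lays out per-trial event times (odor-port entry, valve open, go
#' signal, odor-port exit, reward-port entry/exit) with the configured
#' delay statistics, and draws the odor mixture pseudo-randomly from the
#' configured set. Choices and outcomes are not yet assigned; reward-port
#' times are provisional and are blanked later for no-choice trials.
#'
#' @param cfg a [task_config()].
#' @param n_trials number of trials (>= 1). Defaults to a draw from the
#'   configured session-length distribution.
#' @param session_id,mouse_id,condition labels stored on every row;
#'   `condition` is one of `"baseline"`, `"saline"`, `"muscimol"`.
#' @param seed overrides `cfg$seed`.
#' @return a trial table (`data.frame`) with one row per trial.
#' @export
simulate_trial_events <- function(cfg, n_trials = NULL,
                                  session_id = "s1", mouse_id = "m1",
                                  condition = "baseline", seed = NULL) {
  stopifnot(inherits(cfg, "task_config"))
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    if (is.null(n_trials)) {
      n_trials <- max(50L, round(rnorm(1, cfg$n_trials_mean, cfg$n_trials_sd)))
    }
    if (n_trials < 1) stopf("n_trials must be >= 1")
    n <- as.integer(n_trials)
    odor <- sample(cfg$odor_set, n, replace = TRUE)
    valve_d <- rtnorm_floor(n, cfg$valve_delay_mean_s, cfg$valve_delay_sd_s)
    go_d <- rtnorm_floor(n, cfg$go_delay_mean_s, cfg$go_delay_sd_s)
    react <- rtnorm_floor(n, cfg$reaction_mean_s, cfg$reaction_sd_s)
    move <- rtnorm_floor(n, cfg$movement_duration_mean_s,
                         cfg$movement_duration_sd_s)
    drink <- rtnorm_floor(n, cfg$drink_mean_s, cfg$drink_sd_s)
    iti <- rtnorm_floor(n, cfg$inter_trial_mean_s, cfg$inter_trial_sd_s)

    entry <- numeric(n)
    t0 <- 1.0
    for (i in seq_len(n)) {
      entry[i] <- t0
      t0 <- t0 + valve_d[i] + go_d[i] + react[i] + move[i] + drink[i] + iti[i]
    }
    valve <- entry + valve_d
    go <- valve + go_d
    exit <- go + react
    rentry <- exit + move
    rexit <- rentry + drink

    data.frame(
      session_id = session_id, mouse_id = mouse_id,
      trial_index = seq_len(n) - 1L,
      odor_port_entry = entry, valve_open = valve, go = go,
      odor_port_exit = exit, reward_port_entry = rentry,
      reward_port_exit = rexit,
      odor_left_fraction = odor,
      choice = NA_character_, rewarded = NA_integer_,
      condition = condition,
      stringsAsFactors = FALSE
    )
  })
}

# Per-trial history validity used both by the generator and by
# build_design(): a trial counts as "no choice" history when the mouse
# made no choice, failed to reach a reward port within 1.5 s of odor-port
# exit, or did not re-initiate the next trial within 1.5 s of reward-port
# exit.
history_valid <- function(trials, max_gap_s = 1.5) {
  n <- nrow(trials)
  chose <- !is.na(trials$choice) & trials$choice != "none"
  reached <- !is.na(trials$reward_port_entry) &
    (trials$reward_port_entry - trials$odor_port_exit) <= max_gap_s
  reinit <- rep(TRUE, n)
  if (n > 1) {
    same <- trials$session_id[-1] == trials$session_id[-n]
    gap <- trials$odor_port_entry[-1] - trials$reward_port_exit[-n]
    reinit[-n] <- !same | (!is.na(gap) & gap <= max_gap_s)
  }
  chose & reached & reinit
}

# lag-n history regressors (behavioral coding: left = +1) for each trial,
# computed within session; invalid or out-of-range predecessors code 0.
lag_regressors <- function(trials, lag, valid = history_valid(trials)) {
  n <- nrow(trials)
  xc <- numeric(n); xol <- numeric(n); xor <- numeric(n)
  if (n > lag) {
    idx <- (lag + 1L):n
    ref <- idx - lag
    ok <- trials$session_id[idx] == trials$session_id[ref] & valid[ref]
    left <- ok & trials$choice[ref] == "left"
    right <- ok & trials$choice[ref] == "right"
    rew <- ifelse(is.na(trials$rewarded[ref]), 0L, trials$rewarded[ref])
    xc[idx] <- ifelse(left, 1, ifelse(right, -1, 0))
    xol[idx] <- ifelse(left, ifelse(rew == 1, 1, -1), 0)
    xor[idx] <- ifelse(right, ifelse(rew == 1, 1, -1), 0)
  }
  list(choice = xc, outcome_L = xol, outcome_R = xor)
}

odor_regressors <- function(f_left) {
  list(L = pmax(0, (f_left - 0.5) / 0.5),
       R = pmax(0, ((1 - f_left) - 0.5) / 0.5))
}

#' Simulate history-dependent choices
#'
#' Draws choices sequentially from the generative extended logistic
#' model: on each trial the linear predictor combines odor regressors,
#' lagged choice/outcome regressors computed from the already-simulated
#' earlier trials (with the same no-choice and 1.5-s re-initiation rules
#' the fitting code uses), and a muscimol term on muscimol sessions. With
#' probability `lapse_rate` the model choice is replaced by a fair coin.
#' A configurable fraction of trials is marked `"none"` (no choice);
#' their reward-port times are blanked.
#'
#' Outcomes are assigned as choices are drawn (the generative model needs
#' the previous outcome before the next choice); [assign_outcomes()]
#' applies the identical rule to an existing table.
#'
#' @param trials a trial table from [simulate_trial_events()].
#' @param params a [behavior_params()].
#' @param no_choice_rate fraction of trials without a choice.
#' @param seed integer seed.
#' @return the trial table with `choice` and `rewarded` filled in.
#' @export
simulate_choices <- function(trials, params, no_choice_rate = 0.02,
                             seed = NULL) {
  stopifnot(inherits(params, "behavior_params"))
  n <- nrow(trials)
  if (is.unsorted(trials$odor_port_entry)) {
    stopf("trials must be time-ordered")
  }
  nl <- length(params$beta_choice)
  xo <- odor_regressors(trials$odor_left_fraction)
  xmus <- as.numeric(trials$condition == "muscimol")
  with_seed(seed, {
    u_nc <- runif(n); u_lapse <- runif(n); u_coin <- runif(n)
    u_choice <- runif(n); u_rew <- runif(n)
    choice <- character(n); rewarded <- rep(NA_integer_, n)
    valid <- rep(FALSE, n)
    for (t in seq_len(n)) {
      if (u_nc[t] < no_choice_rate) {
        choice[t] <- "none"
        next
      }
      eta <- params$beta0 + params$beta_odor_L * xo$L[t] +
        params$beta_odor_R * xo$R[t] + params$beta_muscimol * xmus[t]
      if (nl > 0) {
        for (g in seq_len(nl)) {
          ref <- t - g
          if (ref >= 1 && trials$session_id[ref] == trials$session_id[t] &&
              valid[ref]) {
            xc <- if (choice[ref] == "left") 1 else -1
            rw <- if (rewarded[ref] == 1L) 1 else -1
            eta <- eta + params$beta_choice[g] * xc
            if (xc > 0) eta <- eta + params$beta_outcome_L[g] * rw
            else eta <- eta + params$beta_outcome_R[g] * rw
          }
        }
      }
      p_left <- plogis(eta)
      ch <- if (u_choice[t] < p_left) "left" else "right"
      if (u_lapse[t] < params$lapse_rate) {
        ch <- if (u_coin[t] < 0.5) "left" else "right"
      }
      choice[t] <- ch
      rewarded[t] <- outcome_rule(ch, trials$odor_left_fraction[t], u_rew[t])
      # history validity for later lags: choice made, ports reached in time
      reached <- !is.na(trials$reward_port_entry[t]) &&
        (trials$reward_port_entry[t] - trials$odor_port_exit[t]) <= 1.5
      reinit <- TRUE
      if (t < n && trials$session_id[t + 1] == trials$session_id[t]) {
        reinit <- (trials$odor_port_entry[t + 1] -
                     trials$reward_port_exit[t]) <= 1.5
      }
      valid[t] <- reached && reinit
    }
    trials$choice <- choice
    trials$rewarded <- rewarded
    nc <- choice == "none"
    trials$reward_port_entry[nc] <- NA_real_
    trials$reward_port_exit[nc] <- NA_real_
    trials
  })
}

# reward rule: chosen side must match dominant odor; 50/50 trials are
# rewarded with probability 0.5 at the chosen port.
outcome_rule <- function(choice, f_left, u) {
  if (is.na(f_left)) stopf("missing odor fraction")
  if (choice == "none") return(NA_integer_)
  if (f_left == 0.5) return(as.integer(u < 0.5))
  dominant <- if (f_left > 0.5) "left" else "right"
  as.integer(choice == dominant)
}

#' Assign trial outcomes from choices and odor mixtures
#'
#' Reward is delivered when the chosen port matches the dominant odor;
#' on 50/50 mixtures each port is armed independently with probability
#' 0.5, so any choice is rewarded with probability 0.5. No-choice trials
#' get `NA` (serialized as `"none"`).
#'
#' @param trials trial table with `choice` filled in.
#' @param seed integer seed (used only for 50/50 mixtures).
#' @return the trial table with `rewarded` filled in.
#' @export
assign_outcomes <- function(trials, seed = NULL) {
  if (anyNA(trials$choice)) stopf("choices must be present")
  assert_choice_values(trials$choice)
  with_seed(seed, {
    u <- runif(nrow(trials))
    trials$rewarded <- vapply(seq_len(nrow(trials)), function(i) {
      outcome_rule(trials$choice[i], trials$odor_left_fraction[i], u[i])
    }, integer(1))
    trials
  })
}

#' Simulate a spike train for one unit
#'
#' Builds the unit's piecewise-constant rate over the whole session --
#' baseline plus each modulation term's `amplitude * x` inside its
#' event-anchored window, floored at 0 -- and draws an inhomogeneous
#' Poisson process from it (per-segment Poisson counts with uniform
#' placement). Neural coding is used for `x`: contralateral choice = +1
#' given `recorded_side`, rewarded = +1, no choice = 0.
#'
#' @param trials trial table with choices and outcomes.
#' @param neuron a [neuron_params()].
#' @param unit_id,recorded_side unit label and implant hemisphere
#'   (`"left"` or `"right"`); the hemisphere defines ipsi/contra.
#' @param t_end session end time (default: last event + 1 s).
#' @param seed overrides `neuron$seed`.
#' @return an object of class `spike_train`: list with `unit_id`,
#'   `mouse_id`, `session_id`, `recorded_side`, sorted `spike_times`.
#' @export
simulate_spike_train <- function(trials, neuron, unit_id = "u1",
                                 recorded_side = "left", t_end = NULL,
                                 seed = NULL) {
  stopifnot(inherits(neuron, "neuron_params"))
  seed <- seed %||% neuron$seed
  ev <- as.matrix(trials[, event_cols()])
  t_end <- t_end %||% (max(ev, na.rm = TRUE) + 1)
  regs <- code_regressors(trials, recorded_side)

  # breakpoints of the piecewise-constant rate
  starts <- 0; ends <- numeric(0)
  seg_add <- list()
  for (m in neuron$modulation) {
    if (!m$event %in% colnames(ev)) {
      stopf("unknown anchor event '%s'", m$event)
    }
    anchor <- trials[[m$event]]
    x <- regs[[reg_col(m$regressor)]]
    keep <- !is.na(anchor) & x != 0
    if (!any(keep)) next
    a <- anchor[keep] + m$start
    b <- anchor[keep] + m$end
    clip <- a < 0 | b > t_end
    if (any(clip)) {
      warnf("%d modulation window(s) clipped to session bounds", sum(clip))
      a <- pmax(a, 0); b <- pmin(b, t_end)
    }
    ok <- b > a
    seg_add[[length(seg_add) + 1L]] <-
      data.frame(a = a[ok], b = b[ok], add = m$amplitude * x[keep][ok])
  }
  brk <- sort(unique(c(0, t_end, unlist(lapply(seg_add, function(s) c(s$a, s$b))))))
  brk <- brk[brk >= 0 & brk <= t_end]
  lo <- brk[-length(brk)]; hi <- brk[-1]
  rate <- rep(neuron$baseline_rate, length(lo))
  for (s in seg_add) {
    for (i in seq_len(nrow(s))) {
      cover <- lo >= s$a[i] - 1e-12 & hi <= s$b[i] + 1e-12
      rate[cover] <- rate[cover] + s$add[i]
    }
  }
  rate <- pmax(rate, 0)

  with_seed(seed, {
    counts <- rpois(length(lo), rate * (hi - lo))
    times <- sort(unlist(lapply(which(counts > 0), function(i) {
      runif(counts[i], lo[i], hi[i])
    })))
    spike_train(unit_id = unit_id,
                mouse_id = trials$mouse_id[1],
                session_id = trials$session_id[1],
                recorded_side = recorded_side,
                spike_times = as.numeric(times))
  })
}

reg_col <- function(regressor) {
  switch(regressor,
         prev_choice = "x_choice_prev", prev_outcome = "x_outcome_prev",
         cur_choice = "x_choice_cur", cur_outcome = "x_outcome_cur",
         stopf("unknown regressor '%s'", regressor))
}

#' Construct a spike train object
#'
#' @param unit_id,mouse_id,session_id labels.
#' @param recorded_side `"left"` or `"right"`; defines the ipsi/contra
#'   mapping for all neural analyses.
#' @param spike_times numeric vector, seconds from session start; sorted
#'   on construction.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit_id, mouse_id = "m1", session_id = "s1",
                        recorded_side = "left", spike_times = numeric(0)) {
  if (!recorded_side %in% c("left", "right")) {
    stopf("recorded_side must be 'left' or 'right'")
  }
  if (any(spike_times < 0)) stopf("negative spike time")
  structure(list(unit_id = as.character(unit_id),
                 mouse_id = as.character(mouse_id),
                 session_id = as.character(session_id),
                 recorded_side = recorded_side,
                 spike_times = sort(as.numeric(spike_times))),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s | %s/%s | side=%s | %d spikes>\n",
              x$unit_id, x$mouse_id, x$session_id, x$recorded_side,
              length(x$spike_times)))
  invisible(x)
}

#' Simulate one complete session (events, choices, outcomes, spikes)
#'
#' @inheritParams simulate_trial_events
#' @param params a [behavior_params()].
#' @param neurons list of [neuron_params()]; one spike train per entry.
#' @param recorded_side implant hemisphere for all units.
#' @param seed master seed; sub-seeds for events, choices and each unit
#'   are derived deterministically from it.
#' @return list with `trials` (trial table), `spikes` (list of
#'   `spike_train`), `ground_truth` (generating parameters).
#' @export
simulate_session <- function(cfg, params, neurons = list(),
                             n_trials = NULL, session_id = "s1",
                             mouse_id = "m1", condition = "baseline",
                             recorded_side = "left", seed = 1L) {
  trials <- simulate_trial_events(cfg, n_trials, session_id, mouse_id,
                                  condition, seed = derive_seed(seed, 1))
  trials <- simulate_choices(trials, params,
                             no_choice_rate = cfg$no_choice_rate,
                             seed = derive_seed(seed, 2))
  spikes <- lapply(seq_along(neurons), function(i) {
    simulate_spike_train(trials, neurons[[i]],
                         unit_id = sprintf("%s_u%02d", session_id, i),
                         recorded_side = recorded_side,
                         seed = derive_seed(seed, 100 + i))
  })
  list(trials = trials, spikes = spikes,
       ground_truth = list(behavior = params, neurons = neurons))
}

#' Simulate a multi-session mouse
#'
#' @inheritParams simulate_session
#' @param n_sessions number of sessions (the recordings comprised 12 per
#'   animal).
#' @param neurons_per_session list of [neuron_params()] re-used in every
#'   session (fresh spike-generation seeds per session).
#' @return list with `trials` (row-bound table over sessions) and
#'   `spikes` (flat list of spike trains).
#' @export
simulate_mouse <- function(cfg, params, n_sessions = 12,
                           neurons_per_session = list(),
                           mouse_id = "m1", recorded_side = "left",
                           seed = 1L) {
  out_t <- vector("list", n_sessions)
  out_s <- list()
  for (s in seq_len(n_sessions)) {
    ses <- simulate_session(cfg, params, neurons_per_session,
                            session_id = sprintf("%s_s%02d", mouse_id, s),
                            mouse_id = mouse_id,
                            recorded_side = recorded_side,
                            seed = derive_seed(seed, s))
    out_t[[s]] <- ses$trials
    out_s <- c(out_s, ses$spikes)
  }
  list(trials = do.call(rbind, out_t), spikes = out_s,
       ground_truth = list(behavior = params,
                           neurons = neurons_per_session))
}

#' Simulate a muscimol inactivation session set
#'
#' Generates the standard three-session set -- saline (pre), muscimol,
#' saline (post) -- from shared task and behavior parameters. The
#' muscimol session adds `delta_bias` to the bias term (positive =
#' ipsilateral/leftward for a left-hemisphere infusion) and scales the
#' 1-back choice coefficient by `choice1_scale`.
#'
#' @inheritParams simulate_session
#' @param delta_bias additive shift of `beta0` under muscimol.
#' @param choice1_scale multiplier in `[0, 1]` applied to
#'   `beta_choice[1]` under muscimol.
#' @param set_id label prefix for the three sessions.
#' @return list of three session lists (`saline_pre`, `muscimol`,
#'   `saline_post`), plus `trials`, the pooled trial table.
#' @export
simulate_inactivation_set <- function(cfg, params, delta_bias = 0,
                                      choice1_scale = 1, n_trials = NULL,
                                      mouse_id = "m1", set_id = "set1",
                                      seed = 1L) {
  if (choice1_scale < 0 || choice1_scale > 1) {
    stopf("choice1_scale must be in [0, 1]")
  }
  mus <- params
  mus$beta0 <- mus$beta0 + delta_bias
  if (length(mus$beta_choice) > 0) {
    mus$beta_choice[1] <- mus$beta_choice[1] * choice1_scale
  }
  mk <- function(p, cond, k) {
    simulate_session(cfg, p, n_trials = n_trials,
                     session_id = sprintf("%s_%s", set_id, cond),
                     mouse_id = mouse_id, condition = cond,
                     seed = derive_seed(seed, k))
  }
  pre <- mk(params, "saline", 1)
  inj <- mk(mus, "muscimol", 2)
  post <- mk(params, "saline", 3)
  post$trials$session_id <- paste0(post$trials$session_id, "_post")
  list(saline_pre = pre, muscimol = inj, saline_post = post,
       trials = rbind(pre$trials, inj$trials, post$trials))
}

#' Simulate a session with a latent coupling between firing and choice
#'
#' Generates one session plus one unit whose pre-stimulus firing and the
#' animal's choice share a per-trial Gaussian latent: the latent adds
#' `rate_gain * z` spikes/s to the unit's rate inside the pre-stimulus
#' window and `choice_gain * z` to the left-choice log-odds. With both
#' gains positive the unit's preferred side is left, and high normalized
#' pre-stimulus rate predicts preferred-side choices on ambiguous trials
#' -- the positive-slope regime of the choice-linkage analysis. The unit
#' also carries a previous-choice modulation so that it passes the
#' lag-1-selectivity screen.
#'
#' @inheritParams simulate_session
#' @param rate_gain spikes/s per latent SD (0 for a null unit).
#' @param choice_gain log-odds per latent SD (0 for a null unit).
#' @param baseline_rate unit baseline, spikes/s.
#' @param prev_choice_amp amplitude of the unit's previous-choice
#'   modulation in the pre-stimulus window, spikes/s.
#' @return list with `trials`, `spike` (one `spike_train`),
#'   `preferred_side` (`"left"`).
#' @export
simulate_coupled_session <- function(cfg, params, rate_gain = 5,
                                     choice_gain = 1.2,
                                     baseline_rate = 12,
                                     prev_choice_amp = 4,
                                     n_trials = 300, mouse_id = "m1",
                                     session_id = "s1", seed = 1L) {
  trials <- simulate_trial_events(cfg, n_trials, session_id, mouse_id,
                                  seed = derive_seed(seed, 1))
  n <- nrow(trials)
  z <- with_seed(derive_seed(seed, 2), rnorm(n))

  # sequential choice draw with the latent added to the log-odds
  trials2 <- trials
  xo <- odor_regressors(trials$odor_left_fraction)
  with_seed(derive_seed(seed, 3), {
    u_choice <- runif(n); u_rew <- runif(n); u_nc <- runif(n)
    choice <- character(n); rewarded <- rep(NA_integer_, n)
    valid <- rep(FALSE, n)
    nl <- length(params$beta_choice)
    for (t in seq_len(n)) {
      if (u_nc[t] < cfg$no_choice_rate) { choice[t] <- "none"; next }
      eta <- params$beta0 + params$beta_odor_L * xo$L[t] +
        params$beta_odor_R * xo$R[t] + choice_gain * z[t]
      if (nl > 0 && t > 1 && valid[t - 1]) {
        xc <- if (choice[t - 1] == "left") 1 else -1
        rw <- if (rewarded[t - 1] == 1L) 1 else -1
        eta <- eta + params$beta_choice[1] * xc +
          (if (xc > 0) params$beta_outcome_L[1] else
             params$beta_outcome_R[1]) * rw
      }
      choice[t] <- if (u_choice[t] < plogis(eta)) "left" else "right"
      rewarded[t] <- outcome_rule(choice[t], trials$odor_left_fraction[t],
                                  u_rew[t])
      valid[t] <- TRUE
    }
    trials2$choice <- choice
    trials2$rewarded <- rewarded
    nc <- choice == "none"
    trials2$reward_port_entry[nc] <- NA_real_
    trials2$reward_port_exit[nc] <- NA_real_
  })

  # unit: baseline + prev-choice modulation + latent drive, all within the
  # pre-stimulus window (port entry to 100 ms after valve open).
  regs <- code_regressors(trials2, "right") # contra = left choice = +1
  a <- trials2$odor_port_entry
  b <- trials2$valve_open + 0.1
  rate_in <- pmax(0, baseline_rate + prev_choice_amp * regs$x_choice_prev +
                    rate_gain * z)
  t_end <- max(trials2$reward_port_exit, trials2$odor_port_exit,
               na.rm = TRUE) + 1
  with_seed(derive_seed(seed, 4), {
    # baseline spikes over the whole session
    nb <- rpois(1, baseline_rate * t_end)
    st <- runif(nb, 0, t_end)
    # remove baseline spikes inside windows, replace with window-rate spikes
    keep <- rep(TRUE, length(st))
    extra <- numeric(0)
    for (i in seq_len(n)) {
      inwin <- st >= a[i] & st < b[i]
      keep[inwin] <- FALSE
      ni <- rpois(1, rate_in[i] * (b[i] - a[i]))
      if (ni > 0) extra <- c(extra, runif(ni, a[i], b[i]))
    }
    st <- sort(c(st[keep], extra))
  })
  spike <- spike_train(unit_id = paste0(session_id, "_cu"),
                       mouse_id = mouse_id, session_id = session_id,
                       recorded_side = "right", spike_times = st)
  list(trials = trials2, spike = spike, preferred_side = "left")
}
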