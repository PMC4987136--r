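# Shared fixtures, built in code.

# Compact session with deterministic event times: trials spaced so that
# re-initiation gaps stay under the 1.5-s history window.
manual_trials <- function(choices, fractions = rep(0.5, length(choices)),
                          rewarded = NULL, session_id = "s1",
                          mouse_id = "m1", condition = "baseline",
                          spacing = 3.3) {
  n <- length(choices)
  entry <- 1 + (seq_len(n) - 1) * spacing
  valve <- entry + 0.144
  go <- valve + 0.434
  exit <- go + 0.25
  rentry <- exit + 0.35
  rexit <- rentry + 1.0
  if (is.null(rewarded)) {
    rewarded <- vapply(seq_len(n), function(i) {
      if (choices[i] == "none" || fractions[i] == 0.5) return(NA_integer_)
      dom <- if (fractions[i] > 0.5) "left" else "right"
      as.integer(choices[i] == dom)
    }, integer(1))
    rewarded[choices != "none" & fractions == 0.5] <- 1L
  }
  none <- choices == "none"
  rentry[none] <- NA_real_
  rexit[none] <- NA_real_
  data.frame(session_id = session_id, mouse_id = mouse_id,
             trial_index = seq_len(n) - 1L,
             odor_port_entry = entry, valve_open = valve, go = go,
             odor_port_exit = exit, reward_port_entry = rentry,
             reward_port_exit = rexit,
             odor_left_fraction = fractions,
             choice = choices, rewarded = as.integer(rewarded),
             condition = condition, stringsAsFactors = FALSE)
}

# Spike train with `counts[i]` spikes placed evenly inside the
# pre-stimulus window of trial i.
prestim_spikes <- function(trials, counts, unit_id = "u1",
                           recorded_side = "left") {
  st <- unlist(lapply(seq_len(nrow(trials)), function(i) {
    k <- counts[i]
    if (k == 0) return(numeric(0))
    a <- trials$odor_port_entry[i]
    b <- trials$valve_open[i] + 0.1
    a + (seq_len(k) - 0.5) / k * (b - a)
  }))
  spike_train(unit_id, trials$mouse_id[1], trials$session_id[1],
              recorded_side, st)
}

# brute-force ROC area by exhaustive pair counting (ties count 1/2)
roc_bruteforce <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

quick_cfg <- function(n_trials_mean = 200, ...) {
  task_config(n_trials_mean = n_trials_mean, n_trials_sd = 0, ...)
}
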