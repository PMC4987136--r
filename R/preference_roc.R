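#' Define an analysis epoch relative to trial events
#'
#' An epoch resolves, per trial, to the half-open interval
#' `[start_event + start_offset, end_event + end_offset)`. Times are
#' seconds; a spike exactly at the end bound belongs to the next
#' interval.
#'
#' @param name label.
#' @param start_event,end_event trial event column names.
#' @param start_offset_s,end_offset_s offsets in seconds.
#' @return an object of class `epoch_spec`.
#' @export
epoch_spec <- function(name, start_event, end_event,
                       start_offset_s = 0, end_offset_s = 0) {
  structure(list(name = name, start_event = start_event,
                 end_event = end_event, start_offset_s = start_offset_s,
                 end_offset_s = end_offset_s),
            class = "epoch_spec")
}

#' The pre-stimulus epoch: odor-port entry to 100 ms after valve open
#'
#' Before the odor can influence firing; the primary epoch for the
#' preference and choice-linkage analyses.
#'
#' @return an `epoch_spec`.
#' @export
pre_stimulus_epoch <- function() {
  epoch_spec("pre_stimulus", "odor_port_entry", "valve_open",
             end_offset_s = 0.1)
}

resolve_epoch <- function(trials, epoch) {
  for (ev in c(epoch$start_event, epoch$end_event)) {
    if (!ev %in% names(trials)) stopf("unknown epoch event '%s'", ev)
  }
  a <- trials[[epoch$start_event]] + epoch$start_offset_s
  b <- trials[[epoch$end_event]] + epoch$end_offset_s
  bad <- !is.na(a) & !is.na(b) & b <= a
  if (any(bad)) {
    warnf("%d trial(s) with non-positive epoch duration dropped", sum(bad))
    a[bad] <- NA_real_; b[bad] <- NA_real_
  }
  data.frame(start = a, end = b)
}

#' Per-trial firing rate in an epoch
#'
#' Spike count in the half-open epoch interval divided by its (per-trial)
#' duration. Trials whose epoch events are missing return `NA` with a
#' warning.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table.
#' @param epoch an [epoch_spec()] (default: pre-stimulus).
#' @return numeric vector of rates (spikes/s), one per trial.
#' @export
epoch_rate <- function(spikes, trials, epoch = pre_stimulus_epoch()) {
  stopifnot(inherits(spikes, "spike_train"))
  win <- resolve_epoch(trials, epoch)
  miss <- is.na(win$start) | is.na(win$end)
  if (any(miss)) warnf("%d trial(s) without epoch events excluded", sum(miss))
  st <- spikes$spike_times
  vapply(seq_len(nrow(win)), function(i) {
    if (miss[i]) return(NA_real_)
    count_in(st, win$start[i], win$end[i]) / (win$end[i] - win$start[i])
  }, numeric(1))
}

#' ROC-based preference index
#'
#' `preference = 2 * (ROC_area - 0.5)`, where `ROC_area` is the
#' probability that a randomly drawn rate from the positively oriented
#' group exceeds one drawn from the other group (ties count 1/2);
#' equivalently the normalized Mann-Whitney U statistic computed from
#' mid-ranks. The index lies in `[-1, 1]`: +1 means complete separation
#' in favor of `rates_pos`, -1 the reverse, 0 no preference. For choice
#' preference the positive group is contralateral choices; for outcome
#' preference it is rewarded trials.
#'
#' @param rates_pos,rates_neg firing rates for the +1- and -1-oriented
#'   groups; both non-empty.
#' @return preference in `[-1, 1]`.
#' @export
roc_preference <- function(rates_pos, rates_neg) {
  rates_pos <- rates_pos[!is.na(rates_pos)]
  rates_neg <- rates_neg[!is.na(rates_neg)]
  na <- length(rates_pos); nb <- length(rates_neg)
  if (na == 0 || nb == 0) stopf("both groups must be non-empty")
  r <- rank(c(rates_pos, rates_neg))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  # algebraically 2 * (u / (na * nb) - 0.5); this form makes
  # roc_preference(a, b) == -roc_preference(b, a) exact in floating point
  (2 * u - na * nb) / (na * nb)
}

#' Monte Carlo permutation test for an ROC preference
#'
#' Recomputes the preference after randomly reassigning each firing rate
#' to one of the two groups (group sizes preserved), `n_perm` times, and
#' reports the fraction of permuted preferences at least as extreme as
#' the observed one, with the add-one correction
#' `p = (k + 1) / (n_perm + 1)`. The default is two-sided on the
#' preference magnitude; `tail = "one"` reproduces the one-sided count
#' of permuted preferences exceeding the observed value.
#'
#' Inclusion rules: each group needs at least `min_trials` trials and at
#' least one group must have a mean rate of `min_rate` spikes/s or more;
#' otherwise the unit is excluded (`included = FALSE`, `p_value = NA`).
#'
#' @inheritParams roc_preference
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param tail `"two"` (default) or `"one"`.
#' @param min_trials,min_rate inclusion thresholds (defaults 4 trials
#'   and 2 spikes/s).
#' @return list with `preference`, `p_value`, `included`, `n_pos`,
#'   `n_neg`, `mean_rates`.
#' @export
preference_permutation <- function(rates_pos, rates_neg, n_perm = 1000,
                                   seed = NULL, tail = c("two", "one"),
                                   min_trials = 4, min_rate = 2) {
  tail <- match.arg(tail)
  rates_pos <- rates_pos[!is.na(rates_pos)]
  rates_neg <- rates_neg[!is.na(rates_neg)]
  na <- length(rates_pos); nb <- length(rates_neg)
  mr <- c(pos = if (na) mean(rates_pos) else NA_real_,
          neg = if (nb) mean(rates_neg) else NA_real_)
  if (na < min_trials || nb < min_trials ||
      !any(mr >= min_rate, na.rm = TRUE)) {
    return(list(preference = if (na && nb)
                  roc_preference(rates_pos, rates_neg) else NA_real_,
                p_value = NA_real_, included = FALSE,
                n_pos = na, n_neg = nb, mean_rates = mr))
  }
  obs <- roc_preference(rates_pos, rates_neg)
  # mid-ranks of the pooled sample are permutation-invariant: each
  # permuted preference is a U statistic over a random size-na subset.
  r <- rank(c(rates_pos, rates_neg))
  ntot <- na + nb
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      u <- sum(r[sample.int(ntot, na)]) - na * (na + 1) / 2
      (2 * u - na * nb) / (na * nb)
    }, numeric(1))
  })
  k <- if (tail == "two") sum(abs(perm) >= abs(obs) - 1e-12)
       else sum(perm >= obs - 1e-12)
  list(preference = obs, p_value = (k + 1) / (n_perm + 1), included = TRUE,
       n_pos = na, n_neg = nb, mean_rates = mr)
}

# map trials to +1/-1 preference groups for a variable x lag grouping
preference_groups <- function(trials, recorded_side,
                              variable = c("choice", "outcome"), lag = 1L) {
  variable <- match.arg(variable)
  n <- nrow(trials)
  if (lag == 0L) {
    ch <- trials$choice
    rw <- trials$rewarded
    ok <- ch %in% c("left", "right")
  } else {
    valid <- history_valid(trials)
    ok <- rep(FALSE, n); ch <- rep(NA_character_, n); rw <- rep(NA_integer_, n)
    idx <- (lag + 1L):n
    if (n > lag) {
      ref <- idx - lag
      good <- trials$session_id[idx] == trials$session_id[ref] & valid[ref]
      ok[idx] <- good
      ch[idx][good] <- trials$choice[ref][good]
      rw[idx][good] <- trials$rewarded[ref][good]
    }
  }
  if (variable == "choice") {
    contra <- if (recorded_side == "left") "right" else "left"
    pos <- ok & ch == contra
    neg <- ok & ch != contra
  } else {
    pos <- ok & !is.na(rw) & rw == 1L
    neg <- ok & !is.na(rw) & rw == 0L
  }
  list(pos = which(pos), neg = which(neg))
}

#' Preference of one unit for a choice/outcome grouping at a lag
#'
#' Computes epoch firing rates, splits trials by the requested variable
#' (`choice`: contralateral vs ipsilateral; `outcome`: rewarded vs
#' unrewarded) at lag 0 (current trial), 1 or 2 trials back, and runs
#' the ROC preference with its permutation test.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table for the unit's session.
#' @param variable `"choice"` or `"outcome"`.
#' @param lag 0, 1 or 2.
#' @param epoch analysis epoch (default pre-stimulus).
#' @inheritParams preference_permutation
#' @return one-row data.frame (unit_id, variable, lag, preference,
#'   p_value, included, n_pos, n_neg, mean_rate_pos, mean_rate_neg).
#' @export
unit_preference <- function(spikes, trials, variable = "choice", lag = 1L,
                            epoch = pre_stimulus_epoch(), n_perm = 1000,
                            seed = NULL, tail = "two") {
  rates <- suppressWarnings(epoch_rate(spikes, trials, epoch))
  g <- preference_groups(trials, spikes$recorded_side, variable, lag)
  res <- preference_permutation(rates[g$pos], rates[g$neg],
                                n_perm = n_perm, seed = seed, tail = tail)
  data.frame(unit_id = spikes$unit_id, mouse_id = spikes$mouse_id,
             session_id = spikes$session_id,
             variable = variable, lag = as.integer(lag),
             preference = res$preference, p_value = res$p_value,
             included = res$included, n_pos = res$n_pos, n_neg = res$n_neg,
             mean_rate_pos = unname(res$mean_rates["pos"]),
             mean_rate_neg = unname(res$mean_rates["neg"]),
             stringsAsFactors = FALSE)
}

#' Population summary of preference results
#'
#' Aggregates per-unit preference rows (as from [unit_preference()],
#' possibly over several lags): per-lag fractions of significantly
#' positive / negative units, a chi-square test for sign imbalance among
#' significant units, a Kruskal-Wallis test on preference magnitudes
#' across lags with pairwise Wilcoxon post-hocs, and the Pearson
#' correlation between lag-0 and lag-1 preferences per unit.
#'
#' @param results data.frame of per-unit preference rows for one
#'   variable.
#' @param alpha significance level (default 0.05).
#' @return list with `per_lag`, `sign_test` (per lag), `kruskal`,
#'   `pairwise`, `lag01_correlation`.
#' @export
population_preference <- function(results, alpha = 0.05) {
  inc <- results[results$included %in% TRUE, , drop = FALSE]
  if (nrow(inc) == 0) {
    warnf("all units excluded")
    return(list(per_lag = data.frame(), sign_test = data.frame(),
                kruskal = NULL, pairwise = NULL,
                lag01_correlation = NULL))
  }
  lags <- sort(unique(inc$lag))
  per_lag <- do.call(rbind, lapply(lags, function(l) {
    s <- inc[inc$lag == l, ]
    sig <- !is.na(s$p_value) & s$p_value < alpha
    data.frame(lag = l, n = nrow(s),
               frac_significant = mean(sig),
               frac_positive = mean(sig & s$preference > 0),
               frac_negative = mean(sig & s$preference < 0))
  }))
  sign_test <- do.call(rbind, lapply(lags, function(l) {
    s <- inc[inc$lag == l, ]
    sig <- !is.na(s$p_value) & s$p_value < alpha
    npos <- sum(sig & s$preference > 0); nneg <- sum(sig & s$preference < 0)
    p <- if (npos + nneg > 0)
      suppressWarnings(chisq.test(c(npos, nneg))$p.value) else NA_real_
    data.frame(lag = l, n_positive = npos, n_negative = nneg, p_value = p)
  }))
  kw <- if (length(lags) > 1) {
    kruskal.test(abs(inc$preference), factor(inc$lag))
  } else NULL
  pairwise <- if (length(lags) > 1) {
    combs <- utils::combn(lags, 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      wt <- wilcox.test(abs(inc$preference[inc$lag == a]),
                        abs(inc$preference[inc$lag == b]), exact = FALSE)
      data.frame(lag_a = a, lag_b = b, p_value = wt$p.value)
    }))
  } else NULL
  cor01 <- NULL
  if (all(c(0, 1) %in% lags)) {
    a <- inc[inc$lag == 0, c("unit_id", "preference")]
    b <- inc[inc$lag == 1, c("unit_id", "preference")]
    m <- merge(a, b, by = "unit_id", suffixes = c("_lag0", "_lag1"))
    if (nrow(m) >= 3) {
      if (sd(m$preference_lag0) == 0 || sd(m$preference_lag1) == 0) {
        r <- if (all(m$preference_lag0 == m$preference_lag1)) 1 else NA_real_
        cor01 <- list(r = r, p_value = NA_real_, n = nrow(m))
      } else {
        ct <- cor.test(m$preference_lag0, m$preference_lag1)
        cor01 <- list(r = unname(ct$estimate), p_value = ct$p.value,
                      n = nrow(m))
      }
    }
  }
  list(per_lag = per_lag, sign_test = sign_test, kruskal = kw,
       pairwise = pairwise, lag01_correlation = cor01)
}

#' Does a unit code the chosen port or the movement direction?
#'
#' Choice and movement direction are confounded within a single movement,
#' but the outbound movement (odor port to reward port) and the return
#' movement (reward port back to the odor port) are in opposite physical
#' directions while sharing the chosen port. The choice preference is
#' therefore computed separately in the two movement epochs: matching
#' signs mark the unit port-preserving (codes the chosen port), inverted
#' signs mark it direction-preserving.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table.
#' @inheritParams preference_permutation
#' @return one-row data.frame with the outbound and return preferences
#'   and `classification` (`"port_preserving"`, `"direction_preserving"`,
#'   or `NA` when either epoch preference is unavailable or zero).
#' @export
movement_direction_check <- function(spikes, trials, n_perm = 1000,
                                     seed = NULL) {
  n <- nrow(trials)
  out_epoch <- epoch_spec("outbound", "odor_port_exit", "reward_port_entry")
  # return epoch: reward-port exit to the next trial's odor-port entry
  ret <- trials
  nxt <- c(trials$odor_port_entry[-1], NA_real_)
  nxt[c(trials$session_id[-1] != trials$session_id[-n], TRUE)] <- NA_real_
  ret$next_entry <- nxt
  ret_epoch <- epoch_spec("return", "reward_port_exit", "next_entry")

  g <- preference_groups(trials, spikes$recorded_side, "choice", 0L)
  r_out <- suppressWarnings(epoch_rate(spikes, trials, out_epoch))
  r_ret <- suppressWarnings(epoch_rate(spikes, ret, ret_epoch))
  p_out <- preference_permutation(r_out[g$pos], r_out[g$neg],
                                  n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else seed)
  p_ret <- preference_permutation(r_ret[g$pos], r_ret[g$neg],
                                  n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL
                                         else seed + 1L)
  cls <- NA_character_
  if (isTRUE(p_out$included) && isTRUE(p_ret$included) &&
      p_out$preference != 0 && p_ret$preference != 0) {
    cls <- if (sign(p_out$preference) == sign(p_ret$preference))
      "port_preserving" else "direction_preserving"
  }
  data.frame(unit_id = spikes$unit_id,
             preference_outbound = p_out$preference,
             preference_return = p_ret$preference,
             classification = cls, stringsAsFactors = FALSE)
}

#' Population fraction of port-preserving units
#'
#' @param checks data.frame of rows from [movement_direction_check()].
#' @return list with counts, `fraction_port_preserving`, and a
#'   chi-square test against an even split.
#' @export
population_movement_direction <- function(checks) {
  cls <- checks$classification[!is.na(checks$classification)]
  n_port <- sum(cls == "port_preserving")
  n_dir <- sum(cls == "direction_preserving")
  p <- if (n_port + n_dir > 0)
    suppressWarnings(chisq.test(c(n_port, n_dir))$p.value) else NA_real_
  list(n_port_preserving = n_port, n_direction_preserving = n_dir,
       fraction_port_preserving = if (n_port + n_dir > 0)
       n_port / (n_port + n_dir) else NA_real_,
       p_value = p)
}

#' Peristimulus time histogram with Gaussian smoothing
#'
#' Trial-averaged firing rate aligned to a task event, optionally split
#' by a per-trial grouping, binned at `bin_s` and smoothed with a
#' Gaussian kernel (default sigma 15 ms; `sigma = 0` leaves the binned
#' PSTH unsmoothed). The s.e.m. is computed across smoothed per-trial
#' traces.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table.
#' @param align_event trial event column to align to.
#' @param group_by optional per-trial factor/character vector; `NA`
#'   trials are dropped, empty groups omitted.
#' @param window two numbers, seconds relative to the event.
#' @param bin_s bin width (default 1 ms).
#' @param smoothing_sigma_s Gaussian sigma in seconds (default 0.015).
#' @return data.frame with columns `group`, `time_s`, `rate`, `sem`,
#'   `n_trials`.
#' @export
compute_psth <- function(spikes, trials, align_event = "valve_open",
                         group_by = NULL, window = c(-0.5, 1),
                         bin_s = 0.001, smoothing_sigma_s = 0.015) {
  if (!align_event %in% names(trials)) {
    stopf("unknown align event '%s'", align_event)
  }
  anchors <- trials[[align_event]]
  grp <- if (is.null(group_by)) rep("all", nrow(trials))
         else as.character(group_by)
  keep <- !is.na(anchors) & !is.na(grp)
  anchors <- anchors[keep]; grp <- grp[keep]
  edges <- seq(window[1], window[2], by = bin_s)
  centers <- edges[-length(edges)] + bin_s / 2
  st <- spikes$spike_times
  nb <- length(centers)
  mat <- t(vapply(anchors, function(a) {
    rel <- st[st >= a + window[1] & st < a + window[2]] - a
    idx <- floor((rel - window[1]) / bin_s) + 1
    idx <- idx[idx >= 1 & idx <= nb]
    tabulate(idx, nbins = nb) / bin_s
  }, numeric(length(centers))))
  if (smoothing_sigma_s > 0) {
    half <- ceiling(4 * smoothing_sigma_s / bin_s)
    kern <- dnorm(seq(-half, half) * bin_s, sd = smoothing_sigma_s)
    kern <- kern / sum(kern)
    mat <- t(apply(mat, 1, function(row) {
      smoothed <- stats::filter(c(rep(row[1], half), row,
                                  rep(row[length(row)], half)),
                                kern, sides = 2)
      as.numeric(smoothed[(half + 1):(half + length(row))])
    }))
  }
  out <- lapply(unique(grp), function(g) {
    rows <- which(grp == g)
    if (length(rows) == 0) return(NULL)
    m <- mat[rows, , drop = FALSE]
    data.frame(group = g, time_s = centers,
               rate = colMeans(m),
               sem = apply(m, 2, sd) / sqrt(nrow(m)),
               n_trials = length(rows), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
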