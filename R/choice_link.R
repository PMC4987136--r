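#' Build (normalized rate, preferred-choice indicator) pairs for a unit
#'
#' For a unit with a significant previous-choice preference, pairs its
#' pre-stimulus firing rate on each ambiguous current trial (left-odor
#' fraction 0.40, 0.50 or 0.60) with an indicator of whether the mouse
#' chose the unit's preferred port (1) or the antipreferred port (0).
#' Rates are normalized to the unit's maximum across all trials,
#' separately within each previous-choice condition, so normalized rates
#' lie in `[0, 1]`; conditions whose maximum rate is 0 are dropped with
#' a warning. Trials without a valid previous choice or without a
#' current choice are dropped.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table for the unit's session.
#' @param preferred_side `"left"` or `"right"`: the port the unit
#'   prefers. Derived upstream from the sign of its lag-1 choice
#'   preference (positive preference = contralateral port).
#' @param epoch analysis epoch (default pre-stimulus).
#' @param ambiguous_fractions left-odor fractions defining ambiguous
#'   trials.
#' @return data.frame with `normalized_rate`, `preferred` (0/1),
#'   `prev_choice`.
#' @export
link_trials <- function(spikes, trials, preferred_side,
                        epoch = pre_stimulus_epoch(),
                        ambiguous_fractions = c(0.40, 0.50, 0.60)) {
  if (!preferred_side %in% c("left", "right")) {
    stopf("preferred_side must be 'left' or 'right'")
  }
  rates <- suppressWarnings(epoch_rate(spikes, trials, epoch))
  n <- nrow(trials)
  valid <- history_valid(trials)
  prev <- rep(NA_character_, n)
  if (n > 1) {
    same <- trials$session_id[-1] == trials$session_id[-n]
    ok <- same & valid[-n]
    prev[-1][ok] <- trials$choice[-n][ok]
  }
  norm <- rep(NA_real_, n)
  for (cond in c("left", "right")) {
    rows <- which(prev == cond & !is.na(rates))
    if (length(rows) == 0) next
    mx <- max(rates[rows])
    if (mx == 0) {
      warnf("previous-%s condition has zero maximum rate; trials dropped",
            cond)
      next
    }
    norm[rows] <- rates[rows] / mx
  }
  amb <- trials$odor_left_fraction %in% ambiguous_fractions
  chose <- trials$choice %in% c("left", "right")
  keep <- amb & chose & !is.na(norm)
  data.frame(normalized_rate = norm[keep],
             preferred = as.numeric(trials$choice[keep] == preferred_side),
             prev_choice = prev[keep], stringsAsFactors = FALSE)
}

ls_slope <- function(x, y) {
  vx <- sum((x - mean(x))^2)
  if (vx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / vx
}

logit_slope <- function(x, y) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, x), y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 50)))
  unname(coef(fit)[2])
}

#' Permutation test on the rate-to-choice slope of one unit
#'
#' Least-squares slope of the preferred-choice indicator on the
#' normalized pre-stimulus rate (raw trial points, not binned), with a
#' two-sided Monte Carlo permutation test that shuffles the indicators
#' across trials (1000 repeats by default, add-one corrected). A
#' logistic fit of the same points is available; sign classification is
#' expected to agree between the two.
#'
#' @param pairs data.frame from [link_trials()].
#' @param n_perm permutation count (default 1000).
#' @param seed integer seed.
#' @param fit `"line"` (default) or `"logistic"`.
#' @param alpha significance level for the sign class.
#' @return an object of class `slope_result`: list with `slope`,
#'   `p_value`, `sign_class` (`"positive"`, `"negative"`, `"ns"`),
#'   `n_trials`, `fit`.
#' @export
slope_test <- function(pairs, n_perm = 1000, seed = NULL,
                       fit = c("line", "logistic"), alpha = 0.05) {
  fit <- match.arg(fit)
  x <- pairs$normalized_rate; y <- pairs$preferred
  n <- length(x)
  slope_fun <- if (fit == "line") ls_slope else logit_slope
  if (n < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(structure(list(slope = 0, p_value = NA_real_, sign_class = "ns",
                          n_trials = n, fit = fit),
                     class = "slope_result"))
  }
  obs <- slope_fun(x, y)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) slope_fun(x, sample(y)), numeric(1))
  })
  k <- sum(abs(perm) >= abs(obs) - 1e-12, na.rm = TRUE)
  p <- (k + 1) / (n_perm + 1)
  cls <- if (is.na(p) || p >= alpha) "ns"
         else if (obs > 0) "positive" else "negative"
  structure(list(slope = obs, p_value = p, sign_class = cls,
                 n_trials = n, fit = fit),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("<slope_result %s | slope = %.4f | p = %.4g | n = %d (%s)>\n",
              x$sign_class, x$slope, x$p_value, x$n_trials, x$fit))
  invisible(x)
}

#' Population summary of rate-to-choice slopes
#'
#' Fractions of significantly positive, significantly negative and
#' non-significant slopes, overall and per mouse, with a chi-square test
#' comparing the positive and negative counts.
#'
#' @param results data.frame with columns `unit_id`, `mouse_id`,
#'   `slope`, `p_value`, `sign_class` (one row per unit, e.g. built from
#'   [slope_test()] results).
#' @return list with `overall` (counts and fractions, chi-square
#'   p-value) and `per_mouse` (data.frame).
#' @export
population_slopes <- function(results) {
  if (nrow(results) == 0) {
    return(list(overall = NULL, per_mouse = data.frame()))
  }
  summarize <- function(df) {
    npos <- sum(df$sign_class == "positive")
    nneg <- sum(df$sign_class == "negative")
    nns <- sum(df$sign_class == "ns")
    p <- if (npos + nneg > 0)
      suppressWarnings(chisq.test(c(npos, nneg))$p.value) else NA_real_
    data.frame(n = nrow(df), n_positive = npos, n_negative = nneg,
               n_ns = nns, frac_positive = npos / nrow(df),
               frac_negative = nneg / nrow(df), p_value_sign = p)
  }
  per_mouse <- do.call(rbind, lapply(split(results, results$mouse_id),
                                     summarize))
  per_mouse <- cbind(mouse_id = rownames(per_mouse), per_mouse)
  rownames(per_mouse) <- NULL
  list(overall = summarize(results), per_mouse = per_mouse)
}
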