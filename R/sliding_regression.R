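#' Neural regressor codings for the encoding model
#'
#' Per-trial -1/0/+1 codings of the previous and current choice and
#' outcome, in the neural (hemisphere-referenced) convention:
#' contralateral choice = +1, ipsilateral = -1, no choice = 0; rewarded
#' = +1, unrewarded = -1, no choice = 0. `recorded_side` defines
#' ipsi/contra (a left implant makes right choices contralateral).
#' Previous-trial codes treat excluded and late-reinitiation
#' predecessors as "no choice", as in [build_design()].
#'
#' @param trials trial table.
#' @param recorded_side `"left"` or `"right"`.
#' @return data.frame with `x_choice_prev`, `x_outcome_prev`,
#'   `x_choice_cur`, `x_outcome_cur`.
#' @export
code_regressors <- function(trials, recorded_side = "left") {
  if (!recorded_side %in% c("left", "right")) {
    stopf("recorded_side must be 'left' or 'right'")
  }
  # behavioral coding is left = +1; contra = +1 flips sign for a left
  # implant (contra = right) and keeps it for a right implant.
  flip <- if (recorded_side == "left") -1 else 1
  n <- nrow(trials)
  lr <- lag_regressors(trials, 1L)
  x_choice_prev <- flip * lr$choice
  # outcome_L/outcome_R are +-1 only for the matching side; their sum is
  # the side-free rewarded/unrewarded code.
  x_outcome_prev <- lr$outcome_L + lr$outcome_R
  cur_left <- trials$choice == "left"
  cur_right <- trials$choice == "right"
  x_choice_cur <- ifelse(cur_left, flip * 1,
                         ifelse(cur_right, flip * -1, 0))
  rw <- trials$rewarded
  x_outcome_cur <- ifelse(!cur_left & !cur_right | is.na(rw), 0,
                          ifelse(rw == 1, 1, -1))
  data.frame(x_choice_prev = x_choice_prev,
             x_outcome_prev = x_outcome_prev,
             x_choice_cur = x_choice_cur,
             x_outcome_cur = x_outcome_cur)
}

#' Sliding-window firing-rate matrix aligned to a trial event
#'
#' Mean firing rate per trial in 100-ms bins stepped every 10 ms
#' (defaults), aligned to the requested event. Bin `t` covers the
#' half-open interval `[center - width/2, center + width/2)`.
#'
#' @param spikes a `spike_train`.
#' @param trials trial table.
#' @param align_event `"valve_open"`, `"odor_port_entry"`,
#'   `"odor_port_exit"` or `"reward_port_entry"`.
#' @param window two numbers: first and last bin center, seconds
#'   relative to the event.
#' @param bin_width_s bin duration (default 0.1).
#' @param step_s bin spacing (default 0.01).
#' @return an object of class `aligned_rate_matrix`: list with `rates`
#'   (trials x bins), `bin_centers`, `trial_rows` (row indices of
#'   `trials` retained), `align_event`, `bin_width_s`, `step_s`.
#' @export
bin_rates <- function(spikes, trials, align_event = "valve_open",
                      window = c(-0.3, 0.6), bin_width_s = 0.1,
                      step_s = 0.01) {
  stopifnot(inherits(spikes, "spike_train"))
  if (!align_event %in% names(trials)) {
    stopf("unknown align event '%s'", align_event)
  }
  anchors <- trials[[align_event]]
  keep <- which(!is.na(anchors))
  if (length(keep) < length(anchors)) {
    warnf("%d trial(s) without '%s' dropped", length(anchors) - length(keep),
          align_event)
  }
  centers <- seq(window[1], window[2], by = step_s)
  half <- bin_width_s / 2
  st <- spikes$spike_times
  rates <- t(vapply(anchors[keep], function(a) {
    lo <- a + window[1] - half
    hi <- a + window[2] + half
    rel <- st[st >= lo & st < hi] - a
    vapply(centers, function(ct) {
      sum(rel >= ct - half & rel < ct + half) / bin_width_s
    }, numeric(1))
  }, numeric(length(centers))))
  structure(list(rates = rates, bin_centers = centers, trial_rows = keep,
                 align_event = align_event, bin_width_s = bin_width_s,
                 step_s = step_s, unit_id = spikes$unit_id),
            class = "aligned_rate_matrix")
}

#' Per-bin multivariable linear regression of firing rate
#'
#' Fits, for every time bin, the ordinary-least-squares model
#' `FR(t) = b0(t) + bChoicePrev(t) x_choice_prev + bOutcomePrev(t)
#' x_outcome_prev + bChoiceCur(t) x_choice_cur + bOutcomeCur(t)
#' x_outcome_cur`, with t-based 95% confidence intervals; a coefficient
#' is significant in a bin when its CI excludes 0. The design is shared
#' across bins, so a rank-deficient design marks the aliased
#' coefficients undefined in every bin.
#'
#' @param matrix an `aligned_rate_matrix` from [bin_rates()].
#' @param regressors data.frame from [code_regressors()] (full trial
#'   table order; subset to the matrix's retained trials internally).
#' @return an object of class `sliding_fit`: list with `coefficients`,
#'   `ci_lo`, `ci_hi` (bins x terms), `significant` (logical),
#'   `bin_centers`, `align_event`, `n_trials`, `undefined` (character
#'   vector of aliased terms).
#' @export
fit_sliding <- function(matrix, regressors) {
  stopifnot(inherits(matrix, "aligned_rate_matrix"))
  R <- regressors[matrix$trial_rows, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(R))
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1) stopf("need at least %d trials, have %d", p + 1, n)
  qrX <- qr(X)
  undefined <- character(0)
  if (qrX$rank < p) {
    undefined <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    keep_cols <- setdiff(colnames(X), undefined)
    X <- X[, keep_cols, drop = FALSE]
    qrX <- qr(X)
    p <- ncol(X)
  }
  Y <- matrix$rates
  B <- qr.coef(qrX, Y)                        # p x bins
  res <- Y - X %*% B
  df <- n - p
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  piv <- qrX$pivot
  xtx_inv[piv, piv] <- xtx_inv
  se <- sqrt(outer(pmax(diag(xtx_inv), 0), pmax(s2, 0)))  # p x bins
  tcrit <- qt(0.975, df)
  all_terms <- c("(Intercept)", colnames(R))
  pad <- function(m) {
    out <- matrix(NA_real_, length(matrix$bin_centers), length(all_terms),
                  dimnames = list(NULL, all_terms))
    out[, rownames(m)] <- t(m)
    out
  }
  rownames(B) <- colnames(X); rownames(se) <- colnames(X)
  coefs <- pad(B)
  lo <- pad(B - tcrit * se)
  hi <- pad(B + tcrit * se)
  sig <- (lo > 0 | hi < 0)
  sig[is.na(coefs)] <- NA
  structure(list(coefficients = coefs, ci_lo = lo, ci_hi = hi,
                 significant = sig, bin_centers = matrix$bin_centers,
                 align_event = matrix$align_event, n_trials = n,
                 undefined = undefined, unit_id = matrix$unit_id),
            class = "sliding_fit")
}

#' Population time-course of sliding-regression coefficients
#'
#' Averages per-bin coefficients across a set of units (all fitted with
#' the same alignment and bins) and reports, per bin and term, the mean,
#' s.e.m., and fraction of units whose coefficient is significant.
#'
#' @param fits non-empty list of `sliding_fit` objects.
#' @return list with `bin_centers`, `align_event`, `mean`, `sem`,
#'   `fraction_significant` (each bins x terms), `n_units`.
#' @export
population_timecourse <- function(fits) {
  if (length(fits) == 0) stopf("empty unit set")
  bc <- fits[[1]]$bin_centers
  for (f in fits) {
    if (!isTRUE(all.equal(f$bin_centers, bc)) ||
        f$align_event != fits[[1]]$align_event) {
      stopf("all fits must share bins and alignment")
    }
  }
  arr <- simplify2array(lapply(fits, `[[`, "coefficients"))
  sig <- simplify2array(lapply(fits, `[[`, "significant"))
  nun <- length(fits)
  list(bin_centers = bc, align_event = fits[[1]]$align_event,
       mean = apply(arr, c(1, 2), mean, na.rm = TRUE),
       sem = apply(arr, c(1, 2), function(v) {
         v <- v[!is.na(v)]
         if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
       }),
       fraction_significant = apply(sig, c(1, 2), function(v)
         mean(v, na.rm = TRUE)),
       n_units = nun)
}
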