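#' Build a logistic-model design matrix from a trial table
#'
#' Implements the trial codings of the behavioral models. The response is
#' 1 for a left choice and 0 for a right choice. Trials on which no
#' reward port was entered within 1.5 s of odor-port exit (including
#' no-choice trials) are excluded from the response. Odor regressors are
#' `x_odor_L = max(0, (f_L - 0.5) / 0.5)` and
#' `x_odor_R = max(0, (f_R - 0.5) / 0.5)`, each in `[0, 1]` with at most
#' one positive per trial. Lagged regressors are computed within session
#' only; the choice `n` back codes left = +1, right = -1, and 0 for a
#' "no choice" predecessor -- a trial that was itself excluded or after
#' which the next trial was not initiated within 1.5 s of reward-port
#' exit. Outcome regressors are +1 for a rewarded and -1 for an
#' unrewarded choice at the named side, 0 otherwise.
#'
#' Model tags: `"simple"` (bias + odor terms), `"extended1"` /
#' `"extended2"` (adds choice/outcome terms 1 or 1-2 trials back),
#' `"muscimol"` (simple + binary muscimol session indicator),
#' `"reduced_choice1"` (simple + 1-back choice term only).
#'
#' @param trials a trial table (see [simulate_trial_events()] for the
#'   column contract), sorted by time within session.
#' @param model_tag one of `"simple"`, `"extended1"`, `"extended2"`,
#'   `"muscimol"`, `"reduced_choice1"`.
#' @param max_lag overrides the lag depth implied by `model_tag`.
#' @return an object of class `choice_design`: list with `X` (matrix,
#'   all trials), `y` (0/1, all trials; NA where excluded), `included`
#'   (logical mask), `model_tag`.
#' @export
build_design <- function(trials,
                         model_tag = c("simple", "extended1", "extended2",
                                       "muscimol", "reduced_choice1"),
                         max_lag = NULL) {
  model_tag <- match.arg(model_tag)
  for (s in unique(trials$session_id)) {
    tt <- trials$odor_port_entry[trials$session_id == s]
    if (is.unsorted(tt)) stopf("trials unsorted within session '%s'", s)
  }
  assert_choice_values(trials$choice)
  n <- nrow(trials)
  xo <- odor_regressors(trials$odor_left_fraction)
  X <- cbind(`(Intercept)` = rep(1, n), x_odor_L = xo$L, x_odor_R = xo$R)

  n_lag <- switch(model_tag, simple = 0L, extended1 = 1L, extended2 = 2L,
                  muscimol = 0L, reduced_choice1 = 1L)
  if (!is.null(max_lag)) n_lag <- as.integer(max_lag)
  valid <- history_valid(trials)
  if (n_lag > 0) {
    for (g in seq_len(n_lag)) {
      lr <- lag_regressors(trials, g, valid)
      if (model_tag == "reduced_choice1") {
        X <- cbind(X, lr$choice)
        colnames(X)[ncol(X)] <- sprintf("x_choice_%d", g)
      } else {
        X <- cbind(X, lr$choice, lr$outcome_L, lr$outcome_R)
        colnames(X)[(ncol(X) - 2):ncol(X)] <-
          sprintf(c("x_choice_%d", "x_outcome_L_%d", "x_outcome_R_%d"), g)
      }
    }
  }
  if (model_tag == "muscimol") {
    if (anyNA(trials$condition)) stopf("missing condition labels")
    X <- cbind(X, x_muscimol = as.numeric(trials$condition == "muscimol"))
  }

  chose <- trials$choice %in% c("left", "right")
  reached <- !is.na(trials$reward_port_entry) &
    (trials$reward_port_entry - trials$odor_port_exit) <= 1.5
  included <- chose & reached
  y <- rep(NA_real_, n)
  y[included] <- as.numeric(trials$choice[included] == "left")
  structure(list(X = X, y = y, included = included, model_tag = model_tag),
            class = "choice_design")
}

#' Fit a logistic choice model by maximum likelihood
#'
#' Binomial IRLS fit of the design from [build_design()], with Wald 95%
#' confidence intervals. Perfect or quasi-perfect separation is flagged
#' (`separation = TRUE`, `converged = FALSE`) rather than reported as a
#' silent divergence; singular designs error, naming the aliased
#' columns.
#'
#' @param design a `choice_design`, or a trial table (then `model_tag`
#'   is forwarded to [build_design()]).
#' @param model_tag used when `design` is a trial table.
#' @param rows optional logical/integer subset of trials to fit on
#'   (applied after the inclusion mask).
#' @return an object of class `logistic_fit`: coefficients, covariance,
#'   `ci95` (matrix with `lo`/`hi`), log-likelihood, `n_trials_used`,
#'   `converged`, `separation`, `model_tag`.
#' @export
fit_choice_model <- function(design, model_tag = "extended1", rows = NULL) {
  if (is.data.frame(design)) design <- build_design(design, model_tag)
  stopifnot(inherits(design, "choice_design"))
  use <- design$included
  if (!is.null(rows)) {
    sel <- rep(FALSE, length(use))
    sel[rows] <- TRUE
    use <- use & sel
  }
  X <- design$X[use, , drop = FALSE]
  y <- design$y[use]
  if (length(y) == 0 || length(unique(y)) < 2) {
    return(structure(list(coefficients = setNames(rep(NA_real_, ncol(X)),
                                                  colnames(X)),
                          covariance = NULL, ci95 = NULL,
                          log_likelihood = NA_real_,
                          n_trials_used = length(y), converged = FALSE,
                          separation = TRUE, model_tag = design$model_tag),
                     class = "logistic_fit"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("singular design; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 100))
  )
  beta <- coef(fit)
  mu <- fit$fitted.values
  sep <- all(mu > 1 - 1e-8 | mu < 1e-8) || any(abs(beta) > 25)
  # covariance from the weighted QR, as summary.glm does
  p <- ncol(X)
  Rmat <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  cov <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
  if (!is.null(cov)) {
    piv <- fit$qr$pivot[seq_len(p)]
    cov[piv, piv] <- cov
    dimnames(cov) <- list(names(beta), names(beta))
  }
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  z <- qnorm(0.975)
  ci <- cbind(lo = beta - z * se, hi = beta + z * se)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = beta, covariance = cov, ci95 = ci,
                 log_likelihood = ll, n_trials_used = length(y),
                 converged = fit$converged && !sep, separation = sep,
                 model_tag = design$model_tag),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit '%s' | n = %d | logLik = %.2f%s>\n",
              x$model_tag, x$n_trials_used, x$log_likelihood,
              if (isTRUE(x$separation)) " | SEPARATION" else ""))
  if (!is.null(x$ci95)) {
    print(round(cbind(estimate = x$coefficients, x$ci95), 4))
  }
  invisible(x)
}

predict_choice_prob <- function(fit, X) {
  drop(plogis(X[, names(fit$coefficients), drop = FALSE] %*%
                fit$coefficients))
}

#' Cross-validated model comparison by simulated-choice accuracy
#'
#' For each session of one mouse: repeatedly hold out a random 50% of the
#' session's included trials as a test set (stratified by odor mixture),
#' fit both models of the requested pair on all remaining trials of that
#' mouse (all sessions), draw simulated choices on the test trials from
#' each fitted model, and score the percentage of test trials on which
#' the simulated choice matches the actual choice. The improvement of
#' the larger model is averaged over repeats per session, and a
#' one-tailed paired t test across sessions asks whether the mean
#' improvement exceeds zero.
#'
#' @param trials all sessions of one mouse.
#' @param pair `"simple_vs_ext1"` or `"ext1_vs_ext2"`.
#' @param n_repeats test-set redraws per session (default 50).
#' @param seed integer seed.
#' @param deterministic if `TRUE`, predict by thresholding the fitted
#'   probability at 0.5 instead of sampling (default `FALSE`: the models
#'   generate choices).
#' @return list with `per_session` (data.frame: session_id,
#'   mean_improvement in percentage points), `p_value` (one-tailed
#'   paired t test), `t`, `df`.
#' @export
compare_models_cv <- function(trials,
                              pair = c("simple_vs_ext1", "ext1_vs_ext2"),
                              n_repeats = 50, seed = 1L,
                              deterministic = FALSE) {
  pair <- match.arg(pair)
  tags <- if (pair == "simple_vs_ext1") c("simple", "extended1")
          else c("extended1", "extended2")
  d1 <- build_design(trials, tags[1])
  d2 <- build_design(trials, tags[2])
  sessions <- unique(trials$session_id)
  idx_all <- seq_len(nrow(trials))

  per_session <- with_seed(seed, {
    vapply(sessions, function(s) {
      in_s <- which(trials$session_id == s & d1$included)
      imp <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        test <- stratified_half(in_s, trials$odor_left_fraction[in_s])
        for (tries in 1:10) {
          if (length(test) > 0) break
          test <- stratified_half(in_s, trials$odor_left_fraction[in_s])
          warnf("empty test split; resampling")
        }
        train <- setdiff(idx_all, test)
        f1 <- fit_choice_model(d1, rows = train)
        f2 <- fit_choice_model(d2, rows = train)
        p1 <- predict_choice_prob(f1, d1$X[test, , drop = FALSE])
        p2 <- predict_choice_prob(f2, d2$X[test, , drop = FALSE])
        actual <- d1$y[test]
        if (deterministic) {
          c1 <- as.numeric(p1 > 0.5); c2 <- as.numeric(p2 > 0.5)
        } else {
          c1 <- rbinom(length(p1), 1, p1)
          c2 <- rbinom(length(p2), 1, p2)
        }
        imp[r] <- 100 * (mean(c2 == actual) - mean(c1 == actual))
      }
      mean(imp)
    }, numeric(1))
  })
  tt <- if (length(per_session) >= 2 && sd(per_session) > 0) {
    t.test(per_session, mu = 0, alternative = "greater")
  } else NULL
  list(per_session = data.frame(session_id = sessions,
                                mean_improvement = as.numeric(per_session)),
       mean_improvement = mean(per_session),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
       pair = pair)
}

# random half of idx, stratified by the grouping factor g
stratified_half <- function(idx, g) {
  unlist(lapply(split(idx, g), function(v) {
    k <- floor(length(v) / 2)
    if (k == 0) return(integer(0))
    if (length(v) == 1) return(integer(0))
    sample(v, k)
  }), use.names = FALSE)
}

#' Fit the muscimol inactivation model on a three-session set
#'
#' Pools one muscimol session with its flanking saline sessions and fits
#' the simple model plus a binary muscimol indicator. A positive
#' `x_muscimol` coefficient is a leftward (ipsilateral, for a
#' left-hemisphere infusion) influence of muscimol on choice.
#'
#' @param trials pooled trial table containing exactly one muscimol
#'   session and two saline sessions.
#' @return a `logistic_fit` with an `x_muscimol` coefficient.
#' @export
fit_inactivation <- function(trials) {
  if (anyNA(trials$condition)) stopf("missing condition labels")
  conds <- table(unique(trials[, c("session_id", "condition")])$condition)
  if (is.na(conds["muscimol"]) || conds["muscimol"] < 1 ||
      is.na(conds["saline"]) || conds["saline"] < 1) {
    stopf("need at least one muscimol and one saline session")
  }
  fit_choice_model(build_design(trials, "muscimol"))
}

#' Fit the reduced 1-back choice model for one condition
#'
#' Restricts the extended model to bias + odor terms + the 1-back choice
#' term, fitted on the sessions of the requested condition only. Used to
#' ask whether inactivation weakens the dependence of choice on the
#' previous choice.
#'
#' @param trials trial table with condition labels.
#' @param condition `"saline"` or `"muscimol"`.
#' @return a `logistic_fit` with an `x_choice_1` coefficient.
#' @export
fit_reduced_choice1 <- function(trials, condition = c("saline", "muscimol")) {
  condition <- match.arg(condition)
  sub <- trials[trials$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no trials with condition '%s'", condition)
  fit_choice_model(build_design(sub, "reduced_choice1"))
}

#' Compare the 1-back choice coefficient between muscimol and saline
#'
#' Across simulated or recorded session sets, computes the reduced-model
#' 1-back choice coefficient separately per set and condition and tests
#' whether it is lower under muscimol with a one-tailed Mann-Whitney U
#' test.
#'
#' @param sets list of pooled three-session trial tables (as returned in
#'   `$trials` by [simulate_inactivation_set()]); at least 2.
#' @return list with `saline`, `muscimol` (coefficient vectors),
#'   `p_value`, `statistic`.
#' @export
compare_choice1_conditions <- function(sets) {
  if (length(sets) < 2) stopf("need >= 2 session sets for the comparison")
  b_sal <- vapply(sets, function(tr) {
    unname(coef(fit_reduced_choice1(tr, "saline"))["x_choice_1"])
  }, numeric(1))
  b_mus <- vapply(sets, function(tr) {
    unname(coef(fit_reduced_choice1(tr, "muscimol"))["x_choice_1"])
  }, numeric(1))
  wt <- wilcox.test(b_mus, b_sal, alternative = "less", exact = FALSE)
  list(saline = b_sal, muscimol = b_mus,
       p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Per-trial movement metrics and grouped comparisons
#'
#' Computes, per trial, the latency from go signal to odor-port exit, the
#' movement duration from odor-port exit to reward-port entry, and the
#' return duration from reward-port exit to the next trial's odor-port
#' entry (within session). Optionally compares each metric between
#' previous-choice groups (two-tailed unpaired t test per mouse) and
#' between muscimol and saline sessions.
#'
#' @param trials trial table.
#' @param by_prev_choice,by_condition run the grouped comparisons.
#' @return list with `metrics` (per-trial data.frame) and, when
#'   requested, `by_prev_choice` and `by_condition` test tables.
#' @export
movement_metrics <- function(trials, by_prev_choice = TRUE,
                             by_condition = TRUE) {
  n <- nrow(trials)
  latency <- trials$odor_port_exit - trials$go
  movement <- trials$reward_port_entry - trials$odor_port_exit
  ret <- rep(NA_real_, n)
  if (n > 1) {
    same <- trials$session_id[-1] == trials$session_id[-n]
    ret[-n] <- ifelse(same,
                      trials$odor_port_entry[-1] - trials$reward_port_exit[-n],
                      NA_real_)
  }
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(latency) || neg(movement) || neg(ret)) {
    stopf("negative duration encountered; corrupt event times")
  }
  prev_choice <- c(NA_character_, trials$choice[-n])
  if (n > 1) prev_choice[c(FALSE, trials$session_id[-1] !=
                             trials$session_id[-n])] <- NA_character_
  metrics <- data.frame(session_id = trials$session_id,
                        mouse_id = trials$mouse_id,
                        trial_index = trials$trial_index,
                        condition = trials$condition,
                        choice = trials$choice,
                        prev_choice = prev_choice,
                        latency_s = latency, movement_s = movement,
                        return_s = ret, stringsAsFactors = FALSE)
  out <- list(metrics = metrics)
  grp_test <- function(x, g, a, b) {
    xa <- x[!is.na(g) & g == a & !is.na(x)]
    xb <- x[!is.na(g) & g == b & !is.na(x)]
    if (length(xa) < 2 || length(xb) < 2) return(c(NA_real_, NA_real_))
    tt <- t.test(xa, xb)
    c(mean(xa) - mean(xb), tt$p.value)
  }
  if (by_prev_choice) {
    rows <- list()
    for (m in unique(metrics$mouse_id)) {
      sub <- metrics[metrics$mouse_id == m, ]
      for (metric in c("latency_s", "movement_s", "return_s")) {
        r <- grp_test(sub[[metric]], sub$prev_choice, "left", "right")
        rows[[length(rows) + 1L]] <-
          data.frame(mouse_id = m, metric = metric,
                     diff_left_minus_right = r[1], p_value = r[2])
      }
    }
    out$by_prev_choice <- do.call(rbind, rows)
  }
  if (by_condition && any(metrics$condition == "muscimol")) {
    rows <- lapply(c("latency_s", "movement_s", "return_s"), function(metric) {
      r <- grp_test(metrics[[metric]], metrics$condition,
                    "muscimol", "saline")
      data.frame(metric = metric, diff_muscimol_minus_saline = r[1],
                 p_value = r[2])
    })
    out$by_condition <- do.call(rbind, rows)
  }
  out
}

#' Psychometric curve, optionally conditioned on the previous trial
#'
#' Left-choice fraction (with standard error) per odor mixture, plus the
#' best-fit simple-model curve on the same trials. Conditioning selects
#' current trials by the previous trial's choice and outcome.
#'
#' @param trials trial table.
#' @param condition_on one of `"none"`, `"prev_left_rew"`,
#'   `"prev_left_unrew"`, `"prev_right_rew"`, `"prev_right_unrew"`.
#' @return list with `points` (data.frame: odor_left_fraction, n,
#'   p_left, se) and `fit` (simple-model `logistic_fit`, or `NULL` when
#'   the subset cannot be fit).
#' @export
psychometric_conditional <- function(trials,
                                     condition_on = c("none",
                                                      "prev_left_rew",
                                                      "prev_left_unrew",
                                                      "prev_right_rew",
                                                      "prev_right_unrew")) {
  condition_on <- match.arg(condition_on)
  d <- build_design(trials, "extended1")
  keep <- d$included
  if (condition_on != "none") {
    xc <- d$X[, "x_choice_1"]
    xl <- d$X[, "x_outcome_L_1"]; xr <- d$X[, "x_outcome_R_1"]
    keep <- keep & switch(condition_on,
      prev_left_rew   = xc == 1 & xl == 1,
      prev_left_unrew = xc == 1 & xl == -1,
      prev_right_rew  = xc == -1 & xr == 1,
      prev_right_unrew = xc == -1 & xr == -1)
  }
  sub <- trials[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    warnf("empty condition subset '%s'", condition_on)
    return(list(points = data.frame(), fit = NULL))
  }
  mixtures <- sort(unique(trials$odor_left_fraction))
  pts <- do.call(rbind, lapply(mixtures, function(f) {
    ss <- sub[sub$odor_left_fraction == f, ]
    if (nrow(ss) == 0) {
      warnf("no trials at mixture %.2f in subset; point omitted", f)
      return(NULL)
    }
    p <- mean(ss$choice == "left")
    data.frame(odor_left_fraction = f, n = nrow(ss), p_left = p,
               se = sqrt(p * (1 - p) / nrow(ss)))
  }))
  fit <- tryCatch(fit_choice_model(build_design(sub, "simple")),
                  error = function(e) NULL)
  list(points = pts, fit = fit)
}
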