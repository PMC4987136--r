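#' Run the full analysis pipeline from a configuration
#'
#' Executes, as configured: synthetic-cohort simulation (or loading of
#' trial/spike files), behavioral model fitting and cross-validated
#' model comparison per mouse, per-unit ROC preference at lags 0-2,
#' sliding-window encoding regression on the lag-1-choice-selective
#' units, the choice-linkage slope analysis, and inactivation-set
#' contrasts. All outputs are delimited text in `output_dir`, plus a
#' `run_log.json` recording package version, seeds and parameters, so a
#' run is reproducible from its config alone.
#'
#' @param config a `run_config` from [read_run_config()], or a path to
#'   a JSON config.
#' @param output_dir overrides the config's output directory.
#' @return (invisibly) a named list of the result tables.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- simulate or load ------------------------------------------------
  task <- call_known(task_config, config$task %||% list())
  results <- list()
  if (!is.null(config$trials_file)) {
    trials <- stage("load", read_trials(config$trials_file))
    spikes <- if (!is.null(config$spikes_file)) {
      stage("load", read_spikes(config$spikes_file))
    } else list()
  } else {
    cohort <- config$cohort %||% list()
    n_mice <- cohort$n_mice %||% 2L
    n_sessions <- cohort$n_sessions %||% 3L
    n_units <- cohort$neurons_per_session %||% 3L
    bp <- call_known(behavior_params, config$behavior %||% list())
    neurons <- lapply(seq_len(n_units), function(i) {
      neuron_params(baseline_rate = 8 + 2 * i,
                    modulation = list(list(regressor = "prev_choice",
                                           amplitude = 4,
                                           event = "odor_port_entry",
                                           start = -0.05, end = 0.35)))
    })
    sim <- stage("simulate", {
      per <- lapply(seq_len(n_mice), function(m) {
        simulate_mouse(task, bp, n_sessions = n_sessions,
                       neurons_per_session = neurons,
                       mouse_id = sprintf("m%02d", m),
                       seed = derive_seed(seed, 1000 + m))
      })
      list(trials = do.call(rbind, lapply(per, `[[`, "trials")),
           spikes = do.call(c, lapply(per, `[[`, "spikes")))
    })
    trials <- sim$trials
    spikes <- sim$spikes
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_spikes(spikes, file.path(out_dir, "spikes.csv"))
  }

  # --- behavior --------------------------------------------------------
  results$behavior_fits <- stage("behavior", {
    do.call(rbind, lapply(unique(trials$mouse_id), function(m) {
      f <- fit_choice_model(trials[trials$mouse_id == m, ], "extended1")
      data.frame(mouse_id = m, term = names(coef(f)),
                 estimate = unname(coef(f)),
                 ci_lo = f$ci95[, "lo"], ci_hi = f$ci95[, "hi"],
                 row.names = NULL)
    }))
  })
  cv_rep <- (config$behavior$cv_repeats %||% 10L)
  results$model_comparison <- stage("behavior", {
    do.call(rbind, lapply(unique(trials$mouse_id), function(m) {
      cmp <- compare_models_cv(trials[trials$mouse_id == m, ],
                               "simple_vs_ext1", n_repeats = cv_rep,
                               seed = derive_seed(seed, 2000))
      cbind(mouse_id = m, cmp$per_session, p_value = cmp$p_value)
    }))
  })

  # --- preference ------------------------------------------------------
  n_perm <- config$preference$n_perm %||% 500L
  results$preference <- stage("preference", {
    do.call(rbind, lapply(seq_along(spikes), function(i) {
      sp <- spikes[[i]]
      tr <- trials[trials$session_id == sp$session_id, ]
      do.call(rbind, lapply(0:2, function(l) {
        unit_preference(sp, tr, "choice", l, n_perm = n_perm,
                        seed = derive_seed(seed, 3000 + 10 * i + l))
      }))
    }))
  })

  # --- sliding regression on lag-1 selective units ---------------------
  pref1 <- results$preference
  sel <- pref1$lag == 1 & pref1$included %in% TRUE &
    !is.na(pref1$p_value) & pref1$p_value < 0.05
  sel_units <- pref1$unit_id[sel]
  results$sliding <- stage("sliding", {
    fits <- lapply(sel_units, function(u) {
      sp <- spikes[[match(u, vapply(spikes, `[[`, "", "unit_id"))]]
      tr <- trials[trials$session_id == sp$session_id, ]
      fit_sliding(bin_rates(sp, tr, "valve_open"),
                  code_regressors(tr, sp$recorded_side))
    })
    if (length(fits) == 0) NULL else {
      pt <- population_timecourse(fits)
      data.frame(time_s = pt$bin_centers,
                 mean_choice_prev = pt$mean[, "x_choice_prev"],
                 frac_sig_choice_prev =
                   pt$fraction_significant[, "x_choice_prev"],
                 frac_sig_choice_cur =
                   pt$fraction_significant[, "x_choice_cur"],
                 n_units = pt$n_units)
    }
  })

  # --- choice linkage --------------------------------------------------
  results$link <- stage("link", {
    rows <- lapply(seq_along(sel_units), function(i) {
      u <- sel_units[i]
      sp <- spikes[[match(u, vapply(spikes, `[[`, "", "unit_id"))]]
      tr <- trials[trials$session_id == sp$session_id, ]
      prefv <- pref1$preference[pref1$unit_id == u & pref1$lag == 1]
      side <- if (prefv >= 0) {
        if (sp$recorded_side == "left") "right" else "left"
      } else sp$recorded_side
      pairs <- link_trials(sp, tr, side)
      st <- slope_test(pairs, n_perm = config$link$n_perm %||% 500L,
                       seed = derive_seed(seed, 4000 + i))
      data.frame(unit_id = u, mouse_id = sp$mouse_id, slope = st$slope,
                 p_value = st$p_value, sign_class = st$sign_class,
                 n_trials = st$n_trials, stringsAsFactors = FALSE)
    })
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  })

  # --- inactivation ----------------------------------------------------
  inact <- config$inactivation %||% list()
  if (isTRUE(inact$enabled %||% FALSE)) {
    results$inactivation <- stage("inactivation", {
      n_sets <- inact$n_sets %||% 2L
      bp <- call_known(behavior_params, config$behavior %||% list())
      sets <- lapply(seq_len(n_sets), function(k) {
        simulate_inactivation_set(task, bp,
                                  delta_bias = inact$delta_bias %||% 0.8,
                                  choice1_scale = inact$choice1_scale %||% 0.5,
                                  n_trials = inact$n_trials %||% 300L,
                                  set_id = sprintf("set%02d", k),
                                  seed = derive_seed(seed, 5000 + k))$trials
      })
      data.frame(set = seq_len(n_sets),
                 beta_muscimol = vapply(sets, function(tr) {
                   unname(coef(fit_inactivation(tr))["x_muscimol"])
                 }, numeric(1)))
    })
  }

  # --- write + log -----------------------------------------------------
  for (nm in names(results)) {
    if (!is.null(results[[nm]])) {
      write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  log <- list(package = "trialhist",
              version = as.character(packageVersion("trialhist")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = seed, config = unclass(config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic cohort), `behavior fit`,
#' `behavior compare`, `behavior inactivation`, `preference`, `sliding`,
#' `link`, and `run` (full pipeline from a config file). Invoke via
#' `Rscript -e 'trialhist::run_cli()' <subcommand> ...` or the installed
#' script `inst/cli/trialhist`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trialhist <command> [options]",
    "commands: simulate | behavior | preference | sliding | link | run",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--trials", type = "character", default = NULL),
    optparse::make_option("--spikes", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--model", type = "character",
                          default = "extended1"),
    optparse::make_option("--pair", type = "character",
                          default = "simple_vs_ext1"),
    optparse::make_option("--variable", type = "character",
                          default = "choice"),
    optparse::make_option("--lag", type = "integer", default = 1L),
    optparse::make_option("--align", type = "character",
                          default = "valve_open"),
    optparse::make_option("--n-perm", type = "integer", default = 1000L,
                          dest = "n_perm"),
    optparse::make_option("--repeats", type = "integer", default = 50L),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  sub <- if (cmd == "behavior" && length(rest) > 0 &&
             !startsWith(rest[1], "--")) {
    s <- rest[1]; rest <- rest[-1]; s
  } else NULL
  opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                               args = rest)
  if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
  need_trials <- function() {
    if (is.null(opts$trials)) stopf("--trials is required for '%s'", cmd)
    read_trials(opts$trials)
  }
  need_spikes <- function() {
    if (is.null(opts$spikes)) stopf("--spikes is required for '%s'", cmd)
    read_spikes(opts$spikes)
  }
  switch(cmd,
    simulate = {
      if (is.null(opts$config)) stopf("--config is required for 'simulate'")
      cfg <- read_run_config(opts$config)
      task <- call_known(task_config, cfg$task %||% list())
      bp <- call_known(behavior_params, cfg$behavior %||% list())
      cohort <- cfg$cohort %||% list()
      sim <- simulate_mouse(task, bp,
                            n_sessions = cohort$n_sessions %||% 3L,
                            neurons_per_session = list(),
                            seed = cfg$seed)
      write_trials(sim$trials, file.path(opts$out, "trials.csv"))
      message("wrote ", file.path(opts$out, "trials.csv"))
    },
    behavior = {
      trials <- need_trials()
      sub <- sub %||% "fit"
      if (sub == "fit") {
        f <- fit_choice_model(trials, opts$model)
        out <- data.frame(term = names(coef(f)), estimate = unname(coef(f)),
                          ci_lo = f$ci95[, "lo"], ci_hi = f$ci95[, "hi"],
                          row.names = NULL)
        write.csv(out, file.path(opts$out, "behavior_fit.csv"),
                  row.names = FALSE)
      } else if (sub == "compare") {
        cmp <- compare_models_cv(trials, opts$pair,
                                 n_repeats = opts$repeats, seed = opts$seed)
        out <- cbind(cmp$per_session, p_value = cmp$p_value)
        write.csv(out, file.path(opts$out, "model_comparison.csv"),
                  row.names = FALSE)
      } else if (sub == "inactivation") {
        f <- fit_inactivation(trials)
        out <- data.frame(term = names(coef(f)), estimate = unname(coef(f)),
                          ci_lo = f$ci95[, "lo"], ci_hi = f$ci95[, "hi"],
                          row.names = NULL)
        write.csv(out, file.path(opts$out, "inactivation_fit.csv"),
                  row.names = FALSE)
      } else stopf("unknown behavior subcommand '%s'", sub)
    },
    preference = {
      trials <- need_trials(); spikes <- need_spikes()
      out <- do.call(rbind, lapply(seq_along(spikes), function(i) {
        sp <- spikes[[i]]
        tr <- trials[trials$session_id == sp$session_id, ]
        unit_preference(sp, tr, opts$variable, opts$lag,
                        n_perm = opts$n_perm,
                        seed = derive_seed(opts$seed, i))
      }))
      write.csv(out, file.path(opts$out, "preference.csv"),
                row.names = FALSE)
    },
    sliding = {
      trials <- need_trials(); spikes <- need_spikes()
      fits <- lapply(spikes, function(sp) {
        tr <- trials[trials$session_id == sp$session_id, ]
        fit_sliding(bin_rates(sp, tr, opts$align),
                    code_regressors(tr, sp$recorded_side))
      })
      pt <- population_timecourse(fits)
      out <- data.frame(time_s = pt$bin_centers, pt$fraction_significant)
      write.csv(out, file.path(opts$out, "sliding_fraction_significant.csv"),
                row.names = FALSE)
    },
    link = {
      trials <- need_trials(); spikes <- need_spikes()
      rows <- lapply(seq_along(spikes), function(i) {
        sp <- spikes[[i]]
        tr <- trials[trials$session_id == sp$session_id, ]
        pr <- unit_preference(sp, tr, "choice", 1L, n_perm = opts$n_perm,
                              seed = derive_seed(opts$seed, i))
        if (!isTRUE(pr$included) || is.na(pr$p_value) || pr$p_value >= 0.05)
          return(NULL)
        side <- if (pr$preference >= 0) {
          if (sp$recorded_side == "left") "right" else "left"
        } else sp$recorded_side
        st <- slope_test(link_trials(sp, tr, side), n_perm = opts$n_perm,
                         seed = derive_seed(opts$seed, 10000 + i))
        data.frame(unit_id = sp$unit_id, mouse_id = sp$mouse_id,
                   slope = st$slope, p_value = st$p_value,
                   sign_class = st$sign_class, n_trials = st$n_trials)
      })
      out <- do.call(rbind, rows)
      write.csv(out, file.path(opts$out, "link.csv"), row.names = FALSE)
    },
    run = {
      if (is.null(opts$config)) stopf("--config is required for 'run'")
      run_pipeline(opts$config, output_dir = opts$out)
    },
    { message(usage); return(invisible(1L)) }
  )
  invisible(0L)
}
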