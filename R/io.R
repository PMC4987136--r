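#' Read and write trial tables as delimited text
#'
#' The interchange format is a comma-separated file with a header row.
#' Required columns: `session_id`, `mouse_id`, `trial_index`, the six
#' event times in seconds from session start (`odor_port_entry`,
#' `valve_open`, `go`, `odor_port_exit`, `reward_port_entry`,
#' `reward_port_exit`; missing events written as `NA`),
#' `odor_left_fraction`, `choice` (`L`, `R` or `none`), `rewarded`
#' (`0`, `1` or `none`), `condition` (`baseline`, `saline`,
#' `muscimol`). Internally choices are held as `left`/`right`/`none`.
#' `read_trials(write_trials(x))` is the identity on valid tables.
#'
#' @param path file path.
#' @return `read_trials`: a validated trial table.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("session_id", "mouse_id", "trial_index", event_cols(),
                "odor_left_fraction", "choice", "rewarded", "condition")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stopf("trials file missing column(s): %s", paste(miss, collapse = ", "))
  }
  bad <- which(!df$choice %in% c("L", "R", "none"))
  if (length(bad) > 0) {
    stopf("row %d, column 'choice': value '%s' invalid; accepted tokens: L, R, none",
          bad[1], df$choice[bad[1]])
  }
  df$choice <- c(L = "left", R = "right", none = "none")[df$choice]
  if (is.character(df$rewarded)) {
    ok <- df$rewarded %in% c("0", "1", "none")
    if (!all(ok)) {
      stopf("row %d, column 'rewarded': value '%s' invalid; accepted tokens: 0, 1, none",
            which(!ok)[1], df$rewarded[which(!ok)[1]])
    }
    rw <- rep(NA_integer_, nrow(df))
    sel <- df$rewarded != "none"
    rw[sel] <- as.integer(df$rewarded[sel])
    df$rewarded <- rw
  } else {
    df$rewarded <- as.integer(df$rewarded)
  }
  names(df$choice) <- NULL
  for (s in unique(df$session_id)) {
    rows <- which(df$session_id == s)
    ev <- as.matrix(df[rows, event_cols()])
    for (i in seq_along(rows)) {
      tt <- ev[i, !is.na(ev[i, ])]
      if (is.unsorted(tt, strictly = TRUE)) {
        stopf("row %d: event times not strictly increasing", rows[i])
      }
    }
    if (is.unsorted(df$odor_port_entry[rows])) {
      stopf("session '%s': trials not time-ordered", s)
    }
  }
  df[, required]
}

#' @rdname read_trials
#' @param trials a trial table.
#' @return `write_trials`: `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  assert_choice_values(trials$choice)
  out <- trials
  out$choice <- c(left = "L", right = "R", none = "none")[out$choice]
  out$rewarded <- ifelse(is.na(out$rewarded), "none",
                         as.character(out$rewarded))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write spike trains as delimited text
#'
#' One comma-separated file holds all units: columns `unit_id`,
#' `mouse_id`, `session_id`, `recorded_side`, `spike_time_s`. Units are
#' keyed stably by their first appearance; spike times are sorted on
#' load. A unit listed in an accompanying metadata row with no spikes
#' yields an empty train. Round-trips are lossless.
#'
#' @param path file path.
#' @return `read_spikes`: named list of `spike_train` objects.
#' @export
read_spikes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("unit_id", "mouse_id", "session_id", "recorded_side",
                "spike_time_s")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stopf("spikes file missing column(s): %s", paste(miss, collapse = ", "))
  }
  has_spike <- !is.na(df$spike_time_s)
  if (any(df$spike_time_s[has_spike] < 0)) {
    stopf("row %d: negative spike time",
          which(has_spike & df$spike_time_s < 0)[1])
  }
  ids <- unique(df$unit_id)
  out <- lapply(ids, function(u) {
    sub <- df[df$unit_id == u, ]
    spike_train(unit_id = u, mouse_id = sub$mouse_id[1],
                session_id = sub$session_id[1],
                recorded_side = sub$recorded_side[1],
                spike_times = sub$spike_time_s[!is.na(sub$spike_time_s)])
  })
  names(out) <- ids
  out
}

#' @rdname read_spikes
#' @param spikes list of `spike_train` objects (or a single one).
#' @return `write_spikes`: `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  rows <- lapply(spikes, function(s) {
    if (length(s$spike_times) == 0) {
      data.frame(unit_id = s$unit_id, mouse_id = s$mouse_id,
                 session_id = s$session_id, recorded_side = s$recorded_side,
                 spike_time_s = NA_real_)
    } else {
      data.frame(unit_id = s$unit_id, mouse_id = s$mouse_id,
                 session_id = s$session_id, recorded_side = s$recorded_side,
                 spike_time_s = s$spike_times)
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are JSON. Every stochastic stage must carry an
#' explicit seed (a top-level `seed` is required); unknown top-level
#' keys are rejected so typos cannot silently disable a stage.
#'
#' @param path JSON file path.
#' @return validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "output_dir", "trials_file", "spikes_file",
             "cohort", "task", "behavior", "neurons", "preference",
             "sliding", "link", "inactivation", "verbosity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stopf("config must set an explicit 'seed'")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
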