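# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw from a normal truncated below at `floor` by resampling; used for
# event delays, which are strictly positive in the apparatus.
rtnorm_floor <- function(n, mean, sd, floor = 0.01) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
    guard <- guard + 1L
    if (guard > 1000L) {
      x[bad] <- floor
      break
    }
  }
  x
}

# Deterministic sub-seed derivation so composite simulators can hand
# independent streams to their parts while staying reproducible from a
# single user-facing seed. Keeps results in [1, 2^31 - 2].
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 7919
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# call fn with only the arguments it knows; config blocks may carry
# extra stage parameters (e.g. cv_repeats) alongside constructor fields
call_known <- function(fn, args) {
  do.call(fn, args[intersect(names(args), names(formals(fn)))])
}
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# number of spikes (sorted vector `st`) in half-open interval [a, b)
count_in <- function(st, a, b) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  length(st) - length(st[st < a]) - length(st[st >= b])
}

assert_choice_values <- function(x) {
  ok <- x %in% c("left", "right", "none")
  if (!all(ok)) {
    stopf("invalid choice value(s) %s; accepted tokens: left, right, none",
          paste(unique(x[!ok]), collapse = ", "))
  }
  invisible(x)
}
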