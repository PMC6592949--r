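# Internal validators and small numeric helpers shared across modules.

abort_param <- function(msg) rlang::abort(msg, class = "breathephys_param_error")
abort_data <- function(msg) rlang::abort(msg, class = "breathephys_data_error")

#' @noRd
check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_param(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# A trace is a data frame with numeric `time` (seconds, uniformly increasing)
# and `value` columns. Returns the sampling interval.
check_trace <- function(trace, name = "trace") {
  if (!is.data.frame(trace) || !all(c("time", "value") %in% names(trace))) {
    abort_data(sprintf("`%s` must be a data frame with `time` and `value` columns.", name))
  }
  if (nrow(trace) < 2L) abort_data(sprintf("`%s` must contain at least 2 samples.", name))
  dt <- trace$time[2L] - trace$time[1L]
  if (!is.finite(dt) || dt <= 0) {
    abort_data(sprintf("`%s` must have strictly increasing time stamps.", name))
  }
  dt
}

check_finite_values <- function(values, what = "signal") {
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    abort_data(sprintf("Non-finite %s value at frame %d.", what, bad[1L]))
  }
  invisible(values)
}

# Centered moving average with truncated windows at the edges: the mean is
# taken over the frames actually available within half-width h of each frame.
moving_average_centered <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Window = c(start, end) in the units of `t`; inclusive on both ends.
check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window)) ||
      window[2L] <= window[1L]) {
    abort_param(sprintf("`%s` must be c(start, end) with end > start.", name))
  }
  invisible(window)
}

in_window <- function(t, window) t >= window[1L] & t <= window[2L]

# Seeded evaluation that never touches the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_scalar_num(seed, "seed")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

odd_at_least <- function(k, minimum = 1L) {
  k <- max(as.integer(round(k)), minimum)
  if (k %% 2L == 0L) k + 1L else k
}
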