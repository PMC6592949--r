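#' Trinarize a plethysmography trace by double thresholding
#'
#' Converts a raw breathing signal \eqn{s(t)} into a trinary code series
#' \eqn{b(t)}: `+1` where the signal exceeds `upper`, `-1` where it falls below
#' `lower`, and `0` inside the closed band `[lower, upper]`. Positive codes mark
#' the inspiration phase of a breathing cycle, negative codes the expiration
#' phase. The inequalities are strict, so samples exactly at a threshold map
#' to 0.
#'
#' The asymmetric defaults (+0.15 / -0.4 signal units) reflect the asymmetry of
#' whole-body plethysmography deflections; both are instrument-dependent and
#' should be set to match the recording chain.
#'
#' @param trace Data frame with numeric `time` (s) and `value` columns,
#'   uniformly sampled.
#' @param upper Upper threshold (signal units); values strictly above map to +1.
#' @param lower Lower threshold (signal units); values strictly below map to -1.
#' @return A tibble with columns `time` and `code` (integer in \{-1, 0, +1\}),
#'   one row per input frame.
#' @seealso [smooth_retrinarize()], [detect_cycles()]
#' @examples
#' tr <- tibble::tibble(time = (0:2) / 100, value = c(0.2, 0, -0.5))
#' trinarize(tr)$code # 1 0 -1
#' @export
trinarize <- function(trace, upper = 0.15, lower = -0.4) {
  check_trace(trace)
  check_scalar_num(upper, "upper")
  check_scalar_num(lower, "lower")
  if (lower >= upper) abort_param("`lower` must be strictly below `upper`.")
  check_finite_values(trace$value)
  code <- integer(nrow(trace))
  code[trace$value > upper] <- 1L
  code[trace$value < lower] <- -1L
  tibble(time = trace$time, code = code)
}

#' Smooth a trinary series and re-trinarize
#'
#' Applies a centered moving average of `window` frames to the trinary codes,
#' then maps strictly positive means to +1, strictly negative means to -1 and
#' zero means to 0. Smoothing suppresses local threshold flicker so that each
#' breathing phase becomes one contiguous run of a single code. Edge frames use
#' a truncated window (mean over the frames actually available).
#'
#' Means within `zero_tol` of zero are treated as exact zeros so that balanced
#' windows are not classified by floating-point residue.
#'
#' @param trin A tibble as returned by [trinarize()] (`time`, `code`).
#' @param window Moving-average width in frames; odd, default 25.
#' @param zero_tol Magnitude below which a window mean counts as zero.
#' @return A tibble with columns `time` and `code`, same length as the input.
#' @export
smooth_retrinarize <- function(trin, window = 25L, zero_tol = 1e-12) {
  if (!is.data.frame(trin) || !all(c("time", "code") %in% names(trin))) {
    abort_data("`trin` must be a data frame with `time` and `code` columns.")
  }
  if (!all(trin$code %in% c(-1L, 0L, 1L))) {
    abort_data("`trin$code` must only contain -1, 0, +1.")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    abort_param("`window` must be a positive odd integer.")
  }
  if (nrow(trin) <= window) {
    abort_data(sprintf("Series of %d frames is not longer than the %d-frame window.",
                       nrow(trin), window))
  }
  m <- moving_average_centered(as.numeric(trin$code), window)
  code <- integer(length(m))
  code[m > zero_tol] <- 1L
  code[m < -zero_tol] <- -1L
  tibble(time = trin$time, code = code)
}

#' Detect breathing-cycle onsets from a trinary series
#'
#' A positive cycle starts at the first frame of each maximal run of
#' consecutive `+1` codes; negative cycles start analogously at maximal `-1`
#' runs. A run touching the first frame of the series counts, with its onset at
#' frame 1 (frame indices are 1-based).
#'
#' @param trin A tibble with `time` and `code` columns (codes in \{-1,0,+1\}).
#' @return A tibble with one row per cycle onset: `onset` (frame index,
#'   1-based), `time` (s), `polarity` (`"positive"` or `"negative"`), ordered
#'   by onset.
#' @export
detect_cycles <- function(trin) {
  if (!is.data.frame(trin) || !all(c("time", "code") %in% names(trin))) {
    abort_data("`trin` must be a data frame with `time` and `code` columns.")
  }
  if (!all(trin$code %in% c(-1L, 0L, 1L))) {
    abort_data("`trin$code` must only contain -1, 0, +1.")
  }
  r <- rle(as.integer(trin$code))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != 0L
  if (!any(keep)) {
    return(tibble(onset = integer(), time = numeric(), polarity = character()))
  }
  tibble(
    onset = starts[keep],
    time = trin$time[starts[keep]],
    polarity = ifelse(r$values[keep] > 0L, "positive", "negative")
  )
}

#' Compute inter-breathing-cycle intervals (ICI)
#'
#' The ICI is the interval between onsets of consecutive positive cycles that
#' have at least one negative-cycle onset strictly between them; positive
#' pairs without an intervening negative cycle are skipped (they reflect
#' threshold flicker, not a completed breath). Setting `basis = "negative"`
#' computes the mirrored quantity on negative onsets.
#'
#' @param cycles A tibble from [detect_cycles()].
#' @param sampling_interval Seconds per frame; used when `cycles` lacks usable
#'   times (otherwise intervals are taken from onset frame differences times
#'   this value).
#' @param basis `"positive"` (default) or `"negative"`: which cycle polarity
#'   anchors the interval.
#' @return A tibble with one row per qualifying pair: `interval` (s), plus
#'   `onset_from`, `onset_to` (frame indices).
#' @export
compute_ici <- function(cycles, sampling_interval, basis = c("positive", "negative")) {
  basis <- match.arg(basis)
  check_scalar_num(sampling_interval, "sampling_interval", positive = TRUE)
  if (!is.data.frame(cycles) || !all(c("onset", "polarity") %in% names(cycles))) {
    abort_data("`cycles` must be a data frame with `onset` and `polarity` columns.")
  }
  other <- if (basis == "positive") "negative" else "positive"
  anchors <- sort(cycles$onset[cycles$polarity == basis])
  between <- sort(cycles$onset[cycles$polarity == other])
  if (length(anchors) < 2L) {
    return(tibble(interval = numeric(), onset_from = integer(), onset_to = integer()))
  }
  from <- anchors[-length(anchors)]
  to <- anchors[-1L]
  # number of opposite-polarity onsets strictly inside each (from, to) pair
  n_inside <- findInterval(to - 1L, between) - findInterval(from, between)
  keep <- n_inside >= 1L
  tibble(
    interval = (to[keep] - from[keep]) * sampling_interval,
    onset_from = as.integer(from[keep]),
    onset_to = as.integer(to[keep])
  )
}

#' Empirical cumulative distribution of ICIs
#'
#' Returns the right-continuous empirical CDF of an interval sample as a step
#' table: one row per distinct interval value with the cumulative probability
#' at that value. The final cumulative probability is always 1.
#'
#' @param ici A data frame with an `interval` column (s), e.g. from
#'   [compute_ici()] or [breath_ici()].
#' @return A tibble with columns `interval` (sorted, distinct) and `cum_prob`.
#' @export
ici_cdf <- function(ici) {
  if (!is.data.frame(ici) || !"interval" %in% names(ici)) {
    abort_data("`ici` must be a data frame with an `interval` column.")
  }
  x <- ici$interval
  if (length(x) == 0L) abort_data("Empty interval sample: cannot compute a CDF.")
  check_finite_values(x, "interval")
  tab <- sort(unique(x))
  tibble(interval = tab,
         cum_prob = vapply(tab, function(v) mean(x <= v), numeric(1)))
}

#' Run the full breathing pipeline on one trace
#'
#' Convenience chain: [trinarize()] with thresholds `upper`/`lower`, a
#' 25-frame (default) [smooth_retrinarize()], [detect_cycles()] and
#' [compute_ici()]. Optionally restricts the analysis to a time window before
#' processing.
#'
#' @inheritParams trinarize
#' @inheritParams smooth_retrinarize
#' @inheritParams compute_ici
#' @param window_s Optional c(start, end) analysis window in seconds.
#' @param smooth_window Moving-average width in frames.
#' @return A tibble of intervals as from [compute_ici()], with any `animal`
#'   and `group` values carried over from attributes or columns of `trace`.
#' @export
breath_ici <- function(trace, upper = 0.15, lower = -0.4, smooth_window = 25L,
                       basis = c("positive", "negative"), window_s = NULL) {
  basis <- match.arg(basis)
  dt <- check_trace(trace)
  if (!is.null(window_s)) {
    check_window(window_s, "window_s")
    trace <- trace[in_window(trace$time, window_s), , drop = FALSE]
    if (nrow(trace) < 2L) abort_data("Analysis window contains fewer than 2 samples.")
  }
  out <- trace %>%
    trinarize(upper = upper, lower = lower) %>%
    smooth_retrinarize(window = smooth_window) %>%
    detect_cycles() %>%
    compute_ici(sampling_interval = dt, basis = basis)
  for (col in c("animal", "group")) {
    if (col %in% names(trace)) out[[col]] <- trace[[col]][1L]
  }
  out
}
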