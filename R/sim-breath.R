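# Synthetic plethysmography: breathing traces with exact planted ground truth.
#
# Each breathing cycle is rendered as one positive half-sine (inspiration)
# followed, after a short gap, by one negative half-sine (expiration). The
# waveform is built on the sampling grid so that, at zero noise, the frame at
# which the trinarize -> smooth -> detect chain fires is known analytically:
# the raw +1 run starts o - 1 frames after the planted cycle start (o = first
# template frame above the upper threshold) and the centered moving average
# extends that run back by (window - 1) / 2 frames. The returned ground truth
# stores exactly those onsets, so zero-noise recovery is exact by construction.

breath_template <- function(amp, dur, sampling_rate) {
  L <- max(3L, round(dur * sampling_rate))
  amp * sin(pi * (seq_len(L) - 0.5) / L)
}

#' Simulate one breathing trace from explicit cycle intervals
#'
#' Builds a plethysmography-like trace whose cycle onsets are separated by
#' `intervals` (rounded to the sampling grid), plus Gaussian noise. The
#' returned ground truth holds the onset frame that the default analysis
#' pipeline detects at zero noise and the planted inter-cycle intervals
#' (frame-quantized, so zero-noise recovery is exact).
#'
#' @param intervals Intervals between consecutive cycle onsets, seconds; all
#'   must exceed the feasibility floor (cycle footprint plus two smoothing
#'   windows) so cycles never overlap the smoothing kernel.
#' @param sampling_rate Hz (default 1000).
#' @param pos_amp,pos_dur Amplitude (signal units) and duration (s) of the
#'   positive half-sine; `pos_amp` must exceed `upper`.
#' @param neg_amp,neg_dur Amplitude (negative) and duration of the negative
#'   half-sine; `neg_amp` must fall below `lower`.
#' @param gap Silence between the positive and negative phase, seconds.
#' @param noise_sd Additive Gaussian noise SD, signal units.
#' @param upper,lower Thresholds the downstream analysis will use; needed to
#'   compute the ground-truth onsets.
#' @param smooth_window Smoothing window (frames) of the downstream analysis.
#' @param start_time Time of the first cycle start, seconds.
#' @param pad Trailing silence, seconds.
#' @param seed Optional integer seed (only noise is random).
#' @return List with `trace` (tibble `time`, `value`), `onsets` (tibble
#'   `cycle`, `frame`, `time`: ground-truth detected positive onsets), and
#'   `ici` (tibble `interval`: planted inter-breathing-cycle intervals).
#' @export
sim_breath_trace <- function(intervals, sampling_rate = 1000,
                             pos_amp = 1, pos_dur = 0.05,
                             neg_amp = -1, neg_dur = 0.05, gap = 0.02,
                             noise_sd = 0, upper = 0.15, lower = -0.4,
                             smooth_window = 25L, start_time = 0.3, pad = 0.3,
                             seed = NULL) {
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar_num(pos_dur, "pos_dur", positive = TRUE)
  check_scalar_num(neg_dur, "neg_dur", positive = TRUE)
  if (pos_amp <= upper) abort_param("`pos_amp` must exceed `upper` or no cycle is detectable.")
  if (neg_amp >= lower) abort_param("`neg_amp` must fall below `lower`.")
  if (noise_sd < 0) abort_param("`noise_sd` must be >= 0.")
  fs <- sampling_rate
  floor_s <- breath_ici_floor(pos_dur, neg_dur, gap, smooth_window, fs)
  if (length(intervals) > 0L) {
    check_finite_values(intervals, "interval")
    if (any(intervals < floor_s)) {
      abort_param(sprintf("All intervals must be >= the feasibility floor %.3f s.", floor_s))
    }
  }
  tpl_pos <- breath_template(pos_amp, pos_dur, fs)
  tpl_neg <- breath_template(neg_amp, neg_dur, fs)
  gap_f <- round(gap * fs)
  footprint <- length(tpl_pos) + gap_f + length(tpl_neg)
  h <- (as.integer(smooth_window) - 1L) %/% 2L
  o_pos <- which(tpl_pos > upper)[1L]

  starts <- round(start_time * fs) + 1L + cumsum(c(0L, round(intervals * fs)))
  n <- starts[length(starts)] + footprint + round(pad * fs)
  value <- numeric(n)
  for (k in starts) {
    value[k:(k + length(tpl_pos) - 1L)] <- tpl_pos
    ns <- k + length(tpl_pos) + gap_f
    value[ns:(ns + length(tpl_neg) - 1L)] <- tpl_neg
  }
  with_seed(seed, {
    if (noise_sd > 0) value <- value + rnorm(n, 0, noise_sd)
  })
  gt_frames <- starts + (o_pos - 1L) - h
  list(
    trace = tibble(time = (seq_len(n) - 1L) / fs, value = value),
    onsets = tibble(cycle = seq_along(starts), frame = as.integer(gt_frames),
                    time = (gt_frames - 1L) / fs),
    ici = tibble(interval = diff(gt_frames) / fs)
  )
}

breath_ici_floor <- function(pos_dur, neg_dur, gap, smooth_window, sampling_rate) {
  pos_dur + neg_dur + gap + (2L * as.integer(smooth_window) + 5L) / sampling_rate
}

#' Simulate a cohort of breathing traces with group-dependent ICI distributions
#'
#' Each animal's inter-cycle intervals are drawn from a log-normal distribution
#' whose median is set per experimental group (right-skewed, strictly positive,
#' like real inter-breath intervals), truncated below the waveform feasibility
#' floor, until the requested duration is filled. Ground truth (detected-onset
#' frames and planted ICIs) is returned per animal so downstream recovery can
#' be checked without re-deriving it.
#'
#' @param n_per_group Animals per group.
#' @param group_medians Named numeric vector: median ICI (s) per group.
#' @param ici_sdlog Log-scale SD of the ICI distribution (shared).
#' @param duration Trace duration per animal, seconds.
#' @inheritParams sim_breath_trace
#' @param seed Integer seed governing all randomness of the cohort.
#' @return An object of class `breath_cohort`: list with `traces` (named list
#'   of tibbles), `animals` (tibble `animal`, `group`), `onsets` and `ici`
#'   (ground-truth tibbles with `animal`, `group` columns), and `params`.
#' @export
sim_breath_cohort <- function(n_per_group = 8,
                              group_medians = c(wt = 0.3, mut = 0.45),
                              ici_sdlog = 0.35,
                              duration = 60, sampling_rate = 1000,
                              pos_amp = 1, pos_dur = 0.05,
                              neg_amp = -1, neg_dur = 0.05, gap = 0.02,
                              noise_sd = 0, upper = 0.15, lower = -0.4,
                              smooth_window = 25L, seed = NULL) {
  check_scalar_num(n_per_group, "n_per_group", positive = TRUE)
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(names(group_medians)) || any(!nzchar(names(group_medians)))) {
    abort_param("`group_medians` must be a named vector (one median per group).")
  }
  if (any(group_medians <= 0) || ici_sdlog <= 0) {
    abort_param("ICI distribution parameters must be strictly positive.")
  }
  floor_s <- breath_ici_floor(pos_dur, neg_dur, gap, smooth_window, sampling_rate)
  overhead <- 0.3 + pos_dur + gap + neg_dur + 0.3

  with_seed(seed, {
    traces <- list()
    animals <- list()
    onsets <- list()
    icis <- list()
    for (g in names(group_medians)) {
      meanlog <- log(group_medians[[g]])
      for (i in seq_len(n_per_group)) {
        id <- sprintf("%s_%02d", g, i)
        ivs <- numeric(0)
        total <- overhead
        repeat {
          x <- rlnorm(1, meanlog, ici_sdlog)
          if (x < floor_s) next # truncated below the feasibility floor
          if (total + x > duration) break
          ivs <- c(ivs, x)
          total <- total + x
        }
        sim <- sim_breath_trace(
          intervals = ivs, sampling_rate = sampling_rate,
          pos_amp = pos_amp, pos_dur = pos_dur, neg_amp = neg_amp,
          neg_dur = neg_dur, gap = gap, noise_sd = noise_sd,
          upper = upper, lower = lower, smooth_window = smooth_window
        )
        traces[[id]] <- sim$trace
        animals[[id]] <- tibble(animal = id, group = g)
        onsets[[id]] <- dplyr::mutate(sim$onsets, animal = id, group = g)
        icis[[id]] <- dplyr::mutate(sim$ici, animal = id, group = g)
      }
    }
    structure(
      list(
        traces = traces,
        animals = bind_rows(animals),
        onsets = bind_rows(onsets),
        ici = bind_rows(icis),
        params = list(
          n_per_group = n_per_group, group_medians = group_medians,
          ici_sdlog = ici_sdlog, duration = duration,
          sampling_rate = sampling_rate, noise_sd = noise_sd,
          upper = upper, lower = lower, smooth_window = smooth_window,
          seed = seed
        )
      ),
      class = "breath_cohort"
    )
  })
}

#' @export
print.breath_cohort <- function(x, ...) {
  cat(sprintf("<breath_cohort> %d animals in %d groups; %d ground-truth ICIs\n",
              nrow(x$animals), length(unique(x$animals$group)), nrow(x$ici)))
  invisible(x)
}

#' Run the breathing analysis over every trace of a cohort
#'
#' Applies [breath_ici()] (with the thresholds and window the cohort was built
#' for) to each animal's trace and returns the pooled long table of measured
#' intervals.
#'
#' @param cohort A `breath_cohort` from [sim_breath_cohort()].
#' @param ... Passed on to [breath_ici()] to override thresholds or window.
#' @return Tibble with columns `animal`, `group`, `interval`.
#' @export
cohort_ici <- function(cohort, ...) {
  if (!inherits(cohort, "breath_cohort")) abort_param("`cohort` must be a `breath_cohort`.")
  dots <- list(...)
  args <- list(upper = cohort$params$upper, lower = cohort$params$lower,
               smooth_window = cohort$params$smooth_window)
  args[names(dots)] <- dots
  purrr::map_dfr(cohort$animals$animal, function(id) {
    out <- do.call(breath_ici, c(list(trace = cohort$traces[[id]]), args))
    out$animal <- id
    out$group <- cohort$animals$group[cohort$animals$animal == id]
    out[, c("animal", "group", "interval")]
  })
}
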