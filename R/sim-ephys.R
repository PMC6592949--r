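# Synthetic electrophysiology: PSC trains, paired traces with controlled
# correlation, population bursts, and spike trains with a drug epoch.

# Biexponential PSC kernel normalized to unit peak.
psc_kernel <- function(rise, decay, sampling_rate) {
  if (rise <= 0 || decay <= 0) abort_param("Kernel time constants must be > 0.")
  if (rise >= decay) abort_param("`rise` must be shorter than `decay`.")
  dt <- 1 / sampling_rate
  t <- seq(0, rise + 8 * decay, by = dt)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Event amplitudes: gamma with the requested mean and SD (strictly positive,
# right-skewed like PSC amplitude distributions).
draw_amplitudes <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Greedy thinning: drop events closer than `min_sep` to the kept predecessor.
thin_events <- function(times, min_sep) {
  if (min_sep <= 0 || length(times) < 2L) return(seq_along(times))
  keep <- logical(length(times))
  keep[1L] <- TRUE
  last <- times[1L]
  for (i in 2L:length(times)) {
    if (times[i] - last >= min_sep) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  which(keep)
}

# Smooth plateau (raised-cosine edges) of `height` over [start, end] seconds.
add_plateau <- function(value, start, end, height, sampling_rate, edge_frac = 0.15) {
  n <- length(value)
  s <- max(1L, round(start * sampling_rate) + 1L)
  e <- min(n, round(end * sampling_rate))
  if (e <= s) return(value)
  len <- e - s + 1L
  ramp <- max(2L, round(edge_frac * len))
  prof <- rep(1, len)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  prof[seq_len(ramp)] <- up
  prof[(len - ramp + 1L):len] <- rev(up)
  value[s:e] <- value[s:e] + height * prof
  value
}

render_psc_trace <- function(event_times, amplitudes, bursts, duration,
                             sampling_rate, rise, decay, polarity, noise_sd) {
  n <- round(duration * sampling_rate)
  kern <- psc_kernel(rise, decay, sampling_rate)
  if (length(kern) > n) abort_param("PSC kernel is longer than the trace.")
  pol <- if (polarity == "negative") -1 else 1
  drive <- numeric(n)
  for (i in seq_along(event_times)) {
    k0 <- round(event_times[i] * sampling_rate) + 1L
    if (k0 > n) next
    k1 <- min(n, k0 + length(kern) - 1L)
    drive[k0:k1] <- drive[k0:k1] + amplitudes[i] * kern[seq_len(k1 - k0 + 1L)]
  }
  if (!is.null(bursts) && nrow(bursts) > 0L) {
    for (j in seq_len(nrow(bursts))) {
      drive <- add_plateau(drive, bursts$start[j], bursts$end[j],
                           bursts$elevation[j], sampling_rate)
    }
  }
  value <- pol * drive
  if (noise_sd > 0) value <- value + rnorm(n, 0, noise_sd)
  tibble(time = (seq_len(n) - 1L) / sampling_rate, value = value)
}

draw_bursts <- function(burst_rate, burst_events, burst_elevation,
                        burst_duration, duration) {
  n_b <- rpois(1, burst_rate * duration)
  if (n_b == 0L) {
    return(list(
      bursts = tibble(start = numeric(), end = numeric(),
                      n_events = integer(), elevation = numeric()),
      times = numeric(0)
    ))
  }
  starts <- sort(runif(n_b, 0.5, max(0.6, duration - burst_duration - 0.5)))
  # keep bursts apart by at least their own duration
  keep <- c(TRUE, diff(starts) > 2 * burst_duration)
  starts <- starts[keep]
  # events within a burst are kept >= 35 ms apart so each stays individually
  # resolvable: a threshold detector re-arms only after the previous event has
  # decayed below half threshold (~12 ms at the default kinetics) plus its
  # refractory time and a noise margin
  gap <- 0.035
  span <- 0.8 * burst_duration - (burst_events - 1) * gap
  if (span <= 0) abort_param("`burst_duration` too short for `burst_events` discriminable events.")
  times <- unlist(lapply(starts, function(s) {
    s + 0.1 * burst_duration + span * sort(runif(burst_events)) +
      gap * (seq_len(burst_events) - 1L)
  }))
  list(
    bursts = tibble(start = starts, end = starts + burst_duration,
                    n_events = as.integer(burst_events),
                    elevation = burst_elevation),
    times = times
  )
}

#' Simulate a pair of postsynaptic-current traces with controlled correlation
#'
#' Generates two voltage-clamp-like traces sharing a configurable fraction of
#' their synaptic events, emulating dual whole-cell recordings. Events arrive
#' as Poisson processes: a shared pool of rate `baseline_rate *
#' pair_correlation` drives both traces (with identical amplitudes), and each
#' trace receives an independent pool of rate `baseline_rate * (1 -
#' pair_correlation)`, so the expected shared-event fraction equals
#' `pair_correlation`. Optional population bursts (event clusters riding on a
#' baseline-elevation plateau) are synchronized across the pair. Events are
#' rendered by convolving impulse times with a biexponential kernel plus
#' Gaussian noise.
#'
#' @param duration Seconds (default 60).
#' @param sampling_rate Hz (default 5000).
#' @param baseline_rate Event rate per trace, Hz.
#' @param pair_correlation Fraction of events shared between the traces, in
#'   \[0, 1\].
#' @param amp_mean,amp_sd Event peak-amplitude distribution, pA.
#' @param rise,decay Kernel time constants, seconds.
#' @param polarity `"negative"` (inward, default) or `"positive"`.
#' @param burst_rate Population-burst rate, Hz (default 0: no bursts).
#' @param burst_events Events per burst.
#' @param burst_elevation Baseline elevation during a burst, pA.
#' @param burst_duration Burst duration, seconds.
#' @param noise_sd Gaussian noise SD, pA.
#' @param min_separation Minimum separation between consecutive events on a
#'   trace, seconds (default 0: none). Events closer than this to their
#'   predecessor are dropped, keeping every event resolvable by a
#'   threshold-crossing detector.
#' @param seed Optional integer seed.
#' @return An object of class `psc_pair`: list with `trace_a`, `trace_b`
#'   (tibbles `time`, `value`), `events_a`, `events_b` (tibbles `time`,
#'   `amplitude`, ground truth), `bursts` (tibble `start`, `end`, `n_events`,
#'   `elevation`), and `params`.
#' @export
sim_psc_pair <- function(duration = 60, sampling_rate = 5000,
                         baseline_rate = 2, pair_correlation = 0,
                         amp_mean = 30, amp_sd = 8,
                         rise = 0.001, decay = 0.005,
                         polarity = c("negative", "positive"),
                         burst_rate = 0, burst_events = 5L,
                         burst_elevation = 80, burst_duration = 0.4,
                         noise_sd = 2, min_separation = 0, seed = NULL) {
  polarity <- match.arg(polarity)
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (baseline_rate < 0 || burst_rate < 0) abort_param("Rates must be >= 0.")
  if (pair_correlation < 0 || pair_correlation > 1) {
    abort_param("`pair_correlation` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort_param("`noise_sd` must be >= 0.")
  with_seed(seed, {
    n_sh <- rpois(1, baseline_rate * pair_correlation * duration)
    t_sh <- sort(runif(n_sh, 0, duration))
    a_sh <- draw_amplitudes(n_sh, amp_mean, amp_sd)
    indep <- function() {
      m <- rpois(1, baseline_rate * (1 - pair_correlation) * duration)
      list(t = sort(runif(m, 0, duration)), a = draw_amplitudes(m, amp_mean, amp_sd))
    }
    ia <- indep(); ib <- indep()
    bl <- draw_bursts(burst_rate, burst_events, burst_elevation,
                      burst_duration, duration)
    amps_burst <- draw_amplitudes(length(bl$times), amp_mean, amp_sd)
    mk_events <- function(ind) {
      ord <- order(c(t_sh, ind$t, bl$times))
      ev <- tibble(time = c(t_sh, ind$t, bl$times)[ord],
                   amplitude = c(a_sh, ind$a, amps_burst)[ord])
      ev[thin_events(ev$time, min_separation), ]
    }
    ev_a <- mk_events(ia)
    ev_b <- mk_events(ib)
    tr_a <- render_psc_trace(ev_a$time, ev_a$amplitude, bl$bursts, duration,
                             sampling_rate, rise, decay, polarity, noise_sd)
    tr_b <- render_psc_trace(ev_b$time, ev_b$amplitude, bl$bursts, duration,
                             sampling_rate, rise, decay, polarity, noise_sd)
    structure(
      list(trace_a = tr_a, trace_b = tr_b, events_a = ev_a, events_b = ev_b,
           bursts = bl$bursts,
           params = list(duration = duration, sampling_rate = sampling_rate,
                         baseline_rate = baseline_rate,
                         pair_correlation = pair_correlation,
                         amp_mean = amp_mean, amp_sd = amp_sd,
                         rise = rise, decay = decay, polarity = polarity,
                         burst_rate = burst_rate, burst_events = burst_events,
                         burst_elevation = burst_elevation,
                         burst_duration = burst_duration,
                         noise_sd = noise_sd, seed = seed)),
      class = "psc_pair"
    )
  })
}

#' Simulate a single postsynaptic-current trace
#'
#' Single-trace counterpart of [sim_psc_pair()]: one Poisson event train,
#' optional population bursts, biexponential kernel rendering plus noise.
#'
#' @inheritParams sim_psc_pair
#' @param rate Event rate, Hz.
#' @return List with `trace` (tibble), `events` (tibble `time`, `amplitude`),
#'   and `bursts`.
#' @export
sim_psc_train <- function(duration = 60, sampling_rate = 5000, rate = 2,
                          amp_mean = 30, amp_sd = 8,
                          rise = 0.001, decay = 0.005,
                          polarity = c("negative", "positive"),
                          burst_rate = 0, burst_events = 5L,
                          burst_elevation = 80, burst_duration = 0.4,
                          noise_sd = 2, min_separation = 0, seed = NULL) {
  polarity <- match.arg(polarity)
  if (rate < 0 || burst_rate < 0) abort_param("Rates must be >= 0.")
  check_scalar_num(duration, "duration", positive = TRUE)
  with_seed(seed, {
    m <- rpois(1, rate * duration)
    t_ev <- sort(runif(m, 0, duration))
    a_ev <- draw_amplitudes(m, amp_mean, amp_sd)
    bl <- draw_bursts(burst_rate, burst_events, burst_elevation,
                      burst_duration, duration)
    a_b <- draw_amplitudes(length(bl$times), amp_mean, amp_sd)
    ord <- order(c(t_ev, bl$times))
    events <- tibble(time = c(t_ev, bl$times)[ord],
                     amplitude = c(a_ev, a_b)[ord])
    events <- events[thin_events(events$time, min_separation), ]
    trace <- render_psc_trace(events$time, events$amplitude, bl$bursts,
                              duration, sampling_rate, rise, decay, polarity,
                              noise_sd)
    list(trace = trace, events = events, bursts = bl$bursts)
  })
}

#' Simulate a spike train with a drug-response epoch
#'
#' Piecewise-homogeneous Poisson spike times: the baseline rate is multiplied
#' by `drug_multiplier` inside `drug_window` (values < 1 emulate an inhibitory
#' agonist response, > 1 an excitatory one) and by `washout_multiplier` after
#' the drug window.
#'
#' @param duration Seconds.
#' @param baseline_rate Hz.
#' @param drug_multiplier Rate multiplier during the drug window.
#' @param drug_window c(start, end) seconds.
#' @param washout_multiplier Rate multiplier after the drug window (default 1:
#'   full recovery).
#' @param seed Optional integer seed.
#' @return Tibble with a `time` column (sorted spike times); attribute
#'   `duration`.
#' @export
sim_spike_train <- function(duration = 360, baseline_rate = 2,
                            drug_multiplier = 1, drug_window = c(120, 210),
                            washout_multiplier = 1, seed = NULL) {
  check_scalar_num(duration, "duration", positive = TRUE)
  check_window(drug_window, "drug_window")
  if (baseline_rate < 0 || drug_multiplier < 0 || washout_multiplier < 0) {
    abort_param("Rates and multipliers must be >= 0.")
  }
  segs <- list(
    c(0, drug_window[1], baseline_rate),
    c(drug_window[1], min(drug_window[2], duration), baseline_rate * drug_multiplier),
    c(min(drug_window[2], duration), duration, baseline_rate * washout_multiplier)
  )
  with_seed(seed, {
    times <- unlist(lapply(segs, function(s) {
      span <- s[2] - s[1]
      if (span <= 0 || s[3] == 0) return(numeric(0))
      sort(runif(rpois(1, s[3] * span), s[1], s[2]))
    }))
    out <- tibble(time = sort(times))
    attr(out, "duration") <- duration
    out
  })
}
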