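#' Estimate recording noise from an event-free window
#'
#' Standard deviation of the samples inside `baseline_window`, which the caller
#' asserts is free of events (e.g. a bath-solution recording). This is the
#' noise scale against which detection thresholds (3x SD by default) are set.
#'
#' @param trace Data frame with `time` (s) and `value` (pA) columns.
#' @param baseline_window c(start, end) seconds.
#' @return Noise SD in the trace's amplitude units.
#' @export
estimate_noise_sd <- function(trace, baseline_window) {
  check_trace(trace)
  check_window(baseline_window, "baseline_window")
  v <- trace$value[in_window(trace$time, baseline_window)]
  if (length(v) < 100L) {
    abort_data(sprintf("Baseline window contains only %d samples (need >= 100).", length(v)))
  }
  sd(v)
}

# Robust running baseline: running median over a `width`-second window.
running_baseline <- function(values, dt, width) {
  k <- odd_at_least(width / dt, 3L)
  k <- min(k, odd_at_least(length(values) - 2L, 3L))
  runmed(values, k, endrule = "median")
}

#' Detect threshold-crossing events in a current or field trace
#'
#' Events (spikes or postsynaptic currents) are deviations from a robust
#' running-median baseline that exceed `threshold_mult * noise_sd` in the
#' requested polarity. Each event runs from its threshold crossing until the
#' deviation first returns below `rearm_frac` of the threshold; a new event
#' cannot start within `refractory` seconds of the previous event's end
#' (prevents double counts on noisy crossings). Per event, the local baseline
#' is the median of the `local_baseline_s` seconds preceding onset, from which
#' the peak amplitude and the charge (integral of the absolute deviation over
#' the event extent, in pA.s = pC when the trace is in pA) are measured.
#'
#' @param trace Data frame with `time` (s) and `value` (pA).
#' @param noise_sd Noise SD (pA), e.g. from [estimate_noise_sd()]; must be > 0.
#' @param polarity `"negative"` for inward currents (downward deflections) or
#'   `"positive"`.
#' @param threshold_mult Threshold in units of `noise_sd` (default 3).
#' @param refractory Dead time after an event ends, seconds (default 5 ms; use
#'   ~2 ms for extracellular spikes).
#' @param rearm_frac Fraction of threshold the deviation must fall below to end
#'   an event (default 0.5).
#' @param baseline_width Width (s) of the running-median used for the
#'   detection baseline (default 0.2).
#' @param local_baseline_s Pre-onset span (s) defining each event's local
#'   baseline (default 0.05).
#' @param presmooth Width (s) of a short centered boxcar applied to the
#'   deviation before thresholding (default 1 ms; 0 disables). Suppresses
#'   broadband-noise threshold crossings that are much faster than any
#'   synaptic event; amplitudes and charges are still measured on the raw
#'   trace.
#' @return An `event_train`: tibble with one row per event — `time` (onset, s),
#'   `peak_time`, `amplitude` (pA, positive magnitude), `charge` (pC),
#'   `polarity` — plus attributes `duration` (trace span, s) and `polarity`.
#' @export
detect_events <- function(trace, noise_sd, polarity = c("negative", "positive"),
                          threshold_mult = 3, refractory = 0.005,
                          rearm_frac = 0.5, baseline_width = 0.2,
                          local_baseline_s = 0.05, presmooth = 0.001) {
  polarity <- match.arg(polarity)
  dt <- check_trace(trace)
  check_scalar_num(noise_sd, "noise_sd")
  if (noise_sd <= 0) abort_param("`noise_sd` must be > 0: a zero noise SD makes the threshold degenerate.")
  check_scalar_num(threshold_mult, "threshold_mult", positive = TRUE)
  pol <- if (polarity == "negative") -1 else 1
  v <- trace$value
  n <- length(v)
  base <- running_baseline(v, dt, baseline_width)
  dev <- pol * (v - base)
  if (presmooth > 0) {
    k <- odd_at_least(presmooth / dt, 1L)
    if (k > 1L) dev <- moving_average_centered(dev, k)
  }
  thr <- threshold_mult * noise_sd
  above <- dev > thr
  onsets <- which(above & !c(FALSE, above[-n]))
  w_local <- max(1L, round(local_baseline_s / dt))
  refr_frames <- round(refractory / dt)

  rows <- list()
  last_end <- -Inf
  for (on in onsets) {
    if (on <= last_end + refr_frames) next
    rest <- dev[on:n]
    below <- which(rest < rearm_frac * thr)
    end <- if (length(below) == 0L) n else on + below[1L] - 2L
    if (end < on) end <- on
    lb_from <- max(1L, on - w_local)
    local_base <- if (on > 1L) median(v[lb_from:(on - 1L)]) else base[on]
    seg <- v[on:end]
    rows[[length(rows) + 1L]] <- list(
      time = trace$time[on],
      peak_time = trace$time[on + which.max(pol * (seg - local_base)) - 1L],
      amplitude = max(pol * (seg - local_base)),
      charge = sum(abs(seg - local_base)) * dt,
      onset_frame = on,
      end_frame = as.integer(end)
    )
    last_end <- end
  }
  out <- if (length(rows) == 0L) {
    tibble(time = numeric(), peak_time = numeric(), amplitude = numeric(),
           charge = numeric(), onset_frame = integer(), end_frame = integer())
  } else {
    bind_rows(lapply(rows, as_tibble))
  }
  out$polarity <- rep(polarity, nrow(out))
  attr(out, "duration") <- trace$time[n] - trace$time[1L] + dt
  attr(out, "polarity") <- polarity
  class(out) <- c("event_train", class(out))
  out
}

#' Event-frequency time course
#'
#' Bins event times into `bin`-second bins and reports the rate per bin.
#' Counts are conserved: the sum of `count` equals the number of events.
#'
#' @param events Data frame with a `time` column (s), e.g. an `event_train`.
#' @param bin Bin width, seconds.
#' @param duration Total span (s) to cover, starting at `origin`; defaults to
#'   the `duration` attribute of `events` or the last event time.
#' @param origin Start time of the first bin (default 0).
#' @return Tibble with `bin_center` (s), `count`, `frequency` (Hz).
#' @export
frequency_timecourse <- function(events, bin, duration = NULL, origin = 0) {
  check_scalar_num(bin, "bin", positive = TRUE)
  t <- events$time
  if (is.null(duration)) duration <- attr(events, "duration") %||% (if (length(t)) max(t) - origin else bin)
  check_scalar_num(duration, "duration", positive = TRUE)
  n_bins <- max(1L, ceiling(duration / bin - 1e-9))
  edges <- origin + bin * (0:n_bins)
  idx <- pmin(pmax(findInterval(t, edges, left.open = TRUE, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin_center = edges[-length(edges)] + bin / 2,
    count = counts,
    frequency = counts / bin
  )
}

#' Quantify a drug effect on event frequency
#'
#' Event frequency is measured in three ordered, disjoint windows (baseline,
#' drug, washout). The normalized effect is `freq(drug) / freq(baseline)`
#' (values < 1: inhibition; > 1: excitation). The recording passes washout QC
#' only if the washout frequency returns to within `washout_tol` (default
#' +/-20%) of baseline; otherwise it should be excluded.
#'
#' @param events Data frame with a `time` column (s).
#' @param baseline_window,drug_window,washout_window c(start, end) seconds,
#'   disjoint and in this order.
#' @param washout_tol Allowed relative deviation of washout frequency from
#'   baseline (default 0.2).
#' @return One-row tibble: `baseline_hz`, `drug_hz`, `effect`, `washout_hz`,
#'   `washout_ok`.
#' @export
drug_effect <- function(events, baseline_window, drug_window, washout_window,
                        washout_tol = 0.2) {
  check_window(baseline_window, "baseline_window")
  check_window(drug_window, "drug_window")
  check_window(washout_window, "washout_window")
  if (!(baseline_window[2] <= drug_window[1] && drug_window[2] <= washout_window[1])) {
    abort_param("Windows must be disjoint and ordered baseline < drug < washout.")
  }
  rate <- function(w) sum(in_window(events$time, w)) / (w[2] - w[1])
  b <- rate(baseline_window)
  if (b == 0) abort_data("Baseline frequency is 0: normalized effect undefined.")
  d <- rate(drug_window)
  w <- rate(washout_window)
  tibble(
    baseline_hz = b,
    drug_hz = d,
    effect = d / b,
    washout_hz = w,
    washout_ok = abs(w - b) <= washout_tol * b
  )
}

#' Detect population bursts of postsynaptic currents
#'
#' A burst is a minimum of `min_events` detected events riding on a baseline
#' elevation of at least `elevation` pA. Candidate epochs are maximal runs
#' where the running-median baseline (width `baseline_width` s) deviates from
#' the quiet level — the whole-trace median of that baseline — by at least
#' `elevation` in the event polarity; each epoch is then re-checked against its
#' own pre-epoch baseline (median over `pre_window` s before onset) and kept if
#' it contains at least `min_events` event onsets. Per burst the charge
#' (integral of |signal - pre-epoch baseline|), peak amplitude, duration and
#' charge density (charge/duration) are reported.
#'
#' @param events An `event_train` from [detect_events()] on `trace`.
#' @param trace The source trace (`time`, `value`).
#' @param min_events Minimum events per burst (default 3).
#' @param elevation Minimum baseline elevation, pA (default 60).
#' @param baseline_width Running-median width, seconds (default 0.2).
#' @param pre_window Pre-epoch span defining the local reference baseline (s).
#' @return A `burst_set`: tibble with one row per burst — `start`, `end`,
#'   `duration` (s), `n_events`, `charge` (pC), `peak_amplitude` (pA),
#'   `charge_density` (pC/s).
#' @export
detect_bursts <- function(events, trace, min_events = 3L, elevation = 60,
                          baseline_width = 0.2, pre_window = 0.2) {
  dt <- check_trace(trace)
  if (!inherits(events, "event_train")) abort_param("`events` must come from detect_events().")
  check_scalar_num(elevation, "elevation", positive = TRUE)
  min_events <- as.integer(min_events)
  pol <- if (attr(events, "polarity") == "negative") -1 else 1
  v <- trace$value
  n <- length(v)
  base <- running_baseline(v, dt, baseline_width)
  quiet <- median(base)
  elev <- pol * (base - quiet)
  above <- elev >= elevation
  if (!any(above)) return(empty_burst_set())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # burst extent: expand each qualifying epoch to the surrounding contiguous
  # region still elevated by at least half the criterion
  half <- elev >= elevation / 2
  rows <- list()
  w_pre <- max(1L, round(pre_window / dt))
  last_e <- 0L
  for (i in which(keep)) {
    s <- starts[i]; e <- ends[i]
    while (s > last_e + 1L && half[s - 1L]) s <- s - 1L
    while (e < n && half[e + 1L]) e <- e + 1L
    if (s <= last_e) next # merged into the previous burst
    last_e <- e
    pre_from <- max(1L, s - w_pre)
    pre_base <- if (s > 1L) median(v[pre_from:(s - 1L)]) else quiet
    if (max(pol * (base[s:e] - pre_base)) < elevation) next
    t0 <- trace$time[s]; t1 <- trace$time[e]
    # the running median erodes the elevated epoch by up to half its window on
    # each side; count events over the erosion-corrected extent
    n_ev <- sum(events$time >= t0 - baseline_width / 2 &
                  events$time <= t1 + baseline_width / 2)
    if (n_ev < min_events) next
    seg <- v[s:e]
    rows[[length(rows) + 1L]] <- list(
      start = t0, end = t1, duration = t1 - t0 + dt,
      n_events = as.integer(n_ev),
      charge = sum(abs(seg - pre_base)) * dt,
      peak_amplitude = max(pol * (seg - pre_base))
    )
  }
  if (length(rows) == 0L) return(empty_burst_set())
  out <- bind_rows(lapply(rows, as_tibble))
  out$charge_density <- out$charge / out$duration
  class(out) <- c("burst_set", class(out))
  out
}

empty_burst_set <- function() {
  out <- tibble(start = numeric(), end = numeric(), duration = numeric(),
                n_events = integer(), charge = numeric(),
                peak_amplitude = numeric(), charge_density = numeric())
  class(out) <- c("burst_set", class(out))
  out
}

#' Charge density of an event train
#'
#' Total per-event charge divided by the recording duration (pC/s). When a
#' control reference (the mean charge density of the designated control group,
#' supplied explicitly) is given, the normalized value CD/reference is also
#' reported.
#'
#' @param events Data frame with a `charge` column (pC).
#' @param duration Recording duration, seconds.
#' @param control_reference Optional control-group mean CD (pC/s) for
#'   normalization; must be non-zero.
#' @return One-row tibble: `cd` (pC/s) and, if a reference was given,
#'   `cd_normalized`.
#' @export
charge_density <- function(events, duration = NULL, control_reference = NULL) {
  if (is.null(duration)) duration <- attr(events, "duration")
  check_scalar_num(duration, "duration", positive = TRUE)
  cd <- sum(events$charge) / duration
  out <- tibble(cd = cd)
  if (!is.null(control_reference)) {
    check_scalar_num(control_reference, "control_reference")
    if (control_reference == 0) abort_param("`control_reference` must be non-zero.")
    out$cd_normalized <- cd / control_reference
  }
  out
}

#' Inhibition/excitation charge-density ratio
#'
#' Ratio of the inhibitory (sIPSC) to excitatory (sEPSC) charge density of a
#' cell; a net shift toward excitation lowers the ratio.
#'
#' @param ipsc_cd,epsc_cd Charge densities in pC/s; `epsc_cd` must be > 0.
#' @return The dimensionless ratio.
#' @export
ei_ratio <- function(ipsc_cd, epsc_cd) {
  check_scalar_num(ipsc_cd, "ipsc_cd")
  check_scalar_num(epsc_cd, "epsc_cd")
  if (epsc_cd <= 0) abort_param("`epsc_cd` must be > 0.")
  ipsc_cd / epsc_cd
}

#' Paired-trace synchrony: Pearson correlation and cross-correlogram
#'
#' Both traces are binned (mean per `bin` seconds, default 10 ms, so the
#' statistic reflects event co-occurrence rather than within-event kinetics);
#' the zero-lag Pearson coefficient and the normalized cross-correlation over
#' lags up to `max_lag` are computed on the binned series.
#'
#' @param a,b Traces (`time`, `value`) of equal duration and sampling.
#' @param bin Bin width in seconds (default 0.01).
#' @param max_lag Maximum lag (s) for the cross-correlogram (default 0.5).
#' @return An object of class `paired_correlation`: list with `r` (zero-lag
#'   Pearson), `n_bins`, and `correlogram` (tibble `lag`, `correlation`). Has a
#'   [tidy()] method returning the correlogram and [glance()] returning `r`.
#' @export
paired_correlation <- function(a, b, bin = 0.01, max_lag = 0.5) {
  dta <- check_trace(a, "a")
  dtb <- check_trace(b, "b")
  if (nrow(a) != nrow(b) || abs(dta - dtb) > 1e-12) {
    abort_data("Traces must have equal duration and sampling.")
  }
  check_scalar_num(bin, "bin", positive = TRUE)
  per <- max(1L, round(bin / dta))
  nb <- floor(nrow(a) / per)
  if (nb < 3L) abort_data("Fewer than 3 bins: trace too short for the chosen bin.")
  idx <- rep(seq_len(nb), each = per)
  xa <- tapply(a$value[seq_len(nb * per)], idx, mean)
  xb <- tapply(b$value[seq_len(nb * per)], idx, mean)
  if (sd(xa) == 0 || sd(xb) == 0) {
    abort_data("Zero-variance trace: correlation undefined.")
  }
  lag_max <- max(1L, round(max_lag / bin))
  cc <- ccf(as.numeric(xa), as.numeric(xb), lag.max = lag_max, plot = FALSE,
            demean = TRUE)
  structure(
    list(
      r = as.numeric(cor(xa, xb)),
      n_bins = nb,
      bin = bin,
      correlogram = tibble(lag = as.numeric(cc$lag) * bin,
                           correlation = as.numeric(cc$acf))
    ),
    class = "paired_correlation"
  )
}

#' @export
print.paired_correlation <- function(x, ...) {
  cat(sprintf("<paired_correlation> r = %.3f over %d bins of %g s\n",
              x$r, x$n_bins, x$bin))
  invisible(x)
}

#' @rdname paired_correlation
#' @param x A `paired_correlation`.
#' @param ... Unused.
#' @method tidy paired_correlation
#' @export
tidy.paired_correlation <- function(x, ...) x$correlogram

#' @rdname paired_correlation
#' @method glance paired_correlation
#' @export
glance.paired_correlation <- function(x, ...) {
  tibble(r = x$r, n_bins = x$n_bins, bin = x$bin)
}

#' Quality-control filter for whole-cell recordings
#'
#' Applies the recording exclusion rules: a cell is excluded when the magnitude
#' of its holding current at -70 mV exceeds the age-class bound (30 pA at P0,
#' 40 pA at P15 by default, i.e. holding more negative than -30 / -40 pA), or
#' when holding current or input resistance drifted by more than `drift_max`
#' percent during the recording. Exactly one triggering rule is reported per
#' exclusion (checked in the order holding current, holding drift, input
#' resistance drift).
#'
#' @param records Data frame with columns `age_class` ("P0" or "P15"),
#'   `holding_pa` (pA, signed), `holding_drift_pct` and `ir_drift_pct`
#'   (percent, magnitudes). Extra columns (e.g. `cell`) are carried through.
#' @param p0_bound,p15_bound Holding-current magnitude bounds in pA.
#' @param drift_max Maximum tolerated drift, percent (default 15).
#' @return The input tibble with `decision` ("keep"/"exclude") and `reason`
#'   (NA for kept cells) appended.
#' @export
qc_filter <- function(records, p0_bound = 30, p15_bound = 40, drift_max = 15) {
  need <- c("age_class", "holding_pa", "holding_drift_pct", "ir_drift_pct")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort_data(sprintf("`records` must contain columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(is.na(records$age_class)) || !all(records$age_class %in% c("P0", "P15"))) {
    abort_data("`age_class` must be \"P0\" or \"P15\" for every cell.")
  }
  bound <- ifelse(records$age_class == "P0", p0_bound, p15_bound)
  reason <- rep(NA_character_, nrow(records))
  hit_holding <- abs(records$holding_pa) > bound
  hit_hdrift <- records$holding_drift_pct > drift_max
  hit_irdrift <- records$ir_drift_pct > drift_max
  reason[hit_irdrift] <- sprintf("input resistance drift > %g%%", drift_max)
  reason[hit_hdrift] <- sprintf("holding current drift > %g%%", drift_max)
  reason[hit_holding] <- sprintf("holding current beyond %g pA bound",
                                 bound[hit_holding])
  out <- as_tibble(records)
  out$decision <- ifelse(is.na(reason), "keep", "exclude")
  out$reason <- reason
  out
}
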