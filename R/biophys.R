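#' Estimate the GABA-A driving force from single-channel I/V data
#'
#' Fits the mean open-channel current against the imposed potential and takes
#' the zero-current potential as the reversal. In the cell-attached
#' convention the I/V table holds potentials as \code{-Vp} (the negated pipette
#' potential), in which case the fitted reversal is the driving force of the
#' GABA-A current (DF_GABA): positive values mean depolarizing GABA action.
#' With `convention = "vp"` potentials are negated before fitting.
#'
#' The default model is linear, \eqn{I = g (V - V_{rev})}; `model =
#' "quadratic"` adds a curvature term for rectifying channels, and the reversal
#' is then the root nearest the recorded potential span. A fit whose reversal
#' falls outside \[min(V) - 20, max(V) + 20\] mV is flagged as extrapolated
#' with a warning; potentials backed by fewer than `min_openings` channel
#' openings set a QC flag.
#'
#' @param iv Data frame with columns `potential_mv`, `mean_current_pa`, and
#'   optionally `n_openings`.
#' @param model `"linear"` (default) or `"quadratic"`.
#' @param convention `"neg_vp"` (default: potentials are -Vp, as plotted for
#'   cell-attached I/V curves) or `"vp"` (raw pipette potentials).
#' @param min_openings Openings per potential required for full confidence
#'   (default 20).
#' @return An object of class `df_estimate`: list with `reversal_mv`,
#'   `df_gaba_mv`, `slope_pa_per_mv`, `conductance_ps` (slope x 1000),
#'   `sigma` (residual SD), `r_squared`, `extrapolated`, `low_openings`,
#'   `model`, `fit` (the `lm`), `data`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' iv <- tibble::tibble(potential_mv = seq(-100, 60, 10),
#'                      mean_current_pa = 2 * (seq(-100, 60, 10) + 10))
#' fit_iv(iv)$reversal_mv # -10
#' @export
fit_iv <- function(iv, model = c("linear", "quadratic"),
                   convention = c("neg_vp", "vp"), min_openings = 20L) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  if (!is.data.frame(iv) || !all(c("potential_mv", "mean_current_pa") %in% names(iv))) {
    abort_data("`iv` must have columns `potential_mv` and `mean_current_pa`.")
  }
  v <- iv$potential_mv
  if (convention == "vp") v <- -v
  i <- iv$mean_current_pa
  check_finite_values(v, "potential")
  check_finite_values(i, "current")
  if (length(unique(v)) < 3L) {
    abort_data("Need at least 3 distinct potentials to fit an I/V relation.")
  }
  fit <- if (model == "linear") lm(i ~ v) else lm(i ~ v + I(v^2))
  cf <- coef(fit)
  if (model == "linear") {
    if (!is.finite(cf[2]) || cf[2] == 0) abort_data("Zero-slope I/V: reversal undefined.")
    v_rev <- -cf[1] / cf[2]
    slope <- unname(cf[2])
  } else {
    # roots of c2 v^2 + c1 v + c0; take the one nearest the data span
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (!is.finite(disc) || disc < 0) abort_data("Quadratic I/V has no real zero-current root.")
    roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
    mid <- mean(range(v))
    v_rev <- roots[which.min(abs(roots - mid))]
    slope <- unname(cf[2] + 2 * cf[3] * v_rev) # local conductance at reversal
  }
  v_rev <- unname(v_rev)
  extrapolated <- v_rev < min(v) - 20 || v_rev > max(v) + 20
  if (extrapolated) {
    warning(sprintf("Reversal %.1f mV lies outside the recorded range [%g, %g] mV (extrapolated).",
                    v_rev, min(v), max(v)))
  }
  low_openings <- "n_openings" %in% names(iv) && any(iv$n_openings < min_openings)
  res <- stats::residuals(fit)
  ss_tot <- sum((i - mean(i))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(
    list(
      reversal_mv = v_rev,
      df_gaba_mv = v_rev,
      slope_pa_per_mv = slope,
      conductance_ps = slope * 1000,
      sigma = if (length(res) > length(cf)) sqrt(sum(res^2) / (length(res) - length(cf))) else 0,
      r_squared = r2,
      extrapolated = extrapolated,
      low_openings = low_openings,
      model = model,
      fit = fit,
      data = tibble(potential_mv = v, mean_current_pa = i)
    ),
    class = "df_estimate"
  )
}

#' @export
print.df_estimate <- function(x, ...) {
  cat(sprintf("<df_estimate> DF_GABA = %.2f mV; slope = %.3f pA/mV (%s fit)%s\n",
              x$df_gaba_mv, x$slope_pa_per_mv, x$model,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @rdname fit_iv
#' @param x A `df_estimate`.
#' @param ... Unused.
#' @method tidy df_estimate
#' @export
tidy.df_estimate <- function(x, ...) {
  tibble(
    term = names(coef(x$fit)),
    estimate = unname(coef(x$fit)),
    std.error = unname(suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"])
  )
}

#' @rdname fit_iv
#' @method glance df_estimate
#' @export
glance.df_estimate <- function(x, ...) {
  tibble(
    reversal_mv = x$reversal_mv,
    df_gaba_mv = x$df_gaba_mv,
    slope_pa_per_mv = x$slope_pa_per_mv,
    conductance_ps = x$conductance_ps,
    sigma = x$sigma,
    r_squared = x$r_squared,
    extrapolated = x$extrapolated,
    low_openings = x$low_openings
  )
}

#' Onset slope of a field EPSP sweep
#'
#' Measures the slope of the fEPSP rising phase between 30% and 70% of the
#' baseline-to-peak amplitude. The peak is the extremum of the
#' baseline-subtracted sweep inside `onset_window` (largest magnitude in either
#' polarity when `polarity = "auto"`); the regression uses all samples between
#' the window start and the peak whose fractional amplitude lies in `band`.
#'
#' @param sweep Data frame with `time` (s) and `value` (mV).
#' @param onset_window c(start, end) seconds containing the response (after any
#'   stimulus-artifact blanking).
#' @param baseline_window Optional c(start, end) defining the baseline; default
#'   is everything before `onset_window`.
#' @param band Fractional-amplitude band for the regression (default c(0.3, 0.7)).
#' @param polarity `"auto"`, `"negative"` or `"positive"`.
#' @return One-row tibble: `slope` (mV/ms), `peak_time` (s), `amplitude` (mV,
#'   signed), `n_points`.
#' @export
fepsp_slope <- function(sweep, onset_window, baseline_window = NULL,
                        band = c(0.3, 0.7), polarity = c("auto", "negative", "positive")) {
  polarity <- match.arg(polarity)
  check_trace(sweep, "sweep")
  check_window(onset_window, "onset_window")
  if (is.null(baseline_window)) {
    pre <- sweep$value[sweep$time < onset_window[1]]
  } else {
    check_window(baseline_window, "baseline_window")
    pre <- sweep$value[in_window(sweep$time, baseline_window)]
  }
  if (length(pre) < 1L) abort_data("No baseline samples before the onset window.")
  base <- mean(pre)
  inw <- which(in_window(sweep$time, onset_window))
  if (length(inw) < 3L) abort_data("Onset window contains fewer than 3 samples.")
  dv <- sweep$value[inw] - base
  pol <- switch(polarity,
    auto = if (max(dv) >= -min(dv)) 1 else -1,
    positive = 1,
    negative = -1
  )
  peak_rel <- which.max(pol * dv)
  amp <- dv[peak_rel]
  if (pol * amp <= 0) abort_data("No response peak found in the onset window.")
  frac <- pol * dv[seq_len(peak_rel)] / (pol * amp)
  sel <- which(frac >= band[1] & frac <= band[2])
  if (length(sel) < 3L) {
    abort_data(sprintf("Only %d samples in the %g-%g%% rising band (need >= 3).",
                       length(sel), band[1] * 100, band[2] * 100))
  }
  tt <- sweep$time[inw][sel]
  vv <- sweep$value[inw][sel]
  fit <- lm(vv ~ tt)
  tibble(
    slope = unname(coef(fit)[2]) / 1000, # mV/s -> mV/ms
    peak_time = sweep$time[inw][peak_rel],
    amplitude = amp,
    n_points = length(sel)
  )
}

#' Normalize an fEPSP slope series to its baseline
#'
#' Expresses each slope as a percentage of the mean slope over the baseline
#' window (pre-drug). Normalizing an already-normalized series with the same
#' window leaves it unchanged, since its baseline mean is 100.
#'
#' @param series Data frame with `time_min` (minutes, relative to drug washout)
#'   and `slope` columns.
#' @param baseline_window c(start, end) minutes defining the baseline (default
#'   c(-15, -5): the 10 min before drug onset for a 5-min application ending at
#'   washout time 0).
#' @return The input tibble with a `norm_slope` column (% of baseline) added
#'   (replacing `slope` as the normalized measure; `slope` is retained).
#' @export
normalize_slopes <- function(series, baseline_window = c(-15, -5)) {
  if (!is.data.frame(series) || !all(c("time_min", "slope") %in% names(series))) {
    abort_data("`series` must have columns `time_min` and `slope`.")
  }
  check_window(baseline_window, "baseline_window")
  base <- series$slope[in_window(series$time_min, baseline_window)]
  if (length(base) == 0L) abort_data("Baseline window contains no samples.")
  m <- mean(base)
  if (m == 0) abort_data("Zero baseline mean: normalization undefined.")
  out <- as_tibble(series)
  out$norm_slope <- out$slope / m * 100
  out
}

#' Summarise long-term depression over the early and late windows
#'
#' Means and SEMs of the normalized fEPSP slope over the early-LTD window
#' (20-25 min after drug washout) and the late-LTD window (50-55 min). Every
#' sample inside a window contributes exactly once.
#'
#' @param series Data frame with `time_min` and `norm_slope` columns (see
#'   [normalize_slopes()]); a `slope` column plus `baseline_window` may be
#'   given instead, in which case normalization is applied first.
#' @param early_window,late_window c(start, end) minutes after washout.
#' @param baseline_window Passed to [normalize_slopes()] when `norm_slope` is
#'   absent.
#' @return One-row tibble: `early_pct`, `early_sem`, `early_n`, `late_pct`,
#'   `late_sem`, `late_n`.
#' @export
ltd_summary <- function(series, early_window = c(20, 25), late_window = c(50, 55),
                        baseline_window = c(-15, -5)) {
  if (!is.data.frame(series) || !"time_min" %in% names(series)) {
    abort_data("`series` must have a `time_min` column.")
  }
  if (!"norm_slope" %in% names(series)) {
    series <- normalize_slopes(series, baseline_window = baseline_window)
  }
  check_window(early_window, "early_window")
  check_window(late_window, "late_window")
  win_stats <- function(w, label) {
    x <- series$norm_slope[in_window(series$time_min, w)]
    if (length(x) == 0L) {
      abort_data(sprintf("The %s window [%g, %g] min is not covered by the series.",
                         label, w[1], w[2]))
    }
    list(mean = mean(x), sem = if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0,
         n = length(x))
  }
  e <- win_stats(early_window, "early-LTD")
  l <- win_stats(late_window, "late-LTD")
  tibble(
    early_pct = e$mean, early_sem = e$sem, early_n = e$n,
    late_pct = l$mean, late_sem = l$sem, late_n = l$n
  )
}
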