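# Synthetic biophysics inputs: single-channel I/V tables and fEPSP slope
# time courses with known ground truth.

#' Simulate a single-channel I/V dataset
#'
#' Open-channel currents follow the linear relation \eqn{I = g (V - V_{rev})}
#' with `conductance_ps` picosiemens (1 pS x 1 mV = 1e-3 pA) and known
#' reversal potential; at each imposed potential `openings_per_potential`
#' openings are drawn with Gaussian measurement noise and their mean is
#' recorded, mirroring a cell-attached protocol that collects at least 20
#' openings per potential from -100 to +60 mV in 10 mV steps.
#'
#' @param reversal_mv Ground-truth reversal potential (mV); in the -Vp
#'   convention this is the GABA-A driving force.
#' @param conductance_ps Slope conductance, pS.
#' @param potentials Imposed potentials (-Vp, mV); at least 3 distinct values.
#' @param openings_per_potential Openings averaged per potential (default 20).
#' @param current_noise_sd Per-opening current noise SD, pA.
#' @param seed Optional integer seed.
#' @return Tibble with `potential_mv`, `mean_current_pa`, `n_openings`;
#'   attribute `truth` holds the generating parameters.
#' @export
sim_iv_dataset <- function(reversal_mv = -10, conductance_ps = 20,
                           potentials = seq(-100, 60, by = 10),
                           openings_per_potential = 20L,
                           current_noise_sd = 0.2, seed = NULL) {
  check_scalar_num(reversal_mv, "reversal_mv")
  check_scalar_num(conductance_ps, "conductance_ps")
  if (length(unique(potentials)) < 3L) {
    abort_param("Need at least 3 distinct potentials.")
  }
  openings_per_potential <- as.integer(openings_per_potential)
  if (is.na(openings_per_potential) || openings_per_potential < 1L) {
    abort_param("`openings_per_potential` must be a positive integer.")
  }
  if (current_noise_sd < 0) abort_param("`current_noise_sd` must be >= 0.")
  g_pa_per_mv <- conductance_ps / 1000
  with_seed(seed, {
    mean_i <- vapply(potentials, function(v) {
      true_i <- g_pa_per_mv * (v - reversal_mv)
      if (current_noise_sd > 0) {
        mean(true_i + rnorm(openings_per_potential, 0, current_noise_sd))
      } else true_i
    }, numeric(1))
    out <- tibble(
      potential_mv = potentials,
      mean_current_pa = mean_i,
      n_openings = openings_per_potential
    )
    attr(out, "truth") <- list(reversal_mv = reversal_mv,
                               conductance_ps = conductance_ps,
                               current_noise_sd = current_noise_sd)
    out
  })
}

#' Simulate a normalized fEPSP slope time course with early/late depression
#'
#' Emulates a DHPG-induced LTD experiment. Time is in minutes relative to drug
#' washout: a stable baseline (level 1) runs until drug onset at -5 min, the
#' slope drops to `dip_level` during the 5-min application, partially recovers
#' linearly to `early_level` by 20 min, holds that level through the early-LTD
#' window (20-25 min), relaxes linearly to `late_level` by 50 min and holds it
#' through the late-LTD window (50-55 min and beyond). At zero noise the
#' early/late window means equal the configured levels exactly.
#'
#' @param baseline_slope Baseline fEPSP slope, mV/ms.
#' @param early_level,late_level Depression levels as fractions of baseline
#'   (must be > 0).
#' @param noise_sd Additive noise SD on the normalized level (fraction of
#'   baseline).
#' @param sweeps_per_min Sampling density of the time course (default 2).
#' @param t_start,t_end Series span, minutes relative to washout; must cover
#'   the baseline window (<= -15) and the late-LTD window (>= 55).
#' @param dip_level Level during drug application.
#' @param seed Optional integer seed.
#' @return Tibble with `time_min` and `slope` (mV/ms); attribute `truth`.
#' @export
sim_ltd_series <- function(baseline_slope = 0.2, early_level = 0.5218,
                           late_level = 0.7783, noise_sd = 0.03,
                           sweeps_per_min = 2, t_start = -20, t_end = 60,
                           dip_level = 0.35, seed = NULL) {
  check_scalar_num(baseline_slope, "baseline_slope", positive = TRUE)
  if (early_level <= 0 || late_level <= 0 || dip_level <= 0) {
    abort_param("Depression levels must be > 0.")
  }
  if (noise_sd < 0) abort_param("`noise_sd` must be >= 0.")
  check_scalar_num(sweeps_per_min, "sweeps_per_min", positive = TRUE)
  if (t_start > -15 || t_end < 55) {
    abort_param("Series must span at least [-15, 55] min to cover the baseline and late-LTD windows.")
  }
  tt <- seq(t_start, t_end, by = 1 / sweeps_per_min)
  level <- vapply(tt, function(t) {
    if (t <= -5) 1
    else if (t < 0) dip_level
    else if (t < 20) dip_level + (early_level - dip_level) * t / 20
    else if (t <= 25) early_level
    else if (t < 50) early_level + (late_level - early_level) * (t - 25) / 25
    else late_level
  }, numeric(1))
  with_seed(seed, {
    if (noise_sd > 0) level <- level + rnorm(length(level), 0, noise_sd)
    out <- tibble(time_min = tt, slope = baseline_slope * level)
    attr(out, "truth") <- list(baseline_slope = baseline_slope,
                               early_level = early_level,
                               late_level = late_level, noise_sd = noise_sd)
    out
  })
}
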