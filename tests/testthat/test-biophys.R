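test_that("fit_iv solves noiseless linear I/V exactly", {
  v <- seq(-100, 60, by = 10)
  iv <- tibble::tibble(potential_mv = v, mean_current_pa = 2 * (v + 10))
  est <- fit_iv(iv)
  expect_equal(est$reversal_mv, -10, tolerance = 1e-10)
  expect_equal(est$slope_pa_per_mv, 2, tolerance = 1e-10)
  expect_equal(est$df_gaba_mv, est$reversal_mv)
  expect_false(est$extrapolated)

  # sign flip of the currents: reversal unchanged, conductance negated
  flipped <- fit_iv(dplyr::mutate(iv, mean_current_pa = -mean_current_pa))
  expect_equal(flipped$reversal_mv, -10, tolerance = 1e-10)
  expect_equal(flipped$slope_pa_per_mv, -2, tolerance = 1e-10)

  # raw-Vp convention negates potentials before fitting
  raw <- fit_iv(dplyr::mutate(iv, potential_mv = -potential_mv), convention = "vp")
  expect_equal(raw$reversal_mv, -10, tolerance = 1e-10)
})

test_that("fit_iv equals the closed-form least-squares solution", {
  set.seed(14)
  for (i in 1:20) {
    v <- sort(sample(seq(-100, 60, by = 10), sample(5:17, 1)))
    y <- runif(1, -3, 3) * v + rnorm(length(v), 0, 2)
    iv <- tibble::tibble(potential_mv = v, mean_current_pa = y)
    est <- fit_iv(iv)
    # normal equations solved directly
    sl <- sum((v - mean(v)) * (y - mean(y))) / sum((v - mean(v))^2)
    ic <- mean(y) - sl * mean(v)
    expect_equal(est$slope_pa_per_mv, sl, tolerance = 1e-9)
    expect_equal(est$reversal_mv, -ic / sl, tolerance = 1e-9)
  }
})

test_that("fit_iv guards degenerate inputs and flags extrapolation/low openings", {
  expect_error(fit_iv(tibble::tibble(potential_mv = c(0, 10),
                                     mean_current_pa = c(0, 1))), "3 distinct")
  expect_error(fit_iv(tibble::tibble(potential_mv = rep(5, 5),
                                     mean_current_pa = rnorm(5))), "3 distinct")

  v <- seq(-40, 40, by = 10)
  far <- tibble::tibble(potential_mv = v, mean_current_pa = 0.5 * (v - 100))
  expect_warning(est <- fit_iv(far), "extrapolated")
  expect_true(est$extrapolated)

  iv <- sim_iv_dataset(seed = 1, openings_per_potential = 10)
  expect_true(fit_iv(iv)$low_openings)
})

test_that("quadratic I/V picks the root nearest the recorded span", {
  v <- seq(-100, 60, by = 10)
  # rectifying relation with a single zero crossing at -20 inside the span
  y <- 0.02 * (v + 20) * (1 + 0.004 * (v + 100))
  est <- fit_iv(tibble::tibble(potential_mv = v, mean_current_pa = y),
                model = "quadratic")
  expect_equal(est$reversal_mv, -20, tolerance = 1e-6)
})

test_that("reversal recovery from noisy openings stays within 2 mV", {
  errs <- vapply(1:20, function(s) {
    iv <- sim_iv_dataset(reversal_mv = -15, conductance_ps = 20,
                         current_noise_sd = 0.2, seed = s)
    abs(fit_iv(iv)$reversal_mv - (-15))
  }, numeric(1))
  expect_true(all(errs < 2))
})

test_that("fepsp_slope returns a ramp's slope exactly", {
  t <- seq(0, 0.1, by = 1e-4)
  v <- ifelse(t < 0.05, 0, -2000 * (t - 0.05)) # -2 mV/ms falling fEPSP
  sweep <- tibble::tibble(time = t, value = v)
  out <- fepsp_slope(sweep, onset_window = c(0.05, 0.1))
  expect_equal(out$slope, -2, tolerance = 1e-9)

  # doubling the response doubles the slope
  out2 <- fepsp_slope(dplyr::mutate(sweep, value = 2 * value), c(0.05, 0.1))
  expect_equal(out2$slope, 2 * out$slope, tolerance = 1e-9)
})

test_that("fepsp_slope matches brute-force regression over the 30-70% band of a sigmoid", {
  t <- seq(0, 0.2, by = 1e-4)
  A <- -1.4
  v <- A / (1 + exp(-(t - 0.1) / 0.008))
  sweep <- tibble::tibble(time = t, value = v)
  out <- fepsp_slope(sweep, onset_window = c(0.02, 0.2))

  # oracle: enumerate the band over the rising phase and regress directly
  base <- mean(v[t < 0.02])
  inw <- which(t >= 0.02 & t <= 0.2)
  dv <- v[inw] - base
  peak <- which.max(-dv)
  frac <- -dv[seq_len(peak)] / max(-dv)
  sel <- which(frac >= 0.3 & frac <= 0.7)
  fit <- lm(v[inw][sel] ~ t[inw][sel])
  expect_equal(out$slope, unname(coef(fit)[2]) / 1000, tolerance = 1e-9)
  expect_gte(out$n_points, 3)
})

test_that("fepsp_slope rejects windows without a usable rising phase", {
  t <- seq(0, 0.1, by = 1e-3)
  flat <- tibble::tibble(time = t, value = rep(0, length(t)))
  expect_error(fepsp_slope(flat, c(0.05, 0.1)), "peak")

  # a one-sample step leaves < 3 samples inside the band
  step <- tibble::tibble(time = t, value = c(rep(0, 80), rep(-5, 21)))
  expect_error(fepsp_slope(step, c(0.05, 0.1)), "band")
})

test_that("normalize_slopes is idempotent and anchors baseline at 100%", {
  series <- sim_ltd_series(noise_sd = 0)
  norm <- normalize_slopes(series)
  base <- norm$norm_slope[norm$time_min >= -15 & norm$time_min <= -5]
  expect_equal(mean(base), 100, tolerance = 1e-12)

  renorm <- normalize_slopes(
    tibble::tibble(time_min = norm$time_min, slope = norm$norm_slope)
  )
  expect_equal(renorm$norm_slope, norm$norm_slope, tolerance = 1e-12)
})

test_that("ltd_summary recovers configured depression levels exactly at zero noise", {
  s <- sim_ltd_series(early_level = 0.52, late_level = 0.78, noise_sd = 0)
  out <- ltd_summary(s)
  expect_equal(out$early_pct, 52, tolerance = 1e-9)
  expect_equal(out$late_pct, 78, tolerance = 1e-9)
  expect_equal(out$early_sem, 0, tolerance = 1e-9)

  # no depression: both windows at 100%
  none <- ltd_summary(sim_ltd_series(early_level = 1, late_level = 1,
                                     dip_level = 1, noise_sd = 0))
  expect_equal(none$early_pct, 100, tolerance = 1e-9)
  expect_equal(none$late_pct, 100, tolerance = 1e-9)
})

test_that("ltd_summary handles a step series and conserves window samples", {
  t <- seq(-20, 60, by = 0.5)
  series <- tibble::tibble(time_min = t, norm_slope = ifelse(t < 40, 50, 80))
  out <- ltd_summary(series)
  expect_equal(out$early_pct, 50)
  expect_equal(out$late_pct, 80)
  expect_equal(out$early_n, sum(t >= 20 & t <= 25))
  expect_equal(out$late_n, sum(t >= 50 & t <= 55))

  short <- series[series$time_min < 30, ]
  expect_error(ltd_summary(short), "late-LTD")
})

test_that("ltd_summary recovers noisy calibrated levels within sampling error", {
  s <- sim_ltd_series(early_level = 0.5218, late_level = 0.7783,
                      noise_sd = 0.05, sweeps_per_min = 12, seed = 33)
  out <- ltd_summary(s)
  expect_lt(abs(out$early_pct - 52.18), 2 * out$early_sem)
  expect_lt(abs(out$late_pct - 77.83), 2 * out$late_sem)
})
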