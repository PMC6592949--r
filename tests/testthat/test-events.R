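test_that("estimate_noise_sd measures baseline noise and ignores offsets", {
  flat <- make_trace(rep(2.5, 500))
  expect_equal(estimate_noise_sd(flat, c(0, 0.4)), 0)

  set.seed(3)
  noisy <- make_trace(rnorm(20000, 0, 4), fs = 5000)
  est <- estimate_noise_sd(noisy, c(0, 3.9))
  expect_lt(abs(est - 4) / 4, 0.05)

  shifted <- dplyr::mutate(noisy, value = value + 120)
  expect_equal(estimate_noise_sd(shifted, c(0, 3.9)), est)

  expect_error(estimate_noise_sd(make_trace(rnorm(500)), c(0, 0.05)), ">= 100")
})

test_that("detect_events applies the 3xSD threshold rule", {
  sigma <- 3
  # zero-noise fixture: planted 10-sigma events are all found, nothing else
  sim <- sim_psc_train(duration = 20, rate = 1.5, amp_mean = 10 * sigma,
                       amp_sd = 0, noise_sd = 0, min_separation = 0.02, seed = 5)
  ev <- detect_events(sim$trace, noise_sd = sigma)
  m <- match_events(ev$time, sim$events$time)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(nrow(ev), nrow(sim$events))

  # 2-sigma events never cross the 3-sigma threshold
  small <- sim_psc_train(duration = 20, rate = 1.5, amp_mean = 2 * sigma,
                         amp_sd = 0, noise_sd = 0, seed = 5)
  expect_equal(nrow(detect_events(small$trace, noise_sd = sigma)), 0)

  # flat trace yields an empty train
  expect_equal(nrow(detect_events(make_trace(rep(0, 5000), fs = 5000),
                                  noise_sd = sigma)), 0)

  # degenerate threshold is refused
  expect_error(detect_events(sim$trace, noise_sd = 0), "degenerate")
})

test_that("detection recall does not improve with noise", {
  recall_at <- function(noise) {
    r <- vapply(1:3, function(s) {
      sim <- sim_psc_train(duration = 15, rate = 1, amp_mean = 30, amp_sd = 0,
                           noise_sd = noise, min_separation = 0.02, seed = s)
      ev <- detect_events(sim$trace, noise_sd = max(noise, 2))
      match_events(ev$time, sim$events$time)$recall
    }, numeric(1))
    mean(r)
  }
  rs <- vapply(c(0.5, 4, 9), recall_at, numeric(1))
  expect_true(all(diff(rs) <= 0))
  expect_lt(rs[3], 1)
})

test_that("event charge matches the analytic integral and survives resampling", {
  rect_trace <- function(fs) {
    v <- rep(0, fs)
    on <- round(0.4 * fs) + 1
    v[on:(on + round(0.01 * fs) - 1)] <- -10 # 10 pA for 10 ms
    make_trace(v, fs = fs)
  }
  ev1 <- detect_events(rect_trace(1000), noise_sd = 1)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$charge, 0.1, tolerance = 0.02) # 10 pA x 10 ms = 0.1 pC
  expect_equal(ev1$amplitude, 10, tolerance = 1e-6)

  ev2 <- detect_events(rect_trace(5000), noise_sd = 1)
  expect_equal(ev2$charge, ev1$charge, tolerance = 0.01)
})

test_that("frequency_timecourse conserves events", {
  ev <- tibble::tibble(time = seq(0.5, 9.5, by = 1))
  tc <- frequency_timecourse(ev, bin = 1, duration = 10)
  expect_true(all(tc$frequency == 1))
  expect_equal(sum(tc$count), nrow(ev))

  empty <- frequency_timecourse(tibble::tibble(time = numeric()), bin = 1, duration = 5)
  expect_true(all(empty$count == 0))

  set.seed(9)
  pois <- tibble::tibble(time = sort(runif(400, 0, 100)))
  tcp <- frequency_timecourse(pois, bin = 2, duration = 100)
  expect_equal(sum(tcp$count), 400)
  expect_equal(mean(tcp$frequency), 4, tolerance = 0.15)
})

test_that("drug_effect normalizes to baseline and applies the 20% washout rule", {
  ev <- tibble::tibble(time = c(seq(0.25, 9.75, length.out = 20),   # 2 Hz baseline
                                seq(10.5, 19.5, length.out = 10),   # 1 Hz drug
                                seq(20.2, 29.8, length.out = 25)))  # 2.5 Hz washout
  de <- drug_effect(ev, c(0, 10), c(10, 20), c(20, 30))
  expect_equal(de$baseline_hz, 2)
  expect_equal(de$effect, 0.5)
  expect_false(de$washout_ok) # 25% above control exceeds the 20% band

  ev2 <- tibble::tibble(time = c(seq(0.25, 9.75, length.out = 20),
                                 seq(10.2, 19.8, length.out = 30),
                                 seq(20.25, 29.75, length.out = 20)))
  de2 <- drug_effect(ev2, c(0, 10), c(10, 20), c(20, 30))
  expect_equal(de2$effect, 1.5)
  expect_true(de2$washout_ok)

  expect_error(drug_effect(ev, c(0, 12), c(10, 20), c(20, 30)), "ordered")
  none <- tibble::tibble(time = c(15, 16))
  expect_error(drug_effect(none, c(0, 10), c(10, 20), c(20, 30)), "Baseline")
})

test_that("burst rule: >= 3 events riding a >= 60 pA elevation", {
  run_cfg <- function(ev_per_burst, elevation, seed) {
    sim <- sim_psc_train(duration = 25, rate = 0, burst_rate = 0.2,
                         burst_events = ev_per_burst, burst_elevation = elevation,
                         noise_sd = 2, seed = seed)
    det <- detect_bursts(detect_events(sim$trace, noise_sd = 2), sim$trace)
    c(planted = nrow(sim$bursts), detected = nrow(det))
  }
  for (seed in 1:4) {
    ok <- run_cfg(5, 80, seed)
    expect_equal(ok[["detected"]], ok[["planted"]])
    ok3 <- run_cfg(3, 80, seed)
    expect_equal(ok3[["detected"]], ok3[["planted"]])
    expect_equal(run_cfg(2, 80, seed)[["detected"]], 0) # too few events
    expect_equal(run_cfg(5, 40, seed)[["detected"]], 0) # elevation below criterion
  }
})

test_that("isolated events on a flat baseline never form a burst", {
  sim <- sim_psc_train(duration = 20, rate = 0.5, amp_mean = 30, noise_sd = 2,
                       seed = 12)
  ev <- detect_events(sim$trace, noise_sd = 2)
  expect_gte(nrow(ev), 5)
  expect_equal(nrow(detect_bursts(ev, sim$trace)), 0)
})

test_that("burst metrics are internally consistent", {
  sim <- sim_psc_train(duration = 25, rate = 0.5, burst_rate = 0.15,
                       burst_events = 4, burst_elevation = 90, noise_sd = 2,
                       seed = 8)
  bs <- detect_bursts(detect_events(sim$trace, noise_sd = 2), sim$trace)
  expect_gt(nrow(bs), 0)
  expect_true(all(bs$n_events >= 3))
  expect_true(all(bs$duration > 0))
  expect_equal(bs$charge_density, bs$charge / bs$duration)
  # non-overlapping epochs
  if (nrow(bs) > 1) expect_true(all(bs$start[-1] > bs$end[-nrow(bs)]))
})

test_that("charge_density sums event charge per second and normalizes", {
  ev <- tibble::tibble(charge = c(0.2, 0.3, 0.5))
  expect_equal(charge_density(ev, duration = 10)$cd, 0.1)
  out <- charge_density(ev, duration = 10, control_reference = 0.05)
  expect_equal(out$cd_normalized, 2)
  expect_error(charge_density(ev, duration = 10, control_reference = 0), "non-zero")

  # concatenating two recordings gives the duration-weighted mean
  ev_a <- tibble::tibble(charge = runif(5))
  ev_b <- tibble::tibble(charge = runif(3))
  cd_ab <- charge_density(dplyr::bind_rows(ev_a, ev_b), duration = 30)$cd
  cd_a <- charge_density(ev_a, duration = 10)$cd
  cd_b <- charge_density(ev_b, duration = 20)$cd
  expect_equal(cd_ab, (10 * cd_a + 20 * cd_b) / 30)
})

test_that("ei_ratio is a guarded linear ratio", {
  expect_equal(ei_ratio(2, 2), 1)
  expect_equal(ei_ratio(1, 2), ei_ratio(2, 2) / 2)
  expect_error(ei_ratio(1, 0), "> 0")
})

test_that("paired_correlation measures co-occurrence at zero lag", {
  pair <- sim_psc_pair(duration = 20, pair_correlation = 1, noise_sd = 0, seed = 4)
  expect_identical(pair$trace_a$value, pair$trace_b$value)
  pc_self <- paired_correlation(pair$trace_a, pair$trace_a)
  expect_equal(pc_self$r, 1)

  ind <- sim_psc_pair(duration = 30, pair_correlation = 0, noise_sd = 2, seed = 6)
  pc0 <- paired_correlation(ind$trace_a, ind$trace_b)
  expect_lt(abs(pc0$r), 3 / sqrt(pc0$n_bins))

  cor8 <- sim_psc_pair(duration = 30, pair_correlation = 0.8, noise_sd = 2, seed = 6)
  pc8 <- paired_correlation(cor8$trace_a, cor8$trace_b)
  expect_gt(pc8$r, pc0$r)
  expect_true(abs(pc8$r) <= 1)

  # symmetry at zero lag
  expect_equal(paired_correlation(ind$trace_b, ind$trace_a)$r, pc0$r)

  flat <- make_trace(rep(1, 5000), fs = 5000)
  expect_error(paired_correlation(flat, flat), "Zero-variance")
})

test_that("qc_filter applies the holding-current and drift exclusions", {
  rec <- tibble::tibble(
    cell = c("c1", "c2", "c3", "c4"),
    age_class = c("P0", "P15", "P15", "P0"),
    holding_pa = c(-50, -35, -20, -10),
    holding_drift_pct = c(2, 3, 20, 5),
    ir_drift_pct = c(1, 2, 4, 30)
  )
  out <- qc_filter(rec)
  expect_equal(out$decision, c("exclude", "keep", "exclude", "exclude"))
  expect_match(out$reason[1], "holding current beyond 30")
  expect_match(out$reason[3], "holding current drift")
  expect_match(out$reason[4], "input resistance drift")
  # exactly one triggering rule per exclusion
  expect_true(all(is.na(out$reason) == (out$decision == "keep")))

  keepers <- tibble::tibble(age_class = "P15", holding_pa = -20,
                            holding_drift_pct = 5, ir_drift_pct = 5)
  expect_equal(qc_filter(keepers)$decision, "keep")

  expect_error(qc_filter(dplyr::mutate(rec, age_class = NA)), "age_class")
})
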