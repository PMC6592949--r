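test_that("trinarize applies the double-threshold rules with strict inequalities", {
  tr <- make_trace(c(0.2, 0.0, -0.5))
  expect_identical(trinarize(tr)$code, c(1L, 0L, -1L))

  # samples exactly at a threshold fall in the closed zero band
  expect_identical(trinarize(make_trace(c(0.15, -0.4)))$code, c(0L, 0L))

  # already-trinary input is a fixed point
  b <- make_trace(c(1, 0, -1, -1, 1, 0))
  expect_identical(trinarize(b)$code, as.integer(b$value))
  once <- trinarize(tr)
  again <- trinarize(tibble::tibble(time = once$time, value = once$code))
  expect_identical(again$code, once$code)
})

test_that("trinarize validates thresholds and reports the first bad frame", {
  expect_error(trinarize(make_trace(c(0, 1)), upper = -0.5, lower = 0.2),
               "strictly below")
  expect_error(trinarize(make_trace(c(0.2, NA, 0.3))), "frame 2")
  expect_error(trinarize(make_trace(c(Inf, 0))), "frame 1")
})

test_that("smooth_retrinarize keeps constants, zeroes balanced windows, spreads lone codes", {
  const <- make_trinary(rep(1L, 60))
  expect_identical(smooth_retrinarize(const)$code, rep(1L, 60))

  # 12 ones against 12 minus-ones: the two centre frames see a balanced window
  bal <- make_trinary(c(rep(0L, 20), rep(1L, 12), rep(-1L, 12), rep(0L, 20)))
  sm <- smooth_retrinarize(bal)
  expect_identical(sm$code[32:33], c(0L, 0L))

  # a single +1 amid zeros turns positive on exactly the 25 frames whose
  # window covers it (mean 1/25 > 0)
  lone <- make_trinary(c(rep(0L, 49), 1L, rep(0L, 150)))
  sl <- smooth_retrinarize(lone)
  expect_identical(which(sl$code == 1L), 38:62)
  expect_true(all(sl$code[-(38:62)] == 0L))
})

test_that("smooth_retrinarize output is closed over trinary codes and validates input", {
  set.seed(42)
  b <- make_trinary(sample(c(-1L, 0L, 1L), 500, replace = TRUE))
  out <- smooth_retrinarize(b)
  expect_true(all(out$code %in% c(-1L, 0L, 1L)))
  expect_equal(nrow(out), nrow(b))

  expect_error(smooth_retrinarize(b, window = 24), "odd")
  expect_error(smooth_retrinarize(make_trinary(rep(1L, 10))), "window")
  expect_error(smooth_retrinarize(make_trace(c(0.5, 0.2))), "code")
})

test_that("detect_cycles finds one onset per maximal same-sign run", {
  b <- make_trinary(c(0, 1, 1, 0, -1, -1, 0, 1, 1))
  cy <- detect_cycles(b)
  expect_identical(cy$onset[cy$polarity == "positive"], c(2L, 8L))
  expect_identical(cy$onset[cy$polarity == "negative"], 5L)

  expect_equal(nrow(detect_cycles(make_trinary(rep(0L, 10)))), 0)

  # a run touching the first frame counts with onset at frame 1
  head_run <- detect_cycles(make_trinary(c(1, 1, 0)))
  expect_identical(head_run$onset[head_run$polarity == "positive"], 1L)
})

test_that("compute_ici requires an intervening negative cycle", {
  cy <- tibble::tibble(onset = c(2L, 5L, 8L), polarity = c("positive", "negative", "positive"))
  out <- compute_ici(cy, sampling_interval = 0.01)
  expect_equal(out$interval, 0.06)

  # no negative onset between the first positive pair: that pair is skipped
  cy2 <- tibble::tibble(onset = c(2L, 6L, 8L, 10L),
                        polarity = c("positive", "positive", "negative", "positive"))
  out2 <- compute_ici(cy2, sampling_interval = 0.01)
  expect_equal(out2$interval, (10 - 6) * 0.01)

  # fewer than two anchors: empty
  cy3 <- tibble::tibble(onset = 4L, polarity = "positive")
  expect_equal(nrow(compute_ici(cy3, 0.01)), 0)

  # negative basis mirrors the rule
  cy4 <- tibble::tibble(onset = c(2L, 5L, 8L), polarity = c("negative", "positive", "negative"))
  expect_equal(compute_ici(cy4, 0.01, basis = "negative")$interval, 0.06)
})

test_that("every ICI equals a difference of detected onsets, at most n_pos - 1 of them", {
  set.seed(7)
  sim <- sim_breath_trace(intervals = runif(6, 0.3, 0.6), noise_sd = 0.05, seed = 7)
  tr <- smooth_retrinarize(trinarize(sim$trace))
  cy <- detect_cycles(tr)
  ici <- compute_ici(cy, 0.001)
  pos <- cy$onset[cy$polarity == "positive"]
  expect_lte(nrow(ici), length(pos) - 1)
  expect_true(all(ici$onset_from %in% pos) && all(ici$onset_to %in% pos))
  expect_equal(ici$interval, (ici$onset_to - ici$onset_from) * 0.001)
})

test_that("ici_cdf is a right-continuous step table ending at 1", {
  cdf <- ici_cdf(tibble::tibble(interval = c(1, 2, 3)))
  expect_equal(cdf$interval, c(1, 2, 3))
  expect_equal(cdf$cum_prob, c(1 / 3, 2 / 3, 1))

  tied <- ici_cdf(tibble::tibble(interval = rep(0.4, 8)))
  expect_equal(nrow(tied), 1)
  expect_equal(tied$cum_prob, 1)

  expect_error(ici_cdf(tibble::tibble(interval = numeric())), "Empty")
})

test_that("ICI CDF of a large log-normal sample tracks the generating distribution", {
  set.seed(11)
  x <- rlnorm(4000, log(0.35), 0.3)
  cdf <- ici_cdf(tibble::tibble(interval = x))
  theo <- plnorm(cdf$interval, log(0.35), 0.3)
  # Kolmogorov-Smirnov style bound at alpha ~ 0.001 for n = 4000
  expect_lt(max(abs(cdf$cum_prob - theo)), 1.95 / sqrt(4000))
})

test_that("zero-noise cohorts are recovered exactly by the full pipeline", {
  for (seed in 1:3) {
    co <- sim_breath_cohort(n_per_group = 2, duration = 25, noise_sd = 0, seed = seed)
    for (id in co$animals$animal) {
      tr <- smooth_retrinarize(trinarize(co$traces[[id]],
                                         upper = co$params$upper,
                                         lower = co$params$lower),
                               window = co$params$smooth_window)
      cy <- detect_cycles(tr)
      pos <- cy$onset[cy$polarity == "positive"]
      truth <- co$onsets[co$onsets$animal == id, ]
      expect_identical(pos, truth$frame)
      ici <- compute_ici(cy, 1 / co$params$sampling_rate)
      expect_equal(ici$interval, co$ici$interval[co$ici$animal == id])
    }
  }
})

test_that("amplifying the signal never un-crosses a threshold", {
  set.seed(3)
  sim <- sim_breath_trace(intervals = runif(8, 0.25, 0.5), noise_sd = 0.05, seed = 3)
  before <- trinarize(sim$trace)$code
  after <- trinarize(dplyr::mutate(sim$trace, value = value * 2.5))$code
  expect_true(all(after[before == 1L] == 1L))
  expect_true(all(after[before == -1L] == -1L))

  # on a clean signal no cycle is lost (or gained) by amplification
  clean <- sim_breath_trace(intervals = rep(0.5, 5), noise_sd = 0)
  n_cyc <- function(trace) table(detect_cycles(smooth_retrinarize(trinarize(trace)))$polarity)
  expect_identical(n_cyc(dplyr::mutate(clean$trace, value = value * 3)),
                   n_cyc(clean$trace))
})

test_that("breath_ici chains the full pipeline and honors the analysis window", {
  sim <- sim_breath_trace(intervals = rep(0.5, 6), noise_sd = 0)
  full <- breath_ici(sim$trace)
  expect_equal(full$interval, sim$ici$interval)

  # restricting the window drops cycles outside it
  part <- breath_ici(sim$trace, window_s = c(0, 1.5))
  expect_lt(nrow(part), nrow(full))
})
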