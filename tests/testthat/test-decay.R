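test_that("a pure single exponential falls back to a single fit", {
  t <- seq(0, 400, by = 0.04)
  f <- fit_decay(t, exp(-t / 80), fit_start_ms = 0)
  expect_equal(f$fit_kind, "single")
  expect_equal(f$tau_w, 80, tolerance = 0.01)
})

test_that("a planted double exponential recovers the weighted tau exactly", {
  t <- seq(0, 450, by = 0.04)
  y <- 0.5 * exp(-t / 10) + 0.5 * exp(-t / 90)
  f <- fit_decay(t, y, fit_start_ms = 0)
  expect_equal(f$fit_kind, "double")
  expect_equal(f$tau_w, 50, tolerance = 1e-4)
  expect_lt(f$tau1, f$tau2)
  # weighted-tau arithmetic on the recovered components
  expect_equal(f$tau_w, (f$a1 * f$tau1 + f$a2 * f$tau2) / (f$a1 + f$a2))
})

test_that("median weighted tau is recovered within 5% at SNR 20", {
  t <- seq(0, 450, by = 0.04)
  y <- 0.5 * exp(-t / 10) + 0.5 * exp(-t / 90)
  set.seed(1)
  tw <- vapply(1:50, function(i) {
    fit_decay(t, y + rnorm(length(t), sd = 1 / 20), fit_start_ms = 0)$tau_w
  }, numeric(1))
  expect_lt(abs(median(tw) / 50 - 1), 0.05)
})

test_that("negative-going transients are fitted on their own sign", {
  t <- seq(0, 400, by = 0.04)
  f <- fit_decay(t, -3 * exp(-t / 60), fit_start_ms = 0)
  expect_equal(f$tau_w, 60, tolerance = 0.01)
  expect_lt(f$a1, 0)
})

test_that("measure_epsc reports peak, rise, charge and decay", {
  fs <- 25000
  t_s <- (0:11249) / fs
  t0 <- 0.05
  rel <- (t_s - t0) * 1000
  g <- biexp_conductance(rel, 1, 3, 80)
  tr <- tibble::tibble(time_s = t_s, g_nS = g)
  m <- measure_epsc(tr, t0_stim_s = t0)
  expect_equal(m$peak, 1, tolerance = 0.01)
  # analytic integral of the peak-normalised difference of exponentials
  tp <- 3 * 80 / 77 * log(80 / 3)
  N <- 1 / (exp(-tp / 80) - exp(-tp / 3))
  expect_equal(m$charge, N * 77, tolerance = 0.02)
  expect_false(m$low_confidence)
  expect_equal(m$tau_w, 80, tolerance = 0.03)
})

test_that("a linear ramp has a 20-80% rise time of 0.6 of its duration", {
  fs <- 25000
  n <- 5000
  t_s <- (0:(n - 1)) / fs
  t0 <- 0.02
  y <- rep(0, n)
  ramp <- t_s >= t0 & t_s < t0 + 0.001
  y[ramp] <- (t_s[ramp] - t0) / 0.001
  y[t_s >= t0 + 0.001] <- 1            # plateau so smoothing keeps the peak
  m <- measure_epsc(tibble::tibble(time_s = t_s, g_nS = y), t0_stim_s = t0)
  expect_equal(m$rise_20_80_ms, 0.6, tolerance = 0.05)
})

test_that("rectangular pulse charge equals amplitude times duration", {
  fs <- 25000
  n <- 5000
  t_s <- (0:(n - 1)) / fs
  y <- as.numeric(t_s >= 0.05 & t_s < 0.1) * 2   # 2 units for 50 ms
  m <- measure_epsc(tibble::tibble(time_s = t_s, g_nS = y), t0_stim_s = 0.05)
  expect_equal(m$charge, 2 * 50, tolerance = 0.01)
})

test_that("response ratios come out in percent with a log companion", {
  r <- response_ratio(50, 50)
  expect_equal(r$ratio_pct, 100)
  expect_equal(r$log_ratio, 0)
  expect_equal(response_ratio(25, 50)$ratio_pct, 50)
  expect_error(response_ratio(25, 0), "positive")
})
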