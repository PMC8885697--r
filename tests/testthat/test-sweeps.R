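test_that("compensation fraction follows the printed formula and saturates", {
  expect_equal(rs_comp_fraction(3), 0)
  expect_equal(rs_comp_fraction(2), 0)
  expect_equal(rs_comp_fraction(12), 75)
  expect_error(rs_comp_fraction(0), "positive")
  rs <- seq(0.5, 30, by = 0.5)
  f <- rs_comp_fraction(rs)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f[rs <= 3] == 0))
})

test_that("artifact blanking interpolates linearly and only inside the window", {
  n <- 2500
  flat <- make_sweep(rep(0, n), t0 = 0.05)
  expect_equal(blank_stimulus_artifact(flat)$data$current_pA, rep(0, n))

  spik <- flat
  idx <- 1251:1260                       # 0.4 ms spike just after stimulus
  spik$data$current_pA[idx] <- 500
  out <- blank_stimulus_artifact(spik)
  expect_equal(out$data$current_pA, rep(0, n))

  ramp <- make_sweep(seq(0, 100, length.out = n), t0 = 0.05)
  out2 <- blank_stimulus_artifact(ramp)
  expect_equal(out2$data$current_pA, ramp$data$current_pA, tolerance = 1e-12)

  expect_error(blank_stimulus_artifact(flat, window = c(0.09, 0.11)),
               "outside")
})

test_that("series-resistance correction handles identity and the DC case", {
  y <- rep(200, 5000)
  sw <- make_sweep(y, v_hold = 20, rs = 10, cm = 100)
  # rs_final = rs -> fraction 0 -> identity
  expect_identical(correct_series_resistance(sw, rs_final = 10), sw)
  # full compensation of a steady state: I' = I (V-E)/((V-E) - I Rs)
  out <- correct_series_resistance(sw, rs_final = 0)
  mid <- 1000:4000
  expect_equal(out$data$current_pA[mid], rep(200 * 20 / 18, length(mid)),
               tolerance = 1e-6)
})

test_that("unphysical compensation (voltage error >= driving force) errors", {
  sw <- make_sweep(rep(2500, 1000), v_hold = 20, rs = 10, cm = 100)
  expect_error(correct_series_resistance(sw, rs_final = 0), "unphysical")
})

test_that("Ohm's-law conversion and its inverse are exact", {
  sw <- make_sweep(rep(-100, 100), v_hold = -100)
  g <- to_conductance(sw)
  expect_equal(g$g_nS, rep(1, 100))
  sw2 <- make_sweep(rep(20, 100), v_hold = 20)
  expect_equal(to_conductance(sw2)$g_nS, rep(1, 100))
  expect_equal(to_conductance(make_sweep(rep(0, 100)))$g_nS, rep(0, 100))
  swv <- make_sweep(rep(1, 100), v_hold = 0)
  expect_error(to_conductance(swv), "driving force")
})

test_that("AMPA/NMDA separation is exact subtraction", {
  t_ms <- seq(-10, 200, by = 0.04)
  ga <- biexp_conductance(t_ms, 2, 0.3, 3)
  gn <- biexp_conductance(t_ms, 1.5, 3, 80)
  g100 <- tibble::tibble(time_s = t_ms / 1000, g_nS = ga)
  g20 <- tibble::tibble(time_s = t_ms / 1000, g_nS = ga + gn)
  out <- split_ampa_nmda(g100, g20)
  expect_equal(out$ampa$g_nS, ga)
  expect_equal(out$nmda$g_nS, gn, tolerance = 1e-12)
  expect_equal(split_ampa_nmda(g100, g100)$nmda$g_nS, rep(0, length(t_ms)))
  expect_error(split_ampa_nmda(g100, g20[-1, ]), "length")
})

test_that("averaging baselines, averages, and suppresses noise like 1/sqrt(N)", {
  n <- 5000
  tmpl <- c(rep(0, 1500), 100 * exp(-(1:(n - 1500)) / 800))
  one <- make_sweep(tmpl + 7)            # constant offset removed by baseline
  avg1 <- average_sweeps(list(one))
  expect_equal(avg1$data$current_pA, tmpl, tolerance = 1e-10)

  two <- average_sweeps(list(make_sweep(tmpl), {
    s <- make_sweep(-tmpl); s
  }))
  expect_equal(two$data$current_pA, rep(0, n), tolerance = 1e-10)

  set.seed(1)
  rms <- sapply(c(4, 64), function(N) {
    sweeps <- lapply(seq_len(N), function(i)
      make_sweep(tmpl + rnorm(n, sd = 10)))
    sqrt(mean((average_sweeps(sweeps)$data$current_pA - tmpl)^2))
  })
  expect_equal(rms[1] / rms[2], 4, tolerance = 0.5)

  expect_error(average_sweeps(list(make_sweep(tmpl, v_hold = -100),
                                   make_sweep(tmpl, v_hold = 20))),
               "V_hold")
})
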