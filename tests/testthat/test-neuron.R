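# the reduced model used throughout: shipped defaults
test_that("the shipped model rests stably near -65 mV", {
  m <- build_model()
  vr <- validate_rest(m)
  expect_lt(abs(vr + 65), 5)
})

test_that("passive soma follows the R_m C_m membrane time constant", {
  mp <- build_model(densities = passive_densities(), e_leak_mV = -65)
  tr <- run_step_current(mp, amp_nA = -0.05, t_on_ms = 100, t_off_ms = 500,
                         t_stop_ms = 600)
  v0 <- mean(tr$v_soma[tr$t_ms > 90 & tr$t_ms < 100])
  vss <- mean(tr$v_soma[tr$t_ms > 480 & tr$t_ms < 500])
  idx <- which(tr$t_ms >= 100 & tr$t_ms <= 500)
  frac <- (tr$v_soma[idx] - v0) / (vss - v0)
  tau63 <- tr$t_ms[idx][which(frac >= 0.632)[1]] - 100
  # R_m = 1/g_leak = 10 kOhm cm2, C_m = 1 uF/cm2 -> tau_m = 10 ms
  expect_equal(tau63, 10, tolerance = 0.05 * 10)
})

test_that("doubling the leak halves the input resistance (isopotential limit)", {
  rin <- sapply(c(1e-4, 2e-4), function(gl) {
    # a stubby cable keeps the cell effectively isopotential
    mp <- build_model(apical_length_um = 20, apical_diam_um = 2, n_apical = 4,
                      densities = passive_densities(gl), e_leak_mV = -65)
    tr <- run_step_current(mp, amp_nA = -0.05, t_on_ms = 100, t_off_ms = 500,
                           t_stop_ms = 600)
    v0 <- mean(tr$v_soma[tr$t_ms > 90 & tr$t_ms < 100])
    vss <- mean(tr$v_soma[tr$t_ms > 480 & tr$t_ms < 500])
    (vss - v0) / (-0.05)
  })
  expect_equal(rin[2] / rin[1], 0.5, tolerance = 0.05)
})

test_that("no input leaves the membrane potential flat", {
  m <- build_model()
  tr <- run_step_current(m, amp_nA = 0, t_stop_ms = 1000)
  late <- tr$v_soma[tr$t_ms > 500]
  expect_lt(diff(range(late)), 0.05)
})

test_that("synapse placement is uniform along the cable and seed-deterministic", {
  m <- build_model()
  a <- place_synapses(m, 50, seed = 3)
  b <- place_synapses(m, 50, seed = 3)
  expect_identical(a$syn_pos_um, b$syn_pos_um)
  one <- place_synapses(m, 1, seed = 1)
  expect_true(one$syn_pos_um >= 0 && one$syn_pos_um <= 800)
  big <- place_synapses(m, 10000, seed = 5)
  ks <- suppressWarnings(stats::ks.test(big$syn_pos_um, "punif", 0, 800))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero synapses give a flat trace and no spikes", {
  m <- build_model()
  r <- run_train(m, stim_protocol(n_syn = 0, freq_hz = 200, tail_ms = 50),
                 seed = 1)
  expect_equal(count_spikes(r$trace$v_soma, r$trace$t_ms), 0)
  expect_lt(diff(range(r$trace$v_soma[r$trace$t_ms > 20])), 0.2)
})

test_that("a subthreshold NMDA-only synapse follows the driving-force-weighted biexponential", {
  d <- passive_densities(leak = 0.01)     # strong leak approximates a clamp
  mv <- build_model(densities = d, e_leak_mV = -65)
  r <- run_train(mv, stim_protocol(n_syn = 1, freq_hz = 200, n_stim = 1,
                                   tail_ms = 300),
                 synapse_spec(1, ampa_gmax_nS = 0), seed = 2)
  tr <- r$trace
  t0 <- r$protocol$stim_ms[1]
  vrest <- mean(tr$v_soma[tr$t_ms < t0])
  pred <- biexp_conductance(tr$t_ms - t0, 1, 3, 80) * 1e-3 *
    mg_block_factor(vrest) * (vrest - 0)
  sel <- tr$t_ms > t0
  err <- max(abs(tr$i_nmda[sel] - pred[sel])) / max(abs(pred))
  expect_lt(err, 0.05)
})

test_that("identical seed and spec reproduce the simulation bit for bit", {
  m <- build_model()
  r1 <- run_train(m, stim_protocol(40, 200), synapse_spec(1.5), seed = 4)
  r2 <- run_train(m, stim_protocol(40, 200), synapse_spec(1.5), seed = 4)
  expect_identical(r1$trace, r2$trace)
  expect_identical(spine_summaries(r1), spine_summaries(r2))
})

test_that("spike counting respects threshold and refractory period", {
  t <- seq(0, 100, by = 0.1)
  expect_equal(count_spikes(rep(-65, length(t)), t), 0)
  # three separated 1 ms spikes
  vm <- rep(-65, length(t))
  for (tc in c(20, 40, 60)) vm[t >= tc & t < tc + 1] <- 30
  expect_equal(count_spikes(vm, t), 3)
  # 5 sinusoid cycles with 2 ms spacing between crossings
  t2 <- seq(0, 10, by = 0.01)
  vs <- 20 * sin(2 * pi * t2 / 2) - 5
  expect_equal(count_spikes(vs, t2), 5)
})

test_that("summaries integrate by the trapezoid rule above rest", {
  m <- build_model()
  r <- run_train(m, stim_protocol(40, 200), synapse_spec(1), seed = 1)
  s <- spine_summaries(r)
  tr <- r$trace
  t0 <- r$protocol$stim_ms[1]
  post <- tr$t_ms >= t0
  ca0 <- mean(tr$ca_spine[tr$t_ms < t0])
  manual <- sum(diff(tr$t_ms[post]) *
                  (head(tr$ca_spine[post] - ca0, -1) +
                     tail(tr$ca_spine[post] - ca0, -1)) / 2)
  expect_equal(s$spine_ca_int_uM_ms, manual, tolerance = 1e-12)
  expect_gte(s$peak_ca_uM, ca0)
})

test_that("quiescent simulations have zero summary integrals", {
  m <- build_model()
  r <- run_train(m, stim_protocol(n_syn = 0, freq_hz = 20, tail_ms = 50),
                 seed = 1)
  s <- spine_summaries(r)
  expect_equal(s$spike_count, 0)
  expect_lt(abs(s$soma_vm_int_mV_ms), 5)
})

test_that("currentscape shares are normalised within direction", {
  m <- build_model()
  r <- run_train(m, stim_protocol(40, 200), synapse_spec(1), seed = 1)
  cs <- currentscape(r)
  sums <- dplyr::summarise(
    dplyr::group_by(cs[cs$i_nA != 0, ], .data$t_ms, .data$direction),
    s = sum(.data$share), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(cs$share >= 0 & cs$share <= 1))
})

test_that("NMDA inward share grows across a 200 Hz WT train", {
  m <- build_model()
  r <- run_train(m, stim_protocol(40, 200), synapse_spec(1), seed = 1)
  tr <- r$trace
  stim <- r$protocol$stim_ms
  share_at <- function(tm) {
    i <- which.min(abs(tr$t_ms - tm))
    inward <- c(ampa = min(tr$i_ampa[i], 0), nmda = min(tr$i_nmda[i], 0),
                car = min(tr$i_car[i], 0))
    abs(inward["nmda"]) / sum(abs(inward))
  }
  # compare just before the 2nd and just after the last stimulus
  expect_gt(share_at(stim[5] + 2), share_at(stim[2] - 1))
})

test_that("synaptic charge balances capacitive plus leak charge when passive", {
  mp <- build_model(densities = passive_densities(), e_leak_mV = -65)
  r <- run_train(mp, stim_protocol(n_syn = 1, freq_hz = 200, n_stim = 1,
                                   tail_ms = 400), synapse_spec(1), seed = 1)
  residual <- abs(r$q_syn + r$q_cap + r$q_leak) / abs(r$q_syn)
  expect_lt(residual, 1e-6)
})

test_that("the experiment grid is complete, matched by seed, and consistent", {
  m <- build_model()
  grid <- run_experiment_grid(genotypes = c(1, 2), n_syn = 40,
                              freqs_hz = 200, seeds = 1:2, model = m)
  expect_equal(nrow(grid), 4)
  # k = 1 rows duplicate a direct run with the same seed
  direct <- spine_summaries(run_train(m, stim_protocol(40, 200),
                                      synapse_spec(1), seed = 1))
  row1 <- grid[grid$kinetic_scale == 1 & grid$seed == 1, names(direct)]
  expect_equal(as.data.frame(row1), as.data.frame(direct))
  # same seed -> same placement across genotypes
  p1 <- place_synapses(m, 40, seed = 2)
  p2 <- place_synapses(m, 40, seed = 2)
  expect_identical(p1$syn_pos_um, p2$syn_pos_um)
})
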