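test_that("generators are pure functions of their seed", {
  a <- gen_mutation_table(seed = 11)
  b <- gen_mutation_table(seed = 11)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth, b$truth)

  pa <- gen_epsc_pair(seed = 12, n_sweeps = 2, v_hold_mV = c(-100, 20))
  pb <- gen_epsc_pair(seed = 12, n_sweeps = 2, v_hold_mV = c(-100, 20))
  expect_identical(pa$sweeps$data[[1]]$data, pb$sweeps$data[[1]]$data)
})

test_that("noiseless well-separated generator output is classified exactly", {
  skip_if_not_installed("mclust")
  # tight clusters at the default 4 centres, no noise, nothing missing:
  # both factors carry real between-cluster signal
  gen <- gen_mutation_table(noise_sd = 0, missing_fraction = 0,
                            cluster_sd = 0.08, seed = 21)
  fm <- fit_factors(normalize_log(gen$table))
  cl <- kmeans_cluster(fm$scores, 4, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$labels, gen$truth$cluster), 1)
})

test_that("large-n generated scores carry the planted correlation sign", {
  gen <- gen_mutation_table(n_mutations = 200, factor_correlation = 0.5,
                            missing_fraction = 0, seed = 22)
  tau <- kendall_tau_b(gen$truth$factor1, gen$truth$factor2)
  expect_gt(tau, 0)
})

test_that("forward distortion vanishes as rs approaches zero", {
  y <- biexp_conductance(seq(-50, 350, by = 0.04), 2, 3, 80) * 20
  sw <- make_sweep(y, v_hold = 20, rs = 10, cm = 100)
  out <- forward_rs_distort(sw, rs_MOhm = 1e-9, cm_pF = 100)
  expect_equal(out$data$current_pA, y, tolerance = 1e-6)
})

test_that("forward distortion inverts the DC correction example", {
  sw <- make_sweep(rep(222.2222, 2000), v_hold = 20, rs = 10, cm = 100)
  out <- forward_rs_distort(sw)
  expect_equal(out$data$current_pA[1500], 200, tolerance = 1e-3)
})

test_that("idealised noiseless pairs split exactly into their generators", {
  pair <- gen_epsc_pair(noise_sd_pA = 0, artifact_pA = 0, distort = FALSE,
                        mg = "ideal", filter_hz = NULL, n_sweeps = 1, seed = 1)
  sw <- pair$sweeps
  pick <- function(cell, vh) {
    sw$data[[which(sw$cell == cell & sw$v_hold_mV == vh)[1]]]
  }
  comp <- split_ampa_nmda(to_conductance(pick("untransfected", -100)),
                          to_conductance(pick("untransfected", 20)))
  tg <- pair$truth$conductances$untransfected
  expect_lt(max(abs(comp$ampa$g_nS - tg$g_ampa_nS)), 1e-9)
  expect_lt(max(abs(comp$nmda$g_nS - tg$g_nmda_nS)), 1e-9)
})

test_that("charge-matched transfected cells show ~100% NMDA charge ratio", {
  # long sweeps so the slowed transfected decay is fully integrated
  pair <- gen_epsc_pair(kinetic_scale = 2, noise_sd_pA = 0, artifact_pA = 0,
                        distort = FALSE, mg = "ideal", filter_hz = NULL,
                        n_sweeps = 1, duration_s = 1.2, seed = 2)
  m <- process_pair(pair, rs_final = Inf)    # no correction applied
  nm <- m[m$component == "nmda", ]
  ratio <- response_ratio(nm[nm$cell == "transfected", ],
                          nm[nm$cell == "untransfected", ], "charge")
  expect_equal(ratio$ratio_pct, 100, tolerance = 2)
})
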