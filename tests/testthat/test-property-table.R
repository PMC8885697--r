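test_that("property CSV round-trips with EC50-to-potency conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_property_csv(path, tibble::tibble(
    mutation = c("WT", "M1", "M2"),
    glu_ec50_uM = c(3.5, 35, 0.35), gly_ec50_uM = c(1.1, 1.1, 1.1),
    deact_tau_ms = c(50, 100, 25), current_density_pA_pF = c(150, 15, 300),
    open_prob = c(0.5, 0.25, 0.5), surface_rel = c(1, 0.5, 1)))
  tbl <- read_property_table(path)
  expect_s3_class(tbl, "property_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$glu_potency[tbl$mutation == "M1"], 1 / 35)
  expect_false(any(missing_mask(tbl)))
})

test_that("empty cells become missing and are flagged", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_property_csv(path, tibble::tibble(
    mutation = c("WT", "M1"),
    glu_ec50_uM = c(3.5, NA), gly_ec50_uM = c(1.1, 1.1),
    deact_tau_ms = c(50, 100), current_density_pA_pF = c(150, 15),
    open_prob = c(0.5, 0.25), surface_rel = c(1, 0.5)))
  tbl <- read_property_table(path)
  m <- missing_mask(tbl)
  expect_true(m["M1", "glu_potency"])
  expect_equal(sum(m), 1)
})

test_that("non-positive values and missing WT are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_property_csv(path, tibble::tibble(
    mutation = c("WT", "M1"),
    glu_ec50_uM = c(3.5, 2), gly_ec50_uM = c(1.1, 1.1),
    deact_tau_ms = c(50, 0), current_density_pA_pF = c(150, 15),
    open_prob = c(0.5, 0.25), surface_rel = c(1, 0.5)))
  expect_error(read_property_table(path), "deact_tau.*M1")

  df <- tibble::tibble(mutation = "M1", glu_potency = 1, gly_potency = 1,
                       deact_tau = 50, current_density = 100, open_prob = 0.5,
                       surface_level = 1)
  expect_error(as_property_table(df), "WT")
})

test_that("potency proxy scaling follows the opening-frequency/surface rule", {
  expect_equal(approximate_potency_from_proxy(2, 10, 1, 10, 1), 2)
  expect_equal(approximate_potency_from_proxy(2, 10, 1, 5, 1), 1)
  expect_equal(approximate_potency_from_proxy(2, 10, 1, 5, 0.5), 2)
  expect_error(approximate_potency_from_proxy(2, 0, 1, 5, 0.5), "positive")
})

test_that("log-ratio normalisation is zero at WT and decade-scaled", {
  tbl <- make_property_table(list(
    M1 = c(1, 1, 1, 1, 1, 1),                # identical to WT
    M2 = c(1, 1, 1, 100, 1, 1),              # 100x current density
    M3 = c(0.1, 1, 1, 1, 1, 1)))             # 10x larger glutamate EC50
  lr <- normalize_log(tbl)
  expect_equal(unlist(lr[lr$mutation == "WT", prop_cols]),
               setNames(rep(0, 6), prop_cols))
  expect_equal(unlist(lr[lr$mutation == "M1", prop_cols]),
               setNames(rep(0, 6), prop_cols))
  expect_equal(lr$current_density[lr$mutation == "M2"], 2)
  expect_equal(lr$glu_potency[lr$mutation == "M3"], -1)
})
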