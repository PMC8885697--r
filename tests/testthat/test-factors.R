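test_that("KMO equals 1/2 for two variables", {
  # with p = 2 the partial correlation equals the correlation, so the
  # anti-image terms tie the numerator exactly
  set.seed(1)
  df <- tibble::tibble(a = rnorm(30))
  df$b <- 0.6 * df$a + rnorm(30, sd = 0.5)
  expect_equal(kmo_statistic(df), 0.5, tolerance = 1e-12)
})

test_that("KMO approaches 1 under a strong single common factor", {
  set.seed(2)
  f <- rnorm(500)
  df <- tibble::as_tibble(setNames(
    lapply(1:6, function(i) f + rnorm(500, sd = 0.3)), letters[1:6]))
  expect_gt(kmo_statistic(df), 0.9)
})

test_that("constant columns make KMO undefined", {
  df <- tibble::tibble(a = rnorm(10), b = rep(1, 10))
  expect_error(suppressWarnings(kmo_statistic(df)), "constant|singular")
})

test_that("exact 2-D data yields variance fractions summing to one", {
  set.seed(3)
  f <- matrix(rnorm(40), ncol = 2)
  L <- matrix(runif(12, -1, 1), ncol = 2)
  X <- f %*% t(L)
  colnames(X) <- prop_cols
  lr <- structure(dplyr::bind_cols(tibble::tibble(mutation = paste0("M", 1:20)),
                                   tibble::as_tibble(X)),
                  class = c("log_ratio_table", "tbl_df", "tbl", "data.frame"))
  fm <- fit_factors(lr)
  expect_equal(sum(fm$variance_fraction), 1, tolerance = 1e-10)
})

test_that("variance fractions equal eigenvalues over trace", {
  gen <- gen_mutation_table(seed = 4, missing_fraction = 0)
  lr <- normalize_log(gen$table)
  fm <- fit_factors(lr)
  R <- cor(as.matrix(lr[lr$mutation != "WT", prop_cols]))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fm$variance_fraction, ev[1:2] / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(fm$variance_fraction) <= 0))
})

test_that("varimax rotation preserves communalities", {
  gen <- gen_mutation_table(seed = 6, missing_fraction = 0)
  fm <- fit_factors(normalize_log(gen$table), rotation = "varimax")
  expect_equal(rowSums(fm$pattern^2), rowSums(fm$loadings^2),
               tolerance = 1e-8)
})

test_that("unrotated loading columns are orthogonal", {
  gen <- gen_mutation_table(seed = 6, missing_fraction = 0)
  fm <- fit_factors(normalize_log(gen$table))
  ip <- crossprod(fm$loadings)
  expect_equal(ip[1, 2], 0, tolerance = 1e-10)
})

test_that("requesting components beyond the matrix rank errors", {
  gen <- gen_mutation_table(seed = 6, missing_fraction = 0)
  expect_error(fit_factors(normalize_log(gen$table), n_components = 7),
               "exceeds")
})

test_that("promax is available as the oblique option", {
  gen <- gen_mutation_table(seed = 8, missing_fraction = 0)
  fm <- fit_factors(normalize_log(gen$table), rotation = "promax")
  expect_equal(fm$rotation, "promax")
  expect_equal(dim(fm$pattern), c(6L, 2L))
})

test_that("tidy/glance/augment follow broom conventions", {
  gen <- gen_mutation_table(seed = 9, missing_fraction = 0)
  fm <- fit_factors(normalize_log(gen$table))
  td <- tidy(fm)
  expect_named(td, c("property", "factor", "loading"))
  expect_equal(nrow(td), 12)
  gl <- glance(fm)
  expect_equal(gl$n, 20)
  expect_true(gl$kmo > 0 && gl$kmo < 1)
  cl <- kmeans_cluster(fm$scores, 4, seed = 1)
  au <- augment(fm, cl)
  expect_true(all(c("mutation", "factor1", "factor2", "cluster") %in%
                    names(au)))
  expect_s3_class(autoplot(fm, cl), "ggplot")
})
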