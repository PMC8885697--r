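#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation computed by exact pair counting:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where C and D are concordant
#' and discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` are the tied
#' pair counts of each variable.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return tau-b in \[-1, 1\]. Errors if either vector is constant (all pairs
#'   tied), where tau-b is undefined.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least two observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  cpp_kendall_tau_b(as.numeric(x), as.numeric(y))
}

#' Double-bootstrap-calibrated BCa confidence interval
#'
#' Bias-corrected and accelerated (BCa) bootstrap confidence interval for a
#' statistic of paired data, with its central coverage calibrated by an inner
#' (second-level) bootstrap to reduce small-sample bias. For each of `n_outer`
#' first-level resamples an inner bootstrap of `n_inner` resamples evaluates
#' the empirical CDF at the original point estimate; the resulting u-values
#' give the actual coverage of nominal-level percentile intervals,
#' `coverage(lambda) = P(lambda/2 <= u <= 1 - lambda/2)`, and the calibrated
#' level is found by monotone interpolation of this coverage curve at the
#' requested level. The BCa interval is then read from the first-level
#' bootstrap distribution at the calibrated level, with the bias correction
#' `z0` taken from the bootstrap CDF at the point estimate and the
#' acceleration from jackknife skewness.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param statistic `"tau_b"` (default; fast compiled path) or a function
#'   `f(x, y)` returning a scalar.
#' @param n_outer,n_inner First- and second-level resample counts
#'   (defaults 20000 and 200).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% interval).
#' @param seed Integer seed (all resampling is deterministic given it).
#' @param calibrate Set `FALSE` to skip the inner bootstrap and return the
#'   plain BCa interval.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `level_nominal`, `level_calibrated`, `n`.
#' @export
double_bootstrap_bca_ci <- function(x, y, statistic = "tau_b",
                                    n_outer = 20000, n_inner = 200,
                                    alpha = 0.05, seed = 1,
                                    calibrate = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 pairs")
  if (!calibrate) n_inner <- 0

  set.seed(seed)
  if (identical(statistic, "tau_b")) {
    bb <- cpp_double_boot_tau(as.numeric(x), as.numeric(y), n_outer, n_inner)
  } else {
    stopifnot(is.function(statistic))
    bb <- r_double_boot(x, y, statistic, n_outer, n_inner)
  }
  t0 <- bb$t0
  tb <- bb$t_boot[is.finite(bb$t_boot)]
  if (length(tb) < n_outer * 0.5) {
    abort("statistic undefined on most bootstrap resamples")
  }

  # degenerate statistic: all resamples equal the estimate -> zero-width CI
  if (max(tb) - min(tb) == 0) {
    return(tibble::tibble(estimate = t0, ci_low = t0, ci_high = t0,
                          p_value = NA_real_, level_nominal = 1 - alpha,
                          level_calibrated = 1 - alpha, n = n))
  }

  lambda <- alpha
  tj <- bb$t_jack[is.finite(bb$t_jack)]
  if (calibrate) {
    u <- bb$u[is.finite(bb$u)]
    # actual coverage of the BCa interval at nominal miss probability l: the
    # interval from an outer resample covers t0 exactly when the resample's
    # inner CDF value at t0 falls between the BCa-adjusted quantile levels
    lam_grid <- seq(0.001, 0.5, by = 0.001)
    cov_grid <- vapply(lam_grid, function(l) {
      al <- bca_levels(t0, tb, tj, l)
      mean(u >= al[1] & u <= al[2])
    }, numeric(1))
    ok <- !duplicated(cov_grid)
    lambda <- approx(cov_grid[ok], lam_grid[ok], xout = 1 - alpha,
                     rule = 2)$y
    lambda <- min(max(lambda, 1e-4), 0.5)
  }

  ci <- bca_interval(t0, tb, tj, lambda)

  # two-sided bootstrap p-value for the null statistic value 0
  p_lo <- (sum(tb <= 0) + 1) / (length(tb) + 1)
  p_hi <- (sum(tb >= 0) + 1) / (length(tb) + 1)
  p <- min(1, 2 * min(p_lo, p_hi))

  tibble::tibble(estimate = t0, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 level_nominal = 1 - alpha, level_calibrated = 1 - lambda,
                 n = n)
}

# BCa-adjusted quantile levels (bias correction from the bootstrap CDF at the
# estimate, acceleration from jackknife skewness)
bca_levels <- function(t0, t_boot, t_jack, alpha) {
  b <- length(t_boot)
  prop <- (sum(t_boot < t0) + 0.5 * sum(t_boot == t0)) / b
  prop <- min(max(prop, 1 / (b + 1)), b / (b + 1))
  z0 <- qnorm(prop)
  tm <- mean(t_jack)
  num <- sum((tm - t_jack)^3)
  den <- 6 * (sum((tm - t_jack)^2))^1.5
  a <- if (den > 0) num / den else 0
  zl <- qnorm(alpha / 2)
  zh <- qnorm(1 - alpha / 2)
  c(pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl))),
    pnorm(z0 + (z0 + zh) / (1 - a * (z0 + zh))))
}

bca_interval <- function(t0, t_boot, t_jack, alpha) {
  al <- bca_levels(t0, t_boot, t_jack, alpha)
  as.numeric(quantile(t_boot, al, type = 6, names = FALSE))
}

# pure-R double bootstrap for user-supplied statistics
r_double_boot <- function(x, y, statistic, n_outer, n_inner) {
  n <- length(x)
  t0 <- statistic(x, y)
  t_boot <- numeric(n_outer)
  u <- rep(NA_real_, n_outer)
  for (b in seq_len(n_outer)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    t_boot[b] <- tryCatch(statistic(xb, yb), error = function(e) NA_real_)
    if (n_inner > 0) {
      t2 <- numeric(n_inner)
      for (cc in seq_len(n_inner)) {
        j <- sample.int(n, n, replace = TRUE)
        t2[cc] <- tryCatch(statistic(xb[j], yb[j]), error = function(e) NA_real_)
      }
      t2 <- t2[is.finite(t2)]
      if (length(t2) > 0) {
        u[b] <- (sum(t2 < t0) + 0.5 * sum(t2 == t0)) / length(t2)
      }
    }
  }
  t_jack <- vapply(seq_len(n), function(i) {
    tryCatch(statistic(x[-i], y[-i]), error = function(e) NA_real_)
  }, numeric(1))
  list(t0 = t0, t_boot = t_boot, u = u, t_jack = t_jack)
}

#' Kendall tau-b with calibrated bootstrap CI
#'
#' Convenience wrapper pairing [kendall_tau_b()] with
#' [double_bootstrap_bca_ci()], as used to annotate factor-score correlations.
#'
#' @inheritParams double_bootstrap_bca_ci
#' @return One-row tibble as in [double_bootstrap_bca_ci()], with the tau-b
#'   point estimate in `estimate`.
#' @export
correlate_scores <- function(x, y, n_outer = 20000, n_inner = 200,
                             alpha = 0.05, seed = 1) {
  double_bootstrap_bca_ci(x, y, statistic = "tau_b", n_outer = n_outer,
                          n_inner = n_inner, alpha = alpha, seed = seed)
}
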