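#' Fit the decay of an EPSC
#'
#' Fits `a1 exp(-t/tau1) + a2 exp(-t/tau2) + c` (or a single exponential plus
#' offset) to the decay phase, by bounded least squares seeded with a fast
#' non-iterative estimate (log-linear tail regression for the slow component,
#' separable linear amplitudes). A two-component fit is declared failed -- and
#' automatically refit with a single exponential -- when any amplitude comes
#' out negative, the time constants separate by less than 1.5-fold, or the
#' optimiser does not converge.
#'
#' The weighted time constant is the sum of component time constants weighted
#' by their fractional amplitudes: `tau_w = (a1 tau1 + a2 tau2) / (a1 + a2)`.
#'
#' @param time_ms Time base (ms), same length as `y`.
#' @param y Trace (current or conductance), baseline-zeroed.
#' @param fit_start_ms Start of the fit window, normally the peak time.
#'   Defaults to the time of the absolute extremum.
#' @param model `"double"` (default, with single-exponential fallback) or
#'   `"single"`.
#' @return One-row tibble: `a1`, `tau1`, `a2`, `tau2`, `c0`, `tau_w`,
#'   `fit_kind` ("double" or "single"), `converged`.
#' @export
fit_decay <- function(time_ms, y, fit_start_ms = NULL,
                      model = c("double", "single")) {
  model <- match.arg(model)
  stopifnot(length(time_ms) == length(y))
  if (is.null(fit_start_ms)) fit_start_ms <- time_ms[which.max(abs(y))]
  keep <- time_ms >= fit_start_ms
  if (sum(keep) < 50) abort("fewer than 50 samples in the fit window")
  t <- time_ms[keep] - fit_start_ms
  s <- sign(y[keep][1])
  if (s == 0) s <- sign(y[which.max(abs(y))])
  yy <- s * y[keep]                       # decays from a positive peak

  single <- fit_single_exp(t, yy)
  if (model == "single") return(decay_result(single, s, kind = "single"))

  dbl <- fit_double_exp(t, yy, single)
  if (is.null(dbl)) {
    decay_result(single, s, kind = "single")
  } else {
    decay_result(dbl, s, kind = "double")
  }
}

# non-iterative seed + nlsLM refinement, single exponential with offset
fit_single_exp <- function(t, y) {
  c0 <- mean(tail(y, max(5, round(length(y) * 0.05))))
  z <- y - c0
  pos <- z > max(z) * 0.01
  tau0 <- if (sum(pos) > 5) {
    fit <- lm(log(z[pos]) ~ t[pos])
    max(-1 / coef(fit)[2], diff(range(t)) / 50)
  } else {
    diff(range(t)) / 5
  }
  a0 <- max(z[1], max(z) * 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c0f,
                      start = list(a = a0, tau = tau0, c0f = c0),
                      lower = c(0, 1e-3, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(a = c(a0), tau = c(tau0), c0 = c0, converged = FALSE)
  } else {
    cf <- coef(fit)
    list(a = unname(cf["a"]), tau = unname(cf["tau"]), c0 = unname(cf["c0f"]),
         converged = TRUE)
  }
}

fit_double_exp <- function(t, y, single) {
  tau2_0 <- single$tau * 1.5
  tau1_0 <- single$tau / 5
  # separable linear amplitudes at the seed time constants
  X <- cbind(exp(-t / tau1_0), exp(-t / tau2_0), 1)
  ab <- tryCatch(qr.solve(X, y), error = function(e) c(single$a / 2,
                                                       single$a / 2,
                                                       single$c0))
  a1_0 <- max(ab[1], 1e-6); a2_0 <- max(ab[2], 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c0f,
                      start = list(a1 = a1_0, tau1 = tau1_0, a2 = a2_0,
                                   tau2 = tau2_0, c0f = ab[3]),
                      lower = c(0, 1e-3, 0, 1e-3, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  a <- c(cf["a1"], cf["a2"]); tau <- c(cf["tau1"], cf["tau2"])
  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]
  if (any(a < 0) || tau[2] / tau[1] < 1.5) return(NULL)
  # a component carrying <0.1% of amplitude is a degenerate double fit
  if (min(a) / sum(a) < 1e-3) return(NULL)
  # a time constant longer than half the fit window cannot be estimated
  if (tau[2] > diff(range(t)) / 2) return(NULL)
  list(a = unname(a), tau = unname(tau), c0 = unname(cf["c0f"]),
       converged = TRUE)
}

decay_result <- function(fit, s, kind) {
  if (kind == "double") {
    a1 <- fit$a[1]; a2 <- fit$a[2]; tau1 <- fit$tau[1]; tau2 <- fit$tau[2]
    tau_w <- (a1 * tau1 + a2 * tau2) / (a1 + a2)
  } else {
    a1 <- fit$a[1]; a2 <- NA_real_; tau1 <- fit$tau[1]; tau2 <- NA_real_
    tau_w <- tau1
  }
  tibble::tibble(a1 = s * a1, tau1 = tau1, a2 = s * a2, tau2 = tau2,
                 c0 = s * fit$c0, tau_w = tau_w, fit_kind = kind,
                 converged = fit$converged)
}

#' Measure an EPSC transient
#'
#' Computes the standard descriptors of a baseline-zeroed synaptic transient:
#' peak amplitude (extremum after the stimulus, read from a 0.5 ms
#' boxcar-smoothed copy to suppress single-sample noise), 20-80% rise time
#' (linear interpolation between samples on the rising phase), charge
#' (trapezoidal integral from stimulus onset to the end of the sweep), and the
#' decay fit from [fit_decay()].
#'
#' @param trace A conductance tibble from [to_conductance()] /
#'   [split_ampa_nmda()], a `sweep`, or a data frame with `time_s` and one
#'   value column.
#' @param t0_stim_s Stimulus onset; taken from the trace attributes if absent.
#' @param peak_window_ms Upper bound of the peak search window, in ms after
#'   the stimulus (a cursor setting; default `Inf` searches the whole sweep).
#' @return One-row tibble: `peak`, `t_peak_ms`, `rise_20_80_ms`, `charge`
#'   (value units x ms), decay-fit columns, and `low_confidence` (TRUE when
#'   the peak is within 3 baseline SDs of noise).
#' @export
measure_epsc <- function(trace, t0_stim_s = NULL, peak_window_ms = Inf) {
  if (inherits(trace, "sweep")) {
    t0_stim_s <- t0_stim_s %||% trace$t0_stim_s
    df <- trace$data
    val <- df$current_pA
  } else {
    t0_stim_s <- t0_stim_s %||% attr(trace, "t0_stim_s") %||% 0
    df <- trace
    vcol <- setdiff(names(df), "time_s")[1]
    val <- df[[vcol]]
  }
  tt <- df$time_s
  fs <- 1 / (tt[2] - tt[1])

  post <- tt >= t0_stim_s
  pre <- tt < t0_stim_s
  noise_sd <- if (any(pre)) sd(val[pre]) else 0

  # peak on a 0.5 ms boxcar-smoothed copy
  w <- max(1, round(0.0005 * fs))
  sm <- stats::filter(val, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- val[is.na(sm)]
  sm_post <- sm[post]; t_post <- tt[post]
  in_win <- (t_post - t0_stim_s) * 1000 <= peak_window_ms
  ipk <- which.max(abs(sm_post) * in_win)
  peak <- as.numeric(sm_post[ipk])
  t_peak_s <- t_post[ipk]

  low_conf <- is.finite(noise_sd) && noise_sd > 0 && abs(peak) < 3 * noise_sd

  # 20-80% rise time with linear interpolation, on the rising phase
  sgn <- sign(peak)
  ys <- sgn * as.numeric(sm_post[seq_len(ipk)])
  ts <- t_post[seq_len(ipk)]
  th20 <- 0.2 * abs(peak); th80 <- 0.8 * abs(peak)
  t20 <- cross_time(ts, ys, th20)
  t80 <- cross_time(ts, ys, th80)
  rise_ms <- if (is.na(t20) || is.na(t80)) NA_real_ else (t80 - t20) * 1000

  # trapezoidal charge from stimulus onset to sweep end
  charge <- trapz(tt[post] * 1000, val[post])   # units x ms

  dec <- fit_decay((tt - t0_stim_s) * 1000, val,
                   fit_start_ms = (t_peak_s - t0_stim_s) * 1000)

  dplyr::bind_cols(
    tibble::tibble(peak = peak, t_peak_ms = (t_peak_s - t0_stim_s) * 1000,
                   rise_20_80_ms = rise_ms, charge = charge,
                   low_confidence = low_conf),
    dec
  )
}

# first upward crossing time of threshold, linearly interpolated
cross_time <- function(t, y, thr) {
  above <- which(y >= thr)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(t[1])
  t[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Transfected/untransfected response ratio
#'
#' Expresses a transfected-cell measurement relative to its simultaneously
#' recorded untransfected partner, as a percentage, together with the natural
#' log ratio used for downstream statistics.
#'
#' @param tr,untr One-row measure tibbles from [measure_epsc()] (or single
#'   numeric values).
#' @param field Measure column name (e.g. `"peak"`, `"charge"`, `"tau_w"`)
#'   when tibbles are supplied.
#' @return One-row tibble: `field`, `ratio_pct`, `log_ratio`.
#' @export
response_ratio <- function(tr, untr, field = "peak") {
  a <- if (is.data.frame(tr)) abs(tr[[field]]) else abs(tr)
  b <- if (is.data.frame(untr)) abs(untr[[field]]) else abs(untr)
  if (!is.finite(b) || b <= 0) abort("untransfected value must be positive")
  if (!is.finite(a) || a <= 0) abort("transfected value must be positive")
  tibble::tibble(field = field, ratio_pct = 100 * a / b, log_ratio = log(a / b))
}
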