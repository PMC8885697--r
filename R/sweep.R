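#' Construct a recorded sweep
#'
#' A sweep is a uniformly sampled current trace with its acquisition metadata:
#' holding potential (junction-corrected), series resistance and membrane
#' capacitance from the test pulse, sampling rate, and stimulus time.
#'
#' @param current_pA Numeric vector of current samples (pA).
#' @param fs_hz Sampling rate (Hz, default 25000).
#' @param v_hold_mV Holding potential (mV), must be within +-150 mV.
#' @param rs_MOhm Series resistance (MOhm), > 0.
#' @param cm_pF Membrane capacitance (pF).
#' @param t0_stim_s Stimulus onset (s from sweep start).
#' @param baseline_window_s Length-2 interval (s) used for baseline zeroing;
#'   default 10 ms ending 1 ms before the stimulus.
#' @param cell_id,pair_id Optional labels.
#' @return A `sweep` object (list with a `data` tibble `time_s`, `current_pA`
#'   plus metadata fields).
#' @export
new_sweep <- function(current_pA, fs_hz = 25000, v_hold_mV, rs_MOhm, cm_pF,
                      t0_stim_s, baseline_window_s = NULL,
                      cell_id = NA_character_, pair_id = NA_character_) {
  stopifnot(is.numeric(current_pA), length(current_pA) > 1)
  if (rs_MOhm <= 0) abort("series resistance must be positive")
  if (abs(v_hold_mV) > 150) abort("holding potential outside +-150 mV")
  n <- length(current_pA)
  if (is.null(baseline_window_s)) {
    baseline_window_s <- c(max(t0_stim_s - 0.011, 0), max(t0_stim_s - 0.001, 0))
  }
  structure(list(
    data = tibble::tibble(time_s = (seq_len(n) - 1) / fs_hz,
                          current_pA = as.numeric(current_pA)),
    fs_hz = fs_hz, v_hold_mV = v_hold_mV, rs_MOhm = rs_MOhm, cm_pF = cm_pF,
    t0_stim_s = t0_stim_s, baseline_window_s = baseline_window_s,
    cell_id = cell_id, pair_id = pair_id
  ), class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf(
    "sweep: %d samples @ %g kHz, V_hold %g mV, Rs %.1f MOhm, Cm %.0f pF\n",
    nrow(x$data), x$fs_hz / 1000, x$v_hold_mV, x$rs_MOhm, x$cm_pF))
  invisible(x)
}

#' @export
as_tibble.sweep <- function(x, ...) x$data

#' Read a sweep from CSV
#'
#' The CSV dialect carries metadata in `# key=value` header lines
#' (`v_hold_mV`, `rs_MOhm`, `cm_pF`, `fs_Hz`, `t0_stim_s`) followed by
#' `time_s,current_pA` columns.
#'
#' @param path CSV file path.
#' @return A `sweep`.
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  body <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  new_sweep(body$current_pA, fs_hz = meta$fs_Hz %||% 25000,
            v_hold_mV = meta$v_hold_mV, rs_MOhm = meta$rs_MOhm,
            cm_pF = meta$cm_pF, t0_stim_s = meta$t0_stim_s)
}

#' Write a sweep to CSV
#'
#' @param x A `sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  hdr <- sprintf("# %s=%g",
                 c("v_hold_mV", "rs_MOhm", "cm_pF", "fs_Hz", "t0_stim_s"),
                 c(x$v_hold_mV, x$rs_MOhm, x$cm_pF, x$fs_hz, x$t0_stim_s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(x$data, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Series-resistance compensation fraction
#'
#' Percentage of offline compensation applied to a recording so that the
#' residual uncompensated resistance is a constant `rs_final`:
#' `100 * max(1 - rs_final / rs, 0)`.
#'
#' @param rs Measured series resistance (MOhm).
#' @param rs_final Residual series resistance left uncompensated
#'   (MOhm, default 3).
#' @return Compensation percentage in \[0, 100).
#' @export
rs_comp_fraction <- function(rs, rs_final = 3) {
  if (any(rs <= 0)) abort("series resistance must be positive")
  100 * pmax(1 - rs_final / rs, 0)
}

#' Blank the stimulus artifact
#'
#' Replaces samples inside the artifact window by linear interpolation between
#' the window's endpoint samples; all other samples are untouched.
#'
#' @param sweep A `sweep`.
#' @param window Length-2 interval (s). Defaults to 0.2 ms before stimulus
#'   onset (so the window endpoints sit on clean baseline) to 1 ms after.
#' @return The blanked `sweep`.
#' @export
blank_stimulus_artifact <- function(sweep, window = NULL) {
  stopifnot(inherits(sweep, "sweep"))
  if (is.null(window)) window <- sweep$t0_stim_s + c(-0.0002, 0.001)
  t <- sweep$data$time_s
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    abort("artifact window extends outside the sweep")
  }
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) > 2) {
    i0 <- idx[1]; i1 <- idx[length(idx)]
    y <- sweep$data$current_pA
    inner <- idx[-c(1, length(idx))]
    y[inner] <- y[i0] + (y[i1] - y[i0]) * (t[inner] - t[i0]) / (t[i1] - t[i0])
    sweep$data$current_pA <- y
  }
  sweep
}

#' Offline series-resistance correction
#'
#' Two-stage correction for the voltage error and capacitive filtering caused
#' by uncompensated series resistance, applied at the compensation fraction
#' implied by `rs_final` (see [rs_comp_fraction()]); the compensated
#' resistance is `Rs_c = fraction * Rs`:
#'
#' 1. driving-force rescaling, point-wise
#'    `I' = I (V - E) / ((V - E) - I Rs_c)`, which is sign-consistent so the
#'    corrected current is never smaller in magnitude;
#' 2. capacitive correction `I'' = I' + Rs_c Cm dI'/dt`, with the derivative
#'    taken on a low-pass-smoothed copy (4th-order 4 kHz, matching the
#'    acquisition filter) to avoid noise amplification.
#'
#' Assumes an approximately linear I-V relative to the reversal potential.
#'
#' @param sweep A `sweep`.
#' @param rs_final Residual uncompensated resistance (MOhm, default 3). Use 0
#'   for full compensation.
#' @param e_rev Reversal potential (mV, default 0).
#' @param smooth_hz Cutoff of the derivative smoothing filter (default 4000).
#' @return The corrected `sweep`.
#' @export
correct_series_resistance <- function(sweep, rs_final = 3, e_rev = 0,
                                      smooth_hz = 4000) {
  stopifnot(inherits(sweep, "sweep"))
  vd <- sweep$v_hold_mV - e_rev
  if (abs(vd) <= 5) abort("driving force too small (|V - E| <= 5 mV)")
  frac <- rs_comp_fraction(sweep$rs_MOhm, rs_final) / 100
  if (frac == 0) return(sweep)
  rs_c <- frac * sweep$rs_MOhm               # MOhm
  I <- sweep$data$current_pA
  dv_err <- I * rs_c * 1e-3                  # pA * MOhm = uV -> mV
  denom <- vd - dv_err
  if (any(sign(denom) != sign(vd)) || any(denom == 0)) {
    abort("voltage error exceeds the driving force; compensation unphysical")
  }
  I1 <- I * vd / denom

  # capacitive correction on a smoothed derivative
  fs <- sweep$fs_hz
  Ism <- lowpass_smooth(I1, fs, smooth_hz)
  dIdt <- c(diff(Ism), 0) * fs               # pA/s (forward difference)
  tau_s <- rs_c * sweep$cm_pF * 1e-6         # MOhm * pF = us -> s
  sweep$data$current_pA <- I1 + tau_s * dIdt
  sweep
}

lowpass_smooth <- function(y, fs, cutoff_hz) {
  if (cutoff_hz >= fs / 2) return(y)
  bf <- signal::butter(4, cutoff_hz / (fs / 2))
  pad <- min(length(y) - 1, 250)
  yp <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
  ys <- signal::filtfilt(bf, yp)
  ys[(pad + 1):(pad + length(y))]
}

#' Convert a current sweep to conductance
#'
#' Ohm's law: `g(t) = I(t) / (V_hold - E_rev)`, pA/mV = nS.
#'
#' @param sweep A baseline-zeroed `sweep`.
#' @param e_rev Reversal potential (mV, default 0).
#' @return A tibble `time_s`, `g_nS` with attribute `v_hold_mV`.
#' @export
to_conductance <- function(sweep, e_rev = 0) {
  stopifnot(inherits(sweep, "sweep"))
  vd <- sweep$v_hold_mV - e_rev
  if (abs(vd) <= 5) abort("driving force too small to convert to conductance")
  out <- tibble::tibble(time_s = sweep$data$time_s,
                        g_nS = sweep$data$current_pA / vd)
  attr(out, "v_hold_mV") <- sweep$v_hold_mV
  attr(out, "t0_stim_s") <- sweep$t0_stim_s
  out
}

#' Separate AMPA and NMDA conductance components
#'
#' The conductance at -100 mV is taken as purely AMPA-receptor-mediated
#' (NMDARs being blocked by Mg there); subtracting it point-wise from the
#' +20 mV conductance leaves the NMDA component.
#'
#' @param g_m100 Conductance tibble recorded at -100 mV (see
#'   [to_conductance()]).
#' @param g_p20 Conductance tibble recorded at +20 mV.
#' @return A list with `ampa` and `nmda` conductance tibbles on the shared
#'   time base.
#' @export
split_ampa_nmda <- function(g_m100, g_p20) {
  if (nrow(g_m100) != nrow(g_p20)) abort("conductance traces differ in length")
  ampa <- g_m100
  nmda <- g_p20
  nmda$g_nS <- g_p20$g_nS - g_m100$g_nS
  list(ampa = ampa, nmda = nmda)
}

#' Average sweeps after baseline subtraction
#'
#' Each sweep is zeroed on the mean of its baseline window, then sweeps are
#' averaged point-wise. All sweeps must share the holding potential and time
#' base.
#'
#' @param sweeps List of `sweep` objects.
#' @return A single averaged, baseline-zeroed `sweep` (metadata from the
#'   first; Rs and Cm averaged).
#' @export
average_sweeps <- function(sweeps) {
  stopifnot(length(sweeps) >= 1, all(vapply(sweeps, inherits, TRUE, "sweep")))
  vh <- vapply(sweeps, function(s) s$v_hold_mV, numeric(1))
  if (length(unique(vh)) != 1) abort("sweeps recorded at different V_hold")
  ns <- vapply(sweeps, function(s) nrow(s$data), integer(1))
  if (length(unique(ns)) != 1) abort("sweeps differ in length")
  mats <- vapply(sweeps, function(s) {
    bl <- s$baseline_window_s
    t <- s$data$time_s
    idx <- t >= bl[1] & t <= bl[2]
    s$data$current_pA - mean(s$data$current_pA[idx])
  }, numeric(ns[1]))
  avg <- sweeps[[1]]
  avg$data$current_pA <- rowMeans(mats)
  avg$rs_MOhm <- mean(vapply(sweeps, function(s) s$rs_MOhm, numeric(1)))
  avg$cm_pF <- mean(vapply(sweeps, function(s) s$cm_pF, numeric(1)))
  avg
}
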