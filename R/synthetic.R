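#' Generate a mutation property table with planted structure
#'
#' Draws correlated two-factor scores per planted cluster, maps them through a
#' 6 x 2 loading template onto the six receptor properties as log10 effects,
#' adds Gaussian noise, exponentiates against WT reference values, and masks a
#' fraction of cells at random. The planted truth (factor scores, cluster
#' labels, loading template) is returned alongside for oracle-style testing.
#'
#' Defaults emulate the structure of the compiled 20-variant table: factor 1
#' loads on the agonist potencies, deactivation and open probability; factor 2
#' on current density and surface level; factors correlate at 0.5; four
#' clusters (GOF type 1, LOF type 1, LOF type 2, WT-like).
#'
#' @param n_mutations Number of mutant rows (default 20; WT added on top).
#' @param loading_template 6 x 2 matrix of log10-effect loadings.
#' @param cluster_centers k x 2 matrix of factor-space cluster centres.
#' @param cluster_sd Within-cluster factor-score SD (default 0.35).
#' @param factor_correlation Correlation of the two factors' within-cluster
#'   variation (default 0.5).
#' @param noise_sd Per-property residual SD in log10 units (default 0.15,
#'   about the replicate scatter of published EC50-type measurements).
#' @param missing_fraction Fraction of mutant cells masked (default 0.1,
#'   must be < 0.5).
#' @param wt_ref Named WT reference values on the measurement scale.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List with `table` (a `property_table` including the WT row) and
#'   `truth` (tibble of planted scores and cluster labels, plus the template).
#' @export
gen_mutation_table <- function(n_mutations = 20,
                               loading_template = default_loading_template(),
                               cluster_centers = default_cluster_centers(),
                               cluster_sd = 0.35, factor_correlation = 0.5,
                               noise_sd = 0.15, missing_fraction = 0.1,
                               wt_ref = c(glu_potency = 1 / 3.5,
                                          gly_potency = 1 / 1.1,
                                          deact_tau = 50,
                                          current_density = 150,
                                          open_prob = 0.5,
                                          surface_level = 1),
                               seed = 1) {
  if (missing_fraction >= 0.5) abort("missing_fraction must be < 0.5")
  set.seed(seed)
  k <- nrow(cluster_centers)
  labels <- sort(rep_len(seq_len(k), n_mutations))
  rho <- factor_correlation
  chol_f <- chol(matrix(c(1, rho, rho, 1), 2))
  scores <- cluster_centers[labels, , drop = FALSE] +
    cluster_sd * (matrix(rnorm(n_mutations * 2), ncol = 2) %*% chol_f)
  effects <- scores %*% t(loading_template) +
    noise_sd * matrix(rnorm(n_mutations * 6), ncol = 6)
  colnames(effects) <- property_cols()

  vals <- sweep(10^effects, 2, wt_ref[property_cols()], "*")
  tbl <- tibble::as_tibble(vals)
  tbl <- dplyr::bind_cols(
    tibble::tibble(mutation = sprintf("M%02d", seq_len(n_mutations))), tbl)

  if (missing_fraction > 0) {
    n_cells <- n_mutations * 6
    mask <- sample.int(n_cells, round(missing_fraction * n_cells))
    m <- as.matrix(tbl[, property_cols()])
    m[cbind((mask - 1) %% n_mutations + 1, (mask - 1) %/% n_mutations + 1)] <- NA
    # keep at least one observation per column
    for (j in seq_len(ncol(m))) if (all(is.na(m[, j]))) m[1, j] <- vals[1, j]
    for (cl in seq_along(property_cols())) tbl[[property_cols()[cl]]] <- m[, cl]
  }

  wt_row <- tibble::as_tibble(as.list(c(wt_ref[property_cols()])))
  wt_row <- dplyr::bind_cols(tibble::tibble(mutation = "WT"), wt_row)
  out <- as_property_table(dplyr::bind_rows(tbl, wt_row))

  truth <- tibble::tibble(mutation = sprintf("M%02d", seq_len(n_mutations)),
                          factor1 = scores[, 1], factor2 = scores[, 2],
                          cluster = labels)
  list(table = out, truth = truth, loading_template = loading_template)
}

#' @rdname gen_mutation_table
#' @export
default_loading_template <- function() {
  m <- matrix(c(
    # factor1 factor2
    1.0, 0.00,  # glu_potency
    0.7, 0.00,  # gly_potency
    0.6, 0.10,  # deact_tau
    0.1, 1.00,  # current_density
    0.7, 0.05,  # open_prob
    0.0, 0.80   # surface_level
  ), ncol = 2, byrow = TRUE)
  dimnames(m) <- list(property_cols(), c("factor1", "factor2"))
  m
}

#' @rdname gen_mutation_table
#' @export
default_cluster_centers <- function() {
  matrix(c(2.5, 0.3,    # GOF type 1 (strong potency gain)
           -2, 0,       # LOF type 1 (potency loss)
           -0.3, -2.5,  # LOF type 2 (expression/current loss)
           0, 0),       # WT-like
         ncol = 2, byrow = TRUE)
}

#' Forward series-resistance distortion
#'
#' The oracle inverse of [correct_series_resistance()]: applies the
#' driving-force attenuation `I = I_ideal (V - E - dV) / (V - E)` with
#' `dV = I Rs` solved point-wise, then a first-order RC low-pass with
#' `tau = Rs Cm`.
#'
#' @param sweep An ideal `sweep`.
#' @param rs_MOhm,cm_pF Series resistance and capacitance to emulate
#'   (defaults: the sweep's own metadata).
#' @param e_rev Reversal potential (mV).
#' @return The distorted `sweep`.
#' @export
forward_rs_distort <- function(sweep, rs_MOhm = NULL, cm_pF = NULL, e_rev = 0) {
  stopifnot(inherits(sweep, "sweep"))
  rs <- rs_MOhm %||% sweep$rs_MOhm
  cm <- cm_pF %||% sweep$cm_pF
  if (rs < 0 || cm <= 0) abort("rs and cm must be positive")
  vd <- sweep$v_hold_mV - e_rev
  I_ideal <- sweep$data$current_pA
  # point-wise solution of I = I_ideal (vd - I rs) / vd
  I <- I_ideal / (1 + I_ideal * rs * 1e-3 / vd)
  if (rs > 0) {
    tau_ms <- rs * cm * 1e-3             # MOhm * pF = us -> ms
    dt_ms <- 1000 / sweep$fs_hz
    a <- exp(-dt_ms / tau_ms)
    I <- as.numeric(stats::filter(I * (1 - a), a, method = "recursive",
                                  init = I[1]))
  }
  sweep$data$current_pA <- I
  sweep$rs_MOhm <- rs
  sweep$cm_pF <- cm
  sweep
}

#' Generate a synthetic paired recording
#'
#' Forward model of the paired-recording protocol: for each cell
#' (untransfected WT-like and transfected mutant-like) and each holding
#' potential, the ideal current is
#' `I(t) = g_ampa(t) (V - E) + g_nmda(t) B(V) (V - E)` with B the Mg-block
#' factor, which is then distorted by series resistance, given a brief
#' stimulus artifact, and overlaid with Gaussian noise for each of `n_sweeps`
#' repeats.
#'
#' In `mg = "ideal"` mode the NMDA conductance is fully blocked at negative
#' potentials and fully unblocked at positive ones, making the subtraction
#' protocol exact; `mg = "realistic"` uses the Jahr-Stevens factor and leaves
#' residual NMDA conductance at -100 mV, quantifying the protocol's
#' systematic error.
#'
#' @param kinetic_scale NMDA kinetic scale of the transfected cell (1 = WT).
#' @param amplitude_scale NMDA peak-conductance scale of the transfected cell
#'   (default `1 / kinetic_scale`, i.e. charge-matched).
#' @param ampa_gmax_nS,nmda_gmax_nS Untransfected-cell peak conductances.
#' @param v_hold_mV Holding potentials (default -100..+20 mV in 20 mV steps).
#' @param rs_MOhm,cm_pF Access resistance and capacitance (recycled per cell).
#' @param noise_sd_pA Additive Gaussian noise SD before acquisition filtering
#'   (default 5).
#' @param filter_hz Acquisition low-pass (4-pole) applied to signal plus
#'   noise, emulating the recording filter (default 4000; `NULL` disables).
#' @param artifact_pA,artifact_ms Stimulus artifact amplitude and width.
#' @param n_sweeps Sweeps per voltage (default 10).
#' @param syn_delay_ms Synaptic delay between stimulus and conductance onset
#'   (default 1.5 ms), so the artifact window does not overlap the response.
#' @param t0_stim_s Stimulus time (default 0.05 s).
#' @param duration_s Sweep length (default 0.45 s).
#' @param fs_hz Sampling rate (default 25000).
#' @param mg `"realistic"` (Jahr-Stevens) or `"ideal"` (all-or-none block).
#' @param distort Apply [forward_rs_distort()] (default TRUE).
#' @param seed Integer seed; bit-reproducible.
#' @return List with `sweeps` (tibble: `cell`, `v_hold_mV`, `sweep`,
#'   list-column `data` of `sweep` objects) and `truth` (generator settings
#'   and the noiseless undistorted component conductances).
#' @export
gen_epsc_pair <- function(kinetic_scale = 1.5,
                          amplitude_scale = 1 / kinetic_scale,
                          ampa_gmax_nS = 2, nmda_gmax_nS = 2,
                          v_hold_mV = seq(-100, 20, by = 20),
                          rs_MOhm = c(10, 10), cm_pF = c(100, 100),
                          noise_sd_pA = 5, artifact_pA = 200,
                          artifact_ms = 0.6, n_sweeps = 10, syn_delay_ms = 1.5,
                          filter_hz = 4000,
                          t0_stim_s = 0.05, duration_s = 0.45, fs_hz = 25000,
                          mg = c("realistic", "ideal"), distort = TRUE,
                          seed = 1) {
  mg <- match.arg(mg)
  set.seed(seed)
  n <- round(duration_s * fs_hz)
  t_s <- (seq_len(n) - 1) / fs_hz
  t_rel_ms <- (t_s - t0_stim_s) * 1000          # artifact time base
  t_syn_ms <- t_rel_ms - syn_delay_ms           # conductance onset after delay

  cells <- tibble::tibble(
    cell = c("untransfected", "transfected"),
    nmda_scale_k = c(1, kinetic_scale),
    nmda_gmax = c(nmda_gmax_nS, nmda_gmax_nS * amplitude_scale),
    rs = rep_len(rs_MOhm, 2), cm = rep_len(cm_pF, 2))

  rows <- list()
  truth_g <- list()
  for (ci in 1:2) {
    k <- cells$nmda_scale_k[ci]
    g_a <- biexp_conductance(t_syn_ms, ampa_gmax_nS, 0.3, 3)
    g_n <- biexp_conductance(t_syn_ms, cells$nmda_gmax[ci], 3 * k, 80 * k)
    truth_g[[cells$cell[ci]]] <- tibble::tibble(time_s = t_s, g_ampa_nS = g_a,
                                                g_nmda_nS = g_n)
    for (vh in v_hold_mV) {
      B <- if (mg == "ideal") as.numeric(vh > 0) else mg_block_factor(vh)
      I_ideal <- g_a * vh + g_n * B * vh          # nS * mV = pA
      base <- new_sweep(I_ideal, fs_hz = fs_hz, v_hold_mV = vh,
                        rs_MOhm = cells$rs[ci], cm_pF = cells$cm[ci],
                        t0_stim_s = t0_stim_s,
                        cell_id = cells$cell[ci])
      if (distort) base <- forward_rs_distort(base)
      art <- artifact_pA * exp(-pmax(t_rel_ms, 0) / (artifact_ms / 3)) *
        (t_rel_ms >= 0 & t_rel_ms <= artifact_ms)
      for (sw in seq_len(n_sweeps)) {
        s <- base
        y <- s$data$current_pA + rnorm(n, sd = noise_sd_pA)
        if (!is.null(filter_hz)) y <- lowpass_smooth(y, fs_hz, filter_hz)
        s$data$current_pA <- y + art
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell = cells$cell[ci], v_hold_mV = vh, sweep = sw, data = list(s))
      }
    }
  }
  truth <- list(kinetic_scale = kinetic_scale,
                amplitude_scale = amplitude_scale,
                ampa_gmax_nS = ampa_gmax_nS, nmda_gmax_nS = nmda_gmax_nS,
                nmda_tau_ms = c(rise = 3, decay = 80),
                conductances = truth_g, cells = cells, mg = mg,
                noise_sd_pA = noise_sd_pA, seed = seed)
  list(sweeps = dplyr::bind_rows(rows), truth = truth)
}

#' Process a generated recording pair end to end
#'
#' Applies the full offline pipeline to a [gen_epsc_pair()] result: artifact
#' blanking, series-resistance correction, per-voltage averaging, conductance
#' conversion, AMPA/NMDA separation at -100/+20 mV, and EPSC measurement.
#'
#' @param pair Output of [gen_epsc_pair()].
#' @param rs_final Residual uncompensated resistance (MOhm, default 3; 0 for
#'   full compensation).
#' @param smooth_hz Derivative-smoothing cutoff for the capacitive correction
#'   (default 4000; use a lower cutoff, e.g. 500, when only slow NMDA
#'   kinetics are of interest).
#' @return Tibble of measures, one row per (cell, component).
#' @export
process_pair <- function(pair, rs_final = 3, smooth_hz = 4000) {
  sw <- pair$sweeps
  res <- list()
  for (cell in unique(sw$cell)) {
    gs <- list()
    for (vh in c(-100, 20)) {
      sweeps <- sw$data[sw$cell == cell & sw$v_hold_mV == vh]
      sweeps <- lapply(sweeps, blank_stimulus_artifact)
      sweeps <- lapply(sweeps, correct_series_resistance, rs_final = rs_final,
                       smooth_hz = smooth_hz)
      avg <- average_sweeps(sweeps)
      gs[[as.character(vh)]] <- to_conductance(avg)
    }
    comp <- split_ampa_nmda(gs[["-100"]], gs[["20"]])
    for (nm in names(comp)) {
      m <- measure_epsc(comp[[nm]],
                        t0_stim_s = sw$data[[1]]$t0_stim_s)
      res[[length(res) + 1]] <- dplyr::bind_cols(
        tibble::tibble(cell = cell, component = nm), m)
    }
  }
  dplyr::bind_rows(res)
}
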