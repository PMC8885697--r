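#' Build a reduced CA1-like neuron model
#'
#' Constructs a soma plus single tapered apical cable, discretised into
#' compartments, carrying six spatially distributed conductances: fast Na,
#' delayed-rectifier K, A-type K, h-current, high-voltage-activated R-type
#' Ca, and Ca-activated (mAHP) K, plus leak. Channel kinetics are standard
#' Hodgkin-Huxley-style formulations; densities are calibrated so the model
#' rests near -65 mV and a 40-synapse 200 Hz train of WT-like synapses drives
#' somatic spiking while a single volley stays subthreshold.
#'
#' @param soma_L_um,soma_diam_um Soma cylinder dimensions (default 40 x 40).
#' @param apical_length_um,apical_diam_um Apical cable length (default 800 um)
#'   and proximal diameter (default 6 um); the cable tapers linearly to 1 um
#'   distally.
#' @param n_apical Number of cable compartments (default 60).
#' @param ra_ohm_cm Axial resistivity (default 150).
#' @param cm_uF_cm2 Specific capacitance (default 1).
#' @param densities Named list of channel densities (S/cm2) per region; see
#'   [default_densities()].
#' @param e_leak_mV Leak reversal (default -68).
#' @param vshift Voltage offset of the Na/KDR rate functions (mV); sets the
#'   spike threshold (default -56).
#' @param validate Run a 300 ms input-free settling check (default FALSE; see
#'   [validate_rest()]).
#' @return A `neuron_model` object.
#' @export
build_model <- function(soma_L_um = 40, soma_diam_um = 40,
                        apical_length_um = 800, apical_diam_um = 6,
                        n_apical = 60, ra_ohm_cm = 150, cm_uF_cm2 = 1,
                        densities = default_densities(),
                        e_leak_mV = -68, vshift = -56, validate = FALSE) {
  seg_L <- apical_length_um / n_apical
  diam <- c(soma_diam_um,
            seq(apical_diam_um, 1, length.out = n_apical))
  L <- c(soma_L_um, rep(seg_L, n_apical))
  parent <- c(-1L, 0L, seq_len(n_apical - 1))
  region <- c("soma", rep("apical", n_apical))

  comps <- tibble::tibble(
    comp = seq_along(L), parent = parent, region = region,
    L_um = L, diam_um = diam,
    pos_um = c(0, cumsum(rep(seg_L, n_apical)) - seg_L / 2)
  )
  model <- structure(list(
    comps = comps, ra_ohm_cm = ra_ohm_cm, cm_uF_cm2 = cm_uF_cm2,
    densities = densities, e_leak_mV = e_leak_mV,
    e_na = 50, e_k = -90, e_h = -30, e_ca = 120,
    vshift = vshift,
    spine = list(head_L_um = 0.5, head_diam_um = 0.5,
                 neck_L_um = 1.0, neck_diam_um = 0.1,
                 ca_buffer = 20, ca_tau_ms = 15, ca_rest_uM = 0.05),
    dend_ca = list(shell_um = 0.1, buffer = 20, tau_ms = 50)
  ), class = "neuron_model")
  # settle once so simulations can start from the true resting potential
  model$v_rest <- tryCatch({
    tr <- run_step_current(model, 0, t_stop_ms = 300, v_init = -65)
    tail(tr$v_soma, 1)
  }, error = function(e) -65)
  if (validate) validate_rest(model)
  model
}

#' Default channel densities (S/cm2) per region
#'
#' Calibrated once for the shipped morphology: resting potential near -65 mV,
#' subthreshold single volleys at 40 synapses, spiking during 200 Hz WT
#' trains. Spine heads carry the Ca machinery (R-type Ca, KCa, leak) so spine
#' calcium reflects local NMDA and voltage-gated influx.
#'
#' @return Nested named list `region$channel`.
#' @export
default_densities <- function() {
  list(
    soma = c(na = 0.08, kdr = 0.03, ka = 0.006, ih = 1e-4, car = 3e-4,
             kca = 1e-3, leak = 1e-4),
    apical = c(na = 0.005, kdr = 0.004, ka = 0.012, ih = 2e-4, car = 1e-3,
               kca = 1.5e-3, leak = 1e-4),
    spine_head = c(na = 0, kdr = 0, ka = 0, ih = 0, car = 1e-3,
                   kca = 1.5e-3, leak = 1e-4),
    spine_neck = c(na = 0, kdr = 0, ka = 0, ih = 0, car = 0, kca = 0,
                   leak = 1e-4)
  )
}

# geometric helpers (lengths/diameters in um; conductances uS, capacitance nF)
comp_area_cm2 <- function(L_um, diam_um) pi * diam_um * L_um * 1e-8
axial_res_MOhm <- function(L_um, diam_um, ra) {
  4 * ra * (L_um * 1e-4) / (pi * (diam_um * 1e-4)^2) / 1e6
}

#' Attach spines at given cable positions
#'
#' Each spine is two compartments -- a neck joined to the dendrite and a head
#' joined to the neck -- whose head hosts the synapse and the spine Ca pool.
#'
#' @param model A `neuron_model`.
#' @param pos_um Positions along the apical cable (um from soma).
#' @return The model with spine compartments appended and `syn_comp` (head
#'   indices) recorded.
#' @export
attach_spines <- function(model, pos_um) {
  comps <- model$comps
  apical <- comps[comps$region == "apical", ]
  heads <- integer(length(pos_um))
  for (i in seq_along(pos_um)) {
    tgt <- apical$comp[which.min(abs(apical$pos_um - pos_um[i]))]
    sp <- model$spine
    neck_id <- nrow(comps) + 1L
    head_id <- nrow(comps) + 2L
    comps <- dplyr::bind_rows(comps, tibble::tibble(
      comp = c(neck_id, head_id), parent = c(tgt - 1L, neck_id - 1L),
      region = c("spine_neck", "spine_head"),
      L_um = c(sp$neck_L_um, sp$head_L_um),
      diam_um = c(sp$neck_diam_um, sp$head_diam_um),
      pos_um = rep(pos_um[i], 2)
    ))
    heads[i] <- head_id
  }
  model$comps <- comps
  model$syn_comp <- heads
  model
}

#' Randomly place synapses along the apical cable
#'
#' Spine positions are drawn uniformly along the apical cable length;
#' deterministic for a given seed.
#'
#' @param model A `neuron_model`.
#' @param n Number of synapses.
#' @param seed Integer seed.
#' @return Model with `n` spines attached (see [attach_spines()]).
#' @export
place_synapses <- function(model, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  len <- sum(model$comps$L_um[model$comps$region == "apical"])
  pos <- runif(n, 0, len)
  model <- attach_spines(model, pos)
  model$syn_pos_um <- pos
  model
}

# assemble the numeric arrays the C++ integrator consumes
model_arrays <- function(model) {
  comps <- model$comps
  area <- comp_area_cm2(comps$L_um, comps$diam_um)
  c_nF <- area * model$cm_uF_cm2 * 1e3
  raxial <- axial_res_MOhm(comps$L_um, comps$diam_um, model$ra_ohm_cm)
  g_pa <- numeric(nrow(comps))
  for (i in seq_len(nrow(comps))[-1]) {
    p <- comps$parent[i] + 1L
    g_pa[i] <- 1 / (raxial[i] / 2 + raxial[p] / 2)
  }
  chan <- c("na", "kdr", "ka", "ih", "car", "kca", "leak")
  G <- matrix(0, nrow(comps), 7)
  for (i in seq_len(nrow(comps))) {
    dens <- model$densities[[comps$region[i]]]
    G[i, ] <- dens[chan] * area[i] * 1e6   # S -> uS
  }
  # Ca pool scale (uM per nA.ms) and extrusion tau per compartment
  vol_L <- numeric(nrow(comps))
  tau_ca <- rep(model$dend_ca$tau_ms, nrow(comps))
  buffer <- rep(model$dend_ca$buffer, nrow(comps))
  for (i in seq_len(nrow(comps))) {
    if (comps$region[i] == "spine_head") {
      vol_L[i] <- pi * (comps$diam_um[i] * 1e-4 / 2)^2 *
        (comps$L_um[i] * 1e-4) * 1e-3
      tau_ca[i] <- model$spine$ca_tau_ms
      buffer[i] <- model$spine$ca_buffer
    } else {
      vol_L[i] <- area[i] * (model$dend_ca$shell_um * 1e-4) * 1e-3
    }
  }
  ca_scale <- 5.182e-12 / (vol_L * buffer)
  list(parent = as.integer(comps$parent), c_nF = c_nF, g_pa_uS = g_pa,
       gchan_uS = G, ca_scale = ca_scale, tau_ca = tau_ca)
}

#' Stimulation protocol
#'
#' @param n_syn Number of synchronously activated synapses (40 or 200 in the
#'   reference experiments).
#' @param freq_hz Train frequency (20, 40, 80 or 200 Hz).
#' @param n_stim Stimuli per train (default 5).
#' @param t_start_ms First stimulus time (default 10 ms).
#' @param tail_ms Post-train recording time (default 150 ms).
#' @param dt_ms Integration step (default 0.025 ms).
#' @param record_dt_ms Output resolution (default 0.1 ms).
#' @return A `stim_protocol` list with derived `stim_ms` and `t_stop_ms`.
#' @export
stim_protocol <- function(n_syn = 40, freq_hz = 200, n_stim = 5,
                          t_start_ms = 10, tail_ms = 150, dt_ms = 0.025,
                          record_dt_ms = 0.1) {
  stopifnot(n_stim >= 1, freq_hz > 0)
  stim <- t_start_ms + (seq_len(n_stim) - 1) * 1000 / freq_hz
  structure(list(n_syn = n_syn, freq_hz = freq_hz, n_stim = n_stim,
                 t_start_ms = t_start_ms, stim_ms = stim,
                 t_stop_ms = max(stim) + tail_ms, dt_ms = dt_ms,
                 record_dt_ms = record_dt_ms), class = "stim_protocol")
}

#' Simulate a synaptic train
#'
#' Places `protocol$n_syn` spines (deterministically for `seed`), activates
#' all synapses synchronously at the protocol's stimulus times, and integrates
#' the full compartment tree by the implicit (backward Euler) method at
#' `dt_ms`. Outputs are decimated to `record_dt_ms`.
#'
#' @param model A `neuron_model` (without spines; they are placed here).
#' @param protocol A [stim_protocol()].
#' @param syn A [synapse_spec()].
#' @param seed Integer seed controlling synapse placement (the only stochastic
#'   element).
#' @param v_init Initial potential; defaults to the model's settled resting
#'   potential.
#' @param settle_ms Input-free settling period simulated before the protocol
#'   and discarded, so slow states (Ca pools, Ih) reach their rest before the
#'   first stimulus (default 300).
#' @return A `sim_result`: `trace` tibble (`t_ms`, `v_soma`, `v_spine`,
#'   `ca_spine`, per-conductance ensemble-mean spine currents in nA), charge
#'   accounting (`q_syn`, `q_cap`, `q_leak`, in nA ms), and the inputs.
#' @export
run_train <- function(model, protocol, syn = synapse_spec(), seed = 1,
                      v_init = NULL, settle_ms = 300) {
  stopifnot(inherits(model, "neuron_model"), inherits(protocol, "stim_protocol"))
  v_init <- v_init %||% model$v_rest %||% -65
  wired <- if (protocol$n_syn > 0) {
    place_synapses(model, protocol$n_syn, seed = seed)
  } else {
    model
  }
  arr <- model_arrays(wired)
  syn_idx <- if (protocol$n_syn > 0) as.integer(wired$syn_comp - 1L) else integer(0)
  rec_every <- max(1L, as.integer(round(protocol$record_dt_ms / protocol$dt_ms)))
  out <- cpp_run_cable(
    arr$parent, arr$c_nF, arr$g_pa_uS, arr$gchan_uS, arr$ca_scale, arr$tau_ca,
    wired$spine$ca_rest_uM, syn_idx,
    syn$ampa$gmax_nS * 1e-3, syn$ampa$tau_rise, syn$ampa$tau_decay,
    syn$nmda$gmax_nS * 1e-3, syn$nmda$tau_rise, syn$nmda$tau_decay,
    syn$e_rev_mV, syn$mg_mM, 3.57, 0.062, syn$ca_fraction,
    protocol$stim_ms + settle_ms, protocol$dt_ms,
    protocol$t_stop_ms + settle_ms, v_init, rec_every,
    model$vshift, c(0, 0, 0),
    model$e_na, model$e_k, model$e_h, model$e_ca, model$e_leak_mV)
  keep <- out$t_ms >= settle_ms
  trace <- tibble::tibble(
    t_ms = out$t_ms[keep] - settle_ms, v_soma = out$v_soma[keep],
    v_spine = out$v_spine[keep], ca_spine = out$ca_spine[keep],
    i_ampa = out$i_spine[keep, 1], i_nmda = out$i_spine[keep, 2],
    i_car = out$i_spine[keep, 3], i_kca = out$i_spine[keep, 4],
    i_leak = out$i_spine[keep, 5], i_neck = out$i_spine[keep, 6])
  structure(list(trace = trace, q_syn = out$q_syn, q_cap = out$q_cap,
                 q_leak = out$q_leak, protocol = protocol, syn = syn,
                 seed = seed, model = wired, v_init = v_init),
            class = "sim_result")
}

#' Somatic current-clamp step
#'
#' Runs the model without synapses while injecting a rectangular current step
#' at the soma; used for passive characterisation (input resistance, membrane
#' time constant) and rest validation.
#'
#' @param model A `neuron_model`.
#' @param amp_nA Step amplitude (nA).
#' @param t_on_ms,t_off_ms Step onset/offset (ms).
#' @param t_stop_ms,dt_ms,record_dt_ms Simulation timing.
#' @param v_init Initial potential (mV).
#' @return Tibble `t_ms`, `v_soma`.
#' @export
run_step_current <- function(model, amp_nA, t_on_ms = 50, t_off_ms = 250,
                             t_stop_ms = 400, dt_ms = 0.025, v_init = -65,
                             record_dt_ms = 0.1) {
  arr <- model_arrays(model)
  rec_every <- max(1L, as.integer(round(record_dt_ms / dt_ms)))
  out <- cpp_run_cable(
    arr$parent, arr$c_nF, arr$g_pa_uS, arr$gchan_uS, arr$ca_scale, arr$tau_ca,
    model$spine$ca_rest_uM, integer(0),
    0, 0.3, 3, 0, 3, 80, 0, 1, 3.57, 0.062, 0.1,
    numeric(0), dt_ms, t_stop_ms, v_init, rec_every,
    model$vshift, c(amp_nA, t_on_ms, t_off_ms),
    model$e_na, model$e_k, model$e_h, model$e_ca, model$e_leak_mV)
  tibble::tibble(t_ms = out$t_ms, v_soma = out$v_soma)
}

#' Check that the model rests stably
#'
#' Runs 300 ms with no input and errors if the soma still drifts faster than
#' 0.01 mV/ms at the end.
#'
#' @param model A `neuron_model`.
#' @param v_init Starting potential.
#' @return The resting potential (mV), invisibly.
#' @export
validate_rest <- function(model, v_init = -65) {
  tr <- run_step_current(model, 0, t_stop_ms = 300, v_init = v_init)
  n <- nrow(tr)
  drift <- abs(tr$v_soma[n] - tr$v_soma[n - 10]) / (tr$t_ms[n] - tr$t_ms[n - 10])
  if (drift > 0.01) {
    abort(sprintf("unstable rest: drift %.3g mV/ms at %g ms (V = %.1f mV)",
                  drift, tr$t_ms[n], tr$v_soma[n]))
  }
  invisible(tr$v_soma[n])
}

#' Count action potentials
#'
#' Positive-going threshold crossings separated by at least a refractory
#' interval.
#'
#' @param vm Membrane potential trace (mV).
#' @param t_ms Matching time base (ms); defaults to 0.1 ms sampling.
#' @param threshold_mV Crossing threshold (default 0).
#' @param refractory_ms Minimum separation between counted spikes (default 1).
#' @return Integer spike count.
#' @export
count_spikes <- function(vm, t_ms = NULL, threshold_mV = 0, refractory_ms = 1) {
  if (is.null(t_ms)) t_ms <- (seq_along(vm) - 1) * 0.1
  up <- which(vm[-1] >= threshold_mV & vm[-length(vm)] < threshold_mV)
  if (length(up) == 0) return(0L)
  tcross <- t_ms[up + 1]
  count <- 1L
  last <- tcross[1]
  for (tc in tcross[-1]) {
    if (tc - last >= refractory_ms) {
      count <- count + 1L
      last <- tc
    }
  }
  count
}

#' Summarise a simulated train
#'
#' Integrals (above the pre-stimulus resting values, trapezoidal rule) of the
#' soma membrane potential, ensemble-mean spine-head potential and spine
#' calcium, the peak spine calcium, and the somatic spike count.
#'
#' @param result A `sim_result` from [run_train()].
#' @return One-row tibble: `spike_count`, `soma_vm_int_mV_ms`,
#'   `spine_vm_int_mV_ms`, `spine_ca_int_uM_ms`, `peak_ca_uM`, `v_rest_mV`.
#' @export
spine_summaries <- function(result) {
  tr <- result$trace
  t0 <- result$protocol$stim_ms[1]
  base <- tr$t_ms < t0
  v_rest <- mean(tr$v_soma[base])
  vsp_rest <- mean(tr$v_spine[base])
  ca_rest <- mean(tr$ca_spine[base])
  post <- tr$t_ms >= t0
  tms <- tr$t_ms[post]
  tibble::tibble(
    spike_count = count_spikes(tr$v_soma[post], tms),
    soma_vm_int_mV_ms = trapz(tms, tr$v_soma[post] - v_rest),
    spine_vm_int_mV_ms = trapz(tms, tr$v_spine[post] - vsp_rest),
    spine_ca_int_uM_ms = trapz(tms, tr$ca_spine[post] - ca_rest),
    peak_ca_uM = max(tr$ca_spine[post]),
    v_rest_mV = v_rest
  )
}

#' Fractional current contributions over time
#'
#' Normalises the stored per-conductance ensemble-mean spine currents into
#' fractional inward and outward shares at each time point, the
#' representation used for stacked "currentscape" displays.
#'
#' @param result A `sim_result`.
#' @return Long tibble: `t_ms`, `current` (conductance name), `direction`
#'   (`inward`/`outward`), `share` in \[0, 1\], `i_nA` (signed).
#' @export
currentscape <- function(result) {
  tr <- result$trace
  cur <- c("i_ampa", "i_nmda", "i_car", "i_kca", "i_leak", "i_neck")
  long <- tidyr::pivot_longer(tr[, c("t_ms", cur)], -"t_ms",
                              names_to = "current", values_to = "i_nA")
  long$direction <- ifelse(long$i_nA < 0, "inward", "outward")
  long <- dplyr::group_by(long, .data$t_ms, .data$direction)
  long <- dplyr::mutate(long, total = sum(abs(.data$i_nA)),
                        share = ifelse(.data$total > 0,
                                       abs(.data$i_nA) / .data$total, 0))
  dplyr::ungroup(long)[, c("t_ms", "current", "direction", "share", "i_nA")]
}

#' Run the genotype x protocol simulation grid
#'
#' One simulation per (kinetic scale, synapse count, frequency, seed), with
#' seeds shared across genotypes so spine placement is matched within a seed.
#'
#' @param genotypes NMDA kinetic scales (default `c(1, 1.5, 2)` for WT-, GOF-
#'   and LOF-like conductances).
#' @param n_syn Synapse counts (default 40).
#' @param freqs_hz Train frequencies (default `c(20, 200)`).
#' @param seeds Placement seeds (default `1:10`).
#' @param model A `neuron_model` (default [build_model()]).
#' @param ... Further arguments to [synapse_spec()].
#' @return Long tibble: grid coordinates plus the [spine_summaries()] columns.
#' @export
run_experiment_grid <- function(genotypes = c(1, 1.5, 2), n_syn = 40,
                                freqs_hz = c(20, 200), seeds = 1:10,
                                model = build_model(), ...) {
  grid <- tidyr::expand_grid(kinetic_scale = genotypes, n_syn = n_syn,
                             freq_hz = freqs_hz, seed = seeds)
  res <- purrr::pmap(grid, function(kinetic_scale, n_syn, freq_hz, seed) {
    syn <- synapse_spec(kinetic_scale = kinetic_scale, ...)
    prot <- stim_protocol(n_syn = n_syn, freq_hz = freq_hz)
    spine_summaries(run_train(model, prot, syn, seed = seed))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Plot a simulated train
#'
#' Soma and mean spine potential plus spine calcium against time.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, ...) {
  tr <- object$trace
  df <- tidyr::pivot_longer(
    tr[, c("t_ms", "v_soma", "v_spine", "ca_spine")], -"t_ms",
    names_to = "signal", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
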