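#' Peak-normalised difference-of-exponentials conductance
#'
#' `g(t) = gmax * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` for `t >= 0`,
#' with N chosen so that the peak equals `gmax`. The peak occurs at
#' `t_p = tau_rise tau_decay / (tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' @param t Time (ms), vector; values < 0 give 0.
#' @param gmax Peak conductance (nS).
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   `tau_rise < tau_decay`.
#' @return Conductance (nS) at `t`.
#' @export
biexp_conductance <- function(t, gmax, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_rise >= tau_decay) {
    abort("need 0 < tau_rise < tau_decay")
  }
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  N <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- gmax * N * (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise))
  out
}

#' Charge-matched peak conductance for scaled kinetics
#'
#' When both time constants of the peak-normalised difference-of-exponentials
#' conductance are scaled by `k`, its time-integral scales by exactly `k`;
#' dividing the peak conductance by `k` therefore leaves the charge transfer
#' unchanged. With a WT peak of 1 nS this gives 666.7 pS at `k = 1.5`
#' (the GOF-like kinetics) and 500 pS at `k = 2` (LOF-like).
#'
#' @param gmax_wt WT peak conductance (nS).
#' @param k Kinetic scale factor (>= 1 for slowed mutants; any k > 0 allowed).
#' @return Charge-matched peak conductance (nS): `gmax_wt / k`.
#' @export
charge_matched_gmax <- function(gmax_wt, k) {
  if (any(k <= 0)) abort("kinetic scale must be positive")
  gmax_wt / k
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Jahr-Stevens form: `B(v) = 1 / (1 + (mg / K) exp(-gamma v))` with
#' K = 3.57 mM and gamma = 0.062 /mV by default. B is 1 with no Mg and
#' increases monotonically with depolarisation.
#'
#' @param v Membrane potential (mV).
#' @param mg Extracellular Mg concentration (mM, default 1).
#' @param K_mM,gamma Block constants.
#' @return Unblocked fraction in \[0, 1\].
#' @export
mg_block_factor <- function(v, mg = 1, K_mM = 3.57, gamma = 0.062) {
  if (any(mg < 0)) abort("mg concentration must be non-negative")
  1 / (1 + (mg / K_mM) * exp(-gamma * v))
}

#' Synaptic conductance specification
#'
#' Bundles the AMPA and NMDA conductance parameters used at every simulated
#' spine. The NMDA peak is charge-matched to the WT reference: both NMDA time
#' constants are multiplied by `kinetic_scale` and the peak divided by it, so
#' single-EPSC charge transfer is identical across genotypes (1 nS WT,
#' 666.7 pS at 1.5, 500 pS at 2.0).
#'
#' @param kinetic_scale NMDA kinetic scale k (1 = WT-like, 1.5 = GOF-like,
#'   2 = LOF-like).
#' @param ampa_gmax_nS,ampa_tau_rise,ampa_tau_decay AMPA component
#'   (defaults 0.5 nS, 0.3 ms, 3 ms).
#' @param nmda_gmax_wt_nS,nmda_tau_rise,nmda_tau_decay WT NMDA component
#'   (defaults 1 nS, 3 ms, 80 ms).
#' @param e_rev_mV Synaptic reversal potential (default 0).
#' @param mg_mM Extracellular Mg (default 1 mM).
#' @param ca_fraction Fraction of NMDA current carried into the spine Ca pool
#'   (default 0.1).
#' @return A `synapse_spec` list.
#' @export
synapse_spec <- function(kinetic_scale = 1,
                         ampa_gmax_nS = 0.5, ampa_tau_rise = 0.3,
                         ampa_tau_decay = 3,
                         nmda_gmax_wt_nS = 1, nmda_tau_rise = 3,
                         nmda_tau_decay = 80,
                         e_rev_mV = 0, mg_mM = 1, ca_fraction = 0.1) {
  stopifnot(ampa_tau_rise < ampa_tau_decay, nmda_tau_rise < nmda_tau_decay)
  structure(list(
    kinetic_scale = kinetic_scale,
    ampa = list(gmax_nS = ampa_gmax_nS, tau_rise = ampa_tau_rise,
                tau_decay = ampa_tau_decay),
    nmda = list(gmax_nS = charge_matched_gmax(nmda_gmax_wt_nS, kinetic_scale),
                gmax_wt_nS = nmda_gmax_wt_nS,
                tau_rise = nmda_tau_rise * kinetic_scale,
                tau_decay = nmda_tau_decay * kinetic_scale),
    e_rev_mV = e_rev_mV, mg_mM = mg_mM, ca_fraction = ca_fraction
  ), class = "synapse_spec")
}
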