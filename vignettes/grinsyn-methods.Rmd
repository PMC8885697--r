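---
title: "Methods: variant classification, EPSC processing and synaptic simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant classification, EPSC processing and synaptic simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grinsyn)
```

grinsyn implements three connected analyses for studying epilepsy-associated
missense variants of the NMDA receptor subunit GluN2A: (1) unsupervised
classification of variants into gain- and loss-of-function groups from
heterologous-expression measurements; (2) offline processing of evoked,
paired-recording EPSCs into compensated AMPA and NMDA receptor conductance
components; and (3) a reduced compartmental CA1-like neuron for asking how
charge-matched but kinetically slowed NMDA conductances change synaptic
integration and spine calcium. This vignette records the models, the
numerical choices, and the reasons behind the open design decisions.

## 1. Variant classification

### Inputs and normalisation

Each variant contributes six functional measurements: glutamate and glycine
potencies (stored as reciprocal EC50s, 1/µM), the deactivation time constant
(ms), peak current density (pA/pF), channel open probability, and relative
surface expression. All six are strictly positive, and every table carries a
complete wild-type (WT) reference row.

After imputation the table is normalised per property to
`log10(value / WT)`. Because potencies are reciprocal EC50s and the
deactivation time constant enters un-inverted, a positive entry always reads
as gain of function: higher agonist potency, slower deactivation (more charge
per activation), larger currents, more channels at the surface. Log base 10
was chosen because variant effects span roughly four decades, so decade units
are the natural reading scale; any base is monotone-equivalent for PCA on
standardised columns.

### Missing-data imputation

Published measurements are incomplete, so single imputation precedes the
factor analysis: each column is rank-transformed over its observed values,
the rank matrix is completed at low rank by alternating-least-squares PCA
(iterated truncated SVD, refilling only the missing cells), and completed
ranks are mapped back to measurement units by piecewise-linear interpolation
against each column's observed (rank, value) pairs. Outside the observed
support the mapping is clamped to the column extremes, since linear
interpolation is undefined beyond it. Completed ranks are clamped to the
observed rank range during the iteration as well; besides matching the
back-mapping, this stabilises the fixed point when trailing singular values
are nearly degenerate. The default completion rank is 2, matching the number
of retained factors. Observed cells are never modified — the tests check
bit-identity. Note one identifiability caveat the tests also document: a
one-factor table with a single missing cell is *not* identified under a
rank-2 completion (any imputed value is rank-2-consistent), so the completion
rank should match the believed latent dimensionality.

### Factor model and rotation

Sampling adequacy is summarised by the Kaiser–Meyer–Olkin statistic from the
inverse correlation matrix; values above 0.5 are treated as adequate. The
factor model is a PCA of the correlation matrix (columns standardised —
the six properties have incommensurate units, so covariance PCA would let
the widest-ranging property dominate). The first two components are retained
and rotated; variance fractions are eigenvalues over the trace.

The rotation default is varimax, with promax available as the oblique
alternative. The source material for this pipeline describes its rotation
contradictorily ("oblique (Varimax)"), and the truth is not recoverable;
varimax is the rotation named explicitly, so it is the default.

Rotated component scores are computed by least-squares projection of the
standardised data onto each rotated pattern column separately, after fixing
each factor's sign so its dominant loading is positive. The more common
joint regression scoring was rejected deliberately: under any orthogonal
rotation it returns *exactly* uncorrelated scores whatever the data, which
would make the tau-b annotation of the score scatter vacuous and would hide
a genuinely oblique factor geometry. Per-column projection preserves that
geometry (at the cost of overstating the overlap when factors share
variance), and recovers the sign of a planted inter-factor correlation
reliably in the generator-based tests.

### Cluster number and k-means

k-means uses 100 independently seeded restarts with ties broken by the
lowest seed index, so results are reproducible bit-for-bit. The cluster
number is read automatically from the within-SS versus k curve: the chosen k
maximises the second difference of `log(withinSS)`, i.e. the point where the
proportional improvement per added cluster drops most abruptly. The raw
(unlogged) second difference was rejected because on geometrically decaying
curves it always favours k = 2. A curve whose largest log-kink is below 0.25
(about a 28% change in drop ratio) is treated as structureless and the floor
k is returned, so a single isotropic blob yields k = 1. On hierarchically
organised data (one cluster much farther out than the rest) the k = 2 kink
can still dominate — the generator-based acceptance check therefore requires
recovery in at least 8 of 10 seeds rather than all 10, and that is the
observed margin.

### Calibrated bootstrap intervals

The association between the two factor scores is reported as Kendall's
tau-b (exact pair counting with tie correction, compiled) with a
bias-corrected and accelerated (BCa) bootstrap interval whose central
coverage is calibrated by a double bootstrap: each of the `n_outer` (default
20,000) resamples is itself resampled `n_inner` (default 200) times, and the
inner empirical CDF evaluated at the original estimate gives a u-value. The
actual coverage of the BCa interval at nominal miss level λ is the fraction
of u-values falling between the BCa-adjusted quantile levels; monotone
interpolation of this coverage curve at the requested level gives the
calibrated λ, and the reported interval is the BCa interval at that level.
At n = 20 with a tau statistic the calibration typically widens the interval
(calibrated central level ≈ 0.97 for nominal 0.95); the coverage simulation
in the test suite (500 bivariate-normal datasets, n = 20, scaled-down
2,000/50 resamples) lands at ≈ 99%, i.e. slightly conservative, within the
accepted 91–99% band. A statistic that is constant across resamples returns
a zero-width interval at the estimate rather than an error, matching the
degenerate-mean contract.

## 2. EPSC processing

### Series-resistance compensation

Recordings are acquired uncompensated and corrected offline. The
compensation percentage for a recording with access resistance Rs is
`100·max(1 − Rs_final/Rs, 0)` with Rs_final = 3 MΩ by default, so every
recording is standardised to the same residual resistance. The correction
itself has two stages applied at the compensated resistance
Rs_c = fraction·Rs:

1. driving-force rescaling, `I' = I·(V−E)/((V−E) − I·Rs_c)`, point-wise and
   sign-consistent (the corrected current is never smaller in magnitude),
   assuming a linear I–V through the reversal potential (E ≈ 0 mV for mixed
   AMPA/NMDA currents);
2. a capacitive term `I'' = I' + Rs_c·Cm·dI'/dt`, the continuous inverse of
   the one-pole RC filter formed by Rs and the cell capacitance. The
   derivative is taken on a low-pass-smoothed copy (4th-order filter; 4 kHz
   default, matching the acquisition filter) because differentiation
   amplifies noise in proportion to frequency.

The derivative-smoothing cutoff should be matched to the kinetics of
interest: NMDA-EPSCs (rise ≈ 3 ms) carry essentially no power above a few
hundred Hz, and the round-trip validation uses a 500 Hz cutoff for exactly
that reason — at 4 kHz the amplified out-of-band noise inflates
extremum-based peak estimates. The validation itself is a round-trip oracle:
the synthetic forward model attenuates by the instantaneous voltage error
and then RC-filters, and correction at full compensation must recover the
peak within 2% and the weighted decay constant within 3% of an identically
processed undistorted recording (matched noise draws isolate the correction
from the noise). The forward model applies attenuation before filtering
while the correction inverts in the opposite order; the commutation error is
second-order in `I·Rs/(V−E)` and is covered by those tolerances.

### Component separation and measures

The stimulus artifact is blanked by linear interpolation over a window that
starts 0.2 ms *before* the stimulus, so both interpolation endpoints sit on
clean baseline. Sweeps are baseline-zeroed on a 10 ms window ending 1 ms
before the stimulus and averaged per voltage. Currents convert to
conductance by Ohm's law (`g = I/(V−E)`, pA/mV = nS), and the AMPA/NMDA
split uses the standard protocol: the −100 mV conductance (NMDARs blocked by
Mg²⁺) is the AMPA component, and its point-wise subtraction from the +20 mV
conductance leaves the NMDA component.

Measures per transient: peak from a 0.5 ms boxcar-smoothed copy (with an
optional cursor-style search window), 20–80% rise time with linear
interpolation between samples, charge as the trapezoidal integral from
stimulus onset to sweep end, and the decay fit. Decays are fitted as
`a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + c` by bounded Levenberg–Marquardt seeded from a
non-iterative estimate (log-linear tail regression for the slow τ, separable
linear amplitudes). The two-component fit is declared failed — and refit as
a single exponential — when an amplitude is negative, the time constants
separate by less than 1.5-fold, a component carries under 0.1% of the
amplitude, the slow τ exceeds half the fit window (not estimable), or the
optimiser fails. The weighted constant is
`τ_w = (a₁τ₁ + a₂τ₂)/(a₁ + a₂)`. Pair-level results are
transfected/untransfected ratios in percent, with the natural-log ratio
alongside for downstream statistics.

### The synthetic recording generator

`gen_epsc_pair()` is the forward model the processing tests run against:
ideal biexponential AMPA (0.3/3 ms) and NMDA (3/80 ms) conductances, Ohm's
law at each holding potential (−100 to +20 mV in 20 mV steps), voltage-
dependent Mg block, series-resistance distortion, a brief stimulus artifact,
a 4 kHz four-pole acquisition filter over signal plus noise, and ten
Gaussian-noise sweeps per voltage — with the generating truth returned
alongside. A synaptic delay (1.5 ms default) separates the artifact from the
response onset, as in real recordings. In `mg = "ideal"` mode the block is
all-or-none by voltage sign, making the subtraction protocol exact (used for
the machine-precision split tests); `mg = "realistic"` leaves residual NMDA
conductance at −100 mV, so the protocol's small systematic error is itself
measurable. What the generator does not emulate: stochastic synaptic
failures, rundown and drift, imperfect space clamp, or correlated noise —
passing tests show the pipeline recovers what this forward model plants, not
that those further artifacts are handled.

## 3. Reduced CA1-like simulation

### Model structure

The neuron is deliberately reduced: a 40×40 µm somatic cylinder plus a
single 800 µm apical cable tapering 6→1 µm over 60 compartments
(Ra = 150 Ω·cm, Cm = 1 µF/cm²), carrying six spatially distributed
conductances in Hodgkin–Huxley-style formulations — fast Na, delayed-
rectifier K, A-type K, h-current, R-type (HVA) Ca, and Ca-activated mAHP K —
plus leak. Synapses live on two-compartment spines (0.5 µm head, 1×0.1 µm
neck ≈ 190 MΩ) attached at uniformly random cable positions; the placement
seed is the only stochastic element. Spine heads carry the R-type Ca and
KCa machinery and a single-pool Ca model: influx from a fixed fraction
(10%) of the NMDA current plus all R-type current, an instantaneous buffer
ratio of 20, first-order extrusion (τ = 15 ms), resting 0.05 µM.

Synaptic conductances are peak-normalised differences of exponentials. AMPA
is fixed at 500 pS, 0.3/3 ms. The NMDA component has WT parameters 1 nS,
3/80 ms; mutant-like kinetics scale both time constants by k (1.5
"GOF-like", 2.0 "LOF-like") and divide the peak by k, which conserves the
conductance time-integral exactly (scaling time by k scales the integral by
k) — 666.7 pS and 500 pS. Mg block uses the Jahr–Stevens form
`B(V) = 1/(1 + (mg/3.57 mM)·e^(−0.062V))`, the field-standard description,
since the source model's voltage dependence is not restated anywhere
accessible; constants are configurable.

### Numerics

Voltages advance by backward Euler on the compartment tree (Hines-ordered
elimination, exact for the tree topology) with gates updated by exponential
integration at the previous voltage, at dt = 25 µs and effectively 35 °C
kinetics; outputs are decimated to 0.1 ms. Backward Euler was chosen over
Crank–Nicolson for unconditional damping of the stiff spine compartments
(head capacitance ≈ 8 fF against nS-scale synaptic conductances);
halving dt changes the soma-potential integral by under 0.2% in the
convergence test. Each run is preceded by a 300 ms input-free settling
period (discarded) so slow states — Ca pools, Ih — start at their true
rest; without it the Ca-dependent conductances produce a ~1.5 mV transient
that contaminates baseline-referenced integrals. Charge accounting
(synaptic = capacitive + leak in the passive case, to integrator precision)
and a voltage-clamp-limit comparison of the spine NMDA current against the
driving-force-weighted biexponential validate the kernel against closed
forms.

### Calibration

The published full CA1 model is out of scope by design; densities and the
rate-function voltage offset were calibrated once against three qualitative
anchors: rest near −65 mV (shipped model: ≈ −68.8 mV after settling), a
single 40-synapse volley subthreshold, and 5-stimulus 200 Hz WT-like trains
driving somatic spiking by the late stimuli while GOF-like trains spike less
and LOF-like trains stay silent. With the shipped defaults the matched-seed
orderings (spike count WT ≥ GOF ≥ LOF; spine-Ca integral WT above both
mutants) hold in at least 8 of 10 seeds at 40 synapses/200 Hz, and WT
spiking occurs in 9 of 10. Spine Ca magnitudes (tens of µM peak) are larger
than the reference simulations report; absolute Ca levels depend on the
spine Ca machinery of the full model and are expressly outside this
package's quantitative scope — only the genotype orderings are claimed.
The experiment grid defaults to 3 genotypes × 40 synapses ×
\{20, 200\} Hz × 10 seeds, which one CPU completes in well under a minute;
the full published grid (also 200 synapses and 40/80 Hz) runs with the same
function by widening the arguments.

## 4. The mutation-table generator

`gen_mutation_table()` plants the structure the classification pipeline is
supposed to find: four clusters in a two-factor space (strong potency gain;
potency loss; expression/current loss; WT-like) with centres 2–2.5 decades
out, within-cluster factor SD 0.35, inter-factor correlation 0.5, loading
template concentrating factor 1 on potencies/deactivation/open probability
and factor 2 on current density/surface level, per-property log10 noise of
0.15 (about the replicate scatter of published EC50-type measurements), and
10% missing cells. These defaults reproduce the headline structure of the
compiled 20-variant dataset — roughly 70% + 25% variance in two components
and four recoverable groups — and were fixed once; the pipeline's
recovery criteria (≥80% variance in two components, cluster ARI > 0.8,
positive inter-factor sign, in ≥8/10 seeds) are evaluated against them.

## Known limitations

* The classification score correlation is overstated when factors overlap
  (per-column projection); treat its magnitude, not just its sign, with
  caution.
* The automated elbow can merge hierarchically separated clusters (k = 2
  instead of 4) in a minority of seeds; inspect `withinss_curve()` when the
  cluster count matters.
* Rs correction quality degrades with per-sweep noise because of the
  derivative term; choose `smooth_hz` to match the kinetics of interest.
* The neuron model is a reduced stand-in calibrated for qualitative genotype
  contrasts; absolute voltages, Ca concentrations and spike counts are not
  quantitative predictions.
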