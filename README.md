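# grinsyn

Epilepsy-associated missense variants of *GRIN2A*, the gene encoding the
NMDA receptor subunit GluN2A, alter receptor function in strikingly diverse
ways — a single variant can simultaneously gain function in one property and
lose it in another. grinsyn is an R toolkit for working through the
consequences, from molecular phenotype to synaptic physiology, in three
connected stages:

1. **Variant classification.** Given a table of six heterologous-expression
   measurements per variant (glutamate and glycine EC50, deactivation time
   constant, current density, open probability, relative surface level,
   with missing entries allowed), the pipeline imputes missing cells by
   rank-based alternating-least-squares PCA, normalises to WT log10 ratios
   (positive = gain of function), checks sampling adequacy (KMO), fits a
   two-component rotated factor model, clusters the rotated scores by
   elbow-selected k-means, and annotates the inter-factor association with
   Kendall's tau-b and a double-bootstrap-calibrated BCa confidence
   interval.

2. **EPSC processing.** Paired-recording evoked EPSC sweeps are cleaned
   (stimulus-artifact blanking), compensated offline for series resistance
   — `Rs_comp(%) = 100·max(1 − Rs_final/Rs, 0)` with driving-force and
   capacitive corrections — averaged, converted to conductance by Ohm's
   law, and separated into AMPA (−100 mV) and NMDA (+20 mV minus −100 mV)
   components. Each transient is measured (peak, 20–80% rise, charge) and
   its decay fitted as `a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + c` with weighted
   constant `τ_w = (a₁τ₁ + a₂τ₂)/(a₁ + a₂)`, reporting
   transfected/untransfected response ratios per cell pair.

3. **Synaptic simulation.** A reduced CA1-like compartmental neuron (soma +
   tapered apical cable, six active conductances, two-compartment spines
   with local Ca dynamics) compares charge-matched NMDA conductance
   profiles — WT (1 nS, 3/80 ms), "GOF-like" (both τ ×1.5, 666.7 pS) and
   "LOF-like" (both τ ×2, 500 pS) — during trains of 5 synchronous stimuli
   at 20–200 Hz across 40 or 200 spines, reporting spike counts and
   integrals of somatic/spine potential and spine calcium.

Synthetic-data generators (`gen_mutation_table()`, `gen_epsc_pair()`) plant
known structure and return the generating truth, so every stage is testable
end to end without external data.

## Worked example

```r
library(grinsyn)

gen <- gen_mutation_table(seed = 1)         # 20 variants, planted structure
cls <- classify_variants(gen$table, n_outer = 2000, n_inner = 50, seed = 1)
cls
#> Variant classification: 20 mutations, k = 4
#> KMO 0.710 | variance 72% + 27% | tau-b 0.589 [-0.079, 0.893]
#> # A tibble: 20 x 4
#>    mutation factor1 factor2 cluster
#>    <chr>      <dbl>   <dbl>   <int>
#>  1 M01         1.40  1.09         3
#>  2 M02         1.61  1.42         3
#>  ...
```

Two components explain 99% of the variance (72% + 27%), sampling adequacy
is 0.71 (> 0.5), the elbow rule picks four clusters, and the two factor
scores associate positively (tau-b 0.589). `tidy(cls$model)` returns the
pattern matrix, `autoplot(cls$model, cls$clusters)` the annotated score
scatter, and `write_classification(cls, "out/")` the scores CSV and model
JSON.

Simulating charge-matched genotypes on the reduced neuron:

```r
m <- build_model()
grid <- run_experiment_grid(genotypes = c(1, 1.5, 2), freqs_hz = 200,
                            seeds = 1:3, model = m)
#>   kinetic_scale seed spike_count spine_ca_int_uM_ms peak_ca_uM
#> 1           1.0    1           1             5692.9      108.2
#> 4           1.5    1           0             5151.7       74.8
#> 7           2.0    1           0             4153.2       48.1
```

Despite identical single-EPSC charge transfer, the WT-kinetics condition
(`kinetic_scale = 1`) drives somatic spiking during the 200 Hz train and
accumulates the most spine calcium; the slowed, amplitude-reduced
mutant-like profiles summate less effectively and stay subthreshold — the
central qualitative result the simulation module exists to demonstrate.

A thin command-line front-end wraps the same pipeline:

```sh
Rscript inst/cli/grinsyn.R synth --out synth/ --seed 3
Rscript inst/cli/grinsyn.R classify --table synth/mutations.csv --out cls/ --seed 1
```

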