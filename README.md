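# acpdyn

Per-residue stability and dynamics analysis for small proteins studied by
solution NMR, circular dichroism (CD), differential scanning calorimetry
(DSC) and molecular dynamics — built around *Escherichia coli* acyl
carrier protein (ACP), the small four-helix carrier that shuttles growing
fatty-acyl chains between the enzymes of type II fatty-acid synthesis.

The package is for structural biologists and biophysicists who have
per-residue tabular data (peak lists, intensity time courses, denaturant
or temperature response curves, coordinate series) and want the standard
stability and dynamics quantities with tested, reproducible code:

- **H/D exchange** (`fit_hdx()`, `intrinsic_rates()`, `protection()`,
  `hdx_analyze()`): fits per-residue amide intensity decays
  `I(t) = I0 e^{-k_ex t} + C`, computes intrinsic random-coil rates
  `k_rc` from acid/base/water catalysis with neighbor and terminal
  corrections, and converts to protection factors and local unfolding
  free energies,

  `P = k_rc / k_prot`,  `ΔG_local = -RT ln(k_prot / k_rc) = ln(10)·RT·log10(P)`.

- **Chemical denaturation** (`fit_lem()`): the two-state linear
  extrapolation model `ΔG(D) = ΔG_H2O − m·D` with sloping native and
  unfolded baselines; reports `ΔG_H2O` (= `m·Cm`), the m-value, and the
  midpoint `[denaturant]_1/2`.

- **Thermal stability** (`fit_melt()`, `dsc_analyze()`,
  `dsc_two_state_fit()`): two-state melts of the 222 nm ellipticity
  (`T_m`, van 't Hoff ΔH), DSC baseline subtraction and integration
  (`ΔH_cal` as the area under the excess heat capacity, `C_p,max`), and
  the two-state excess heat-capacity fit
  `C_p,exc = ΔH_cal·ΔH_vH·K / (R T² (1+K)²)`.

- **Chemical-shift perturbation and metal titrations** (`csp()`,
  `significance_flags()`, `titration_trajectory()`,
  `paramagnetic_ratio()`): the weighted amide CSP
  `Δδ = sqrt(½[(ΔδH)² + (α ΔδN)²])` with `α = 0.14` for glycine and
  `0.2` otherwise, mean + SD significance flagging, fast-exchange
  titration profiles, and paramagnetic intensity ratios with the
  vanished-peak (ratio 0) convention.

- **Backbone relaxation** (`fit_relaxation()`, `hnoe()`,
  `classify_dynamics()`): R1/R2 mono-exponential fits with noise
  estimated from duplicate delays, heteronuclear NOE ratios, and
  mean ± SD flagging of exchange-broadened and flexible residues.

- **Trajectory geometry** (`dihedral_angle()`, `chi1_series()`,
  `radius_of_gyration()`, `com_distance()`, `hbond_occupancy()`,
  `switch_detect()`): χ1 torsions in the IUPAC convention, mass-weighted
  radius of gyration, center-of-mass distances, distance-cutoff
  hydrogen-bond occupancy, and wrap-aware rotamer-state assignment.

- **Synthetic data with ground truth** (`gen_hdx()`,
  `gen_denaturation()`, `gen_melt()`, `gen_dsc()`, `gen_shift_tables()`,
  `gen_titration_states()`, `gen_paramagnetic()`, `gen_relaxation()`,
  `gen_trajectory()`): every pipeline input can be generated with known
  parameters and controlled noise, so every stage is testable end to end
  without downloads.

All user-facing functions take data frames and return tibbles; fitted
objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()` methods. Units are seconds, Kelvin, molar and kcal/mol
internally; conversion happens only at I/O boundaries
(`read_series()`, `read_peaklist()`, `write_scores()`).

## Worked example

Fit a chemical denaturation curve, run the H/D-exchange pipeline on four
residues, and compare local against global stability:

```r
library(acpdyn)

den <- gen_denaturation(sigma = 0.01, seed = 8)   # Gdn-HCl curve, 1% noise
fit <- fit_lem(den$data)
glance(fit)
#>   dG_H2O m_value    Cm Cm_crossing temperature      sse     n
#> 1   3.80    1.03  3.68        3.68        298. 0.000952    27

hdx <- gen_hdx(residues = c(11, 28, 59, 72),
               logP = c(4.27, 3.4, 3.1, 4.41), sigma = 0.02, seed = 8)
prot <- hdx_analyze(hdx$data)
prot[, c("residue", "aa", "k_ex", "k_rc", "logP", "dG_local")]
#>   residue aa     k_ex   k_rc logP dG_local
#> 1      11  I 4.62e-06 0.0944 4.31     5.88
#> 2      28  F 4.04e-04 0.9882 3.39     4.62
#> 3      59  A 4.74e-04 0.6093 3.11     4.24
#> 4      72  I 8.07e-06 0.1798 4.35     5.93

compare_stability(prot, fit)
#> Stability comparison at 298.15 K
#>   dG_global = 3.803 kcal/mol (logP equivalent 2.79)
#>   1.5x threshold = 5.704 kcal/mol (logP equivalent 4.18)
#>   residues above dG_global: 4; above 1.5x: 2
```

Reading the output: the denaturation fit puts the global unfolding free
energy near 3.8 kcal/mol with a midpoint near 3.7 M. The exchange
pipeline recovers each residue's protection factor (`logP`) and local
unfolding free energy; the two isoleucines protected above the 1.5 ×
ΔG_global line (logP ≈ 4.2 at 25 °C) are the hydrophobic-core anchors,
and `compare_stability()` lists exactly those.

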