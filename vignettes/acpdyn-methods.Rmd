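---
title: "Models and methods behind acpdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acpdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpdyn)
```

acpdyn implements the per-residue stability and dynamics analyses used to
characterize *E. coli* acyl carrier protein (ACP): hydrogen/deuterium
exchange protection, two-state chemical and thermal unfolding
thermodynamics, chemical-shift perturbation and metal-titration analysis,
backbone spin relaxation, and trajectory geometry. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
choices, and states what the synthetic-data generators do and do not
emulate. All free energies are in kcal/mol, temperatures in Kelvin,
times in seconds and concentrations in molar, with
`R = 1.9872e-3 kcal mol^-1 K^-1`.

## Hydrogen/deuterium exchange

For each backbone amide the exchange of the proton for deuterium is
followed as a peak-intensity decay and fitted as

$$I(t) = I_0\,e^{-k_{ex} t} + C,$$

with the observed `k_ex` identified with the protected rate
`k_prot`. The fit uses Levenberg–Marquardt least squares with
multi-start initialization over `k` (decades 1e-6 to 1e-3 s^-1 plus a
log-linear heuristic), tie-broken by lowest SSE. Two physical bounds
matter in practice: the amplitude cannot exceed the initial-intensity
scale (`I0 <= 1.5 max(y)`) and the plateau is a non-negative intensity.
Without them a barely-decaying series is degenerate — a tiny rate with a
huge amplitude reproduces a straight line — and slow but measurable
decays (20–30% over the window) can be mis-fit and spuriously censored.

**Censoring.** With a 1000-minute observation window, rates producing
less than 5% total decay are not resolvable. A fit is flagged censored
when `k_ex * t_max < 0.05` or when the fitted amplitude fraction is
below 5% (the flat-series case); the reported rate is then the value
giving exactly 5% decay over the window, an upper bound, which makes the
derived protection factor a lower bound.

**Intrinsic rates.** The unprotected (random-coil) rate is the sum of
acid-, base- and water-catalyzed terms,

$$k_{rc} = k_A 10^{-pD} + k_B 10^{pD - pK_D} + k_W,$$

each corrected multiplicatively (additively in log10) for the residue's
own side chain and its preceding neighbor, with extra corrections when
the preceding group is the free N-terminal ammonium or the residue
carries the C-terminal carboxylate, and Arrhenius temperature scaling
with activation energies of 14, 17 and 19 kcal/mol for the three terms
(reference 293.15 K, pK_D = 15.05). The constants follow the standard
poly-alanine-based random-coil parameterization on the pD scale and are
packaged as data (`acpdyn:::RC_CORRECTIONS`). Aspartate
and glutamate use their ionized-side-chain entries, appropriate near
pD 6.5; histidine uses the protonated-imidazole entries, a simplification
at pD 6.5 where the imidazole is partially titrated — no quantity
reported by the package depends on the histidine entry. Proline has no
backbone amide and is rejected. The default conditions are pD 6.5
(meter reading 6.1 plus the standard +0.4 glass-electrode correction;
both the correction and the neighbor-set edition are config-exposed via
the `pD` argument since sources vary) and 298.15 K.

**Protection.** `P = k_rc/k_prot`, `logP = log10 P`, and
`dG_local = ln(10)·R·T·logP`, an identity asserted to machine precision
in the tests. At 298.15 K, `logP = 4.2` corresponds to 5.73 kcal/mol.

## Chemical denaturation (linear extrapolation model)

A reversible two-state N ⇌ U equilibrium with the unfolding free energy
linear in denaturant, `ΔG(D) = ΔG_H2O − m·D = m(Cm − D)`, unfolded
fraction `f_U = 1/(1 + exp(ΔG/RT))`, and linear baselines on both sides.
The fit is re-parameterized in `(Cm, m)` — better conditioned than
`(ΔG, m)` because `Cm` is pinned by the data — with the four baseline
parameters profiled linearly on a multi-start grid of `Cm` at 0.25 M
spacing before final refinement, so `ΔG_H2O = m·Cm` holds exactly by
construction. Two cross-checks guard the result: the fitted `Cm` must
lie inside the sampled range with both baselines actually reached
(otherwise "transition not bracketed"), and the concentration at which
the fitted curve crosses the baseline midline must agree with `Cm`
within 2%.

The reported `ΔG_H2O` is the zero-denaturant extrapolation. For the ACP
reference conditions the package defaults pair 3.83 kcal/mol with a
3.7 M midpoint, implying m ≈ 1.04 kcal mol^-1 M^-1 — a physically
plausible m-value for a ~9 kDa protein. Whether a literature value
quoted "at the midpoint" is the extrapolated ΔG_H2O or a mid-transition
quantity is ambiguous in general; this package's convention is the
extrapolation, stated here as its own choice.

## Thermal unfolding: CD melts and DSC

The CD melt model uses `ΔG(T) = ΔH_vH (1 − T/Tm)` with linear baselines;
the heat-capacity change of unfolding is neglected (no ΔCp term), a
deliberate limitation — ΔCp mainly curves the post-transition baseline
and is rarely identifiable from a single melt. `f_U(Tm) = 1/2` exactly.

DSC thermograms are baseline-subtracted and integrated:
`ΔH_cal = ∫ C_p,exc dT` (trapezoid rule; the quadrature error at a
0.2 K grid is far below 0.1%). Baseline options:

- `"linear"`: straight lines fitted to pre- and post-transition
  segments, interpolated linearly across the transition window;
- `"progress"` (default): the two segment lines weighted by the
  integrated fractional progress of the transition, iterated to
  self-consistency — the behavior of common DSC software;
- `"none"`: the input is already baseline-free; only integrate.

The transition window is found iteratively: from the current excess
estimate the peak position and half-height width are measured, the
window is set to ±5 half-widths (a two-state peak retains under 0.1% of
its height there), and the segment lines are refitted outside it, while
always keeping at least 8% of the points in each outer segment as
anchors. This matters for broad peaks, where naive outer-15% segments
sit on the peak tails and visibly depress the integral. `Tm` is reported
as the grid position of the excess-heat-capacity maximum, so it carries
the grid resolution (0.2 K at the default sampling).

The two-state excess model
`C_p,exc = ΔH_cal ΔH_vH K/(R T²(1+K)²)`, `K = exp(−(ΔH_vH/R)(1/T − 1/Tm))`,
peaks at `ΔH_cal ΔH_vH/(4 R Tm²)` at `T = Tm` (where `K = 1`).
`dsc_two_state_fit()` fits `(Tm, ΔH_vH, ΔH_cal)`; with `drift = TRUE` it
also absorbs a residual linear offset, which compensates the small bias
any empirical baseline subtraction leaves in the peak tails.

## Chemical-shift perturbation and metal titrations

The combined amide CSP is
`Δδ = sqrt(½[(ΔδH)² + (α ΔδN)²])` with `α = 0.14` for glycine and `0.2`
otherwise — the only reading of the weighting consistent with ppm units;
the alternative convention with the ½ outside the root is available via
`half = "outside"`. Significance uses the customary bar-plot rule:
flag residues strictly above mean + one sample SD of all finite CSPs.
The flag set is invariant under global rescaling, and with all values
equal (SD 0) the strict inequality flags nothing.

Titration trajectories are CSPs of each step against the
zero-concentration reference, with a per-residue Spearman monotonicity
score. No dissociation constant is fitted — the fast-exchange two-site
generator (`gen_titration_states()`, observed shift = population-weighted
average with bound fraction `c/(c + Kd)`) exists to test monotonicity
and endpoint behavior, not to support Kd estimation.

Paramagnetic (e.g. Mn²⁺) analysis reports per-residue intensity ratios
against the metal-free spectrum. A peak broadened beyond detection is
assigned ratio 0; this is a reporting convention, not a distance
conversion — no PRE-to-distance modeling is attempted. Missing peaks are
encoded as absent intensities, never as zeros, so "vanished under metal"
remains distinguishable from "weak".

## Backbone relaxation

R1/R2 decays are fitted as `I(τ) = I0 exp(−rate·τ)` without a plateau
(standard for peak-height relaxation series; a plateau can be enabled).
Per-point noise σ is estimated from duplicate delays as the rms of
paired differences divided by √2, and the rate's standard error is the
covariance-based error rescaled to that σ. The packaged default delay
schedules include the duplicates; the R2 list is kept verbatim from the
acquisition schedule it models even though two entries break the
otherwise monotone spacing — fits are order-agnostic, so the anomaly is
preserved rather than silently repaired. The hNOE is the plain ratio
`I_sat/I_unsat` with first-order error propagation; negative values pass
through, as flexible termini genuinely invert.

Dynamic classification mirrors the common highlighting convention:
`exchange_broadened` where R2 exceeds the trimmed mean + SD, `flexible`
where the hNOE falls below the trimmed mean − SD, with 5% tails excluded
on each side so the outliers being sought do not inflate their own
threshold. No model-free (Lipari–Szabo) analysis is attempted.

## Trajectory geometry

Dihedrals use the plane-normal atan2 construction with the IUPAC sign
convention (cis = 0°, trans = 180°), returning angles in (−180°, 180°];
the χ1 atom quartet N–CA–CB–Xγ is packaged for all 18 χ1-bearing residue
types (CG1 for Ile/Val, OG for Ser, OG1 for Thr, SG for Cys; Ala/Gly
rejected). Hydrogen-bond occupancy is the fraction of frames with
donor–acceptor distance ≤ 3.5 Å — a distance-only criterion with no
angle term, applied to whichever atom pair the caller names (heavy-atom
N···O by default usage; the choice of donor atom is the caller's).
Rotamer-state assignment (`switch_detect()`) is wrap-aware: each frame
goes to the nearest state center on the circle if within the tolerance,
else unassigned; state windows may not overlap, and transitions are
counted between successive assigned frames. Radius of gyration and
center-of-mass distances are mass-weighted where masses are supplied;
all metrics are invariant under rigid-body transforms (tested to
1e-10 Å against 100 random rotations/translations).

Frames are read from multi-model PDB (MODEL/ENDMDL, via bio3d) or a
plain whitespace table; binary trajectory formats (DCD/XTC) are out of
scope.

## Synthetic data and what the tests show

Each generator produces one stage's input with recorded ground truth and
per-stage child seeds derived deterministically from a master seed, so
adding one table never perturbs another and regeneration is
byte-identical. Defaults are the study conditions the analyses model:
exchange sampled every 10 min to 1000 min; the printed R1/R2 delay
ladders; a denaturation truth of 3.83 kcal/mol with a 3.7 M midpoint;
melts and thermograms at the reported melting temperatures and
enthalpies; Ca²⁺ 0–30 mM and Mn²⁺ 0–0.1 mM ladders. Noise defaults
(2% intensity noise for decays, 1% of baseline span for curves) are
typical of good solution-NMR and CD data. Where a condition is not
stated anywhere — e.g. the number of denaturant points (27) or the melt
sampling (51 points over 25–100 °C) — the defaults are what a careful
experiment would use, chosen once.

The trajectory generator places a χ1 quartet by natural-extension
(NeRF) geometry so scheduled torsions are realized exactly, schedules
hydrogen-bond distances with exact frame counts at the requested dwell
fraction, and applies a random rigid transform per frame. It emulates
switching torsions, intermittent contacts and rigid-body motion — not
force-field physics, solvent, or correlated internal motions. Passing
recovery tests on these data therefore demonstrates the correctness of
the estimators, not the realism of any simulation.

The same caveat applies throughout: Gaussian noise on ideal two-state
or mono-exponential truths contains no systematic artifacts (baseline
drift beyond linear, slow-exchange EX1 behavior, aggregation upturns in
DSC, peak overlap in spectra), so green tests certify the numerics and
the conventions, not robustness to every pathology of real data.

## Numerical choices and degenerate inputs

- All nonlinear fits are Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  grid multi-starts and SSE tie-breaks; sigmoid models profile their
  baseline parameters linearly at each grid node before refinement.
- Degenerate inputs fail loudly: flat denaturation or melt data raise
  "transition not bracketed"; an inverted DSC peak (negative excess
  dominating) raises a baseline-misfit error; a flat thermogram returns
  zero enthalpy and no Tm rather than an arbitrary peak.
- Strict inequalities throughout the flagging rules (CSP significance,
  stability comparison) so ties are never flagged.
- The stability report recomputes its thresholds from its inputs on
  every call; `threshold(1.5×) = 1.5 × threshold(1×)` exactly.

## Interfaces

The package's interface is its functions plus the scripts: every stage
is a data-frame-in/tibble-out function, the orchestrator
`run_pipeline()` drives file-based runs from a YAML config with
deterministic outputs, and `scripts/acceptance.R` reproduces the
headline numbers from a single seed. Problem sizes in the shipped tests
(500-replicate Monte-Carlo calibrations, 1000-case dihedral oracle
sweeps, 8000-triplet intrinsic-rate comparisons, 10^4-frame telegraph
series) were chosen to characterize estimator bias and coverage well
while keeping a full run comfortable on a laptop.
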