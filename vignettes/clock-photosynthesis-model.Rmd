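---
title: "A circadian-clock-controlled model of tomato photosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A circadian-clock-controlled model of tomato photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoclock)
```

## The model

`photoclock` implements a kinetic model of how light intensity shapes
photosynthesis in tomato through the circadian clock. The system has 29
state variables:

* **Core oscillator (12 states).** Six gene pairs — CL (CCA1/LHY), P97
  (PRR9/PRR7), P51 (PRR5/TOC1), EL (ELF4/LUX), GI and RVE8 — each as an
  mRNA/protein pair. Transcription is Hill-type (shared exponent 2 by
  default), translation and degradation are first order.
* **Complexes and active pools (8 states).** The evening complex EC
  (formed from EL protein), the RVE8–LNK coactivator complex RL, the
  light-stabilised ZTL–GI complex ZG with its free ZTL pool, the COP1
  conversion chain (cytoplasmic, nuclear-night, nuclear-day), and HY5.
* **Light-sensitive protein P (1 state).** `dP/dt = s_p D (1 − P) −
  d_p f L P`: P accumulates in darkness towards saturation at 1 and is
  degraded in light, so it is maximal at dawn and conveys acute dawn
  light inputs `q · f · L · P` to the light-responsive promoters (CL,
  P97, EL, RVE8).
* **Photosynthetic output (8 states).** Four gene pairs: *Lhcb1*
  (activated by CL, inhibited by GI in the extended variant; CL-only in
  the control variant), and *psbA*, *RbcS1*, *atpA* (repressed by CL).

The regulatory wiring follows the compact plant-clock tradition:
CL represses P97, P51, GI and its own promoter; the evening complex
represses P97 and P51; RL (driven by dawn-phased RVE8) coactivates P51
and EL, closing the RVE8 ⇄ P51 negative loop; GI is repressed by CL,
P97 and P51. The two post-translational couplings (COP1 action on EC,
ZG-mediated dark destabilisation of P51) are present in the equations
but fixed at zero in the default parameter set: fits behave equally well
without them, so the default is the lower-dimensional set and they are
exposed through the free/fixed mask for anyone who wants to explore
them.

### Light input

Light enters three ways:

1. the binary gate `L`/`D` (1 = lights on / off) from the protocol;
2. the dimensionless intensity scale `f(I) = I / (I_A I² + I_B I +
   I_C)`, neutral at `(0, 1, 0)`; the shipped constants solve
   `f(100) = 1` and `f(62.5) = 0.8` with `I_A = 0`, which puts
   `f(187.5)` at 1.24 and keeps `f` strictly increasing and saturating
   (at `1/I_B ≈ 1.71`) — the monotone member of the family matching the
   required orderings;
3. intensity-scaled light-gated degradation `m·f·L` on the evening
   transcripts (MEL, MGI) and on P and nuclear COP1.

The third term deserves a note. The acute `q f L P` input vanishes under
constant light because P decays to zero, yet free-running behaviour must
still depend on fluence rate (periods shorten with intensity, and
*Lhcb1* loses rhythmicity above a fluence threshold). Scaling the
light-gated turnover terms by `f` gives constant light a persistent,
intensity-dependent effect with a single mechanism, and produces both
the period ordering and the high-intensity loss of rhythm without any
extra parameters.

## Simulation

The integrator is the classical fixed-step fourth-order Runge–Kutta
scheme (compiled; `dt` must divide one hour so that light switches fall
on grid boundaries — the light state is frozen at each step's midpoint,
so no step straddles a discontinuity mid-stage). The default step is
0.025 h; halving it changes no state by more than 1e-4 relative at the
end of a two-segment protocol, which is the convergence gate the test
suite enforces. The reliability scans use 0.05 h, whose integration
error is still orders of magnitude below the rhythm-estimator
tolerances they feed. States are clamped at zero only against sub-1e-8
round-off undershoot; any real excursion aborts integration with the
offending step.

Protocols are ordered segments (duration, photoperiod, intensity).
The canonical ones: `muller_LL` (5 d LD 12:12 at 100 µmol m⁻² s⁻¹, then
constant light at 100 — the free-run design of the calibration data),
`MI_to_LI` / `MI_to_NI` (entrain at 100, then 48 h of LD at 62.5 /
187.5), and `MI_to_MI` (continuation control). `run_protocol()`
prepends a 10-cycle LD burn-in by default (the experimental designs
entrain 5 days; the longer burn-in brings the state close to the
entrained orbit and is discarded — full convergence of the shipped set
to cycle-to-cycle repetition below 1% takes about 15 cycles, which is
what the entrainment test uses) and re-zeroes time at lights-on of the
first treatment day, so all reported phases are ZT hours.

## Rhythm analysis

Three estimators, used per series and aggregated (arithmetic mean/SD for
period, circular mean for phase):

* `estimate_mfourfit()` — least squares with a mean plus three harmonics
  of a shared fundamental, the fundamental optimised over 18–34 h
  (coarse grid, then local refinement). Phase is the ZT time of the
  fitted curve's maximum; estimates landing on the window edge carry a
  boundary flag.
* `estimate_mesa()` — Burg maximum-entropy AR spectrum (order by AIC)
  evaluated on a fine frequency grid (2 × 10⁻⁵ cycles/h) with quadratic
  peak refinement. The fine grid is deliberate: a 10⁻³ cycles/h grid
  would limit period resolution to ~0.6 h at 24 h, coarser than the
  0.5 h cross-method concordance the suite checks.
* `estimate_enright()` — the folding periodogram: bin the series modulo
  each candidate period (bin width = sampling interval) and score the
  variance of bin means over total variance; phase is the peak bin.

Phase throughout is "peak time in ZT hours", matching how peak times are
reported for the experimental series, not the acrophase of a cosine
fundamental. Sparse replicate series (the RT-qPCR-like design: 2 h
sampling in cycle 1, 4 h in cycle 2, three replicates) are analysed per
replicate and aggregated across replicates; dense simulated series are
analysed once per method and aggregated across methods.

## Parameter estimation

`cost_delta()` scores a parameter set against targets as
`w_expr · RMSE` (both sides max-normalised, so raw scaling of the data
is irrelevant) plus period and phase penalties that are hard-zeroed
inside the target windows (period 24–28 h; LL peak windows CL 0–4,
P97 6–10, P51 12–15, EL 10–15, GI 11–13, RVE8 0–3 ZT h). Failed
simulations contribute a large finite penalty (1e6) rather than an
exception, so the optimiser can traverse bad regions.

`simulated_annealing()` is a plain Metropolis annealer: single-coordinate
proposals, multiplicative in log space for strictly positive
coordinates (rates and thresholds span decades; additive steps would
either freeze small parameters or blow past bounds), geometric cooling
(factor 0.95 per 50 proposals by default), stop at `T < 10⁻³ T₀`,
best-ever state returned, fully reproducible from the seed.

### The calibrated default set

No reference parameter values are available to load, so the shipped
default set was produced by the package's own staged annealing runs
against the constraints above: first the four-pair oscillator skeleton
(sustained limit cycle, period near 24.5 h, phase ordering), then GI,
RVE8 and the complexes, then the light-coupling parameters against the
light-flux conditions (period ordering 62.5 > 100 > 187.5 and the 1–2 h
peak delay of low versus normal light), and finally the photosynthetic
gene parameters against their target peak times (Lhcb1 mid-morning,
psbA midday, RbcS1/atpA evening). The staging exploits the wiring: the
photosynthetic side reads CL and GI but never feeds back, and the
light-coupling terms are inert in the free-run fit, so later stages
cannot undo earlier ones. Calibration quality is asserted by the test
suite (`check_constraints()` passes; period and phase orderings hold),
not by agreement with any published table to a fixed tolerance — the
published simulated values depend on a parameter set and digitised
series that are not redistributable, so only their structure (orderings,
windows, intervals) is reproducible here.

## Reliability analysis

* `robustness_scan()` perturbs every free parameter ±10%, re-simulates
  the free run, and reports percent changes in CL and P51 mRNA period
  and phase. Phase changes are circular distance divided by the baseline
  period ×100 — the only scale-free choice since no denominator is
  prescribed. Arrhythmic perturbed runs are flagged and excluded from
  the maxima with a warning.
* `sensitivity_scan()` scans folds of 10⁻³–10³ (25 log-spaced points)
  per parameter and records whether the period window and all six phase
  windows still hold; the viable range is the maximal contiguous passing
  interval around fold 1.
* `hopf_scan()` classifies rhythmicity two ways — post-transient
  peak-to-trough above 1% of the mean (no amplitude threshold is
  prescribed; 1% separates numerical ripple from genuine cycling), and
  the sign of the leading complex eigenvalue pair at the constant-light
  fixed point (damped Newton from the trajectory mean, central
  finite-difference Jacobian with step 1e-6·max(1, |state|)) — and
  bisects criterion sign changes to 1e-3 relative. The two criteria
  disagree only near the bifurcation (a subcritical window or slow
  transients), which is why both are reported.

## Synthetic data

`generate_qpcr()` emulates relative-quantification expression series:
simulate the truth, sample on the 2 h / 4 h two-cycle grid, multiply by
mean-one lognormal noise per replicate (σ = 0.1 by default — a typical
relative-quantification replicate CV, configurable and not derived from
any published value), and max-normalise so the replicate-mean curve
peaks at 1. `generate_gas_exchange()` evaluates the Hill output model

P_i = α_i + ( CL²/(K_i1²+CL²) + Σ_j X_j²/(H_ij²+X_j²) ) · K_i3²/(K_i2²+GI²)

on simulated drivers (CL, GI and the four photosynthetic proteins
X_j) and adds the same noise. `K_i3` acts as an output amplitude scale
in the parameter's native units; it is the only coefficient whose role
is an interpretation rather than a stated mechanism, and it is fitted
like the others. The output model is algebraic — an observable of the
trajectory, not an additional differential equation.

What the generator does *not* emulate: amplification-curve mechanics,
reference-gene normalisation error, serial correlation of replicate
noise, photobleaching/drift in gas-exchange instruments, or
developmental trends across the two measurement days. Tests passing on
these synthetic data therefore demonstrate internal consistency of the
pipeline (round-trip recovery, orderings, window logic), not field
validity.

## What the shipped calibration does and does not achieve

The staged fit gives a self-sustained ~24.4 h free-running clock that
entrains to LD 12:12, shows strict Aschoff ordering of estimated
periods across 62.5/100/187.5 µmol m⁻² s⁻¹ for all ten genes, peak
delays of 1.1–1.5 h at low versus normal intensity for the
morning-to-evening genes, and photosynthetic output with *Lhcb1*
peaking mid-morning and *psbA* at midday under GI inhibition that
measurably improves the fit over the CL-only control variant. Three
gaps are structural to this compact re-derivation and are reported,
not hidden:

* **P51's free-run peak window.** P51 and P97 share their
  transcription window (CL clearance opens both, the evening complex
  closes both), so P51 mRNA peaks mid-morning rather than in the
  target early-afternoon window. Every wiring variant that pushed P51
  later destabilised the limit cycle or displaced other genes.
* **Dawn-gene peak delays.** CL and RVE8 are anchored to dawn by their
  acute light inputs, so their low-light peak delays stay well under
  1 h; dawn genes shifting much less than evening genes is the expected
  signature of strong dawn anchoring.
* **Phase robustness.** With an intrinsic period of ~24.4 h against
  the 24 h zeitgeber, the entrained phase angle is sensitive to ±10%
  parameter changes (single perturbations can move release-day peaks
  by hours even though the period shifts by a few percent at most).
  The same weak coupling is what produces the intensity-dependent
  phase delays, so stiffening entrainment to stabilise phase would
  erase the delay behaviour; the trade-off is intrinsic to this
  equation set.
* **Evening photosynthetic phases.** *RbcS1* and *atpA* peak
  mid-afternoon rather than in the evening: their only modelled
  regulator is CL repression, and the calibrated CL protein reoccupies
  their promoters from mid-afternoon on.

## Numerical choices and limitations

* Problem sizes in the shipped tests and acceptance script: free-run
  analyses use 10 burn-in cycles + 4–6 analysis days at dt = 0.05 h;
  optimisation loops use dt = 0.1 h and 6–8 burn-in cycles. These are
  the coarsest settings whose integration and estimator error stay
  well under the assertion tolerances.
* Robustness percent-changes use the harmonic fit's fitted-curve peak
  rather than the raw dominant-peak label: the label can jump between
  near-equal humps of a multi-modal waveform under infinitesimal
  changes, which would measure relabelling rather than dynamics.
* Parameter recovery from max-normalised expression data has the usual
  sloppy direction (synthesis and turnover of the same transcript
  rescale each other); refits pin the well-conditioned parameters
  tightly while the sloppy combination can stay ~30% off with the
  fitted cost below the noise floor. The fitter therefore reports its
  cost trace, and the recovery tests check both the parameter errors
  and the cost floor.
* Degenerate inputs: constant series are an error for min–max
  normalisation and MESA (no spectral peak), an empty result for peak
  detection, and a flagged violation (not an exception) for constraint
  checks.
* Ties in peak detection resolve to the earliest peak; quadratic
  interpolation uses the three points around each discrete argmax.
* The Hill exponent is global (default 2). Gene-specific exponents are
  representable in the registry but were not needed to meet the
  constraints.
* The model holds temperature constant, has no light-quality input and
  no sugar feedback from photosynthesis to the clock; the gas-exchange
  model is phenomenological (no Farquhar-type mechanistic layer), so
  absolute gas-exchange units are only as meaningful as the fitted
  coefficients.
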