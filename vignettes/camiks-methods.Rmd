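---
title: "Methods: from CaM-variant biophysics to simulated action potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CaM-variant biophysics to simulated action potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camiks)
```

# Scope

Loss-of-function calmodulin (CaM) variants found in long-QT-syndrome
patients reduce the slow delayed-rectifier potassium current IKs carried by
Kv7.1/KCNE1. `camiks` implements the quantitative chain that connects the
wet-lab observables of such a study to a prediction about the ventricular
action potential:

1. voltage-clamp analysis (current densities, normalised conductance,
   Boltzmann activation fits) and the fractional IKs reduction per variant;
2. binding biophysics (one-/two-site ITC isotherms, thermodynamic
   decomposition, NMR chemical-shift perturbation, thermal melts,
   proteolysis densitometry, flow-cytometry surface density, extinction
   coefficients);
3. a human ventricular myocyte model in which a Hill-type CaM-dependent
   block multiplies the IKs conductance, with the block constant calibrated
   so the simulated reduction in peak IKs equals the measured one, and the
   action-potential duration at 50% repolarisation (APD50) read out.

Every stage has a synthetic-data generator with the statistical structure
the stage assumes, so the whole pipeline is testable without instrument
data.

# The myocyte model

The simulation engine is the O'Hara–Rudy human ventricular myocyte model in
its CiPA v1.0 (2017) form: the 2011 membrane and calcium-handling equations
with the 2017 rescaled maximal conductances (ICaL ×1.007, IKr ×1.013,
IKs ×1.87, INaL ×2.661, IK1 ×1.698) and the six-state hERG Markov scheme
for IKr. The drug-bound hERG states of the published scheme are identically
zero without drug and are omitted, leaving 45 state variables. The
transcription lives twice in the package, deliberately: a compiled C
right-hand side (the production path used by the `deSolve` integrator) and
an independently written pure-R transcription. The test suite compares the
two at 100 randomised states to below 1e-8 relative error, which guards
against coding slips in either copy.

Integration uses `lsoda` with relative tolerance 1e-6 and absolute
tolerance 1e-8; each beat is integrated as a stimulus segment followed by a
free segment so the stimulus discontinuity never sits inside a solver step.
Tightening both tolerances tenfold moves APD50 by less than 0.05 ms.

## Pacing and the steady-state convention

The study protocol is: endocardial cell, cycle length 1000 ms, stimulus
−80 µA/µF for 0.5 ms, paced until the APD50 of consecutive beats changes by
less than 0.1 ms (at least 20 beats, cap 1000). Cell type, rate and
stimulus are exposed in `ord_params()` / `pacing_protocol()` because none
of them is uniquely dictated by the biology; the defaults are the model's
published reference protocol.

One behaviour deserves note: after the consecutive-beat criterion is met
(around beat 20 from rest), intracellular Na⁺ keeps drifting on a much
slower timescale, and APD50 creeps down by a further ~2.5 ms over hundreds
of beats. The consecutive-beat criterion is the package's convention for
"steady state"; users who want the fully drift-free limit can raise
`min_beats`. All headline APD50 numbers in this package use the stated
convention.

## APD measurement

Amplitude is the peak potential minus the pre-stimulus diastolic potential.
APD at fraction *p* runs from the time of maximum upstroke velocity to the
first subsequent downward crossing of `V_peak − p·amplitude`, with linear
interpolation between samples (0.25 ms output grid). The "duration at 50%
of the amplitude" phrase underdetermines both the start anchor and the
amplitude reference; this choice is the conventional one and is applied
uniformly, so variant-versus-WT differences are insensitive to it.

# The CaM block and its calibration

The block enters as a single multiplier on the IKs conductance,

$$f = \frac{[c]}{[c] + K_b},$$

with the CaM concentration term $[c]$ held constant (default 1, arbitrary
units). Since only the achieved reduction in peak IKs is observable, only
$f$ is identifiable; $[c]$ and $K_b$ are reported for interpretability but
any pair with the same ratio is equivalent. A hook for binding $[c]$ to a
time-varying model signal exists in the code path (the multiplier is
evaluated inside the right-hand side) but is off by default, because the
source model carries no explicit free-CaM state to bind to.

`calibrate_kb()` finds $K_b$ by bracketed root finding so that the
steady-state peak IKs of the blocked, re-paced model is reduced by the
target fraction to within 1e-3 (closed loop: AP-shape feedback on IKs is
included). Because peak IKs responds almost linearly to $f$, the bracket
$[1-r, 1]$ nearly always contains the root and calibration costs only a few
re-pacings, each warm-started from the converged unblocked state. A
`feedback = "frozen"` mode replays the baseline waveform, under which peak
IKs is exactly proportional to $f$ and the calibration is exact in one
step; it exists as a diagnostic for how much the closed loop matters (the
calibrated $f$ differs from $1-r$ by well under 0.05).

## Which measured condition supplies the block targets

The measured current densities at +100 mV exist at two free-Ca²⁺ levels
(resting, 100 nM; high, 1 µM). The package defaults to the resting-Ca²⁺
fractions (D95V 0.537, N97I 0.271, D131H 0.343) because only that
condition's variant ordering — D95V > D131H > N97I — matches the ordering
of the reported APD prolongations. This is a documented inference, not a
statement from the source; `cam_block_targets("high_1uM")` switches
conditions and any tibble of `variant`/`r` pairs can be supplied.

# Voltage-clamp analysis

Chord conductance is computed from peak step currents,
$G(V) = I_\mathrm{peak}(V)/(V - E_K)$, with $E_K \approx -88.5$ mV, the K⁺
Nernst potential for 4 mM external / 130 mM internal K⁺ near room
temperature. $E_K$ is an argument, never hard-coded, because tail-current
conductance (the main alternative reading of "normalised peak conductance")
would change $G_{max}$ but not the activation midpoint. Activation curves
are fitted per cell with
$G/G_{max} = g_{max}/(1 + \exp((V_{1/2}-V)/k))$ by Levenberg–Marquardt,
initialised at the empirical half-maximum voltage with a 15 mV slope. The
amplitude is left free: normalising by the largest *sampled* conductance
puts the top of the curve slightly below 1, and pinning it would bias
$V_{1/2}$ by tenths of a millivolt even on noiseless data. With noise, the
per-cell estimator scatters exactly as per-cell experimental estimates do
(several mV at 5%-of-peak current noise); the Monte-Carlo mean stays within
1 mV of truth.

`block_fraction()` is deliberately trivial — $r = 1 - I_{var}/I_{WT}$,
clipped at 0 — because it is the single number that couples the
experimental half of the package to the simulation half.

# ITC isotherms

Both forward models share one displacement-dilution convention with the
synthetic generator: after cumulative injected volume $v$ into an active
volume $V_0$, cell species scale by $(1 - v/2V_0)/(1 + v/2V_0)$ and total
titrant is $X_s\,(v/V_0)/(1 + v/2V_0)$. Per-injection heats are
differential heats of the cumulative binding heat
$Q_i = V_0 M_i \sum_j n_j \Delta H_j \theta_{ij}$ with the displaced-volume
correction $\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$.
One-site occupancy solves the usual quadratic; the two-site (independent
classes) free-ligand concentration solves the mass balance by bracketed
root finding polished to machine precision, so bound-plus-free titrant
closes to ~1e-15 relative. First-injection discard is available but off by
default (drop the first row of `injections` to apply it).

Fitting is Levenberg–Marquardt on $(\log n, \log_{10} K_d, \Delta H)$ per
site class. The two-site fit starts from the one-site fit, but a single
start is not reliable here: a tight first site at tens-of-µM cell
concentration has a c-value around 10⁴–10⁵, far beyond the identifiable
window, and one start routinely lands in a local minimum. The fitter
therefore uses a fixed six-point grid of affinity splits around the
one-site solution (factors 1, 10⁻², 10⁻⁴ on the tight side and 1, 10² on
the weak side, stoichiometry halved) and keeps the lowest-SSE result.
The grid is deterministic, so fits are reproducible; on noiseless synthetic
isotherms at the study's own reported parameter regimes it recovers both
dissociation constants to better than 1e-6 relative. Site classes are
reported in ascending $K_d$.

Thermodynamics use $\Delta G = RT\ln K_d$ (molar standard state,
R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, default 298.15 K) and
$-T\Delta S = \Delta G - \Delta H$, so the closure
$\Delta G = \Delta H + (-T\Delta S)$ holds to rounding.

# Small metrics

* **Chemical-shift perturbation**: $\Delta\delta = \sqrt{\Delta H^2 +
  (0.15\,\Delta N)^2}$ ppm. Unassigned residues keep `NA` in every numeric
  column; the conventional −0.1 ppm value appears only in a dedicated
  `delta_display` column, so the display sentinel can never leak into an
  average.
* **Thermal melts** are fitted as Boltzmann sigmoids with free plateaus
  (robust to imperfect normalisation); the melting temperature is the
  midpoint parameter and must fall inside the sampled range. The fit
  expects an unfolding signal that increases with temperature; normalise a
  decreasing ellipticity trace before fitting.
* **Flow cytometry** implements the gated-count quotient
  (double-positive − label-only)/channel-positive, clipped to [0, 1]; the
  gates are independent so the difference can legitimately be negative
  before clipping.
* **Densitometry** normalises band intensities by the zero-protease lane
  (lanes at concentration 0 are averaged if replicated).
* **Extinction coefficients** use the composition rule
  5500·Trp + 1490·Tyr + 125·cystine, reduced cysteines contributing
  nothing by default. None of the bundled sequences contains a disulfide,
  so the oxidised option does not affect them.

# Synthetic data: what it does and does not emulate

The generators draw additive Gaussian noise around the exact forward models
(peak currents over the −60…+100 mV ladder; per-injection heats under the
20 × 2 µl protocol into ~50 µM macromolecule; 15–90 °C melts in 1 °C steps;
per-residue shift tables with a localised perturbed region). Noise levels
are not estimates of any instrument — the source data report none — and the
defaults (5% of peak current; 0.1 µcal; 0.02 signal units; 5 mppm baseline
shifts) were chosen once as values a practitioner would call realistic.
Every generator takes an explicit integer seed and is bit-reproducible; no
global RNG state is consumed.

What passing the round-trip tests shows is that the estimators are correct
and well-conditioned *under the stated noise model*. Real recordings add
structure the generators deliberately omit: leak and capacitance artefacts
and rundown in voltage clamp, baseline drift and first-injection anomalies
in ITC, spectral overlap in NMR, saturating gels in densitometry. The
analysis functions make no claim of robustness to those; they assume the
field-standard preprocessing has already happened.

# Known limitations

* The myocyte model is a single-cell endocardial description; no tissue
  coupling, no transmural dispersion, no arrhythmia end-points.
* The CaM block is a time-independent conductance multiplier; state- or
  Ca²⁺-dependent block would need the time-varying hook.
* Only independent-site ITC models are provided (no sequential or
  cooperative schemes), matching how the study's isotherms were fitted.
* Experimental parameter values (V₁/₂ tables, binding constants) are
  *inputs or fit targets* here; raw traces are not reconstructable from
  them, and the package does not pretend otherwise.
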