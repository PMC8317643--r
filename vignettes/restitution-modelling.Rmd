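---
title: "Restitution-driven calibration of minimal ventricular models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restitution-driven calibration of minimal ventricular models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restforge)
```

# The problem

Action potential duration restitution (APDR) — the dependence of action
potential duration (APD) on the preceding diastolic interval (DI) — is a
central dynamic property of ventricular myocardium: steep restitution
promotes APD alternans and wavebreak, and remodeled myocardium (for example
the surviving tissue of ischemic cardiomyopathy, ICMP) shows steeper APDR
than structurally normal left ventricles (SNLV). Clinically, APDR is
measured during decremental fixed-rate pacing from unipolar electrograms:
the activation-recovery interval (ARI, the interval from the steepest
negative deflection of the activation complex to the steepest positive
deflection of the repolarization wave — the Wyatt convention) is a
validated surrogate of local APD.

`restforge` implements the full computational chain that turns such pacing
data into mechanistic statements about arrhythmia susceptibility:

1. **Signal processing** — Wyatt ARI extraction, beat exclusion, robust
   logarithmic restitution fits (`wyatt_ari()`, `build_apdr()`,
   `fit_log_robust()`).
2. **Model calibration** — a genetic algorithm (GA) fits the 28-parameter
   four-variable minimal ventricular model to a cohort APDR target
   (`run_ga()`).
3. **Uncertainty quantification** — agglomerative hierarchical clustering
   of the final GA population (`ahc_linkage()`, `cut_top()`,
   `percentile_constrain()`).
4. **Pro-arrhythmia assessment** — single-cell alternans scans
   (`alternans_scan()`) and 2-D monodomain S1S2 cross-field re-entry
   sweeps (`inducibility_sweep()`).

A synthetic electrogram generator (`synth_truth()`, `synth_unieg()`) with
per-beat ground truth makes the signal-processing stage testable without
clinical recordings.

# The cell model

The minimal ventricular model evolves a dimensionless transmembrane
variable `u` and three gates `v, w, s` under three currents — fast inward
(`J_fi`, excitation), slow outward (`J_so`, repolarization) and slow
inward (`J_si`, plateau) — switched by Heaviside thresholds (we take
`H(0) = 1`). The package uses the published endocardial parameter column
(`base_params()`) and the published affine rescaling `V = 85.7 u − 84` mV.
The resting state is the model's true fixed point
`(u_o, 1, 1, s_inf(u_o))`: note that `s_inf(u_o) ≈ 0.0216`, not 0; with
`s = 0` the `s`-gate rate would be nonzero at rest.

Integration is explicit forward Euler. The model is stiff only during the
upstroke (`tau_fi = 0.1` ms); `dt = 0.02` ms is the reference step
(halving it moves APD90 by well under 0.5 ms), `dt = 0.05` ms is used
inside tissue simulations and `dt = 0.1` ms inside GA fitness evaluation,
where the residual discretization bias (below ~1 ms in APD90) is far
inside the calibration tolerance and halves the cost of a population
evaluation.

## Pacing, stimulus and biomarkers

The pacing stimulus is rectangular, 1 ms long, at twice the diastolic
threshold of the base model (threshold found once by bisection,
`diastolic_threshold()`). APD measurement: activation is the time of
maximum dV/dt during the upstroke; APDx is the interval from activation to
the **last** downward crossing of `RMP + (1 − x/100)·(Vmax − RMP)` before
the next stimulus (linear interpolation between samples; the last crossing
makes the measure robust to the spike-notch-dome shape). The diastolic
interval runs from the previous beat's 90%-repolarization time to the next
activation.

## The reference biomarker table protocol

The endocardial model has an unusually strong voltage-memory mechanism:
`w_inf = 1 − u/0.0273` reacts to the slowly decaying diastolic voltage
tail (`tau_o1 = 470` ms below `theta_o`), so during sustained pacing the
`w` gate rests near 0.87 rather than 1 and steady-paced APDs are ~40 ms
shorter than a beat elicited from true rest. The published biomarker panel
for the base model (RMP −84.0 mV, APD30 123.7, APD50 226.5, APD90 276.3
ms, Vmax 53.8 mV) is reproduced, to printed precision, by a **single
action potential from rest** at a 500 ms cycle length with a 1 ms stimulus
at three times the diastolic threshold; the peak value (u ≈ 1.61 > u_u)
requires a fully recovered `v` gate and is therefore itself evidence of a
from-rest beat. `table_biomarkers()` implements exactly this protocol;
steady-paced biomarkers remain available through `simulate_train()` +
`extract_biomarkers()`. Because Vmax, Tmax and dV/dt_max depend directly
on the (unknown) stimulus specification, only the voltage-threshold
durations should be treated as protocol-robust.

# The synthetic electrogram generator

`synth_truth()` draws, per patient and electrode, a restitution slope from
the clinical variance components (between-subject SD 13.9 / 29.1 ms and
within-subject SD 6.4 / 29.1 ms for SNLV / ICMP; slopes truncated to the
physiologic 5–180 ms range), pivots each electrode's log curve through the
cohort's 600 ms anchor (intercept variance components are not reported
clinically, so a 6 ms intercept jitter is a free parameter), and then
iterates the explicit pacing recursion `DI_n = CL − ARI_(n−1)`,
`ARI_n = alpha + beta·log(DI_n) + noise` through the clinical protocol
(20 beats per burst, 600→350 ms in 50 ms steps, 2 s inter-burst gaps —
electrically equivalent to the clinical minutes-long pauses). The DI
entering the curve is capped at the electrode's 600 ms steady-state value
(restitution saturation), which also bounds post-gap first beats. Beats
whose DI would be non-positive are flagged and not emitted.

`synth_unieg()` renders each beat as a fast derivative-of-Gaussian
activation wavelet (scale 4 ms) and a slower repolarization wave of
opposite polarity (scale 20 ms), sampled at 977 Hz. A
derivative-of-Gaussian has its single dominant time-derivative extremum
exactly at its center, so the Wyatt fiducial points are placed at the
ground-truth activation/repolarization times *by construction* — the
property the extraction stage is tested against. Optional noise: white
noise, baseline wander, 60 Hz interference, and biphasic pacing artifacts.

What the generator does **not** emulate: far-field forward-modelled
electrogram morphology, fractionated or low-voltage scar signals,
catheter motion, and ARI temporal lability beyond white noise. Passing the
round-trip tests therefore demonstrates the correctness of the detector's
logic and its noise robustness in the modelled regime, not clinical-grade
performance on pathological signals.

# ARI extraction and restitution fitting

`wyatt_ari()` uses fixed, deterministic windows: activation in
`[stimulus + 2 ms, stimulus + 0.4·CL]`, repolarization in
`[AT + 0.25·CL, next stimulus − 5 ms]`; derivatives are centred
differences after Savitzky–Golay smoothing (cubic, 11 samples), and a
window whose extremum does not exceed 5 MADs of the channel derivative is
marked `no-detection`. The clinical pipeline used a semi-automatic
template-matching workflow whose details are not public; fixed windows
trade a little generality for reproducibility.

`build_apdr()` applies the clinical steady-state rule — drop the first
three and the last beat of each burst — and pools the remainder.
`fit_log_robust()` fits `ARI = alpha + beta·ln(DI)` by IRLS with Tukey
bisquare weights (tuning constant 4.685, convergence 1e-8 or 50
iterations; `MASS::rlm` provides the IRLS machinery). R² is computed with
the final robust weights (the robust-R² definition is not standardized;
this one reduces to ordinary R² when all weights are 1) and curves with
R² ≤ 50% are rejected. The natural logarithm is used throughout; slope
values are base-dependent.

`compare_cohorts()` provides a dependency-light cohort contrast: the
difference of cohort means of patient-mean slopes with a patient-level
(cluster) bootstrap percentile CI, respecting the nesting of electrodes
within patients. It replaces, without imitating, the clinical
mixed-effects analysis, which is out of scope.

# GA calibration

## Target reconstruction

Two reconstructions of a cohort's average APDR curve are offered by
`cohort_target()`:

* `method = "average"` (default): slopes from the published mixed-model
  contrasts — SNLV `30.8/0.38 = 81.1` ms, ICMP `81.1 + 30.8 = 111.9` ms —
  anchored through the cohort centroid `(mean ln DI, mean ARI)` of the
  reference table. The reconstruction is internally validated: the implied
  intercept difference (−185.5 ms) matches the published −182.3 ± 57.7 ms.
* `method = "anchors"`: OLS log fit to the per-cycle-length cohort mean
  (DI, ARI) anchors. Averaging points across heterogeneous electrodes
  flattens the curve (slopes 49.3 / 93.8 ms), so this underestimates the
  electrode-level average steepness.

Both curves agree near the clinical 500 ms operating point, so either
reproduces the published fitted-model APD90 at 500 ms; only the steeper
average curves also reproduce the published alternans onsets, which is why
`"average"` is the default.

## Search design

The genome is the 27 searched parameters in log space,
`z = log(p/base)`; `u_o` is pinned (the affine voltage map fixes
RMP = −84 mV). Bounds: `[1/20, 20]×base` for time constants and slope
factors (wide enough for the ~17-fold gate-kinetics remodeling the
calibration discovers), `[0.5, 2]×base` clipped to (0, 1.6) for
thresholds and gate midpoints. Operators: tournament selection (size 3),
per-gene blend crossover (BLX-0.5, probability 0.9), per-gene Gaussian
log-space mutation (probability 2/28, SD 0.1), elitism 2, and a stall rule
(stop when the best fitness improves by under 0.01 ms across 25
generations).

Initialization is **local-iterative** by default: Gaussian log-space
perturbations of the base model (SD 0.15) with the base individual
injected once. The minimal model's fitness landscape is heavily
degenerate; at desk-scale population sizes a log-uniform initialization
over the full 400-fold box converges to arbitrary far corners (for
example ~18-fold changes in upstroke time constants that clinical
restitution data cannot inform) whose emergent alternans behavior varies
wildly from seed to seed. Starting in the physiological basin produces
the single-dominant-cluster population structure and seed-stable emergent
behavior; `init = "uniform"` remains available for landscape exploration.

Fitness is the mean absolute error (ms) between the simulated
dynamic-restitution points (clinical beat exclusion, DIs inside the
target's validity range) and the target curve, plus `lambda = 0.1` times
the mean absolute voltage deviation (mV) from an action-potential
morphology template (the base model's beat at the protocol's first cycle
length, resampled at 1 ms). Non-capturing or diverging parameter sets
receive a finite 1000 ms penalty so the population search continues.

Desk-scale defaults (`ga_config_desk()`): population 100, at most 60
generations, fitness protocol 600→350 ms in 50 ms steps with 10 beats per
block at `dt = 0.1` ms — a few minutes per cohort on one CPU. The
reference scale (population 1512, hundreds of generations, 20-beat
blocks) is available through `ga_config()`.

# Clustering the calibrated population

Populations are normalized to log2 fold-change versus the base set
(`normalize_population()`) so distances are scale-free; clustering is
average-linkage (UPGMA) on Euclidean distances, chosen because it defines
the cophenetic structure being reported and is robust to the
one-giant-cluster geometry these populations exhibit. The cophenetic
correlation coefficient (between original and dendrogram-implied
distances) quantifies tree faithfulness. `cut_top()` cuts at the k−1
highest merge heights (ties resolved by the deterministic merge order),
reports sizes in decreasing order, and returns cluster centroids
(arithmetic means in normalized space, de-normalized for output).
`percentile_constrain()` implements the extreme-value sensitivity
analysis; the published phrase "within the 99th percentile" is ambiguous
between one- and two-sided readings — it is implemented as the two-sided
per-parameter `[100−p, p]` marginal band.

# Alternans scans

`alternans_scan()` paces 10 beats per cycle length over the 620→260 ms,
5 ms grid and applies the published rule: onset is the longest cycle
length with `|APD_last − APD_prev| ≥ 2` ms at two consecutive cycle
lengths. Two block-chaining modes exist because the published protocol
does not specify one:

* `"burst"` (default): each cycle-length block starts from the same
  pre-paced steady state (100 beats at 600 ms) — the natural
  embarrassingly-parallel layout, and the same pre-pacing used at tissue
  level. For models with long pacing memory, post-step adaptation is then
  part of what the last-two-beat criterion measures, and calibrated
  cohort models show onsets in the clinically reported range, stable
  across seeds and solution families.
* `"continuous"`: state carried across blocks (a strict decremental
  ramp). Memory-heavy models settle further by the time a given cycle
  length is reached and register onsets 100+ ms later in the ramp.

The grid is truncated at the first block losing 1:1 capture, where
alternation ceases to be assessable. `map_alternans_scan()` iterates the
memoryless 1-D restitution map through the same protocol and onset rule;
its bifurcation point has the closed form `CL* ≈ alpha + beta(1 + ln
beta)`, which the test suite uses as an oracle for the detection logic.
One property worth knowing: with only 10 beats per block the rule fires
slightly *above* the asymptotic bifurcation for slowly-settling maps,
because residual settling drift can reach the 2 ms criterion.

# Tissue simulations

The monodomain sheet is 2 cm × 2 cm (the 0.25 mm physical thickness is
collapsed to a 2-D monolayer — no transmural dynamics are possible at
that thickness), isotropic, `dx = 0.025` cm (80 × 80 nodes),
`dt = 0.05` ms, five-point Laplacian with no-flux (mirror) boundaries
(absent neighbors contribute nothing, so the discrete operator sums to
zero — exact conservation). The CFL-type bound `dt ≤ dx²/(4D)` is
enforced at run time. Conductivity maps to diffusivity via `D = kappa·
sigma`; `kappa` is calibrated once (`calibrate_kappa()`) so the
plane-wave conduction velocity at 0.012 S/m equals 74 cm/s, the top of
the clinically observed 17–74 cm/s range, using the square-root
CV–diffusivity scaling of cable theory as the update rule. At the default
grid the upstroke is spanned by only ~2.5 nodes, so absolute CV carries a
discretization bias that the one-time calibration absorbs; grid
convergence (CV changes < 5% per halving of dx) holds from
`dx = 0.0125` cm downward and is verified on a narrow transverse strip,
which is equivalent for a planar wave.

Pre-pacing is performed at cell level (100 beats at 600 ms) and the final
state broadcast to all nodes — exactly equivalent to tissue pre-pacing
because diffusion of a uniform state vanishes, at a tiny fraction of the
cost. The S1S2 cross-field protocol delivers S1 over the bottom
2 cm × 0.5 mm strip at t = 0 and S2 over the lower-left 1 cm × 1 cm
square at the coupling interval; activation is an upward crossing of the
rescaled −40 mV level with a 5 ms per-node deadtime. Activity persisting
beyond 2 s after S2 is "sustained" re-entry; "induced" means activity
outlasting a single planar response (> 500 ms after S2). Simulations
terminate early once the sheet is quiescent, or as soon as an activation
beyond the 2 s horizon proves sustainment. `inducibility_sweep()`
records the sustained outcome over a conductivity × coupling-interval
grid and extracts per-conductivity windows; individual failures are
recorded as missing and a partial map can be resumed.

# Problem sizes

The shipped tests and the acceptance script run everything at desk
scale, chosen so the full suite completes comfortably on one CPU:
GA population 100 with at most 60 generations per cohort; alternans scans
on the full 620→260 ms, 5 ms grid; the tissue sweep on sigma ∈ {0.003,
0.006, 0.009} S/m with a 15 ms coupling-interval grid spanning 375→180
ms; synthetic cohorts of up to 50 patients × 4 electrodes for statistical
calibration checks. The full-scale settings (population 1512, the
complete 23 × 91 conductivity sweep) are plain configuration changes and
run in hours rather than minutes.

# Known limitations

* All calibration inertia rests on APDR alone; action-potential
  morphology enters only through a weak template constraint, and
  phenomena such as post-repolarization refractoriness are outside the
  minimal model's expressiveness.
* The GA solution is intrinsically non-unique. The population-level
  clustering quantifies — but does not remove — that degeneracy; fitted
  parameter values should not be read as cellular electrophysiology.
* The reconstruction of the clinical average APDR curves from published
  summary statistics carries their uncertainty (the slope contrast was
  reported as 30.8 ± 10 ms).
* Tissue simulations are isotropic monolayers without fiber architecture,
  scar, or bidomain effects; absolute re-entry window edges inherit the
  conduction-velocity calibration uncertainty, so ordering statements
  (ICMP more inducible than SNLV) are the robust output. At the clinical
  conduction-velocity range the calibrated models' wavelength
  (CV x refractory period) exceeds the 2 cm sheet: cross-field re-entry
  forms (the ICMP model rotates for several cycles at low conductivity
  where SNLV shows none) but self-terminates before the 2 s sustainment
  horizon, so sustained-window comparisons at this domain size are
  vacuous and the inducibility ordering is carried by the re-excitation
  ("induced") criterion.
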