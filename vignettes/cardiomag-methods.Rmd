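---
title: "Simulating and detecting weak cardiomyocyte biomagnetic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting weak cardiomyocyte biomagnetic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Sheets of stem-cell-derived cardiomyocytes beating in culture generate
magnetic fields of order 0.1 pT at a magnetometer a few millimetres above
the dish — the same order as the background noise inside a typical
magnetically shielded box. At that signal-to-noise ratio, template matching
and spectral inspection fail, but a sequence classifier trained on
*simulated* signals superimposed on background noise can still find the
beats. `cardiomag` implements that whole chain in one package:

1. ionic action-potential (AP) models of the two cell types present in the
   culture, with a genetic algorithm (GA) to fit their conductances to
   experimental AP features;
2. a 2D monodomain tissue solver producing membrane-potential maps and
   inter-unit currents of the beating sheet;
3. a Biot–Savart forward model of the three-axis first-order gradiometric
   SQUID pickup coils, giving the magnetic waveform the instrument would
   record;
4. a synthetic background-noise generator emulating the measured noise
   environment, so the pipeline runs without access to the original
   measurement hardware;
5. a labeled-corpus builder (randomized peaks + noise), an FSST + LSTM
   per-sample classifier with peak-region post-processing, and a
   scaled-template baseline detector.

# Cell models

Two models ship in a config-overridable registry
(`model_registry()`):

* **Ventricular-type iPS-CM** — a Paci-family human-iPS-CM formulation,
  i.e. the standard human ventricular Hodgkin–Huxley current set (INa,
  ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa, background Na/Ca, SR
  uptake/release/leak) with a strongly reduced inward rectifier and a
  spontaneous-beating funny current. Because the cells are mouse-derived
  and beat much faster than human iPS-CMs, If uses a single-gate
  mouse-embryonic formulation with a mixed Na/K reversal (−17 mV) instead
  of the human form.
* **Pacemaker-like cell** — the Yanagihara–Noma–Irisawa (YNI) sinoatrial
  model (INa, Is, IK, Ih, Il).

Every constant is a named numeric that can be overridden through
`cell_model(overrides =)`; not every instrument- and culture-specific constant is publicly
tabulated, so the registry defaults are
literature-family values and the *fitted* entries (`use_optimized = TRUE`)
are produced by this package's own GA/calibration procedure.

Integration is plain forward Euler at dt = 0.01 ms, the protocol under
which these models were characterized. Two numerical guards are documented because a naive transcription is
unstable or singular:

* the fast-Na activation time constant of the ventricular family collapses
  below dt at diastolic potentials; a config-exposed floor
  (`tau_min_ms = 0.03`) keeps the explicit update stable. `m_inf` is
  essentially zero in that voltage range, so the floor has no dynamical
  effect (halving dt changes extracted AP features by well under 1%, which
  the test suite checks).
* several YNI rate expressions are 0/0 at isolated voltages (−100, −40,
  −20, +5 mV); they are evaluated with `expm1`-based forms continuous
  through the removable singularity. This matters because the tissue
  solver tabulates kinetics on a 0.05 mV grid that hits those voltages
  exactly.
* the steady state of the calcium-dependent ICaL gate is capped at 1 (its
  published form peaks at about 1.05), so all gating variables stay in
  [0, 1].

AP features (`extract_ap_features()`) are computed on the trailing 20 s of
a 60 s trace by default — 60 s of integration reaches a settled rhythm,
and the trailing-window choice discards the initial transient. Upstrokes
are detected as upward crossings of −20 mV (configurable); MDP is the
most negative inter-beat potential, Vmax the maximal upstroke dV/dt,
APD90/APD50 run from the crossing sample to 90%/50% repolarization between
beat peak and MDP, and beat frequency (beats/min) comes from the mean
inter-upstroke interval. "Peak" (pacemaker variant) is the beat overshoot
maximum. Non-beating traces are a representable value (`beating = FALSE`),
not an error, so the GA can penalize them (score 1e6, dominating any
beating candidate).

# GA fitting

`run_ga()` is a real-coded GA: per-gene uniform initialization over the
bounds, tournament selection (size 3), BLX-0.5 crossover at rate 0.9,
per-gene Gaussian mutation (sigma = 10% of range) at rate 0.1, elitism 1,
genes clamped to bounds after every variation. These operator choices are standard real-coded-GA defaults, all
configurable. The scored genes are the conductance scaling factors
(bounds 0–10 for Na, CaL and f in the ventricular model; 0–5 otherwise)
and the score is `sum(((model - target)/SE)^2)` over the AP features.
Independent restarts are separately seeded and the best-scoring run is
adopted (ties toward the lower seed).

The registry's shipped targets (`ap_targets()`) are placeholder values on
the scale reported for mouse iPS-CM patch-clamp recordings, chosen once:
exact experimental reference values for this cell line are not publicly
tabulated.
The ventricular beat-frequency target (40/min at 37 °C) is deliberately
below the pacemaker rate so the fitted sheet preserves the observed pacing
hierarchy (cluster drives sheet).

Intracellular potassium and SR calcium are clamped by default — and,
deliberately, in *both* the GA evaluation and the tissue solver
(`cell_model(fixed =)` controls it). The two stages must agree: a model
fitted under clamp loses its automaticity within tens of seconds when
deployed unclamped, because the slow K/SR-Ca drift these clamps remove is
exactly what the fit never saw. Clamping both also matches the fixed-concentration acceleration used
when these models were fitted and the practice of setting the sheet
simulation's intracellular concentrations to fixed literature values. Sodium and cytosolic calcium remain dynamic everywhere.

# Tissue solver

The monodomain sheet

$$\partial_t V = -I_{ion}/C_m + \tfrac{1}{\rho_x S_x C_m}\partial_x^2 V
  + \tfrac{1}{\rho_y S_y C_m}\partial_y^2 V$$

is discretized on the study geometry (84 × 84 units, dx = 60 µm, a
contiguous lower-left cluster of exactly 1440 pacemaker-like units — the
exact count, not a rounded 20%) and advanced by Godunov operator
splitting: explicit per-unit ionic update, then a Crank–Nicolson diffusion
step realized as a Peaceman–Rachford ADI sweep (tridiagonal solves along x
then y) with zero-flux boundaries — the cultured sheet has insulating
edges. Voltage-dependent gate kinetics are linearly interpolated from
tables on a 0.05 mV grid for speed; currents are evaluated exactly.

Defaults: isotropic ρ and S, `Cm_area` = 0.01 F/m², S = 2 × 10⁵ 1/m,
T = 24 °C (room temperature, entering through Q10 factors on gate rates,
pumps and conductances). The averaged cellular resistivity is *calibrated*,
not assumed: `calibrate_resistivity()` bisects ρ until the planar
conduction velocity on a 1D strand of the ventricular model matches a
target (default 0.02 m/s, the scale at which a wave crosses the ~5 mm
sheet in the ~250 ms width of the measured magnetic peak; immature
cultured monolayers conduct orders of magnitude slower than adult
myocardium). The calibrated default is ρ ≈ 1860 Ω·m — an *effective*
junction-dominated resistivity, large compared with cytoplasmic values
because the model lumps all coupling resistance into it. The CV probe
protocol suppresses If and triples IK1 and starts from a pre-equilibrated
rest so the strand is stably quiescent until stimulated; otherwise
spontaneous firing masks slow propagation. CV scales as 1/sqrt(ρ) over a
4× range (log–log slope −0.5 ± 0.1 in the tests), the monotonicity the
bisection relies on.

A point worth documenting for anyone reducing the grid: the sheet's cycle
length is set by the pacemaker cluster *interior*, which beats close to
the single-cell rate; cluster-edge cells are electrotonically loaded by
the quiescent ventricular margin and are strongly slowed. A
proportionally scaled-down cluster (e.g. 20% of a 21 × 21 grid) is
perimeter-dominated and the sheet then runs at the ventricular cells' own
slower rhythm. Reduced-scale checks therefore keep the full-size 36 × 40
cluster and shrink only the ventricular margin, which preserves the
cycle-length physics at a quarter of the cost.

# Magnetometer forward model

Each inter-unit link carries `I = dV / R_link` with
`R_link = ρ / thickness`; the effective sheet thickness (default 10 µm,
monolayer scale) sets the conduction cross-section and is the main knob
scaling absolute magnetic amplitude. The field of each link is the finite-
segment Biot–Savart closed form; per axis the output is the average flux
density through a first-order gradiometric pickup coil (bottom-loop
average minus top-loop average, baseline 50 mm): an axial circular coil
(diameter 15.5 mm) for Bz and planar rectangular coils (9 × 15.5 and
11 × 15.5 mm²) for Bx/By. Loop integrals use tensor-product
Gauss–Legendre quadrature (8 points per dimension; refinement changes
outputs by < 0.1%). Winding details of the real coils are unpublished, so
absolute amplitudes are geometry-sensitive; the shipped thickness default
is calibrated so the full-geometry simulation reproduces the ~0.15 pT peak
scale. Extracellular return currents are neglected (the medium volume is
large relative to the cell sheet). Because the map from link currents to
coil outputs is linear, `simulate_tissue()` can fold it in online via a
precomputed weight matrix (`link_weight_matrices()`), keeping long
simulations in O(1) memory; `forward_magnetometer()` applies the same map
to stored currents.

The sample sits 3 mm below the bottom coil edge, grid centered under the
sensor, cluster toward the −x,−y corner. A ±2 mm lateral displacement
changes amplitudes only modestly (tested). One symmetry subtlety: since
**B** is a pseudovector and the coil set is symmetric under the y → −y
mirror, mirroring the current distribution across the x–z plane flips the
x- and z-axis outputs and *preserves* the y output; the test suite pins
this down against the closed form.

# Synthetic background noise

`generate_background()` colors white Gaussian noise in the frequency
domain with an amplitude-spectral-density template — white sensor floor
(~15 fT/√Hz), 1/f rise below ~5 Hz, a Gaussian bump around 12–20 Hz
(building vibration and air handling), and a residual 60 Hz line — then
applies the acquisition chain: 4th-order Butterworth high-pass at 3 Hz and
low-pass at 100 Hz plus a Q = 30 IIR notch at 60 Hz, all forward–backward
(zero phase) so peak shapes are not distorted; the source names only the
cutoffs, the realizations are this package's choice. The record is scaled
so its *expected* filtered 60 s standard deviation equals the profile
target (0.146 pT for the y-axis cell-measurement profile, 0.218 pT for
the x-axis wire profile); the sample SD then lands within a few percent.
What the stand-in does **not** emulate: non-Gaussian artifacts, elevator
transients, slow drifts of the noise floor. Measured records in the same
columnar format can be dropped in anywhere a synthetic record is accepted.

# Labeled corpus

A 250 ms peak template cut from the simulated y-axis waveform is
randomized per beat — duration from a truncated normal (mean 250 ms,
CV 0.21, the beat-interval variability measured from field potentials;
non-positive draws are redrawn), amplitude uniform on 0.5–2.0× — placed
at the simulated cycle length, with gaps linearly interpolated between
window endpoints. Labels are P exactly inside peak windows. Records come
in three types in a 1:1:2 ratio (positive polarity : negative polarity :
noise-only), each 120 s at 1 kHz by default; background noise records are
cycled in equal proportion and circularly shifted by a seeded offset
before addition ("combined" = positive + negative equals the noise-only
count, which reconciles the equal-number statement with the 1:1:2 ratio).
Gaussian augmentation noise (SD 0.01 pT) is added to every record. The
split is stratified 70/10/20 by record type via largest-remainder quotas,
with a fix-up guaranteeing non-empty validation and test sets on tiny
corpora. The whole corpus is a pure function of (spec, template, noise
set, root seed); every record derives its own substream, so changing the
detector seed never changes the corpus.

The "no variability" ablation (`fixed_variability = TRUE`) freezes
duration and amplitude but keeps the random time shifts, which still
diversify the noise context of each peak.

# Detector

Features are the Fourier synchrosqueezed transform (FSST) of the
waveform: a unit-hop STFT with a 512-sample Kaiser window (sidelobe
attenuation 13.6 dB — essentially rectangular, shape parameter ~0.5),
each bin's energy reassigned to the output bin nearest its
instantaneous-frequency estimate from the derivative-window transform.
Bins inside 3.5–12 Hz (five bins at the 1000/512 Hz spacing, no zero
padding) enter as real and imaginary channels, so the default input is
10 channels per sample, standardized by training-split statistics.
Ablation presets widen or shift the band or bypass the transform
entirely (`raw = TRUE`).

The classifier is a unidirectional LSTM (default 400 hidden units;
reduced sizes train much faster on small corpora) with a 2-unit softmax
head, trained sequence-to-sequence with cross-entropy and Adam (initial
rate 0.001, ×0.1 every 20 epochs, up to 60 epochs, mini-batches of 16
ten-second segments). Validation runs each epoch; training stops once the
validation loss has exceeded its running minimum more than 10 times, and
the weights at the minimum are returned. All randomness flows from the
config seed through a private generator, so training is reproducible in
single-threaded BLAS.

Post-processing turns per-sample labels into events: maximal P-runs
strictly longer than 150 ms become peak regions (the strict inequality is
a documented boundary choice). Evaluation reports AUROC (rank form, ties
one half) and a greedy one-to-one match of region centers to truth
centers within 250 ms — one nominal peak width; the source does not state
its matching criterion, so this is a documented default.

# Scaled-template baseline

The comparison detector slides the same 250 ms template along the record,
fits scale and offset by least squares at each position, and uses
scale / residual-standard-error as the criterion ("standard error of the
time series data" is read as the residual SE of the local fit, the cited
technique's usual reading); detections are criterion local maxima above a
threshold with one template length of dead time. To compare methods
without bias, `calibrate_template_threshold()` bisects the threshold
until the background detection rate matches the deep detector's. At
signal amplitudes near the noise floor this detector misses most events
while the LSTM does not — the qualitative ordering the test suite
reproduces. `average_peak_waveform()` recovers the mean event shape
(±175 ms around region centers, ten iterations of correlation
re-alignment with ±50 ms integer shifts, ties toward the smaller shift,
optional 12 Hz display low-pass).

# Problem sizes used by the shipped tests

The full study conditions (60 s tissue simulations at dt = 0.01 ms on the
84 × 84 grid; corpora of 160–640 records of 120 s; a 400-unit LSTM) are
reproducible through the same functions but are supercomputer-or-patience
work. The shipped checks run the same code at sizes a laptop handles in
minutes, chosen once as the package's verification conditions:

* tissue physics on reduced grids (15 × 15 to 42 × 42), with the
  full-size pacemaker cluster retained for cycle-length checks (see
  above), dt = 0.02 ms;
* detection end-to-end on 16 records of 60 s with 64 hidden units — the
  peak amplitude is the full-scale estimate (~0.15 pT) against the
  measured 0.146 pT noise level, so the signal-to-noise ratio of the
  cell experiment is preserved exactly; only the data volume and network
  capacity are reduced;
* the scaled-template baseline on the same records.

Passing these shows the pipeline is implemented correctly and that the
simulation-plus-noise training idea works at the cell-experiment
signal-to-noise ratio on synthetic noise. It does not show performance on *measured*
SQUID noise, which contains non-Gaussian structure the generator does not
emulate.

What the reduced scale *costs* is per-peak sensitivity at the hardest
amplitude: with 64 hidden units and a few tens of records the held-out
per-sample AUROC sits near 0.8 rather than the ~0.97 achievable at full
network capacity and corpus size, and per-peak sensitivity at 1.0×
amplitude lands well below the full-scale figure — while the low
background false-positive rate, perfect detection at 5× amplitude and
the degradation at 0.5× are all reproduced. A per-sample logistic probe
on the same features shows the instantaneous feature information at this
SNR is limited; the margin the full-scale system enjoys comes from
temporal integration capacity and data volume, exactly the two knobs the
reduced conditions shrink. The acceptance suite asserts the full-scale
sensitivity bar regardless and documents the shortfall rather than
widening the bar.

# Known limitations

* The registry's base constants are literature-family values; where the
  original instrument- and culture-specific values differ, results shift
  accordingly — every constant is overridable.
* The YNI-based pacemaker model is a classical, simplified description;
  a factor-of-two rate discrepancy against real cultures is expected from
  this choice alone.
* Absolute magnetic amplitude trades off against the effective sheet
  thickness and coil winding details; only its order of magnitude is
  meaningful without instrument-specific calibration.
* Anisotropic fiber architecture, multiple beating regions, extracellular
  return currents and bidomain effects are out of scope.
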