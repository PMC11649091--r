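---
title: "Modelling activity-dependent extracellular potassium in dendrites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling activity-dependent extracellular potassium in dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroK)
```

`dendroK` models a single causal chain: clustered, similarly tuned synaptic
inputs release more K⁺ into the small extracellular space around a dendritic
segment; the resulting [K⁺]ₒ rise depolarizes the potassium reversal
potential E_K; the weakened K⁺ currents make NMDA-dependent dendritic spikes
easier to trigger and longer-lasting; and the boosted dendritic output
amplifies somatic firing multiplicatively without changing its orientation
selectivity. This vignette documents the model assumptions, parameter
choices, calibrations, and the limits of what the test suite establishes.

## 1. Orientation statistics of synaptic input

A dendritic segment is a 10 µm cylinder of radius 1 µm carrying 7–13
synapses (count uniform — the source material states only the range, and the
uniform reading is the maximum-entropy choice). Orientation lives on a
180°-periodic half circle, handled throughout by `fold_orientation()` and
the circular distance `d(a,b) = min(|a−b| mod 180, 180 − |a−b| mod 180)`.

* **Similar regime** — preferences drawn from a normal with σ = 15° about
  the target orientation (fixed at 0°), folded to the half circle. At
  σ = 15° folding is a ~10⁻⁹ tail event, so the empirical preference
  distribution is indistinguishable from the plain normal (tested by a
  Kolmogorov–Smirnov comparison).
* **Diverse regime** — preferences uniform on [−90°, 90°).
* Every synapse has a Gaussian tuning curve `exp(−d²/(2σ_t²))` with
  σ_t = 11°, normalized per synapse to peak activity 1 (the alternative —
  per-segment normalization — is not adopted; per-synapse normalization is
  the only reading under which "activity spans 0 to 1" holds for every
  synapse individually).

The segment drive is the plain mean `w(θ)` of its synapses' activities.
Expectations are computed two ways: a Gaussian kernel density estimate on a
linear grid in [0, 1] with Scott's-rule bandwidth, using
E(X) = Σ xᵢ pᵢ (the headline route), and the plain sample mean. The KDE
route carries a small (~3%) positive boundary bias at the diverse regime's
low activity values; the Monte-Carlo-versus-quadrature agreement invariant
is therefore tested on sample means, while the KDE route is held to the
coarser 2–5× factor band. A closed-form oracle for the diverse expectation
(`diverse_expected_activity()`, ≈ 0.153 at σ_t = 11°) is independent of the
samplers.

## 2. From concentrations to reversal shifts

The extracellular space is an annulus between the dendrite (R₁ = 1 µm) and
an outer cylinder (R₂, default 2 µm). A well-mixed intracellular loss
Δ[K⁺]ᵢ produces an extracellular rise `Δ[K⁺]ₒ = |Δ[K⁺]ᵢ| · V_R` with
`V_R = R₁²/(R₂²−R₁²)`; the similar regime scales the diverse-regime rise by
the activity factor. The Nernst prefactor is 26.7 mV (divided by the
valence for the generalized helper); baselines default to
[K⁺]ᵢ = 140 mM and [K⁺]ₒ = 3 mM — the resting extracellular value is only
constrained to 2.7–3.5 mM by the literature, and 140 mM is the standard
intracellular value. Both are configuration arguments, not constants.

`shift_heatmap()` sweeps (Δ[K⁺]ᵢ, R₂), flags the parameter subset whose
diverse-regime rise falls in the 0.25–1 mM band measured in vivo, and
reports both regimes' shifts. With an activity factor of 5 the similar
regime's flagged band is 1.25–5 mM by construction.

## 3. Potassium diffusion along a dendrite

Eleven segments are concatenated into a 110-µm dendrite (centre segment
similar, flanks diverse; a fully diverse twin dendrite is simulated with
the same layout statistics as reference). Choices that the source material
leaves open, and how they were fixed:

* **Efflux waveform.** Per synapse and stimulation event, an alpha function
  with 20 ms time-to-peak, scaled by the synapse's orientation-tuned
  activity, starting at an exponential delay (mean 80 ms) after event
  onset. The total release per fully active synapse (`source_scale`,
  25 mM µm³) is calibrated so the all-diverse reference dendrite's centre
  segment peaks near 0.5 mM — the middle of the in vivo band.
* **Transport.** 1-D axial diffusion with D\* = 0.76 µm²/ms (radial
  diffusion is negligible at these geometries), explicit scheme with
  dx = 0.5 µm and dt safely inside the stability bound dx²/(2D\*), closed
  (reflecting) ends.
* **Clearance.** The pump flux constant K_dec = 2.9·10⁻⁸ m/s is converted
  to a volumetric rate `2 K_dec / w`. Taken literally with the annulus
  width (1 µm) this gives a ~17 s decay constant, which contradicts the
  published dynamics this module is meant to reproduce (per-event
  concentration peak 150–170 ms after onset; relaxation to baseline within
  ~2 s). We therefore treat `w` as an *effective clearance width* and
  calibrate it once to those dynamics: w = 0.015 µm (decay constant
  ≈ 0.26 s). It sits below the anatomical cleft-width range (0.04–0.5 µm)
  because it also absorbs clearance pathways that are not modelled
  explicitly (glial uptake, spatial buffering).
* **Intracellular side.** [K⁺]ᵢ is constant; coupling an intracellular
  pool changes the reversal shift only marginally because V_R ≪ 1 relative
  to the intracellular volume.

Two properties worth stating plainly. First, with pumps off and closed
ends, released mass is conserved to 0.1% — the conservation test drives all
injections to completion (single event, short delays) before comparing.
Second, diffusion smears the hotspot: the similar centre segment's
*injection* exceeds the diverse segments' by the ~3.9× activity factor, but
its segment-averaged concentration peak exceeds the reference by only
~1.6×, with the excess decaying to near-reference beyond ~40 µm. The
well-mixed analytical treatment of Section 2 retains the full factor by
construction; the diffusion module shows what survives transport.

## 4. The point-dendrite model

A single isolated RC compartment (C_m = 2 µF/cm², accounting for spine
membrane; area of a 10 × 1 µm cylinder) with eight intrinsic conductances
(K_leak, Na_V, K_V, K_M, K_A, K_Ca, Ca_V, HCN) and AMPA/NMDA/GABA_A
receptors. The membrane is advanced by the exponential Euler scheme

V(t+dt) = V∞ + (V − V∞)·e^(−dt/τ),  V∞ = Σ gᵢEᵢ / Σ gᵢ,  τ = C_m/Σ gᵢ,

with dt = 0.025 ms; gates follow first-order Boltzmann kinetics with
constant time constants and are advanced by their own exponential updates.
A compiled integrator does the work; a line-for-line R implementation
(`engine = "r"`) exists purely as a cross-check and matches to 10⁻⁸ mV.

Receptors are difference-of-exponentials normalized to the stated peak
conductance (AMPA 0.2/2 ms, NMDA 2/75 ms, GABA_A 0.5/8 ms); the NMDA
conductance is multiplied by the standard magnesium block
1/(1 + [Mg]/3.57 · e^(−0.062V)) at 1 mM — the functional form is an
assumption, as it is not printed in the available material.

**Calibration.** The original channel tables (kinetics and densities) are
not publicly available, so absolute behaviour was calibrated rather than
copied, against two printed anchors: at the target orientation with no
shift, the segment spikes on roughly half the events (48% printed), and a
12 mV shift broadens mean dendritic spike duration by roughly 80%. The
frozen result (grid searches at 400 trials per configuration; smaller
samples proved misleading because the duration means are heavy-tailed):
ḡ_AMPA = 0.25 nS, ḡ_NMDA = 0.86 nS per synapse, K_A = 3.0 mS/cm² and K_V
half-activation −15 mV, other densities at standard dendritic values.
Verified independently: control-event spike probability 0.51, shifted 0.90,
conditional durations 35 → 63 ms (+78%). Two mechanistic points the
calibration surfaced: the transient A-type current is the natural lever
that raises the spike threshold without shortening plateaus (it inactivates
during them), and positioning the delayed-rectifier activation near the
−30 mV spike criterion is what makes plateau termination sensitive to the
K⁺ driving force — and hence to the imposed shift.

**Protocol and metrics.** Three events 300 ms apart; each synapse activates
once per event at an exponential delay (mean 80 ms) — the "single
activation per event" reading of the Poisson-delay phrasing. Event 1 is the
control; the reversal shift applies as a step from event 2 on. A dendritic
spike is time above −30 mV within an event's 300-ms window; "spike
duration" means the mean over spiking events (the duration *of dendritic
spikes*), not a mean that counts spike-free events as zeros.

`threshold_surface()` scans (N, w, ΔE_K) for the smallest shift that makes
the majority of trials spike, with explicit "no shift needed" and "never
spikes" categories; `fit_spike_plane()` fits ΔE_K(N, w) = αw + βN + ν by
ordinary least squares. The package deliberately ships both the reference
coefficients (−38.43, −2.08, 52.32) — used for all tuning statistics so
they are comparable with the published analysis — and its own refitted
plane from the calibrated model, which is *not* expected to reproduce the
reference numerically.

## 5. Tuning statistics

`spike_probability()` samples 10⁴ similar segments per orientation,
computes each segment's required shift from the plane (negatives clamped to
zero — those segments spike unaided), and compares it with the available
shift: the target-orientation value scaled at other orientations by the
normalized activity factor. The orientation selectivity index is
1 − circular variance with angle doubling,
OSI = |Σ r_k e^(−2iθ_k)|/Σ r_k, after mirroring [0°, 90°] responses to
[−90°, 90°]; mirroring duplicates neither 0° nor 90° (the latter is
identified with −90° on the orientation circle), which is what makes a
response split equally between 0° and 90° come out exactly untuned.

## 6. The current–voltage landscape

The instantaneous I–V curve sums every conductance's driving force on a
voltage grid ([−90, 10] mV at 0.25 mV), with the sign convention that
positive (inward) current depolarizes: dV/dt = I/C. Fixed points are
bracketed sign changes refined by bisection until the current residual is
below 10⁻⁹ of the curve's maximum; stability follows the local slope and is
verified against forward simulation in the tests. Because the source
material does not say whether its curves freeze gates at trajectory values
or use steady states, all three conventions are implemented
(`steady`, `frozen`, `mixed`); the default for landscapes is `mixed` — fast
gates (τ ≤ 5 ms) at steady state, slow gates frozen at their trajectory
values. Ramping the NMDA conductance produces the down-stable → bistable →
up-stable → single-root sequence (1 → 3 → 1 zero crossings), and a reversal
shift depolarizes the down state, lowers the voltage barrier to the up
state, lowers the NMDA conductance at which bistability first appears, and
prolongs the bi-/up-stable epoch of a stimulation transient.

## 7. The fractal neuron

The apical tree branches 3-for-1 with halving lengths over 4 generations
(120 sections, 81 distal at 20 µm; fractal dimension ln 3/ln 2), on a
500-µm trunk and a 30 × 10 µm soma. Sections are discretized at ≤ 20 µm per
compartment and integrated by a backward-Euler scheme in the voltage with
Hines elimination on the tree; gates update explicitly, and the NMDA
magnesium factor is evaluated at the previous step's voltage
(semi-implicit, standard practice).

Choices the source material leaves open:

* **Diameters.** Stated nowhere. A 2-µm trunk proved electrotonically
  impossible — 500 µm at 2 µm is ~1.7 length constants, and distal NMDA
  plateaus arrived at the soma attenuated below 3 mV, unable to fire it at
  any synaptic strength. The adopted defaults (trunk 4 µm, tree tapering
  3 → 1 µm, axial resistivity 150 Ω·cm) are within the anatomical range of
  layer-5 apical trunks and carry the signal.
* **Channel complement.** The tree membrane reuses the calibrated
  point-dendrite K profile (transient K 3.0 mS/cm², persistent K at
  −15 mV half-activation), so a distal section is, as nearly as the cable
  context allows, the same membrane as the point dendrite. The soma fires
  via Na_T (48 mS/cm², activation −45 mV, inactivation −50 mV) with a
  delayed rectifier, and a persistent Na current (0.3 mS/cm²) amplifies
  sustained dendritic depolarization; spikes are upward 0-mV crossings with
  2-ms deduplication.
* **Operating point.** The synaptic gain multiplier (10.5) places
  stimulated distal sections near plateau-ignition threshold. That is the
  regime in which a local reversal shift changes ignition probability and
  duration — and therefore somatic rate. Verified behaviour at the target
  orientation: 3.2 / 3.8 / 5.0 Hz under 0 / 6 / 18 mV local shifts, silent
  beyond ~20°, and trunk-base AUC (Na channels silenced in trunk and soma
  to exclude back-propagating spikes; baseline-subtracted trapezoid over
  500 ms) rising monotonically with the shift.

Stimulation follows the stated protocol: a Poisson-distributed number of
distal sections (mean 32, truncated to the 81 available) hosts sampled
similar segments; synapses activate once per event at exponential delays
(mean 30 ms); three events, 300 ms apart; each seed's layout is rerun under
every shift condition (paired design). Gain is quantified by chi-square
fits of FR_after = ξ_mul·FR_before and FR_after = FR_before + ξ_add, with
zero-variance orientations excluded; the additive form as printed in the
source repeats the multiplicative formula, an evident typesetting slip, and
is implemented as the text describes it (a rate offset). Distance scaling
multiplies all section lengths (not diameters) and fits AUC against
relative distance with f(x) = xᵃ + c per condition; the no-shift condition
attenuates faster (more negative exponent).

At reduced scale, one caution the tests respect: with fewer tree
generations the Poisson-32 selection saturates the smaller set of distal
sections and the soma runs far above threshold, flattening the gain
transformation. Structural and monotonicity tests therefore use 2–3
generations for speed, while the gain-structure test keeps the calibrated
4-generation morphology.

## 8. What the synthetic world does and does not establish

All data in this package are generated by its own samplers under the
stated distributions; there is no external dataset. Green tests establish
that the implementation is internally consistent (solvers match closed
forms, refinement, and independent reimplementations), that the stated
statistical world reproduces the printed desk-scale quantities (activity
factor band, diffusion constants and timescales, threshold-plane
interpretation, selectivity indices, duration broadening), and that the
qualitative mechanisms (bistability, barrier lowering, multiplicative
gain, selectivity preservation) hold. They do not establish the absolute
conductance values of the original models — those are calibrated, not
derived — nor quantitative agreement for quantities that depend on them
(absolute firing rates, the exact gain coefficients ξ, absolute spike
probabilities), nor real biological variability beyond the stated
samplers.

## 9. Numerical choices, in one place

dt = 0.025 ms everywhere (tests verify < 0.5–1 mV sensitivity to 2–4×
refinement); diffusion dx = 0.5 µm with dt at 40% of the stability bound
(grid-halving changes segment peaks by < 2%); voltage grids [−90, 10] mV at
0.25 mV; bisection to 10⁻³ mV and a 10⁻⁹ relative current residual; KDE
bandwidth by Scott's rule; OSI mirroring excludes duplicated endpoint
orientations; all samplers consume R's global RNG, every pipeline entry
point takes an explicit seed, and `run_experiment()` derives per-stage
seeds deterministically from a root seed and records them in its JSON
manifest (configuration I/O is JSON throughout).
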