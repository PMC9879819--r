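---
title: "Methods: NPQ deconvolution and thermal-response fitting in quenchmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NPQ deconvolution and thermal-response fitting in quenchmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and its observables

quenchmap analyses pulse-amplitude-modulated (PAM) chlorophyll-fluorescence
measurements of microalgal cultures in 96-well plates placed on a gradient
thermocycler, so that each plate column is held at a different temperature
while rows within a column are biological replicates. The measurement
protocol modelled throughout the package is: 10 min far-red
pre-illumination of the dark-adapted sample (far-red preferentially excites
PSI, oxidising the plastoquinone pool and driving the antenna into state 1),
then 5 min of actinic white light at 500 µmol photons m⁻² s⁻¹, then 5 min of
darkness, with a saturating pulse every minute. Pulse 0 is the dark-adapted
reference (F0, Fm); pulses 1–5 are taken in light and 6–10 in darkness.

Non-photochemical quenching at pulse *k* is the Stern–Volmer expression

$$\mathrm{NPQ}_k = \frac{F_m - F_m'^{(k)}}{F_m'^{(k)}}.$$

Fm is always the well's own dark-adapted maximum — never a plate average —
because every equation below subscripts a single Fm per sample.

## Deconvolution with dynamic dark-phase Fm′ selection

The first Fm′ measured in darkness is frequently *lower* than the last Fm′
in light (a transient "positive NPQ spike" at the light→dark transition),
so the dark-phase extrema of Fm′ are selected dynamically rather than taken
from fixed pulses. With $\max F_m'_{6\text{–}10}$ and
$\min F_m'_{6\text{–}10}$ the extreme dark-phase values (ties broken by the
earliest pulse, for determinism):

* **qE-type (fast-relaxing) NPQ** — what relaxes in darkness:
  $\mathrm{qE} = \frac{F_m - F_m'_5}{F_m'_5} -
  \frac{F_m - \max F_m'_{6\text{–}10}}{\max F_m'_{6\text{–}10}}$.
  It may be negative (high-light acclimated cultures show negative dips),
  and negative NPQ generally raises a warning but is never clamped.
* **Slow-relaxing NPQ** — the minimum NPQ reached in darkness:
  $\frac{F_m - \max F_m'_{6\text{–}10}}{\max F_m'_{6\text{–}10}}$
  (zeaxanthin-dependent quenching, photoinhibition and other slow pools).
* **qT2-type NPQ** — the steady NPQ rise in darkness (state 1 → state 2):
  the span $\frac{F_m - \min F_m'_{6\text{–}10}}{\min F_m'_{6\text{–}10}} -
  \frac{F_m - \max F_m'_{6\text{–}10}}{\max F_m'_{6\text{–}10}} \ge 0$.
  The operand order is chosen so that reported amplitudes are positive;
  written in the opposite order the same span is non-positive whenever dark
  NPQ rises, which cannot match positive reported amplitudes.
* **qT1-type NPQ** — the far-red-responsive part of the dark quenching:
  slow-relaxing NPQ without far-red minus slow-relaxing NPQ with far-red in
  the dark phase, computed over paired wells of paired runs.

Two identities follow directly and are enforced by property tests:
qE + slow-relaxing equals NPQ at the last light pulse, and every
dimensionless output is invariant under rescaling all fluorescence values.

Y(II) is $(F_m' - F)/F_m'$ at the last light pulse (the 5-minute light
value, not a steady-state average), and Fv/Fm is $(F_m - F_0)/F_m$.

### Kramer energy partition

The partition into photochemistry Y(II), regulated losses Y(NPQ) and
unregulated losses Y(NO) needs F0′ and qL, which the protocol does not
measure. The default is the Oxborough–Baker estimate

$$F_0' = \frac{F_0}{F_v/F_m + F_0/F_m'}, \qquad
qL = \frac{F_m' - F}{F_m' - F_0'} \cdot \frac{F_0'}{F}, \qquad
Y(NO) = \frac{1}{\mathrm{NPQ} + 1 + qL\,(F_m/F_0 - 1)},$$

with Y(NPQ) = 1 − Y(II) − Y(NO), so the partition sums to one by
construction. The simplified lake-model forms (Y(NO) = F/Fm,
Y(NPQ) = F/Fm′ − F/Fm) are available behind a switch for comparison with
software that uses them. 1 − qL approximates the closed-reaction-centre
fraction.

## Thermal-response assembly

Four overlapping gradients (default: 10–21, 18–29, 26–37, 34–45 °C in 1 °C
column steps; the true instrument gradients are user-configurable because
they are instrument-specific) jointly cover 10–45 °C. Per-well component
values from all runs are pooled onto one ascending temperature axis.
Overlapping temperatures are *kept as distinct replicate points* — fits are
drawn through all replicates (n = 4 rows per gradient, 8 at overlaps) — and
every point keeps its (run, well) provenance. Merging is invariant under
permutation of the run list.

## Curve models and extremum extraction

* **Cubic polynomial** (ordinary least squares) for the dip-shaped qE
  response. Its critical points come from the closed-form roots of the
  derivative, filtered by second-derivative sign; ties are broken by the
  more extreme fitted value, then the lower temperature.
* **Biphasic Hill** for bell-shaped responses (slow-relaxing, qT2, Y(II)):
  $$y(T) = y_0 + \frac{P_m}{\left(1 + (K_a/T)^{H_a}\right)
  \left(1 + (T/K_i)^{H_i}\right)},$$
  the product of an activating and an inhibiting Hill term. This
  parameterisation was chosen because it reproduces rise-then-fall thermal
  performance curves with independently tunable flanks; the exact functional
  form used by commercial fitting software is not published. Fitting is
  Levenberg–Marquardt (minpack.lm) with bounds $K_a, K_i \in [5, 60]$ °C and
  $H_a, H_i \in [0.5, 50]$, heuristic starts (baseline = min, peak at the
  argmax, midpoints from half-maximum crossings, slopes 8), and up to 10
  restarts from deterministically jittered starts (fixed internal seed, so a
  fit is a pure function of the data). Dips are fitted by negating the
  values internally. Points are put in a canonical sort order first, making
  the fit invariant under row permutations.
* **Extremum**: for the biphasic Hill curve the fitted curve is scanned on a
  0.01 °C grid and refined by golden-section search (verified against a
  0.001 °C exhaustive scan to within 0.05 °C on randomized parameter
  draws). An extremum within 0.25 °C of the fit-range boundary carries a
  `boundary` flag rather than being silently accepted; a curve that is
  extreme *at* the boundary raises a distinct no-extremum error.
* **Uncertainty**: the origin of published ± values on peak positions is
  typically unstated, so quenchmap uses a replicate bootstrap: values are
  resampled with replacement within each temperature, the model is refitted
  and the extremum re-extracted (default 1000 resamples, mandatory seed).
  The reported uncertainty is the SD of the bootstrap extremum temperatures;
  more than 20% failed refits raises an unstable-fit error. The bootstrap
  SD is validated against a Monte-Carlo regeneration oracle (agreement
  within a factor of two) and is exactly zero for noise-free data. As with
  any within-group bootstrap of few replicates, the SD underestimates the
  true sampling spread by about $\sqrt{(n-1)/n}$ (≈ 0.87 for the n = 4
  replicate design); users wanting calibrated intervals should multiply the
  reported SD by $\sqrt{n/(n-1)}$.

## The synthetic-data generator

Because raw plate fluorescence data for this assay are generally not
deposited, every stage is validated against a trace generator that emulates
the protocol. Its two halves are:

**Thermal profiles** (`thermal_profile()`, presets in
`inst/extdata/presets.yml`): per condition, the *observable* component
values as functions of temperature — a cubic with an exact interior dip for
qE (dip position/value from the published fitted summary; edge values 0.35
and 0.80 for low-light, 0.50 and 1.20 for high-light presets, matching the
reported behaviour that qE is the only quenching active at low temperature
and keeps rising above 40 °C); bell-shaped biphasic Hill profiles for
slow-relaxing NPQ (peak ≈ 40–41 °C), qT2 (active only ≈ 30–40 °C, so a
steep bell: Ha = 25, Hi = 40), and the Y(II) optimum (baseline 0.05,
broader flanks, steeper high-temperature flank for high-light presets).
For each bell the activation midpoint is solved in closed form so the
maximum sits *exactly* at the configured temperature with the configured
amplitude. The far-red-on qT2 bell is configured separately; the difference
between the two bells is the far-red-responsive qT1 pool (present in all
presets because the published ±FR amplitudes differ in both light regimes).

**Kinetics** (`kinetic_config()`): NPQ rises in light as
$(\mathrm{qE}+\mathrm{slow})(1 - e^{-t/\tau_{ind}})$ (τ = 60 s); in
darkness qE decays (τ = 45 s), a 0.05 NPQ spike is added during the first
pulse interval (the light→dark transition artefact that motivated the
dynamic Fm′ selection), and qT2 rises after a 120 s lag with τ = 90 s.
F follows Fm′ through the Y(II) profile in light and relaxes towards F0 in
darkness; F0/Fm = 0.2. Noise is multiplicative Gaussian, CV 2% by default,
independent per reading, with one deterministic RNG substream per well
(hash of run seed, row and column), so plates are reproducible and
independent of generation order. These time constants are generator
choices: they provide the time-scale separation the deconvolution assumes
and are not organism-derived measurements.

**Calibration.** The finite induction time (factor $1-e^{-5}$), the
residual qE at the dark minimum and the truncated dark rise (factor
$1-e^{-(300-\mathrm{lag})/\tau}$ ≈ 0.86 at the defaults) mean the raw
trajectory would under-deliver the configured observables by up to ~14%.
Since the profiles state what a noise-free measurement should deconvolute
to, `simulate_trace()` inverts this attenuation by a damped fixed-point
iteration per temperature (underlying amplitudes adjusted until the
pulse-sampled deconvolution reproduces the targets to 10⁻¹⁰; amplitudes
clamped at physical bounds). With calibration on and no noise, the pipeline
recovers configured qE, slow-relaxing and Y(II) dip/peak positions and
amplitudes essentially exactly, which is the basis of the package's
end-to-end validation.

## What the generator does and does not emulate — known limitations

* **Extremum-selection noise bias.** Selecting the max/min Fm′ over five
  noisy dark pulses biases the extrema outward: where the dark phase is
  nearly flat the expected maximum of five readings exceeds the true value
  by ≈ 1.16 σ. At CV 2% this inflates measured qE by ≈ +0.02 NPQ
  (substantial relative to shallow low-light dip amplitudes ≈ 0.09) and
  deflates the slow-relaxing amplitude by ≈ 3–4% at its peak. The bias is
  a property of the dynamic-selection estimator itself — real measurements
  carry it too — and it leaves extremum *positions* essentially unbiased.
  Amplitude validation therefore anchors on the Y(II) channel, whose
  estimator involves no extremum selection.
* **qT2 tails.** With the default kinetics, the first dark pulse retains
  $e^{-60/45} \approx 26\%$ of qE plus the spike, so wherever qE is large
  (low and very high temperatures) the dark NPQ maximum falls on pulse 6
  and the qT2 estimator reads ≈ 0.26·qE(T) + 0.05 instead of ≈ 0. The
  simulated qT2 thermal response therefore carries non-zero tails that
  shift its fitted bell by ~1 °C even without noise. Well-level qT2
  recovery (within 5% when lag + 2τ fits inside the dark phase) holds as
  designed; full-map qT2 fitting should be read with this artefact in mind.
* The generator is phenomenological: no electron-transport, ΔpH or
  xanthophyll-cycle mechanism, no plate-position effects, no drift, and the
  dark spike is a one-parameter transient confined to the first dark pulse.
  Passing recovery tests therefore demonstrate correctness of the analysis
  chain under the stated noise model, not instrument realism.

## Problem sizes and determinism

The shipped validation simulates 4 gradients × 12 columns × 4 replicate
rows (192 wells per far-red state and preset, 10 pulses each) — small
enough that a full simulate-and-fit cycle takes seconds while giving 36
distinct temperatures with 4–8 replicates each. Property suites run on
1000 randomized traces; grid oracles use 0.001 °C scans. Every stochastic
step (noise, bootstrap, restart jitter) is seeded, and identical
configuration + seed yields byte-identical output tables.
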