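---
title: "Methods: a virtual comparison of prompt gamma imaging and range probing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual comparison of prompt gamma imaging and range probing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In pencil-beam-scanned proton therapy the dose is deposited by thousands of
narrow beams whose stopping depth — the Bragg peak position — depends on
the water-equivalent thickness (WET) of everything upstream of it. Small
anatomical changes (AC: material added to or removed from the beam path) or
setup errors (SE: a rigidly displaced patient) translate the Bragg peaks
and can degrade the treatment. Two independent verification systems can
detect such range deviations:

* **Prompt gamma imaging (PGI)**: a slit camera, fixed in the treatment
  room, images the prompt-gamma emission along each treatment beam as a
  1-D profile; the distal fall-off of the profile tracks the proton range
  in room coordinates, *during* treatment delivery, at no extra dose.
* **Range probing (RP)**: before treatment, a low-weight field of
  high-energy spots is shot *through* the patient into a multi-layer
  ionization chamber (MLIC); each spot's integral depth-dose (IDD) curve
  gives the residual range and hence the WET traversed.

`protonrv` re-creates the experimental head-to-head comparison of the two
systems as a fully synthetic, seeded, desk-scale pipeline: a layered head
phantom, both spot plans, ten deviation scenarios, analytic detector
forward models with configurable noise, the two shift-extraction pipelines,
the geometric-to-WET conversion, and inverse-variance-weighted
accuracy/precision scoring.

## Coordinate frame and sign convention

One fixed room frame is shared by all modules: the beam travels along +x
(horizontal field, gantry 270°, couch 0°); in beam's eye view (BEV) y is
vertical (up positive) and z horizontal (left positive); the isocenter is
the origin. Detectors are fixed in this frame; the couch moves only the
phantom.

Reported range shifts are **pullback-positive**: +w mm means w mm of
water-equivalent material was effectively added upstream of the Bragg peak
(the range shortened). An upstream slab of 2 mm WET therefore appears as
+2 mm in every table, for both systems. Internally the matchers return the
raw distal-positive displacement of the measured curve; the pipelines flip
the sign once, at a documented point.

## The synthetic phantom

The phantom is a 1-D layer stack along x — air / tissue (9 mm, SPR 1.0) /
skull (2 mm, SPR 1.5) / brain (130 mm, SPR 1.04) / skull / tissue / air —
centered on the isocenter. The brain SPR of 1.04 is the mean
stopping-power ratio of the target region and also the SE conversion
constant. Two features make the phantom a useful stand-in rather than a
trivial slab:

* a **lateral gradient** of the entry tissue thickness
  (0.25 mm/mm in y, 0.15 mm/mm in z), so that lateral couch shifts change
  the WET seen by each spot: a 2 mm couch drop adds 0.5 mm WET, a 2 mm
  left shift removes 0.3 mm. Without it, SE scenarios would be degenerate
  (invisible to both systems). The gradient is linear, so within one
  scenario every spot experiences the same WET change — the aggregated
  PGI profiles then translate rigidly, which keeps the noise-free
  scenario recoveries exact. Real anatomy has nonlinear gradients; this
  is a deliberate idealization.
* the layer thicknesses are chosen so that the whole treatment field
  stops inside the brain layer with margin for the largest (5 mm) slab:
  the shallowest layer (115 MeV behind the 73.8 mm-WET range shifter) has
  23.9 mm WET of residual range against 12 mm WET of tissue+skull.

Slabs (SPR 1) mimicking AC are fixed in the room: upstream slabs sit on a
rack 20 mm before the nominal entry surface, the downstream slab halfway
between phantom exit and the MLIC. The ten scenarios (three upstream slabs
of 2/3/5 mm, one 5 mm downstream slab, couch movements of 2/3 mm left,
down, and upstream in BEV) are generated by `scenario_table()` /
`apply_scenario()`.

## Spot plans

* **Probe field**: 81 spots (9×9, 5 mm pitch, ±20 mm), 210 MeV, no range
  shifter, each at the lowest deliverable weight 0.04 MU = 6.2×10⁶
  protons. At 210 MeV the range in water is 283.6 mm against a phantom
  WET of ~160 mm, so every spot reaches the MLIC.
* **Treatment field**: 15 energy layers, 115–160 MeV, behind the
  73.8 mm-WET range shifter. The clinical plan's optimizer is out of
  scope, so the target coverage is a regular 7×7 lattice (5 mm pitch) per
  layer — 735 spots, close to the 779 of a clinical plan of this kind —
  and per-spot proton numbers are drawn log-uniformly from
  [2×10⁷, 3×10⁸]. The draw straddles the 0.5×10⁸ statistics filter of the
  PGI pipeline deliberately, so the filter is exercised; with the default
  seed, 505 of 735 spots survive filtering (the clinical analogue kept
  596 of 779).

## Detector forward models

**IDD / MLIC.** The noise-free depth-dose shape is analytic in the
residual-range coordinate r (remaining WET before stopping):
a unit plateau with an exponentially rising peak, cut at r = 0 and
convolved *in closed form* with a Gaussian range-straggling kernel
(σ = 1.2% of range):
f(r) = Φ(r/σ) + A·exp(σ²/2τ² − r/τ)·Φ(r/σ − σ/τ), with A = 11, τ = 12 mm.
Because both terms are exact Gaussian convolutions, a change of upstream
WET translates the sampled curve *exactly* — the property all shift
matching relies on, and the reason a closed form is used instead of a
numerical convolution (a unit test pins the closed form to an independent
numeric convolution). The MLIC samples f on 180 channels at 2 mm pitch,
treated as water-equivalent depths, fixed in the room. Per-channel noise
is multiplicative Gaussian (default 1%). Spots that stop before the
detector are flagged `range_out`; peaks at the channel-range edge
`clipped`; spots outside the 120 mm entrance window `aperture`.

**PGI.** Prompt-gamma emission is modeled as a constant density per mm of
track wherever material is present, terminated by a logistic fall-off (in
WET, width 1.5 mm) where the accumulated WET approaches the spot's
effective range, offset 2 mm upstream of the dose fall-off. The offset and
width are free parameters; scenario *shifts* are invariant to both. The
density is convolved with the camera's Gaussian point spread (σ = 5 mm —
the 4 mm crystal pitch is modeled as resolution, not binning) and
integrated over 1 mm room-frame bins inside a ±70 mm field of view.
Expected counts are protons × (yield × density + background) with defaults
10⁻⁴ and 5×10⁻⁶ per proton per mm, giving ~10⁴ counts per bin near the
fall-off for a 10⁸-proton spot; counts are Poisson-sampled. The real
camera's absolute photon economy is not published; these are stated free
parameters, and the package's precision figures consequently do not
emulate the measured ones (see *Limitations*).

## Shift extraction

**PGI pipeline.** The ten undisturbed deliveries are accumulated bin-wise
into one high-statistics reference per spot. Spots are kept if they
deliver ≥ 0.5×10⁸ protons and their predicted fall-off lies ≥ 5 mm inside
the FOV. Profiles of each energy layer are aggregated with a normalized
2-D Gaussian kernel over BEV distance (σ = 7.8 mm, never across layers,
unweighted by spot intensity), applied identically to reference and
measurement. Each aggregated pair is background-subtracted (median over a fixed-length
15 mm window starting 20 mm beyond the profile's own fall-off — anchoring
the window on the fall-off makes the preparation translation-equivariant,
so residual tail leakage cancels between reference and measurement),
plateau-normalized, and matched by least squares within the fall-off
window of the reference (between the distal crossings of 80% and 20% of
the plateau).

**RP pipeline.** Delivery k of a modified scenario is aligned against
delivery k of the reference — strictly index-paired, never pooled — spot
by spot, over a window anchored on the distal edge of the reference curve
(from the proximal 75%-of-peak crossing to the distal 10% crossing), after
area normalization. The per-repeat results form ten 9×9 range-shift maps.

**Matcher numerics.** Both matchers share one core: a coarse 0.1 mm grid
search over ±15 mm, a 0.01 mm fine grid around the coarse minimum, and
parabolic sub-grid refinement; ties break toward the smallest |shift|.
Two numerical choices matter and were made deliberately:

* curves are resampled with natural cubic splines. Linear interpolation
  of the 2 mm MLIC grid biases off-node shifts by ~2% (the interpolant is
  systematically below the curve between nodes on the convex peak).
* the amplitude is free in the fit. Plain SSD after area normalization
  underestimates shifts by ~1.5–2%: translating a curve moves part of it
  out of the finite channel range, the normalized amplitudes mismatch,
  and the fit trades amplitude error against translation. The PGI
  matcher fits the optimal amplitude per trial shift (scale-invariant
  least squares in the linear domain — Poisson counts can be zero in the
  tail). The RP matcher evaluates the misfit in log-dose space with a
  free offset: the window is bounded below by 10% of the peak, the log
  transform turns the multiplicative channel noise into additive
  homoscedastic noise, and the noise contribution to the expected misfit
  then no longer depends on the trial shift — a linear-domain amplitude
  fit showed a reproducible few-µm overestimate under measurement noise
  that the log fit removes (and it is ~2.6× more efficient). With these
  choices the noise-free scenario recoveries are exact to < 0.01 mm.

Failures are flagged (`no_falloff`, `boundary`, `clipped`), never silent.

## Ground truth and the WET conversion

A noise-free run of the same forward model and the same matcher
(`expected_shifts()`) stands in for the independent Monte-Carlo dose
recalculation of the clinical workflow. It is used twice:

* For AC scenarios, the conversion factor SPR_ΔR = S_WET,slab /
  S_geom,calc (known slab WET over calculated geometric shift) converts
  measured PGI geometric shifts to WET: S_WET,meas = S_geom,meas × SPR_ΔR.
  The factor is computed once per scenario from the spot-median calculated
  shift; with Bragg peaks in brain it evaluates to ≈ 1.04. For the
  downstream slab there is no Bragg-peak shift to calibrate on
  (S_geom,calc ≈ 0, Eq. degenerate); the brain SPR is used as fallback and
  the ground truth is 0.
* For SE scenarios the geometric ground truth itself is the spot-median
  calculated shift, and measured shifts convert by the brain mean SPR:
  S_WET,meas = S_geom,meas × 1.04 (couch movements displace the Bragg
  peak within homogeneous brain).

Ground truths G: slab WET for upstream slabs (2/3/5 mm, both systems);
0 for the downstream slab with PGI, 5 mm with RP; the calculated median
for couch scenarios — which evaluates to ≈ ±(0.3–0.75) mm WET for lateral
moves (from the phantom's lateral gradient), ≈ couch distance × 1.04 for
upstream moves with PGI (the camera is fixed in the room), and ≈ 0 for
upstream moves with RP (only the air gap changes).

## Weighted accuracy and precision

Each spot's measurement is the median M_i of its 10 repeats; weights are
inverse repeat variances w_i = 1/max(σ_i², 10⁻⁴ mm²). The variance floor
keeps weights defined when repeats agree exactly (noise-free runs); it is
configurable. Per scenario and system:

* weighted mean: μ̂ = Σ w_i M_i / Σ w_i
* weighted variance: σ̂² = Σw / ((Σw)² − Σw²) · Σ w_i (M_i − μ̂)², which
  reduces to the unbiased sample variance for equal weights (tested at
  machine precision)
* accuracy: A = μ̂ − G.

A deliberate single-delivery run keeps its spots with floored variance;
in repeated runs spots with fewer than two valid repeats are flagged out.

One caveat on interpreting σ̂/√N as the standard error of μ̂: the
in-layer aggregation correlates neighbouring PGI spots (σ = 7.8 mm
against a 5 mm pitch), so the effective number of independent spots is
much smaller than N and σ̂/√N understates the sampling error of μ̂. The
package's unbiasedness checks therefore estimate the standard error of
the accuracy A across independently seeded runs rather than from the
within-run spot scatter.

## Seeding and reproducibility

Every random draw derives from the master seed through a counter-based
fan-out: each (system, scenario, delivery) triple gets an arithmetic child
seed below 2³¹, so simulating a subset of scenarios never changes the
draws of the others. Within one delivery the spot draws are consumed in
plan order (subsetting *spots* would change draws — accepted, since plans
are fixed objects here). Identical configuration and seed reproduce every
table bit-identically.

## Problem sizes and runtime

Defaults: 735 treatment spots (505 evaluated), 81 probe spots, 11×10
deliveries per system, ~50 000 PGI and ~8 000 RP matches; the full default
experiment runs in about 2 minutes on one CPU. The test suite uses reduced
lattices (2–3 layers, 2×3–3×3 spots) except where the acceptance checks
exercise the full-size noise-free pipeline.

## Limitations

* The detector noise magnitudes are free parameters: the package
  reproduces the *structure* of the comparison (what each system can and
  cannot see, the estimator, the conversion) and its deterministic
  recoveries, but not the experimentally measured precision values, which
  depend on unpublished detector physics. Likewise the real PGI
  underestimation of thicker slabs (a physics effect of the camera) is
  not emulated: here both systems recover slabs accurately.
* The phantom is layered and its lateral gradient linear; real anatomy
  produces spot-to-spot variation within a scenario that the synthetic
  setup only shows through its (linear) gradient.
* Monte-Carlo transport, CT/DECT imaging chains, dose optimization and
  RBE modelling are out of scope; the analytic Bragg model is valid for
  shift extraction because only the distal edge matters.
* Couch positioning uncertainty (sub-mm in the real experiment) is not
  modeled; scenario magnitudes are exact.

## A worked example

```{r, eval = FALSE}
library(protonrv)

cfg <- experiment_config(scenarios = c(1, 4, 9), repeats = 10, seed = 42)
res <- run_experiment(cfg)
glance(res)      # per-scenario N, mu_hat, sigma_hat, G, A
tidy(res)        # per-spot medians, variances, weights
autoplot(res)    # boxplots of per-spot median WET shifts vs ground truth
plot_rsm(res, 1) # BEV map of the probe-field shifts for scenario 1
```
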