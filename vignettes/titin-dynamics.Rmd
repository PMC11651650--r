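---
title: "Quantifying titin dynamics in myotubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying titin dynamics in myotubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinflow)
```

## The biological problem

Skeletal muscle fibers are syncytia: many myocytes fuse into one
multinucleated cell whose sarcomeres contain titin, a giant (~3–4 MDa)
elastic protein anchored at the Z-disk and M-band. When two cells carrying
differently labelled titin (e.g. mCherry at the Z-disk of one, eGFP at the
M-band of the other) fuse, the labels gradually mix along the fiber. Three
quantitative questions follow, and this package implements the machinery
for each:

1. **How mobile is titin within the sarcomere lattice?** Measured by FRAP:
   bleach a region, watch fluorescence return as unbleached protein
   exchanges in.
2. **How fast does protein from one nucleus spread through the syncytium
   after fusion?** Measured by threshold-based classification of
   two-channel movies into mixing classes and the growth rate of the mixed
   area.
3. **Is the observed spread compatible with passive diffusion plus protein
   turnover?** Answered by a diffusion-with-decay model: the steady-state
   gradient width implied by a diffusion coefficient `D` and half-life
   `tau` is compared with the measured width.

Because raw microscopy data of this kind are rarely redistributable, the
package pairs every analysis stage with a seeded synthetic generator that
emits ground truth, so all claims are tested by parameter recovery.

## FRAP kinetics

### Normalization

A raw trace holds the bleached-ROI intensity `I_frap(t)`, the whole-cell
intensity `I_whole(t)` (which falls through acquisition photobleaching) and
the background `I_base(t)`, plus pre-bleach anchors. `normalize_trace()`
applies the standard double normalization

$$I_{norm}(t) = \frac{I_{frap}(t) - I_{base}(t)}{I_{whole}(t) - I_{base}(t)}
  \cdot \frac{I_{whole,pre}}{I_{frap,pre}},$$

so pre-bleach samples map to ~1 and acquisition bleaching cancels. The
pre-bleach factor deliberately uses the raw anchors without background
subtraction; the two conventions differ only by a multiplicative constant
near 1 when the background is small relative to the pre-bleach signal, and
the chosen form keeps the anchors directly interpretable as recorded
intensities.

### Association models

`frap_fit()` fits the post-bleach curve (t = 0 at the first post-bleach
frame) with

- one phase: $y(t) = y_0 + M_f\,(1 - e^{-K t})$,
- two phases: $y(t) = y_0 + M_f\,[f\,(1 - e^{-K_{fast} t}) + (1 - f)(1 - e^{-K_{slow} t})]$,

with bounds $y_0, M_f \in [0, 1.5]$ (configurable) and positive rates.
$M_f$ is the fitted recovery span; the conventional mobile fraction
$(F_{end} - F_{post})/(F_{pre} - F_{post})$ is derived as
$M_f / (1 - y_0)$ since the normalized pre-bleach level is 1. The
exchange half-life is $\ln 2 / K$ for one phase; for two phases it is the
time at which half of the span has recovered, found by root-finding, which
reduces to $\ln 2 / K$ when $f$ is 0 or 1. `percent_fast` is $100 f$.

Two phases typically reflect two co-expressed titin isoform populations
with different exchange kinetics, so most myotube recoveries are biphasic.

### Numerical choices

- **Multi-start optimization.** Rates are poorly scaled (half-lives from
  minutes to many hours on a 14-hr schedule), so Levenberg–Marquardt is
  started from a log-spaced grid of `K` values ($10^{-4}$ to $1$ per
  minute, 7 starts; rate pairs for the two-phase model). Best residual sum
  of squares wins; ties go to the smaller rate.
- **Flat-fit guard.** On recovery-free data, $M_f$ and $K$ are jointly
  unidentifiable (only their product is constrained), and an unguarded
  optimizer returns an arbitrary span with a rate at the boundary. Each fit
  is therefore compared with the constant model by an extra-sum-of-squares
  F-test; when the association terms do not significantly reduce the
  residual (p ≥ 0.05), a flat fit with $M_f = 0$ and unidentifiable (NA)
  rates is reported. This is what makes fixed-cell controls report a
  mobile fraction of ~0 instead of noise-driven nonsense.
- **Model selection.** One- vs two-phase is decided by the
  extra-sum-of-squares F-test at α = 0.05 (3 vs 5 parameters), the
  convention of the widely used curve-fitting packages; `select_model()`
  exposes the p-value. A fitted rate ratio below 1.5 is flagged as
  practically monophasic. If the two-phase rss exceeds the one-phase rss —
  impossible for exact nested optima, possible numerically — the one-phase
  model is chosen with a warning.
- A fit that fails from every start returns `converged = FALSE` with
  diagnostics rather than throwing, so one bad cell does not abort a batch.

## Two-channel mixing classification

`calibrate_channel()` anchors each channel on reference cells — the mean
over a negative cell is 0%, over a bright positive neighbour 100% — and
pixel intensities become percentages clipped to [0, 150]. Calibration is
per movie (first frame), not per frame: recalibrating each frame would
absorb photobleaching into the calibration and confound it with mixing.

`classify_pixels()` applies the two thresholds, weak = 20% and
strong = 50%, to both channels and assigns each pixel to one of
`r length(mixing_classes())` classes: `only_red` (red signal, no green),
`majority_red` (strong red, weak green), `mixed` (both strong),
`majority_green`, `only_green`, `background` (neither), and `both_weak`
(both channels between the thresholds). The five named classes follow the
standard scheme; `both_weak` is added and reported separately because the
five alone do not cover that combination, and exhaustiveness is required
for the area bookkeeping (per frame, class areas must sum exactly to the
frame area). Threshold equality falls to the weaker category — a fixed,
documented convention rather than a claim about the right one.

`measure_areas()` converts pixel counts to µm² (areas are pixel counts
times the squared pixel size; no sub-pixel contours, matching the
threshold/count methodology), `mixing_timeseries()` assembles per-frame
class areas and the mixed-area percentage, `filter_cells_by_area()`
excludes very small (< 1000 µm²) and very large (> 10,000 µm²) cells whose
size would confound speed comparisons (inclusive bounds), and
`spread_rate()` reports the least-squares slope of absolute mixed area
over the initial growth window — from the first frame with nonzero mixed
area to the first frame at 90% of the final mixed area — in µm²/hr and
µm²/s. An optional 3×3 median filter (edge-replicated) suppresses shot
noise before thresholding; it is on by default for real movies and
switched off when classifying noiseless synthetic data against ground
truth.

`gradient_width()` operationalizes the visible extent of protein spread
between neighbouring nuclei as the axial distance between the 50% and 20%
crossings of the invading channel's (optionally smoothed) profile, located
by linear interpolation. For an exponential profile
$100\,e^{-x/\lambda}$ this gives $\lambda \ln(50/20) \approx 0.916\,
\lambda$. How such widths are read off published images is rarely
specified; the crossing-point definition is one reasonable, reproducible
choice and is documented as such.

## Diffusion with decay

Treat the invading species as produced at its nucleus (a fixed-concentration
source), diffusing with coefficient `D` and decaying with half-life `tau`
(rate $k = \ln 2/\tau$). The steady state of
$\partial_t c = D\,\partial_x^2 c - k c$ with a source decays as
$e^{-x/\lambda}$ with decay length

$$\lambda = \sqrt{D \tau / \ln 2}.$$

`decay_length()`, `required_half_life()` ($\tau = \ln 2\, d^2 / D$) and
`required_diffusion()` ($D = \ln 2\, d^2 / \tau$) are algebraically
consistent inverses of one another; `consistency_report()` bundles them
with a verdict: an observed gradient width `d_obs` is compatible with
(`D`, `tau`) iff $\lambda$ lies within a configurable factor (default 2)
of `d_obs`. With the literature-derived inputs — D = 0.3 µm²/s, τ = 3.5
days, d ≈ 50 µm — the decay length is ~360 µm, far wider than the observed
gradient; explaining 50 µm would need either a half-life under 100 min or
a diffusion coefficient two orders of magnitude smaller, which is the
quantitative argument that something beyond passive diffusion restricts
titin spread. All three functions accept an `ln2` argument; passing the
rounded literal 0.693 reproduces arithmetic done with that constant
exactly (e.g. $0.693 \cdot 50^2 / 0.3 = 5775$ s), while the default is
full precision — the two agree to well beyond the precision such numbers
are quoted at.

`simulate_1d()` validates the closed forms numerically: an explicit
forward-time centred-space (FTCS) scheme, chosen for transparency, with
the decay applied as an exact integrating factor $e^{-k\Delta t}$ each
step. Consequences:

- pure decay is exact per grid cell, and total mass under reflecting
  boundaries decays exactly as $e^{-k t}$ (the diffusion stencil is
  conservative);
- stability requires $\Delta t \le \Delta x^2 / (2D)$, and the solver
  refuses to run otherwise instead of silently adjusting the step;
- spatial truncation error is second order in $\Delta x$, verified by a
  grid-refinement test.

Boundary conditions are a fixed-concentration source region (a nuclear
domain producing protein at capacity) and reflecting walls; sources are
re-clamped after every step. When comparing a finite domain with the
infinite-domain exponential, the reflecting far wall lifts the profile by
roughly $e^{-2(L - x)/\lambda}$, so oracle tests use domains of 6–8
decay lengths and compare within 3.

## Synthetic data: what it emulates and what it does not

`gen_frap_trace()` builds raw intensities whose double normalization is
exactly the configured recovery curve: pre-bleach at 1, post-bleach
$y_0 + M_f(1 - y_0)[\ldots]$ with $y_0$ the bleach depth, a whole-cell
channel decaying at the configured acquisition-bleaching rate, a constant
background, and additive Gaussian noise. Defaults are the Z-disk titin
conditions: mobile fraction 0.73, 37% fast phase with the fast phase
recovering within ~5 min (`k_fast` = ln 2 / 2.5 min) and an overall
half-life of ~1.5 hr (`k_slow` = ln 2 / 90 min), bleach depth 0.2, noise
sd 0.01 on the standard schedule — one pre-bleach frame, then every 5 min
for 30 min, every 30 min to 2 hr, and hourly to 14 hr (23 samples).
`gen_fixed_cell_trace()` is the same generator with the mobile fraction
forced to 0, the negative control in which the striated pattern must not
recover.

The noise model is additive Gaussian on relative intensity — read noise
dominating at these signal levels — which keeps parameter-recovery
tolerances analytic; a Poisson shot-noise option is deliberately deferred.

`gen_fusion_movie()` places a red and a green cell end-to-end (disjoint
halves of a fiber), fuses them at a configurable frame, and lets each
species evolve by the 1-D solver along the fiber axis — replenished at its
nuclear source, decaying at $\ln 2/\tau$ — broadcast across the fiber
width. Transport is 1-D because the gradient analysis is 1-D; movies are
2-D images only in the sense that each profile is replicated across the
width. Intensities are quantized to the 16-bit camera grid (which also
makes TIFF round-trips bit-exact), and ground-truth class maps are
computed from the quantized noiseless fields by the same classifier the
analysis uses, so "classification equals ground truth" is a meaningful
pipeline test rather than a tautology about floating-point luck. Defaults:
200 × 20 µm fiber, two frames per hour over 8 hr, fusion at the second
frame, D = 0.3 µm²/s for both species, τ = 3.024 × 10⁵ s (3.5 days),
nuclear domains 10 µm from each fiber end.

Two documented departures from the obvious defaults:

- **Pixel size defaults to 0.5 µm, not the 0.1311 µm microscope pitch.**
  The transport substep count scales as $1/\Delta x^2$; at the microscope
  pitch a default movie would need ~10⁶ substeps per frame for no gain in
  the quantities under test. 0.1311 µm remains a valid input. (The
  published pitch "0.1311 × 0.311 µm²" is internally inconsistent; it is
  treated as a typo for square 0.1311 µm pixels.)
- **Time units are per surface, not globally uniform**: FRAP works in
  minutes (rates per minute, CSV column `time_min`), fusion time series in
  hours, the diffusion module in seconds — each matching the units its
  results are conventionally quoted in.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: optical blur (no PSF), sarcomeric striation texture,
cell-shape irregularity and motion, z-sectioning, photobleaching of the
*bleached-ROI* fluorophore during acquisition beyond the whole-cell decay
term, active (motor-driven) transport, and mRNA logistics. Parameter
recovery under this model demonstrates the estimators are correct and
well-conditioned at realistic noise, not that segmentation-free
thresholding suffices on arbitrary microscopy.

## Problem sizes and determinism

Every generator takes an integer seed and restores the caller's RNG state;
the same seed reproduces traces, stacks and ground truth bit-for-bit. The
test suite and the acceptance script use deliberately modest problem
sizes — 50 seeded traces for recovery statistics, fibers of 100–200 µm at
0.5–2 µm pixels, steady-state grids of ~300 cells at λ/50 — chosen so the
full analysis re-runs from scratch in seconds while leaving every
tolerance comfortably analytic.

## Known limitations

- Pure exchange kinetics: no reaction–diffusion FRAP model, so very fast
  diffusive recovery would be absorbed into `k_fast`.
- The classifier has no segmentation or tracking; the cell mask is implied
  by the non-background classes, which is adequate for end-to-end fused
  pairs but not for dividing or overlapping cells.
- The 1-D transport model ignores fiber taper and cross-sectional
  structure; `D` is an effective axial coefficient.
- `gradient_width()` assumes a monotone-decaying invasion front after
  smoothing; profiles with interior maxima return the first consistent
  crossing pair.
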