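---
title: "Quantifying microtubule network architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule network architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mtquant quantifies how a cell's microtubule (MT) network is organised:
whether polymer mass sits in a centrosomal aster or is spread towards the
periphery, how many individual filaments there are and how long they are,
where growing plus-ends (EB1 comets) originate, how fast tips switch
between growth, shrinkage and pause, and how densely a microtubule-binding
protein decorates filaments of different ages. This vignette explains each
procedure, the parameters that matter, the model behind the simulators,
and the numerical decisions a maintainer would want to know about. It
states no measured numbers: every empirical claim about the package is
made (and re-made on each run) by the test suite and by
`scripts/acceptance.R`.

## The Microtubule Distribution Index (MDI)

The MDI condenses the radial organisation of tubulin fluorescence into one
number per cell. The inputs are a manually chosen central point (placed in
the region of highest tubulin signal) and a polygon outlining the cell
border. From the center, straight line profiles are drawn to the boundary
at a fixed angular interval — 3° by default, giving
`floor(360 / 3) = 120` lines. Along each line the image is sampled at
roughly one-pixel arc spacing with bilinear interpolation. The mean
intensity over the inner 10% of the line (adjacent to the center) is
`I_i`; the mean over the outer 40% (adjacent to the border) is `I_o`; the
middle 50% contributes to neither, as the window definitions imply. Each
line yields the ratio `R = I_o / I_i`, and the MDI is the arithmetic mean
of all defined `R` values:

* a **low** MDI means intensity is concentrated at the center — an
  aster-like, centrosome-dominated network;
* an MDI near 1 means a uniform radial distribution, and values above 1
  indicate peripheral enrichment.

Two identities pin the scale down: a uniform image has `R = 1` on every
line (MDI = 1), and an image whose intensity lies entirely inside the
inner windows has MDI = 0. Because `R` is a ratio, the MDI is invariant
under global intensity scaling, so it is comparable across cells and
imaging sessions with different exposure.

Tunables (`mdi_config()`): `angle_interval_deg` (default 3°),
`inner_fraction` (0.10), `outer_fraction` (0.40), and the aggregate
(`mean`, with `max` available). The aster-versus-dispersed ordering is
insensitive to the window choice across inner 0.05–0.20 and outer
0.30–0.50, which the acceptance suite verifies on synthetic pairs.

Decisions the definition leaves open, and how they are resolved here:

* **`I_i = 0`.** A ray whose inner window contains no signal has an
  undefined ratio. Such lines are excluded from the per-cell average
  rather than mapped to infinity or zero; only if *every* line is
  undefined does `compute_mdi()` raise an error. In practice the center is
  placed inside the brightest tubulin region, so empty inner windows mean
  a degenerate annotation, not a property of the cell.
* **Concave outlines.** A ray can cross a concave boundary several times;
  the first crossing is used so the profile stays inside the cell.
* **Conventions.** Angles are measured counterclockwise from the +x image
  axis; pixels are indexed 0-based at pixel centers (x = column,
  y = row). These are stated because reproducibility requires *some*
  fixed convention.

## Filament segmentation and counting

Individual MTs in a repolymerization image are quantified in three steps:

1. **Ridge enhancement** (`enhance_tubular()`). The image is smoothed
   with a Gaussian at `scale_px` (match it to the PSF width; single MTs
   are diffraction-limited) and the Hessian eigenvalues are computed per
   pixel. Bright curvilinear structures have one strongly negative
   eigenvalue across the ridge; the response is
   `scale² · max(0, −λ_low)`. Flat regions respond zero and compact
   blobs — notably the dense centrosome core — respond weaker than lines
   of equal peak intensity, which is exactly why a tubularity filter is
   applied before counting.
2. **Skeletonization and labelling** (`skeletonize_and_count()`). The
   response is binarized (Otsu's threshold on the enhanced image by
   default; the original protocol does not state its binarization rule,
   so it is config-exposed), thinned to one-pixel-wide skeletons with the
   Zhang–Suen algorithm, and 8-connected components are labelled. Path
   length counts orthogonal skeleton steps as 1 pixel and diagonal steps
   as √2, skipping diagonal shortcuts where two orthogonal steps already
   connect the pixels; a lone isolated pixel is assigned its 1-pixel
   footprint so lengths stay positive.
3. **Size thresholds.** The original protocol removed, per image and by
   eye, objects so large they were evidently several overlapping MTs
   merged into one. Here that is an explicit, recorded configuration
   value: `size_max_um` removes overlong objects, `size_min_um` drops
   specks. Reproducibility is preferred over per-image judgement.

**De novo calling** (`call_de_novo()`): after drug-induced
depolymerization, surviving MTs carry tubulin acetylation, a mark of
long-lived polymer. An object counts as truly de novo only if *no* pixel
of its skeleton — dilated by `overlap_dilation_px` (default 1, absorbing
small channel-registration offsets) — exceeds `acetyl_threshold` in the
acetyl channel. Any sign of acetylation disqualifies. By construction,
de novo + acetylated = total.

**Aster area** (`aster_area()`): the manual protocol outlines the aster
and takes the polygon area; `mode = "roi"` reproduces that (shoelace area
× pixel area). `mode = "seeded"` is an automation convenience beyond the
manual method: Otsu threshold in a window around a seed point, then the
area of the 8-connected above-threshold region containing the seed.

Endpoint behaviour worth knowing: thinning erodes roughly one pixel per
filament end, so measured skeleton lengths sit a few percent below the
geometric truth on clean images (the tests bound the total error at 10%).
Two filaments whose rendered, PSF-blurred images touch — in particular
near-collinear ends closer than ~5 PSF sigma — merge into one object; that
is a physical resolution limit, not a counting bug, and it is the reason
the original protocol needed an overlap size threshold at all.

## EB1 comet origin classification

A comet track qualifies only when followed for more than three frames
(`min_frames = 4`); shorter tracks are excluded outright. A qualifying
track is **centrosomal** if it starts within `centrosomal_radius_um`
(default 2 µm) of the annotated centrosome *and* its first step does not
decrease its distance to the centrosome. The distance test, rather than a
velocity–radius angle, is used because comets born essentially on the
centrosome have a start radius comparable to localisation noise, where an
angle is meaningless but the distance change (one step, ~0.75 µm at
typical speeds) is robust. A track is **non-centrosomal** if it starts
beyond `ambiguity_factor × centrosomal_radius_um` (default 2×, i.e. 4 µm).
Starts inside the annulus between the two radii, and centrosome-proximal
starts moving inward, are **excluded** as ambiguous — the visual
"unambiguous origin" criterion of the manual protocol mapped to explicit
radii. Calls are invariant under rigid motions of all coordinates, which
the tests check.

Time zero of a washout movie (`detect_time_zero()`) is the first frame
whose summed fluorescence exceeds the baseline — median of the first
`baseline_frames` (5) frames — by `n_sigma` (5) times the baseline's
scaled MAD, floored at 10% of the baseline so an exactly flat baseline
cannot produce a zero threshold. A trace that never crosses is flagged
"no burst detected" rather than assigned a frame.

## Dynamic instability from discretely sampled tracks

### Phase segmentation

Tip positions are sampled every `frame_interval_s` (3 s). For each
consecutive frame pair the displacement, projected onto "away from the
reference", classifies the interval: magnitude below
`static_threshold_um = 0.3` µm per frame ⇒ **pause**; at least the
threshold moving away ⇒ **growth**; towards ⇒ **shrinkage**. The
reference (`direction_ref`) is either a minus-end proxy point — growth
increases the distance to it — or a signed image axis for tracks whose
geometry makes a point reference ill-defined (a trajectory crossing its
reference point would otherwise have its motion rectified). Tracks with
skipped frames are split at the gaps (`split_track_at_gaps()`); "moved
less than 0.3 µm per frame" is a per-frame rule and is not rescaled
across gaps.

### Summary statistics

`summarize_dynamics()` pools segmentations into a life-history table:
percentage of time in each phase (summing to 100 by construction), mean
speed over growth and over shrinkage intervals, and the switching
frequencies. A **catastrophe** is a transition from growth *or pause*
into shrinkage; a **rescue** is a transition from shrinkage *or pause*
into growth. "Frequency" needs a denominator, and the convention is
config-exposed because the table format this mirrors does not state it:
`at_risk = "with_pause"` (default) divides catastrophes by time in
growth + pause and rescues by time in shrinkage + pause — the standard
at-risk-time convention matching the transition definitions — while
`"phase_only"` divides by pure growth or shrinkage time. A frequency
whose at-risk time is zero is reported as `NA`, never as 0.

### Finite-sampling bias and its correction

At a 3 s frame interval, per-interval labelling is blind to fast
structure, and the naive event-count estimator is biased low — by roughly
`k · dt` relative terms, up to tens of percent at 4 events/min:

* an excursion (catastrophe followed by rescue, or vice versa) that fits
  inside about one frame interval produces no label change at all, so
  both events vanish;
* an interval containing a transition is labelled as a single whole
  phase, so at-risk time leaks between denominators.

`summarize_dynamics(..., discretization_correction = TRUE)` inverts both
effects analytically. Under exponential phase durations, a phase of rate
`k` starting at a uniform offset within a frame fails to push any
interval's occupancy fraction above a threshold `s` with probability
`M(s, k) = P(e ≤ s) + E[(2s − e)⁺/dt; e > s]`, which has a closed form.
With `fS` and `fG` the occupancy fractions at which an interval's net
displacement crosses −threshold and +threshold (computed from the median
within-phase speeds, which transition intervals do not bias), the
probability that a catastrophe or rescue goes uncounted, and the expected
at-risk-time shift per event (`dt·(1/2 − fS)` and `dt·(fG − 1/2)`, plus
the durations of fully invisible excursions parked in the wrong
denominator), combine into a small fixed-point problem solved by
iteration. The default remains the uncorrected estimator — it is the
literal definition — and the correction is the package's recommended
estimator for rate recovery from regularly sampled data. The tests
require the corrected estimator to recover simulation truth within three
standard errors across a 3×3 grid of catastrophe/rescue rates spanning
0.5–4/min; the derivation above was done analytically, not fitted to
those runs. The correction assumes the two-state switch dominates; with
substantial pausing (`p_pause` well above 0) it is approximate.

## In vitro nucleation fields and immunogold density

`quantify_field()` reproduces fixed-minimum particle analysis: binarize
at `min_intensity`, label 8-connected components, discard components
below `min_area_px` (default 4 pixels, suppressing single-pixel noise —
the protocol's "fixed minimum" referred to intensity only), return count
and areas. `aggregate_fields()` gives mean ± SEM per condition and warns
below 25 fields, the assay's sampling convention; with a single field the
SEM is `NA`.

For immuno-EM, filaments arrive as polylines with gold-particle
coordinates (`em_filament()`, the "bound" criterion made explicit by a
25 nm capture offset in the generator: gold radius plus antibody reach).
`particle_density()` is particles per µm of filament length.
`density_length_correlation()` computes the Spearman rank correlation of
density against length: average ranks for ties, Pearson on the ranks, and
a two-sided p-value from the exact permutation distribution for n ≤ 10
(all n! permutations; symmetric, so the two-sided value is twice one
tail) or the t approximation `t = ρ√((n−2)/(1−ρ²))` otherwise. Constant
inputs flag the correlation undefined. A brute-force rank oracle, written
independently in the tests, must agree to 1e-12 on a thousand random
small inputs. A negative ρ means shorter — younger — microtubules carry
denser decoration.

## What the simulators emulate, and what they do not

`make_filament_image()` renders straight filaments as unit-amplitude,
one-pixel-wide anti-aliased lines — the correct model for
diffraction-limited MTs, whose true width is far below the PSF — then
convolves with a Gaussian PSF, adds a constant background and Gaussian or
Poisson noise. Aster layouts radiate from a centrosome point; dispersed
layouts place midpoints and orientations uniformly. Overlap-free
placement is by rejection sampling (10,000 attempts, then a "no placement
area" error, bounding runtime). Acetylated filaments are rendered into a
second channel. Not emulated: curved filaments, 3-D stacks,
photobleaching, a structured centrosome body, autofluorescence gradients.
Passing counts on these images therefore demonstrates correctness of the
measurement chain, not robustness to everything real images do.

`simulate_di_track()` is a three-state continuous-time model: growth
advances the tip at `v_growth`, shrinkage retreats at `v_shrink`, pause
is stationary. Catastrophes fire at `k_catastrophe`, rescues at
`k_rescue`; with probability `p_pause` a transition is interrupted by an
exponential pause (exit rate 1/min by default) and completes on exit, so
each pause-mediated switch counts exactly one catastrophe or rescue —
consistent with the "growth (or pause) to shrinkage" event definitions.
The tip position is sampled every frame with isotropic Gaussian
localisation jitter. Defaults were chosen once as field-typical for
interphase cells and are not tuned per test: `v_growth` 15 µm/min,
`v_shrink` 20 µm/min, frame interval 3 s, jitter σ 0.05 µm — deliberately
well under the 0.3 µm/frame threshold so jitter alone never flips a
classification (at these speeds, per-frame steps are 0.75 and 1.0 µm,
≥ 12σ of the differenced jitter). The manual-tracking precision of the
original protocol is unknown; jitter is a free simulation parameter, not
a measured value. The simulator records its full event history, so
estimators are scored against exact continuous-time truth, and the true
occupancy converges to the analytic stationary distribution of the
four-state generator (growth, shrinkage, and the two pause sub-states) —
a property the tests check after a burn-in, since tracks never start
paused.

`simulate_comets()` produces labelled origin ground truth with start
zones separated by construction (centrosomal within `start_radius_um`,
non-centrosomal beyond `exclusion_radius_um`); when the exclusion radius
is at least the ambiguity band, zone membership guarantees the correct
call, which is what makes 100% agreement a meaningful requirement rather
than luck. `make_em_filaments()` draws lengths from a configurable
distribution and scatters gold by a Poisson process with
length-dependent intensity, e.g. `density ∝ 1/L` to emulate preferential
binding to young MTs.

All generators route randomness through a private seeded RNG stream and
restore the caller's RNG state: identical seeds give bit-identical
output.

## Numerical choices and conventions

* Coordinates: 0-based pixel centers, x = column, y = row; µm and
  minutes in all outputs.
* Bilinear interpolation for line profiles, ~1-pixel arc spacing.
* Gaussian smoothing uses replicate padding (no wrap-around of border
  structures), and FFT residues below 1e-9 of the maximum are truncated
  to exact zero so that empty background is exactly empty — ratio
  statistics and the ridge response rely on zero meaning zero.
* TIFF output is written at the standard 16-bit microscopy depth;
  intensities are snapped to the 16-bit grid on write (quantization
  ≤ 7.7 × 10⁻⁶), after which write/read round trips are bit-identical.
  Pixel size comes from TIFF resolution tags when present or an explicit
  override; without either, reading fails rather than guessing.
* Otsu thresholds are computed after affinely mapping the image to
  [0, 1] and mapping the threshold back.
* Ties in Spearman ranks get average ranks; the exact permutation
  enumeration is limited to n ≤ 10 (10! ≈ 3.6 million orderings).

## Problem sizes

The shipped analyses and checks run at sizes chosen to make their
statistical guarantees meaningful while staying desk-scale: 192²–320²
pixel images (the in vitro default remains 1024² at 0.1 µm/pixel), 50
seed replicates for image-based count and ordering checks, 500 ten-minute
tracks per condition on a 3×3 rate grid for dynamics recovery, 200 EM
filaments for the density–length trend, and 1,000 random small inputs for
the Spearman oracle.

## Interface

The package's functions are the API; the numbered scripts under
`analysis/` are thin narrative drivers that generate the synthetic study
data (`01_simulate.R`) and run each analysis stage over it
(`02_mdi.R` … `06_invitro_em.R`), writing tables under `results/` together
with a metadata block (`run_metadata()`: package version, seed, verbatim
parameters, config hash) sufficient to reproduce any deterministic stage
bit-exactly. `scripts/acceptance.R --seed S --out path.json` recomputes
the headline quantities from scratch.

## Known limitations

* Filament counting resolves overlaps only by the size-threshold
  heuristic; crossing filaments are removed, not disentangled.
* The discretization correction targets the two-state switch; heavy
  pausing makes it approximate, and it assumes exponential dwell times.
* The comet ambiguity band is a geometric proxy for a visual judgement;
  tracks that pass near the centrosome without originating there are
  excluded, not resolved.
* MDI compares cells only up to the annotation quality of center and
  boundary; automatic segmentation and center detection are out of scope
  by design.
* 3-D stacks are handled only by maximum projection.
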