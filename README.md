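# mtquant

Quantification of microtubule (MT) network architecture and dynamics from
fluorescence microscopy, for cell biologists studying how the balance
between centrosomal and non-centrosomal microtubules is regulated — for
example by small heat shock proteins during network repolymerization after
nocodazole washout.

The package implements, as tested R functions over plain containers
(matrices, data frames), the measurement chain such a study needs:

* **MDI — Microtubule Distribution Index.** Per cell, radial line
  profiles are drawn from a central point to the boundary polygon at a
  fixed angular interval (3° ⇒ 120 lines). For each line,
  `R = I_o / I_i`, the ratio of the mean intensity over the outer 40% of
  the line to the mean over the inner 10%; the MDI is the mean of all
  defined `R`. Low MDI ⇒ centrosome-concentrated (aster-like) network;
  higher MDI ⇒ peripherally spread network. Scale-invariant by
  construction.
* **Filament counting.** Hessian ridge (tubularity) enhancement →
  binarization → Zhang–Suen skeletonization → 8-connected labelling with
  √2-weighted path lengths, plus explicit upper/lower size thresholds for
  the overlap-removal step; de novo MTs are objects with *no* acetyl
  channel signal along their (dilated) skeleton; aster area from a manual
  ROI polygon or a seeded Otsu region.
* **EB1 comet origin.** Tracks followed for more than three frames are
  classified centrosomal (start within 2 µm of the centrosome, first step
  moving away) or non-centrosomal (start beyond 2× that radius); starts
  in between are excluded as ambiguous. Time zero of a washout movie is
  the first fluorescence burst over a robust baseline.
* **Dynamic instability.** Per-frame displacements below 0.3 µm/frame are
  pause; otherwise growth or shrinkage by the sign of motion away from a
  reference. Summaries report phase percentages, speeds, and catastrophe
  frequency `f_cat = N(growth|pause → shrink) / T_at-risk` (per minute;
  rescues symmetric), with both at-risk conventions and an optional
  analytic correction for frame-discretization bias.
* **In vitro / immuno-EM.** Fixed-minimum particle analysis of nucleation
  fields with ≥25-field mean ± SEM aggregation; gold particles per µm of
  MT, and the Spearman rank correlation (exact permutation p for n ≤ 10)
  of binding density against MT length.
* **Synthetic ground truth.** Seed-deterministic generators for aster vs
  dispersed filament images (PSF blur + noise, optional acetylation
  channel), three-state dynamic-instability tracks with recorded
  continuous-time truth, labelled comet tracks, and Poisson-decorated EM
  filaments — every analysis stage is testable without any microscope.

## Worked example

```r
library(mtquant)

# an aster-like and a dispersed cell with identical filament statistics
spec  <- image_spec(192, 192, psf_sigma_px = 1.5, background_level = 0.05, seed = 7)
aster <- make_filament_image(spec, 40, c(2, 6), layout = "aster")
disp  <- make_filament_image(spec, 40, c(2, 6), layout = "dispersed")
geo   <- circle_geometry(c(95.5, 95.5), radius_px = 90)
compute_mdi(aster$image, geo)
#> <mdi_result> MDI = 0.0664 over 120 lines (0 undefined)
compute_mdi(disp$image, geo)
#> <mdi_result> MDI = 0.4085 over 120 lines (0 undefined)
```

The aster scores ~6× lower: its intensity sits in the inner windows of
the 120 radial lines, the dispersed network pushes mass outward.

```r
# count filaments in a clean, non-overlapping image
spec <- image_spec(192, 192, psf_sigma_px = 1.5, seed = 11)
g  <- make_filament_image(spec, 12, c(1.5, 4), min_separation_px = 8)
skeletonize_and_count(enhance_tubular(g$image, scale_px = 1.5))
#> <filament_set> 12 objects, total length 27.11 um (threshold 0.05591)
sum(g$truth$lengths_um)
#> [1] 27.55
```

All 12 filaments are recovered; the skeleton total is ~1.6% short of the
geometric truth because thinning erodes about one pixel per filament end.

```r
# dynamic instability: 200 simulated 10-min tracks at k_cat = k_res = 2/min
segs <- lapply(1:200, function(i) {
  p <- dynamics_params(k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                       n_frames = 201, seed = i)
  segment_phases(simulate_di_track(p), direction_ref = "+x")
})
summarize_dynamics(segs, discretization_correction = TRUE)
#> <dynamics_summary> 200 tracks, 2000.0 min
#>   growth 48.2% @ 14.76 um/min | shrink 48.5% @ 19.49 um/min | pause 3.3%
#>   catastrophe 2.036 /min (n=1819) | rescue 1.981 /min (n=1722)
```

The corrected estimator recovers the simulated rates (2/min each) and
speeds (15 / 20 µm/min) from the 3-s-sampled, jittered positions alone.

```r
# immunogold density vs MT length, decoration ~ 1/length
em  <- make_em_filaments(200, length_dist = list(dist = "uniform", min = 0.5, max = 6),
                         density_fn = function(L) 6 / L, seed = 1)
res <- density_length_correlation(em)
sprintf("Spearman rho = %.3f (p = %.3g)", res$rho, res$p_value)
#> [1] "Spearman rho = -0.682 (p = 9.12e-29)"
```

A strongly negative rank correlation: shorter (younger) microtubules are
more densely decorated.

## Analysis workflow

The numbered drivers under `analysis/` run the full synthetic study and
write tables to `results/`:

```sh
Rscript analysis/01_simulate.R    # images, tracks, EM annotations + metadata
Rscript analysis/02_mdi.R         # MDI, aster vs dispersed, window robustness
Rscript analysis/03_filaments.R   # counts, lengths, de novo calls
Rscript analysis/04_dynamics.R    # life-history table, both conventions
Rscript analysis/05_comets.R      # origin classification, time zero
Rscript analysis/06_invitro_em.R  # nucleation fields, density vs length
```

Each driver states what it found on stdout and records a metadata block
(version, seed, parameters, config hash) beside its outputs. The methods
vignette (`vignettes/microtubule-quantification.Rmd`) documents the
models, parameter defaults, numerical decisions and limitations.

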