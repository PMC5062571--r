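---
title: "wormhts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormhts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wormhts)
```

This vignette explains the models and procedures implemented in `wormhts`,
the assumptions behind them, and the design decisions taken where the
underlying assay leaves a choice open. It states no empirical numbers beyond
what the package's own tests and scripts compute.

## The assay

*C. elegans* strains expressing polyglutamine::YFP fusions in body-wall
muscle report aggregation propensity: Q24 stays diffuse while Q35 forms
discrete 1–5 µm fluorescent puncta by day-3 adulthood. The screening
platform immobilizes up to 96 populations at once in a microfluidic chip —
40 parallel tapered trapping channels per well at 150 µm pitch — and images
each well as 4 camera fields of view (FOVs) of 10 channels, with a 15-plane
z-stack at 5 µm steps per FOV (2048 × 2048 px, 0.74 µm/px at 10×). The
phenotype score of an animal is its number of detected aggregates per µm of
body length.

## Chip geometry and stage calibration

`chip_layout()` holds the plate geometry; `enumerate_acquisitions()` expands
wells into the ordered (well, FOV, z) event list with nominal stage
coordinates. Conventions the hardware does not dictate and that we fixed
once: the chip frame has its origin at the centre of well A01, x along
columns, z toward the objective, all lengths in µm; wells are visited
row-major (A01 → H12); the 4 FOVs tile the 40 channels in channel order; and
the z-stack is centred on the corrected focal estimate. The default stack
spans (15 − 1) × 5 = 70 µm, matching the largest substrate bending the
calibration must absorb.

`calibrate_from_markers()` fits three corrections from four corner markers:

* **Rotation θ_XY** — closed-form 2-D least-squares (Procrustes) rotation of
  the nominal onto the measured in-plane marker positions, with the implied
  translation.
* **Tilt δ_XZ, δ_YZ** — the plane fit of the z offset over the corrected
  (x, y).
* **Bending Δ(x, y)** — whatever z residual remains after rotation and tilt
  removal, interpolated over the chip. When the samples form a regular grid
  (e.g. per-well focal surveys, the default use) the field is bilinear with
  nearest-value clamping outside the grid; for scattered samples (e.g. the
  four markers plus a centre point) an inverse-distance-squared interpolant
  is used. Both reproduce every sample exactly and never exceed the sampled
  range, so a `max_bending` bound on the samples (default 70 µm) bounds the
  whole field. Degenerate (collinear) marker sets are rejected.

Because each stage is exact on exact data, a marker set that is exactly a
rotation + tilt of the nominal is reproduced to machine precision — the
round-trip property the tests assert at 1e-6 µm.

## Hydraulic equivalent circuit

Loading the chip requires similar flow through every well under the single
gasket pressure P₁. Channels are laminar rectangular ducts; we use the
standard low-aspect-ratio resistance

R = 12 µ L / (w h³ (1 − 0.63 h/w)),  w ≥ h,

which is within ~13% of the exact Fourier-series solution even for square
ducts (the tests compare against the series truncated at 100 odd terms).
Units are µm, Pa, Pa·s, so flows come out in µm³/s. A well's 40 identical
traps are lumped as one branch with a parallel `multiplicity`.

`solve_flows()` performs nodal analysis: Dirichlet pressures at the inlet
(P₁) and exit (gauge 0, atmospheric), interior pressures from flow
conservation, branch flows from Ohm's analogy. The solver is validated
against an independently formulated dense solve (pressures *and* flows as
unknowns) to 1e-9.

`optimize_exit_widths()` equalizes the per-well flows of the four-well
repeating unit (wells drain through exit branches R_A..R_D into consecutive
junctions of a shared main line, sections R_23..R_50). It runs bounded
coordinate descent — one monotone 1-D root solve per adjustable width per
pass — until the relative spread (max − min)/mean of the well flows is below
the tolerance (default 1%, "similar flows" made concrete). Wells farther
from the exit port end up with wider exit channels. If the bounds make the
tolerance infeasible, the best-achieved spread is reported rather than
silently accepted. The shipped `chip_exit_network()` uses representative
dimensions (the fabricated dimensions are not part of the package's scope);
the solver and optimizer are dimension-agnostic.

## Synthetic renderer

The renderer produces the ground truth the pipeline is validated against. It
emulates what the assay images look like, not the underlying optics:

* Worms are straight bands along their channel (the traps keep animals
  straight), with a super-Gaussian lateral profile (half intensity at the
  nominal body edge, default width 45 µm) and raised-cosine 10 µm end
  tapers. Body-to-background contrast defaults to 10:1 over a 100-count
  background; worm-to-worm brightness varies by ±5%.
* Aggregates are compact discs of their stated diameter with a 0.5 px
  logistic edge, at 3× the body signal above background. A soft disc (rather
  than a broad Gaussian) makes the *planted diameter* the quantity the
  segmentation measures: the footprint above any reasonable threshold is the
  disc plus a ~1–2 px halo, nearly independent of where the calibrated
  threshold lands. Puncta are planted with a minimum centre separation of
  10 µm — the assay counts resolvable aggregates, and closer pairs would be
  merged by any single-plane segmentation.
* Per-worm aggregate counts are `round(density × length)` with the per-worm
  density drawn around the population value (default 0.032 µm⁻¹, SD 0.002 —
  the day-3 Q35 operating point; diffuse worms carry none), so the
  population median converges to the specified density.
* Each worm has a true focal plane drawn from the middle third of the
  stack; planes away from it are blurred with σ = 0.4 µm per µm of z offset
  (a linear defocus proxy, not a physical PSF). Gaussian read noise
  (SD 50 counts) is added everywhere; Poisson shot noise is optional and
  off by default.
* Rendering is deterministic given the seed; `generate_plate()` writes
  16-bit TIFFs named `{well}_f{fov}_z{zz}.tif`, a YAML truth sidecar per
  well, and the loading map.

What the renderer does *not* emulate: body curvature and pose, internal
anatomy (gut autofluorescence, embryos), optical vignetting, z-dependent
aberrations, or trapping dynamics. Tests passing on synthetic data therefore
demonstrate the *algorithmic* correctness and calibration behaviour of the
pipeline, not its robustness to every real-world artefact.

## Scoring pipeline

Per well: (1) the four FOV stacks are summed over z and concatenated along
the channel axis; (2) the summed image is projected across the channels,
smoothed, and a channel is called occupied when the profile at its
pitch-grid position exceeds the median of the *between-channel* rows by 6
MADs — the between-channel reference stays valid even when every trap is
filled, where a whole-profile reference breaks down; (3) each occupied
channel is cropped one pitch wide through all planes; (4) the best focal
plane maximizes the variance of the LoG-filtered (σ = 7 px) crop, ties going
to the lowest plane; (5) body length is the largest contiguous run of the
along-channel projection above 2× background, the background being the
median of the crop's outer (between-channel) rows; runs touching the crop
ends are flagged `edge_truncated`, empty crops `empty`.

The aggregate threshold is calibrated per chip: the 97th percentile (1 − 3%)
of the pooled worm-body pixels of all vehicle-treated punctate wells. "Worm
pixels" are pixels inside the measured span that pass the 2×-background body
rule — not the whole frame, which is dominated by empty background and would
make the percentile meaningless. Segmentation multiplies two binary masks:
intensity above the threshold, and positive bright-blob LoG response (the
minimal, parameter-free reading of "regions of higher gradient"); connected
components use 8-connectivity (implemented as 4-connected labelling plus a
union-find merge of diagonal contacts, since `EBImage::bwlabel` is
4-connected).

The particle filter keeps components with area in `particle_area_bounds`
(default 2–96 px² at 10×: the 1–5 µm diameter range plus the segmentation
halo), centroid inside the worm span, and peak intensity at least
`particle_peak_ratio` (default 1.5) × threshold. The peak criterion is our
resolution of an ambiguity in what "a particle filter" bounds: the 3% rule
by construction leaves ~3% of vehicle worm-body pixels above threshold even
when aggregates cover less than that, and those threshold-grazing noise
pixels form small clusters; genuine puncta rise several-fold above the
threshold, so a scale-free peak ratio separates the two without touching the
calibrated threshold itself. All criteria are ratios or areas, so scores are
invariant under a global intensity rescaling applied jointly to images and
threshold — a property the tests assert.

Aggregates are counted on the single best-focus plane only (no 3-D merging),
and an animal's score is count / length (µm⁻¹); wells are summarized by the
median and SD over valid animals. The 4× mode runs the same pipeline with
σ = 7/2.5 = 2.8 px, area bounds rescaled by the (2.5)² pixel-area factor,
and an optional trap-region crop; on paired renders it detects no more
median aggregates than the 10× mode, mirroring the resolution loss.

## Screening statistics

The screening window is Z′ = 1 − 3(σ_p + σ_n)/|µ_p − µ_n|. Because the
assay reports populations as median ± SD, `population_stats()` uses the
median as centre by default (the classic definition uses means; switch with
`center = "mean"`). `multiwell_z_prime()` evaluates the window after
averaging control wells in consecutive groups of k (k = 1 reduces to the
per-well case); averaging shrinks the spread, so the window typically widens
with k.

Chips are normalized individually: one factor brings the chip's pooled
vehicle-control median to the reference 0.0318 µm⁻¹, and every density on
the chip is multiplied by it (idempotent by construction). Candidate wells
fall strictly below the vehicle median − 3×SD, both statistics across the
vehicle wells' medians — the plate-level band. Confirmation requires a
two-tailed Welch test against the pooled vehicle animals at p < 0.005
*and* a reduced median *and* a reduced SD (a real suppressor shifts and
tightens the distribution); 0.005 ≤ p < 0.05 is tiered "moderate", and
candidates with fewer than 15 animals are flagged underpowered rather than
confirmed. Decision boundaries are strict inequalities throughout. No
multiple-testing correction is applied, matching the assay's practice; the
null-plate simulations in the tests check the resulting false-confirmation
rate stays at the nominal level.

## Numerical choices and degenerate inputs

Ties in focus variance go to the lowest plane; empty channels yield flagged,
unscored records that never enter well statistics; a zero vehicle median
makes normalization fail loudly (the assay is invalid, not zero); equal
control centres make Z′ undefined and error; collinear markers, disconnected
networks, non-positive resistances and sub-minimal bending samples all
raise immediately. Dead wells (all images missing) are skipped and logged,
never imputed.

## Validation problem sizes

The test suite validates the full pipeline on a scaled-down rendered plate:
12 wells (6 punctate at the 0.032 µm⁻¹ operating point, 6 diffuse), 10
traps per well over 2 FOVs, 9 z-planes at 5 µm, at the full 0.74 µm/px
resolution (1014 × 2048 px per FOV) — small enough to render and score
quickly, while preserving the per-pixel scales (LoG σ, particle areas,
pitch) the pipeline's parameters are expressed in. The paired 10×/4×
comparison uses a single five-channel FOV. These sizes are the package's
validation choice; every operation accepts the full-scale layout.

## Known limitations

* The renderer's intensity scales are placeholders (real Q::YFP intensity
  statistics are not published); all contrasts are configurable.
* Aggregates are counted in 2-D on one plane; axially separated aggregates
  that overlap in (x, y) merge.
* The hydraulic model is steady-state and single-phase: no compliance,
  no worm-occluded channels.
* The bending field is interpolation, not plate mechanics; extrapolation
  beyond the sampled footprint is clamped, not modelled.
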