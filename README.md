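# wormhts

High-throughput, on-chip phenotyping of *C. elegans* protein-aggregation
models in R.

Polyglutamine (polyQ) expansion diseases such as Huntington's are modelled in
*C. elegans* by strains expressing Q::YFP fusions in body-wall muscle: short
tracts (Q24) stay diffuse, while longer tracts (Q35) condense into discrete
fluorescent aggregates by day-3 adulthood. Screening compound libraries
against this phenotype requires imaging thousands of animals per run, which a
96-well microfluidic chip makes possible: each well funnels its population
into 40 parallel tapered trapping channels at 150 µm pitch, imaged as 4
fields of view of 10 channels with a 15-plane fluorescence z-stack (5 µm
steps) per field — 5,760 images per chip.

`wormhts` implements the complete computational stack around that assay:

- **Chip model & calibration** — acquisition-event planning
  (well × FOV × z), and the stage-calibration geometry correcting nominal
  coordinates for chip rotation θ_XY, tilt slopes δ_XZ/δ_YZ, and the
  pressure-induced bending Δ(x, y) of the glass substrate (up to ~70 µm
  across the chip), fit from four corner markers.
- **Hydraulic network** — an equivalent-circuit solver
  (R = 12µL / (wh³(1 − 0.63 h/w)) per rectangular segment, nodal analysis
  under a common gasket pressure P₁ with the exit at atmospheric P₀) and an
  optimizer that equalizes well loading flows by adjusting exit-channel
  widths.
- **Synthetic renderer** — ground-truth-bearing 16-bit TIFF z-stacks of
  immobilized worms: diffuse (Q24-like) or punctate (Q35-like) animals with
  1–5 µm aggregates planted at a controlled per-length density, with
  z-defocus blur and camera noise. Every dataset carries a truth sidecar, so
  the pipeline can be validated against known answers.
- **Scoring pipeline** — merge/sum of a well's stacks, occupied-channel
  detection from the cross-channel intensity profile, best-focus selection by
  maximal variance of the Laplacian-of-Gaussian (σ = 7 px) response, worm
  length from the 2×-background projection rule, an intensity threshold
  calibrated so 3% of vehicle-control worm pixels exceed it, and aggregate
  segmentation as the product of the intensity and LoG blob masks followed by
  a particle filter. Each animal is scored as aggregates per µm of body
  length. A 4× mode (σ = 7/2.5) mirrors low-resolution acquisition.
- **Screening statistics** — the screening-window coefficient
  Z′ = 1 − 3(σ_p + σ_n)/|µ_p − µ_n| (with 1/2/3-well averaging), per-chip
  normalization to the reference vehicle median 0.0318 µm⁻¹, candidate
  calling below the vehicle median − 3×SD band, and hit confirmation by
  two-tailed Welch *t*-test (p < 0.005, with reduced median and SD).

## Worked example

Render a small two-well plate (one punctate vehicle well, one diffuse well),
score it, and compute the screening window:

```r
library(wormhts)

layout <- chip_layout(n_rows = 1, n_cols = 2, traps_per_well = 10,
                      fovs_per_well = 2, channels_per_fov = 5, z_planes = 9)
optics <- optics_config("10x", image_size = c(1014, 2048))
map <- data.frame(well = c("A01", "A02"),
                  compound_id = c("VEHICLE_POLYQ35", "VEHICLE_POLYQ24"),
                  role = c("vehicle_polyq35", "vehicle_polyq24"),
                  phenotype = c("punctate", "diffuse"),
                  effect = 1, occupancy = 0.8)

dir <- tempfile("plate")
generate_plate(dir, map, layout, optics, seed = 7)
scores <- score_dataset(dir)
scores$wells[, c("well", "role", "n", "median_density", "sd_density")]
#>   well            role  n median_density  sd_density
#> 1  A01 vehicle_polyq35  8     0.03248563 0.002299676
#> 2  A02 vehicle_polyq24 10     0.00000000 0.000000000

z_prime(population_stats(scores$animals$density_per_um[
          scores$animals$well == "A01" & scores$animals$valid]),
        population_stats(scores$animals$density_per_um[
          scores$animals$well == "A02" & scores$animals$valid]))
#> [1] 0.7876
```

The punctate well is planted at the day-3 Q35 phenotype, 0.032 aggregates
per µm of body length (worm-to-worm SD 0.002); the pipeline recovers a well
median of 0.0325 µm⁻¹ with SD 0.0023, the diffuse well scores exactly zero,
and the resulting per-animal screening window Z′ ≈ 0.79 — an excellent assay
window (Z′ > 0.5).

A shell entry point wraps the same functions
(`inst/scripts/wormhts generate|score|screen|plan|flow`).

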