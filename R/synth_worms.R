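#' Optical configuration of the synthetic renderer
#'
#' Camera and objective parameters for rendering synthetic fluorescence
#' z-stacks. The default emulates the screening configuration: a 2048 x 2048
#' 16-bit CCD behind a 10x objective (0.74 um/pixel, so one FOV spans
#' ~1.5 x 1.5 mm and covers 10 trapping channels at 150 um pitch). The `"4x"`
#' preset models the low-resolution alternative (1.85 um/pixel).
#'
#' Out-of-focus planes are blurred with a Gaussian whose sigma grows linearly
#' with the axial offset from the worm's true focal plane
#' (`defocus_slope` um of sigma per um of offset). Camera noise is Gaussian
#' read noise plus optional Poisson shot noise.
#'
#' @param magnification `"10x"` or `"4x"`; sets `pixel_size` unless given.
#' @param image_size Image dimensions `c(rows, cols)` in pixels; rows run
#'   across channels, columns along the channel length. Smaller sizes render
#'   proportionally smaller FOVs (fewer channels / shorter channel view).
#' @param pixel_size um per pixel.
#' @param bit_depth Camera bit depth (16).
#' @param defocus_slope Blur sigma (um) added per um of z-offset from focus.
#' @param read_noise Gaussian read-noise SD (counts).
#' @param shot_noise Add Poisson shot noise on top of read noise?
#' @param background Mean background level (counts).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(magnification = c("10x", "4x"),
                          image_size = NULL, pixel_size = NULL,
                          bit_depth = 16L, defocus_slope = 0.4,
                          read_noise = 50, shot_noise = FALSE,
                          background = 100) {
  magnification <- match.arg(magnification)
  if (is.null(pixel_size))
    pixel_size <- switch(magnification, "10x" = 0.74, "4x" = 1.85)
  if (is.null(image_size))
    image_size <- switch(magnification, "10x" = c(2048L, 2048L),
                         "4x" = c(820L, 820L))
  stopifnot(pixel_size > 0, all(image_size >= 16), defocus_slope >= 0,
            read_noise >= 0, background >= 0)
  structure(list(magnification = magnification,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, bit_depth = as.integer(bit_depth),
                 defocus_slope = defocus_slope, read_noise = read_noise,
                 shot_noise = isTRUE(shot_noise), background = background),
            class = "optics_config")
}

#' Population specification for synthetic worms
#'
#' Describes one well's worm population for the synthetic renderer. The two
#' phenotypes mirror the polyQ reporter strains: `"diffuse"` worms (Q24-like)
#' show uniform body-wall fluorescence and carry no aggregates; `"punctate"`
#' worms (Q35-like) additionally carry discrete fluorescent puncta of 1-5 um
#' diameter at a controllable per-length density. The default punctate
#' density, 0.032 aggregates per um of body length with a population SD of
#' 0.002, matches the day-3 adult Q35 phenotype the assay is calibrated on.
#'
#' @param phenotype `"punctate"` or `"diffuse"`.
#' @param density Mean aggregate density (per um of body length).
#' @param density_sd Worm-to-worm SD of the per-worm density.
#' @param effect Multiplicative treatment effect on density (1 = untreated;
#'   e.g. 0.5 emulates a compound halving the aggregate load).
#' @param occupancy Probability that a trap holds a worm.
#' @param length_range Body length range (um), sampled uniformly.
#' @param body_width Rendered body width (um).
#' @param body_contrast Body-to-background intensity ratio.
#' @param aggregate_contrast Punctum amplitude as a multiple of the body
#'   signal above background.
#' @param diameter_range Aggregate diameter range (um), sampled uniformly.
#' @param min_separation Minimum centre-to-centre distance between puncta
#'   (um); the assay counts resolvable aggregates, so planted puncta are kept
#'   at least this far apart.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(phenotype = c("punctate", "diffuse"),
                            density = 0.032, density_sd = 0.002,
                            effect = 1, occupancy = 0.95,
                            length_range = c(900, 1100), body_width = 45,
                            body_contrast = 10, aggregate_contrast = 3,
                            diameter_range = c(1, 5), min_separation = 10) {
  phenotype <- match.arg(phenotype)
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  stopifnot(density_sd >= 0, effect >= 0, occupancy >= 0, occupancy <= 1,
            length_range[1] > 0, diff(length_range) >= 0,
            body_width > 0, body_contrast > 1, aggregate_contrast > 0,
            diameter_range[1] >= 1, diameter_range[2] <= 5)
  structure(list(phenotype = phenotype, density = density,
                 density_sd = density_sd, effect = effect,
                 occupancy = occupancy, length_range = length_range,
                 body_width = body_width, body_contrast = body_contrast,
                 aggregate_contrast = aggregate_contrast,
                 diameter_range = diameter_range,
                 min_separation = min_separation),
            class = "population_spec")
}

#' Sample one worm's ground truth from a population specification
#'
#' Draws a single immobilized worm: its body span along the channel, its
#' per-worm aggregate density (normal around the population density,
#' truncated at zero), and the resulting aggregate list with positions,
#' diameters and amplitudes. The aggregate count is `round(density * length)`
#' so the population median density converges to the specified density.
#' Diffuse worms always carry zero aggregates.
#'
#' Uses R's global random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param spec A [population_spec].
#' @param channel_index 0-based index of the trap channel holding the worm.
#' @param z_planes Number of z-planes in the stack (the true focal plane is
#'   drawn from the middle third of the stack).
#' @param fov_length_um Usable channel length inside the FOV (um); the worm
#'   is placed to fit inside it.
#' @param deterministic If `TRUE`, suppress all sampling noise: length is
#'   the mid-range value (or `length_um`), the density is exactly
#'   `density * effect`, and the focal plane is the stack centre.
#' @param length_um Optional forced body length (um).
#' @return A list of class `worm_truth` with fields `channel_index`,
#'   `span` (start/end, um), `length`, `body_width`, `intensity_factor`,
#'   `aggregates` (data.frame: `position`, `offset`, `diameter`,
#'   `amplitude`), `focus_plane` (0-based), `phenotype`.
#' @export
sample_worm <- function(spec, channel_index = 0L, z_planes = 15L,
                        fov_length_um = 1500, deterministic = FALSE,
                        length_um = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  len <- if (!is.null(length_um)) length_um
    else if (deterministic) mean(spec$length_range)
    else stats::runif(1, spec$length_range[1], spec$length_range[2])
  margin <- 30
  max_start <- max(margin, fov_length_um - len - margin)
  start <- if (deterministic) margin
    else stats::runif(1, margin, max_start)
  dens <- spec$density * spec$effect
  if (!deterministic && spec$density_sd > 0)
    dens <- max(0, stats::rnorm(1, dens, spec$density_sd))
  n_agg <- if (spec$phenotype == "diffuse") 0L else as.integer(round(dens * len))

  aggregates <- data.frame(position = numeric(0), offset = numeric(0),
                           diameter = numeric(0), amplitude = numeric(0))
  if (n_agg > 0) {
    pos <- draw_separated(n_agg, start + 10, start + len - 10,
                          spec$min_separation)
    n_agg <- length(pos)  # may fall short if the body cannot hold them all
    aggregates <- data.frame(
      position = pos,
      offset = stats::runif(n_agg, -spec$body_width / 3, spec$body_width / 3),
      diameter = stats::runif(n_agg, spec$diameter_range[1],
                              spec$diameter_range[2]),
      amplitude = spec$aggregate_contrast *
        stats::runif(n_agg, 0.9, 1.1))
  }
  mid <- (z_planes - 1) / 2
  focus <- if (deterministic || z_planes <= 2) as.integer(floor(mid))
    else sample(seq.int(floor(mid - z_planes / 6), ceiling(mid + z_planes / 6)), 1)
  focus <- max(0L, min(z_planes - 1L, as.integer(focus)))
  structure(list(channel_index = as.integer(channel_index),
                 span = c(start = start, end = start + len), length = len,
                 body_width = spec$body_width,
                 intensity_factor = if (deterministic) 1
                   else stats::runif(1, 0.95, 1.05),
                 body_contrast = spec$body_contrast,
                 aggregates = aggregates, focus_plane = focus,
                 phenotype = spec$phenotype),
            class = "worm_truth")
}

# Rejection-sample n points in [lo, hi] with pairwise distance >= sep.
draw_separated <- function(n, lo, hi, sep, max_tries = 200L) {
  pts <- numeric(0)
  tries <- 0L
  while (length(pts) < n && tries < max_tries * n) {
    tries <- tries + 1L
    p <- stats::runif(1, lo, hi)
    if (!length(pts) || min(abs(pts - p)) >= sep) pts <- c(pts, p)
  }
  sort(pts)
}
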