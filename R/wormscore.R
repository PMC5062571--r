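#' Configuration of the aggregate-scoring image pipeline
#'
#' Parameters of the automated image analysis that converts a well's z-stacks
#' into per-animal aggregate scores. Defaults are the high-resolution (10x)
#' operating point: Laplacian-of-Gaussian sigma of 7 pixels for both the
#' focus measure and the blob/gradient mask, a worm-body rule of intensity
#' above 2 x the local background, an intensity threshold calibrated so that
#' 3% of the bright (worm-body) pixels of the vehicle-treated punctate
#' controls exceed it, and a particle filter keeping connected components
#' (8-connectivity) whose area is compatible with aggregates of 1-5 um
#' diameter. `low_res_config()` is the 4x operating point with the LoG
#' rescaled by the 2.5x de-magnification (sigma = 7/2.5 = 2.8) and area
#' bounds rescaled accordingly.
#'
#' @param pixel_size um per pixel (0.74 at 10x).
#' @param log_sigma LoG sigma in pixels.
#' @param background_factor Worm-body rule: body pixels exceed
#'   `background_factor * background`.
#' @param bright_pixel_fraction Fraction of worm-body pixels of the vehicle
#'   controls left above the calibrated intensity threshold.
#' @param particle_area_bounds Inclusive `c(min, max)` particle area (pixel^2)
#'   kept by the particle filter.
#' @param particle_peak_ratio Particle filter's intensity criterion: a kept
#'   particle's peak intensity must reach at least this multiple of the
#'   calibrated threshold. Aggregates rise several-fold above the body
#'   signal while threshold-grazing noise clusters do not, so this
#'   separates the two regardless of the global intensity scale.
#' @param occupancy_k Channel-occupancy rule: a channel is occupied when the
#'   smoothed cross-channel profile at its position exceeds the profile
#'   median by `occupancy_k` MADs.
#' @param channel_pitch Channel pitch (um), used to place the profile grid.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.74, log_sigma = 7,
                            background_factor = 2,
                            bright_pixel_fraction = 0.03,
                            particle_area_bounds = c(2, 96),
                            particle_peak_ratio = 1.5,
                            occupancy_k = 6, channel_pitch = 150) {
  stopifnot(pixel_size > 0, log_sigma > 0,
            bright_pixel_fraction > 0, bright_pixel_fraction < 1,
            particle_area_bounds[1] > 0,
            particle_area_bounds[1] <= particle_area_bounds[2],
            particle_peak_ratio >= 1, occupancy_k > 0, channel_pitch > 0)
  structure(list(pixel_size = pixel_size, log_sigma = log_sigma,
                 background_factor = background_factor,
                 bright_pixel_fraction = bright_pixel_fraction,
                 particle_area_bounds = particle_area_bounds,
                 particle_peak_ratio = particle_peak_ratio,
                 occupancy_k = occupancy_k, channel_pitch = channel_pitch),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
low_res_config <- function(pixel_size = 1.85, log_sigma = 7 / 2.5,
                           particle_area_bounds = c(1, 16), ...) {
  pipeline_config(pixel_size = pixel_size, log_sigma = log_sigma,
                  particle_area_bounds = particle_area_bounds, ...)
}

# Laplacian-of-Gaussian kernel with blob polarity: the response of a bright
# blob is positive at its centre. Zero-sum, so flat regions respond 0.
log_kernel <- function(sigma) {
  half <- ceiling(3.5 * sigma)
  x <- seq(-half, half)
  g <- outer(x^2, x^2, "+")
  k <- -(g - 2 * sigma^2) / sigma^4 * exp(-g / (2 * sigma^2))
  k - mean(k)
}

# LoG response of a 2-D image, replicate boundary.
log_response <- function(img, sigma) {
  EBImage::filter2(img, log_kernel(sigma), boundary = "replicate")
}

#' Load the four FOV z-stacks of a well from a dataset directory
#'
#' Reads the TIFF planes named `{well}_f{fov}_z{zz}.tif`, returning
#' intensities in camera counts. A completely missing FOV yields `NULL` in
#' its slot (see [load_and_merge()] for how that is handled); a partially
#' missing stack is an error.
#'
#' @param dir Dataset directory.
#' @param well Well label.
#' @param layout A [chip_layout].
#' @param bit_depth Camera bit depth used when the TIFFs were written.
#' @return List of `fovs_per_well` arrays `[rows, cols, z]`, or `NULL` slots.
#' @export
load_well_stacks <- function(dir, well, layout = chip_layout(),
                             bit_depth = 16L) {
  max_val <- 2^bit_depth - 1
  lapply(seq_len(layout$fovs_per_well) - 1L, function(f) {
    paths <- file.path(dir, sprintf("%s_f%d_z%02d.tif", well, f,
                                    seq_len(layout$z_planes) - 1L))
    ok <- file.exists(paths)
    if (!any(ok)) return(NULL)
    if (!all(ok))
      stop("incomplete z-stack for ", well, " FOV ", f, call. = FALSE)
    planes <- lapply(paths, function(p) tiff::readTIFF(p) * max_val)
    array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  })
}

#' Merge a well's FOV stacks into one summed image
#'
#' Sums each FOV stack over z (increasing the contrast between animals and
#' background) and concatenates the per-FOV sums along the channel-index
#' axis (rows), producing one 2-D image whose rows span all of the well's
#' trapping channels. A missing (`NULL`) FOV is replaced by zeros and
#' recorded in the `"missing_fovs"` attribute.
#'
#' @param stacks List of FOV arrays `[rows, cols, z]` of identical shape
#'   (from [load_well_stacks()] or [render_fov_stack()]).
#' @return The merged matrix with attribute `"fov_rows"` (rows per FOV) and
#'   `"missing_fovs"` (0-based indices, possibly empty).
#' @export
load_and_merge <- function(stacks) {
  dims <- lapply(stacks, dim)
  have <- !vapply(stacks, is.null, logical(1))
  if (!any(have)) stop("all FOV stacks are missing", call. = FALSE)
  ref <- dims[have][[1]]
  if (!all(vapply(dims[have], function(d) all(d == ref), logical(1))))
    stop("FOV stacks have mismatched shapes", call. = FALSE)
  sums <- lapply(stacks, function(s) {
    if (is.null(s)) matrix(0, ref[1], ref[2]) else rowSums(s, dims = 2)
  })
  merged <- do.call(rbind, sums)
  attr(merged, "fov_rows") <- ref[1]
  attr(merged, "missing_fovs") <- which(!have) - 1L
  merged
}

#' Detect which trapping channels hold an animal
#'
#' Projects the merged well image onto the axis perpendicular to the worms
#' (row means), smooths the profile, and declares a channel occupied when
#' the profile at its expected position on the channel-pitch grid exceeds
#' the profile median by `occupancy_k` MADs.
#'
#' @param merged Merged image from [load_and_merge()].
#' @param layout A [chip_layout].
#' @param config A [pipeline_config].
#' @return Sorted 0-based indices of occupied channels (possibly empty).
#' @export
detect_occupied_channels <- function(merged, layout, config) {
  pitch_px <- config$channel_pitch / config$pixel_size
  fov_rows <- attr(merged, "fov_rows")
  if (is.null(fov_rows)) fov_rows <- nrow(merged)
  n_fov <- nrow(merged) / fov_rows
  cpf <- layout$channels_per_fov
  profile <- rowMeans(merged)
  w <- max(3L, 2L * floor(pitch_px / 8) + 1L)
  sm <- stats::filter(profile, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- profile[is.na(sm)]
  centers <- unlist(lapply(seq_len(n_fov) - 1L, function(f)
    f * fov_rows + round((seq_len(cpf) - 0.5) * pitch_px)))
  centers <- pmin(pmax(centers, 1L), nrow(merged))
  # background reference: rows near the channel *boundaries* of the pitch
  # grid, which stay worm-free even when every channel is occupied
  half <- floor(pitch_px / 8)
  bg_rows <- unlist(lapply(seq_len(n_fov) - 1L, function(f) {
    bnd <- round((seq_len(cpf + 1L) - 1L) * pitch_px)
    f * fov_rows + unlist(lapply(bnd, function(b) (b - half):(b + half)))
  }))
  bg <- sm[bg_rows[bg_rows >= 1 & bg_rows <= nrow(merged)]]
  cut <- stats::median(bg) + config$occupancy_k * stats::mad(bg)
  which(sm[centers] > cut) - 1L
}

#' Crop one trapping channel through all z-planes
#'
#' Extracts the one-channel-pitch-wide strip of the channel's FOV stack,
#' through every z-plane, together with its coordinates.
#'
#' @param stacks List of FOV stacks (well order).
#' @param channel_index 0-based global channel index within the well.
#' @param layout A [chip_layout].
#' @param config A [pipeline_config].
#' @return List of class `channel_crop`: `crop` (array `[rows, cols, z]`),
#'   `channel_index`, `fov`, `rows` (bounds in the FOV frame).
#' @export
crop_channel <- function(stacks, channel_index, layout, config) {
  cpf <- layout$channels_per_fov
  n_chan <- layout$fovs_per_well * cpf
  if (channel_index < 0L || channel_index >= n_chan)
    stop("channel index must be in 0..", n_chan - 1L, call. = FALSE)
  fov <- channel_index %/% cpf
  within <- channel_index %% cpf
  st <- stacks[[fov + 1L]]
  if (is.null(st)) stop("FOV ", fov, " is missing", call. = FALSE)
  pitch_px <- config$channel_pitch / config$pixel_size
  r0 <- max(1L, round(within * pitch_px) + 1L)
  r1 <- min(nrow(st), round((within + 1) * pitch_px))
  structure(list(crop = st[r0:r1, , , drop = FALSE],
                 channel_index = as.integer(channel_index),
                 fov = as.integer(fov), rows = c(r0, r1)),
            class = "channel_crop")
}

#' Select the best-focus plane of a channel crop
#'
#' The best focal plane is the z-plane whose Laplacian-of-Gaussian-filtered
#' image has maximal variance; ties break toward the lowest plane index.
#'
#' @param crop A `channel_crop` or a plain array `[rows, cols, z]`.
#' @param config A [pipeline_config].
#' @return 0-based index of the best-focus plane.
#' @export
select_best_focus <- function(crop, config) {
  arr <- if (inherits(crop, "channel_crop")) crop$crop else crop
  nz <- dim(arr)[3]
  v <- vapply(seq_len(nz), function(z)
    stats::var(as.vector(log_response(arr[, , z], config$log_sigma))),
    numeric(1))
  which.max(v) - 1L
}

# Background estimate of a channel crop: median intensity of the
# between-channel rows (outer quarter of rows on each side of the strip).
estimate_background <- function(plane) {
  q <- max(1L, floor(nrow(plane) / 4))
  stats::median(plane[c(seq_len(q), nrow(plane) - seq_len(q) + 1L), ])
}

#' Measure the worm's body length on the best-focus plane
#'
#' Projects the crop onto the axis parallel to the channel (column means)
#' and finds the largest contiguous run of positions whose profile exceeds
#' `background_factor` x the background estimate. The run's extent is the
#' body length.
#'
#' @param plane Best-focus 2-D plane of a channel crop.
#' @param background Background estimate (counts); default from the crop's
#'   between-channel rows.
#' @param config A [pipeline_config].
#' @return List: `length_um`, `span` (first/last column of the run, pixels;
#'   `NA` when empty), `flags` (character vector, possibly empty: `"empty"`,
#'   `"edge_truncated"`).
#' @export
measure_worm_length <- function(plane, config,
                                background = estimate_background(plane)) {
  profile <- colMeans(plane)
  mask <- profile > config$background_factor * background
  r <- rle(mask)
  flags <- character(0)
  if (!any(mask))
    return(list(length_um = 0, span = c(NA_integer_, NA_integer_),
                flags = "empty"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  span <- c(starts[best], ends[best])
  if (span[1] == 1L || span[2] == length(profile))
    flags <- c(flags, "edge_truncated")
  list(length_um = diff(span) * config$pixel_size + config$pixel_size,
       span = span, flags = flags)
}

# Worm-body pixels of a plane: within the measured span and above the body
# rule. These form the pool from which the intensity threshold is
# calibrated.
collect_worm_pixels <- function(plane, span, config,
                                background = estimate_background(plane)) {
  if (anyNA(span)) return(numeric(0))
  vals <- plane[, span[1]:span[2]]
  vals[vals > config$background_factor * background]
}

#' Calibrate the aggregate intensity threshold from vehicle controls
#'
#' The intensity threshold is set on the vehicle-treated punctate controls
#' so that a fixed small fraction (default 3%) of their worm-body pixels
#' lies above it; it is then applied unchanged to every well of the chip.
#' Pooling across all vehicle wells of a chip absorbs day-to-day intensity
#' variation chip by chip.
#'
#' @param pixel_pools List (or vector) of worm-body pixel intensities from
#'   the vehicle-control wells.
#' @param config A [pipeline_config].
#' @param source_wells Optional well labels recorded for provenance.
#' @return List of class `threshold_model`: `threshold` (counts),
#'   `n_pixels`, `bright_pixel_fraction`, `source_wells`.
#' @export
compute_intensity_threshold <- function(pixel_pools, config = pipeline_config(),
                                        source_wells = NULL) {
  pool <- unlist(pixel_pools, use.names = FALSE)
  if (!length(pool))
    stop("no vehicle-control worm pixels: cannot calibrate the threshold",
         call. = FALSE)
  thr <- stats::quantile(pool, 1 - config$bright_pixel_fraction, names = FALSE)
  structure(list(threshold = thr, n_pixels = length(pool),
                 bright_pixel_fraction = config$bright_pixel_fraction,
                 source_wells = source_wells),
            class = "threshold_model")
}

# 8-connected labelling of a binary mask: 4-connected labelling (EBImage)
# followed by union of labels that touch diagonally.
label_mask_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(lab)
  pairs <- rbind(diag_pairs(lab, 1L, 1L), diag_pairs(lab, 1L, -1L))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      while (parent[a] != a) a <- parent[a]
      while (parent[b] != b) b <- parent[b]
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), function(i) {
      while (parent[i] != i) i <- parent[i]; i
    }, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

# Label pairs that touch along a diagonal offset (dr, dc).
diag_pairs <- function(lab, dr, dc) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- seq_len(nr - dr)
  c1 <- if (dc > 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dr, c1 + dc, drop = FALSE]
  sel <- a > 0 & b > 0 & a != b
  if (!any(sel)) return(matrix(integer(0), 0, 2))
  unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
}

#' Segment aggregate particles on a best-focus plane
#'
#' Implements the two-mask rule: an intensity mask (pixels above the
#' vehicle-calibrated threshold) is multiplied with a gradient/blob mask
#' (positive bright-blob Laplacian-of-Gaussian response), so only regions of
#' both high intensity and high curvature survive. Connected components
#' (8-connectivity) are then passed through the particle filter: area within
#' `particle_area_bounds` and centroid within the worm's measured span.
#'
#' @param plane Best-focus 2-D plane of a channel crop (counts).
#' @param span Worm span (columns) from [measure_worm_length()].
#' @param threshold_model A `threshold_model` from
#'   [compute_intensity_threshold()].
#' @param config A [pipeline_config].
#' @return Data frame of particles: `row`, `col` (centroid, pixels),
#'   `area_px`, `area_um2`, `equiv_diameter_um`, `mean_intensity`.
#' @export
segment_aggregates <- function(plane, span, threshold_model, config) {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      equiv_diameter_um = numeric(0),
                      mean_intensity = numeric(0),
                      peak_intensity = numeric(0))
  if (anyNA(span)) return(empty)
  mask_a <- plane > threshold_model$threshold
  mask_b <- log_response(plane, config$log_sigma) > 0
  mask <- mask_a & mask_b
  if (!any(mask)) return(empty)
  lab <- label_mask_8(mask)
  ids <- sort(unique(lab[lab > 0]))
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  vals <- plane[lab > 0]
  out <- do.call(rbind, lapply(ids, function(i) {
    sel <- labs == i
    data.frame(row = mean(idx[sel, 1]), col = mean(idx[sel, 2]),
               area_px = sum(sel), mean_intensity = mean(vals[sel]),
               peak_intensity = max(vals[sel]))
  }))
  out$area_um2 <- out$area_px * config$pixel_size^2
  out$equiv_diameter_um <- 2 * sqrt(out$area_um2 / pi)
  b <- config$particle_area_bounds
  keep <- out$area_px >= b[1] & out$area_px <= b[2] &
    out$peak_intensity >= config$particle_peak_ratio *
      threshold_model$threshold &
    out$col >= span[1] & out$col <= span[2]
  out <- out[keep, c("row", "col", "area_px", "area_um2",
                     "equiv_diameter_um", "mean_intensity",
                     "peak_intensity")]
  rownames(out) <- NULL
  out
}

#' Assemble a per-animal phenotype score
#'
#' @param well,channel_index,best_z Identity of the animal.
#' @param length_um Measured body length (um).
#' @param particles Particle table from [segment_aggregates()].
#' @param flags Character vector of quality flags (`"empty"`,
#'   `"edge_truncated"`, `"low_signal"`); a flagged empty animal carries no
#'   score and is excluded from well statistics.
#' @return One-row data.frame: `well`, `channel_index`, `best_z`,
#'   `length_um`, `aggregate_count`, `density_per_um` (aggregates per um of
#'   body length), `mean_aggregate_area_um2`, `flags` (comma-separated,
#'   `""` if none), `valid`.
#' @export
score_animal <- function(well, channel_index, best_z, length_um, particles,
                         flags = character(0)) {
  valid <- length_um > 0 && !("empty" %in% flags)
  n <- if (valid) nrow(particles) else NA_integer_
  data.frame(well = well, channel_index = as.integer(channel_index),
             best_z = as.integer(best_z), length_um = length_um,
             aggregate_count = n,
             density_per_um = if (valid) n / length_um else NA_real_,
             mean_aggregate_area_um2 =
               if (valid && n > 0) mean(particles$area_um2) else
                 if (valid) 0 else NA_real_,
             flags = paste(flags, collapse = ","),
             valid = valid, stringsAsFactors = FALSE)
}

#' Summarize a well's animal scores
#'
#' Per-well population statistics over the valid animals: the phenotype
#' score is the median aggregate density (per um), with its SD, the animal
#' count, and the SD of the aggregate-size distribution.
#'
#' @param animals Data frame of per-animal scores (rows of
#'   [score_animal()]).
#' @return One-row data.frame: `n`, `median_density`, `sd_density`,
#'   `size_sd_um2`, `flagged` (number of invalid animals).
#' @export
score_well <- function(animals) {
  ok <- animals$valid
  d <- animals$density_per_um[ok]
  data.frame(n = sum(ok),
             median_density = if (any(ok)) stats::median(d) else NA_real_,
             sd_density = if (sum(ok) > 1) stats::sd(d) else
               if (any(ok)) 0 else NA_real_,
             size_sd_um2 = if (any(ok))
               stats::sd(animals$mean_aggregate_area_um2[ok]) else NA_real_,
             flagged = sum(!ok))
}

#' Analyze one well's stacks up to (but not including) segmentation
#'
#' Runs the per-well front half of the pipeline: merge and sum the FOV
#' stacks, detect occupied channels, and for each occupied channel select
#' the best-focus plane, estimate the background, and measure the worm.
#' Segmentation needs the chip-wide vehicle-calibrated threshold and is done
#' afterwards by [score_well_stacks()].
#'
#' @param stacks List of the well's FOV stacks.
#' @param layout A [chip_layout].
#' @param config A [pipeline_config].
#' @return List of per-channel records: `channel_index`, `best_z`,
#'   `background`, `length_um`, `span`, `flags`, `best_plane` (matrix),
#'   `worm_pixels` (vector).
#' @export
analyze_well <- function(stacks, layout, config) {
  merged <- load_and_merge(stacks)
  occupied <- detect_occupied_channels(merged, layout, config)
  lapply(occupied, function(ch) {
    cr <- crop_channel(stacks, ch, layout, config)
    best_z <- select_best_focus(cr, config)
    plane <- cr$crop[, , best_z + 1L]
    bg <- estimate_background(plane)
    m <- measure_worm_length(plane, config, background = bg)
    list(channel_index = ch, best_z = best_z, background = bg,
         length_um = m$length_um, span = m$span, flags = m$flags,
         best_plane = plane,
         worm_pixels = collect_worm_pixels(plane, m$span, config,
                                           background = bg))
  })
}

#' Score one well given the chip-wide threshold
#'
#' Completes the pipeline for a well: segments aggregates on each detected
#' animal's best-focus plane with the vehicle-calibrated threshold and
#' assembles the per-animal scores.
#'
#' @param records Output of [analyze_well()] (or `stacks` to analyze here).
#' @param well Well label.
#' @param threshold_model A `threshold_model`.
#' @param config A [pipeline_config].
#' @return List: `animals` (data.frame of per-animal scores), `particles`
#'   (data.frame of kept particles with `well`, `channel_index` columns),
#'   `summary` (one-row well summary from [score_well()]).
#' @export
score_well_stacks <- function(records, well, threshold_model, config) {
  animals <- list(); particles <- list()
  for (rec in records) {
    p <- segment_aggregates(rec$best_plane, rec$span, threshold_model, config)
    animals[[length(animals) + 1L]] <-
      score_animal(well, rec$channel_index, rec$best_z, rec$length_um, p,
                   rec$flags)
    if (nrow(p)) {
      p$well <- well; p$channel_index <- rec$channel_index
      particles[[length(particles) + 1L]] <- p
    }
  }
  animals <- if (length(animals)) do.call(rbind, animals) else
    score_animal(well, 0L, 0L, 0, NULL, "empty")[0, ]
  particles <- if (length(particles)) do.call(rbind, particles) else
    data.frame()
  list(animals = animals, particles = particles,
       summary = cbind(well = well, score_well(animals)))
}

#' Score a whole plate
#'
#' Runs the full pipeline over a set of wells: a first pass analyzes the
#' vehicle-control punctate wells and calibrates the chip-wide intensity
#' threshold from their pooled worm-body pixels; a second pass scores every
#' well with that threshold.
#'
#' @param loading_map Data frame with at least `well` and `role` columns;
#'   wells with role `"vehicle_polyq35"` calibrate the threshold.
#' @param loader Function `function(well)` returning the well's list of FOV
#'   stacks (e.g. closing over a dataset directory, or over in-memory
#'   renders).
#' @param layout A [chip_layout].
#' @param config A [pipeline_config].
#' @return List of class `plate_scores`: `animals`, `wells` (per-well
#'   summaries joined to the loading map), `particles`, `threshold`.
#' @export
score_plate <- function(loading_map, loader, layout, config) {
  veh <- loading_map$well[loading_map$role == "vehicle_polyq35"]
  if (!length(veh))
    stop("no vehicle_polyq35 wells in the loading map: ",
         "the intensity threshold cannot be calibrated", call. = FALSE)
  pools <- lapply(veh, function(w) {
    recs <- analyze_well(loader(w), layout, config)
    unlist(lapply(recs, `[[`, "worm_pixels"))
  })
  thr <- compute_intensity_threshold(pools, config, source_wells = veh)

  animals <- list(); wells <- list(); particles <- list()
  for (w in loading_map$well) {
    recs <- analyze_well(loader(w), layout, config)
    sc <- score_well_stacks(recs, w, thr, config)
    animals[[w]] <- sc$animals
    wells[[w]] <- sc$summary
    if (nrow(sc$particles)) particles[[w]] <- sc$particles
  }
  animals <- do.call(rbind, animals)
  rownames(animals) <- NULL
  wells <- do.call(rbind, wells)
  rownames(wells) <- NULL
  wells <- merge(loading_map, wells, by = "well", sort = TRUE)
  structure(list(animals = animals, wells = wells,
                 particles = if (length(particles))
                   do.call(rbind, particles) else data.frame(),
                 threshold = thr),
            class = "plate_scores")
}

#' Score a well imaged in the low-resolution (4x) mode
#'
#' Same pipeline as the high-resolution mode with two changes: the merged
#' images are first cropped to the trap region (the columns actually holding
#' the traps, since the 4x FOV sees more than the trap array), and the
#' Laplacian-of-Gaussian is rescaled by the 2.5x de-magnification
#' (sigma = 7/2.5). Scores are in the same units (aggregates per um) as the
#' 10x mode.
#'
#' @param stacks The well's FOV stacks at 4x.
#' @param well Well label.
#' @param threshold_model Threshold calibrated from 4x vehicle wells.
#' @param layout A [chip_layout] describing the 4x acquisition (typically 5
#'   z-planes at 20 um).
#' @param config A [pipeline_config]; default [low_res_config()].
#' @param trap_region Optional column range (pixels) to crop to; `NULL`
#'   keeps everything.
#' @return As [score_well_stacks()].
#' @export
run_low_res_mode <- function(stacks, well, threshold_model, layout,
                             config = low_res_config(), trap_region = NULL) {
  if (!is.null(trap_region))
    stacks <- lapply(stacks, function(s)
      if (is.null(s)) NULL else
        s[, trap_region[1]:trap_region[2], , drop = FALSE])
  recs <- analyze_well(stacks, layout, config)
  score_well_stacks(recs, well, threshold_model, config)
}
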