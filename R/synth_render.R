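#' Render one field of view's synthetic fluorescence z-stack
#'
#' Renders the worms trapped in one FOV as a z-stack of 2-D intensity
#' rasters. Each worm is a soft-edged bright band along its channel (body
#' fluorescence above background), and each aggregate a compact bright
#' punctum of its stated diameter (a disc with a smooth sub-pixel edge) whose
#' peak rises above the local body signal. Planes away from the worm's true
#' focal plane are blurred with a Gaussian whose sigma grows linearly with
#' the axial offset; Gaussian read noise (and optionally Poisson shot noise)
#' is added everywhere. Channels without worms contain background only.
#'
#' Rows index the across-channel direction (channel `c` is centred at row
#' `(c + 0.5) * pitch / pixel_size`), columns the along-channel direction.
#'
#' @param worms List of `worm_truth` objects (see [sample_worm()]); their
#'   `channel_index` must lie in `0:(channels_per_fov - 1)`, at most one worm
#'   per channel.
#' @param optics An [optics_config].
#' @param layout A [chip_layout] (provides channel pitch, z-plane count and
#'   step).
#' @return A numeric array `[rows, cols, z_planes]` of intensities (counts,
#'   clipped to the camera bit depth), with the worm list attached as
#'   attribute `"truth"`.
#' @export
render_fov_stack <- function(worms, optics, layout) {
  stopifnot(inherits(optics, "optics_config"), inherits(layout, "chip_layout"))
  chans <- vapply(worms, function(w) w$channel_index, integer(1))
  if (length(chans)) {
    if (any(chans < 0L | chans >= layout$channels_per_fov))
      stop("worm channel index outside this FOV", call. = FALSE)
    if (anyDuplicated(chans))
      stop("more than one worm in a single trapping channel", call. = FALSE)
  }
  nr <- optics$image_size[1]; nc <- optics$image_size[2]
  nz <- layout$z_planes
  px <- optics$pixel_size
  pitch_px <- layout$channel_pitch / px
  stack <- array(0, dim = c(nr, nc, nz))

  sprites <- lapply(worms, worm_sprite, optics = optics, layout = layout)
  max_val <- 2^optics$bit_depth - 1

  for (z in seq_len(nz) - 1L) {
    plane <- matrix(optics$background, nr, nc)
    if (optics$read_noise > 0)
      plane <- plane + matrix(stats::rnorm(nr * nc, 0, optics$read_noise),
                              nr, nc)
    for (i in seq_along(worms)) {
      w <- worms[[i]]
      off_um <- abs(z - w$focus_plane) * layout$z_step
      sig_px <- optics$defocus_slope * off_um / px
      sp <- sprites[[i]]
      img <- if (sig_px > 0.05) EBImage::gblur(sp$img, sigma = sig_px)
        else sp$img
      # centre row of the worm's channel; sprite rows are relative offsets
      r0 <- round((w$channel_index + 0.5) * pitch_px)
      rows <- sp$row_off + r0
      cols <- sp$cols
      ok_r <- rows >= 1 & rows <= nr
      ok_c <- cols >= 1 & cols <= nc
      plane[rows[ok_r], cols[ok_c]] <-
        plane[rows[ok_r], cols[ok_c]] + img[ok_r, ok_c]
    }
    if (optics$shot_noise) {
      pos <- plane > 0
      plane[pos] <- stats::rpois(sum(pos), plane[pos])
    }
    stack[, , z + 1L] <- pmin(pmax(plane, 0), max_val)
  }
  attr(stack, "truth") <- worms
  stack
}

# In-focus additive sprite of one worm (body band + puncta) on its own
# padded canvas. Padding leaves room for the largest defocus blur kernel so
# the sprite can be blurred before being pasted into the plane.
worm_sprite <- function(w, optics, layout) {
  px <- optics$pixel_size
  wpx <- w$body_width / px
  sig_max <- optics$defocus_slope * (layout$z_planes - 1) * layout$z_step / px
  pad <- ceiling(3 * sig_max + 6 / px)
  half <- ceiling(wpx / 2) + pad
  row_off <- seq(-half, half)

  c0 <- max(1L, floor(w$span[["start"]] / px) - pad)
  c1 <- ceiling(w$span[["end"]] / px) + pad
  cols <- seq(c0, c1)
  body_add <- (w$body_contrast - 1) * optics$background * w$intensity_factor

  # lateral super-Gaussian profile: half intensity at the body edge
  lat <- exp(-log(2) * (2 * row_off / wpx)^4)
  # longitudinal raised-cosine end taper
  taper <- 10 / px
  xs <- cols * px
  lon <- pmin(1, pmax(0, (xs - w$span[["start"]]) / (taper * px)))
  lon2 <- pmin(1, pmax(0, (w$span[["end"]] - xs) / (taper * px)))
  lon <- (1 - cos(pi * pmin(lon, 1))) / 2 * (1 - cos(pi * pmin(lon2, 1))) / 2
  img <- body_add * outer(lat, lon)

  if (nrow(w$aggregates)) {
    edge <- 0.5  # px; sub-pixel logistic edge of the punctum disc
    for (k in seq_len(nrow(w$aggregates))) {
      a <- w$aggregates[k, ]
      rr <- a$offset / px
      cc <- a$position / px
      rad <- a$diameter / 2 / px
      win_r <- which(abs(row_off - rr) <= rad + 6)
      win_c <- which(abs(cols - cc) <= rad + 6)
      if (!length(win_r) || !length(win_c)) next
      d <- sqrt(outer((row_off[win_r] - rr)^2, (cols[win_c] - cc)^2, "+"))
      img[win_r, win_c] <- img[win_r, win_c] +
        a$amplitude * body_add / (1 + exp((d - rad) / edge))
    }
  }
  list(img = img, row_off = row_off, cols = cols)
}

#' Loading map of a screening chip
#'
#' Builds the per-well loading map of a synthetic screening plate: which
#' compound (or control) each well received, its control role, and the
#' population parameters the renderer should use. The default mirrors one
#' screening run: 80 compound wells, 8 wells of vehicle-treated diffuse
#' (Q24-like) animals, 6 wells of vehicle-treated punctate (Q35-like)
#' animals, and 2 positive-control wells (aggregation-suppressing
#' treatment).
#'
#' @param layout A [chip_layout].
#' @param n_compound,n_vehicle_q24,n_vehicle_q35,n_positive Well counts per
#'   arm; they must not exceed the number of wells on the chip.
#' @param compound_effects Named numeric vector of density multipliers for
#'   specific compound ids (default: all compounds inactive, effect 1).
#' @param positive_effect Density multiplier of the positive control.
#' @param occupancy Trap-filling probability for every well.
#' @return A data.frame with columns `well`, `compound_id`, `role`,
#'   `phenotype`, `effect`, `occupancy`. Roles are `"compound"`,
#'   `"vehicle_polyq24"`, `"vehicle_polyq35"`, `"positive"`.
#' @export
screening_loading_map <- function(layout = chip_layout(), n_compound = 80,
                                  n_vehicle_q24 = 8, n_vehicle_q35 = 6,
                                  n_positive = 2, compound_effects = NULL,
                                  positive_effect = 0.5, occupancy = 0.95) {
  wells <- well_labels(layout)
  n_used <- n_compound + n_vehicle_q24 + n_vehicle_q35 + n_positive
  if (n_used > length(wells))
    stop("more populated wells than wells on the chip", call. = FALSE)
  role <- c(rep("compound", n_compound),
            rep("vehicle_polyq24", n_vehicle_q24),
            rep("vehicle_polyq35", n_vehicle_q35),
            rep("positive", n_positive))
  map <- data.frame(
    well = wells[seq_len(n_used)],
    compound_id = NA_character_, role = role,
    phenotype = "punctate", effect = 1, occupancy = occupancy,
    stringsAsFactors = FALSE)
  is_cmp <- map$role == "compound"
  map$compound_id[is_cmp] <- sprintf("CMP%03d", seq_len(sum(is_cmp)))
  map$compound_id[!is_cmp] <- toupper(map$role[!is_cmp])
  map$phenotype[map$role == "vehicle_polyq24"] <- "diffuse"
  map$effect[map$role == "positive"] <- positive_effect
  if (!is.null(compound_effects)) {
    i <- match(names(compound_effects), map$compound_id)
    if (anyNA(i)) stop("unknown compound id in compound_effects",
                       call. = FALSE)
    map$effect[i] <- compound_effects
  }
  map
}

#' Simulate one well of a synthetic plate
#'
#' Samples the worm occupancy and truth of one well and renders its FOV
#' stacks. Deterministic given the RNG state (seed with [set.seed()]).
#'
#' @param map_row One row of a loading map (see [screening_loading_map()]).
#' @param layout A [chip_layout].
#' @param optics An [optics_config].
#' @param base_spec A [population_spec] supplying the population defaults
#'   that the loading-map row (phenotype, effect, occupancy) overrides.
#' @return A list with `stacks` (list of `fovs_per_well` rendered arrays)
#'   and `worms` (list of `worm_truth`, channel indices global to the well).
#' @export
simulate_well <- function(map_row, layout, optics,
                          base_spec = population_spec()) {
  spec <- base_spec
  spec$phenotype <- map_row$phenotype
  spec$effect <- map_row$effect
  spec$occupancy <- map_row$occupancy
  cpf <- layout$channels_per_fov
  fov_len <- optics$image_size[2] * optics$pixel_size

  worms <- list()
  stacks <- vector("list", layout$fovs_per_well)
  for (f in seq_len(layout$fovs_per_well) - 1L) {
    occupied <- which(stats::runif(cpf) < spec$occupancy) - 1L
    fw <- lapply(occupied, function(ch)
      sample_worm(spec, channel_index = ch, z_planes = layout$z_planes,
                  fov_length_um = fov_len))
    stacks[[f + 1L]] <- render_fov_stack(fw, optics, layout)
    fw <- lapply(fw, function(w) {
      w$channel_index <- w$channel_index + f * cpf  # global within well
      w
    })
    worms <- c(worms, fw)
  }
  list(stacks = stacks, worms = worms)
}

#' Generate a synthetic screening dataset on disk
#'
#' Renders a whole plate to a dataset directory: one 16-bit grayscale TIFF
#' per (well, FOV, z-plane) named `{well}_f{fov}_z{zz}.tif`, a ground-truth
#' sidecar per well (`{well}_truth.yaml`), the loading map
#' (`loading_map.csv`), and the layout/optics configuration
#' (`dataset.yaml`). Identical (specification, seed) pairs reproduce the
#' dataset bit for bit.
#'
#' @param out_dir Dataset directory (created; must not already hold a
#'   dataset unless `overwrite = TRUE`).
#' @param loading_map Data frame from [screening_loading_map()] (or of the
#'   same shape).
#' @param layout A [chip_layout].
#' @param optics An [optics_config].
#' @param base_spec A [population_spec] of population defaults.
#' @param seed Integer seed controlling all sampling and noise.
#' @param overwrite Allow writing into an existing dataset directory.
#' @return The dataset directory, invisibly.
#' @export
generate_plate <- function(out_dir, loading_map = screening_loading_map(),
                           layout = chip_layout(), optics = optics_config(),
                           base_spec = population_spec(), seed = 1L,
                           overwrite = FALSE) {
  if (file.exists(file.path(out_dir, "dataset.yaml")) && !overwrite)
    stop("dataset already exists at ", out_dir,
         " (use overwrite = TRUE)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  max_val <- 2^optics$bit_depth - 1
  set.seed(seed)
  for (i in seq_len(nrow(loading_map))) {
    well <- loading_map$well[i]
    sim <- simulate_well(loading_map[i, ], layout, optics, base_spec)
    for (f in seq_along(sim$stacks)) {
      st <- sim$stacks[[f]]
      for (z in seq_len(dim(st)[3])) {
        path <- file.path(out_dir, sprintf("%s_f%d_z%02d.tif",
                                           well, f - 1L, z - 1L))
        tiff::writeTIFF(round(st[, , z]) / max_val, path,
                        bits.per.sample = 16L, compression = "none")
      }
    }
    write_worm_truth(sim$worms, file.path(out_dir,
                                          sprintf("%s_truth.yaml", well)))
  }
  utils::write.csv(loading_map, file.path(out_dir, "loading_map.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(layout = unclass(layout),
                        optics = unclass(optics), seed = seed),
                   file.path(out_dir, "dataset.yaml"))
  invisible(out_dir)
}

#' Read and write worm ground-truth sidecars
#'
#' @param worms List of `worm_truth` objects.
#' @param path YAML sidecar path.
#' @export
write_worm_truth <- function(worms, path) {
  yaml::write_yaml(lapply(worms, function(w)
    list(channel_index = w$channel_index,
         span = as.numeric(w$span), length = w$length,
         body_width = w$body_width,
         intensity_factor = w$intensity_factor,
         body_contrast = w$body_contrast,
         focus_plane = w$focus_plane, phenotype = w$phenotype,
         aggregates = as.list(w$aggregates))), path)
  invisible(path)
}

#' @rdname write_worm_truth
#' @export
read_worm_truth <- function(path) {
  lapply(yaml::read_yaml(path), function(v) {
    agg <- as.data.frame(v$aggregates)
    if (!nrow(agg))
      agg <- data.frame(position = numeric(0), offset = numeric(0),
                        diameter = numeric(0), amplitude = numeric(0))
    structure(list(channel_index = v$channel_index,
                   span = c(start = v$span[1], end = v$span[2]),
                   length = v$length, body_width = v$body_width,
                   intensity_factor = v$intensity_factor,
                   body_contrast = v$body_contrast,
                   aggregates = agg, focus_plane = v$focus_plane,
                   phenotype = v$phenotype),
              class = "worm_truth")
  })
}
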