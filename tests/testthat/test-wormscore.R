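# Fast, fully controlled fixtures: small stacks built directly in code.

blank_stack <- function(nr = 203, nc = 400, nz = 3, value = 0) {
  array(value, dim = c(nr, nc, nz))
}

test_that("merging sums over z and tiles FOVs along the channel axis", {
  s <- blank_stack()
  m0 <- load_and_merge(list(s, s, s, s))
  expect_true(all(m0 == 0))
  expect_equal(dim(m0), c(4 * 203, 400))

  s2 <- blank_stack()
  s2[, , 2] <- 7
  m <- load_and_merge(list(s, s2, s, s))
  expect_true(all(m[204:406, ] == 7))   # second FOV quadrant only
  expect_true(all(m[1:203, ] == 0))

  # merged mean equals the sum over z of per-plane means
  set.seed(1)
  r <- array(runif(203 * 100 * 4), dim = c(203, 100, 4))
  mm <- load_and_merge(list(r))
  expect_equal(mean(mm), sum(apply(r, 3, mean)))

  # a missing FOV merges as zeros but is flagged
  pm <- load_and_merge(list(s2, NULL, s2, s2))
  expect_equal(attr(pm, "missing_fovs"), 1L)
  expect_true(all(pm[204:406, ] == 0))

  expect_error(load_and_merge(list(s, blank_stack(nr = 100))), "mismatch")
  expect_error(load_and_merge(list(NULL, NULL)), "missing")
})

test_that("channel detection finds exactly the occupied channels", {
  layout <- mini_layout()
  cfg <- pipeline_config()
  # background-only image: nothing detected
  set.seed(2)
  noise <- matrix(rnorm(2 * 1014 * 500, 900, 20), 2 * 1014, 500)
  attr(noise, "fov_rows") <- 1014
  expect_length(detect_occupied_channels(noise, layout, cfg), 0)

  # ground truth from the rendered mini plate: exact set per well
  truth <- mini_truth()
  dir <- mini_dataset()
  for (wl in names(truth)[c(1, 7)]) {
    stacks <- load_well_stacks(dir, wl, mini_layout())
    det <- detect_occupied_channels(load_and_merge(stacks), layout, cfg)
    expect_equal(det, sort(vapply(truth[[wl]], `[[`, integer(1),
                                  "channel_index")))
  }
})

test_that("every channel is found when all traps are filled", {
  layout <- tiny_layout()
  optics <- tiny_optics()
  set.seed(13)
  worms <- lapply(0:2, function(ch)
    sample_worm(population_spec(), channel_index = ch, z_planes = 5,
                fov_length_um = 1600 * 0.74))
  st <- render_fov_stack(worms, optics, layout)
  det <- detect_occupied_channels(load_and_merge(list(st)), layout,
                                  pipeline_config())
  expect_equal(det, 0:2)
})

test_that("channel crops partition the merged image", {
  layout <- tiny_layout()
  cfg <- pipeline_config()
  set.seed(14)
  st <- array(runif(608 * 300 * 2), dim = c(608, 300, 2))
  crops <- lapply(0:2, function(ch) crop_channel(list(st), ch, layout, cfg))
  widths <- vapply(crops, function(cr) nrow(cr$crop), integer(1))
  expect_equal(sum(widths), 608)
  stitched <- do.call(rbind, lapply(crops, function(cr) cr$crop[, , 1]))
  expect_equal(stitched, st[, , 1])
  expect_error(crop_channel(list(st), 3, layout, cfg), "channel index")
})

test_that("best-focus selection maximizes LoG variance with low-index ties", {
  cfg <- pipeline_config()
  expect_equal(select_best_focus(blank_stack(nz = 1), cfg), 0L)
  expect_equal(select_best_focus(blank_stack(nz = 4, value = 5), cfg), 0L)

  # recovered true focal planes on the rendered mini plate
  truth <- mini_truth()
  scores <- mini_scores()
  an <- scores$animals
  hits <- 0; total <- 0
  for (wl in names(truth)) {
    tf <- vapply(truth[[wl]], `[[`, integer(1), "focus_plane")
    names(tf) <- vapply(truth[[wl]], `[[`, integer(1), "channel_index")
    sub <- an[an$well == wl, ]
    m <- match(as.character(sub$channel_index), names(tf))
    total <- total + sum(!is.na(m))
    hits <- hits + sum(abs(sub$best_z - tf[m]) <= 1, na.rm = TRUE)
  }
  expect_gte(hits / total, 0.95)
})

test_that("worm length is measured within 5% of the planted length", {
  cfg <- pipeline_config()
  blank <- matrix(0, 203, 400)
  m <- measure_worm_length(blank, cfg, background = 100)
  expect_equal(m$length_um, 0)
  expect_equal(m$flags, "empty")

  # a band spanning the full crop is flagged edge-truncated
  full <- matrix(100, 203, 400)
  full[80:120, ] <- 1000
  m2 <- measure_worm_length(full, cfg, background = 100)
  expect_equal(m2$span, c(1, 400))
  expect_true("edge_truncated" %in% m2$flags)

  truth <- mini_truth()
  an <- mini_scores()$animals
  rel_err <- c()
  for (wl in names(truth)) {
    tl <- vapply(truth[[wl]], `[[`, numeric(1), "length")
    names(tl) <- vapply(truth[[wl]], `[[`, integer(1), "channel_index")
    sub <- an[an$well == wl & an$valid, ]
    m <- match(as.character(sub$channel_index), names(tl))
    rel_err <- c(rel_err, abs(sub$length_um - tl[m]) / tl[m])
  }
  expect_gt(length(rel_err), 50)
  expect_lt(max(rel_err, na.rm = TRUE), 0.05)
})

test_that("threshold calibration follows the 3%-bright-pixel rule", {
  cfg <- pipeline_config()
  ramp <- compute_intensity_threshold(list(0:100), cfg)
  expect_equal(ramp$threshold, 97)

  const <- compute_intensity_threshold(list(rep(42, 500)), cfg)
  expect_equal(const$threshold, 42)

  expect_error(compute_intensity_threshold(list(numeric(0)), cfg),
               "cannot calibrate")

  # on the mini plate the threshold separates body from punctum peaks
  scores <- mini_scores()
  thr <- scores$threshold$threshold
  body_peak <- 100 + (10 - 1) * 100 * 1.05       # brightest body level
  punctum_peak <- 100 + 900 + 3 * 0.9 * 900 * 0.95  # dimmest punctum peak
  expect_gt(thr, 100 + 900 * 0.5)
  expect_lt(thr, punctum_peak)
})

test_that("aggregate segmentation needs both intensity and blob response", {
  cfg <- pipeline_config()
  tm <- structure(list(threshold = 500), class = "threshold_model")

  # uniform bright plane: above threshold everywhere but zero gradient
  flat <- matrix(1000, 120, 200)
  expect_equal(nrow(segment_aggregates(flat, c(1, 200), tm, cfg)), 0)

  # a single bright compact blob is found once
  blob <- matrix(100, 120, 200)
  d <- sqrt(outer((1:120 - 60)^2, (1:200 - 100)^2, "+"))
  blob <- blob + 900 / (1 + exp((d - 3) / 0.5))
  p <- segment_aggregates(blob, c(1, 200), tm, cfg)
  expect_equal(nrow(p), 1)
  expect_equal(p$col, 100, tolerance = 1)

  # an 8-connected pair of pixels is one particle, excluded by the minimum
  # area bound when below it
  tiny <- matrix(0, 60, 60)
  tiny[30, 30] <- 1000; tiny[31, 31] <- 1000
  cfg_min3 <- pipeline_config(particle_area_bounds = c(3, 96))
  expect_equal(nrow(segment_aggregates(tiny, c(1, 60), tm, cfg_min3)), 0)
  cfg_min2 <- pipeline_config(particle_area_bounds = c(2, 96),
                              particle_peak_ratio = 1)
  expect_equal(nrow(segment_aggregates(tiny, c(1, 60), tm, cfg_min2)), 1)

  # particles with centroid outside the worm span are discarded
  expect_equal(nrow(segment_aggregates(blob, c(150, 200), tm, cfg)), 0)
})

test_that("five planted 3-um puncta are recovered as five particles", {
  layout <- tiny_layout()
  optics <- tiny_optics()
  set.seed(21)
  w <- sample_worm(population_spec(density = 0), channel_index = 1,
                   z_planes = 5, fov_length_um = 1600 * 0.74,
                   length_um = 900)
  w$aggregates <- data.frame(
    position = w$span["start"] + c(150, 300, 450, 600, 750),
    offset = c(-8, 5, 0, 7, -4), diameter = 3, amplitude = 3)
  st <- render_fov_stack(list(w), optics, layout)
  cfg <- pipeline_config()
  cr <- crop_channel(list(st), 1, layout, cfg)
  bz <- select_best_focus(cr, cfg)
  plane <- cr$crop[, , bz + 1]
  m <- measure_worm_length(plane, cfg)
  px <- wormhts:::collect_worm_pixels(plane, m$span, cfg)
  tm <- compute_intensity_threshold(list(px), cfg)
  p <- segment_aggregates(plane, m$span, tm, cfg)
  expect_equal(nrow(p), 5)
  expect_equal(sort(p$col) * optics$pixel_size,
               as.numeric(w$aggregates$position), tolerance = 5)
})

test_that("scores are invariant to a joint global intensity rescaling", {
  layout <- tiny_layout()
  optics <- tiny_optics()
  set.seed(22)
  w <- sample_worm(population_spec(), channel_index = 1, z_planes = 5,
                   fov_length_um = 1600 * 0.74)
  st <- render_fov_stack(list(w), optics, layout)
  cfg <- pipeline_config()
  cr <- crop_channel(list(st), 1, layout, cfg)
  bz <- select_best_focus(cr, cfg)
  plane <- cr$crop[, , bz + 1]
  m <- measure_worm_length(plane, cfg)
  px <- wormhts:::collect_worm_pixels(plane, m$span, cfg)
  tm <- compute_intensity_threshold(list(px), cfg)
  p1 <- segment_aggregates(plane, m$span, tm, cfg)

  k <- 2.7
  tm2 <- tm; tm2$threshold <- tm$threshold * k
  p2 <- segment_aggregates(plane * k, m$span, tm2, cfg)
  expect_equal(nrow(p2), nrow(p1))
  expect_equal(p2$area_px, p1$area_px)
})

test_that("animal and well scoring compute the density arithmetic", {
  parts <- data.frame(area_um2 = rep(2, 32))
  a <- score_animal("A01", 3, 7, 1000, parts)
  expect_equal(a$density_per_um, 0.032)
  expect_equal(score_animal("A01", 3, 7, 800,
                            parts[0, , drop = FALSE])$density_per_um, 0)
  flagged <- score_animal("A01", 4, 0, 0, NULL, flags = "empty")
  expect_false(flagged$valid)

  animals <- rbind(score_animal("w", 0, 0, 1000, data.frame(area_um2 = rep(1, 10))),
                   score_animal("w", 1, 0, 1000, data.frame(area_um2 = rep(1, 30))),
                   score_animal("w", 2, 0, 1000, data.frame(area_um2 = rep(1, 50))),
                   flagged)
  s <- score_well(animals)
  expect_equal(s$median_density, 0.03)
  expect_equal(s$n, 3)
  expect_equal(s$flagged, 1)

  one <- score_well(animals[2, , drop = FALSE])
  expect_equal(one$median_density, 0.03)
  expect_equal(one$sd_density, 0)
})

test_that("diffuse worms always score zero aggregates", {
  scores <- mini_scores()
  wells <- mini_map()
  diffuse <- wells$well[wells$role == "vehicle_polyq24"]
  sub <- scores$animals[scores$animals$well %in% diffuse & scores$animals$valid, ]
  expect_gt(nrow(sub), 20)
  expect_true(all(sub$aggregate_count == 0))
})

test_that("recovered densities track the planted truth per animal", {
  truth <- mini_truth()
  an <- mini_scores()$animals
  wells <- mini_map()
  punctate <- wells$well[wells$role == "vehicle_polyq35"]
  for (wl in punctate) {
    td <- vapply(truth[[wl]], function(w) nrow(w$aggregates) / w$length,
                 numeric(1))
    names(td) <- vapply(truth[[wl]], `[[`, integer(1), "channel_index")
    sub <- an[an$well == wl & an$valid, ]
    m <- match(as.character(sub$channel_index), names(td))
    rel <- abs(sub$density_per_um - td[m]) / td[m]
    expect_lt(median(rel, na.rm = TRUE), 0.10)
  }
})
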