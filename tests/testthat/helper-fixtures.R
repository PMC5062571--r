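# Shared fixtures. The mini plate is a scaled-down study: 12 wells (6
# punctate vehicle-Q35-like at 0.032 per um, 6 diffuse vehicle-Q24-like),
# 10 traps per well over 2 FOVs, 9 z-planes at 5 um, full-resolution pixel
# size (0.74 um). It is rendered to disk once per test session and reused
# by every test that needs ground-truth imagery.

mini_layout <- function() {
  chip_layout(n_rows = 1, n_cols = 12, traps_per_well = 10,
              fovs_per_well = 2, channels_per_fov = 5, z_planes = 9)
}

mini_optics <- function() {
  optics_config("10x", image_size = c(1014, 2048))
}

mini_map <- function() {
  screening_loading_map(mini_layout(), n_compound = 0, n_vehicle_q24 = 6,
                        n_vehicle_q35 = 6, n_positive = 0)
}

mini_seed <- 101L

.fixture_env <- new.env(parent = emptyenv())

mini_dataset <- function() {
  if (!is.null(.fixture_env$mini_dir)) return(.fixture_env$mini_dir)
  dir <- file.path(tempdir(), "wormhts-mini-plate")
  if (!file.exists(file.path(dir, "dataset.yaml")))
    generate_plate(dir, mini_map(), mini_layout(), mini_optics(),
                   seed = mini_seed, overwrite = TRUE)
  .fixture_env$mini_dir <- dir
  dir
}

mini_scores <- function() {
  if (!is.null(.fixture_env$mini_scores)) return(.fixture_env$mini_scores)
  .fixture_env$mini_scores <- score_dataset(mini_dataset())
  .fixture_env$mini_scores
}

mini_truth <- function() {
  dir <- mini_dataset()
  map <- mini_map()
  stats::setNames(lapply(map$well, function(w)
    read_worm_truth(file.path(dir, sprintf("%s_truth.yaml", w)))), map$well)
}

# A tiny single-FOV configuration for fast rendering tests.
tiny_layout <- function(z_planes = 5) {
  chip_layout(n_rows = 1, n_cols = 1, traps_per_well = 3, fovs_per_well = 1,
              channels_per_fov = 3, z_planes = z_planes)
}

tiny_optics <- function() {
  optics_config("10x", image_size = c(608, 1600))
}

# Paired 10x / 4x render of the same worms (4 punctate + 1 diffuse in one
# 5-channel FOV), scored in both modes. Cached per session.
lowres_pair <- function() {
  if (!is.null(.fixture_env$lowres)) return(.fixture_env$lowres)
  layout10 <- chip_layout(n_rows = 1, n_cols = 1, traps_per_well = 5,
                          fovs_per_well = 1, channels_per_fov = 5,
                          z_planes = 9)
  layout4 <- chip_layout(n_rows = 1, n_cols = 1, traps_per_well = 5,
                         fovs_per_well = 1, channels_per_fov = 5,
                         z_planes = 5, z_step = 20)
  optics10 <- mini_optics()
  optics4 <- optics_config("4x", image_size = c(405, 820))
  set.seed(31)
  worms <- c(lapply(0:3, function(ch)
    sample_worm(population_spec(), channel_index = ch, z_planes = 9,
                fov_length_um = 2048 * 0.74)),
    list(sample_worm(population_spec(phenotype = "diffuse"),
                     channel_index = 4, z_planes = 9,
                     fov_length_um = 2048 * 0.74)))
  st10 <- render_fov_stack(worms, optics10, layout10)
  worms4 <- lapply(worms, function(w) { w$focus_plane <- 2L; w })
  st4 <- render_fov_stack(worms4, optics4, layout4)

  cfg10 <- pipeline_config()
  rec10 <- analyze_well(list(st10), layout10, cfg10)
  thr10 <- compute_intensity_threshold(
    lapply(rec10, `[[`, "worm_pixels"), cfg10)
  sc10 <- score_well_stacks(rec10, "W", thr10, cfg10)

  cfg4 <- low_res_config()
  rec4 <- analyze_well(list(st4), layout4, cfg4)
  thr4 <- compute_intensity_threshold(
    lapply(rec4, `[[`, "worm_pixels"), cfg4)
  sc4 <- run_low_res_mode(list(st4), "W", thr4, layout4, cfg4)

  .fixture_env$lowres <- list(truth = worms, animals10 = sc10$animals,
                              animals4 = sc4$animals)
  .fixture_env$lowres
}

# Independent dense solve of a hydraulic network: stacks the per-branch Ohm
# relations, interior-node conservation, and boundary pressures into one
# linear system in (pressures, flows) and solves it directly. Used as the
# oracle against the nodal solver.
oracle_solve <- function(net, p1) {
  b <- net$branches
  nodes <- net$nodes
  nb <- nrow(b); nn <- length(nodes)
  nun <- nn + nb  # pressures then flows
  rows <- list(); rhs <- c()
  for (k in seq_len(nb)) {           # Q_k - (p_f - p_t)/R_k = 0
    r <- numeric(nun)
    r[nn + k] <- 1
    r[match(b$from[k], nodes)] <- -1 / b$resistance[k]
    r[match(b$to[k], nodes)] <- 1 / b$resistance[k]
    rows <- c(rows, list(r)); rhs <- c(rhs, 0)
  }
  for (nd in setdiff(nodes, c(net$inlet, net$outlet))) {  # conservation
    r <- numeric(nun)
    r[nn + which(b$to == nd)] <- 1
    r[nn + which(b$from == nd)] <- -1
    rows <- c(rows, list(r)); rhs <- c(rhs, 0)
  }
  for (nd in c(net$inlet, net$outlet)) {                  # boundaries
    r <- numeric(nun)
    r[match(nd, nodes)] <- 1
    rows <- c(rows, list(r)); rhs <- c(rhs, if (nd == net$inlet) p1 else 0)
  }
  a <- do.call(rbind, rows)
  sol <- qr.solve(a, rhs)
  list(pressures = stats::setNames(sol[seq_len(nn)], nodes),
       flows = stats::setNames(sol[nn + seq_len(nb)], b$id))
}

# Random single-inlet ladder: n_wells parallel paths with random segment
# dimensions joining a shared main line.
random_ladder <- function(n_wells, seed) {
  set.seed(seed)
  wells <- paste0("w", seq_len(n_wells))
  junc <- paste0("j", seq_len(n_wells))
  feed <- data.frame(id = paste0("feed_", wells), from = "IN", to = wells,
                     length = runif(n_wells, 500, 4000),
                     width = runif(n_wells, 40, 200),
                     height = runif(n_wells, 20, 80))
  drop <- data.frame(id = paste0("drop_", wells), from = wells, to = junc,
                     length = runif(n_wells, 500, 4000),
                     width = runif(n_wells, 40, 200),
                     height = runif(n_wells, 20, 80))
  main <- data.frame(id = paste0("main_", seq_len(n_wells)),
                     from = junc, to = c(junc[-1], "OUT"),
                     length = runif(n_wells, 1000, 9000),
                     width = runif(n_wells, 100, 400),
                     height = runif(n_wells, 40, 100))
  hydraulic_network(rbind(feed, drop, main), inlet = "IN", outlet = "OUT")
}

# Welch test written out from the textbook formulas, independent of
# stats::t.test.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Statistical-level plate (no imagery): per-animal densities drawn from the
# population model with a 5% well-to-well random effect (culture batches),
# assembled into the same tables score_plate() produces.
simulate_score_tables <- function(n_compound = 78, effects = NULL,
                                  n_per_well = 35, seed = 1,
                                  density = 0.032, density_sd = 0.002,
                                  well_cv = 0.05) {
  set.seed(seed)
  n_wells <- n_compound + 6 + 6
  wells <- sprintf("W%03d", seq_len(n_wells))
  role <- c(rep("compound", n_compound), rep("vehicle_polyq35", 6),
            rep("vehicle_polyq24", 6))
  eff <- rep(1, n_wells)
  if (!is.null(effects)) eff[seq_along(effects)] <- effects
  animals <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
    mu <- density * eff[i] * rnorm(1, 1, well_cv)
    d <- if (role[i] == "vehicle_polyq24") rep(0, n_per_well) else
      pmax(0, rnorm(n_per_well, mu, density_sd))
    data.frame(well = wells[i], density_per_um = d, valid = TRUE)
  }))
  well_tab <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
    d <- animals$density_per_um[animals$well == wells[i]]
    data.frame(well = wells[i], role = role[i],
               compound_id = if (role[i] == "compound")
                 sprintf("C%03d", i) else toupper(role[i]),
               n = length(d), median_density = median(d),
               sd_density = sd(d))
  }))
  structure(list(animals = animals, wells = well_tab), class = "plate_scores")
}
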