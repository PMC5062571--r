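test_that("the Z'-factor formula reproduces the assay's worked example", {
  pos <- list(center = 0.032, spread = 0.002)
  neg <- list(center = 0.000, spread = 0.000)
  expect_equal(z_prime(pos, neg), 0.8125)
  expect_equal(round(z_prime(pos, neg), 1), 0.8)

  expect_equal(z_prime(list(center = 1, spread = 0),
                       list(center = 0, spread = 0)), 1)
  # boundary: 3 * (spreads) equal to the separation gives exactly 0
  expect_equal(z_prime(list(center = 0.3, spread = 0.06),
                       list(center = 0, spread = 0.04)), 0)
  expect_error(z_prime(list(center = 1, spread = 1),
                       list(center = 1, spread = 2)), "undefined")
})

test_that("Z' is affine-invariant, bounded by 1, and decreasing in spread", {
  set.seed(101)
  for (i in 1:20) {
    mu <- sort(runif(2)); s <- runif(2, 0, 0.2)
    z <- z_prime(list(center = mu[2], spread = s[1]),
                 list(center = mu[1], spread = s[2]))
    expect_lte(z, 1)
    a <- runif(1, 0.5, 3); b <- runif(1, -1, 1)
    z2 <- z_prime(list(center = a * mu[2] + b, spread = a * s[1]),
                  list(center = a * mu[1] + b, spread = a * s[2]))
    expect_equal(z2, z, tolerance = 1e-12)
    z3 <- z_prime(list(center = mu[2], spread = s[1] * 1.1),
                  list(center = mu[1], spread = s[2]))
    expect_lt(z3, z)
  }
})

test_that("k-well averaging reduces to k = 1 and typically improves Z'", {
  pos <- c(0.031, 0.033, 0.032, 0.030, 0.034, 0.032)
  neg <- c(0.001, 0.002, 0.000, 0.001, 0.002, 0.001)
  expect_equal(multiwell_z_prime(pos, neg, 1),
               z_prime(population_stats(pos), population_stats(neg)))
  # identical wells: any k gives the degenerate spread-free score
  expect_equal(multiwell_z_prime(rep(0.032, 6), rep(0.001, 6), 3),
               multiwell_z_prime(rep(0.032, 6), rep(0.001, 6), 1))
  expect_error(multiwell_z_prime(pos[1:2], neg, 3), "at least k")

  # Monte-Carlo: averaging noisy wells improves the expected score
  set.seed(7)
  deltas <- replicate(200, {
    p <- rnorm(6, 0.032, 0.003); n <- rnorm(6, 0.001, 0.003)
    multiwell_z_prime(p, n, 3) - multiwell_z_prime(p, n, 1)
  })
  expect_gt(mean(deltas), 0)
})

test_that("plate normalization scales to the reference and is idempotent", {
  plate <- simulate_score_tables(n_compound = 10, seed = 3)
  norm <- normalize_plate(plate)
  veh <- norm$animals$well %in%
    norm$wells$well[norm$wells$role == "vehicle_polyq35"]
  expect_equal(median(norm$animals$density_per_um[veh]), 0.0318)

  # already at the reference: factor 1
  again <- normalize_plate(norm)
  expect_equal(again$animals$density_per_um, norm$animals$density_per_um)
  expect_equal(again$wells$median_density, norm$wells$median_density)

  # a doubled plate halves
  dbl <- plate
  dbl$animals$density_per_um <- dbl$animals$density_per_um * 2
  dbl$wells$median_density <- dbl$wells$median_density * 2
  dbl$wells$sd_density <- dbl$wells$sd_density * 2
  ndbl <- normalize_plate(dbl)
  expect_equal(ndbl$animals$density_per_um, norm$animals$density_per_um,
               tolerance = 1e-12)

  broke <- plate
  broke$animals$density_per_um[] <- 0
  expect_error(normalize_plate(broke), "cannot normalize")
})

test_that("candidate calling applies the strict 3-SD band", {
  plate <- simulate_score_tables(n_compound = 20,
                                 effects = c(0.5, 0.5, rep(1, 18)),
                                 seed = 5)
  plate <- normalize_plate(plate)
  cand <- call_candidates(plate)
  expect_setequal(cand, plate$wells$well[1:2])

  # a plate sitting exactly at the vehicle level yields no candidates
  flat <- simulate_score_tables(n_compound = 10, seed = 6)
  flat$wells$median_density[flat$wells$role == "compound"] <-
    median(flat$wells$median_density[flat$wells$role == "vehicle_polyq35"])
  expect_length(call_candidates(flat), 0)

  # boundary: exactly at the cutoff is not a candidate
  b <- simulate_score_tables(n_compound = 3, seed = 7)
  cc <- call_candidates(b)
  cut <- attr(cc, "cutoff")
  b$wells$median_density[1] <- cut
  expect_false(b$wells$well[1] %in% call_candidates(b))
})

test_that("the Welch test matches an independent implementation to 1e-10", {
  expect_equal(welch_t_test(1:5, 2:6), oracle_welch(1:5, 2:6),
               tolerance = 1e-10)
  expect_equal(welch_t_test(1:5, 2:6), welch_t_test(2:6, 1:5))
  # identical groups: t = 0, p = 1
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(welch_t_test(1, 1:5), "at least 2")
  set.seed(8)
  for (i in 1:40) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.1, 3))
    expect_equal(welch_t_test(a, b), oracle_welch(a, b), tolerance = 1e-10)
  }
})

test_that("hit confirmation recovers planted effects without false calls", {
  # 2 true suppressors among 78 inactive compounds, 35 animals per well
  plate <- simulate_score_tables(n_compound = 78,
                                 effects = c(0.5, 0.5, rep(1, 76)),
                                 seed = 9)
  plate <- normalize_plate(plate)
  cand <- call_candidates(plate)
  hits <- confirm_hits(plate, cand)
  expect_setequal(hits$confirmed, plate$wells$well[1:2])
  expect_true(all(hits$table$p_value[hits$table$tier == "confirmed"] < 0.005))

  # a candidate with reduced median but increased SD is never confirmed
  plate2 <- plate
  i <- plate2$animals$well == plate2$wells$well[1]
  m <- median(plate2$animals$density_per_um[i])
  plate2$animals$density_per_um[i] <-
    m + (plate2$animals$density_per_um[i] - m) * 25
  hits2 <- confirm_hits(plate2, plate2$wells$well[1])
  expect_false(plate2$wells$well[1] %in% hits2$confirmed)

  # small populations are flagged underpowered, not confirmed
  plate3 <- simulate_score_tables(n_compound = 2, effects = c(0.5, 1),
                                  n_per_well = 10, seed = 10)
  hits3 <- confirm_hits(plate3, plate3$wells$well[1])
  expect_equal(hits3$table$tier, "underpowered")
})

test_that("null plates control the false-confirmation rate", {
  # exchangeable animals (no batch effect): the p < 0.005 gate is binding
  confirmed <- vapply(1:10, function(s) {
    plate <- simulate_score_tables(n_compound = 78, seed = 100 + s,
                                   well_cv = 0)
    plate <- normalize_plate(plate)
    length(confirm_hits(plate, call_candidates(plate))$confirmed)
  }, numeric(1))
  expect_lte(mean(confirmed), 0.005 * 78)
})

test_that("screen_plate assembles the full plate report", {
  plate <- simulate_score_tables(n_compound = 20,
                                 effects = c(0.5, rep(1, 19)), seed = 12)
  res <- screen_plate(plate)
  expect_s3_class(res, "plate_result")
  expect_true(plate$wells$well[1] %in% res$candidates)
  expect_gte(res$z_prime_per_animal, 0.5)
  expect_length(res$z_prime_by_k, 3)
  # more averaging never leaves the diagnostic undefined
  expect_true(all(is.finite(res$z_prime_by_k)))
})
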