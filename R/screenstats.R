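#' Population statistics of an animal group
#'
#' The assay reports populations as median +/- standard deviation of the
#' per-animal aggregate density, so the screening-window statistics here use
#' the median as the centre and the SD as the spread by default (the
#' original screening-window coefficient uses means; switch with
#' `center = "mean"`).
#'
#' @param densities Per-animal aggregate densities (per um).
#' @param label Optional population label.
#' @param center `"median"` (default) or `"mean"`.
#' @return List of class `population_stats`: `center`, `spread`, `n`,
#'   `label`.
#' @export
population_stats <- function(densities, label = NA_character_,
                             center = c("median", "mean")) {
  center <- match.arg(center)
  densities <- densities[is.finite(densities)]
  if (!length(densities)) stop("no finite densities", call. = FALSE)
  structure(list(center = if (center == "median") stats::median(densities)
                   else mean(densities),
                 spread = if (length(densities) > 1) stats::sd(densities)
                   else 0,
                 n = length(densities), label = label),
            class = "population_stats")
}

#' Screening-window coefficient (Z'-factor)
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' computed from the positive- and negative-control population statistics.
#' Always <= 1, and equal to 1 only when both spreads vanish; values above
#' 0.5 indicate an excellent assay window. With the assay's characterization
#' statistics (negative control 0.000 +/- 0.000, disease model
#' 0.032 +/- 0.002 aggregates per um, median +/- SD) this gives
#' 1 - 3(0.002)/0.032 = 0.8125, i.e. 0.8 to one decimal.
#'
#' @param pos,neg [population_stats] (or lists with `center` and `spread`)
#'   of the positive and negative control populations.
#' @return The Z'-factor (unitless).
#' @examples
#' z_prime(list(center = 0.032, spread = 0.002),
#'         list(center = 0.000, spread = 0.000))   # 0.8125
#' @export
z_prime <- function(pos, neg) {
  sep <- abs(pos$center - neg$center)
  if (sep == 0)
    stop("control centers are equal: Z'-factor is undefined", call. = FALSE)
  1 - 3 * (pos$spread + neg$spread) / sep
}

#' Z'-factor under k-well averaging
#'
#' Replicate control wells can be averaged in groups of k before computing
#' the screening window: the per-well scores of each arm are split into
#' consecutive groups of k wells, each group replaced by its mean, and the
#' Z'-factor computed from the centre and spread of the group means. k = 1
#' reduces to the per-well Z'-factor. Averaging shrinks the spread, so the
#' score typically grows with k.
#'
#' @param pos_wells,neg_wells Numeric vectors of per-well scores (e.g. well
#'   medians) of the positive and negative control arms.
#' @param k Wells averaged per group (>= 1); each arm needs at least k
#'   wells.
#' @return The Z'-factor of the k-well averages.
#' @export
multiwell_z_prime <- function(pos_wells, neg_wells, k = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(pos_wells) < k || length(neg_wells) < k)
    stop("need at least k wells per control arm", call. = FALSE)
  group_means <- function(x) {
    n <- (length(x) %/% k) * k
    colMeans(matrix(x[seq_len(n)], nrow = k))
  }
  z_prime(population_stats(group_means(pos_wells)),
          population_stats(group_means(neg_wells)))
}

#' Normalize a scored plate to the reference vehicle median
#'
#' Chip-to-chip (day-to-day) intensity and culture variation is absorbed by
#' rescaling every well of a chip by one factor: the factor that brings the
#' chip's pooled vehicle-control (punctate) median density to the reference
#' value 0.0318 per um established during assay characterization. All
#' per-animal densities, well medians and SDs are multiplied by the same
#' factor, so the operation is idempotent.
#'
#' @param plate A `plate_scores` object from [score_plate()] (or any list
#'   with `animals` and `wells` tables of the same shape).
#' @param reference_median Reference vehicle median density (per um).
#' @return The plate with rescaled densities, the factor recorded in
#'   `normalization_factor`, and `normalized = TRUE`.
#' @export
normalize_plate <- function(plate, reference_median = 0.0318) {
  veh <- plate$animals$well %in%
    plate$wells$well[plate$wells$role == "vehicle_polyq35"]
  d <- plate$animals$density_per_um[veh & plate$animals$valid]
  med <- stats::median(d, na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    stop("vehicle median is zero or undefined: cannot normalize",
         call. = FALSE)
  f <- reference_median / med
  plate$animals$density_per_um <- plate$animals$density_per_um * f
  plate$wells$median_density <- plate$wells$median_density * f
  plate$wells$sd_density <- plate$wells$sd_density * f
  plate$normalization_factor <-
    f * (plate$normalization_factor %||% 1)
  plate$normalized <- TRUE
  plate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call candidate hit wells on a normalized plate
#'
#' A compound well is a candidate when its median aggregate density falls
#' strictly below the vehicle median minus 3 x the vehicle SD, where both
#' statistics are taken across the vehicle wells' medians (the plate-level
#' band drawn around the vehicle arm). Flagged or empty wells are excluded.
#'
#' @param plate A (normalized) `plate_scores` object.
#' @param k_sd Width of the band in vehicle SDs (default 3).
#' @return Character vector of candidate well labels (possibly empty), with
#'   the band recorded in attributes `"vehicle_median"` and `"cutoff"`.
#' @export
call_candidates <- function(plate, k_sd = 3) {
  w <- plate$wells
  veh <- w$role == "vehicle_polyq35" & is.finite(w$median_density)
  if (!any(veh)) stop("no vehicle wells with valid scores", call. = FALSE)
  v_med <- stats::median(w$median_density[veh])
  v_sd <- if (sum(veh) > 1) stats::sd(w$median_density[veh]) else 0
  cutoff <- v_med - k_sd * v_sd
  cand <- w$role == "compound" & is.finite(w$median_density) & w$n > 0 &
    w$median_density < cutoff
  structure(w$well[cand], vehicle_median = v_med, vehicle_sd = v_sd,
            cutoff = cutoff)
}

#' Welch's unequal-variance t-test (two-tailed)
#'
#' Two-tailed Student's t-test with unequal variances
#' (Welch-Satterthwaite degrees of freedom), as used for hit confirmation.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return Two-tailed p-value.
#' @export
welch_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations", call. = FALSE)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Confirm candidate hits against the vehicle population
#'
#' A candidate is confirmed when its per-animal densities differ from the
#' pooled vehicle-control animals at p < 0.005 (two-tailed Welch test) AND
#' both its median and its SD are below the vehicle values (a genuine
#' suppressor shifts and tightens the distribution). Candidates with
#' 0.005 <= p < 0.05 are tiered `"moderate"`; candidates with fewer than
#' `min_n` animals are flagged `"underpowered"` and never confirmed.
#'
#' @param plate A (normalized) `plate_scores` object.
#' @param candidates Candidate well labels from [call_candidates()].
#' @param p_confirm,p_moderate Significance cuts (strict inequalities).
#' @param min_n Minimum animals per candidate well.
#' @param n_screened Number of compounds screened (for the hit rate);
#'   default the number of compound wells on the plate.
#' @return List of class `hit_calls`: `table` (per-candidate data.frame with
#'   `well`, `n`, `median`, `sd`, `p_value`, `tier`), `confirmed` (labels),
#'   `hit_rate_percent` (confirmed / screened * 100, one decimal).
#' @export
confirm_hits <- function(plate, candidates, p_confirm = 0.005,
                         p_moderate = 0.05, min_n = 15,
                         n_screened = NULL) {
  w <- plate$wells
  if (is.null(n_screened)) n_screened <- sum(w$role == "compound")
  veh_wells <- w$well[w$role == "vehicle_polyq35"]
  veh <- plate$animals$density_per_um[
    plate$animals$well %in% veh_wells & plate$animals$valid]
  v_med <- stats::median(veh); v_sd <- stats::sd(veh)

  rows <- lapply(candidates, function(cw) {
    d <- plate$animals$density_per_um[
      plate$animals$well %in% cw & plate$animals$valid]
    p <- if (length(d) >= 2) welch_t_test(d, veh) else NA_real_
    med <- stats::median(d); s <- stats::sd(d)
    tier <- if (length(d) < min_n) "underpowered"
      else if (is.na(p)) "untestable"
      else if (p < p_confirm && med < v_med && s < v_sd) "confirmed"
      else if (p < p_moderate && med < v_med) "moderate"
      else "not_confirmed"
    data.frame(well = cw, n = length(d), median = med, sd = s,
               p_value = p, tier = tier, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(0), n = integer(0), median = numeric(0),
               sd = numeric(0), p_value = numeric(0), tier = character(0))
  confirmed <- tab$well[tab$tier == "confirmed"]
  structure(list(table = tab, confirmed = confirmed,
                 n_screened = n_screened,
                 hit_rate_percent = hit_rate(length(confirmed), n_screened)),
            class = "hit_calls")
}

#' @rdname confirm_hits
#' @param n_confirmed,n_total Confirmed and screened compound counts.
#' @return `hit_rate()`: the percentage of confirmed hits, one decimal
#'   (4 of 983 gives 0.4).
#' @export
hit_rate <- function(n_confirmed, n_total) {
  round(100 * n_confirmed / n_total, 1)
}

#' Full screening analysis of a scored plate
#'
#' Normalizes the plate, calls candidates, confirms hits, and computes the
#' control-arm Z'-factor diagnostics (1-, 2- and 3-well averaging when
#' enough control wells exist).
#'
#' @param plate A `plate_scores` object from [score_plate()].
#' @param reference_median Reference vehicle median for normalization.
#' @param ... Passed to [confirm_hits()].
#' @return List of class `plate_result`: the normalized `plate`,
#'   `candidates`, `hits` (a `hit_calls`), `z_prime_per_animal` (pooled
#'   per-animal control stats), and `z_prime_by_k` (named vector, k-well
#'   averaging over the control-arm well medians).
#' @export
screen_plate <- function(plate, reference_median = 0.0318, ...) {
  plate <- normalize_plate(plate, reference_median)
  w <- plate$wells
  pos_wells <- w$well[w$role == "vehicle_polyq35"]
  neg_wells <- w$well[w$role == "vehicle_polyq24"]
  an <- plate$animals
  pos <- an$density_per_um[an$well %in% pos_wells & an$valid]
  neg <- an$density_per_um[an$well %in% neg_wells & an$valid]
  zp_animal <- if (length(pos) && length(neg) &&
                   stats::median(pos) != stats::median(neg))
    z_prime(population_stats(pos), population_stats(neg)) else NA_real_

  pos_med <- w$median_density[match(pos_wells, w$well)]
  neg_med <- w$median_density[match(neg_wells, w$well)]
  ks <- seq_len(min(3L, length(pos_med), length(neg_med)))
  zp_k <- vapply(ks, function(k)
    tryCatch(multiwell_z_prime(pos_med, neg_med, k), error = function(e)
      NA_real_), numeric(1))
  names(zp_k) <- paste0("k", ks)

  candidates <- call_candidates(plate)
  hits <- confirm_hits(plate, candidates, ...)
  structure(list(plate = plate, candidates = candidates, hits = hits,
                 z_prime_per_animal = zp_animal, z_prime_by_k = zp_k),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("plate_result: %d wells, Z' (per-animal) = %.3f\n",
              nrow(x$plate$wells), x$z_prime_per_animal))
  cat(sprintf("  candidates: %d; confirmed: %d (hit rate %.1f%%)\n",
              length(x$candidates), length(x$hits$confirmed),
              x$hits$hit_rate_percent))
  invisible(x)
}
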