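#' Stage-calibration model for chip imaging
#'
#' Maps nominal (design) stage coordinates to corrected coordinates that
#' account for the three systematic misalignments of a chip clamped in its
#' gasket on the stage: an in-plane rotation of the chip relative to the
#' stage axes (`theta_xy`), an overall tilt of the chip plane expressed as
#' the two slopes of z over x and y (`delta_xz`, `delta_yz`), and the bending
#' of the glass substrate under the applied gasket pressure, a smooth scalar
#' field `bending(x, y)` that can displace the focal plane by tens of
#' micrometres (up to ~70 um) across the chip.
#'
#' A model is usually fit from reference markers with
#' [calibrate_from_markers()]; this constructor builds one directly from its
#' parameters. The identity model (`calibration_model()`) leaves every point
#' unchanged.
#'
#' @param theta_xy In-plane rotation angle (radians).
#' @param delta_xz,delta_yz Tilt slopes: um of z per um of x (resp. y).
#' @param tilt_offset Constant z offset (um) of the tilt plane.
#' @param rotation_center Point (x, y) about which the rotation is applied.
#' @param translation In-plane translation (x, y, um) applied after rotation.
#' @param bending A `bending_field` from [fit_bending_field()], or `NULL`
#'   for no bending correction.
#' @param markers Optional 2-column list of the measured/nominal marker sets
#'   the model was fit from (kept for provenance).
#' @param footprint Chip footprint `c(xmin, xmax, ymin, ymax)` (um), or
#'   `NULL` to disable the outside-footprint warning.
#' @param max_bending Largest admissible |bending| (um); default 70.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(theta_xy = 0, delta_xz = 0, delta_yz = 0,
                              tilt_offset = 0, rotation_center = c(0, 0),
                              translation = c(0, 0), bending = NULL,
                              markers = NULL, footprint = NULL,
                              max_bending = 70) {
  stopifnot(is.finite(theta_xy), is.finite(delta_xz), is.finite(delta_yz))
  if (!is.null(bending) && !inherits(bending, "bending_field"))
    stop("'bending' must be a bending_field or NULL", call. = FALSE)
  structure(list(theta_xy = theta_xy, delta_xz = delta_xz,
                 delta_yz = delta_yz, tilt_offset = tilt_offset,
                 rotation_center = as.numeric(rotation_center),
                 translation = as.numeric(translation),
                 bending = bending, markers = markers,
                 footprint = footprint, max_bending = max_bending),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("calibration_model: theta_xy = %.3g rad, ",
                     "delta_xz = %.3g, delta_yz = %.3g um/um, %s bending\n"),
              x$theta_xy, x$delta_xz, x$delta_yz,
              if (is.null(x$bending)) "no" else "with"))
  invisible(x)
}

#' Fit a calibration model from reference markers
#'
#' Estimates the calibration from paired marker observations: four corner
#' markers (M1..M4) whose nominal chip positions are known and whose actual
#' stage positions were measured before a run. The in-plane rotation and
#' translation are the least-squares rigid transform of the nominal onto the
#' measured (x, y); the tilt slopes are the plane fit of the z offset
#' (measured minus nominal z) over the corrected (x, y); any z residual left
#' after rotation and tilt removal seeds the substrate-bending field.
#'
#' @param measured,nominal Matrices (n x 3, n >= 3, typically 4) of marker
#'   coordinates (um), same row order.
#' @param bending_samples Optional extra data.frame/matrix with columns
#'   x, y, z of measured residual focal offsets across the chip (e.g. one per
#'   well) used to refine the bending field beyond the markers.
#' @param max_bending Largest admissible |bending| (um).
#' @return A [calibration_model].
#' @seealso [apply_corrections()], [fit_bending_field()]
#' @export
calibrate_from_markers <- function(measured, nominal, bending_samples = NULL,
                                   max_bending = 70) {
  measured <- as.matrix(measured); nominal <- as.matrix(nominal)
  if (!all(dim(measured) == dim(nominal)) || ncol(measured) != 3L ||
      nrow(measured) < 3L)
    stop("need matching n x 3 marker matrices with n >= 3", call. = FALSE)
  xy_n <- nominal[, 1:2, drop = FALSE]
  xy_m <- measured[, 1:2, drop = FALSE]
  c_n <- colMeans(xy_n); c_m <- colMeans(xy_m)
  a <- sweep(xy_n, 2, c_n); b <- sweep(xy_m, 2, c_m)
  if (svd(a)$d[2] < 1e-9 * max(1, svd(a)$d[1]))
    stop("markers are collinear: calibration geometry is degenerate",
         call. = FALSE)
  # closed-form 2-D least-squares rotation (Kabsch/Procrustes)
  theta <- atan2(sum(a[, 1] * b[, 2] - a[, 2] * b[, 1]),
                 sum(a[, 1] * b[, 1] + a[, 2] * b[, 2]))

  # tilt: plane fit of the z offset over the corrected in-plane position
  rot <- rot2(theta)
  xy_c <- sweep(a %*% t(rot), 2, c_m, "+")
  dz <- measured[, 3] - nominal[, 3]
  fit <- stats::lm.fit(cbind(1, xy_c), dz)
  coefs <- fit$coefficients
  resid <- fit$residuals

  bending <- NULL
  samp <- data.frame(x = xy_c[, 1], y = xy_c[, 2], z = resid)
  if (!is.null(bending_samples)) {
    bs <- as.data.frame(bending_samples)
    names(bs)[1:3] <- c("x", "y", "z")
    # residual bending at extra samples, after removing the fitted tilt plane
    bs$z <- bs$z - (coefs[1] + coefs[2] * bs$x + coefs[3] * bs$y)
    samp <- rbind(samp, bs[, c("x", "y", "z")])
  }
  if (any(abs(samp$z) > 1e-9))
    bending <- fit_bending_field(samp, max_bending = max_bending)

  # footprint in the corrected (stage) frame, with a small pad so the
  # markers themselves never graze the boundary check
  pad <- 1e-6 * max(1, diff(range(xy_m)))
  footprint <- c(min(xy_m[, 1]) - pad, max(xy_m[, 1]) + pad,
                 min(xy_m[, 2]) - pad, max(xy_m[, 2]) + pad)
  calibration_model(theta_xy = theta,
                    delta_xz = unname(coefs[2]), delta_yz = unname(coefs[3]),
                    tilt_offset = unname(coefs[1]),
                    rotation_center = c_n, translation = c_m - c_n,
                    bending = bending,
                    markers = list(measured = measured, nominal = nominal),
                    footprint = footprint, max_bending = max_bending)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Substrate bending field
#'
#' Interpolates measured residual focal offsets (after rotation and tilt
#' removal) into a smooth scalar field over the chip footprint. When the
#' samples form a regular rectangular grid the field is bilinear within the
#' grid with nearest-value (clamped) extrapolation at the edges; for
#' scattered samples an inverse-distance-squared interpolant is used. Both
#' schemes reproduce each sample exactly and stay within the sampled range,
#' so the field is bounded by `max_bending` whenever the samples are.
#'
#' @param samples Data frame or matrix with columns x, y (um) and z, the
#'   residual focal offset (um) at that point. At least 3 samples.
#' @param max_bending Largest admissible |z| (um); samples beyond it error.
#' @return An object of class `bending_field`; evaluate with
#'   [eval_bending()].
#' @export
fit_bending_field <- function(samples, max_bending = 70) {
  samples <- as.data.frame(samples)
  names(samples)[1:3] <- c("x", "y", "z")
  if (nrow(samples) < 3L)
    stop("need at least 3 bending samples", call. = FALSE)
  if (any(!is.finite(unlist(samples[, 1:3]))))
    stop("bending samples must be finite", call. = FALSE)
  if (any(abs(samples$z) > max_bending))
    stop("bending sample exceeds max_bending (", max_bending, " um)",
         call. = FALSE)
  xs <- sort(unique(samples$x)); ys <- sort(unique(samples$y))
  grid <- NULL
  if (length(xs) >= 2 && length(ys) >= 2 &&
      nrow(samples) == length(xs) * length(ys)) {
    key <- paste(samples$x, samples$y)
    full <- paste(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    if (setequal(key, full) && !anyDuplicated(key)) {
      z <- matrix(samples$z[match(full, key)], nrow = length(xs))
      grid <- list(xs = xs, ys = ys, z = z)
    }
  }
  structure(list(samples = samples, grid = grid, max_bending = max_bending),
            class = "bending_field")
}

#' @rdname fit_bending_field
#' @param field A `bending_field`.
#' @param x,y Coordinates (um) at which to evaluate; recycled together.
#' @export
eval_bending <- function(field, x, y) {
  stopifnot(inherits(field, "bending_field"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (!is.null(field$grid)) {
    g <- field$grid
    # clamp => nearest-value extrapolation beyond the sampled grid
    xc <- pmin(pmax(x, g$xs[1]), g$xs[length(g$xs)])
    yc <- pmin(pmax(y, g$ys[1]), g$ys[length(g$ys)])
    i <- pmin(findInterval(xc, g$xs), length(g$xs) - 1L)
    j <- pmin(findInterval(yc, g$ys), length(g$ys) - 1L)
    tx <- (xc - g$xs[i]) / (g$xs[i + 1L] - g$xs[i])
    ty <- (yc - g$ys[j]) / (g$ys[j + 1L] - g$ys[j])
    z00 <- g$z[cbind(i, j)];       z10 <- g$z[cbind(i + 1L, j)]
    z01 <- g$z[cbind(i, j + 1L)];  z11 <- g$z[cbind(i + 1L, j + 1L)]
    (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
      (1 - tx) * ty * z01 + tx * ty * z11
  } else {
    s <- field$samples
    vapply(seq_len(n), function(k) {
      d2 <- (s$x - x[k])^2 + (s$y - y[k])^2
      hit <- which(d2 < 1e-12)
      if (length(hit)) return(s$z[hit[1]])
      w <- 1 / d2
      sum(w * s$z) / sum(w)
    }, numeric(1))
  }
}

#' Apply calibration corrections to nominal stage coordinates
#'
#' Rotates the in-plane position by `theta_xy` about the model's rotation
#' centre (plus the fitted translation) and adjusts z by the tilt plane and
#' the bending field evaluated at the corrected (x, y). The identity model
#' returns its input unchanged. Points outside the chip footprint trigger a
#' warning and the bending field is evaluated at the nearest footprint edge.
#'
#' @param cal A [calibration_model].
#' @param xyz Numeric vector of length 3 or an n x 3 matrix (um).
#' @return Corrected coordinates, same shape as the input.
#' @export
apply_corrections <- function(cal, xyz) {
  stopifnot(inherits(cal, "calibration_model"))
  vec <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  xy <- sweep(xyz[, 1:2, drop = FALSE], 2, cal$rotation_center)
  xy <- sweep(xy %*% t(rot2(cal$theta_xy)), 2,
              cal$rotation_center + cal$translation, "+")
  if (!is.null(cal$footprint)) {
    fp <- cal$footprint
    outside <- xy[, 1] < fp[1] | xy[, 1] > fp[2] |
      xy[, 2] < fp[3] | xy[, 2] > fp[4]
    if (any(outside))
      warning(sum(outside), " point(s) outside the chip footprint; ",
              "bending extrapolated from the nearest edge", call. = FALSE)
  }
  z <- xyz[, 3] + cal$tilt_offset +
    cal$delta_xz * xy[, 1] + cal$delta_yz * xy[, 2]
  if (!is.null(cal$bending)) {
    bx <- xy[, 1]; by <- xy[, 2]
    if (!is.null(cal$footprint)) {
      fp <- cal$footprint
      bx <- pmin(pmax(bx, fp[1]), fp[2])
      by <- pmin(pmax(by, fp[3]), fp[4])
    }
    z <- z + eval_bending(cal$bending, bx, by)
  }
  out <- cbind(xy, z)
  colnames(out) <- c("x", "y", "z")
  if (vec) out[1, ] else out
}

#' @rdname calibration_model
#' @param cal A `calibration_model`.
#' @param path Destination YAML file.
#' @export
write_calibration <- function(cal, path) {
  obj <- list(theta_xy = cal$theta_xy, delta_xz = cal$delta_xz,
              delta_yz = cal$delta_yz, tilt_offset = cal$tilt_offset,
              rotation_center = cal$rotation_center,
              translation = cal$translation,
              footprint = cal$footprint, max_bending = cal$max_bending,
              bending_samples = if (!is.null(cal$bending))
                as.list(cal$bending$samples))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname calibration_model
#' @export
read_calibration <- function(path) {
  v <- yaml::read_yaml(path)
  bending <- NULL
  if (!is.null(v$bending_samples))
    bending <- fit_bending_field(as.data.frame(v$bending_samples),
                                 max_bending = v$max_bending)
  calibration_model(theta_xy = v$theta_xy, delta_xz = v$delta_xz,
                    delta_yz = v$delta_yz, tilt_offset = v$tilt_offset,
                    rotation_center = unlist(v$rotation_center),
                    translation = unlist(v$translation),
                    bending = bending,
                    footprint = if (!is.null(v$footprint)) unlist(v$footprint),
                    max_bending = v$max_bending)
}
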