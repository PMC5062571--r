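#' Chip layout for a multi-well C. elegans imaging chip
#'
#' Describes the geometry of a 96-well microfluidic immobilization chip:
#' parallel trapping channels grouped into camera fields of view (FOVs),
#' and the fluorescence z-stack acquired at each FOV. The default layout is
#' the full-scale screening chip: 8 x 12 wells spaced 9 mm apart, 40 parallel
#' traps per well at 150 um pitch, imaged as 4 FOVs of 10 channels each with
#' 15 z-planes at 5 um steps.
#'
#' @param n_rows,n_cols Number of well rows (lettered A..) and columns.
#' @param traps_per_well Number of parallel trapping channels per well.
#' @param fovs_per_well Number of camera fields of view tiling the traps.
#' @param channels_per_fov Trapping channels covered by one FOV.
#' @param channel_pitch Centre-to-centre spacing of parallel channels (um).
#' @param z_planes Number of z-planes per stack.
#' @param z_step Axial step between planes (um).
#' @param fov_extent Side length of the (square) FOV (um).
#' @param well_pitch Centre-to-centre well spacing (um).
#' @return An object of class `chip_layout`.
#' @examples
#' layout <- chip_layout()
#' n_traps(layout)        # 3840
#' @export
chip_layout <- function(n_rows = 8L, n_cols = 12L, traps_per_well = 40L,
                        fovs_per_well = 4L, channels_per_fov = 10L,
                        channel_pitch = 150, z_planes = 15L, z_step = 5,
                        fov_extent = 1500, well_pitch = 9000) {
  layout <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    traps_per_well = as.integer(traps_per_well),
    fovs_per_well = as.integer(fovs_per_well),
    channels_per_fov = as.integer(channels_per_fov),
    channel_pitch = as.numeric(channel_pitch),
    z_planes = as.integer(z_planes), z_step = as.numeric(z_step),
    fov_extent = as.numeric(fov_extent), well_pitch = as.numeric(well_pitch)
  ), class = "chip_layout")
  validate_chip_layout(layout)
}

validate_chip_layout <- function(layout) {
  counts <- c(layout$n_rows, layout$n_cols, layout$traps_per_well,
              layout$fovs_per_well, layout$channels_per_fov, layout$z_planes)
  if (any(!is.finite(counts)) || any(counts < 1L))
    stop("all layout counts must be >= 1", call. = FALSE)
  if (layout$traps_per_well != layout$fovs_per_well * layout$channels_per_fov)
    stop("traps_per_well must equal fovs_per_well * channels_per_fov",
         call. = FALSE)
  pitches <- c(layout$channel_pitch, layout$z_step, layout$fov_extent,
               layout$well_pitch)
  if (any(!is.finite(pitches)) || any(pitches <= 0))
    stop("all pitches and extents must be positive", call. = FALSE)
  layout
}

#' @rdname chip_layout
#' @param layout A `chip_layout`.
#' @export
n_traps <- function(layout) {
  layout$n_rows * layout$n_cols * layout$traps_per_well
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("chip_layout: %d x %d wells (%.1f mm pitch), %d traps/well\n",
              x$n_rows, x$n_cols, x$well_pitch / 1000, x$traps_per_well))
  cat(sprintf("  %d FOVs/well x %d channels (%.0f um pitch), %d z-planes at %.0f um\n",
              x$fovs_per_well, x$channels_per_fov, x$channel_pitch,
              x$z_planes, x$z_step))
  invisible(x)
}

#' Well addressing on a plate-format chip
#'
#' Wells are addressed row letter + zero-padded column, `"A01"` .. `"H12"` on
#' the default 8 x 12 layout, enumerated row-major (A01, A02, ..., H12).
#'
#' @param layout A `chip_layout`.
#' @return `well_labels()` returns the full ordered vector of labels;
#'   `well_address()` a data.frame with columns `row`, `col`, `label`.
#' @export
well_labels <- function(layout = chip_layout()) {
  rows <- LETTERS[seq_len(layout$n_rows)]
  as.vector(t(outer(rows, seq_len(layout$n_cols),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' @rdname well_labels
#' @param label Character vector of well labels such as `"A01"`.
#' @export
well_address <- function(label, layout = chip_layout()) {
  label <- toupper(as.character(label))
  if (!all(grepl("^[A-Z][0-9]{2}$", label)))
    stop("well labels must look like 'A01'", call. = FALSE)
  row <- match(substr(label, 1, 1), LETTERS)
  col <- as.integer(substr(label, 2, 3))
  bad <- row > layout$n_rows | col < 1L | col > layout$n_cols | is.na(row)
  if (any(bad))
    stop("well label(s) outside layout: ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  data.frame(row = row, col = col, label = label, stringsAsFactors = FALSE)
}

# Chip-frame centre of a well; origin at the centre of well A01,
# x along increasing column number, y along increasing row letter.
well_center <- function(row, col, layout) {
  cbind(x = (col - 1) * layout$well_pitch, y = (row - 1) * layout$well_pitch)
}

# Across-channel offset (x, um) of the centre of FOV `fov` (0-based) from the
# well centre. FOV f covers channels [f*cpf, (f+1)*cpf); channel i (0-based)
# sits at (i - (traps-1)/2) * pitch from the well centre.
fov_offset_x <- function(fov, layout) {
  cpf <- layout$channels_per_fov
  (fov * cpf + (cpf - 1) / 2 - (layout$traps_per_well - 1) / 2) *
    layout$channel_pitch
}

#' Enumerate the acquisition events of an imaging run
#'
#' Expands a set of wells into the full ordered list of single-image
#' acquisition events: one event per (well, FOV, z-plane), ordered well-major
#' (row-major A01 -> H12), then FOV, then z. Nominal stage coordinates follow
#' the layout pitches with the chip origin at the centre of well A01; the
#' z-stack is centred on `focal_z`. When a [calibration_model] is supplied the
#' nominal coordinates are additionally mapped through [apply_corrections()].
#'
#' The default full layout yields 96 x 4 x 15 = 5760 events.
#'
#' @param layout A `chip_layout`.
#' @param wells Character vector of well labels; defaults to every well.
#' @param calibration Optional `calibration_model`; `NULL` means identity.
#' @param focal_z Nominal best-focus z (um) at which the stack is centred.
#' @return A data.frame with one row per event: `well`, `fov`, `z` (0-based
#'   indices) and `nominal_x/y/z`, `corrected_x/y/z` (um).
#' @examples
#' plan <- enumerate_acquisitions(chip_layout())
#' nrow(plan)   # 5760
#' @export
enumerate_acquisitions <- function(layout = chip_layout(),
                                   wells = well_labels(layout),
                                   calibration = NULL, focal_z = 0) {
  if (length(wells) == 0L)
    stop("'wells' must contain at least one well", call. = FALSE)
  addr <- well_address(unique(wells), layout)
  # keep row-major chip order regardless of input order
  addr <- addr[order(addr$row, addr$col), , drop = FALSE]
  fovs <- seq_len(layout$fovs_per_well) - 1L
  zs <- seq_len(layout$z_planes) - 1L

  grid <- expand.grid(z = zs, fov = fovs, well = addr$label,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("well", "fov", "z")]
  i <- match(grid$well, addr$label)
  wc <- well_center(addr$row[i], addr$col[i], layout)
  nominal_x <- wc[, "x"] + fov_offset_x(grid$fov, layout)
  nominal_y <- wc[, "y"]
  nominal_z <- focal_z + (grid$z - (layout$z_planes - 1) / 2) * layout$z_step

  out <- data.frame(grid,
                    nominal_x = nominal_x, nominal_y = nominal_y,
                    nominal_z = nominal_z, stringsAsFactors = FALSE)
  if (is.null(calibration)) {
    out$corrected_x <- out$nominal_x
    out$corrected_y <- out$nominal_y
    out$corrected_z <- out$nominal_z
  } else {
    corr <- apply_corrections(calibration,
                              cbind(out$nominal_x, out$nominal_y, out$nominal_z))
    out$corrected_x <- corr[, 1]
    out$corrected_y <- corr[, 2]
    out$corrected_z <- corr[, 3]
  }
  rownames(out) <- NULL
  out
}

#' Read and write acquisition plans and chip layouts
#'
#' Acquisition plans are exchanged as plain CSV with the columns produced by
#' [enumerate_acquisitions()]; layouts serialize to YAML.
#'
#' @param plan Data frame from [enumerate_acquisitions()].
#' @param path Destination file.
#' @export
write_acquisition_plan <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_acquisition_plan
#' @export
read_acquisition_plan <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_acquisition_plan
#' @param layout A `chip_layout`.
#' @export
write_chip_layout <- function(layout, path) {
  yaml::write_yaml(unclass(layout), path)
  invisible(path)
}

#' @rdname write_acquisition_plan
#' @export
read_chip_layout <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(chip_layout, vals)
}
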