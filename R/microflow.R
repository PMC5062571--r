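#' Hydraulic resistance of a rectangular microchannel segment
#'
#' Laminar, fully developed flow in a rectangular duct, using the standard
#' low-aspect-ratio approximation
#' \deqn{R = \frac{12 \mu L}{w h^3 (1 - 0.63\, h/w)}, \quad w \ge h,}
#' with width and height swapped when `width < height` (the formula requires
#' the wide dimension in the denominator). Accurate to ~13% even for a square
#' duct and much better for flat channels. Units: dimensions in um, viscosity
#' in Pa s, resistance in Pa s / um^3 (so that pressure in Pa over resistance
#' gives a volumetric flow in um^3/s).
#'
#' @param length,width,height Segment dimensions (um).
#' @param viscosity Dynamic viscosity (Pa s); default water, 1e-3.
#' @return Resistance (Pa s / um^3), linear in `length` and `viscosity`.
#' @examples
#' segment_resistance(1000, 100, 50)
#' @export
segment_resistance <- function(length, width, height, viscosity = 1e-3) {
  if (any(c(length, width, height) <= 0) || any(viscosity <= 0))
    stop("channel dimensions and viscosity must be positive", call. = FALSE)
  w <- pmax(width, height)
  h <- pmin(width, height)
  12 * viscosity * length / (w * h^3 * (1 - 0.63 * h / w))
}

#' Hydraulic network of a chip's trap and exit channels
#'
#' A network is a set of labelled pressure nodes connected by rectangular
#' channel segments, the hydraulic analogue of a resistor circuit: the single
#' inlet node carries the common gasket pressure and the single exit node is
#' at atmospheric reference (gauge 0). Branch resistances are computed from
#' the segment dimensions with [segment_resistance()]; a `multiplicity`
#' column models k identical channels in parallel (resistance / k), e.g. a
#' well's 40-trap array as one lumped branch.
#'
#' @param branches Data frame with columns `id`, `from`, `to`, `length`,
#'   `width`, `height`, and optionally `viscosity` (Pa s, default 1e-3) and
#'   `multiplicity` (default 1).
#' @param inlet,outlet Node labels of the pressure inlet and the exit port.
#' @return An object of class `hydraulic_network`.
#' @seealso [solve_flows()], [optimize_exit_widths()], [chip_exit_network()]
#' @export
hydraulic_network <- function(branches, inlet, outlet) {
  branches <- as.data.frame(branches)
  need <- c("id", "from", "to", "length", "width", "height")
  if (!all(need %in% names(branches)))
    stop("branches need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(branches$viscosity)) branches$viscosity <- 1e-3
  if (is.null(branches$multiplicity)) branches$multiplicity <- 1
  if (anyDuplicated(branches$id))
    stop("branch ids must be unique", call. = FALSE)
  branches$resistance <- segment_resistance(
    branches$length, branches$width, branches$height,
    branches$viscosity) / branches$multiplicity
  nodes <- unique(c(branches$from, branches$to, inlet, outlet))
  if (!inlet %in% c(branches$from, branches$to) ||
      !outlet %in% c(branches$from, branches$to))
    stop("inlet and outlet must appear in the branch list", call. = FALSE)
  net <- structure(list(branches = branches, nodes = nodes,
                        inlet = inlet, outlet = outlet),
                   class = "hydraulic_network")
  if (!all(reachable_nodes(net) == TRUE))
    stop("network is disconnected", call. = FALSE)
  net
}

reachable_nodes <- function(net) {
  adj <- rbind(net$branches[, c("from", "to")],
               stats::setNames(net$branches[, c("to", "from")],
                               c("from", "to")))
  seen <- net$inlet
  repeat {
    nxt <- unique(adj$to[adj$from %in% seen])
    new <- setdiff(nxt, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  stats::setNames(net$nodes %in% seen, net$nodes)
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat(sprintf("hydraulic_network: %d branches, %d nodes (%s -> %s)\n",
              nrow(x$branches), length(x$nodes), x$inlet, x$outlet))
  invisible(x)
}

#' Solve branch flows and node pressures of a hydraulic network
#'
#' Nodal analysis of the equivalent resistor circuit: the inlet node is held
#' at `inlet_pressure` (gauge), the exit node at 0, and interior node
#' pressures are solved from flow conservation (the hydraulic Kirchhoff
#' current law). Branch flows follow as pressure drop over resistance.
#'
#' @param net A [hydraulic_network].
#' @param inlet_pressure Gasket pressure at the inlet node (Pa, gauge).
#' @return A list of class `flow_solution` with `node_pressures` (named, Pa)
#'   and `branches`, the branch table augmented with `pressure_drop` (Pa,
#'   from - to) and `flow` (um^3/s, positive from -> to).
#' @export
solve_flows <- function(net, inlet_pressure) {
  stopifnot(inherits(net, "hydraulic_network"))
  b <- net$branches
  if (any(!is.finite(b$resistance)) || any(b$resistance <= 0))
    stop("all branch resistances must be positive and finite", call. = FALSE)
  nodes <- net$nodes
  g <- 1 / b$resistance
  n <- length(nodes)
  lap <- matrix(0, n, n, dimnames = list(nodes, nodes))
  fi <- match(b$from, nodes); ti <- match(b$to, nodes)
  for (k in seq_along(g)) {
    lap[fi[k], fi[k]] <- lap[fi[k], fi[k]] + g[k]
    lap[ti[k], ti[k]] <- lap[ti[k], ti[k]] + g[k]
    lap[fi[k], ti[k]] <- lap[fi[k], ti[k]] - g[k]
    lap[ti[k], fi[k]] <- lap[ti[k], fi[k]] - g[k]
  }
  p <- stats::setNames(numeric(n), nodes)
  p[net$inlet] <- inlet_pressure
  interior <- setdiff(nodes, c(net$inlet, net$outlet))
  if (length(interior)) {
    rhs <- -lap[interior, c(net$inlet, net$outlet), drop = FALSE] %*%
      c(inlet_pressure, 0)
    p[interior] <- solve(lap[interior, interior, drop = FALSE], rhs)
  }
  b$pressure_drop <- p[b$from] - p[b$to]
  b$flow <- b$pressure_drop / b$resistance
  structure(list(node_pressures = p, branches = b,
                 inlet = net$inlet, outlet = net$outlet,
                 inlet_pressure = inlet_pressure),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d branches at P1 = %g Pa; total flow %.4g um^3/s\n",
              nrow(x$branches), x$inlet_pressure, total_flow(x)))
  invisible(x)
}

#' @rdname solve_flows
#' @param sol A `flow_solution`.
#' @return `total_flow()`: the net flow leaving the inlet node (Q_0, um^3/s).
#' @export
total_flow <- function(sol) {
  b <- sol$branches
  sum(b$flow[b$from == sol$inlet]) - sum(b$flow[b$to == sol$inlet])
}

#' Representative trap-and-exit ladder network of one chip repeating unit
#'
#' Builds the equivalent circuit of one repeating unit of the chip: four
#' wells (A closest to the far end, D closest to the exit port), each lumping
#' a parallel array of identical trapping channels, draining through its own
#' exit branch (R_A .. R_D) into consecutive junctions of a shared main exit
#' line whose sections (R_23, R_34, R_45, R_50) lead to the exit port.
#' Because the wells sit at different distances from the exit, equal exit
#' widths give unequal well flows; see [optimize_exit_widths()].
#'
#' Dimensions are representative defaults, not fabricated values.
#'
#' @param traps_per_well Parallel trapping channels lumped per well.
#' @param trap_dims,exit_dims,main_dims Length/width/height (um) of the trap
#'   channels, the per-well exit branches, and the main exit-line sections.
#' @param main_lengths Lengths (um) of the four main-line sections R_23,
#'   R_34, R_45, R_50.
#' @return A [hydraulic_network] with inlet `"P1"` and outlet `"P0"`.
#' @export
chip_exit_network <- function(traps_per_well = 40,
                              trap_dims = c(length = 2000, width = 60,
                                            height = 50),
                              exit_dims = c(length = 4000, width = 150,
                                            height = 80),
                              main_dims = c(width = 400, height = 80),
                              main_lengths = c(9000, 9000, 9000, 4000)) {
  wells <- c("A", "B", "C", "D")
  junctions <- c("n2", "n3", "n4", "n5")
  traps <- data.frame(
    id = paste0("traps_", wells), from = "P1", to = paste0("w", wells),
    length = trap_dims[["length"]], width = trap_dims[["width"]],
    height = trap_dims[["height"]], multiplicity = traps_per_well)
  exits <- data.frame(
    id = paste0("R_", wells), from = paste0("w", wells), to = junctions,
    length = exit_dims[["length"]], width = exit_dims[["width"]],
    height = exit_dims[["height"]], multiplicity = 1)
  mains <- data.frame(
    id = c("R_23", "R_34", "R_45", "R_50"),
    from = junctions, to = c(junctions[-1], "P0"),
    length = main_lengths,
    width = main_dims[["width"]], height = main_dims[["height"]],
    multiplicity = 1)
  hydraulic_network(rbind(traps, exits, mains), inlet = "P1", outlet = "P0")
}

#' Equalize well flows by adjusting exit-channel widths
#'
#' Wells at different distances from the exit port see different series
#' resistance along the main exit line, so equal exit-channel widths produce
#' unequal loading flows. This optimizer widens or narrows the per-well exit
#' branches (bounded coordinate descent, one 1-D root solve per branch and
#' pass) until the relative spread (max - min) / mean of the well flows falls
#' below `tolerance`. Branches far from the exit end up wider.
#'
#' @param net A [hydraulic_network]; adjustable branches must carry their
#'   segment dimensions so width changes re-derive their resistance.
#' @param adjustable Character vector of branch ids whose widths may change.
#' @param inlet_pressure Gasket pressure (Pa) at which flows are matched.
#' @param bounds Width bounds (um) for every adjustable branch.
#' @param tolerance Target relative flow spread; default 0.01 (1%).
#' @param max_passes Maximum coordinate-descent passes.
#' @return A list with `widths` (named, um), `spread` (achieved relative
#'   spread), `converged`, `flows` (named well flows at the optimum), and
#'   `network` (the updated [hydraulic_network]). If the tolerance cannot be
#'   met within bounds the best-achieved spread is reported with
#'   `converged = FALSE`.
#' @export
optimize_exit_widths <- function(net, adjustable, inlet_pressure = 1000,
                                 bounds = c(20, 2000), tolerance = 0.01,
                                 max_passes = 60) {
  stopifnot(inherits(net, "hydraulic_network"), tolerance > 0)
  idx <- match(adjustable, net$branches$id)
  if (anyNA(idx))
    stop("unknown adjustable branch id(s)", call. = FALSE)

  branch_flows <- function(n) {
    sol <- solve_flows(n, inlet_pressure)
    stats::setNames(abs(sol$branches$flow[match(adjustable,
                                                sol$branches$id)]),
                    adjustable)
  }
  set_width <- function(n, id, w) {
    i <- match(id, n$branches$id)
    n$branches$width[i] <- w
    n$branches$resistance[i] <- segment_resistance(
      n$branches$length[i], w, n$branches$height[i],
      n$branches$viscosity[i]) / n$branches$multiplicity[i]
    n
  }
  spread_of <- function(q) (max(q) - min(q)) / mean(q)

  q <- branch_flows(net)
  best <- list(net = net, spread = spread_of(q), q = q)
  pass <- 0L
  while (best$spread > tolerance && pass < max_passes) {
    pass <- pass + 1L
    target <- mean(branch_flows(net))
    for (id in adjustable) {
      f <- function(w) branch_flows(set_width(net, id, w))[[id]] - target
      flo <- f(bounds[1]); fhi <- f(bounds[2])
      w_new <- if (flo > 0) bounds[1]
        else if (fhi < 0) bounds[2]
        else stats::uniroot(f, bounds, tol = 1e-4)$root
      net <- set_width(net, id, w_new)
    }
    q <- branch_flows(net)
    s <- spread_of(q)
    if (s < best$spread) best <- list(net = net, spread = s, q = q)
  }
  widths <- stats::setNames(
    best$net$branches$width[match(adjustable, best$net$branches$id)],
    adjustable)
  list(widths = widths, spread = best$spread,
       converged = best$spread <= tolerance, flows = best$q,
       network = best$net)
}

#' Read and write hydraulic networks and flow solutions
#'
#' Networks serialize to YAML (branch table plus inlet/outlet labels); flow
#' solutions export to CSV with one row per branch.
#'
#' @param net A [hydraulic_network].
#' @param path Destination file.
#' @export
write_network <- function(net, path) {
  yaml::write_yaml(list(inlet = net$inlet, outlet = net$outlet,
                        branches = as.list(net$branches[
                          , c("id", "from", "to", "length", "width",
                              "height", "viscosity", "multiplicity")])),
                   path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  v <- yaml::read_yaml(path)
  hydraulic_network(as.data.frame(v$branches), inlet = v$inlet,
                    outlet = v$outlet)
}

#' @rdname write_network
#' @param sol A `flow_solution` from [solve_flows()].
#' @export
write_flow_solution <- function(sol, path) {
  utils::write.csv(sol$branches[, c("id", "from", "to", "resistance",
                                    "pressure_drop", "flow")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
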