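#' @include AllClasses.R
NULL

#' Build a resistor network for the stimulation chamber
#'
#' Each edge is either a plain resistor (`resistance` in ohms) or a physical
#' channel section carrying a [ChannelGeometry-class], whose resistance is
#' computed from `medium` by [channelResistance()]. Parallel edges between
#' the same pair of nodes are allowed (a current divider).
#'
#' @param edges data.frame with columns `from`, `to` and either `resistance`
#'   or `NA` where a geometry applies; optional `label`.
#' @param source list or named vector with `from`, `to` and `current`
#'   (amperes): the drive current enters at `from` and exits at `to`.
#' @param geometries named list of [ChannelGeometry-class] objects keyed by
#'   edge label.
#' @param medium an [Electrolyte-class]; required when `geometries` is
#'   non-empty.
#' @return a [ResistorNetwork-class].
#' @export
ResistorNetwork <- function(edges, source, geometries = list(), medium = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$label)) edges$label <- NA_character_
  if (is.null(edges$resistance)) edges$resistance <- NA_real_
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  edges$label <- as.character(edges$label)
  if (length(geometries)) {
    if (is.null(medium)) stop("geometry-bearing edges need an Electrolyte")
    for (lab in names(geometries)) {
      idx <- which(edges$label == lab)
      if (length(idx) != 1L) stop("geometry label '", lab, "' must match exactly one edge")
      edges$resistance[idx] <- channelResistance(geometries[[lab]], medium)
    }
  }
  if (anyNA(edges$resistance))
    stop("every edge needs a resistance or a geometry")
  new("ResistorNetwork", edges = edges, geometries = geometries,
      source = list(from = as.character(source[["from"]]),
                    to = as.character(source[["to"]]),
                    current = as.numeric(source[["current"]])))
}

#' Solve branch currents by nodal analysis
#'
#' Builds the node conductance matrix (the graph Laplacian weighted by 1/R),
#' grounds the source exit node, injects the source current, and solves for
#' node potentials. Branch currents are signed along each edge's `from -> to`
#' direction. Kirchhoff's current law holds at every node to solver
#' tolerance and the full source current is conserved end to end.
#'
#' @param net a [ResistorNetwork-class].
#' @return the edge data.frame with added columns `current` (A) and
#'   `voltage` (V, drop from `from` to `to`); node potentials as attribute
#'   `"potentials"`.
#' @export
solveNetwork <- function(net) {
  stopifnot(is(net, "ResistorNetwork"))
  validObject(net)
  ed <- net@edges
  nodes <- unique(c(ed$from, ed$to))
  n <- length(nodes)
  gi <- match(ed$from, nodes); gj <- match(ed$to, nodes)
  g <- 1 / ed$resistance
  G <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_along(g)) {
    G[gi[k], gi[k]] <- G[gi[k], gi[k]] + g[k]
    G[gj[k], gj[k]] <- G[gj[k], gj[k]] + g[k]
    G[gi[k], gj[k]] <- G[gi[k], gj[k]] - g[k]
    G[gj[k], gi[k]] <- G[gj[k], gi[k]] - g[k]
  }
  inj <- setNames(numeric(n), nodes)
  inj[net@source$from] <- net@source$current
  inj[net@source$to] <- -net@source$current
  keep <- nodes != net@source$to           # ground the exit terminal
  Gr <- G[keep, keep, drop = FALSE]
  v <- setNames(numeric(n), nodes)
  sol <- tryCatch(solve(Gr, inj[keep]),
                  error = function(e) stop("singular network system: ",
                                           conditionMessage(e)))
  v[keep] <- sol
  ed$voltage <- v[ed$from] - v[ed$to]
  ed$current <- ed$voltage / ed$resistance
  attr(ed, "potentials") <- v
  ed
}

#' Per-section electric fields of a solved chamber
#'
#' Converts the branch current through every geometry-bearing edge (the
#' stimulation sections) into a field via `E = i / (sigma * w * h)`.
#'
#' @param net a [ResistorNetwork-class] with at least one geometry edge.
#' @param medium an [Electrolyte-class].
#' @param sections optional character vector selecting/ordering section
#'   labels; defaults to all geometry labels in network order.
#' @return named numeric vector of fields in V/m (= mV/mm).
#' @export
sectionFields <- function(net, medium, sections = NULL) {
  stopifnot(is(net, "ResistorNetwork"), is(medium, "Electrolyte"))
  sol <- solveNetwork(net)
  labs <- names(net@geometries)
  if (!length(labs)) stop("network has no geometry-bearing sections")
  if (is.null(sections)) sections <- labs
  missing <- setdiff(sections, labs)
  if (length(missing))
    stop("unknown section label(s): ", paste(missing, collapse = ", "))
  vapply(sections, function(lab) {
    i_br <- abs(sol$current[sol$label == lab])
    fieldFromCurrent(i_br, net@geometries[[lab]], medium)
  }, numeric(1))
}

#' Read a chamber description from a YAML/JSON config
#'
#' Expected structure: `electrolyte: {sigma}`, `source: {from, to, current}`,
#' `edges:` a list of `{from, to, resistance}` or
#' `{from, to, label, geometry: {length, width, height}}` entries (SI units
#' throughout), and optionally `electrode: {diameter, capacitance,
#' voltage_window}`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return list with `network` ([ResistorNetwork-class]), `electrolyte`
#'   ([Electrolyte-class]) and `electrode` ([ElectrodeSpec-class] or NULL).
#' @export
readChamberConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (is.null(cfg$electrolyte$sigma)) stop("config needs electrolyte: {sigma}")
  medium <- Electrolyte(cfg$electrolyte$sigma)
  geoms <- list()
  ed <- do.call(rbind, lapply(cfg$edges, function(e) {
    data.frame(from = e$from, to = e$to,
               resistance = if (is.null(e$resistance)) NA_real_ else e$resistance,
               label = if (is.null(e$label)) NA_character_ else e$label,
               stringsAsFactors = FALSE)
  }))
  for (e in cfg$edges) {
    if (!is.null(e$geometry)) {
      if (is.null(e$label)) stop("geometry edges need a label")
      geoms[[e$label]] <- ChannelGeometry(e$geometry$length, e$geometry$width,
                                          e$geometry$height, e$label)
    }
  }
  net <- ResistorNetwork(ed, cfg$source, geometries = geoms, medium = medium)
  electrode <- NULL
  if (!is.null(cfg$electrode))
    electrode <- ElectrodeSpec(cfg$electrode$diameter,
      if (is.null(cfg$electrode$capacitance)) NA_real_ else cfg$electrode$capacitance,
      if (is.null(cfg$electrode$voltage_window)) NA_real_ else cfg$electrode$voltage_window)
  list(network = net, electrolyte = medium, electrode = electrode)
}

#' Field and charge dose report for a chamber at a given current
#'
#' Convenience wrapper: rescales the configured network to `current`, solves
#' it, and reports per-section fields plus the charge budget of the supplied
#' protocol and, when the electrode is parameterized, the disk current
#' density and the capacitive window.
#'
#' @param config result of [readChamberConfig()] or a path to a config file.
#' @param current drive current in amperes; defaults to the config's source
#'   current.
#' @param protocol optional [StimulationProtocol-class].
#' @return list with `fields_V_per_m`, `branch_currents`, and when available
#'   `charge_C`, `current_density_A_per_m2`, `capacitive_window_s`.
#' @export
doseReport <- function(config, current = NULL, protocol = NULL) {
  if (is.character(config)) config <- readChamberConfig(config)
  net <- config$network
  if (!is.null(current)) net@source$current <- current
  out <- list(fields_V_per_m = sectionFields(net, config$electrolyte),
              branch_currents = solveNetwork(net))
  if (!is.null(protocol)) out$charge_C <- deliveredCharge(protocol)
  el <- config$electrode
  if (!is.null(el)) {
    out$current_density_A_per_m2 <- diskCurrentDensity(net@source$current, el)
    if (!is.na(el@capacitance) && !is.na(el@voltageWindow))
      out$capacitive_window_s <- capacitiveDischargeTime(el, net@source$current)
  }
  out
}
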