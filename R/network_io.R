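#' Read an arterial network from a YAML file
#'
#' The schema is documented in the packaged example files (see
#' `system.file("extdata", package = "mtflow")`): a `fluid` block; one
#' record per vessel (name, length, `A0` or `radius`, `h0`, `E`, optional
#' `nu`, `Pext`, `M`); one record per junction (`kind` and `ends` given as
#' `"vessel:proximal"` / `"vessel:distal"` strings); one record per boundary
#' (`inlet`, `windkessel`, `flow` or `reflect` with their parameters);
#' optional `sites` and `symmetry` maps. All values are SI (the `units`
#' header must be `"SI"`).
#'
#' @param file path to a YAML network description.
#' @return a validated `arterial_network`.
#' @export
load_network <- function(file) {
  doc <- yaml::read_yaml(file)
  if (!is.null(doc$units) && !identical(doc$units, "SI"))
    stop("network file declares units '", doc$units, "'; only SI is supported")
  fl <- doc$fluid
  fluid <- fluid_properties(
    density = fl$density %||% 1060,
    viscosity = fl$viscosity %||% 4e-3,
    gamma_v = fl$gamma_v %||% 2,
    alpha = fl$alpha %||% (4 / 3))
  vessels <- lapply(doc$vessels, function(v) {
    if (is.null(v$name)) stop("vessel record without a name")
    vessel_segment(v$name, L = v$length, A0 = v$A0, radius = v$radius,
                   h0 = v$h0, E = v$E, nu = v$nu %||% 0.5,
                   Pext = v$Pext %||% 0, M = v$M)
  })
  junctions <- lapply(doc$junctions, function(j) {
    ends <- lapply(j$ends, parse_end)
    list(kind = j$kind, ends = ends)
  })
  boundaries <- lapply(doc$boundaries, function(b) {
    params <- switch(b$type,
      inlet = inlet_waveform(peak_flow = b$peak_flow %||% 3.5e-4,
                             systole = b$systole %||% 0.3,
                             period = b$period %||% 1.0,
                             scale = b$scale %||% 1.0),
      windkessel = windkessel3(R1 = b$R1, R2 = b$R2, C = b$C,
                               Pout = b$Pout %||% 0,
                               Pc = b$Pc %||% b$Pout %||% 0),
      flow = list(q = b$q),
      reflect = NULL,
      stop("boundary for ", b$vessel, " has unknown type '", b$type, "'"))
    list(vessel = b$vessel, end = b$end, type = b$type, params = params)
  })
  sites <- lapply(doc$sites %||% list(), function(s) {
    if (is.character(s) && length(s) == 1L) parse_end(s, default_end = "distal")
    else s
  })
  symmetry <- unlist(doc$symmetry %||% list())
  arterial_network(vessels, junctions, boundaries, sites, symmetry, fluid)
}

parse_end <- function(x, default_end = NULL) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    if (is.null(default_end)) stop("end spec '", x, "' lacks :proximal/:distal")
    return(list(vessel = parts[1], end = default_end))
  }
  if (!parts[2] %in% c("proximal", "distal"))
    stop("end spec '", x, "' must use :proximal or :distal")
  list(vessel = parts[1], end = parts[2])
}

fmt_end <- function(e) paste0(e$vessel, ":", e$end)

#' Write an arterial network to a YAML file
#'
#' Inverse of [load_network()]: `load_network(write_network(net, f))`
#' reproduces the network semantically.
#'
#' @param net an `arterial_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file) {
  doc <- list(
    units = "SI",
    fluid = list(density = net$fluid$density,
                 viscosity = net$fluid$viscosity,
                 gamma_v = net$fluid$gamma_v,
                 alpha = net$fluid$alpha),
    vessels = lapply(unname(net$vessels), function(v)
      list(name = v$name, length = v$L, A0 = v$A0, h0 = v$h0, E = v$E,
           nu = v$nu, Pext = v$Pext, M = v$M)),
    junctions = lapply(net$junctions, function(j)
      list(kind = j$kind, ends = vapply(j$ends, fmt_end, character(1)))),
    boundaries = lapply(net$boundaries, function(b) {
      rec <- list(vessel = b$vessel, end = b$end, type = b$type)
      p <- b$params
      if (b$type == "inlet")
        rec <- c(rec, list(peak_flow = p$peak_flow, systole = p$systole,
                           period = p$period, scale = p$scale))
      if (b$type == "windkessel")
        rec <- c(rec, list(R1 = p$R1, R2 = p$R2, C = p$C, Pout = p$Pout))
      if (b$type == "flow") rec <- c(rec, list(q = p$q))
      rec
    }))
  if (length(net$sites))
    doc$sites <- lapply(net$sites, fmt_end)
  if (length(net$symmetry))
    doc$symmetry <- as.list(net$symmetry)
  yaml::write_yaml(doc, file, precision = 15L)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
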