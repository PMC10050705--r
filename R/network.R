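#' Assemble an arterial network
#'
#' An arterial network is a directed graph of [vessel_segment()]s joined at
#' junctions (conjunctions 1-to-1, bifurcations 1-to-2, anastomoses 2-to-1),
#' with every free vessel end carrying a boundary model (inlet waveform,
#' three-element windkessel, prescribed flow, or a zero-flow reflector).
#' Positive flow in a vessel runs proximal to distal.
#'
#' @param vessels list of [vessel_segment()] objects.
#' @param junctions list of junctions; each is `list(kind =, ends =)` where
#'   `kind` is one of `"conjunction"`, `"bifurcation"`, `"anastomosis"` and
#'   `ends` is a list of `list(vessel = <name>, end = "proximal"|"distal")`.
#' @param boundaries list of boundary attachments; each is
#'   `list(vessel =, end =, type =, params =)` with `type` one of
#'   `"inlet"` (params: an [inlet_waveform()]), `"windkessel"` (params: a
#'   [windkessel3()]), `"flow"` (params: `list(q = <m^3/s>)`, positive along
#'   +z), or `"reflect"` (zero-flow, full wave reflector; no params).
#' @param sites named list mapping anatomical labels (e.g. `"MCA"`,
#'   `"ICApp"`, `"brachial"`) to `list(vessel =, end =)`; `end` defaults to
#'   `"distal"`.
#' @param symmetry named character vector pairing left/right homologous
#'   vessel names (an involution).
#' @param fluid a [fluid_properties()].
#' @param validate run [validate_network()] on the result.
#' @return an object of class `arterial_network`.
#' @export
arterial_network <- function(vessels, junctions = list(), boundaries = list(),
                             sites = list(), symmetry = character(),
                             fluid = fluid_properties(), validate = TRUE) {
  names(vessels) <- vapply(vessels, function(v) v$name, character(1))
  sites <- lapply(sites, function(s) {
    if (is.character(s)) s <- list(vessel = s)
    if (is.null(s$end)) s$end <- "distal"
    s
  })
  net <- structure(list(vessels = vessels, junctions = junctions,
                        boundaries = boundaries, sites = sites,
                        symmetry = symmetry, fluid = fluid),
                   class = "arterial_network")
  if (validate) validate_network(net)
  net
}

end_key <- function(vessel, end) paste0(vessel, ":", end)

#' All vessel-end attachments of a network
#'
#' @param net an `arterial_network`.
#' @return data.frame with columns vessel, end, kind ("junction" or boundary
#'   type) and index into the junction/boundary list.
#' @keywords internal
attachment_table <- function(net) {
  rows <- list()
  for (j in seq_along(net$junctions)) {
    jn <- net$junctions[[j]]
    for (e in jn$ends)
      rows[[length(rows) + 1L]] <- data.frame(
        vessel = e$vessel, end = e$end, kind = "junction", index = j,
        stringsAsFactors = FALSE)
  }
  for (b in seq_along(net$boundaries)) {
    bd <- net$boundaries[[b]]
    rows[[length(rows) + 1L]] <- data.frame(
      vessel = bd$vessel, end = bd$end, kind = bd$type, index = b,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(vessel = character(), end = character(),
                      kind = character(), index = integer()))
  do.call(rbind, rows)
}

junction_degree <- c(conjunction = 2L, bifurcation = 3L, anastomosis = 3L)

#' Validate an arterial network
#'
#' Checks structural invariants: unique vessel names; every vessel end
#' attached to exactly one junction or boundary; junction degrees matching
#' their kind; at most one heart inlet; graph connectivity; the symmetry map
#' being an involution over existing vessels.
#'
#' @param net an `arterial_network`.
#' @return `net`, invisibly; errors name the offending record.
#' @export
validate_network <- function(net) {
  vn <- names(net$vessels)
  if (anyDuplicated(vn))
    stop("duplicate vessel names: ",
         paste(unique(vn[duplicated(vn)]), collapse = ", "))
  at <- attachment_table(net)
  for (nm in vn) for (e in c("proximal", "distal")) {
    k <- sum(at$vessel == nm & at$end == e)
    if (k == 0L)
      stop("dangling vessel end: ", end_key(nm, e),
           " has no junction or boundary")
    if (k > 1L)
      stop("vessel end ", end_key(nm, e), " attached ", k, " times")
  }
  bad <- at$vessel[!(at$vessel %in% vn)]
  if (length(bad))
    stop("attachment references unknown vessel: ",
         paste(unique(bad), collapse = ", "))
  for (j in seq_along(net$junctions)) {
    jn <- net$junctions[[j]]
    if (!jn$kind %in% names(junction_degree))
      stop("junction ", j, " has unknown kind '", jn$kind, "'")
    if (length(jn$ends) != junction_degree[[jn$kind]])
      stop("junction ", j, " (", jn$kind, ") has ", length(jn$ends),
           " ends; expected ", junction_degree[[jn$kind]])
  }
  n_inlet <- sum(vapply(net$boundaries, function(b) b$type == "inlet",
                        logical(1)))
  if (n_inlet > 1L) stop("network has ", n_inlet, " inlet boundaries")
  # connectivity: vessels adjacent when sharing a junction
  if (length(vn) > 1L) {
    adj <- lapply(net$junctions, function(jn)
      vapply(jn$ends, function(e) e$vessel, character(1)))
    seen <- structure(rep(FALSE, length(vn)), names = vn)
    queue <- vn[1L]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (grp in adj) if (v %in% grp) {
        nxt <- grp[!seen[grp]]
        seen[nxt] <- TRUE
        queue <- c(queue, nxt)
      }
    }
    if (!all(seen))
      stop("network is not connected; unreachable vessels: ",
           paste(vn[!seen], collapse = ", "))
  }
  for (s in names(net$sites)) {
    sv <- net$sites[[s]]$vessel
    if (!sv %in% vn) stop("site '", s, "' references unknown vessel '",
                          sv, "'")
  }
  if (length(net$symmetry)) {
    sy <- net$symmetry
    for (l in names(sy)) {
      if (!l %in% vn || !sy[[l]] %in% vn)
        stop("symmetry pair ", l, " -> ", sy[[l]],
             " references unknown vessel")
      r <- sy[[l]]
      if (!is.null(sy[[r]]) && sy[[r]] != l)
        stop("symmetry map is not an involution at ", l)
    }
  }
  invisible(net)
}

#' @export
print.arterial_network <- function(x, ...) {
  nb <- vapply(x$boundaries, function(b) b$type, character(1))
  cat("Arterial network:", length(x$vessels), "vessels,",
      length(x$junctions), "junctions\n")
  cat("  boundaries:", paste(sprintf("%s x%d", names(table(nb)), table(nb)),
                             collapse = ", "), "\n")
  if (length(x$sites))
    cat("  sites:", paste(names(x$sites), collapse = ", "), "\n")
  invisible(x)
}

#' Total diastolic vascular volume
#'
#' Sum of A0 * L over all vessels; preserved by topology edits that do not
#' explicitly narrow a lumen.
#'
#' @param net an `arterial_network`.
#' @return volume in m^3.
#' @export
network_volume <- function(net) {
  sum(vapply(net$vessels, function(v) v$A0 * v$L, numeric(1)))
}

#' Count the windkessel outlets of a network
#'
#' @param net an `arterial_network`.
#' @return integer number of windkessel boundaries.
#' @export
n_outlets <- function(net) {
  sum(vapply(net$boundaries, function(b) b$type == "windkessel", logical(1)))
}

#' Resolve a named anatomical site
#'
#' @param net an `arterial_network`.
#' @param label a site label present in `net$sites`, or a vessel name.
#' @return `list(vessel =, end =)`.
#' @export
resolve_site <- function(net, label) {
  if (label %in% names(net$sites)) return(net$sites[[label]])
  if (label %in% names(net$vessels))
    return(list(vessel = label, end = "distal"))
  stop("unknown site or vessel: '", label, "'")
}

find_attachment <- function(net, vessel, end) {
  at <- attachment_table(net)
  hit <- at[at$vessel == vessel & at$end == end, ]
  if (!nrow(hit)) stop("vessel end ", end_key(vessel, end), " not attached")
  hit[1L, ]
}

#' Split a vessel into two segments
#'
#' Replaces `vessel` by two segments of length `fraction * L` and
#' `(1 - fraction) * L` joined by a conjunction, inheriting all wall
#' properties. Cell counts are divided proportionally; both daughters must
#' keep at least 5 cells. Sites and symmetry entries naming the split vessel
#' are remapped to the matching daughter (proximal sites to the first
#' segment, distal to the second).
#'
#' @param net an `arterial_network`.
#' @param vessel vessel name.
#' @param fraction split position in (0, 1), measured from the proximal end.
#' @param names optional character(2) names for the daughters; default
#'   `<vessel>_seg1`, `<vessel>_seg2`.
#' @return the modified network; the new conjunction is the last junction.
#' @export
split_vessel_at <- function(net, vessel, fraction, names = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  v <- net$vessels[[vessel]]
  if (is.null(v)) stop("unknown vessel '", vessel, "'")
  M1 <- as.integer(round(fraction * v$M))
  M2 <- v$M - M1
  if (M1 < 5L || M2 < 5L)
    stop("cannot split '", vessel, "' at ", fraction,
         ": a daughter segment would fall below the 5-cell floor")
  if (is.null(names)) names <- paste0(vessel, c("_seg1", "_seg2"))
  L1 <- fraction * v$L
  L2 <- (1 - fraction) * v$L
  seg1 <- vessel_segment(names[1], L = L1, A0 = v$A0, h0 = v$h0, E = v$E,
                         nu = v$nu, Pext = v$Pext, M = M1)
  seg2 <- vessel_segment(names[2], L = L2, A0 = v$A0, h0 = v$h0, E = v$E,
                         nu = v$nu, Pext = v$Pext, M = M2)
  vidx <- match(vessel, base::names(net$vessels))
  net$vessels <- append(net$vessels[-vidx], list(seg1, seg2), after = vidx - 1L)
  base::names(net$vessels) <- vapply(net$vessels, `[[`, character(1), "name")
  remap <- function(e) {
    if (e$vessel == vessel)
      e$vessel <- if (e$end == "proximal") names[1] else names[2]
    e
  }
  net$junctions <- lapply(net$junctions, function(jn) {
    jn$ends <- lapply(jn$ends, remap)
    jn
  })
  net$boundaries <- lapply(net$boundaries, function(b) {
    b2 <- remap(list(vessel = b$vessel, end = b$end))
    b$vessel <- b2$vessel
    b
  })
  net$sites <- lapply(net$sites, remap)
  if (length(net$symmetry)) {
    sy <- net$symmetry
    sy <- sy[base::names(sy) != vessel & sy != vessel]
    net$symmetry <- sy
  }
  net$junctions <- c(net$junctions, list(list(
    kind = "conjunction",
    ends = list(list(vessel = names[1], end = "distal"),
                list(vessel = names[2], end = "proximal")))))
  validate_network(net)
  net
}

#' Detach a vessel end from a junction and give it a boundary
#'
#' Removes the named vessel end from its junction, attaches the replacement
#' boundary to it, and re-joins the remaining vessels as a lower-degree
#' junction: a three-way junction with one limb removed becomes a
#' conjunction. Detaching from a conjunction would leave a single orphaned
#' end, so it is only allowed when `replacement_remaining` supplies a
#' boundary for it.
#'
#' @param net an `arterial_network`.
#' @param vessel,end the vessel end to detach.
#' @param replacement boundary spec for the detached end:
#'   `list(type =, params =)`.
#' @param replacement_remaining optional boundary spec for the remaining end
#'   when detaching from a conjunction.
#' @return the modified network.
#' @export
detach_junction_edge <- function(net, vessel, end, replacement,
                                 replacement_remaining = NULL) {
  at <- find_attachment(net, vessel, end)
  if (at$kind != "junction")
    stop("vessel end ", end_key(vessel, end),
         " is attached to a boundary, not a junction")
  j <- at$index
  jn <- net$junctions[[j]]
  keep <- !vapply(jn$ends, function(e)
    e$vessel == vessel && e$end == end, logical(1))
  rest <- jn$ends[keep]
  net$boundaries <- c(net$boundaries, list(
    list(vessel = vessel, end = end, type = replacement$type,
         params = replacement$params)))
  if (length(rest) == 2L) {
    net$junctions[[j]] <- list(kind = "conjunction", ends = rest)
  } else if (length(rest) == 1L) {
    if (is.null(replacement_remaining))
      stop("detaching ", end_key(vessel, end), " from a conjunction leaves ",
           end_key(rest[[1]]$vessel, rest[[1]]$end),
           " orphaned; supply replacement_remaining")
    net$junctions[[j]] <- NULL
    net$boundaries <- c(net$boundaries, list(
      list(vessel = rest[[1]]$vessel, end = rest[[1]]$end,
           type = replacement_remaining$type,
           params = replacement_remaining$params)))
  } else stop("junction ", j, " would be left with no attachments")
  validate_network(net)
  net
}
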