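#' The clot retrieval path
#'
#' Site labels of the vessels the clot traverses from the occlusion site to
#' the proximal aspiration point, distal to proximal.
#'
#' @return character vector `c("MCA", "ICAd", "ICApd", "ICApp")`.
#' @export
retrieval_path <- function() c("MCA", "ICAd", "ICApd", "ICApp")

#' Enumerate the thrombectomy network configurations
#'
#' For each aspiration-catheter position, the clot is placed successively in
#' every retrieval-path vessel between the occlusion site (MCA) and the
#' aspiration point, and finally removed: aspiration at ICApp gives clot in
#' MCA, ICAd, ICApd, ICApp, then removed (C1-C5); at ICApd clot in MCA,
#' ICAd, ICApd, then removed (C6-C9); at ICAd clot in MCA, ICAd, then
#' removed (C10-C12) -- twelve configurations. Phase 1 (clot still in the
#' MCA) fully occludes the MCA outlet; phases 2 (retrieval) and 3 (clot
#' removed) restore the pre-intervention MCA outlet.
#'
#' @param aspiration_sites aspiration positions, ordered; must lie on the
#'   retrieval path.
#' @param path retrieval-path labels, distal to proximal.
#' @return data.frame with columns `config` (C1...), `bgc_site`,
#'   `aspiration_site`, `clot` (site label or `"removed"`), `mca_outlet`
#'   (`"full_occlusion"` or `"pre_intervention"`) and `phase` (1, 2, 3).
#' @export
enumerate_configurations <- function(aspiration_sites = c("ICApp", "ICApd",
                                                          "ICAd"),
                                     path = retrieval_path()) {
  bad <- setdiff(aspiration_sites, path)
  if (length(bad))
    stop("aspiration site off the retrieval path: ",
         paste(bad, collapse = ", "))
  rows <- list()
  for (site in aspiration_sites) {
    clots <- c(path[seq_len(match(site, path))], "removed")
    for (clot in clots) {
      phase <- if (clot == "MCA") 1L else if (clot == "removed") 3L else 2L
      rows[[length(rows) + 1L]] <- data.frame(
        bgc_site = "ICApp", aspiration_site = site, clot = clot,
        mca_outlet = if (phase == 1L) "full_occlusion" else "pre_intervention",
        phase = phase, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(config = paste0("C", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

#' Model a balloon guide catheter by proximal flow arrest
#'
#' The inflated BGC at the junction of the common, external and internal
#' carotid arteries arrests flow into the ipsilateral proximal ICA. It is
#' modelled by disconnecting the ICApp proximal end from that three-way
#' junction and giving it a zero-flow (fully reflective) boundary; the CCA
#' and ECA remain joined as a conjunction. Idempotent; the contralateral
#' side is untouched.
#'
#' @param net an `arterial_network` with an `"ICApp"` site.
#' @param site site label of the proximal ICA segment. Default `"ICApp"`.
#' @return the modified network.
#' @export
apply_bgc <- function(net, site = "ICApp") {
  vsl <- resolve_site(net, site)$vessel
  at <- find_attachment(net, vsl, "proximal")
  if (at$kind == "reflect") return(net)  # already applied
  if (at$kind != "junction")
    stop("BGC site: proximal end of ", vsl,
         " is not attached to a junction")
  jn <- net$junctions[[at$index]]
  if (length(jn$ends) != 3L)
    stop("BGC site is not a degree-3 junction (found ", jn$kind,
         " of degree ", length(jn$ends), ")")
  detach_junction_edge(net, vsl, "proximal",
                       replacement = list(type = "reflect", params = NULL))
}

#' Insert an aspiration catheter as a constant-flow sink
#'
#' The aspiration catheter tip is modelled as a node on the host vessel
#' (created with [split_vessel_at()]) joined to a short stub whose free end
#' carries a constant prescribed-flow boundary withdrawing `rate` ml/s from
#' the lumen. A rate of 0 leaves the haemodynamics of the unmodified
#' network unchanged to within solver tolerance.
#'
#' @param net an `arterial_network`.
#' @param site site label (or vessel name) hosting the catheter tip.
#' @param rate aspiration rate in ml/s (>= 0).
#' @param fraction axial tip position along the host vessel (0, 1); default
#'   0.5 (subject to the 5-cell discretisation floor of each daughter
#'   segment).
#' @param stub_length,stub_radius,stub_h0,stub_E,stub_cells geometry and
#'   wall mechanics of the catheter stub. Fixed defaults (1 cm, 1.5 mm
#'   radius) independent of the host vessel's state, so scenario edits
#'   commute.
#' @return the modified network; the stub is named `<host>_asp`.
#' @export
insert_aspiration <- function(net, site, rate, fraction = 0.5,
                              stub_length = 0.01, stub_radius = 1.5e-3,
                              stub_h0 = 3e-4, stub_E = 8e5,
                              stub_cells = 5L) {
  if (rate < 0) stop("aspiration rate must be >= 0")
  host <- resolve_site(net, site)$vessel
  hv <- net$vessels[[host]]
  segs <- paste0(host, c("_seg1", "_seg2"))
  net <- split_vessel_at(net, host, fraction, names = segs)
  stub_name <- paste0(host, "_asp")
  stub <- vessel_segment(stub_name, L = stub_length, radius = stub_radius,
                         h0 = stub_h0, E = stub_E, nu = hv$nu,
                         Pext = hv$Pext, M = stub_cells)
  net$vessels <- c(net$vessels, stats::setNames(list(stub), stub_name))
  j <- length(net$junctions)  # the conjunction created by the split
  net$junctions[[j]] <- list(kind = "bifurcation", ends = c(
    net$junctions[[j]]$ends,
    list(list(vessel = stub_name, end = "proximal"))))
  net$boundaries <- c(net$boundaries, list(list(
    vessel = stub_name, end = "distal", type = "flow",
    params = list(q = mls_to_m3s(rate)))))
  validate_network(net)
  net
}

#' Place the clot: full occlusion or a moving stenosis
#'
#' Phase 1 (clot lodged in the MCA) is a complete occlusion, modelled by
#' replacing the MCA outlet windkessel with a zero-flow boundary. During
#' retrieval (phase 2) the moving clot is modelled as a stenosis of the
#' artery it currently occupies: the vessel's diastolic lumen area is
#' reduced by `severity` over its whole length, with the wall stiffness
#' beta recomputed from the reduced area (configurable).
#'
#' @param net an `arterial_network`.
#' @param vessel host vessel name or site label (for a stenosis).
#' @param severity fraction of the lumen removed, in `[0, 1)`; 0.7 is the
#'   default moving-clot severity. Use `full_occlusion = TRUE` instead of
#'   severity 1.
#' @param full_occlusion replace the vessel's outlet windkessel by a
#'   zero-flow boundary instead of narrowing the lumen.
#' @param basis severity convention: fraction of `"area"` (default) or of
#'   `"diameter"` removed.
#' @param recompute_beta recompute the tube stiffness from the reduced
#'   area (default TRUE); FALSE keeps the original beta.
#' @return the modified network.
#' @export
apply_clot <- function(net, vessel, severity = 0.7, full_occlusion = FALSE,
                       basis = c("area", "diameter"),
                       recompute_beta = TRUE) {
  basis <- match.arg(basis)
  host <- resolve_site(net, vessel)$vessel
  if (full_occlusion) {
    at <- find_attachment(net, host, "distal")
    if (at$kind == "reflect") return(net)
    if (at$kind != "windkessel")
      stop("full occlusion: distal end of ", host,
           " does not carry a windkessel outlet")
    net$boundaries[[at$index]] <- list(vessel = host, end = "distal",
                                       type = "reflect", params = NULL)
    return(net)
  }
  if (severity >= 1)
    stop("severity must be < 1; use full_occlusion = TRUE for a total block")
  if (severity < 0) stop("severity must be >= 0")
  if (severity == 0) return(net)
  shrink <- if (basis == "area") 1 - severity else (1 - severity)^2
  # the host may have been split for catheter insertion (and a site label
  # then resolves to one daughter); narrow the whole original vessel, i.e.
  # all its segments, but never the aspiration stub
  base <- sub("_seg[12]$", "", host)
  targets <- intersect(names(net$vessels),
                       c(base, paste0(base, c("_seg1", "_seg2"))))
  if (!length(targets)) stop("unknown vessel '", host, "'")
  for (nm in targets) {
    v <- net$vessels[[nm]]
    A0new <- v$A0 * shrink
    v2 <- vessel_segment(nm, L = v$L, A0 = A0new, h0 = v$h0, E = v$E,
                         nu = v$nu, Pext = v$Pext, M = v$M)
    if (!recompute_beta) v2$beta <- v$beta
    net$vessels[[nm]] <- v2
  }
  net
}

#' Build the network of one thrombectomy configuration
#'
#' Applies the documented edit sequence BGC, aspiration, clot to a
#' subject's pre-intervention network.
#'
#' @param net the subject's `arterial_network`.
#' @param config one row of [enumerate_configurations()].
#' @param rate aspiration rate, ml/s.
#' @param ... passed to [insert_aspiration()] and [apply_clot()].
#' @return the scenario `arterial_network`.
#' @export
scenario_network <- function(net, config, rate, ...) {
  stopifnot(nrow(config) == 1L)
  net <- apply_bgc(net, config$bgc_site)
  net <- insert_aspiration(net, config$aspiration_site, rate)
  if (config$phase == 1L) {
    net <- apply_clot(net, "MCA", full_occlusion = TRUE)
  } else if (config$phase == 2L) {
    net <- apply_clot(net, config$clot, severity = 0.7, ...)
  }
  net
}

#' Enumerate the jobs of a thrombectomy campaign
#'
#' @param subjects number of subjects, or a vector of subject identifiers.
#' @param rates aspiration rates, ml/s. Default `c(0.5, 5, 10)`.
#' @param configs configuration table; default
#'   [enumerate_configurations()].
#' @return data.frame with one row per (subject, configuration, rate) job.
#' @export
enumerate_campaign_jobs <- function(subjects, rates = c(0.5, 5, 10),
                                    configs = enumerate_configurations()) {
  ids <- if (length(subjects) == 1L && is.numeric(subjects))
    seq_len(subjects) else subjects
  if (!length(ids))
    return(data.frame(subject = character(), config = character(),
                      rate = numeric()))
  jobs <- expand.grid(config = configs$config, rate = rates, subject = ids,
                      stringsAsFactors = FALSE)
  jobs <- merge(jobs, configs, by = "config", sort = FALSE)
  jobs <- jobs[order(match(jobs$subject, ids), jobs$rate,
                     match(jobs$config, configs$config)), ]
  rownames(jobs) <- NULL
  jobs[c("subject", "config", "rate", "bgc_site", "aspiration_site",
         "clot", "mca_outlet", "phase")]
}

#' Run a thrombectomy simulation campaign
#'
#' Runs every (subject x configuration x aspiration-rate) job: builds the
#' scenario network, converges it, and extracts cycle-mean flows and
#' directions for the retrieval path and its neighbour vessels plus the MCA
#' outlet flow. Non-converged jobs are flagged and excluded from summaries,
#' not fatal.
#'
#' @param subjects named list of subject `arterial_network`s (e.g. from
#'   [subject_networks()]).
#' @param rates aspiration rates, ml/s.
#' @param configs configuration table; default all twelve.
#' @param vessels site labels to report. Default the retrieval path and its
#'   neighbours.
#' @param threshold,max_cycles,settings solver controls.
#' @param verbose print one line per job.
#' @return an object of class `mt_campaign`: `$results` is a tidy
#'   data.frame (subject, config, rate, vessel, mean flow ml/min,
#'   direction, MCA PI, convergence flag), `$jobs` the job table.
#' @export
run_campaign <- function(subjects, rates = c(0.5, 5, 10),
                         configs = enumerate_configurations(),
                         vessels = c("MCA", "ICAd", "ICApd", "ICApp", "ACA",
                                     "PCoA", "Ophthalmic"),
                         threshold = 3, max_cycles = 50,
                         settings = solver_settings(init_pc = mmhg_to_pa(75)),
                         verbose = FALSE) {
  ids <- names(subjects)
  if (is.null(ids)) ids <- as.character(seq_along(subjects))
  jobs <- enumerate_campaign_jobs(ids, rates, configs)
  empty <- data.frame(subject = character(), config = character(),
                      rate = numeric(), aspiration_site = character(),
                      clot = character(), phase = integer(),
                      vessel = character(), mean_flow = numeric(),
                      direction = character(), mca_outlet_flow = numeric(),
                      mca_pi = numeric(), converged = logical())
  if (!nrow(jobs))
    return(structure(list(results = empty, jobs = jobs),
                     class = "mt_campaign"))
  results <- list()
  for (k in seq_len(nrow(jobs))) {
    job <- jobs[k, ]
    net0 <- subjects[[job$subject]]
    cfg <- configs[configs$config == job$config, ]
    row_base <- data.frame(subject = job$subject, config = job$config,
                           rate = job$rate,
                           aspiration_site = cfg$aspiration_site,
                           clot = cfg$clot, phase = cfg$phase,
                           stringsAsFactors = FALSE)
    sim <- tryCatch({
      snet <- scenario_network(net0, cfg, job$rate)
      suppressWarnings(run_to_convergence(snet, threshold = threshold,
                                          max_cycles = max_cycles,
                                          settings = settings))
    }, error = function(e) e)
    if (inherits(sim, "error") || !sim$converged) {
      results[[k]] <- cbind(row_base, data.frame(
        vessel = NA_character_, mean_flow = NA_real_,
        direction = NA_character_, mca_outlet_flow = NA_real_,
        mca_pi = NA_real_, converged = FALSE))
      if (verbose) cat("job", k, "FAILED\n")
      next
    }
    mca_vessel <- resolve_site(sim$network, "MCA")$vessel
    mca_out <- vessel_mean_flow(sim, mca_vessel, where = "dist")
    mca_pi <- tryCatch(vessel_pi(sim, "MCA"), error = function(e) NA_real_)
    rows <- lapply(vessels, function(sv) {
      mq <- tryCatch(vessel_mean_flow(sim, sv), error = function(e) NA_real_)
      cbind(row_base, data.frame(
        vessel = sv, mean_flow = mq,
        direction = as.character(classify_direction(mq)),
        mca_outlet_flow = mca_out, mca_pi = mca_pi, converged = TRUE))
    })
    results[[k]] <- do.call(rbind, rows)
    if (verbose)
      cat(sprintf("job %d/%d: %s %s rate %.1f ml/s MCA %.1f ml/min\n",
                  k, nrow(jobs), job$subject, job$config, job$rate,
                  rows[[1]]$mean_flow[1]))
  }
  structure(list(results = do.call(rbind, results), jobs = jobs),
            class = "mt_campaign")
}

#' @export
print.mt_campaign <- function(x, ...) {
  ok <- sum(x$results$converged[!duplicated(
    x$results[c("subject", "config", "rate")])])
  cat("Thrombectomy campaign:", nrow(x$jobs), "jobs (", ok, "converged )\n")
  invisible(x)
}

#' Population flow table of a campaign
#'
#' Median (min, max) of the per-subject mean MCA flow during the active
#' retrieval phase (phase 2), by aspiration site and rate.
#'
#' @param campaign an `mt_campaign`.
#' @param vessel reported vessel site. Default `"MCA"`.
#' @param phases phases included. Default 2 (active retrieval).
#' @param per_subject how to reduce a subject's multiple phase-2
#'   configurations before the population median: `"mean"` (default) or
#'   `"median"`.
#' @return data.frame: aspiration_site, rate, n, median, min, max (ml/min).
#' @export
campaign_flow_table <- function(campaign, vessel = "MCA", phases = 2L,
                                per_subject = c("mean", "median")) {
  per_subject <- match.arg(per_subject)
  r <- campaign$results
  r <- r[r$converged & r$vessel == vessel & r$phase %in% phases, ]
  if (!nrow(r)) stop("no converged results for vessel '", vessel, "'")
  agg <- stats::aggregate(
    mean_flow ~ subject + aspiration_site + rate, data = r,
    FUN = if (per_subject == "mean") mean else stats::median)
  population_summary(agg, "mean_flow", by = c("aspiration_site", "rate"))
}
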