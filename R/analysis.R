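#' Cycle-mean flow of a trace
#'
#' Time average \eqn{(1/T)\int Q\,dt} of a volumetric flow trace over one
#' cardiac cycle, by the trapezoidal rule, reported in ml/min.
#'
#' @param Q flow trace.
#' @param t sample times, s, spanning exactly one cycle (same length as
#'   `Q`).
#' @param input_units unit of `Q`: `"m3s"` (default) or `"mlmin"`.
#' @return signed cycle-mean flow in ml/min.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' mean_flow(rep(2e-6, length(t)), t)   # constant 2 ml/s -> 120 ml/min
#' @export
mean_flow <- function(Q, t, input_units = c("m3s", "mlmin")) {
  input_units <- match.arg(input_units)
  n <- length(Q)
  if (length(t) != n) stop("Q and t must have the same length")
  if (n < 2L) stop("trace shorter than a cycle")
  span <- t[n] - t[1L]
  if (span <= 0) stop("trace spans no time")
  m <- sum(diff(t) * (Q[-n] + Q[-1L]) / 2) / span
  if (input_units == "m3s") m3s_to_mlmin(m) else m
}

#' Pulsatility index of a velocity trace
#'
#' \deqn{PI = (V_{max} - V_{min}) / V_{mean}} over one cardiac cycle.
#' Undefined (error) for a zero-mean trace.
#'
#' @param v velocity trace over one cycle (any consistent unit).
#' @param t optional sample times for the mean (trapezoidal); arithmetic
#'   mean if omitted (exact on a uniform grid).
#' @return dimensionless pulsatility index.
#' @export
pulsatility_index <- function(v, t = NULL) {
  vmean <- if (is.null(t)) mean(v) else {
    n <- length(v)
    sum(diff(t) * (v[-n] + v[-1L]) / 2) / (t[n] - t[1L])
  }
  if (abs(vmean) < .Machine$double.eps * max(1, max(abs(v))))
    stop("pulsatility index undefined: zero-mean velocity trace")
  (max(v) - min(v)) / vmean
}

#' Classify flow direction from a signed cycle-mean
#'
#' Positive flow runs along the vessel's declared proximal-to-distal
#' orientation (antegrade); negative flow is retrograde. An exact zero mean
#' is reported antegrade with the `zero_flow` attribute set.
#'
#' @param mean_q signed cycle-mean flow (any unit).
#' @return `"antegrade"` or `"retrograde"`, with logical attribute
#'   `zero_flow`.
#' @export
classify_direction <- function(mean_q) {
  out <- ifelse(mean_q < 0, "retrograde", "antegrade")
  attr(out, "zero_flow") <- mean_q == 0
  out
}

#' Median (min, max) summary of per-subject metrics by group
#'
#' Reduces per-subject values to median, minimum and maximum per group, the
#' layout used for population flow tables (rows = aspiration site, columns
#' = aspiration rate). Empty groups are omitted with a warning.
#'
#' @param data data.frame of per-subject values.
#' @param value name of the value column.
#' @param by character vector of grouping column names.
#' @return data.frame with the grouping columns plus `n`, `median`, `min`,
#'   `max`.
#' @export
population_summary <- function(data, value, by = character()) {
  if (!value %in% names(data)) stop("no column '", value, "' in data")
  if (!length(by)) {
    v <- data[[value]]
    if (!length(v)) stop("no values to summarise")
    return(data.frame(n = length(v), median = stats::median(v),
                      min = min(v), max = max(v)))
  }
  groups <- unique(data[by])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (g in by) sel <- sel & data[[g]] == groups[[g]][i]
    v <- data[[value]][sel & !is.na(data[[value]])]
    if (!length(v)) {
      warning("empty group omitted: ",
              paste(g <- unlist(groups[i, , drop = TRUE]), collapse = "/"))
      return(NULL)
    }
    cbind(groups[i, , drop = FALSE],
          data.frame(n = length(v), median = stats::median(v),
                     min = min(v), max = max(v)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-vessel flow summary of a converged simulation
#'
#' @param sim an `mt_simulation`.
#' @param vessels vessel names (default: all).
#' @param where trace location: `"mid"` (default), `"prox"` or `"dist"`.
#' @return data.frame with signed cycle-mean flow (ml/min), direction,
#'   zero-flow flag and instantaneous min/max flow.
#' @export
flow_summary <- function(sim, vessels = NULL,
                         where = c("mid", "prox", "dist")) {
  where <- match.arg(where)
  if (is.null(vessels)) vessels <- names(sim$vessels)
  col <- paste0("Q_", where)
  rows <- lapply(vessels, function(vn) {
    tr <- vessel_trace(sim, vn, units = "SI")
    mq <- mean_flow(tr[[col]], sim$time)
    dir <- classify_direction(mq)
    data.frame(vessel = vn, mean_flow = mq,
               direction = as.character(dir),
               zero_flow = attr(dir, "zero_flow"),
               min_flow = m3s_to_mlmin(min(tr[[col]])),
               max_flow = m3s_to_mlmin(max(tr[[col]])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cycle-mean flow through one vessel
#'
#' @inheritParams flow_summary
#' @param vessel vessel name or site label.
#' @return signed mean flow in ml/min.
#' @export
vessel_mean_flow <- function(sim, vessel, where = c("mid", "prox", "dist")) {
  where <- match.arg(where)
  vessel <- resolve_site(sim$network, vessel)$vessel
  tr <- vessel_trace(sim, vessel, units = "SI")
  mean_flow(tr[[paste0("Q_", where)]], sim$time)
}

#' Mid-vessel pulsatility index
#'
#' PI of the mid-vessel velocity u = Q/A.
#'
#' @inheritParams vessel_mean_flow
#' @return dimensionless PI.
#' @export
vessel_pi <- function(sim, vessel) {
  vessel <- resolve_site(sim$network, vessel)$vessel
  tr <- vessel_trace(sim, vessel, units = "SI")
  pulsatility_index(tr$u_mid, sim$time)
}

#' Systolic and diastolic pressure at a named site
#'
#' Maximum and minimum of the mid-vessel pressure trace over the converged
#' cycle, in mmHg; by default at the site labelled `"brachial"`.
#'
#' @param sim an `mt_simulation`.
#' @param site site label or vessel name.
#' @return named numeric `c(SBP =, DBP =)` in mmHg.
#' @export
site_pressures <- function(sim, site = "brachial") {
  vessel <- resolve_site(sim$network, site)$vessel
  tr <- vessel_trace(sim, vessel)
  c(SBP = max(tr$P_mid), DBP = min(tr$P_mid))
}

#' Cycle-averaged mass balance of a converged run
#'
#' Compares the cycle-mean inlet inflow with the sum of cycle-mean outflows
#' through windkessel outlets and prescribed-flow sinks. For a converged
#' periodic state the relative imbalance should be small (windkessel
#' capacitors neither charge nor discharge on average).
#'
#' @param sim an `mt_simulation`.
#' @return list with `inflow`, `outflow`, `sink` (ml/min) and
#'   `relative_error`.
#' @export
cycle_mass_balance <- function(sim) {
  net <- sim$network
  inflow <- 0; outflow <- 0; sink <- 0
  for (b in net$boundaries) {
    tr <- vessel_trace(sim, b$vessel, units = "SI")
    q <- if (b$end == "proximal") -mean_flow(tr$Q_prox, sim$time)
         else mean_flow(tr$Q_dist, sim$time)  # ml/min leaving the network
    if (b$type == "inlet") inflow <- inflow - q
    else if (b$type == "windkessel") outflow <- outflow + q
    else if (b$type == "flow") sink <- sink + q
  }
  list(inflow = inflow, outflow = outflow, sink = sink,
       relative_error = abs(inflow - outflow - sink) / abs(inflow))
}
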