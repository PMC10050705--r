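bc_code <- c(junction = 0L, reflect = 1L, inlet = 2L, flow = 3L,
             windkessel = 4L)
junction_code <- c(conjunction = 0L, bifurcation = 1L, anastomosis = 2L)

# Flatten an arterial_network into the list structure the compiled cycle
# driver consumes. init_pc (Pa) seeds all windkessel capacitor pressures.
build_solver_net <- function(net, init_pc = NULL) {
  vn <- names(net$vessels)
  vlist <- lapply(net$vessels, function(v) {
    list(M = v$M, dx = v$dx, A0 = v$A0, beta = v$beta, Pext = v$Pext,
         A = rep(v$A0, v$M), Q = rep(0, v$M),
         bc = c(0L, 0L), bc_params = list(NULL, NULL))
  })
  for (b in net$boundaries) {
    i <- match(b$vessel, vn)
    e <- if (b$end == "proximal") 1L else 2L
    vlist[[i]]$bc[e] <- bc_code[[b$type]]
    p <- b$params
    if (b$type == "windkessel") {
      pc0 <- if (!is.null(init_pc)) init_pc else p$Pc
      p <- list(R1 = p$R1, R2 = p$R2, C = p$C, Pout = p$Pout, Pc = pc0)
    }
    if (b$type == "inlet")
      p <- list(peak_flow = p$peak_flow, systole = p$systole,
                period = p$period, scale = p$scale)
    vlist[[i]]$bc_params[e] <- list(p)  # [e] <- list() keeps NULL slots
  }
  jlist <- lapply(net$junctions, function(jn) {
    list(kind = junction_code[[jn$kind]],
         vi = vapply(jn$ends, function(e) match(e$vessel, vn), integer(1)) - 1L,
         ve = vapply(jn$ends, function(e)
           if (e$end == "proximal") 0L else 1L, integer(1)))
  })
  list(vessels = unname(vlist), junctions = unname(jlist),
       fluid = unclass(net$fluid))
}

initial_state <- function(cppnet) {
  list(A = lapply(cppnet$vessels, `[[`, "A"),
       Q = lapply(cppnet$vessels, `[[`, "Q"),
       Pc = t(vapply(cppnet$vessels, function(v) {
         pc <- c(0, 0)
         for (e in 1:2)
           if (v$bc[e] == bc_code[["windkessel"]])
             pc[e] <- v$bc_params[[e]]$Pc
         pc
       }, numeric(2))))
}

#' Advance a single vessel one MUSCL time step
#'
#' Second-order slope-limited (minmod) finite-volume update of the 1D mass
#' and momentum equations with the wall-friction source term, using Heun
#' two-stage time integration. Vessel ends are treated as full wave
#' reflectors (mirror ghost cells) unless switched to free outflow
#' (constant extrapolation). Raises an explicit stability error when `dt`
#' violates the CFL condition for the current state.
#'
#' @param state `list(A =, Q =, t =)` with per-cell area (m^2) and flow
#'   (m^3/s).
#' @param vessel a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @param dt time step, s.
#' @param reflect_proximal,reflect_distal treat the end as a zero-flow
#'   reflector (default) rather than free outflow.
#' @return the updated state with `t` advanced by `dt`.
#' @export
muscl_step <- function(state, vessel, fluid = fluid_properties(), dt,
                       reflect_proximal = TRUE, reflect_distal = TRUE) {
  stopifnot(length(state$A) == vessel$M, length(state$Q) == vessel$M)
  out <- cpp_muscl_step(state$A, state$Q, vessel$dx, vessel$A0, vessel$beta,
                        vessel$Pext, unclass(fluid), dt,
                        reflect_proximal, reflect_distal)
  list(A = out$A, Q = out$Q, t = (state$t %||% 0) + dt)
}

#' Largest stable time step for a vessel state
#'
#' @inheritParams muscl_step
#' @return dt limit (s) for CFL number 1; multiply by the CFL number in use.
#' @export
cfl_limit <- function(state, vessel, fluid = fluid_properties()) {
  cpp_cfl_dt(state$A, state$Q, vessel$dx, vessel$A0, vessel$beta,
             unclass(fluid))
}

#' Solve the coupling conditions at a junction
#'
#' Given the interior states adjacent to a junction, solves the nonlinear
#' system imposing zero net flow plus continuity of total pressure
#' \eqn{P + \rho u^2 / 2} (conjunctions) or static pressure (bifurcations
#' and anastomoses), together with the outgoing characteristic
#' compatibility of each attached vessel. Returns the boundary-cell values.
#'
#' @param kind `"conjunction"`, `"bifurcation"` or `"anastomosis"`.
#' @param ends character vector, per attachment: `"proximal"` or `"distal"`
#'   (which end of the attached vessel meets the junction).
#' @param A,Q interior area (m^2) and flow (m^3/s) adjacent to the junction,
#'   one per attachment.
#' @param vessels list of [vessel_segment()]s, one per attachment.
#' @param fluid a [fluid_properties()].
#' @return `list(A =, Q =)` of updated boundary values per attachment; flow
#'   conservation holds to near machine precision at the solution.
#' @export
junction_solve <- function(kind, ends, A, Q, vessels,
                           fluid = fluid_properties()) {
  kind <- match.arg(kind, names(junction_code))
  d <- length(vessels)
  stopifnot(length(ends) == d, length(A) == d, length(Q) == d,
            length(vessels) == junction_degree[[kind]])
  sgn <- ifelse(ends == "distal", 1L, -1L)
  tryCatch(
    cpp_junction_solve(junction_code[[kind]], as.integer(sgn), A, Q,
                       vapply(vessels, `[[`, numeric(1), "A0"),
                       vapply(vessels, `[[`, numeric(1), "beta"),
                       vapply(vessels, `[[`, numeric(1), "Pext"),
                       unclass(fluid)),
    error = function(e) stop("junction (", kind, " of ",
                             paste(vapply(vessels, `[[`, character(1), "name"),
                                   collapse = ", "),
                             ") failed to converge: ", conditionMessage(e)))
}

#' Update a windkessel-terminated vessel end
#'
#' Couples the outgoing characteristic of the vessel to the three-element
#' windkessel ODE \eqn{C\,dP_c/dt = Q - (P_c - P_{out})/R_2},
#' \eqn{P = P_c + Q R_1} (capacitor advanced by backward Euler), and returns
#' the updated boundary state and capacitor pressure. Choosing R1 equal to
#' the characteristic impedance \eqn{\rho c_0 / A_0} minimises the linear
#' reflection of incident pulses.
#'
#' @param outlet a [windkessel3()].
#' @param A_end,Q_end current boundary-cell area and flow.
#' @param vessel the terminated [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @param dt time step, s.
#' @return `list(A =, Q =, outlet =)` with the updated capacitor pressure
#'   stored in `outlet$Pc`.
#' @export
windkessel_update <- function(outlet, A_end, Q_end, vessel,
                              fluid = fluid_properties(), dt) {
  out <- cpp_windkessel_update(A_end, Q_end, vessel$A0, vessel$beta,
                               vessel$Pext, unclass(fluid),
                               outlet$R1, outlet$R2, outlet$C, outlet$Pout,
                               outlet$Pc, dt)
  outlet$Pc <- out$Pc
  list(A = out$A, Q = out$Q, outlet = outlet)
}

#' Characteristic impedance of a vessel
#'
#' \eqn{Z_c = \rho c_0 / A_0}, the proximal resistance value that makes a
#' windkessel outlet non-reflecting for small-amplitude waves.
#'
#' @param vessel a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return impedance in Pa s/m^3.
#' @export
characteristic_impedance <- function(vessel, fluid = fluid_properties()) {
  fluid$density * wave_speed(vessel$A0, vessel, fluid) / vessel$A0
}

#' Match windkessel proximal resistances to the characteristic impedance
#'
#' Replaces R1 of every windkessel outlet by the characteristic impedance of
#' its vessel, keeping the total resistance R1 + R2 unchanged. Errors if an
#' outlet's total resistance is below the impedance.
#'
#' @param net an `arterial_network`.
#' @param fluid fluid to evaluate the impedance with; defaults to the
#'   network's fluid.
#' @return the modified network.
#' @export
match_impedance <- function(net, fluid = net$fluid) {
  net$boundaries <- lapply(net$boundaries, function(b) {
    if (b$type != "windkessel") return(b)
    zc <- characteristic_impedance(net$vessels[[b$vessel]], fluid)
    rtot <- b$params$R1 + b$params$R2
    if (rtot <= zc)
      stop("outlet at ", b$vessel, ": total resistance ", rtot,
           " below characteristic impedance ", zc)
    b$params$R1 <- zc
    b$params$R2 <- rtot - zc
    b
  })
  net
}

#' Cycle-to-cycle convergence error of a pressure trace
#'
#' Time-normalised L2 (root-mean-square) distance between the midpoint
#' pressure traces of two consecutive cardiac cycles:
#' \deqn{\sqrt{\frac{1}{t_f - t_0}\int_{t_0}^{t_f} |P^n - P^{n-1}|^2 dt}}
#' evaluated by the trapezoidal rule on a common uniform grid. Traces
#' differing by a constant give back that constant.
#'
#' @param p_current,p_previous pressure traces sampled on the same uniform
#'   grid spanning one cycle (any pressure unit; the result is in the same
#'   unit).
#' @return RMS pressure difference.
#' @export
convergence_error <- function(p_current, p_previous) {
  n <- length(p_current)
  if (length(p_previous) != n)
    stop("cycle traces have different lengths (", n, " vs ",
         length(p_previous), ")")
  d2 <- (p_current - p_previous)^2
  w <- c(0.5, rep(1, n - 2L), 0.5)
  sqrt(sum(w * d2) / (n - 1L))
}

#' Solver control settings
#'
#' @param cfl CFL number of the explicit scheme (0 < cfl <= 1). Default 0.9.
#' @param sample_dt output/comparison sampling interval, s. Cycle traces are
#'   resampled on this fixed grid (default 1 ms) for convergence checking
#'   and reporting.
#' @param init_pc initial windkessel capacitor pressure, Pa, applied to all
#'   outlets; `NULL` keeps each outlet's own `Pc`. Starting near the
#'   expected diastolic pressure shortens the transient.
#' @return list of settings for [run_to_convergence()].
#' @export
solver_settings <- function(cfl = 0.9, sample_dt = 1e-3, init_pc = NULL) {
  stopifnot(cfl > 0, cfl <= 1, sample_dt > 0)
  list(cfl = cfl, sample_dt = sample_dt, init_pc = init_pc)
}

#' Run a network to its periodic steady state
#'
#' Simulates successive cardiac cycles of the full network until the
#' largest cycle-to-cycle midpoint-pressure RMS error across all vessels
#' falls below `threshold` (mmHg), or `max_cycles` is reached (the result is
#' then flagged non-converged). The returned time series are those of the
#' last simulated cycle.
#'
#' @param net an `arterial_network`.
#' @param threshold convergence threshold, mmHg. Default 3.
#' @param max_cycles maximum number of cardiac cycles. Default 50.
#' @param period cardiac period, s; defaults to the inlet waveform's period
#'   (1 s when the network has no inlet).
#' @param settings a [solver_settings()] list.
#' @param state optional initial solver state (from a previous result's
#'   `$state`) to warm-start the run.
#' @return an object of class `mt_simulation`: sampled per-vessel time
#'   series over the last cycle, convergence diagnostics, and the final
#'   solver state.
#' @examples
#' \donttest{
#' net <- single_vessel_network()
#' sim <- run_to_convergence(net, threshold = 3)
#' summary(sim)
#' }
#' @export
run_to_convergence <- function(net, threshold = 3, max_cycles = 50,
                               period = NULL, settings = solver_settings(),
                               state = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(period)) {
    period <- 1.0
    for (b in net$boundaries)
      if (b$type == "inlet") period <- b$params$period
  }
  cppnet <- build_solver_net(net, init_pc = settings$init_pc)
  if (is.null(state)) state <- initial_state(cppnet)
  vn <- names(net$vessels)
  betas <- vapply(net$vessels, `[[`, numeric(1), "beta")
  A0s <- vapply(net$vessels, `[[`, numeric(1), "A0")
  Pexts <- vapply(net$vessels, `[[`, numeric(1), "Pext")

  prev_pmid <- NULL
  errors <- numeric(0)
  converged <- FALSE
  t0 <- 0
  cycle <- 0L
  res <- NULL
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    res <- cpp_run_cycle(cppnet, state, t0, period, settings$cfl,
                         settings$sample_dt)
    state <- res$state
    t0 <- res$t_end
    pmid <- vapply(seq_along(vn), function(i) {
      Amid <- res$samples[[i]][, 3L]
      pa_to_mmhg(Pexts[i] + betas[i] * (sqrt(Amid / A0s[i]) - 1))
    }, numeric(nrow(res$samples[[1L]])))
    if (!is.null(prev_pmid)) {
      err <- max(vapply(seq_along(vn), function(i)
        convergence_error(pmid[, i], prev_pmid[, i]), numeric(1)))
      errors <- c(errors, err)
      if (err < threshold) { converged <- TRUE; break }
    }
    prev_pmid <- pmid
  }
  if (!converged)
    warning("network did not converge within ", max_cycles,
            " cycles (last error ",
            signif(if (length(errors)) errors[length(errors)] else NA, 4),
            " mmHg)")

  tgrid <- seq(0, period, by = settings$sample_dt)
  vessels_out <- stats::setNames(lapply(seq_along(vn), function(i) {
    s <- res$samples[[i]]
    colnames(s) <- c("A_prox", "Q_prox", "A_mid", "Q_mid", "A_dist", "Q_dist")
    s
  }), vn)
  structure(list(time = tgrid, vessels = vessels_out, network = net,
                 converged = converged, n_cycles = cycle, errors = errors,
                 threshold = threshold, period = period, state = state,
                 settings = settings),
            class = "mt_simulation")
}

sim_vessel_samples <- function(sim, vessel) {
  s <- sim$vessels[[vessel]]
  if (is.null(s)) stop("no vessel '", vessel, "' in this simulation")
  s
}

#' Per-vessel time series of a converged simulation
#'
#' @param sim an `mt_simulation`.
#' @param vessel vessel name.
#' @param units `"clinical"` (pressure mmHg, flow ml/min, velocity m/s) or
#'   `"SI"`.
#' @return data.frame with time and proximal/mid/distal pressure and flow,
#'   mid-vessel area and velocity.
#' @export
vessel_trace <- function(sim, vessel, units = c("clinical", "SI")) {
  units <- match.arg(units)
  s <- sim_vessel_samples(sim, vessel)
  v <- sim$network$vessels[[vessel]]
  P <- function(A) v$Pext + v$beta * (sqrt(A / v$A0) - 1)
  out <- data.frame(
    t = sim$time,
    P_prox = P(s[, "A_prox"]), P_mid = P(s[, "A_mid"]),
    P_dist = P(s[, "A_dist"]),
    Q_prox = s[, "Q_prox"], Q_mid = s[, "Q_mid"], Q_dist = s[, "Q_dist"],
    A_mid = s[, "A_mid"], u_mid = s[, "Q_mid"] / s[, "A_mid"])
  if (units == "clinical") {
    out[c("P_prox", "P_mid", "P_dist")] <-
      lapply(out[c("P_prox", "P_mid", "P_dist")], pa_to_mmhg)
    out[c("Q_prox", "Q_mid", "Q_dist")] <-
      lapply(out[c("Q_prox", "Q_mid", "Q_dist")], m3s_to_mlmin)
  }
  out
}

#' Write simulation time series to CSV
#'
#' One CSV per vessel (clinical units), named `<vessel>.csv` under `dir`.
#'
#' @param sim an `mt_simulation`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_results <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (vn in names(sim$vessels))
    utils::write.csv(vessel_trace(sim, vn),
                     file.path(dir, paste0(vn, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat("1D pulse-wave simulation:", length(x$vessels), "vessels, ",
      x$n_cycles, "cycles,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(last error %.3g mmHg, threshold %g mmHg)\n",
              if (length(x$errors)) x$errors[length(x$errors)] else NA,
              x$threshold))
  invisible(x)
}

#' @export
summary.mt_simulation <- function(object, ...) {
  rows <- lapply(names(object$vessels), function(vn) {
    tr <- vessel_trace(object, vn)
    data.frame(vessel = vn,
               P_sys = max(tr$P_mid), P_dia = min(tr$P_mid),
               Q_mean = mean_flow(tr$Q_mid, object$time, input_units = "mlmin"),
               u_mean = mean(tr$u_mid))
  })
  out <- do.call(rbind, rows)
  attr(out, "converged") <- object$converged
  class(out) <- c("summary.mt_simulation", "data.frame")
  out
}

#' @export
print.summary.mt_simulation <- function(x, digits = 4, ...) {
  cat("Per-vessel cycle summary (P mmHg at midpoint, Q ml/min, u m/s):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mt_simulation <- function(x, vessels = NULL, what = c("pressure", "flow"),
                               ...) {
  what <- match.arg(what)
  if (is.null(vessels)) vessels <- utils::head(names(x$vessels), 4L)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::par(mfrow = c(1, 1))
  col <- grDevices::hcl.colors(length(vessels), "Dark 3")
  tr <- lapply(vessels, function(v) vessel_trace(x, v))
  y <- if (what == "pressure") lapply(tr, `[[`, "P_mid")
       else lapply(tr, `[[`, "Q_mid")
  ylab <- if (what == "pressure") "midpoint pressure [mmHg]"
          else "midpoint flow [ml/min]"
  graphics::matplot(x$time, do.call(cbind, y), type = "l", lty = 1,
                    col = col, xlab = "time in cycle [s]", ylab = ylab, ...)
  graphics::legend("topright", legend = vessels, col = col, lty = 1,
                   bty = "n")
  invisible(x)
}
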