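#' Wall stiffness coefficient of an elastic vessel
#'
#' Computes the stiffness coefficient \eqn{\beta} of the pressure--area
#' constitutive law \eqn{P(A) = P_{ext} + \beta(\sqrt{A/A_0} - 1)} from the
#' wall properties of a thin elastic tube:
#' \deqn{\beta = \frac{\sqrt{\pi}\, E\, h_0}{(1 - \nu^2)\sqrt{A_0}}}
#'
#' @param E Young's modulus of the wall, Pa.
#' @param h0 wall thickness, m.
#' @param nu Poisson ratio of the wall (0 <= nu < 1); 0.5 for an
#'   incompressible wall.
#' @param A0 diastolic lumen area, m^2.
#' @return stiffness coefficient beta, Pa.
#' @examples
#' compute_beta(E = 1e6, h0 = 5e-4, nu = 0.5, A0 = 2e-5)
#' @export
compute_beta <- function(E, h0, nu, A0) {
  if (any(E <= 0) || any(h0 <= 0) || any(A0 <= 0))
    stop("E, h0 and A0 must be > 0")
  if (any(nu < 0) || any(nu >= 1))
    stop("nu must satisfy 0 <= nu < 1")
  sqrt(pi) * E * h0 / ((1 - nu^2) * sqrt(A0))
}

#' Define one elastic vessel segment
#'
#' A vessel is a straight elastic tube characterised by its length, diastolic
#' lumen area (or radius), wall thickness, Young's modulus and Poisson ratio.
#' The stiffness coefficient beta of the tube law is derived with
#' [compute_beta()] and stored on the segment. The lumen is discretised into
#' `M` finite-volume cells.
#'
#' @param name identifier, unique within a network.
#' @param L length, m.
#' @param A0 diastolic lumen area, m^2. Give either `A0` or `radius`.
#' @param radius diastolic lumen radius, m (used if `A0` is missing).
#' @param h0 wall thickness, m.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio; default 0.5.
#' @param Pext external pressure, Pa; default 0.
#' @param M number of finite-volume cells (>= 5). If `NULL`, chosen so the
#'   cell size is at most `dx_target` with a floor of 10 cells.
#' @param dx_target target cell size, m, used when `M` is `NULL`.
#' @return an object of class `vessel_segment`.
#' @examples
#' vessel_segment("mca", L = 0.06, radius = 1.4e-3, h0 = 3e-4, E = 8e5)
#' @export
vessel_segment <- function(name, L, A0 = NULL, radius = NULL, h0, E,
                           nu = 0.5, Pext = 0, M = NULL, dx_target = 5e-3) {
  if (is.null(A0)) {
    if (is.null(radius)) stop("give A0 or radius for vessel '", name, "'")
    A0 <- pi * radius^2
  }
  if (L <= 0 || A0 <= 0 || h0 <= 0 || E <= 0)
    stop("L, A0, h0, E must be > 0 for vessel '", name, "'")
  if (is.null(M)) M <- max(10L, as.integer(ceiling(L / dx_target)))
  M <- as.integer(M)
  if (M < 5L) stop("vessel '", name, "' needs at least 5 cells, got ", M)
  structure(list(name = as.character(name), L = L, A0 = A0, h0 = h0,
                 E = E, nu = nu, Pext = Pext, M = M, dx = L / M,
                 beta = compute_beta(E, h0, nu, A0)),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("Vessel '%s': L = %.3g m, A0 = %.3g m^2, h0 = %.3g m, E = %.3g Pa, M = %d cells, beta = %.4g Pa\n",
              x$name, x$L, x$A0, x$h0, x$E, x$M, x$beta))
  invisible(x)
}

#' Transmural pressure from lumen area
#'
#' Evaluates the tube law \eqn{P(A) = P_{ext} + \beta(\sqrt{A/A_0} - 1)}.
#' Monotonically increasing in A.
#'
#' @param A lumen area(s), m^2; must be > 0.
#' @param vessel a [vessel_segment()].
#' @return pressure in Pa.
#' @export
pressure_from_area <- function(A, vessel) {
  if (any(A <= 0)) stop("invalid state: lumen area must be > 0")
  vessel$Pext + vessel$beta * (sqrt(A / vessel$A0) - 1)
}

#' Local pulse wave speed
#'
#' The characteristic speed \eqn{c = \sqrt{(A/\rho)\, dP/dA}} of the 1D
#' system, which for the square-root tube law evaluates to
#' \eqn{c(A) = \sqrt{\beta \sqrt{A} / (2 \rho \sqrt{A_0})}}. At the diastolic
#' area this reduces to \eqn{c_0 = \sqrt{\beta/(2\rho)}}.
#'
#' @inheritParams pressure_from_area
#' @param fluid a [fluid_properties()].
#' @return wave speed in m/s.
#' @export
wave_speed <- function(A, vessel, fluid = fluid_properties()) {
  if (any(A <= 0)) stop("invalid state: lumen area must be > 0")
  sqrt(vessel$beta * sqrt(A) / (2 * fluid$density * sqrt(vessel$A0)))
}

#' Half-sine inlet flow waveform
#'
#' The cardiac inflow imposed at the network inlet: half a sinusoid of peak
#' amplitude `peak_flow` lasting `systole` seconds, followed by zero flow for
#' the remainder of the cardiac period. The amplitude is multiplied by the
#' dimensionless cardiac-output scale `scale`, which is how the ageing model
#' modulates cardiac output.
#'
#' @param peak_flow peak inflow, m^3/s. Default 3.5e-4 (350 ml/s).
#' @param systole systole duration t_s, s. Default 0.3.
#' @param period cardiac period T, s. Default 1.0.
#' @param scale dimensionless amplitude multiplier. Default 1.
#' @return an object of class `inlet_waveform`; call it via
#'   [inlet_flow()] to evaluate the flow at time t.
#' @examples
#' w <- inlet_waveform()
#' inlet_flow(w, c(0, 0.15, 0.3, 0.5))
#' @export
inlet_waveform <- function(peak_flow = 3.5e-4, systole = 0.3,
                           period = 1.0, scale = 1.0) {
  if (systole <= 0 || systole >= period) stop("need 0 < systole < period")
  if (peak_flow <= 0) stop("peak_flow must be > 0")
  structure(list(peak_flow = peak_flow, systole = systole,
                 period = period, scale = scale),
            class = "inlet_waveform")
}

#' Evaluate an inlet waveform
#'
#' @param waveform an [inlet_waveform()].
#' @param t time(s), s; evaluated modulo the cardiac period.
#' @return inflow in m^3/s.
#' @export
inlet_flow <- function(waveform, t) {
  tm <- t %% waveform$period
  ifelse(tm <= waveform$systole,
         waveform$scale * waveform$peak_flow * sin(pi * tm / waveform$systole),
         0)
}

#' Three-element windkessel outlet
#'
#' Lumped model of the distal vasculature terminating a 1D vessel: proximal
#' resistance R1 in series with the parallel combination of distal
#' resistance R2 and compliance C, discharging at pressure Pout. The
#' capacitor pressure Pc is the model state.
#'
#' @param R1 proximal resistance, Pa s/m^3 (>= 0). Setting R1 to the
#'   characteristic impedance rho c0/A0 of the attached vessel minimises
#'   spurious wave reflection.
#' @param R2 distal resistance, Pa s/m^3 (> 0).
#' @param C compliance, m^3/Pa (> 0).
#' @param Pout outflow (venous) pressure, Pa. Default 0.
#' @param Pc initial capacitor pressure, Pa. Default `Pout`.
#' @return an object of class `windkessel3`.
#' @export
windkessel3 <- function(R1, R2, C, Pout = 0, Pc = Pout) {
  if (R1 < 0) stop("R1 must be >= 0")
  if (R2 <= 0) stop("R2 must be > 0")
  if (C <= 0) stop("C must be > 0")
  structure(list(R1 = R1, R2 = R2, C = C, Pout = Pout, Pc = Pc),
            class = "windkessel3")
}
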