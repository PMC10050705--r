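#' Blood rheology and velocity-profile constants
#'
#' Bundles the fluid parameters of the 1D momentum balance: density
#' \eqn{\rho}, dynamic viscosity \eqn{\mu}, the velocity-profile exponent
#' \eqn{\gamma_v} and the Coriolis (momentum-flux correction) coefficient
#' \eqn{\alpha}. The defaults describe blood with a parabolic velocity
#' profile (\eqn{\gamma_v = 2}, \eqn{\alpha = 4/3}), for which the wall
#' friction term reduces to the Poiseuille value \eqn{-8\pi\nu Q/A}.
#'
#' @param density blood density \eqn{\rho} in kg/m^3. Default 1060.
#' @param viscosity dynamic viscosity \eqn{\mu} in Pa s. Default 4e-3.
#' @param gamma_v velocity-profile exponent (>= 2); 2 gives a parabolic
#'   profile.
#' @param alpha Coriolis coefficient (>= 1); 4/3 for a parabolic profile.
#' @return an object of class `fluid_properties`.
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(density = 1060, viscosity = 4e-3,
                             gamma_v = 2, alpha = 4 / 3) {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(viscosity) || viscosity <= 0) stop("viscosity must be > 0")
  if (gamma_v < 2) stop("gamma_v must be >= 2")
  if (alpha < 1) stop("alpha must be >= 1")
  structure(list(density = density, viscosity = viscosity,
                 gamma_v = gamma_v, alpha = alpha),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid: rho =", x$density, "kg/m^3, mu =", x$viscosity,
      "Pa s, gamma_v =", x$gamma_v, ", alpha =", round(x$alpha, 4), "\n")
  invisible(x)
}
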