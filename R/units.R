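#' Unit conversion helpers
#'
#' The solver works in SI units internally (Pa, m, s). Reported quantities
#' follow clinical convention: pressures in mmHg, flows in ml/min or ml/s,
#' velocities in m/s. These helpers convert between the two.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

MMHG_PA <- 133.322387415

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
mls_to_m3s <- function(x) x * 1e-6

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * 6e7

#' @rdname units
#' @export
mlmin_to_m3s <- function(x) x / 6e7
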