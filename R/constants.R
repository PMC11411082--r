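#' Physical constants in internal units
#'
#' The package works in a fixed internal unit system: length in Angstrom (A),
#' time in femtoseconds (fs), energy in electron-volts (eV), charge in units
#' of the elementary charge (e), temperature in Kelvin (K). In these units an
#' electric field given in V/A is numerically identical to eV e^-1 A^-1, so
#' the coupling of a field to a charge (or to an atomic polar tensor, which
#' is dimensionless in e) needs no conversion factor: a charge of 1 e in a
#' field of 1 V/A feels a force of exactly 1 eV/A.
#'
#' Masses are supplied in g/mol and converted internally to eV fs^2 A^-2
#' (see [massToInternal()]).
#'
#' @return A named list with elements
#' \describe{
#'   \item{epsilon0}{vacuum permittivity, e^2 eV^-1 A^-1 (approx. 5.5263e-3)}
#'   \item{kB}{Boltzmann constant, eV K^-1 (approx. 8.6173e-5)}
#'   \item{cLight}{speed of light, A fs^-1 (2997.92458)}
#'   \item{cLightCm}{speed of light, cm fs^-1 (used for wavenumber grids)}
#'   \item{coulomb}{Coulomb constant 1/(4 pi epsilon0), eV A e^-2
#'     (approx. 14.3996)}
#'   \item{massConv}{conversion factor g/mol -> eV fs^2 A^-2
#'     (approx. 103.6427)}
#' }
#' @examples
#' physicalConstants()$kB
#' @export
physicalConstants <- function() {
  list(
    epsilon0 = 5.526349406e-3,
    kB       = 8.617333262e-5,
    cLight   = 2997.92458,
    cLightCm = 2.99792458e-5,
    coulomb  = 14.39964548,
    massConv = 103.642697
  )
}

#' Convert atomic masses from g/mol to internal units
#'
#' Internal masses carry units of eV fs^2 A^-2 so that
#' `0.5 * m * v^2` with velocities in A/fs is an energy in eV.
#'
#' @param mass numeric vector of masses in g/mol.
#' @return numeric vector of masses in eV fs^2 A^-2.
#' @export
massToInternal <- function(mass) {
  mass * physicalConstants()$massConv
}
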