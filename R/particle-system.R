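#' Construct a particle system
#'
#' A `ParticleSystem` is the mechanical state of a simulation: per-atom
#' species labels, masses, positions, velocities, a cubic periodic cell and a
#' molecule index grouping atoms into molecules. Positions are kept
#' *unwrapped*: they may lie outside `[0, cellEdge)`, and the minimum-image
#' convention is applied only inside interaction and geometry code, so that
#' the dipole moment of a charge model is a continuous function of time.
#'
#' @param species character vector of element labels, length N.
#' @param mass numeric vector of masses in g/mol, length N, strictly positive.
#' @param position N x 3 numeric matrix, Angstrom.
#' @param velocity N x 3 numeric matrix, A/fs. Defaults to zeros.
#' @param cellEdge scalar cubic cell edge, Angstrom, > 0.
#' @param moleculeIndex integer vector grouping atoms into molecules;
#'   indices must be contiguous starting at 1 and all atoms of one molecule
#'   must share one index. Defaults to one atom per molecule.
#' @return An object of class `ParticleSystem`.
#' @examples
#' sys <- particleSystem(
#'   species = c("A", "B"), mass = c(1, 1),
#'   position = rbind(c(0, 0, 0), c(1, 0, 0)),
#'   cellEdge = 10, moleculeIndex = c(1, 1)
#' )
#' nAtoms(sys)
#' @export
particleSystem <- function(species, mass, position, velocity = NULL,
                           cellEdge, moleculeIndex = NULL) {
  position <- as.matrix(position)
  n <- nrow(position)
  if (ncol(position) != 3L)
    stop("`position` must be an N x 3 matrix")
  if (length(species) != n || length(mass) != n)
    stop("`species` and `mass` must have one entry per atom")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("masses must be strictly positive and finite")
  if (!is.numeric(cellEdge) || length(cellEdge) != 1L || cellEdge <= 0)
    stop("`cellEdge` must be a positive scalar")
  if (is.null(velocity)) velocity <- matrix(0, n, 3L)
  velocity <- as.matrix(velocity)
  if (!all(dim(velocity) == c(n, 3L)))
    stop("`velocity` must be an N x 3 matrix")
  if (is.null(moleculeIndex)) moleculeIndex <- seq_len(n)
  moleculeIndex <- as.integer(moleculeIndex)
  if (length(moleculeIndex) != n)
    stop("`moleculeIndex` must have one entry per atom")
  u <- unique(moleculeIndex)
  if (!identical(sort(u), seq_along(u)))
    stop("molecule indices must be contiguous starting at 1")
  structure(
    list(
      species = as.character(species),
      mass = as.numeric(mass),
      position = unname(position),
      velocity = unname(velocity),
      cellEdge = as.numeric(cellEdge),
      moleculeIndex = moleculeIndex
    ),
    class = "ParticleSystem"
  )
}

#' @export
print.ParticleSystem <- function(x, ...) {
  cat("ParticleSystem:", length(x$species), "atoms,",
      max(x$moleculeIndex), "molecules\n")
  cat("  species:", paste(names(table(x$species)),
                          table(x$species), collapse = ", "), "\n")
  cat("  cubic cell edge:", format(x$cellEdge), "A\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `ParticleSystem`.
#' @return integer atom count.
#' @export
nAtoms <- function(system) length(system$species)

#' Cell volume
#' @param system a `ParticleSystem`.
#' @return volume in A^3.
#' @export
cellVolume <- function(system) system$cellEdge^3

#' Minimum-image convention for displacement vectors
#'
#' Maps each Cartesian component of a displacement into
#' `[-cellEdge/2, cellEdge/2)` (lower-closed convention). Idempotent.
#'
#' @param displacement numeric 3-vector or N x 3 matrix of displacements, A.
#' @param cellEdge cubic cell edge, A, > 0.
#' @return object of the same shape with each component wrapped.
#' @examples
#' minimumImage(c(9, 0, 0), 10)   # -> c(-1, 0, 0)
#' @export
minimumImage <- function(displacement, cellEdge) {
  if (!is.numeric(cellEdge) || length(cellEdge) != 1L || cellEdge <= 0)
    stop("invalid geometry: `cellEdge` must be a positive scalar")
  displacement - cellEdge * floor(displacement / cellEdge + 0.5)
}

#' Kinetic energy of a system
#'
#' `sum_i 1/2 m_i |v_i|^2` with masses converted from g/mol to internal
#' eV fs^2 A^-2 units, so the result is in eV.
#'
#' @param system a `ParticleSystem`.
#' @return kinetic energy, eV.
#' @export
kineticEnergy <- function(system) {
  m <- massToInternal(system$mass)
  0.5 * sum(m * rowSums(system$velocity^2))
}

#' Centre-of-mass momentum
#'
#' `sum_i m_i v_i` in internal units (eV fs A^-1). Conserved by any
#' translation-invariant potential, and conserved under a homogeneous field
#' when the atomic polar tensors satisfy the acoustic sum rule.
#'
#' @param system a `ParticleSystem`.
#' @return numeric 3-vector.
#' @export
comMomentum <- function(system) {
  m <- massToInternal(system$mass)
  colSums(system$velocity * m)
}

#' Instantaneous kinetic temperature
#'
#' `2 E_kin / ((3N - nConstraints) kB)` in Kelvin.
#'
#' @param system a `ParticleSystem`.
#' @param nConstraints number of removed degrees of freedom (default 0).
#' @return temperature, K.
#' @export
instantaneousTemperature <- function(system, nConstraints = 0) {
  ndof <- 3L * nAtoms(system) - nConstraints
  if (ndof <= 0) stop("non-positive number of degrees of freedom")
  2 * kineticEnergy(system) / (ndof * physicalConstants()$kB)
}

#' Mass density of a system
#'
#' Total mass over cell volume, reported in kg/L (= g/cm^3).
#'
#' @param system a `ParticleSystem`.
#' @return density, kg/L.
#' @examples
#' # 128 water molecules in a 15.6627 A box have density ~0.996 kg/L
#' @export
massDensity <- function(system) {
  avogadro <- 6.02214076e23
  grams <- sum(system$mass) / avogadro
  volumeCm3 <- cellVolume(system) * 1e-24
  grams / volumeCm3
}

#' Simulation state record
#'
#' Bundles the energy bookkeeping of one MD frame. The conserved quantity of
#' a run under a static field is
#' `kinetic + potential + fieldEnergy - thermostatWork`, where
#' `fieldEnergy = -E . M` and `thermostatWork` accumulates the heat the
#' thermostat has injected.
#'
#' @param time time, fs.
#' @param step integer step counter.
#' @param potentialEnergy eV.
#' @param kineticEnergy eV.
#' @param fieldEnergy eV (the -E.M coupling term; 0 at zero field).
#' @param thermostatWork accumulated thermostat heat, eV.
#' @return An object of class `SimulationState`.
#' @export
simulationState <- function(time = 0, step = 0L, potentialEnergy = 0,
                            kineticEnergy = 0, fieldEnergy = 0,
                            thermostatWork = 0) {
  st <- list(time = time, step = as.integer(step),
             potentialEnergy = potentialEnergy,
             kineticEnergy = kineticEnergy,
             fieldEnergy = fieldEnergy,
             thermostatWork = thermostatWork)
  st$conservedQuantity <- potentialEnergy + kineticEnergy + fieldEnergy -
    thermostatWork
  if (!is.finite(st$conservedQuantity))
    stop("non-finite conserved quantity in simulation state")
  structure(st, class = "SimulationState")
}
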