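#' Specification of a synthetic starting configuration
#'
#' Describes a programmatically generated system: a box of flexible toy
#' water molecules, an ideal dipolar gas of +q/-q diatomics, or a gas of
#' neutral harmonic diatomics. Molecules are placed by rejection sampling
#' with uniformly random rigid orientations; velocities are drawn from the
#' Maxwell-Boltzmann distribution at the requested temperature with the
#' centre-of-mass drift removed. Generation is deterministic given `seed`.
#'
#' @param kind one of `"water_box"`, `"dipole_gas"`,
#'   `"harmonic_diatomic"`.
#' @param nMolecules number of molecules.
#' @param cellEdge cubic cell edge, A.
#' @param temperature initial kinetic temperature, K.
#' @param minSeparation smallest allowed intermolecular atom-atom distance,
#'   A.
#' @param seed integer RNG seed.
#' @param bondLength equilibrium bond length of the diatomic kinds, A.
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(kind = c("water_box", "dipole_gas",
                                 "harmonic_diatomic"),
                        nMolecules, cellEdge, temperature = 300,
                        minSeparation = 1.5, seed = 1,
                        bondLength = 1.0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, nMolecules = as.integer(nMolecules),
                 cellEdge = cellEdge, temperature = temperature,
                 minSeparation = minSeparation, seed = as.integer(seed),
                 bondLength = bondLength),
            class = "FixtureSpec")
}

#' @keywords internal
#' @noRd
randomRotation <- function() {
  # uniform rotation from a random unit quaternion
  u <- stats::runif(3L)
  q <- c(sqrt(1 - u[1L]) * sin(2 * pi * u[2L]),
         sqrt(1 - u[1L]) * cos(2 * pi * u[2L]),
         sqrt(u[1L]) * sin(2 * pi * u[3L]),
         sqrt(u[1L]) * cos(2 * pi * u[3L]))
  w <- q[4L]; x <- q[1L]; y <- q[2L]; z <- q[3L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Build a starting configuration from a fixture specification
#'
#' @param spec a [fixtureSpec()].
#' @return A `ParticleSystem`.
#' @examples
#' sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = 10,
#'                                 cellEdge = 20, seed = 7))
#' @export
buildFixture <- function(spec) {
  set.seed(spec$seed)
  template <- switch(spec$kind,
    water_box = {
      th <- 109.47 * pi / 180
      r0 <- spec$bondLength
      list(species = c("O", "H", "H"),
           mass = c(15.999, 1.008, 1.008),
           coords = rbind(c(0, 0, 0),
                          r0 * c(sin(th / 2), 0, cos(th / 2)),
                          r0 * c(-sin(th / 2), 0, cos(th / 2))))
    },
    dipole_gas = list(
      species = c("A", "B"), mass = c(2.0, 2.0),
      coords = rbind(c(0, 0, spec$bondLength / 2),
                     c(0, 0, -spec$bondLength / 2))),
    harmonic_diatomic = list(
      species = c("X", "Y"), mass = c(4.0, 4.0),
      coords = rbind(c(0, 0, spec$bondLength / 2),
                     c(0, 0, -spec$bondLength / 2)))
  )
  natPer <- length(template$species)
  n <- spec$nMolecules
  exclusion <- n * (4 / 3) * pi * (spec$minSeparation / 2)^3 * natPer
  if (exclusion >= spec$cellEdge^3)
    stop("infeasible packing: shrink the system or enlarge the cell")
  placed <- matrix(NA_real_, 0L, 3L)
  positions <- matrix(NA_real_, n * natPer, 3L)
  maxAttempts <- 500L * n
  attempts <- 0L
  for (im in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("packing failed after ", maxAttempts,
             " attempts; try a larger cell or smaller minSeparation")
      rot <- randomRotation()
      com <- stats::runif(3L, 0, spec$cellEdge)
      cand <- template$coords %*% t(rot) +
        matrix(com, natPer, 3L, byrow = TRUE)
      ok <- TRUE
      if (nrow(placed)) {
        for (a in seq_len(natPer)) {
          d <- minimumImage(sweep(placed, 2L, cand[a, ], "-"),
                            spec$cellEdge)
          if (min(rowSums(d^2)) < spec$minSeparation^2) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    rows <- ((im - 1L) * natPer + 1L):(im * natPer)
    positions[rows, ] <- cand
    placed <- rbind(placed, cand)
  }
  sys <- particleSystem(
    species = rep(template$species, n),
    mass = rep(template$mass, n),
    position = positions,
    cellEdge = spec$cellEdge,
    moleculeIndex = rep(seq_len(n), each = natPer)
  )
  if (spec$temperature > 0)
    sys <- maxwellBoltzmannVelocities(sys, spec$temperature)
  sys
}
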