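# Shared builders for test systems. Everything is generated in code under
# fixed seeds; no data files.

# random proper rotation matrix
randomRotationMatrix <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# diatomic gas with every bond stretched by `stretch` (fraction) and zero
# velocities: pure vibrational excitation, no rotation
stretchedDiatomics <- function(n, cellEdge, stretch = 0.05, seed = 1,
                               kind = "harmonic_diatomic") {
  sys <- buildFixture(fixtureSpec(kind, nMolecules = n, cellEdge = cellEdge,
                                  temperature = 0, seed = seed,
                                  minSeparation = 2.5))
  p <- sys$position
  for (m in seq_len(n)) {
    idx <- which(sys$moleculeIndex == m)
    com <- colMeans(p[idx, , drop = FALSE])
    p[idx, ] <- sweep(p[idx, , drop = FALSE], 2L, com) * (1 + stretch) +
      rep(com, each = 2L)
  }
  sys$position <- p
  sys
}

# a compact cluster far from the cell boundary: minimum-image wrapping is
# inactive, so rotations of the cluster are exact symmetries of the
# neighbour environment
clusterDipoleGas <- function(n, seed = 1, q = 0.83) {
  sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = n,
                                  cellEdge = 60, temperature = 0,
                                  seed = seed, minSeparation = 2))
  sys$position <- sys$position * 0.2 + 20
  sys
}

# bond-charge training pairs with jittered bond lengths
bondChargeTrainingPair <- function(seed, nMolecules = 10, cellEdge = 18,
                                   q0 = 0.8, kappa = 0.4, r0 = 1) {
  sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = nMolecules,
                                  cellEdge = cellEdge, temperature = 300,
                                  seed = seed, minSeparation = 2))
  sys$position <- sys$position +
    matrix(stats::rnorm(nAtoms(sys) * 3L, sd = 0.05), ncol = 3L)
  list(system = sys, apts = bondChargeAPT(sys, q0 = q0, kappa = kappa,
                                          r0 = r0))
}

# finite-difference force on one coordinate from the energy alone
fdForce <- function(potential, system, i, xi, h = 1e-4) {
  sp <- system; sp$position[i, xi] <- sp$position[i, xi] + h
  sm <- system; sm$position[i, xi] <- sm$position[i, xi] - h
  -(potential(sp)$energy - potential(sm)$energy) / (2 * h)
}
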