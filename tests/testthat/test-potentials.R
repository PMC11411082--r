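test_that("isolated water at its equilibrium geometry has zero energy and forces", {
  sys <- buildFixture(fixtureSpec("water_box", nMolecules = 1,
                                  cellEdge = 20, temperature = 0, seed = 1))
  res <- evaluateHarmonicWater(sys)
  expect_equal(res$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(res$forces)), 0, tolerance = 1e-10)
})

test_that("stretching one OH bond costs the harmonic energy", {
  sys <- buildFixture(fixtureSpec("water_box", nMolecules = 1,
                                  cellEdge = 20, temperature = 0, seed = 1))
  params <- waterModelParams()
  delta <- 0.07
  d <- sys$position[2L, ] - sys$position[1L, ]
  sys$position[2L, ] <- sys$position[1L, ] + d * (1 + delta)
  res <- evaluateHarmonicWater(sys, params)
  # bond stretched by delta*r0; the angle is unchanged by radial scaling
  expect_equal(res$energy, 0.5 * params$kBond * (delta * params$r0)^2,
               tolerance = 1e-10)
})

test_that("diatomic potentials are harmonic in the bond length", {
  sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = 3,
                                  cellEdge = 20, temperature = 0, seed = 2))
  expect_equal(evaluateIdealDipoleGas(sys, q = 0.8, kBond = 5,
                                      r0 = 1)$energy, 0, tolerance = 1e-12)
  # stretch one bond by delta
  delta <- 0.04
  idx <- which(sys$moleculeIndex == 2L)
  com <- colMeans(sys$position[idx, ])
  sys$position[idx, ] <- sweep(sys$position[idx, ], 2L, com) * (1 + delta) +
    rep(com, each = 2L)
  res <- evaluateIdealDipoleGas(sys, q = 0.8, kBond = 5, r0 = 1)
  expect_equal(res$energy, 0.5 * 5 * delta^2, tolerance = 1e-10)
  # forces on the stretched pair: equal magnitude k*delta, antiparallel
  f <- res$forces[idx, ]
  expect_equal(f[1L, ], -f[2L, ])
  expect_equal(sqrt(sum(f[1L, ]^2)), 5 * delta, tolerance = 1e-10)
  expect_error(evaluateHarmonicOscillator(
    buildFixture(fixtureSpec("water_box", nMolecules = 1, cellEdge = 20,
                             temperature = 0, seed = 1)), 5, 1),
    "topology")
})

test_that("forces are the exact negative gradient for all potentials", {
  set.seed(31)
  pots <- list(
    water = list(
      make = function(seed) {
        s <- buildFixture(fixtureSpec("water_box", nMolecules = 6,
                                      cellEdge = 14, seed = seed,
                                      minSeparation = 1.8))
        s$position <- s$position +
          matrix(rnorm(nAtoms(s) * 3, sd = 0.04), ncol = 3L)
        s
      },
      fn = function(s) evaluateHarmonicWater(s)),
    gas = list(
      make = function(seed) {
        s <- buildFixture(fixtureSpec("dipole_gas", nMolecules = 6,
                                      cellEdge = 14, seed = seed,
                                      minSeparation = 2))
        s$position <- s$position +
          matrix(rnorm(nAtoms(s) * 3, sd = 0.05), ncol = 3L)
        s
      },
      fn = function(s) evaluateIdealDipoleGas(s, q = 0.8, kBond = 5,
                                              r0 = 1))
  )
  for (p in pots) {
    for (seed in 1:10) {
      sys <- p$make(seed)
      res <- p$fn(sys)
      scale <- max(1, max(abs(res$forces)))
      for (probe in 1:3) {
        i <- sample.int(nAtoms(sys), 1L)
        xi <- sample.int(3L, 1L)
        fd <- fdForce(p$fn, sys, i, xi)
        expect_lt(abs(fd - res$forces[i, xi]) / scale, 1e-6)
      }
      # translation invariance of a periodic potential
      shifted <- sys
      shifted$position <- sweep(sys$position, 2L, c(1.7, -0.9, 4.2), "+")
      expect_equal(p$fn(shifted)$energy, res$energy, tolerance = 1e-10)
      # net force vanishes
      expect_lt(max(abs(colSums(res$forces))), 1e-10)
    }
  }
})

test_that("harmonic diatomic NVE trajectory conserves energy tightly", {
  sys <- stretchedDiatomics(1, cellEdge = 20, stretch = 0.05, seed = 3)
  k <- 5
  freq <- harmonicFrequency(k, 4, 4)
  dt <- (2 * pi / freq$omega0) / 100
  pot <- function(s) evaluateHarmonicOscillator(s, k = k, r0 = 1)
  traj <- runProtocol(sys, pot, NULL, fieldProtocol(1e4 * dt, c(0, 0, 0)),
                      dt = dt, stride = 1L)
  e <- traj$energies[, "potential"] + traj$energies[, "kinetic"]
  # symplectic integrator: the energy error is a bounded oscillation of
  # amplitude O((w*dt)^2) with no secular drift; period-averaged energies
  # at the two ends of the run agree to <1e-5 relative
  nAvg <- 1000L
  drift <- abs(mean(e[seq_len(nAvg)]) - mean(e[length(e) - seq_len(nAvg)]))
  expect_lt(drift / abs(e[1L]), 1e-5)
  omegaDt <- freq$omega0 * dt
  expect_lt(max(abs(e - mean(e))) / abs(e[1L]), omegaDt^2)
})

test_that("dipolar-gas alignment under a field follows the Langevin function", {
  set.seed(44)
  q <- 0.83; r0 <- 1; Tt <- 300; Ez <- 0.012
  sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = 100,
                                  cellEdge = 32, temperature = Tt,
                                  seed = 44, minSeparation = 2))
  pot <- function(s) evaluateIdealDipoleGas(s, q = q, kBond = 5, r0 = r0)
  model <- fixedChargeModel(dipoleGasCharges(sys, q))
  traj <- runProtocol(sys, pot, model,
                      fieldProtocol(c(6000, 18000),
                                    rbind(c(0, 0, Ez), c(0, 0, Ez))),
                      thermostat = thermostatConfig("andersen", Tt, 500),
                      dt = 1, stride = 20L,
                      dipoleFn = function(s)
                        systemDipole(s, dipoleGasCharges(s, q)))
  sel <- traj$segment == 2L
  # <M_z> = N mu L(mu E / kB T) for independent classical dipoles
  mz <- traj$M[sel, 3L]
  kB <- physicalConstants()$kB
  x <- q * r0 * Ez / (kB * Tt)
  langevin <- 1 / tanh(x) - 1 / x
  expectMz <- 100 * q * r0 * langevin
  act <- integratedAutocorrelationTime(mz, 20)
  sem <- sd(mz) / sqrt(length(mz) * 20 / (2 * act))
  expect_lt(abs(mean(mz) - expectMz), 4 * sem + 0.02 * expectMz)
})

test_that("zero-field dipolar gas has <M> near zero and <M^2> near N mu^2", {
  set.seed(45)
  q <- 0.83; r0 <- 1
  sys <- buildFixture(fixtureSpec("dipole_gas", nMolecules = 100,
                                  cellEdge = 32, temperature = 300,
                                  seed = 45, minSeparation = 2))
  pot <- function(s) evaluateIdealDipoleGas(s, q = q, kBond = 5, r0 = r0)
  model <- fixedChargeModel(dipoleGasCharges(sys, q))
  traj <- runProtocol(sys, pot, model, fieldProtocol(25000, c(0, 0, 0)),
                      thermostat = thermostatConfig("andersen", 300, 500),
                      dt = 1, stride = 20L,
                      dipoleFn = function(s)
                        systemDipole(s, dipoleGasCharges(s, q)))
  sel <- traj$times > 5000
  m <- traj$M[sel, ]
  nmu2 <- 100 * (q * r0)^2
  # independent dipoles: <M^2> = N mu^2 (up to bond-vibration corrections)
  expect_lt(abs(mean(rowSums(m^2)) - nmu2) / nmu2, 0.35)
  expect_lt(max(abs(colMeans(m))) / sqrt(nmu2), 1.0)
})
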