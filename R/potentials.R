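#' @keywords internal
#' @noRd
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' @keywords internal
#' @noRd
moleculeList <- function(system) {
  split(seq_len(nAtoms(system)), system$moleculeIndex)
}

#' @keywords internal
#' @noRd
potentialResult <- function(energy, forces) {
  structure(list(energy = energy, forces = forces), class = "PotentialResult")
}

#' @export
print.PotentialResult <- function(x, ...) {
  cat("PotentialResult: energy", format(x$energy), "eV, max |F|",
      format(max(abs(x$forces))), "eV/A\n")
  invisible(x)
}

# all i<j pairs within `cutoff` under minimum image; returns displacement
# r_i - r_j (wrapped), distance, and atom indices
#' @keywords internal
#' @noRd
pairTable <- function(system, cutoff) {
  n <- nAtoms(system)
  if (n < 2L)
    return(list(i = integer(0), j = integer(0),
                dx = matrix(0, 0, 3), r = numeric(0)))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  dx <- minimumImage(system$position[i, , drop = FALSE] -
                     system$position[j, , drop = FALSE], system$cellEdge)
  r <- sqrt(rowSums(dx^2))
  keep <- r < cutoff
  list(i = i[keep], j = j[keep], dx = dx[keep, , drop = FALSE], r = r[keep])
}

#' Parameters of the flexible toy water model
#'
#' A flexible three-site water model used as an analytic stand-in for a
#' machine-learned interatomic potential: harmonic O-H bonds, a harmonic
#' H-O-H angle, Lennard-Jones between oxygen pairs and damped-shifted-force
#' (Wolf-style) real-space Coulomb between atoms of different molecules.
#' Both non-bonded terms are force- and potential-shifted so energy and
#' forces go to zero continuously at the cutoff; the model is exactly
#' differentiable, which the finite-difference force tests exploit.
#' Charges default to SPC/E values.
#'
#' @param kBond harmonic bond constant, eV/A^2.
#' @param r0 equilibrium O-H bond length, A.
#' @param kAngle harmonic angle constant, eV/rad^2.
#' @param theta0 equilibrium H-O-H angle, rad.
#' @param qO,qH partial charges, e; must satisfy `qO + 2 qH = 0`.
#' @param ljEpsilon,ljSigma Lennard-Jones parameters for O-O pairs, eV and A.
#' @param coulombCutoff real-space cutoff for Coulomb and LJ, A.
#' @param wolfAlpha Wolf damping parameter, 1/A.
#' @return A list of class `WaterModelParams`.
#' @export
waterModelParams <- function(kBond = 25.0, r0 = 1.0, kAngle = 3.0,
                             theta0 = 109.47 * pi / 180,
                             qO = -0.8476, qH = 0.4238,
                             ljEpsilon = 6.739e-3, ljSigma = 3.166,
                             coulombCutoff = 6.0, wolfAlpha = 0.2) {
  if (abs(qO + 2 * qH) > 1e-12)
    stop("water model must be neutral: qO + 2*qH = 0")
  structure(list(kBond = kBond, r0 = r0, kAngle = kAngle, theta0 = theta0,
                 qO = qO, qH = qH, ljEpsilon = ljEpsilon, ljSigma = ljSigma,
                 coulombCutoff = coulombCutoff, wolfAlpha = wolfAlpha),
            class = "WaterModelParams")
}

#' Per-atom charges of a water system
#'
#' @param system a `ParticleSystem` of O,H,H molecules.
#' @param params a `WaterModelParams`.
#' @return numeric vector of charges, e.
#' @export
waterCharges <- function(system, params) {
  ifelse(system$species == "O", params$qO, params$qH)
}

#' Evaluate the flexible toy water potential
#'
#' Energy and exact analytic forces of the model described in
#' [waterModelParams()]. Every molecule must contain exactly three atoms in
#' the order O, H, H.
#'
#' @param system a `ParticleSystem`.
#' @param params a `WaterModelParams`.
#' @return A `PotentialResult` with `energy` (eV) and `forces`
#'   (N x 3 matrix, eV/A).
#' @export
evaluateHarmonicWater <- function(system, params = waterModelParams()) {
  mols <- moleculeList(system)
  if (any(lengths(mols) != 3L))
    stop("topology error: every water molecule must have exactly 3 atoms (O,H,H)")
  if (params$coulombCutoff >= system$cellEdge / 2)
    stop("cutoff must be smaller than half the cell edge")
  n <- nAtoms(system)
  forces <- matrix(0, n, 3L)
  energy <- 0

  # intramolecular terms use unwrapped coordinates (bonded atoms stay close)
  for (m in mols) {
    iO <- m[1L]; iH1 <- m[2L]; iH2 <- m[3L]
    for (iH in c(iH1, iH2)) {
      d <- system$position[iH, ] - system$position[iO, ]
      b <- sqrt(sum(d^2))
      db <- b - params$r0
      energy <- energy + 0.5 * params$kBond * db^2
      f <- -params$kBond * db * d / b
      forces[iH, ] <- forces[iH, ] + f
      forces[iO, ] <- forces[iO, ] - f
    }
    u <- system$position[iH1, ] - system$position[iO, ]
    v <- system$position[iH2, ] - system$position[iO, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    cth <- sum(u * v) / (lu * lv)
    cth <- min(1, max(-1, cth))
    th <- acos(cth)
    sth <- sqrt(max(1 - cth^2, 1e-12))
    dth <- th - params$theta0
    energy <- energy + 0.5 * params$kAngle * dth^2
    # dtheta/du = (cos(th) u/|u| - v/|v|) / (|u| sin th), likewise for v
    dthdu <- (cth * u / lu - v / lv) / (lu * sth)
    dthdv <- (cth * v / lv - u / lu) / (lv * sth)
    fH1 <- -params$kAngle * dth * dthdu
    fH2 <- -params$kAngle * dth * dthdv
    forces[iH1, ] <- forces[iH1, ] + fH1
    forces[iH2, ] <- forces[iH2, ] + fH2
    forces[iO, ] <- forces[iO, ] - fH1 - fH2
  }

  pt <- pairTable(system, params$coulombCutoff)
  if (length(pt$i)) {
    sameMol <- system$moleculeIndex[pt$i] == system$moleculeIndex[pt$j]
    inter <- !sameMol
    # damped-shifted-force Coulomb, intermolecular pairs only
    if (any(inter)) {
      q <- waterCharges(system, params)
      ii <- pt$i[inter]; jj <- pt$j[inter]
      r <- pt$r[inter]; dx <- pt$dx[inter, , drop = FALSE]
      a <- params$wolfAlpha; rc <- params$coulombCutoff
      ke <- physicalConstants()$coulomb
      s  <- function(x) erfc(a * x) / x
      sp <- function(x) -erfc(a * x) / x^2 -
        2 * a / sqrt(pi) * exp(-a^2 * x^2) / x
      qq <- ke * q[ii] * q[jj]
      energy <- energy + sum(qq * (s(r) - s(rc) - (r - rc) * sp(rc)))
      fmag <- -qq * (sp(r) - sp(rc))          # dV/dr with sign flipped
      fvec <- dx * (fmag / r)
      for (k in 1:3) {
        forces[, k] <- forces[, k] +
          as.vector(tapply(fvec[, k], factor(ii, levels = 1:n), sum,
                           default = 0)) -
          as.vector(tapply(fvec[, k], factor(jj, levels = 1:n), sum,
                           default = 0))
      }
    }
    # force-shifted LJ between oxygen pairs (always intermolecular)
    isO <- system$species[pt$i] == "O" & system$species[pt$j] == "O" & !sameMol
    if (any(isO)) {
      ii <- pt$i[isO]; jj <- pt$j[isO]
      r <- pt$r[isO]; dx <- pt$dx[isO, , drop = FALSE]
      eps <- params$ljEpsilon; sg <- params$ljSigma
      rc <- params$coulombCutoff
      vlj  <- function(x) 4 * eps * ((sg / x)^12 - (sg / x)^6)
      vljp <- function(x) 4 * eps * (-12 * sg^12 / x^13 + 6 * sg^6 / x^7)
      energy <- energy + sum(vlj(r) - vlj(rc) - (r - rc) * vljp(rc))
      fmag <- -(vljp(r) - vljp(rc))
      fvec <- dx * (fmag / r)
      for (k in 1:3) {
        forces[, k] <- forces[, k] +
          as.vector(tapply(fvec[, k], factor(ii, levels = 1:n), sum,
                           default = 0)) -
          as.vector(tapply(fvec[, k], factor(jj, levels = 1:n), sum,
                           default = 0))
      }
    }
  }
  potentialResult(energy, forces)
}

#' Evaluate the ideal dipolar gas potential
#'
#' Diatomic molecules carrying charges +q (first atom) and -q (second atom)
#' bound by a harmonic bond; there are *no* intermolecular interactions, so
#' the dielectric constant of the gas has the Langevin closed form
#' `eps_r - 1 = N mu^2 / (3 eps0 V kB T)` with `mu = q * bondLength`,
#' making it the analytic reference system for the dielectric observables.
#'
#' @param system a `ParticleSystem` of 2-atom molecules.
#' @param q charge magnitude, e.
#' @param kBond harmonic bond constant, eV/A^2.
#' @param r0 equilibrium bond length, A.
#' @return A `PotentialResult`.
#' @export
evaluateIdealDipoleGas <- function(system, q, kBond, r0) {
  evaluateHarmonicOscillator(system, k = kBond, r0 = r0)
}

#' Evaluate harmonic diatomic oscillators
#'
#' Per-molecule harmonic bond energy `1/2 k (b - r0)^2` for 2-atom
#' molecules; no intermolecular terms. The analytic vibrational angular
#' frequency is `omega0 = sqrt(k / muRed)` with the reduced mass in internal
#' units (see [harmonicFrequency()]), which the IR spectrum tests use as the
#' exact line position.
#'
#' @param system a `ParticleSystem` of 2-atom molecules.
#' @param k bond constant, eV/A^2.
#' @param r0 equilibrium bond length, A.
#' @return A `PotentialResult`.
#' @export
evaluateHarmonicOscillator <- function(system, k, r0) {
  p <- diatomicPartners(system)
  d <- system$position[p$a1, , drop = FALSE] -
       system$position[p$a2, , drop = FALSE]
  b <- sqrt(rowSums(d^2))
  db <- b - r0
  energy <- 0.5 * k * sum(db^2)
  fmat <- d * (-k * db / b)
  forces <- matrix(0, nAtoms(system), 3L)
  forces[p$a1, ] <- fmat
  forces[p$a2, ] <- -fmat
  potentialResult(energy, forces)
}

# first/second atom index of each 2-atom molecule (stable in atom order)
#' @keywords internal
#' @noRd
diatomicPartners <- function(system) {
  mi <- system$moleculeIndex
  if (length(mi) %% 2L != 0L || any(tabulate(mi) != 2L))
    stop("topology error: every molecule must have exactly 2 atoms")
  o <- order(mi)
  list(a1 = o[seq(1L, length(o), 2L)], a2 = o[seq(2L, length(o), 2L)])
}

#' Analytic vibration frequency of a harmonic diatomic
#'
#' @param k bond constant, eV/A^2.
#' @param mass1,mass2 atomic masses, g/mol.
#' @return list with `omega0` (rad/fs) and `wavenumber` (cm^-1).
#' @export
harmonicFrequency <- function(k, mass1, mass2) {
  mu <- massToInternal(mass1 * mass2 / (mass1 + mass2))
  omega0 <- sqrt(k / mu)
  list(omega0 = omega0,
       wavenumber = omega0 / (2 * pi * physicalConstants()$cLightCm))
}

#' Per-atom charges of a diatomic +q/-q gas
#'
#' @param system a `ParticleSystem` of 2-atom molecules.
#' @param q charge magnitude, e (first atom +q, second -q).
#' @return numeric vector of charges.
#' @export
dipoleGasCharges <- function(system, q) {
  p <- diatomicPartners(system)
  ch <- numeric(nAtoms(system))
  ch[p$a1] <- q
  ch[p$a2] <- -q
  ch
}

#' Total cell dipole moment of a fixed-charge model
#'
#' `M = sum_i q_i r_i` evaluated with unwrapped positions, so it is a
#' continuous function of time along a trajectory (the itinerant dipole of
#' a point-charge model).
#'
#' @param system a `ParticleSystem`.
#' @param charges per-atom charges, e.
#' @return numeric 3-vector, e A.
#' @export
systemDipole <- function(system, charges) {
  if (length(charges) != nAtoms(system))
    stop("`charges` must have one entry per atom")
  colSums(system$position * charges)
}
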