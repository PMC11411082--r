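#' Atomic polar tensor sets
#'
#' An `APTSet` stores one 3x3 atomic polar tensor (Born effective charge
#' tensor) per atom as an `N x 3 x 3` array with the storage convention
#' `tensors[i, zeta, xi] = dM_zeta / dr_{i,xi}`: the *row* index `zeta` is
#' the dipole component, the *column* index `xi` is the atomic displacement
#' component. With this convention the field-induced force is the
#' transpose contraction `F_{i,xi} = sum_zeta tensors[i, zeta, xi] E_zeta`
#' (see [fieldForces()]), and the dipole rate is
#' `Mdot_zeta = sum_{i,xi} tensors[i, zeta, xi] v_{i,xi}`
#' (see [dipoleRate()]).
#'
#' @param tensors an `N x 3 x 3` numeric array (or an `3 x 3` matrix for a
#'   single atom), all entries finite.
#' @return An object of class `APTSet`.
#' @export
aptSet <- function(tensors) {
  if (is.matrix(tensors) && all(dim(tensors) == c(3L, 3L)))
    tensors <- array(tensors, c(1L, 3L, 3L))
  if (!is.array(tensors) || length(dim(tensors)) != 3L ||
      dim(tensors)[2L] != 3L || dim(tensors)[3L] != 3L)
    stop("`tensors` must be an N x 3 x 3 array")
  if (any(!is.finite(tensors)))
    stop("APT entries must be finite")
  structure(list(tensors = tensors), class = "APTSet")
}

#' @export
print.APTSet <- function(x, ...) {
  s <- aptSum(x)
  cat("APTSet:", dim(x$tensors)[1L], "atoms; max |sum rule residual|",
      format(max(abs(s))), "\n")
  invisible(x)
}

#' Componentwise sum of an APT set over atoms
#'
#' The acoustic sum rule requires this 3x3 matrix to vanish.
#'
#' @param apts an `APTSet`.
#' @return 3x3 matrix `sum_i tensors[i, , ]`.
#' @export
aptSum <- function(apts) {
  apply(apts$tensors, c(2L, 3L), sum)
}

#' Exact APTs of a fixed-charge model
#'
#' For a dipole `M = sum_i q_i r_i` with configuration-independent charges,
#' the polar tensor of atom i is exactly `q_i` times the identity. For a
#' neutral system the acoustic sum rule holds exactly.
#'
#' @param system a `ParticleSystem`.
#' @param charges per-atom charges, e.
#' @return An `APTSet`.
#' @export
fixedChargeAPT <- function(system, charges) {
  n <- nAtoms(system)
  if (length(charges) != n)
    stop("`charges` must have one entry per atom")
  tensors <- array(0, c(n, 3L, 3L))
  for (k in 1:3) tensors[, k, k] <- charges
  aptSet(tensors)
}

#' Exact APTs of the bond-charge diatomic model
#'
#' An anisotropic analytic oracle: each diatomic molecule carries a
#' bond-length-dependent charge `q(b) = q0 + kappa (b - r0)` on its first
#' atom and `-q(b)` on its second, giving a molecular dipole
#' `M = q(b) (r1 - r2)`. The product rule yields, for atom 1,
#' `dM_zeta/dr_{1,xi} = q(b) delta_{zeta,xi} + kappa d_zeta bhat_xi`
#' with `d = r1 - r2`, `bhat = d/b`, and the negative of that for atom 2,
#' so the sum rule holds exactly molecule by molecule. The off-diagonal
#' dyadic term is what a learned APT model must capture beyond effective
#' point charges.
#'
#' @param system a `ParticleSystem` of 2-atom molecules.
#' @param q0 charge at the equilibrium bond length, e.
#' @param kappa charge-transfer slope, e/A.
#' @param r0 reference bond length, A.
#' @return An `APTSet`.
#' @export
bondChargeAPT <- function(system, q0, kappa, r0) {
  p <- diatomicPartners(system)
  n <- nAtoms(system)
  tensors <- array(0, c(n, 3L, 3L))
  d <- system$position[p$a1, , drop = FALSE] -
       system$position[p$a2, , drop = FALSE]
  b <- sqrt(rowSums(d^2))
  q <- q0 + kappa * (b - r0)
  bhat <- d / b
  for (zeta in 1:3) {
    for (xi in 1:3) {
      t1 <- kappa * d[, zeta] * bhat[, xi]
      if (zeta == xi) t1 <- t1 + q
      tensors[p$a1, zeta, xi] <- t1
      tensors[p$a2, zeta, xi] <- -t1
    }
  }
  aptSet(tensors)
}

#' Dipole function of the bond-charge model
#'
#' Returns `M(r^N) = sum_mol q(b) (r1 - r2)` for use with the
#' finite-difference oracle.
#'
#' @inheritParams bondChargeAPT
#' @return numeric 3-vector, e A.
#' @export
bondChargeDipole <- function(system, q0, kappa, r0) {
  p <- diatomicPartners(system)
  d <- system$position[p$a1, , drop = FALSE] -
       system$position[p$a2, , drop = FALSE]
  b <- sqrt(rowSums(d^2))
  q <- q0 + kappa * (b - r0)
  colSums(d * q)
}

#' Finite-difference dipole-derivative oracle
#'
#' Central differences of an arbitrary dipole function with respect to every
#' atomic Cartesian coordinate:
#' `tensors[i, zeta, xi] = (M_zeta(r_{i,xi}+h) - M_zeta(r_{i,xi}-h)) / 2h`.
#' Exact for dipoles linear in the coordinates (fixed charges) and
#' second-order accurate otherwise; the independent reference against which
#' analytic APTs and the learned regressor are validated.
#'
#' @param dipoleFn function of a `ParticleSystem` returning the 3-vector
#'   dipole moment, e A.
#' @param system a `ParticleSystem`.
#' @param h displacement step, A (> 0). Default 1e-3 balances truncation
#'   against round-off for dipoles of order e A.
#' @return An `APTSet`.
#' @export
finiteDifferenceAPT <- function(dipoleFn, system, h = 1e-3) {
  if (h <= 0) stop("`h` must be positive")
  n <- nAtoms(system)
  tensors <- array(0, c(n, 3L, 3L))
  for (i in seq_len(n)) {
    for (xi in 1:3) {
      sysP <- system; sysP$position[i, xi] <- sysP$position[i, xi] + h
      sysM <- system; sysM$position[i, xi] <- sysM$position[i, xi] - h
      tensors[i, , xi] <- (dipoleFn(sysP) - dipoleFn(sysM)) / (2 * h)
    }
  }
  aptSet(tensors)
}

#' Project an APT set onto the acoustic sum rule
#'
#' Charge conservation requires the polar tensors summed over all atoms to
#' vanish componentwise. The correction computes the componentwise sum,
#' divides by the number of atoms, and subtracts that mean tensor from every
#' atom, distributing the excess evenly. This is an orthogonal projection:
#' idempotent, and the smallest possible uniform-shift correction in the
#' Frobenius norm.
#'
#' @param apts an `APTSet`.
#' @return An `APTSet` whose componentwise atom sum is zero to round-off.
#' @export
enforceSumRule <- function(apts) {
  n <- dim(apts$tensors)[1L]
  excess <- aptSum(apts) / n
  tensors <- apts$tensors
  for (zeta in 1:3)
    for (xi in 1:3)
      tensors[, zeta, xi] <- tensors[, zeta, xi] - excess[zeta, xi]
  aptSet(tensors)
}
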