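#' Field-induced forces from atomic polar tensors
#'
#' The first-order coupling of a homogeneous field to the system dipole
#' gives a force on atom i of
#' `F_{i,xi} = sum_zeta tensors[i, zeta, xi] * E_zeta`
#' (the transpose of the polar tensor contracted with the field). In the
#' internal unit system a field in V/A yields forces directly in eV/A.
#' If the tensor set satisfies the acoustic sum rule the forces sum to zero,
#' so the field exerts no net force on a charge-conserving system.
#'
#' @param apts an `APTSet`.
#' @param field numeric 3-vector, V/A.
#' @return N x 3 matrix of forces, eV/A.
#' @export
fieldForces <- function(apts, field) {
  t <- apts$tensors
  n <- dim(t)[1L]
  matrix(t[, 1L, ], n, 3L) * field[1L] +
    matrix(t[, 2L, ], n, 3L) * field[2L] +
    matrix(t[, 3L, ], n, 3L) * field[3L]
}

#' APT model constructors
#'
#' An *APT model* is the pluggable object that supplies per-configuration
#' polar tensors during dynamics: a list with a `predict(system)` function
#' returning an `APTSet`, and optionally a `fieldForce(system, field)`
#' short-cut. Models:
#' \describe{
#'   \item{`fixedChargeModel(charges)`}{exact tensors `q_i I` of a
#'     fixed-charge system.}
#'   \item{`bondChargeModel(q0, kappa, r0)`}{exact analytic tensors of the
#'     bond-charge diatomic model.}
#'   \item{`regressorModel(state)`}{a fitted [fitAPTRegressor()] model;
#'     predictions are sum-rule projected.}
#'   \item{`directChargeModel(charges)`}{computes the field force directly
#'     as `q_i E` without going through tensors; the independent route used
#'     to verify that tensor-contracted propagation reproduces plain
#'     electrostatics exactly.}
#' }
#'
#' @param charges per-atom charges, e.
#' @param q0,kappa,r0 bond-charge model parameters (see [bondChargeAPT()]).
#' @param state a fitted `aptRegressor`.
#' @return A list of class `aptModel`.
#' @name aptModels
NULL

#' @rdname aptModels
#' @export
fixedChargeModel <- function(charges) {
  cached <- NULL  # tensors are configuration-independent for fixed charges
  structure(list(
    predict = function(system) {
      if (is.null(cached)) cached <<- fixedChargeAPT(system, charges)
      cached
    },
    label = "fixed-charge"
  ), class = "aptModel")
}

#' @rdname aptModels
#' @export
bondChargeModel <- function(q0, kappa, r0) {
  structure(list(
    predict = function(system) bondChargeAPT(system, q0, kappa, r0),
    label = "bond-charge"
  ), class = "aptModel")
}

#' @rdname aptModels
#' @export
regressorModel <- function(state) {
  structure(list(
    predict = function(system) predictAPT(state, system),
    label = "regressor"
  ), class = "aptModel")
}

#' @rdname aptModels
#' @export
directChargeModel <- function(charges) {
  structure(list(
    predict = function(system) fixedChargeAPT(system, charges),
    fieldForce = function(system, field)
      outer(charges, field),
    label = "direct-charge"
  ), class = "aptModel")
}

#' @keywords internal
#' @noRd
modelFieldForce <- function(aptModel, apts, system, field) {
  if (!is.null(aptModel$fieldForce))
    aptModel$fieldForce(system, field)
  else
    fieldForces(apts, field)
}

#' Piecewise-constant field protocol
#'
#' A schedule of homogeneous field vectors, each held constant for a given
#' duration; the building block of step-response and sweep experiments.
#'
#' @param durations numeric vector of segment durations, fs (> 0).
#' @param fields matrix with one row per segment (V/A), or a single
#'   3-vector recycled across segments.
#' @return Object of class `FieldProtocol`.
#' @examples
#' # step response: 2 ps at zero field, then 8 ps at 0.01 V/A along z
#' fieldProtocol(c(2000, 8000), rbind(c(0, 0, 0), c(0, 0, 0.01)))
#' @export
fieldProtocol <- function(durations, fields) {
  if (is.null(dim(fields))) fields <- matrix(fields, nrow = length(durations),
                                             ncol = 3L, byrow = TRUE)
  fields <- as.matrix(fields)
  if (length(durations) != nrow(fields) || ncol(fields) != 3L)
    stop("`fields` must have one 3-vector row per duration")
  if (any(durations <= 0)) stop("segment durations must be positive")
  structure(list(durations = as.numeric(durations), fields = unname(fields)),
            class = "FieldProtocol")
}

#' Sweep protocol in fixed field increments
#'
#' Convenience constructor for the staircase protocol used to measure the
#' dielectric constant: the field magnitude along `axis` is stepped from
#' `from` to `to` in steps of `increment`, holding each value for
#' `duration`.
#'
#' @param from,to first and last field magnitudes, V/A.
#' @param increment step size, V/A (> 0); sign is inferred from direction.
#' @param duration time per field value, fs.
#' @param axis unit 3-vector, default +z.
#' @return A `FieldProtocol`.
#' @export
sweepProtocol <- function(from, to, increment, duration, axis = c(0, 0, 1)) {
  if (increment <= 0) stop("`increment` must be positive")
  mags <- seq(from, to, by = if (to >= from) increment else -increment)
  fieldProtocol(rep(duration, length(mags)), outer(mags, axis))
}

#' @export
print.FieldProtocol <- function(x, ...) {
  cat("FieldProtocol:", length(x$durations), "segments, total",
      format(sum(x$durations) / 1000), "ps\n")
  invisible(x)
}

#' Thermostat configuration
#'
#' `"csvr"` (canonical sampling through velocity rescaling) is the default
#' choice for condensed, well-mixed systems: a single global stochastic
#' rescaling of the kinetic energy. Its correctness relies on the
#' underlying dynamics being ergodic on the energy shell; the ideal
#' dipolar gas is *integrable* (no intermolecular coupling, and each
#' molecule separately conserves the angular momentum component along the
#' field), so global rescaling alone cannot relax its orientational
#' distribution to the Boltzmann form. For such analytic reference systems
#' use `"andersen"`: random re-draws of individual atomic velocities from
#' the Maxwell-Boltzmann distribution, which samples the canonical
#' ensemble without any ergodicity assumption.
#'
#' @param kind `"none"` for NVE, `"csvr"` for global stochastic velocity
#'   rescaling, `"andersen"` for stochastic collisions.
#' @param targetT target temperature, K.
#' @param tau time constant, fs (> 0); for `"andersen"` the mean time
#'   between collisions per atom. Default 1000 fs.
#' @param ndofRemoved degrees of freedom excluded from the kinetic target
#'   of `"csvr"`; defaults to 3 because velocities are initialized with
#'   zero centre-of-mass momentum, which global rescaling preserves
#'   (Andersen collisions do not, and ignore this setting).
#' @return Object of class `ThermostatConfig`.
#' @export
thermostatConfig <- function(kind = c("none", "csvr", "andersen"),
                             targetT = 300, tau = 1000, ndofRemoved = 3L) {
  kind <- match.arg(kind)
  if (kind != "none" && tau <= 0) stop("`tau` must be positive")
  structure(list(kind = kind, targetT = targetT, tau = tau,
                 ndofRemoved = as.integer(ndofRemoved)),
            class = "ThermostatConfig")
}

#' One Andersen (stochastic collision) thermostat step
#'
#' Each atom independently suffers a collision with probability
#' `1 - exp(-dt/tau)`; colliding atoms have their velocity redrawn from
#' the Maxwell-Boltzmann distribution at the target temperature. Exact
#' canonical sampling for any dynamics, ergodic or not, at the price of
#' discontinuous momenta.
#'
#' @param system a `ParticleSystem`.
#' @param targetT target temperature, K.
#' @param tau mean time between collisions per atom, fs.
#' @param dt coupling interval, fs.
#' @return list with `system` and `heat` (kinetic energy added, eV).
#' @export
andersenStep <- function(system, targetT, tau, dt) {
  if (tau <= 0 || dt <= 0) stop("`tau` and `dt` must be positive")
  n <- nAtoms(system)
  hit <- stats::runif(n) < (1 - exp(-dt / tau))
  if (!any(hit)) return(list(system = system, heat = 0))
  k0 <- kineticEnergy(system)
  m <- massToInternal(system$mass[hit])
  sigma <- sqrt(physicalConstants()$kB * targetT / m)
  system$velocity[hit, ] <- matrix(stats::rnorm(3L * sum(hit)),
                                   ncol = 3L) * sigma
  list(system = system, heat = kineticEnergy(system) - k0)
}

#' One CSVR (stochastic velocity rescaling) step
#'
#' Rescales the total kinetic energy toward its canonical distribution with
#' a single global factor, following the stochastic dynamics of the
#' canonical-sampling-through-velocity-rescaling thermostat. In the
#' `tau -> Inf` limit the factor tends to 1 and NVE dynamics is recovered.
#' Uses the R random number stream; seed it with `set.seed()` for
#' reproducible runs.
#'
#' @param system a `ParticleSystem`.
#' @param targetT target temperature, K.
#' @param tau time constant, fs.
#' @param dt coupling interval, fs.
#' @param ndofRemoved removed degrees of freedom (see [thermostatConfig()]).
#' @return list with `system` (rescaled velocities) and `heat`, the kinetic
#'   energy added (eV), to be accumulated into the thermostat work so the
#'   conserved quantity can be monitored.
#' @export
csvrStep <- function(system, targetT, tau, dt, ndofRemoved = 3L) {
  if (tau <= 0 || dt <= 0) stop("`tau` and `dt` must be positive")
  nf <- 3L * nAtoms(system) - ndofRemoved
  k <- kineticEnergy(system)
  if (k <= 0) {
    # degenerate start: draw fresh Maxwell-Boltzmann velocities
    system <- maxwellBoltzmannVelocities(system, targetT,
                                         removeDrift = ndofRemoved >= 3L)
    return(list(system = system, heat = kineticEnergy(system)))
  }
  kbar <- 0.5 * nf * physicalConstants()$kB * targetT
  cc <- exp(-dt / tau)
  r1 <- stats::rnorm(1L)
  s <- if (nf > 1L) stats::rchisq(1L, df = nf - 1L) else 0
  alpha2 <- cc + (1 - cc) * (s + r1^2) * kbar / (nf * k) +
    2 * r1 * sqrt(cc * (1 - cc) * kbar / (nf * k))
  system$velocity <- system$velocity * sqrt(alpha2)
  list(system = system, heat = k * (alpha2 - 1))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param system a `ParticleSystem`.
#' @param temperature target temperature, K.
#' @param removeDrift subtract the centre-of-mass velocity (default TRUE).
#' @return the system with fresh velocities.
#' @export
maxwellBoltzmannVelocities <- function(system, temperature,
                                       removeDrift = TRUE) {
  m <- massToInternal(system$mass)
  sigma <- sqrt(physicalConstants()$kB * temperature / m)
  v <- matrix(stats::rnorm(3L * nAtoms(system)), ncol = 3L) * sigma
  if (removeDrift) {
    vc <- colSums(v * m) / sum(m)
    v <- sweep(v, 2L, vc)
  }
  system$velocity <- v
  system
}

#' One velocity-Verlet step with perturbative field forces
#'
#' Propagates the system one step of size `dt` under the total force
#' `F = F_unperturbed + F_field`, where the field contribution is the polar
#' tensors of the APT model contracted with the (step-constant) field. The
#' tensors are re-evaluated once per step at the post-drift positions.
#'
#' @param system a `ParticleSystem`.
#' @param potential function `(ParticleSystem) -> PotentialResult`.
#' @param aptModel an `aptModel` (see [aptModels]); may be `NULL` at zero
#'   field.
#' @param field numeric 3-vector, V/A.
#' @param dt time step, fs (> 0).
#' @param cache optional evaluation cache returned by a previous call;
#'   avoids recomputing forces at the current positions.
#' @return list with elements `system`, `cache` (forces, potential energy,
#'   tensors at the new positions) and `Mdot`, the instantaneous dipole
#'   rate (e A/fs; `NULL` without an APT model).
#' @export
mdStep <- function(system, potential, aptModel = NULL, field = c(0, 0, 0),
                   dt, cache = NULL) {
  if (dt <= 0) stop("`dt` must be positive")
  m <- massToInternal(system$mass)
  if (is.null(cache)) cache <- evaluateForces(system, potential, aptModel,
                                              field)
  v <- system$velocity + cache$forces * (0.5 * dt / m)
  system$position <- system$position + v * dt
  cache <- evaluateForces(system, potential, aptModel, field)
  system$velocity <- v + cache$forces * (0.5 * dt / m)
  mdot <- if (!is.null(cache$apts)) dipoleRate(cache$apts, system$velocity)
  list(system = system, cache = cache, Mdot = mdot)
}

#' @keywords internal
#' @noRd
evaluateForces <- function(system, potential, aptModel, field) {
  pot <- potential(system)
  forces <- pot$forces
  apts <- NULL
  if (!is.null(aptModel)) {
    apts <- aptModel$predict(system)
    if (any(field != 0))
      forces <- forces + modelFieldForce(aptModel, apts, system, field)
  }
  if (any(!is.finite(forces))) {
    bad <- which(!is.finite(rowSums(forces)))[1L]
    stop("propagation error: non-finite force on atom ", bad)
  }
  list(forces = forces, potentialEnergy = pot$energy, apts = apts)
}

#' Run a field protocol
#'
#' Propagates a system through every segment of a [fieldProtocol()],
#' applying the segment's field, optionally coupling a CSVR thermostat as
#' half-steps before and after each velocity-Verlet step, integrating the
#' dipole rate into the itinerant dipole moment, and recording frames every
#' `stride` steps.
#'
#' The conserved-quantity diagnostic uses `-E.M` with `M` taken from
#' `dipoleFn` when supplied (exact for analytic charge models) and from the
#' trapezoid-integrated dipole rate otherwise.
#'
#' @param system a `ParticleSystem`.
#' @param potential function `(ParticleSystem) -> PotentialResult`.
#' @param aptModel an `aptModel`, or `NULL` for zero-field runs.
#' @param protocol a `FieldProtocol`.
#' @param thermostat a [thermostatConfig()]; default NVE.
#' @param dt time step, fs. Default 1 fs for field runs; use 0.5 fs for
#'   stiff zero-field systems.
#' @param stride store every `stride`-th step (default 1).
#' @param dipoleFn optional exact dipole function
#'   `(ParticleSystem) -> 3-vector` used for the initial dipole anchor and
#'   the conserved-quantity diagnostic.
#' @param recordPositions also store positions per frame (memory-heavy).
#' @param recordTheta record the mean bisector/bond angle to `thetaAxis`.
#' @param thetaAxis axis for `recordTheta` (default +z).
#' @return A `Trajectory`: list with per-frame `times`, `Mdot`, `M`
#'   (itinerant, trapezoid-integrated), `energies` (matrix with potential,
#'   kinetic, field, thermostat work and conserved columns), `comMomentum`,
#'   `segment` index, optional `theta` and `positions`, and the final
#'   `system`.
#' @export
runProtocol <- function(system, potential, aptModel, protocol,
                        thermostat = thermostatConfig("none"),
                        dt = 1, stride = 1L, dipoleFn = NULL,
                        recordPositions = FALSE, recordTheta = FALSE,
                        thetaAxis = c(0, 0, 1)) {
  nseg <- length(protocol$durations)
  stepsPerSeg <- round(protocol$durations / dt)
  ntot <- sum(stepsPerSeg)
  nframes <- if (ntot == 0L) 0L else length(seq(stride, ntot, by = stride))
  times <- numeric(nframes)
  mdotMat <- matrix(NA_real_, nframes, 3L)
  mMat <- matrix(NA_real_, nframes, 3L)
  energies <- matrix(NA_real_, nframes, 5L,
                     dimnames = list(NULL, c("potential", "kinetic", "field",
                                             "thermostatWork", "conserved")))
  comMat <- matrix(NA_real_, nframes, 3L)
  segIdx <- integer(nframes)
  theta <- if (recordTheta) numeric(nframes) else NULL
  positions <- if (recordPositions) vector("list", nframes) else NULL

  useCsvr <- thermostat$kind != "none"
  thermoStep <- switch(thermostat$kind,
    none = NULL,
    csvr = function(s, dtc) csvrStep(s, thermostat$targetT, thermostat$tau,
                                     dtc, thermostat$ndofRemoved),
    andersen = function(s, dtc) andersenStep(s, thermostat$targetT,
                                             thermostat$tau, dtc))
  thermoWork <- 0
  m0 <- if (!is.null(dipoleFn)) dipoleFn(system) else c(0, 0, 0)
  mItin <- m0
  cache <- NULL
  mdotPrev <- NULL
  frame <- 0L
  step <- 0L
  tNow <- 0

  for (seg in seq_len(nseg)) {
    field <- protocol$fields[seg, ]
    cache <- evaluateForces(system, potential, aptModel, field)
    if (!is.null(cache$apts))
      mdotPrev <- dipoleRate(cache$apts, system$velocity)
    for (k in seq_len(stepsPerSeg[seg])) {
      if (useCsvr) {
        cs <- thermoStep(system, dt / 2)
        system <- cs$system
        thermoWork <- thermoWork + cs$heat
      }
      out <- mdStep(system, potential, aptModel, field, dt, cache)
      system <- out$system
      cache <- out$cache
      if (useCsvr) {
        cs <- thermoStep(system, dt / 2)
        system <- cs$system
        thermoWork <- thermoWork + cs$heat
      }
      step <- step + 1L
      tNow <- tNow + dt
      if (!is.null(out$Mdot)) {
        mdotNew <- if (useCsvr) dipoleRate(cache$apts, system$velocity)
                   else out$Mdot
        mItin <- mItin + 0.5 * dt * (mdotPrev + mdotNew)
        mdotPrev <- mdotNew
      }
      if (step %% stride == 0L) {
        frame <- frame + 1L
        times[frame] <- tNow
        segIdx[frame] <- seg
        if (!is.null(mdotPrev)) {
          mdotMat[frame, ] <- mdotPrev
          mMat[frame, ] <- mItin
        }
        ke <- kineticEnergy(system)
        mRef <- if (!is.null(dipoleFn)) dipoleFn(system) else mItin
        fieldE <- -sum(field * mRef)
        energies[frame, ] <- c(cache$potentialEnergy, ke, fieldE, thermoWork,
                               cache$potentialEnergy + ke + fieldE -
                                 thermoWork)
        comMat[frame, ] <- comMomentum(system)
        if (recordTheta) theta[frame] <- meanOrientation(system, thetaAxis)
        if (recordPositions) positions[[frame]] <- system$position
      }
    }
  }
  structure(list(times = times, Mdot = mdotMat, M = mMat,
                 energies = energies, comMomentum = comMat,
                 segment = segIdx, theta = theta, positions = positions,
                 system = system, dt = dt, stride = as.integer(stride),
                 protocol = protocol, M0 = m0),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "frames, dt", x$dt, "fs, stride",
      x$stride, "\n")
  if (length(x$times)) {
    drift <- conservedDrift(x)
    cat("  conserved-quantity drift:", format(drift),
        "eV/atom/ps\n")
  }
  invisible(x)
}

#' Linear drift of the conserved quantity
#'
#' Least-squares slope of the conserved quantity over time, per atom and
#' per picosecond — the standard correctness diagnostic for a perturbed-
#' Hamiltonian integrator.
#'
#' @param trajectory a `Trajectory`.
#' @return drift in eV/atom/ps.
#' @export
conservedDrift <- function(trajectory) {
  q <- trajectory$energies[, "conserved"]
  t <- trajectory$times
  n <- nAtoms(trajectory$system)
  slope <- stats::cov(t, q) / stats::var(t)
  slope * 1000 / n
}
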