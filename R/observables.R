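#' Instantaneous dipole rate from polar tensors and velocities
#'
#' `Mdot_zeta = sum_{i,xi} tensors[i, zeta, xi] v_{i,xi}` — the transient
#' current of the cell. For fixed charges this reduces exactly to
#' `sum_i q_i v_i`. Integrated over time it yields the itinerant dipole
#' moment, which is single-valued under periodic boundary conditions.
#'
#' @param apts an `APTSet`.
#' @param velocities N x 3 matrix, A/fs.
#' @return numeric 3-vector, e A / fs.
#' @export
dipoleRate <- function(apts, velocities) {
  t <- apts$tensors
  if (dim(t)[1L] != nrow(velocities))
    stop("atom counts of APT set and velocities disagree")
  c(sum(t[, 1L, ] * velocities),
    sum(t[, 2L, ] * velocities),
    sum(t[, 3L, ] * velocities))
}

#' Anchored trapezoid integration of the dipole rate
#'
#' Integrates a sampled dipole-rate series into the itinerant dipole moment
#' `M(t)`, restarting the running trapezoid integral at every *anchor*: a
#' time at which an independently computed reference dipole is available.
#' At anchor times the integrated value is replaced by the anchor value,
#' discarding accumulated integration error — the analogue of periodically
#' recomputing the cell dipole with the reference electronic-structure
#' method. Anchor times must coincide exactly with frame times; no
#' interpolation is performed.
#'
#' @param rates F x 3 matrix of dipole rates, e A/fs.
#' @param times frame times, fs (uniformly increasing).
#' @param anchorTimes times of the anchors, fs; must include `times[1]`.
#' @param anchorValues matrix with one 3-vector row per anchor, e A.
#' @return A `DipoleTrace`: list with `times`, `rates`, `anchoredM`
#'   (F x 3), `anchorTimes`, `anchorValues`.
#' @export
integrateDipole <- function(rates, times, anchorTimes, anchorValues) {
  rates <- as.matrix(rates)
  anchorValues <- matrix(anchorValues, ncol = 3L)
  f <- length(times)
  if (nrow(rates) != f) stop("`rates` must have one row per time")
  ai <- match(anchorTimes, times)
  if (anyNA(ai))
    stop("anchor time not on the frame grid (no interpolation is done)")
  if (ai[1L] != 1L)
    stop("the first anchor must supply the initial dipole M(t0)")
  m <- matrix(0, f, 3L)
  ord <- order(ai)
  ai <- ai[ord]
  anchorValues <- anchorValues[ord, , drop = FALSE]
  anchorTimes <- anchorTimes[ord]
  cur <- anchorValues[1L, ]
  m[1L, ] <- cur
  nextAnchor <- 2L
  for (k in seq_len(f)[-1L]) {
    cur <- cur + 0.5 * (times[k] - times[k - 1L]) *
      (rates[k, ] + rates[k - 1L, ])
    if (nextAnchor <= length(ai) && k == ai[nextAnchor]) {
      cur <- anchorValues[nextAnchor, ]
      nextAnchor <- nextAnchor + 1L
    }
    m[k, ] <- cur
  }
  structure(list(times = times, rates = rates, anchoredM = m,
                 anchorTimes = anchorTimes, anchorValues = anchorValues),
            class = "DipoleTrace")
}

#' Polarization of a cell dipole moment
#'
#' `P = M / V` for a cubic cell.
#'
#' @param M numeric 3-vector or F x 3 matrix, e A.
#' @param cellEdge cubic cell edge, A (> 0).
#' @return same shape as `M`, e A^-2.
#' @export
polarization <- function(M, cellEdge) {
  if (cellEdge <= 0) stop("`cellEdge` must be positive")
  M / cellEdge^3
}

#' Time-mean polarization with autocorrelation-adjusted error
#'
#' Averages a scalar dipole-component series after an equilibration cut and
#' reports the standard error of the mean adjusted for statistical
#' inefficiency: `SEM = sd / sqrt(N_eff)` with
#' `N_eff = N * dtFrame / (2 * act)` capped at N, `act` being the
#' autocorrelation time of the series.
#'
#' @param M numeric vector: one Cartesian component of the cell dipole
#'   along the frames, e A.
#' @param times frame times, fs.
#' @param cellEdge cubic cell edge, A.
#' @param equilibrationCut discard frames with `time <= equilibrationCut`,
#'   fs.
#' @param act autocorrelation time, fs.
#' @return list with `mean` and `sem` (polarization units, e A^-2) and
#'   `nEff`.
#' @export
meanPolarization <- function(M, times, cellEdge, equilibrationCut = 0,
                             act) {
  keep <- times > equilibrationCut
  if (!any(keep)) stop("no samples left after the equilibration cut")
  p <- polarization(M[keep], cellEdge)
  n <- length(p)
  dtFrame <- if (n > 1L) (max(times[keep]) - min(times[keep])) / (n - 1L)
             else 0
  nEff <- if (act > 0 && dtFrame > 0) min(n, n * dtFrame / (2 * act)) else n
  list(mean = mean(p),
       sem = if (n > 1L) stats::sd(p) / sqrt(nEff) else 0,
       nEff = nEff)
}

#' Integrated autocorrelation time of a scalar series
#'
#' `act = dtFrame * (1/2 + sum_k rho_k)` with the sum over normalized
#' autocorrelations truncated at the first non-positive value (the
#' initial-positive-sequence rule). Used to adjust standard errors of time
#' averages for statistical inefficiency.
#'
#' @param x numeric series.
#' @param dtFrame frame spacing, fs.
#' @param maxLag truncation lag in frames (default half the series).
#' @return autocorrelation time, fs (at least `dtFrame / 2`).
#' @export
integratedAutocorrelationTime <- function(x, dtFrame,
                                          maxLag = length(x) %/% 2L) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) return(dtFrame / 2)
  n <- length(x)
  s <- 0.5
  for (k in seq_len(min(maxLag, n - 1L))) {
    rho <- mean(x[1:(n - k)] * x[(k + 1):n]) / v
    if (rho <= 0) break
    s <- s + rho
  }
  s * dtFrame
}

#' Static dielectric constant from a field sweep
#'
#' Fits the mean polarization versus field magnitude to a straight line
#' through the origin (weighted by the inverse squared standard errors when
#' available) and converts the slope to the relative permittivity,
#' `eps_r = 1 + slope / eps0`.
#'
#' @param fields field magnitudes, V/A; at least one nonzero.
#' @param meanP mean polarization at each field, e A^-2.
#' @param sems optional standard errors of `meanP`; used as weights
#'   `1/sem^2` when all are positive.
#' @return A `DielectricResult`: list with `epsilonR`, `stderr`, `slope`,
#'   `slopeStderr`, `rSquared`, `method = "sweep"`.
#' @export
dielectricFromSweep <- function(fields, meanP, sems = NULL) {
  if (all(fields == 0)) stop("at least one field must be nonzero")
  eps0 <- physicalConstants()$epsilon0
  if (!is.null(sems) && all(sems > 0)) {
    w <- 1 / sems^2
    slope <- sum(w * fields * meanP) / sum(w * fields^2)
    slopeSe <- sqrt(1 / sum(w * fields^2))
  } else {
    slope <- sum(fields * meanP) / sum(fields^2)
    res <- meanP - slope * fields
    n <- length(fields)
    slopeSe <- if (n > 1L) sqrt(sum(res^2) / (n - 1L) / sum(fields^2)) else 0
  }
  res <- meanP - slope * fields
  ss <- sum(meanP^2)
  r2 <- if (ss > 0) 1 - sum(res^2) / ss else NA_real_
  structure(list(epsilonR = 1 + slope / eps0, stderr = slopeSe / eps0,
                 slope = slope, slopeStderr = slopeSe, rSquared = r2,
                 method = "sweep"),
            class = "DielectricResult")
}

#' Static dielectric constant from zero-field dipole fluctuations
#'
#' Kirkwood-type estimator
#' `eps_r = eps_inf + (⟨M^2⟩ - ⟨M⟩^2) / (3 eps0 kB V T)`
#' with `M^2` the squared vector magnitude of the cell dipole sampled at
#' zero field and `eps_inf` the optical dielectric constant.
#'
#' @param M F x 3 matrix of cell dipole samples, e A.
#' @param cellEdge cubic cell edge, A.
#' @param temperature temperature, K (> 0).
#' @param epsilonInf optical dielectric constant (default 1: rigid
#'   non-polarizable charges).
#' @param act optional autocorrelation time (fs) together with `dtFrame` to
#'   adjust the error estimate for statistical inefficiency.
#' @param dtFrame frame spacing, fs.
#' @return A `DielectricResult` with `method = "fluctuation"`.
#' @export
dielectricFromFluctuations <- function(M, cellEdge, temperature,
                                       epsilonInf = 1, act = NULL,
                                       dtFrame = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least two dipole samples")
  if (temperature <= 0) stop("temperature must be positive")
  k <- physicalConstants()
  v <- cellEdge^3
  mbar <- colMeans(M)
  dev2 <- rowSums(sweep(M, 2L, mbar)^2)   # |M - <M>|^2 per frame
  fluct <- mean(dev2)
  denom <- 3 * k$epsilon0 * k$kB * v * temperature
  n <- nrow(M)
  nEff <- if (!is.null(act) && !is.null(dtFrame) && act > 0)
    min(n, n * dtFrame / (2 * act)) else n
  se <- stats::sd(dev2) / sqrt(nEff) / denom
  structure(list(epsilonR = epsilonInf + fluct / denom, stderr = se,
                 slope = NA_real_, slopeStderr = NA_real_,
                 rSquared = NA_real_, method = "fluctuation"),
            class = "DielectricResult")
}

#' @export
print.DielectricResult <- function(x, ...) {
  cat("DielectricResult (", x$method, "): eps_r = ", format(x$epsilonR),
      " +/- ", format(x$stderr), "\n", sep = "")
  invisible(x)
}

#' Flag the end of the linear response regime
#'
#' Walks the sweep points in order of field magnitude and reports the first
#' field whose mean polarization deviates from the origin-line fit to the
#' preceding points by more than `nSigma` standard errors, or `Inf` when no
#' point deviates.
#'
#' @param fields field magnitudes, V/A (ascending).
#' @param meanP mean polarizations, e A^-2.
#' @param sems standard errors of `meanP`.
#' @param nSigma deviation threshold in SEM units (default 2).
#' @return the first nonlinear field magnitude, V/A (or `Inf`).
#' @export
linearRegimeThreshold <- function(fields, meanP, sems, nSigma = 2) {
  ord <- order(fields)
  fields <- fields[ord]; meanP <- meanP[ord]; sems <- sems[ord]
  for (k in 2:length(fields)) {
    use <- seq_len(k - 1L)
    slope <- sum(fields[use] * meanP[use]) / sum(fields[use]^2)
    if (abs(meanP[k] - slope * fields[k]) > nSigma * sems[k])
      return(fields[k])
  }
  Inf
}

#' Infrared spectrum from the dipole-rate autocorrelation
#'
#' Computes the Beer-Lambert absorption coefficient times refractive index,
#' `alpha(omega) n(omega)`, as the cosine transform of the vector
#' autocorrelation function of the dipole rate:
#' `pi / (3 V c eps0 kB T) * (1/2pi) * Int dt e^{-i omega t} <Mdot(0).Mdot(t)>`.
#' The autocorrelation is averaged over all time origins up to `maxLag`,
#' optionally Hann-windowed, and transformed onto a wavenumber grid whose
#' spacing is set by `maxLag` and whose upper end is the Nyquist limit of
#' the frame spacing.
#'
#' @param rates F x 3 matrix of dipole rates along the trajectory, e A/fs.
#' @param dtFrame frame spacing, fs.
#' @param cellEdge cubic cell edge, A.
#' @param temperature temperature, K.
#' @param window `"hann"` (default) or `"none"`.
#' @param maxLag maximum correlation lag, fs (default 2000).
#' @param wavenumbers optional explicit wavenumber grid, cm^-1.
#' @return A `SpectrumResult`: list with `wavenumbers` (cm^-1), `alphaN`
#'   (internal units e^2 A^-2 fs^-1 cm / (eV A^3) scaled by the analytic
#'   prefactor), `acf`, `window`, `correlationLength`.
#' @export
irSpectrum <- function(rates, dtFrame, cellEdge, temperature,
                       window = c("hann", "none"), maxLag = 2000,
                       wavenumbers = NULL) {
  window <- match.arg(window)
  rates <- as.matrix(rates)
  f <- nrow(rates)
  nlag <- floor(maxLag / dtFrame)
  if (f < 2L * nlag)
    stop("series too short: need at least 2*maxLag/dtFrame frames")
  acf <- numeric(nlag + 1L)
  for (lag in 0:nlag) {
    n <- f - lag
    acf[lag + 1L] <- sum(rates[1:n, ] * rates[(1L + lag):f, ]) / n
  }
  w <- if (window == "hann") 0.5 * (1 + cos(pi * (0:nlag) / nlag)) else
    rep(1, nlag + 1L)
  k <- physicalConstants()
  cCm <- k$cLightCm
  pref <- 1 / (6 * cellEdge^3 * cCm * k$epsilon0 * k$kB * temperature)
  if (is.null(wavenumbers)) {
    dnu <- 1 / (2 * cCm * nlag * dtFrame)
    nuMax <- 1 / (2 * cCm * dtFrame)
    wavenumbers <- seq(0, nuMax, by = dnu)
  }
  cw <- acf * w
  lagT <- (0:nlag) * dtFrame
  alphaN <- numeric(length(wavenumbers))
  chunk <- 256L
  for (s in seq(1L, length(wavenumbers), by = chunk)) {
    e <- min(s + chunk - 1L, length(wavenumbers))
    ang <- outer(2 * pi * cCm * wavenumbers[s:e], lagT)
    contrib <- cos(ang) %*% cw
    # integral over (-inf, inf) = C(0) dt + 2 sum_{lag>=1} C cos dt
    alphaN[s:e] <- pref * dtFrame * (2 * contrib - cw[1L])
  }
  structure(list(wavenumbers = wavenumbers, alphaN = as.numeric(alphaN),
                 acf = acf, window = window,
                 correlationLength = nlag * dtFrame),
            class = "SpectrumResult")
}

#' @export
print.SpectrumResult <- function(x, ...) {
  pk <- x$wavenumbers[which.max(x$alphaN)]
  cat("SpectrumResult:", length(x$wavenumbers), "wavenumbers up to",
      format(max(x$wavenumbers)), "cm^-1; peak at", format(pk), "cm^-1\n")
  invisible(x)
}

#' Mean molecular orientation relative to an axis
#'
#' For 3-atom (O,H,H) molecules the per-molecule direction is the bisector
#' of the two O-H bond vectors (minimum-image convention); for 2-atom
#' molecules it is the bond vector from the second atom to the first (i.e.
#' from -q to +q in the dipolar gas, the molecular dipole direction). The
#' angle of each direction to `axis` is taken via `acos` of the normalized
#' dot product and averaged arithmetically over molecules.
#'
#' @param system a `ParticleSystem` of uniform 2- or 3-atom molecules.
#' @param axis 3-vector; normalized internally.
#' @return mean angle in degrees, in `[0, 180]`.
#' @export
meanOrientation <- function(system, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  mi <- system$moleculeIndex
  sizes <- tabulate(mi)
  if (all(sizes == 2L)) {
    p <- diatomicPartners(system)
    d <- system$position[p$a1, , drop = FALSE] -
         system$position[p$a2, , drop = FALSE]
  } else if (all(sizes == 3L)) {
    o <- order(mi)
    iO <- o[seq(1L, length(o), 3L)]
    iH1 <- o[seq(2L, length(o), 3L)]
    iH2 <- o[seq(3L, length(o), 3L)]
    u <- minimumImage(system$position[iH1, , drop = FALSE] -
                      system$position[iO, , drop = FALSE], system$cellEdge)
    v <- minimumImage(system$position[iH2, , drop = FALSE] -
                      system$position[iO, , drop = FALSE], system$cellEdge)
    u <- u / sqrt(rowSums(u^2))
    v <- v / sqrt(rowSums(v^2))
    d <- u + v
  } else {
    stop("molecules must all have 2 atoms or all have 3 atoms")
  }
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) stop("degenerate zero-length bisector")
  cth <- pmin(1, pmax(-1, (d %*% axis)[, 1L] / len))
  mean(acos(cth)) * 180 / pi
}

#' Fit exponential orientational relaxation
#'
#' Fits `Theta(t) = ThetaInf + (Theta0 - ThetaInf) exp(-t / tau)` to a mean
#' orientation series by nonlinear least squares, with `Theta0` fixed at
#' the first sample so only `(tau, ThetaInf)` are free — identifiable even
#' on short series.
#'
#' @param times times, fs (>= 4 points).
#' @param meanAngles mean angles, degrees.
#' @return list with `tau` (fs), `thetaInf` (degrees), `rSquared`.
#' @export
fitExponentialRelaxation <- function(times, meanAngles) {
  if (length(times) < 4L) stop("need at least 4 points")
  if (stats::sd(meanAngles) == 0)
    stop("constant series: relaxation time is unidentifiable")
  theta0 <- meanAngles[1L]
  t0 <- times[1L]
  df <- data.frame(t = times - t0, y = meanAngles)
  start <- list(thetaInf = meanAngles[length(meanAngles)],
                tau = max(diff(range(times)) / 3, 1))
  fit <- minpack.lm::nlsLM(
    y ~ thetaInf + (theta0 - thetaInf) * exp(-t / tau),
    data = df, start = start,
    lower = c(thetaInf = -Inf, tau = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  res <- stats::resid(fit)
  ss <- sum((meanAngles - mean(meanAngles))^2)
  list(tau = unname(est["tau"]), thetaInf = unname(est["thetaInf"]),
       rSquared = 1 - sum(res^2) / ss)
}

#' Force-error decomposition against a reference
#'
#' Pools all atoms, Cartesian components and configurations and reports the
#' root-mean-square error of model forces against reference forces for the
#' total force, the unperturbed (zero-field) contribution, and the
#' field-induced contribution (field force minus zero-field force), along
#' with relative RMSEs defined as RMSE divided by the root-mean-square of
#' the corresponding reference forces.
#'
#' @param modelZero,modelField lists of N x 3 model force matrices sampled
#'   at zero field and under the field (or single matrices).
#' @param refZero,refField matching reference force sets.
#' @return data.frame with columns `component`, `rmse`, `relRmse`.
#' @export
forceErrorDecomposition <- function(modelZero, modelField, refZero,
                                    refField) {
  asList <- function(x) if (is.list(x)) x else list(x)
  mz <- asList(modelZero); mf <- asList(modelField)
  rz <- asList(refZero); rf <- asList(refField)
  if (length(unique(c(length(mz), length(mf), length(rz), length(rf)))) != 1L)
    stop("all four force sets must have the same number of configurations")
  flat <- function(lst) do.call(c, lapply(lst, as.numeric))
  a <- flat(mz); b <- flat(mf); c0 <- flat(rz); d <- flat(rf)
  if (length(unique(c(length(a), length(b), length(c0), length(d)))) != 1L)
    stop("force arrays have mismatching shapes")
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  rms <- function(x) sqrt(mean(x^2))
  relOrNA <- function(e, r) if (r > 0) e / r else NA_real_
  data.frame(
    component = c("total", "unperturbed", "field-induced"),
    rmse = c(rmse(b, d), rmse(a, c0), rmse(b - a, d - c0)),
    relRmse = c(relOrNA(rmse(b, d), rms(d)),
                relOrNA(rmse(a, c0), rms(c0)),
                relOrNA(rmse(b - a, d - c0), rms(d - c0)))
  )
}
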