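#' Linear E(3)-equivariant local APT regressor
#'
#' A learned stand-in for a graph-neural-network polar-tensor model. The
#' tensor of atom i is expanded in rotationally equivariant features of its
#' local environment within a cutoff:
#' \deqn{P_i \approx a_{s_i} I
#'   + \sum_{j \ne i} \sum_k d_{s_i s_j k} B_k(r_{ij}) I
#'   + \sum_{j \ne i} \sum_k c_{s_i s_j k} B_k(r_{ij})
#'     (\hat r_{ij} \otimes \hat r_{ij} - I/3),}
#' with a Gaussian radial basis \eqn{B_k} modulated by a smooth cosine
#' cutoff. Because the identity is rotation-invariant and the traceless
#' dyadic transforms as a rank-2 tensor, predictions are exactly equivariant:
#' rotating the input rotates the output tensors as \eqn{R P R^T}.
#' Coefficients are fit per (centre-species, neighbour-species, basis
#' function) by ridge-regularised least squares on all 9N tensor components
#' of the training set. Training data are generated at zero field only; the
#' model never sees the field.
#'
#' @param training a list of training pairs, each a list with elements
#'   `system` (a `ParticleSystem`) and `apts` (an `APTSet`).
#' @param cutoff environment cutoff, A; must be below half the cell edge.
#' @param nRadial number of Gaussian radial basis functions (>= 1).
#' @param ridge ridge penalty (>= 0). A strictly positive value keeps the
#'   normal equations well conditioned; the default is small enough not to
#'   bias exactly representable targets beyond ~1e-10.
#' @return An object of class `aptRegressor` with the fitted coefficients.
#' @seealso [predictAPT()], [writeAPTRegressor()]
#' @export
fitAPTRegressor <- function(training, cutoff, nRadial = 4, ridge = 1e-10) {
  if (length(training) < 1L) stop("training set must contain at least one pair")
  for (pair in training) {
    if (!inherits(pair$system, "ParticleSystem") ||
        !inherits(pair$apts, "APTSet"))
      stop("each training pair must hold a ParticleSystem and an APTSet")
    if (dim(pair$apts$tensors)[1L] != nAtoms(pair$system))
      stop("atom counts of system and APT set disagree")
    if (cutoff >= pair$system$cellEdge / 2)
      stop("cutoff must be below half the cell edge")
  }
  species <- sort(unique(unlist(lapply(training,
                                       function(p) p$system$species))))
  centers <- seq(0, cutoff, length.out = nRadial + 1L)[-1L]
  width <- if (nRadial > 1L) centers[2L] - centers[1L] else cutoff / 2
  state <- structure(
    list(species = species, cutoff = cutoff, nRadial = as.integer(nRadial),
         centers = centers, width = width, ridge = ridge, coef = NULL),
    class = "aptRegressor"
  )
  p <- regressorNCoef(state)
  xtx <- matrix(0, p, p)
  xty <- numeric(p)
  for (pair in training) {
    X <- regressorDesign(state, pair$system)
    y <- flattenTensors(pair$apts$tensors)
    xtx <- xtx + crossprod(X)
    xty <- xty + crossprod(X, y)[, 1L]
  }
  reg <- xtx + diag(ridge, p)
  coef <- tryCatch(solve(reg, xty), error = function(e) {
    stop("normal equations are singular; refit with ridge > 0", call. = FALSE)
  })
  state$coef <- as.numeric(coef)
  state
}

#' @export
print.aptRegressor <- function(x, ...) {
  cat("aptRegressor: species {", paste(x$species, collapse = ", "),
      "}, cutoff", x$cutoff, "A,", x$nRadial, "radial functions,",
      regressorNCoef(x), "coefficients\n")
  invisible(x)
}

#' Predict atomic polar tensors with a fitted regressor
#'
#' Evaluates the equivariant expansion for every atom and then projects the
#' result onto the acoustic sum rule (see [enforceSumRule()]), so predicted
#' tensor sets always conserve charge, which in turn guarantees zero net
#' field force during dynamics.
#'
#' @param state a fitted `aptRegressor`.
#' @param system a `ParticleSystem` whose species all occurred in training.
#' @return An `APTSet`.
#' @export
predictAPT <- function(state, system) {
  if (is.null(state$coef)) stop("regressor has not been fitted")
  if (!all(system$species %in% state$species))
    stop("system contains species unseen during training: ",
         paste(setdiff(unique(system$species), state$species), collapse = ", "))
  X <- regressorDesign(state, system)
  yhat <- as.numeric(X %*% state$coef)
  n <- nAtoms(system)
  tensors <- array(0, c(n, 3L, 3L))
  row <- 1L
  for (i in seq_len(n)) {
    for (zeta in 1:3) {
      for (xi in 1:3) {
        tensors[i, zeta, xi] <- yhat[row]
        row <- row + 1L
      }
    }
  }
  enforceSumRule(aptSet(tensors))
}

# flatten an N x 3 x 3 tensor array in design-row order:
# atom-major, then zeta, then xi
#' @keywords internal
#' @noRd
flattenTensors <- function(tensors) {
  n <- dim(tensors)[1L]
  out <- numeric(9L * n)
  row <- 1L
  for (i in seq_len(n)) {
    for (zeta in 1:3) {
      for (xi in 1:3) {
        out[row] <- tensors[i, zeta, xi]
        row <- row + 1L
      }
    }
  }
  out
}

#' @keywords internal
#' @noRd
regressorNCoef <- function(state) {
  ns <- length(state$species)
  ns + 2L * ns * ns * state$nRadial
}

# column layout: [intercept a_s] then for each (s, t, k): iso d, then dyad c
#' @keywords internal
#' @noRd
regressorColIndex <- function(state, kind, s, t = NULL, k = NULL) {
  ns <- length(state$species)
  si <- match(s, state$species)
  if (kind == "intercept") return(si)
  ti <- match(t, state$species)
  base <- ns + ((si - 1L) * ns + (ti - 1L)) * 2L * state$nRadial
  if (kind == "iso") base + k else base + state$nRadial + k
}

# rows: 9 per atom (zeta-major over xi); columns per regressorColIndex
#' @keywords internal
#' @noRd
regressorDesign <- function(state, system) {
  n <- nAtoms(system)
  p <- regressorNCoef(state)
  X <- matrix(0, 9L * n, p)
  diagRows <- function(i) (i - 1L) * 9L + c(1L, 5L, 9L)  # zeta == xi rows
  for (i in seq_len(n)) {
    X[diagRows(i), regressorColIndex(state, "intercept",
                                     system$species[i])] <- 1
  }
  pt <- pairTable(system, state$cutoff)
  if (length(pt$i)) {
    fc <- 0.5 * (cos(pi * pt$r / state$cutoff) + 1)
    for (idx in seq_along(pt$i)) {
      i <- pt$i[idx]; j <- pt$j[idx]
      r <- pt$r[idx]
      rhat <- pt$dx[idx, ] / r
      dyad <- outer(rhat, rhat) - diag(3) / 3
      bk <- exp(-((r - state$centers)^2) / (2 * state$width^2)) * fc[idx]
      for (pair in list(c(i, j), c(j, i))) {
        ci <- pair[1L]; nj <- pair[2L]
        s <- system$species[ci]; t <- system$species[nj]
        for (k in seq_len(state$nRadial)) {
          colIso <- regressorColIndex(state, "iso", s, t, k)
          colDyad <- regressorColIndex(state, "dyad", s, t, k)
          X[diagRows(ci), colIso] <- X[diagRows(ci), colIso] + bk[k]
          rows <- (ci - 1L) * 9L + 1:9
          X[rows, colDyad] <- X[rows, colDyad] +
            bk[k] * as.vector(t(dyad))  # zeta-major flattening
        }
      }
    }
  }
  X
}

#' Serialize a fitted APT regressor to a key-value file
#'
#' Writes the species alphabet, basis definition and coefficient array as
#' YAML so a fitted model can be stored beside a trajectory and reloaded
#' with [readAPTRegressor()].
#'
#' @param state a fitted `aptRegressor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAPTRegressor <- function(state, path) {
  yaml::write_yaml(
    list(species = as.list(state$species), cutoff = state$cutoff,
         n_radial = state$nRadial, centers = as.list(state$centers),
         width = state$width, ridge = state$ridge,
         coef = as.list(state$coef)),
    path, precision = 17L
  )
  invisible(path)
}

#' Read a serialized APT regressor
#'
#' @param path file written by [writeAPTRegressor()].
#' @return An `aptRegressor`.
#' @export
readAPTRegressor <- function(path) {
  d <- yaml::read_yaml(path)
  structure(
    list(species = as.character(unlist(d$species)), cutoff = d$cutoff,
         nRadial = as.integer(d$n_radial),
         centers = as.numeric(unlist(d$centers)), width = d$width,
         ridge = d$ridge, coef = as.numeric(unlist(d$coef))),
    class = "aptRegressor"
  )
}
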