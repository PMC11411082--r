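#' Read an extended-XYZ trajectory
#'
#' Parses a (possibly multi-frame) extended-XYZ file: per frame an atom
#' count line, a header line with `Lattice="..."` and
#' `Properties=name:type:ncols:...` entries, then one row per atom. Only
#' cubic lattices are supported. Recognized per-atom properties are
#' `species` (S:1), `pos` (R:3), `vel` (R:3), `forces` (R:3), `mass` (R:1),
#' `apt` (R:9, row-major: dipole-component major over displacement
#' component) and `mol_id` (I:1). Velocity columns that are absent are
#' *flagged* (`hasVelocities = FALSE`), never silently zero-filled.
#'
#' @param path file path.
#' @return list of frames; each frame is a list with `system`
#'   (a `ParticleSystem`), `apts` (an `APTSet` or `NULL`), `forces`
#'   (N x 3 or `NULL`), `hasVelocities`, and `comment` (the raw header
#'   line).
#' @export
readExtXYZ <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln])) {
      if (grepl("^\\s*$", lines[ln])) { ln <- ln + 1L; next }
      stop("parse error at line ", ln, ": expected an atom count")
    }
    n <- as.integer(trimws(lines[ln]))
    if (ln + 1L > length(lines))
      stop("parse error at line ", ln + 1L, ": missing header line")
    header <- lines[ln + 1L]
    lat <- regmatches(header, regexpr('Lattice="[^"]*"', header))
    if (!length(lat))
      stop("parse error at line ", ln + 1L, ": missing Lattice key")
    lv <- as.numeric(strsplit(trimws(gsub('Lattice="|"', "", lat)),
                              "\\s+")[[1L]])
    if (length(lv) != 9L)
      stop("parse error at line ", ln + 1L, ": Lattice needs 9 numbers")
    lmat <- matrix(lv, 3L, 3L, byrow = TRUE)
    offDiag <- lmat; diag(offDiag) <- 0
    if (any(offDiag != 0) || length(unique(diag(lmat))) != 1L)
      stop("unsupported geometry: only cubic lattices are handled")
    cellEdge <- lmat[1L, 1L]
    prop <- regmatches(header, regexpr("Properties=[^ ]+", header))
    if (!length(prop))
      stop("parse error at line ", ln + 1L, ": missing Properties key")
    toks <- strsplit(sub("Properties=", "", prop), ":")[[1L]]
    if (length(toks) %% 3L != 0L)
      stop("parse error at line ", ln + 1L, ": malformed Properties")
    cols <- data.frame(name = toks[seq(1L, length(toks), 3L)],
                       type = toks[seq(2L, length(toks), 3L)],
                       n = as.integer(toks[seq(3L, length(toks), 3L)]))
    if (ln + 1L + n > length(lines))
      stop("parse error: truncated frame starting at line ", ln)
    body <- lines[(ln + 2L):(ln + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    nf <- sum(cols$n)
    if (any(lengths(fields) != nf))
      stop("parse error in frame starting at line ", ln,
           ": expected ", nf, " columns per atom row")
    fm <- do.call(rbind, fields)
    offset <- 0L
    get <- function(name) {
      k <- which(cols$name == name)
      if (!length(k)) return(NULL)
      start <- if (k == 1L) 1L else sum(cols$n[1:(k - 1L)]) + 1L
      fm[, start:(start + cols$n[k] - 1L), drop = FALSE]
    }
    species <- as.character(get("species"))
    pos <- matrix(as.numeric(get("pos")), n, 3L)
    velRaw <- get("vel")
    hasVel <- !is.null(velRaw)
    vel <- if (hasVel) matrix(as.numeric(velRaw), n, 3L) else NULL
    massRaw <- get("mass")
    mass <- if (!is.null(massRaw)) as.numeric(massRaw) else
      defaultMasses(species)
    molRaw <- get("mol_id")
    mol <- if (!is.null(molRaw)) as.integer(molRaw) else seq_len(n)
    forcesRaw <- get("forces")
    forces <- if (!is.null(forcesRaw)) matrix(as.numeric(forcesRaw), n, 3L)
              else NULL
    aptRaw <- get("apt")
    apts <- NULL
    if (!is.null(aptRaw)) {
      av <- matrix(as.numeric(aptRaw), n, 9L)
      tensors <- array(0, c(n, 3L, 3L))
      for (zeta in 1:3)
        for (xi in 1:3)
          tensors[, zeta, xi] <- av[, (zeta - 1L) * 3L + xi]
      apts <- aptSet(tensors)
    }
    system <- particleSystem(species, mass, pos, vel, cellEdge, mol)
    frames[[length(frames) + 1L]] <-
      list(system = system, apts = apts, forces = forces,
           hasVelocities = hasVel, comment = header)
    ln <- ln + 2L + n
  }
  frames
}

#' @keywords internal
#' @noRd
defaultMasses <- function(species) {
  table <- c(H = 1.008, O = 15.999, C = 12.011, N = 14.007, A = 2.0,
             B = 2.0, X = 4.0, Y = 4.0)
  m <- table[species]
  if (anyNA(m))
    stop("unknown species without a mass column: ",
         paste(unique(species[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Write frames as extended-XYZ
#'
#' Inverse of [readExtXYZ()]. Floats are written with `%.17g` (lossless round-trip), APT tensors
#' as 9 per-atom columns in dipole-component-major order.
#'
#' @param path output file path.
#' @param frames list of frames as returned by [readExtXYZ()] (each needs
#'   at least a `system`; `apts` and `forces` are written when present and
#'   requested).
#' @param include character subset of
#'   `c("vel", "forces", "apt", "mass", "mol_id")` to write.
#' @param comment extra key=value text appended to each header line.
#' @return `path`, invisibly.
#' @export
writeExtXYZ <- function(path, frames,
                        include = c("vel", "forces", "apt", "mass",
                                    "mol_id"),
                        comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  g <- function(x) sprintf("%.17g", x)
  for (fr in frames) {
    sys <- fr$system
    n <- nAtoms(sys)
    props <- "species:S:1:pos:R:3"
    cols <- list(sys$species, t(apply(sys$position, 1L, g)))
    if ("mass" %in% include) {
      props <- paste0(props, ":mass:R:1")
      cols <- c(cols, list(g(sys$mass)))
    }
    if ("vel" %in% include) {
      props <- paste0(props, ":vel:R:3")
      cols <- c(cols, list(t(apply(sys$velocity, 1L, g))))
    }
    if ("forces" %in% include && !is.null(fr$forces)) {
      props <- paste0(props, ":forces:R:3")
      cols <- c(cols, list(t(apply(fr$forces, 1L, g))))
    }
    if ("apt" %in% include && !is.null(fr$apts)) {
      av <- matrix("", n, 9L)
      for (zeta in 1:3)
        for (xi in 1:3)
          av[, (zeta - 1L) * 3L + xi] <- g(fr$apts$tensors[, zeta, xi])
      props <- paste0(props, ":apt:R:9")
      cols <- c(cols, list(av))
    }
    if ("mol_id" %in% include) {
      props <- paste0(props, ":mol_id:I:1")
      cols <- c(cols, list(as.character(sys$moleculeIndex)))
    }
    l <- g(sys$cellEdge)
    header <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=%s',
                      l, l, l, props)
    if (nzchar(comment)) header <- paste(header, comment)
    writeLines(as.character(n), con)
    writeLines(header, con)
    body <- do.call(cbind, cols)
    writeLines(apply(body, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}
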