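# Internal helpers: typed errors, seed hygiene, coordinate layout, bases.

# Typed condition so callers can test on error class rather than message text.
.err <- function(type, msg) {
  cond <- structure(
    class = c(paste0("e2dyn_", type), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Run `code` with a locally seeded RNG, restoring the caller's RNG state.
# Every stochastic operation takes one explicit integer seed; no global state
# leaks out of the package.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .err("invalid_argument", "seed must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coordinate layout: a frame is an n x 3 matrix (nm); its flat form is the
# length-3n vector (x1, y1, z1, x2, ...). Ensembles store frames x atoms x 3
# arrays; covariance/PCA work on frames x 3n flat matrices.
.flatten <- function(m) as.vector(t(m))

.unflatten <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

.arrayToFlat <- function(a) {
  n <- dim(a)[2L]
  x <- matrix(NA_real_, dim(a)[1L], 3L * n)
  x[, seq(1L, 3L * n, by = 3L)] <- a[, , 1L]
  x[, seq(2L, 3L * n, by = 3L)] <- a[, , 2L]
  x[, seq(3L, 3L * n, by = 3L)] <- a[, , 3L]
  x
}

.flatToArray <- function(x, nAtoms) {
  x <- rbind(x)
  a <- array(NA_real_, c(nrow(x), nAtoms, 3L))
  a[, , 1L] <- x[, seq(1L, 3L * nAtoms, by = 3L)]
  a[, , 2L] <- x[, seq(2L, 3L * nAtoms, by = 3L)]
  a[, , 3L] <- x[, seq(3L, 3L * nAtoms, by = 3L)]
  a
}

# van der Waals radii (nm) used for solvent accessibility, and atomic masses
# (u) used for mass weighting. Element symbols are upper-case.
.vdwRadii <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120, P = 0.180)
.atomicMasses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                   P = 30.974)

#' Random orthonormal basis
#'
#' Draws `k` orthonormal columns in `n` dimensions by QR decomposition of a
#' standard-normal matrix, with a deterministic sign convention (positive
#' diagonal of R).  Optionally the basis is constrained to the orthogonal
#' complement of a given set of directions, e.g. the rigid-body modes of a
#' structure, so that sampled displacements carry no net translation/rotation.
#'
#' @param n dimension of the space.
#' @param k number of basis vectors (default `n`, or `n - ncol(orthogonalTo)`).
#' @param seed integer seed.
#' @param orthogonalTo optional `n x m` matrix of directions the basis must be
#'   orthogonal to.
#' @return an `n x k` matrix with orthonormal columns.
#' @export
randomOrthonormalBasis <- function(n, k = NULL, seed = 1L, orthogonalTo = NULL) {
  if (n < 1) .err("invalid_argument", "n must be >= 1")
  q0 <- NULL
  if (!is.null(orthogonalTo)) {
    q0 <- qr.Q(qr(as.matrix(orthogonalTo)))
  }
  free <- n - if (is.null(q0)) 0L else ncol(q0)
  if (is.null(k)) k <- free
  if (k > free) {
    .err("invalid_argument",
         sprintf("cannot draw %d orthonormal vectors in a %d-dimensional complement", k, free))
  }
  .withSeed(seed, {
    m <- matrix(stats::rnorm(n * min(n, k + if (is.null(q0)) 0L else ncol(q0))), nrow = n)
    if (!is.null(q0)) m <- m - q0 %*% crossprod(q0, m)
    d <- qr(m)
    qm <- qr.Q(d)
    r <- qr.R(d)
    s <- sign(diag(r))
    s[s == 0] <- 1
    qm <- sweep(qm, 2L, s, "*")
    qm[, seq_len(k), drop = FALSE]
  })
}

# Orthonormal basis of the (up to 6) rigid-body modes of a coordinate set:
# 3 translations plus 3 infinitesimal rotations about the centroid.
.rigidBasis <- function(coords) {
  n <- nrow(coords)
  cen <- colMeans(coords)
  rel <- sweep(coords, 2L, cen)
  modes <- matrix(0, 3L * n, 6L)
  for (ax in 1:3) {
    t <- matrix(0, n, 3L)
    t[, ax] <- 1
    modes[, ax] <- .flatten(t)
    e <- c(0, 0, 0)
    e[ax] <- 1
    rot <- t(apply(rel, 1L, function(r) c(e[2] * r[3] - e[3] * r[2],
                                          e[3] * r[1] - e[1] * r[3],
                                          e[1] * r[2] - e[2] * r[1])))
    modes[, 3L + ax] <- .flatten(rot)
  }
  d <- qr(modes)
  qr.Q(d)[, seq_len(d$rank), drop = FALSE]
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); used by the Shrake-Rupley surface.
.spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * k / n)
  azim <- pi * (1 + sqrt(5)) * k
  cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
}

# Element symbol from a PDB atom name when the element column is absent:
# strip digits/primes, take the leading alphabetic character(s) conservatively.
.elementFromName <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  toupper(substr(nm, 1L, 1L))
}
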