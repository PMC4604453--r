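#' @include AllClasses.R
NULL

# Essential dynamics: least-squares superposition, covariance of positional
# fluctuations, eigendecomposition, projections.

#' Kabsch least-squares superposition
#'
#' Returns the proper rotation and translation minimizing the weighted RMSD
#' of `mobile` onto `reference` (row-vector convention: a frame transforms as
#' `x %*% rotation + translation`).
#'
#' @param mobile n x 3 coordinate matrix (nm).
#' @param reference n x 3 coordinate matrix (nm).
#' @param weights optional non-negative per-atom weights (default uniform).
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (nm, weighted).
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L ||
      nrow(mobile) != nrow(reference)) {
    .err("invalid_argument", "coordinate sets must be matching n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) .err("invalid_argument", "at least 3 atoms are required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    .err("invalid_argument", "weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  m <- sweep(mobile, 2L, cm)
  r <- sweep(reference, 2L, cr)
  a <- crossprod(m * w, r)
  sv <- svd(a)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cr - as.vector(cm %*% rot)
  rmsd <- sqrt(sum(w * rowSums((m %*% rot - r)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

# Apply a kabschSuperpose() transform to an n x 3 coordinate matrix.
.applyFit <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, "+")
}

# Superpose every frame of a flat frames x 3M matrix onto a flat reference.
.superposeFlat <- function(flat, refFlat, weights = NULL) {
  ref <- .unflatten(refFlat)
  t(apply(flat, 1L, function(fr) {
    m <- .unflatten(fr)
    .flatten(.applyFit(m, kabschSuperpose(m, ref, weights)))
  }))
}

#' Covariance matrix of positional fluctuations
#'
#' Superposes the ensemble onto its iterated mean (two passes: fit to the
#' first frame, compute the mean, refit to that mean, recompute the mean) and
#' returns the 3M x 3M covariance of fluctuations about the final mean,
#' divided by the frame count, so the trace equals the mean squared
#' fluctuation.
#'
#' Mass weighting multiplies each atom's fluctuation components by
#' `sqrt(m)`; on a Calpha-only selection all masses are equal, so weighting
#' is a uniform rescale of the spectrum and the default is unweighted, which
#' keeps eigenvalues in nm^2.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param map optional atom selection: an integer index vector, or an
#'   [AlignmentMap-class] entry via `mappedAtoms()` (default: all atoms).
#' @param massWeighting multiply fluctuations by `sqrt(mass)` per element.
#' @return list with `covariance` (3M x 3M, nm^2), `mean` (flat 3M vector),
#'   and `atomIndices`.
#' @export
buildCovariance <- function(ensemble, map = NULL, massWeighting = FALSE) {
  idx <- if (is.null(map)) seq_len(nAtoms(ensemble)) else as.integer(map)
  flat <- .flatCoords(ensemble, idx)
  if (nrow(flat) < 2L) .err("invalid_argument", "need at least 2 frames")
  ref <- flat[1L, ]
  for (pass in 1:2) {
    fitted <- .superposeFlat(flat, ref)
    ref <- colMeans(fitted)
  }
  fluct <- sweep(fitted, 2L, ref)
  if (massWeighting) {
    top <- topology(ensemble)
    if (is.null(top)) {
      .err("configuration_error", "mass weighting requires a topology")
    }
    el <- top@atoms$element[idx]
    unknown <- setdiff(unique(el), names(.atomicMasses))
    if (length(unknown)) {
      .err("configuration_error",
           sprintf("no mass for element(s): %s", paste(unknown, collapse = ", ")))
    }
    fluct <- sweep(fluct, 2L, rep(sqrt(.atomicMasses[el]), each = 3L), "*")
  }
  covar <- crossprod(fluct) / nrow(fluct)
  list(covariance = covar, mean = ref, atomIndices = idx)
}

#' Eigendecomposition of a covariance matrix
#'
#' Full symmetric eigendecomposition in descending order with a deterministic
#' sign convention (the largest-magnitude component of every eigenvector is
#' positive).  Slightly negative eigenvalues within `-1e-10 * lambda_1` are
#' clamped to zero; anything more negative is an error.
#'
#' @param covariance 3M x 3M symmetric matrix, or the list returned by
#'   [buildCovariance()].
#' @param mean optional flat mean-coordinate vector (taken from the
#'   [buildCovariance()] list when present; defaults to zeros).
#' @param atomIndices optional atom indices carried along for bookkeeping.
#' @return an [EssentialSubspace-class].
#' @export
pcaDecompose <- function(covariance, mean = NULL, atomIndices = NULL) {
  if (is.list(covariance) && !is.null(covariance$covariance)) {
    if (is.null(mean)) mean <- covariance$mean
    if (is.null(atomIndices)) atomIndices <- covariance$atomIndices
    covariance <- covariance$covariance
  }
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    .err("invalid_argument", "covariance matrix is not symmetric (tol 1e-8)")
  }
  if (is.null(mean)) mean <- numeric(nrow(covariance))
  dec <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  lam <- dec$values
  lam1 <- max(lam[1L], .Machine$double.eps)
  if (any(lam < -1e-10 * lam1 - 1e-300)) {
    .err("invalid_argument",
         "matrix is not positive semi-definite within tolerance")
  }
  trace0 <- sum(diag(covariance))
  lam[lam < 0] <- 0
  vec <- dec$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  methods::new("EssentialSubspace", mean = as.numeric(mean), vectors = vec,
               values = lam, totalVariance = trace0,
               atomIndices = if (is.null(atomIndices)) integer()
                             else as.integer(atomIndices))
}

#' Essential-dynamics PCA of an ensemble
#'
#' Convenience wrapper: [buildCovariance()] followed by [pcaDecompose()].
#'
#' @inheritParams buildCovariance
#' @return an [EssentialSubspace-class].
#' @export
essentialDynamics <- function(ensemble, map = NULL, massWeighting = FALSE) {
  pcaDecompose(buildCovariance(ensemble, map = map,
                               massWeighting = massWeighting))
}

#' Project an ensemble onto the leading eigenvectors of a subspace
#'
#' Per frame, `p_i(t) = (x(t) - mean) . v_i` after superposing each frame
#' onto the subspace mean (set `fit = FALSE` to project raw coordinates).
#'
#' @param ensemble a [TrajectoryEnsemble-class]; either defined on the same
#'   atoms as the subspace, or carrying more atoms from which the subspace's
#'   `atomIndices` select the mapped subset.
#' @param subspace an [EssentialSubspace-class].
#' @param k number of leading PCs to project on (`k = 0` gives a frames x 0
#'   matrix).
#' @param fit superpose frames onto the subspace mean first (default TRUE).
#' @return frames x k matrix of projections (nm), one column per PC.
#' @export
projectOnto <- function(ensemble, subspace, k, fit = TRUE) {
  m <- meanCoords(subspace)
  nSub <- length(m) / 3L
  if (nAtoms(ensemble) == nSub) {
    flat <- .flatCoords(ensemble)
  } else if (length(subspace@atomIndices) == nSub &&
             max(subspace@atomIndices) <= nAtoms(ensemble)) {
    flat <- .flatCoords(ensemble, subspace@atomIndices)
  } else {
    .err("consistency_error",
         "ensemble atoms do not match the subspace dimension")
  }
  if (k > ncol(eigenvectors(subspace))) {
    .err("invalid_argument", "k exceeds the number of eigenvectors")
  }
  if (k == 0L) {
    return(matrix(numeric(0), nrow = nFrames(ensemble), ncol = 0L))
  }
  if (fit) flat <- .superposeFlat(flat, m)
  p <- sweep(flat, 2L, m) %*% eigenvectors(subspace)[, seq_len(k), drop = FALSE]
  colnames(p) <- paste0("PC", seq_len(k))
  p
}

#' Cumulative variance fraction of the leading eigenvectors
#'
#' @param subspace an [EssentialSubspace-class].
#' @param k number of leading PCs, `1 <= k <=` subspace dimension.
#' @return `sum(lambda[1:k]) / sum(lambda)`, in `[0, 1]`.
#' @export
varianceExplained <- function(subspace, k) {
  lam <- eigenvalues(subspace)
  if (k < 1L || k > length(lam)) {
    .err("invalid_argument", sprintf("k must be in 1..%d", length(lam)))
  }
  tot <- sum(lam)
  if (tot == 0) return(0)
  sum(lam[seq_len(k)]) / tot
}
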