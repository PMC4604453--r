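#' @include AllClasses.R
NULL

# Subspace comparison: squared inner products, eigenvalue crossing-over,
# RMSIP, cosine content, class-wise boxplot statistics.

# Extract an eigenvector matrix from an EssentialSubspace or plain matrix.
.vecs <- function(x) {
  if (methods::is(x, "EssentialSubspace")) eigenvectors(x) else as.matrix(x)
}

#' Matrix of squared inner products between two eigenvector sets
#'
#' Entry `(i, j)` is `(v_i . w_j)^2`.  Over a complete orthonormal basis the
#' column (and row) sums equal 1, so the matrix reads as the distribution of
#' each eigenvector of one system over the eigenvectors of the other.
#'
#' @param V,W [EssentialSubspace-class] objects or eigenvector matrices of
#'   the same row dimension.
#' @param k1,k2 numbers of leading eigenvectors to compare.
#' @return `k1 x k2` matrix of squared inner products in `[0, 1]`.
#' @export
overlapMatrix <- function(V, W, k1 = NULL, k2 = NULL) {
  V <- .vecs(V); W <- .vecs(W)
  if (nrow(V) != nrow(W)) {
    .err("consistency_error", "eigenvector dimensions differ")
  }
  if (is.null(k1)) k1 <- ncol(V)
  if (is.null(k2)) k2 <- ncol(W)
  if (k1 > ncol(V) || k2 > ncol(W)) {
    .err("invalid_argument", "k exceeds the available eigenvectors")
  }
  crossprod(V[, seq_len(k1), drop = FALSE], W[, seq_len(k2), drop = FALSE])^2
}

#' Eigenvalue crossing-over diagnostic for one reference PC
#'
#' Reports the squared overlap of a chosen reference eigenvector with each of
#' the first `kMax` eigenvectors of another system, and the index with the
#' maximal overlap.  A best match at an index other than the reference PC's
#' own is the "crossing-over" that confounds naive per-PC comparison of
#' homologous variants.
#'
#' @param referencePc numeric eigenvector (3M vector), e.g.
#'   `eigenvectors(V)[, 1]`.
#' @param W [EssentialSubspace-class] or eigenvector matrix of the variant.
#' @param kMax how many variant PCs to scan (default 10).
#' @return list with `profile` (`data.frame` of `pc`, `overlap`),
#'   `bestMatch` (index) and `bestOverlap`.
#' @export
bestMatchPC <- function(referencePc, W, kMax = 10L) {
  v <- as.numeric(referencePc)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) .err("invalid_argument", "reference eigenvector is zero")
  v <- v / nrm
  W <- .vecs(W)
  if (length(v) != nrow(W)) {
    .err("consistency_error", "eigenvector dimensions differ")
  }
  if (kMax < 1L) .err("invalid_argument", "kMax must be >= 1")
  if (kMax > ncol(W)) .err("invalid_argument", "kMax exceeds available PCs")
  ov <- as.vector(crossprod(W[, seq_len(kMax), drop = FALSE], v))^2
  best <- which.max(ov)
  list(profile = data.frame(pc = seq_len(kMax), overlap = ov),
       bestMatch = best, bestOverlap = ov[best])
}

#' Root mean square inner product of two essential subspaces
#'
#' `sqrt( (1/D) * sum_{i,j <= D} (v_i . w_j)^2 )`: 1 for identical spans of
#' the first `D` eigenvectors, 0 for orthogonal spans.  Symmetric in its
#' arguments and invariant under rotations within either retained
#' `D`-dimensional span.
#'
#' @param V,W [EssentialSubspace-class] objects or eigenvector matrices.
#' @param D subspace depth (default 20, the conventional choice for
#'   essential-dynamics comparison).
#' @return scalar in `[0, 1]`.
#' @export
rmsip <- function(V, W, D = 20L) {
  V <- .vecs(V); W <- .vecs(W)
  if (nrow(V) != nrow(W)) {
    .err("consistency_error", "eigenvector dimensions differ")
  }
  if (D < 1L || D > ncol(V) || D > ncol(W)) {
    .err("invalid_argument", "D exceeds the available PCs")
  }
  ip <- crossprod(V[, seq_len(D), drop = FALSE], W[, seq_len(D), drop = FALSE])
  min(1, sqrt(sum(ip^2) / D))
}

#' Cosine content of a principal-component projection
#'
#' Similarity of the projection time series `p(t)` to a half-period cosine of
#' index `i`:
#' `c_i = (2/T) * ( int p(t) cos(i pi t / T) dt )^2 / int p(t)^2 dt`,
#' integrals taken by the trapezoid rule over the frame index (`t = 0 ... T`,
#' `T = nFrames - 1`), clamped to `[0, 1]`.  Values near 1 indicate
#' random-diffusion-like, undersampled motion.
#'
#' @param p numeric projection series (>= 4 frames).
#' @param i PC index entering the cosine frequency (default 1).
#' @return scalar in `[0, 1]`.
#' @export
cosineContent <- function(p, i = 1L) {
  p <- as.numeric(p)
  n <- length(p)
  if (n < 4L) .err("invalid_argument", "need at least 4 frames")
  if (all(p == 0)) .err("undefined_error", "cosine content of a zero series")
  t <- seq(0, n - 1)
  T <- n - 1
  num <- pracma::trapz(t, p * cos(i * pi * t / T))
  den <- pracma::trapz(t, p^2)
  ci <- (2 / T) * num^2 / den
  min(1, max(0, ci))
}

#' Class-wise boxplot statistics of labelled values
#'
#' Median, quartiles (linear-interpolation quantile convention), whiskers at
#' 1.5 x IQR clipped to the data range, and outliers, per class; the summary
#' used to compare RMSIP distributions between variant classes.
#'
#' @param values numeric vector (e.g. pairwise RMSIP values).
#' @param classes class label per value.
#' @return `data.frame` with one row per non-empty class: `class`, `n`,
#'   `median`, `q25`, `q75`, `whiskerLow`, `whiskerHigh`, `nOutliers`; the
#'   outlying values themselves are attached as the `"outliers"` attribute
#'   (a named list).  Empty classes (levels with no values) are skipped with
#'   a warning.
#' @export
groupBoxplotStats <- function(values, classes) {
  if (length(values) != length(classes)) {
    .err("invalid_argument", "values and classes must have equal length")
  }
  lev <- if (is.factor(classes)) levels(classes) else unique(classes)
  rows <- list()
  outliers <- list()
  for (cl in lev) {
    v <- values[classes == cl & !is.na(values)]
    if (length(v) == 0L) {
      warning(sprintf("class '%s' has no values; skipped", cl))
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- min(v[v >= q[1L] - 1.5 * iqr])
    hi <- max(v[v <= q[3L] + 1.5 * iqr])
    out <- v[v < lo | v > hi]
    rows[[cl]] <- data.frame(class = cl, n = length(v), median = q[2L],
                             q25 = q[1L], q75 = q[3L], whiskerLow = lo,
                             whiskerHigh = hi, nOutliers = length(out),
                             stringsAsFactors = FALSE)
    outliers[[cl]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- outliers
  res
}
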