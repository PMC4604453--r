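#' @include AllClasses.R
NULL

# Synthetic-ensemble generator.
#
# The package analyses conformational ensembles whose statistics it does not
# control (molecular dynamics output); this module generates ensembles whose
# second-order statistics ARE controlled: Gaussian fluctuations with a
# prescribed eigen-spectrum along a known orthonormal basis, plus controlled
# rotations/swaps of that basis across "variants".  Every downstream stage
# (covariance PCA, RMSIP, crossing-over, persistence) depends only on
# second-order structure or per-frame geometry, so ground truth is exact.

#' Specify an eigenvalue spectrum for a synthetic ensemble
#'
#' @param eigenvalues numeric variances (nm^2), descending, all >= 0.
#' @param nAtoms number of atoms the ensemble will carry.
#' @param seed integer seed associated with the spectrum's basis.
#' @return a `SpectrumSpec` (validated list).
#' @export
spectrumSpec <- function(eigenvalues, nAtoms, seed = 1L) {
  if (any(eigenvalues < 0)) .err("invalid_argument", "eigenvalues must be >= 0")
  if (is.unsorted(rev(eigenvalues))) {
    .err("invalid_argument", "eigenvalues must be in descending order")
  }
  if (length(eigenvalues) > 3L * nAtoms) {
    .err("invalid_argument", "more eigenvalues than coordinate dimensions")
  }
  structure(list(eigenvalues = as.numeric(eigenvalues),
                 nAtoms = as.integer(nAtoms), seed = as.integer(seed)),
            class = "SpectrumSpec")
}

#' Specify a subspace perturbation for a variant ensemble
#'
#' A perturbation rotates selected ground-truth eigenvectors by `angle` into
#' directions orthogonal to the whole reference spectrum, and/or swaps pairs
#' of eigenvector positions (`swapMap`), which emulates the eigenvalue
#' crossing-over seen when homologous variants reorder their principal
#' motions.
#'
#' @param angle rotation angle in radians, in `[0, pi/2]`.
#' @param swapMap optional list of length-2 integer vectors: PC index pairs to
#'   interchange; pairs must be disjoint.
#' @param modes indices of the spectral modes to rotate (default: all).
#' @return a `PerturbationSpec` (validated list).
#' @export
perturbationSpec <- function(angle = 0, swapMap = NULL, modes = NULL) {
  if (angle < 0 || angle > pi / 2) {
    .err("invalid_argument", "angle must lie in [0, pi/2]")
  }
  if (!is.null(swapMap)) {
    idx <- unlist(swapMap)
    if (any(vapply(swapMap, length, integer(1L)) != 2L)) {
      .err("invalid_argument", "swap entries must be index pairs")
    }
    if (anyDuplicated(idx)) .err("invalid_argument", "swap pairs must be disjoint")
  }
  structure(list(angle = angle, swapMap = swapMap, modes = modes),
            class = "PerturbationSpec")
}

#' Build a small self-avoiding toy structure
#'
#' A compact self-avoiding Calpha trace (0.38 nm spacing along a
#' boustrophedon walk through a cubic lattice, so the fold is globular
#' rather than rod-like) with one pseudo-side-chain atom (`CB`) per residue
#' offset along the lattice diagonal, plus a small deterministic seeded
#' jitter; the construction guarantees a minimum inter-atomic separation
#' above 0.2 nm.
#'
#' @param nResidues number of residues (>= 2).
#' @param seed integer seed.
#' @param sequence optional one-letter amino-acid sequence of length
#'   `nResidues`; sets residue names (default all `ALA`).
#' @return a [Structure-class] with `2 * nResidues` atoms.
#' @export
makeToyStructure <- function(nResidues, seed = 1L, sequence = NULL) {
  if (nResidues < 2) .err("invalid_argument", "nResidues must be >= 2")
  if (!is.null(sequence) && nchar(sequence) != nResidues) {
    .err("invalid_argument", "sequence length must equal nResidues")
  }
  resNames <- if (is.null(sequence)) rep("ALA", nResidues) else {
    vapply(strsplit(sequence, "")[[1L]], function(a) {
      r <- suppressWarnings(bio3d::aa123(toupper(a)))
      if (is.na(r) || r == toupper(a)) "UNK" else r
    }, character(1L))
  }
  .withSeed(seed, {
    s <- ceiling(nResidues^(1 / 3))
    i0 <- seq_len(nResidues) - 1L
    iz <- i0 %/% (s * s)
    rem <- i0 %% (s * s)
    iy <- rem %/% s
    iy <- ifelse(iz %% 2L == 1L, s - 1L - iy, iy)
    ix <- rem %% s
    ix <- ifelse((iy + iz) %% 2L == 1L, s - 1L - ix, ix)
    jitter <- matrix(stats::runif(3L * nResidues, -0.01, 0.01), ncol = 3L)
    ca <- 0.38 * cbind(ix, iy, iz) + jitter
    cb <- ca + 0.25 / sqrt(3) * matrix(1, nResidues, 3L)
    xyz <- matrix(NA_real_, 2L * nResidues, 3L)
    xyz[seq(1L, 2L * nResidues, 2L), ] <- ca
    xyz[seq(2L, 2L * nResidues, 2L), ] <- cb
    atomTab <- data.frame(
      serial = seq_len(2L * nResidues),
      elety = rep(c("CA", "CB"), nResidues),
      element = "C",
      resid = rep(resNames, each = 2L),
      resno = rep(seq_len(nResidues), each = 2L),
      chain = "A",
      stringsAsFactors = FALSE)
    Structure(atomTab, xyz)
  })
}

# Calpha-only reference structure used as the mean of abstract ensembles.
.caTrace <- function(nAtoms, seed = 1L) {
  full <- makeToyStructure(max(nAtoms, 2L), seed = seed)
  idx <- which(full@atoms$elety == "CA")[seq_len(nAtoms)]
  Structure(full@atoms[idx, , drop = FALSE], full@coords[idx, , drop = FALSE])
}

#' Sample a Gaussian ensemble with a prescribed spectrum
#'
#' Frames are `mean + sum_i sqrt(lambda_i) z_i v_i` with independent standard
#' normal `z_i`: the population covariance has exactly the prescribed
#' eigenvalues along the prescribed basis.
#'
#' @param mean a [Structure-class] giving the mean conformation.
#' @param spectrum a [spectrumSpec()] or plain numeric eigenvalue vector (nm^2).
#' @param eigenvectors 3M x k matrix with orthonormal columns (deviation from
#'   orthonormality beyond 1e-8 is an error).
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed.
#' @param system system id for the returned ensemble.
#' @param replicate replicate id assigned to all frames.
#' @return a [TrajectoryEnsemble-class].
#' @export
sampleGaussianEnsemble <- function(mean, spectrum, eigenvectors, nFrames,
                                   seed = 1L, system = "synthetic",
                                   replicate = 1L) {
  lam <- if (inherits(spectrum, "SpectrumSpec")) spectrum$eigenvalues else
    as.numeric(spectrum)
  v <- as.matrix(eigenvectors)
  if (nFrames < 1) .err("invalid_argument", "nFrames must be >= 1")
  if (length(lam) != ncol(v)) {
    .err("invalid_argument", "one eigenvalue per eigenvector is required")
  }
  m <- .flatten(coords(mean))
  if (nrow(v) != length(m)) {
    .err("invalid_argument", "eigenvector dimension must be 3 * nAtoms(mean)")
  }
  g <- crossprod(v)
  if (max(abs(g - diag(ncol(v)))) > 1e-8) {
    .err("invalid_argument", "eigenvectors are not orthonormal (tol 1e-8)")
  }
  x <- .withSeed(seed, {
    z <- matrix(stats::rnorm(nFrames * length(lam)), nFrames, length(lam))
    sweep(z, 2L, sqrt(lam), "*") %*% t(v)
  })
  flat <- sweep(x, 2L, m, "+")
  TrajectoryEnsemble(flat, topology = mean, system = system,
                     replicate = rep(replicate, nFrames))
}

#' Generate a reference + perturbed-variant ensemble family
#'
#' Emulates a wild-type versus mutant comparison: the first returned ensemble
#' samples the unperturbed reference basis; each subsequent ensemble samples
#' the same eigenvalue spectrum along a basis rotated (by the perturbation
#' angle, into directions orthogonal to the whole spectrum) and/or
#' column-swapped.  The exact RMSIP of each variant basis against the
#' reference is emitted alongside, computed directly on the constructed bases.
#'
#' All bases are drawn orthogonal to the rigid-body modes of the mean
#' structure, so the prescribed spectra survive the superposition step of the
#' downstream PCA.
#'
#' @param referenceSpectrum a [spectrumSpec()].
#' @param perturbations list of [perturbationSpec()] (>= 1).
#' @param nFrames frames per replicate.
#' @param nReplicates replicates per variant (>= 1).
#' @param seed integer seed.
#' @param D subspace depth for the emitted ground-truth RMSIP (default 20,
#'   capped at the spectrum length).
#' @return list with `ensembles` (reference first), `bases` (3M x L
#'   eigenvector matrices), `groundTruthRmsip` (vs reference; 1 for the
#'   reference itself), `spectrum`, and `mean` structure.
#' @export
makeVariantFamily <- function(referenceSpectrum, perturbations, nFrames,
                              nReplicates = 1L, seed = 1L, D = 20L) {
  if (!inherits(referenceSpectrum, "SpectrumSpec")) {
    .err("invalid_argument", "referenceSpectrum must be a spectrumSpec()")
  }
  if (length(perturbations) < 1L) {
    .err("invalid_argument", "at least one perturbation is required")
  }
  if (nReplicates < 1L) .err("invalid_argument", "nReplicates must be >= 1")
  lam <- referenceSpectrum$eigenvalues
  L <- length(lam)
  nAt <- referenceSpectrum$nAtoms
  dim3 <- 3L * nAt
  meanStruct <- .caTrace(nAt, seed = referenceSpectrum$seed)
  rigid <- .rigidBasis(coords(meanStruct))
  maxRot <- max(vapply(perturbations, function(p) {
    length(if (is.null(p$modes)) seq_len(L) else p$modes)
  }, integer(1L)))
  if (dim3 - ncol(rigid) < L + maxRot) {
    .err("invalid_argument",
         "not enough non-rigid dimensions for the spectrum plus rotation targets")
  }
  # Basis: L spectral directions followed by rotation-target directions,
  # all orthogonal to the rigid-body modes.
  B <- randomOrthonormalBasis(dim3, k = L + maxRot,
                              seed = referenceSpectrum$seed,
                              orthogonalTo = rigid)
  V <- B[, seq_len(L), drop = FALSE]
  bases <- list(V)
  for (p in perturbations) {
    if (!inherits(p, "PerturbationSpec")) {
      .err("invalid_argument", "perturbations must be perturbationSpec() objects")
    }
    modes <- if (is.null(p$modes)) seq_len(L) else as.integer(p$modes)
    if (any(modes < 1L | modes > L)) {
      .err("invalid_argument", "perturbation modes beyond spectrum length")
    }
    W <- V
    for (j in seq_along(modes)) {
      W[, modes[j]] <- cos(p$angle) * V[, modes[j]] +
        sin(p$angle) * B[, L + j]
    }
    if (!is.null(p$swapMap)) {
      for (pair in p$swapMap) {
        pair <- as.integer(pair)
        if (any(pair < 1L | pair > L)) {
          .err("invalid_argument", "swap index beyond spectrum length")
        }
        W[, pair] <- W[, rev(pair)]
      }
    }
    bases <- c(bases, list(W))
  }
  Duse <- min(D, L)
  gt <- vapply(bases, function(W) rmsip(V, W, D = Duse), numeric(1L))
  ensembles <- vector("list", length(bases))
  for (k in seq_along(bases)) {
    reps <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      reps[[r]] <- sampleGaussianEnsemble(
        meanStruct, lam, bases[[k]], nFrames,
        seed = seed + 1000L * (k - 1L) + r,
        system = if (k == 1L) "reference" else paste0("variant", k - 1L),
        replicate = r)
    }
    ensembles[[k]] <- .concatenateEnsembles(reps)
  }
  list(ensembles = ensembles, bases = bases, groundTruthRmsip = gt,
       spectrum = lam, mean = meanStruct)
}

# Concatenate replicate ensembles of one system, keeping provenance.
.concatenateEnsembles <- function(reps) {
  nA <- vapply(reps, nAtoms, integer(1L))
  if (length(unique(nA)) != 1L) {
    .err("consistency_error", "replicates differ in atom count")
  }
  coordsAll <- do.call(abind3, reps)
  repIds <- unlist(lapply(reps, replicateIds))
  TrajectoryEnsemble(coordsAll, topology = topology(reps[[1L]]),
                     system = systemId(reps[[1L]]), replicate = repIds)
}

# Minimal 3-d array bind along frames (avoids an abind dependency).
abind3 <- function(...) {
  parts <- lapply(list(...), function(e) {
    if (methods::is(e, "TrajectoryEnsemble")) e@coords else e
  })
  nA <- dim(parts[[1L]])[2L]
  flat <- do.call(rbind, lapply(parts, .arrayToFlat))
  .flatToArray(flat, nA)
}

#' Ensemble whose leading projection is a pure half-period cosine
#'
#' Frames are `amplitude * cos(pi * t / T)` along a single unit direction,
#' `t = 0 ... T` with `T = nFrames - 1`; the fixture against which the
#' cosine-content diagnostic is calibrated.
#'
#' @param mode unit 3M vector.
#' @param amplitude amplitude in nm.
#' @param nFrames number of frames (>= 4).
#' @param mean optional mean [Structure-class] (default: a Calpha trace of the
#'   implied size).
#' @return a [TrajectoryEnsemble-class].
#' @export
makeCosineTrajectory <- function(mode, amplitude, nFrames, mean = NULL) {
  if (nFrames < 4) .err("invalid_argument", "nFrames must be >= 4")
  nrm <- sqrt(sum(mode^2))
  if (nrm == 0) .err("invalid_argument", "mode vector must be non-zero")
  mode <- mode / nrm
  nAt <- length(mode) / 3L
  if (nAt != round(nAt)) .err("invalid_argument", "mode length must be 3 * nAtoms")
  if (is.null(mean)) mean <- .caTrace(as.integer(nAt))
  t <- seq(0L, nFrames - 1L)
  p <- amplitude * cos(pi * t / (nFrames - 1L))
  flat <- outer(p, mode) + matrix(.flatten(coords(mean)), nFrames,
                                  3L * nAt, byrow = TRUE)
  TrajectoryEnsemble(flat, topology = mean, system = "cosine")
}

#' Two-atom ensemble with designed per-frame contact occupancy
#'
#' A lysine-like NZ and an aspartate-like OD1 atom separated by
#' `boundDistance` in frames where the pattern is `TRUE` and by
#' `unboundDistance` otherwise; the fixture for persistence analysis.
#'
#' @param occupancyPattern logical vector, one entry per frame (non-empty).
#' @param boundDistance bound separation (nm), `< unboundDistance`.
#' @param unboundDistance unbound separation (nm).
#' @return a [TrajectoryEnsemble-class] with 2 atoms.
#' @export
makeContactSeries <- function(occupancyPattern, boundDistance = 0.30,
                              unboundDistance = 0.80) {
  if (length(occupancyPattern) == 0L) {
    .err("invalid_argument", "occupancy pattern must be non-empty")
  }
  if (boundDistance >= unboundDistance) {
    .err("invalid_argument", "boundDistance must be below unboundDistance")
  }
  atomTab <- data.frame(
    serial = 1:2, elety = c("NZ", "OD1"), element = c("N", "O"),
    resid = c("LYS", "ASP"), resno = c(1L, 2L), chain = c("A", "B"),
    stringsAsFactors = FALSE)
  top <- Structure(atomTab, rbind(c(0, 0, 0), c(unboundDistance, 0, 0)))
  d <- ifelse(occupancyPattern, boundDistance, unboundDistance)
  flat <- cbind(0, 0, 0, d, 0, 0)
  TrajectoryEnsemble(flat, topology = top, system = "contact")
}

#' Homologous sequence/structure set with known alignment ground truth
#'
#' Builds `nSystems` homologs of a random reference sequence, applies the
#' requested per-system deletions (gap in that row) and insertions (extra
#' column, gap in every other row), and returns toy structures whose residues
#' correspond exactly to the non-gap alignment positions, together with the
#' ground-truth shared columns and per-system Calpha indices.
#'
#' @param nSystems number of systems (>= 2).
#' @param indelSpec optional list, one entry per system, each a list with
#'   integer vectors `deletions` (reference column indices to gap out) and
#'   `insertions` (reference columns after which to insert a residue).
#' @param seed integer seed.
#' @param nResidues length of the ungapped reference sequence (default 10).
#' @return list with `msa` ([MSA-class]), `structures` (named list of
#'   [Structure-class]), `sharedColumns` (1-based columns ungapped in all
#'   systems) and `atomIndices` (per-system Calpha indices for those columns).
#' @export
makeHomologSet <- function(nSystems, indelSpec = NULL, seed = 1L,
                           nResidues = 10L) {
  if (nSystems < 2L) .err("invalid_argument", "need at least two systems")
  ids <- paste0("sys", seq_len(nSystems))
  if (is.null(indelSpec)) indelSpec <- vector("list", nSystems)
  if (length(indelSpec) != nSystems) {
    .err("invalid_argument", "one indel entry per system is required")
  }
  aaPool <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")
  base <- .withSeed(seed, sample(aaPool, nResidues, replace = TRUE))
  # Column plan: reference columns 1..n plus one extra column per insertion.
  cols <- lapply(seq_len(nResidues), function(j) list(ref = j, owner = NA))
  for (s in seq_len(nSystems)) {
    ins <- indelSpec[[s]]$insertions
    for (after in ins) {
      pos <- which(vapply(cols, function(cl) identical(cl$ref, as.integer(after)),
                          logical(1L)))
      if (length(pos) != 1L) {
        .err("invalid_argument", "insertion position outside the reference")
      }
      cols <- append(cols, list(list(ref = NA, owner = s)), after = pos)
    }
  }
  width <- length(cols)
  ali <- matrix("-", nSystems, width, dimnames = list(ids, NULL))
  extra <- .withSeed(seed + 1L, sample(aaPool, width, replace = TRUE))
  for (s in seq_len(nSystems)) {
    del <- indelSpec[[s]]$deletions
    for (j in seq_len(width)) {
      cl <- cols[[j]]
      if (!is.na(cl$ref)) {
        if (!(cl$ref %in% del)) ali[s, j] <- base[cl$ref]
      } else if (identical(cl$owner, s)) {
        ali[s, j] <- extra[j]
      }
    }
    if (sum(ali[s, ] != "-") < 2L) {
      .err("invalid_argument",
           sprintf("indels leave fewer than 2 residues in %s", ids[s]))
    }
  }
  shared <- which(colSums(ali == "-") == 0L)
  if (length(shared) < 2L) {
    .err("invalid_argument", "indels leave fewer than 2 shared columns")
  }
  structures <- list()
  atomIdx <- list()
  for (s in seq_len(nSystems)) {
    seqS <- ali[s, ali[s, ] != "-"]
    st <- makeToyStructure(length(seqS), seed = seed + 10L + s,
                           sequence = paste(seqS, collapse = ""))
    structures[[ids[s]]] <- st
    caIdx <- which(st@atoms$elety == "CA")
    rank <- cumsum(ali[s, ] != "-")
    atomIdx[[ids[s]]] <- caIdx[rank[shared]]
  }
  msa <- MSA(stats::setNames(apply(ali, 1L, paste, collapse = ""), ids))
  list(msa = msa, structures = structures,
       sharedColumns = as.integer(shared), atomIndices = atomIdx)
}
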