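#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- Structure

#' Structure: a single protein conformation
#'
#' Holds an atom table and one set of Cartesian coordinates in nanometres.
#' Coordinates in PDB files are Angstrom; the readers and writers convert.
#'
#' @slot atoms `data.frame` with columns `serial`, `elety` (atom name),
#'   `element`, `resid` (residue name), `resno` (1-based residue number),
#'   `chain`.
#' @slot coords numeric atoms x 3 matrix, nm.
#' @export
setClass("Structure",
         representation(atoms = "data.frame", coords = "matrix"))

setValidity("Structure", function(object) {
  a <- object@atoms
  x <- object@coords
  need <- c("serial", "elety", "element", "resid", "resno", "chain")
  if (!all(need %in% names(a))) {
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) != nrow(x) || ncol(x) != 3L) {
    return("coords must be an atoms x 3 matrix")
  }
  if (!all(is.finite(x))) return("coordinates must be finite")
  for (ch in unique(a$chain)) {
    rn <- a$resno[a$chain == ch]
    if (is.unsorted(rn)) {
      return(sprintf("residue numbers must be non-decreasing within chain '%s'", ch))
    }
  }
  TRUE
})

#' Construct a Structure
#'
#' @param atoms atom table (see [Structure-class]).
#' @param coords atoms x 3 coordinate matrix in nm.
#' @return a [Structure-class] object.
#' @export
Structure <- function(atoms, coords) {
  methods::new("Structure", atoms = as.data.frame(atoms),
               coords = as.matrix(coords))
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname coords
#' @export
setMethod("coords", "Structure", function(x) x@coords)

#' @rdname atoms
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

setMethod("show", "Structure", function(object) {
  cat("Structure:", nAtoms(object), "atoms,",
      length(unique(paste(object@atoms$chain, object@atoms$resno))),
      "residues\n")
})

# ------------------------------------------------------- TrajectoryEnsemble

#' TrajectoryEnsemble: a multi-frame conformational ensemble
#'
#' Frames x atoms x 3 coordinate block (nm) with per-frame replicate
#' provenance and an optional reference [Structure-class] topology.  A
#' "macro-trajectory" — the concatenated equilibrated portions of several
#' replicates of one system — is represented by the same class with mixed
#' `replicate` values.
#'
#' @slot system character system identifier.
#' @slot replicate per-frame replicate id.
#' @slot coords frames x atoms x 3 array (nm).
#' @slot topology a [Structure-class] in a length-0/1 list (S4 cannot hold
#'   "Structure or NULL" directly).
#' @export
setClass("TrajectoryEnsemble",
         representation(system = "character", replicate = "ANY",
                        coords = "array", topology = "list"))

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3L] != 3L) return("coords must be frames x atoms x 3")
  if (d[1L] < 1L) return("ensemble must contain at least one frame")
  if (length(object@replicate) != d[1L]) {
    return("replicate ids must have one entry per frame")
  }
  if (length(object@topology) > 0L) {
    top <- object@topology[[1L]]
    if (!methods::is(top, "Structure")) return("topology must be a Structure")
    if (nAtoms(top) != d[2L]) {
      return("topology atom count must match the coordinate block")
    }
  }
  TRUE
})

#' Construct a TrajectoryEnsemble
#'
#' @param coords frames x atoms x 3 array, or a frames x 3M flat matrix (nm).
#' @param topology optional [Structure-class] reference topology.
#' @param system system id (default "system").
#' @param replicate per-frame replicate ids (default all `1L`).
#' @param nAtoms atom count, required when `coords` is a flat matrix and no
#'   topology is given.
#' @return a [TrajectoryEnsemble-class] object.
#' @export
TrajectoryEnsemble <- function(coords, topology = NULL, system = "system",
                               replicate = NULL, nAtoms = NULL) {
  if (is.matrix(coords)) {
    if (is.null(nAtoms)) {
      if (is.null(topology)) {
        .err("invalid_argument",
             "nAtoms or a topology is required with flat coordinates")
      }
      nAtoms <- nrow(topology@atoms)
    }
    coords <- .flatToArray(coords, nAtoms)
  }
  if (is.null(replicate)) replicate <- rep(1L, dim(coords)[1L])
  methods::new("TrajectoryEnsemble", system = system, replicate = replicate,
               coords = coords,
               topology = if (is.null(topology)) list() else list(topology))
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@coords)[1L])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "TrajectoryEnsemble", function(x) dim(x@coords)[2L])

#' @rdname coords
#' @export
setMethod("coords", "TrajectoryEnsemble", function(x) x@coords)

#' @rdname topology
#' @export
setMethod("topology", "TrajectoryEnsemble", function(x) {
  if (length(x@topology)) x@topology[[1L]] else NULL
})

#' @rdname atoms
#' @export
setMethod("atoms", "TrajectoryEnsemble", function(x) {
  top <- topology(x)
  if (is.null(top)) .err("invalid_argument", "ensemble carries no topology")
  top@atoms
})

#' @rdname replicateIds
#' @export
setMethod("replicateIds", "TrajectoryEnsemble", function(x) x@replicate)

#' @rdname systemId
#' @export
setMethod("systemId", "TrajectoryEnsemble", function(x) x@system)

#' Subset an ensemble by frames and/or atoms
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param i frame indices.
#' @param j atom indices.
#' @param ... ignored.
#' @param drop ignored; the result is always an ensemble.
#' @return the subsetted [TrajectoryEnsemble-class].
#' @export
setMethod("[", "TrajectoryEnsemble", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nFrames(x))
  if (missing(j)) j <- seq_len(nAtoms(x))
  top <- topology(x)
  if (!is.null(top)) {
    top <- Structure(top@atoms[j, , drop = FALSE], top@coords[j, , drop = FALSE])
  }
  TrajectoryEnsemble(x@coords[i, j, , drop = FALSE], topology = top,
                     system = x@system, replicate = x@replicate[i])
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble '", object@system, "': ", nFrames(object),
      " frames x ", nAtoms(object), " atoms, ",
      length(unique(object@replicate)), " replicate(s)\n", sep = "")
})

# Frame f as a Structure (requires a topology).
.frameStructure <- function(ensemble, f) {
  top <- topology(ensemble)
  if (is.null(top)) .err("invalid_argument", "ensemble carries no topology")
  Structure(top@atoms, ensemble@coords[f, , ])
}

# Flat frames x 3M coordinate matrix, optionally over an atom subset.
.flatCoords <- function(ensemble, atomIdx = NULL) {
  a <- ensemble@coords
  if (!is.null(atomIdx)) a <- a[, atomIdx, , drop = FALSE]
  .arrayToFlat(a)
}

# ------------------------------------------------------------ AlignmentMap

#' AlignmentMap: cross-system Calpha correspondence through an MSA
#'
#' Columns of the multiple sequence alignment ungapped in every mapped system,
#' with the matching Calpha atom index in each system's structure.  Column
#' indices are 1-based (R convention).
#'
#' @slot columns strictly increasing integer MSA column indices (1-based).
#' @slot atomIndices named list (one per system) of integer Calpha atom
#'   indices, all of the same length as `columns`.
#' @slot ids character system ids, in mapping order.
#' @export
setClass("AlignmentMap",
         representation(columns = "integer", atomIndices = "list",
                        ids = "character"))

setValidity("AlignmentMap", function(object) {
  if (length(object@ids) != length(object@atomIndices)) {
    return("one atom-index vector per id is required")
  }
  if (is.unsorted(object@columns, strictly = TRUE)) {
    return("columns must be strictly increasing")
  }
  lens <- vapply(object@atomIndices, length, integer(1L))
  if (any(lens != length(object@columns))) {
    return("every per-system atom list must match the column count")
  }
  TRUE
})

setMethod("show", "AlignmentMap", function(object) {
  cat("AlignmentMap:", length(object@columns), "shared columns across",
      length(object@ids), "systems (", paste(object@ids, collapse = ", "), ")\n")
})

#' Atom indices of an alignment map for one system
#' @param map an [AlignmentMap-class].
#' @param id system id.
#' @return integer vector of Calpha atom indices.
#' @export
mappedAtoms <- function(map, id) {
  if (!id %in% map@ids) {
    .err("consistency_error", sprintf("system '%s' is not in the map", id))
  }
  map@atomIndices[[id]]
}

#' Shared MSA columns of an alignment map
#' @param map an [AlignmentMap-class].
#' @return integer vector of 1-based column indices.
#' @export
mappedColumns <- function(map) map@columns

# ----------------------------------------------------------------------- MSA

#' MSA: a multiple sequence alignment
#'
#' Equal-length gapped amino-acid sequences stored as a character matrix
#' (rows = sequences, columns = alignment columns, gap = "-").
#'
#' @slot ali character matrix with unique rownames (sequence ids).
#' @export
setClass("MSA", representation(ali = "matrix"))

setValidity("MSA", function(object) {
  if (nrow(object@ali) < 1L) return("alignment must contain >= 1 record")
  ids <- rownames(object@ali)
  if (is.null(ids) || anyDuplicated(ids)) return("sequence ids must be unique")
  TRUE
})

#' Construct an MSA from gapped sequences
#'
#' @param sequences named character vector of equal-length gapped sequences
#'   over the amino-acid alphabet plus `-`.
#' @return an [MSA-class] object.
#' @export
MSA <- function(sequences) {
  if (length(sequences) < 1L) .err("format_error", "alignment needs >= 1 record")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    .err("format_error", "every sequence needs an id")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    .err("format_error", sprintf(
      "ragged alignment: lengths %s", paste(unique(lens), collapse = ", ")))
  }
  if (anyDuplicated(names(sequences))) {
    .err("format_error", "duplicate sequence id in alignment")
  }
  ali <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(ali) <- names(sequences)
  allGap <- rowSums(ali != "-") == 0L
  if (any(allGap)) {
    message("MSA: all-gap row(s): ", paste(names(sequences)[allGap], collapse = ", "))
  }
  methods::new("MSA", ali = ali)
}

#' Sequence ids of an alignment
#' @param msa an [MSA-class] object.
#' @return character vector of ids.
#' @export
msaIds <- function(msa) rownames(msa@ali)

#' Number of columns in an alignment
#' @param msa an [MSA-class] object.
#' @return integer alignment width.
#' @export
msaWidth <- function(msa) ncol(msa@ali)

setMethod("show", "MSA", function(object) {
  cat("MSA:", nrow(object@ali), "sequences x", ncol(object@ali), "columns\n")
})

# ------------------------------------------------------- EssentialSubspace

#' EssentialSubspace: result of essential-dynamics PCA
#'
#' Mean coordinates, orthonormal eigenvectors and non-negative eigenvalues
#' (descending) of the covariance matrix of positional fluctuations.
#'
#' @slot mean flat 3M mean-coordinate vector (nm).
#' @slot vectors 3M x k orthonormal eigenvector matrix, descending order.
#' @slot values eigenvalues (nm^2), descending, clamped non-negative.
#' @slot totalVariance trace of the covariance matrix (nm^2).
#' @slot atomIndices indices of the mapped atoms in the source topology
#'   (may be empty).
#' @export
setClass("EssentialSubspace",
         representation(mean = "numeric", vectors = "matrix",
                        values = "numeric", totalVariance = "numeric",
                        atomIndices = "integer"))

setValidity("EssentialSubspace", function(object) {
  v <- object@vectors
  lam <- object@values
  if (length(object@mean) != nrow(v)) return("mean length must match vector rows")
  if (ncol(v) != length(lam)) return("one eigenvalue per eigenvector")
  if (any(lam < 0)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(lam))) return("eigenvalues must be descending")
  g <- crossprod(v)
  if (max(abs(g - diag(ncol(v)))) > 1e-8) {
    return("eigenvectors must be orthonormal to 1e-8")
  }
  if (abs(sum(lam) - object@totalVariance) >
      1e-8 * max(object@totalVariance, .Machine$double.eps)) {
    return("eigenvalue sum must equal the covariance trace (1e-8 relative)")
  }
  TRUE
})

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "EssentialSubspace", function(x) x@values)

#' @rdname eigenvectors
#' @export
setMethod("eigenvectors", "EssentialSubspace", function(x) x@vectors)

#' @rdname meanCoords
#' @export
setMethod("meanCoords", "EssentialSubspace", function(x) x@mean)

#' @rdname varianceFractions
#' @export
setMethod("varianceFractions", "EssentialSubspace", function(x) {
  tot <- sum(x@values)
  if (tot == 0) rep(0, length(x@values)) else x@values / tot
})

setMethod("show", "EssentialSubspace", function(object) {
  k <- length(object@values)
  cat("EssentialSubspace: dim", nrow(object@vectors), ",", k, "modes;",
      "total variance", format(object@totalVariance, digits = 4), "nm^2\n")
  kk <- min(3L, k)
  if (kk > 0) {
    cat("  leading eigenvalues (nm^2):",
        paste(format(object@values[seq_len(kk)], digits = 4), collapse = ", "),
        "\n")
  }
})

# ------------------------------------------------------------ ContactSeries

#' ContactSeries: per-frame distance of an atom-group pair
#'
#' Produced by [distanceSeries()] (distances only) and completed by
#' [contactPersistence()] (per-frame contact booleans and the persistence
#' fraction).
#'
#' @slot distances per-frame group distance (nm).
#' @slot cutoff contact distance cutoff (nm; `NA` until applied).
#' @slot contact per-frame logical contact indicator.
#' @slot persistenceFraction fraction of frames in contact (`NA` until applied).
#' @slot mode distance mode, `"min-heavy"` or `"named-pair"`.
#' @export
setClass("ContactSeries",
         representation(distances = "numeric", cutoff = "numeric",
                        contact = "logical", persistenceFraction = "numeric",
                        mode = "character"))

setValidity("ContactSeries", function(object) {
  if (any(object@distances < 0, na.rm = TRUE)) return("distances must be >= 0")
  if (length(object@contact) &&
      length(object@contact) != length(object@distances)) {
    return("contact flags must match the distance series length")
  }
  if (length(object@contact) && !is.na(object@persistenceFraction) &&
      abs(object@persistenceFraction - mean(object@contact)) > 1e-12) {
    return("persistence must equal the mean of the contact flags")
  }
  TRUE
})

#' @rdname distances
#' @export
setMethod("distances", "ContactSeries", function(x) x@distances)

#' @rdname persistence
#' @export
setMethod("persistence", "ContactSeries", function(x) x@persistenceFraction)

setMethod("show", "ContactSeries", function(object) {
  cat("ContactSeries (", object@mode, "): ", length(object@distances),
      " frames", sep = "")
  if (!is.na(object@persistenceFraction)) {
    cat("; cutoff ", object@cutoff, " nm; persistence ",
        format(object@persistenceFraction, digits = 4), sep = "")
  }
  cat("\n")
})

# -------------------------------------------------------------- ActivityFit

#' ActivityFit: exponential activity-distance model
#'
#' The fitted relation `activity = b * exp(-c * distance)` between a
#' catalytic-geometry observable (e.g. the mean catalytic Cys to substrate
#' Lys side-chain distance, nm) and a measured conjugation activity.
#'
#' @slot b amplitude (activity units at zero distance).
#' @slot c decay rate (nm^-1).
#' @slot correlation Pearson correlation of observed vs fitted activities
#'   (reported as 0 for degenerate fits).
#' @slot residuals per-point observed minus fitted activity.
#' @slot fitted fitted activities.
#' @slot distances input distances (nm).
#' @slot activities input activities.
#' @slot degenerate flag for degenerate fits (e.g. constant activities).
#' @export
setClass("ActivityFit",
         representation(b = "numeric", c = "numeric", correlation = "numeric",
                        residuals = "numeric", fitted = "numeric",
                        distances = "numeric", activities = "numeric",
                        degenerate = "logical"))

setValidity("ActivityFit", function(object) {
  if (!is.finite(object@c)) return("decay rate must be finite")
  if (!is.na(object@correlation) &&
      (object@correlation < -1 - 1e-12 || object@correlation > 1 + 1e-12)) {
    return("correlation must lie in [-1, 1]")
  }
  TRUE
})

setMethod("show", "ActivityFit", function(object) {
  cat("ActivityFit: activity = b * exp(-c * x)\n")
  cat("  b =", format(object@b, digits = 6),
      " c =", format(object@c, digits = 6), "nm^-1",
      " correlation =", format(object@correlation, digits = 3), "\n")
  if (object@degenerate) cat("  [degenerate fit]\n")
})
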