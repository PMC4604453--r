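#' @include utils.R
NULL

#' Number of frames in an ensemble
#' @param x a [TrajectoryEnsemble-class] object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a [Structure-class] or [TrajectoryEnsemble-class] object.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Cartesian coordinates (nm)
#' @param x a [Structure-class] (atoms x 3 matrix) or
#'   [TrajectoryEnsemble-class] (frames x atoms x 3 array).
#' @return numeric matrix or array of coordinates in nanometres.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Atom table of a structure or ensemble topology
#' @param x a [Structure-class] or [TrajectoryEnsemble-class] object.
#' @return `data.frame` with columns serial, elety, element, resid, resno, chain.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Reference topology of an ensemble
#' @param x a [TrajectoryEnsemble-class] object.
#' @return a [Structure-class] object, or `NULL` when none is attached.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Per-frame replicate identifiers
#' @param x a [TrajectoryEnsemble-class] object.
#' @return vector of replicate ids, one per frame.
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' System identifier of an ensemble
#' @param x a [TrajectoryEnsemble-class] object.
#' @return character system id.
#' @export
setGeneric("systemId", function(x) standardGeneric("systemId"))

#' Eigenvalues of an essential subspace (nm^2, descending)
#' @param x an [EssentialSubspace-class] object.
#' @return numeric vector of non-negative eigenvalues.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Orthonormal eigenvectors (columns, descending eigenvalue order)
#' @param x an [EssentialSubspace-class] object.
#' @return numeric matrix of eigenvector columns.
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' Mean coordinates of the subspace (flat 3M vector, nm)
#' @param x an [EssentialSubspace-class] object.
#' @return numeric vector of length 3M.
#' @export
setGeneric("meanCoords", function(x) standardGeneric("meanCoords"))

#' Fraction of total variance carried by each eigenvector
#' @param x an [EssentialSubspace-class] object.
#' @return numeric vector summing to 1 (zero-variance subspaces excepted).
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' Persistence fraction of a contact series
#' @param x a [ContactSeries-class] object.
#' @return fraction of frames (in `[0, 1]`) satisfying the contact criterion,
#'   `NA` before [contactPersistence()] has been applied.
#' @export
setGeneric("persistence", function(x) standardGeneric("persistence"))

#' Per-frame distances of a contact series (nm)
#' @param x a [ContactSeries-class] object.
#' @return numeric vector of per-frame group distances.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
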