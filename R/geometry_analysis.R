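#' @include AllClasses.R
NULL

# Per-frame structural measurements: equilibration trimming and
# macro-trajectory assembly, Shrake-Rupley solvent accessible surface,
# side-chain distances, contact persistence.

#' Trim equilibration frames and assemble a macro-trajectory
#'
#' Removes the leading (unequilibrated) frames of every replicate and
#' concatenates the remainders in replicate order, keeping per-frame
#' replicate provenance.  The trim is a frame count (integer `>= 1`) or a
#' fraction of each replicate's length (`< 1`); callers convert a time-based
#' equilibration window via their frame spacing.
#'
#' @param replicates list of [TrajectoryEnsemble-class] replicates, or one
#'   ensemble whose `replicateIds()` partition the frames.
#' @param trim frames to discard per replicate: a count, or a fraction in
#'   `[0, 1)`.
#' @return the macro-trajectory as one [TrajectoryEnsemble-class].
#' @export
preprocessMacroTrajectory <- function(replicates, trim = 0) {
  if (methods::is(replicates, "TrajectoryEnsemble")) {
    ids <- replicateIds(replicates)
    replicates <- lapply(unique(ids), function(r) {
      replicates[which(ids == r), ]
    })
  }
  if (length(replicates) < 1L) {
    .err("invalid_argument", "at least one replicate is required")
  }
  trimmed <- vector("list", length(replicates))
  for (k in seq_along(replicates)) {
    rep_k <- replicates[[k]]
    nf <- nFrames(rep_k)
    nTrim <- if (trim < 1) floor(trim * nf) else as.integer(trim)
    if (nTrim >= nf) {
      .err("invalid_argument",
           sprintf("trim (%d frames) leaves no frames in replicate %d of '%s'",
                   nTrim, k, systemId(rep_k)))
    }
    keep <- rep_k[seq(nTrim + 1L, nf), ]
    # renumber provenance by replicate position when ids collide
    keep@replicate <- rep(k, nFrames(keep))
    trimmed[[k]] <- keep
  }
  .concatenateEnsembles(trimmed)
}

#' Shrake-Rupley solvent accessible surface area of a selection
#'
#' Sphere-point algorithm: for every selected atom, the fraction of `nPoints`
#' quasi-uniform points on its solvent-extended sphere (radius
#' `r_vdw + probe`) lying inside no other atom's extended sphere, times
#' `4 pi (r + probe)^2`, summed over the selection.  All atoms of the
#' structure occlude, whether selected or not.
#'
#' Radii (nm): C 0.170, N 0.155, O 0.152, S 0.180, H 0.120, P 0.180;
#' probe 0.14 (water).
#'
#' @param structure a [Structure-class] frame.
#' @param selection integer atom indices (non-empty); see [selectAtoms()].
#' @param probeRadius probe radius in nm (default 0.14).
#' @param nPoints sphere points per atom (default 960; accuracy on an
#'   isolated sphere is ~2%, halving at 3840 points).
#' @return SASA in nm^2.
#' @export
sasaShrakeRupley <- function(structure, selection, probeRadius = 0.14,
                             nPoints = 960L) {
  selection <- as.integer(selection)
  if (length(selection) == 0L) {
    .err("invalid_argument", "selection must be non-empty")
  }
  el <- toupper(structure@atoms$element)
  unknown <- setdiff(unique(el), names(.vdwRadii))
  if (length(unknown)) {
    .err("configuration_error",
         sprintf("no van der Waals radius for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  xyz <- structure@coords
  rExt <- .vdwRadii[el] + probeRadius
  sph <- .spherePoints(nPoints)
  total <- 0
  for (i in selection) {
    ri <- rExt[i]
    pts <- sweep(sph * ri, 2L, xyz[i, ], "+")
    d0 <- sqrt(rowSums(sweep(xyz, 2L, xyz[i, ])^2))
    nb <- which(d0 < ri + rExt & seq_along(d0) != i)
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      dj2 <- rowSums(sweep(pts, 2L, xyz[j, ])^2)
      # points on the occluder's extended sphere count as buried, so fully
      # coincident atoms shadow each other completely
      acc <- acc & dj2 > rExt[j]^2 * (1 + 1e-12)
      if (!any(acc)) break
    }
    total <- total + 4 * pi * ri^2 * mean(acc)
  }
  total
}

#' Per-frame SASA of a selection over an ensemble
#'
#' @param ensemble a [TrajectoryEnsemble-class] with a topology.
#' @param selection integer atom indices.
#' @param stride analyse every `stride`-th frame (default 1).
#' @inheritParams sasaShrakeRupley
#' @return list with `perFrame` (`data.frame` of `frame`, `replicate`,
#'   `sasa`) and `byReplicate` (`data.frame` of `replicate`, `n`, `mean`,
#'   `sd`).
#' @export
sasaSeries <- function(ensemble, selection, probeRadius = 0.14,
                       nPoints = 960L, stride = 1L) {
  frames <- seq(1L, nFrames(ensemble), by = stride)
  vals <- vapply(frames, function(f) {
    sasaShrakeRupley(.frameStructure(ensemble, f), selection,
                     probeRadius = probeRadius, nPoints = nPoints)
  }, numeric(1L))
  reps <- replicateIds(ensemble)[frames]
  perFrame <- data.frame(frame = frames, replicate = reps, sasa = vals)
  agg <- lapply(split(vals, reps), function(v) {
    c(n = length(v), mean = mean(v), sd = stats::sd(v))
  })
  byRep <- data.frame(replicate = names(agg),
                      do.call(rbind, agg), row.names = NULL)
  list(perFrame = perFrame, byReplicate = byRep)
}

#' Select atoms of a structure by chain, residue and atom name
#'
#' @param structure a [Structure-class] (or ensemble topology).
#' @param chain,resno,elety,element optional filters (vectors allowed).
#' @param sidechain keep only side-chain atoms (drops backbone names
#'   N, CA, C, O, OXT and backbone hydrogens).
#' @return integer atom indices (possibly empty).
#' @export
selectAtoms <- function(structure, chain = NULL, resno = NULL, elety = NULL,
                        element = NULL, sidechain = FALSE) {
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (sidechain) {
    keep <- keep & !a$elety %in% c("N", "CA", "C", "O", "OXT", "H", "HA")
  }
  which(keep)
}

#' Per-frame distance between two atom groups
#'
#' Mode `"min-heavy"` takes, per frame, the minimum distance over all
#' heavy-atom (non-hydrogen) pairs between the groups — the convention for
#' side-chain contacts and ion pairs.  Mode `"named-pair"` requires
#' single-atom groups (e.g. catalytic Cys SG vs substrate Lys NZ) and returns
#' their per-frame distance.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param groupA,groupB disjoint, non-empty integer atom-index vectors.
#' @param mode `"min-heavy"` (default) or `"named-pair"`.
#' @return a [ContactSeries-class] holding the distances (persistence unset).
#' @export
distanceSeries <- function(ensemble, groupA, groupB,
                           mode = c("min-heavy", "named-pair")) {
  mode <- match.arg(mode)
  groupA <- as.integer(groupA)
  groupB <- as.integer(groupB)
  if (length(groupA) == 0L || length(groupB) == 0L) {
    .err("selection_error", "atom groups must be non-empty")
  }
  if (length(intersect(groupA, groupB))) {
    .err("selection_error", "atom groups overlap")
  }
  if (mode == "min-heavy") {
    top <- topology(ensemble)
    if (!is.null(top)) {
      heavy <- which(toupper(top@atoms$element) != "H")
      groupA <- intersect(groupA, heavy)
      groupB <- intersect(groupB, heavy)
      if (length(groupA) == 0L || length(groupB) == 0L) {
        .err("selection_error", "no heavy atoms left in a group")
      }
    }
  } else {
    if (length(groupA) != 1L || length(groupB) != 1L) {
      .err("selection_error", "named-pair mode requires single-atom groups")
    }
  }
  a <- ensemble@coords
  nf <- dim(a)[1L]
  d <- rep(Inf, nf)
  for (i in groupA) {
    for (j in groupB) {
      dij <- sqrt((a[, i, 1L] - a[, j, 1L])^2 +
                  (a[, i, 2L] - a[, j, 2L])^2 +
                  (a[, i, 3L] - a[, j, 3L])^2)
      d <- pmin(d, dij)
    }
  }
  methods::new("ContactSeries", distances = d, cutoff = NA_real_,
               contact = logical(), persistenceFraction = NA_real_,
               mode = mode)
}

#' Apply a contact criterion and compute persistence
#'
#' A frame is in contact when its distance is below `cutoff` (default
#' 0.48 nm, the ion-pair threshold for charged-group heavy atoms) and, when a
#' hydrogen-bond criterion is supplied, the donor-acceptor distance is below
#' `dCutoff` with a donor-hydrogen-acceptor angle of at least `minAngleDeg`.
#' Persistence is the fraction of frames in contact.
#'
#' @param series a [ContactSeries-class] from [distanceSeries()], or a plain
#'   numeric distance vector (nm).
#' @param cutoff contact distance cutoff in nm (> 0; default 0.48).
#' @param hbond optional list with `ensemble`, `donor`, `hydrogen`,
#'   `acceptor` (atom indices), and optional `dCutoff` (nm, default 0.35) and
#'   `minAngleDeg` (default 120).  A missing hydrogen index is a
#'   configuration error.
#' @return the completed [ContactSeries-class] (contact flags + persistence).
#' @export
contactPersistence <- function(series, cutoff = 0.48, hbond = NULL) {
  if (cutoff <= 0) .err("invalid_argument", "cutoff must be > 0")
  if (is.numeric(series)) {
    series <- methods::new("ContactSeries", distances = as.numeric(series),
                           cutoff = NA_real_, contact = logical(),
                           persistenceFraction = NA_real_, mode = "named-pair")
  }
  contact <- series@distances < cutoff
  if (!is.null(hbond)) {
    if (is.null(hbond$hydrogen) || anyNA(hbond$hydrogen) ||
        length(hbond$hydrogen) == 0L) {
      .err("configuration_error",
           "hydrogen-bond criterion requested but no hydrogen atom given")
    }
    dCut <- if (is.null(hbond$dCutoff)) 0.35 else hbond$dCutoff
    minAng <- if (is.null(hbond$minAngleDeg)) 120 else hbond$minAngleDeg
    a <- hbond$ensemble@coords
    don <- a[, hbond$donor[1L], ]
    hyd <- a[, hbond$hydrogen[1L], ]
    acc <- a[, hbond$acceptor[1L], ]
    if (is.null(dim(don))) { don <- rbind(don); hyd <- rbind(hyd); acc <- rbind(acc) }
    dDA <- sqrt(rowSums((don - acc)^2))
    v1 <- don - hyd
    v2 <- acc - hyd
    cosang <- rowSums(v1 * v2) /
      pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), .Machine$double.eps)
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hok <- dDA < dCut & ang >= minAng
    if (length(hok) != length(contact)) {
      .err("consistency_error",
           "hydrogen-bond ensemble frame count differs from the series")
    }
    contact <- contact & hok
  }
  methods::new("ContactSeries", distances = series@distances, cutoff = cutoff,
               contact = contact, persistenceFraction = mean(contact),
               mode = series@mode)
}
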