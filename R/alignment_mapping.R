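#' @include AllClasses.R
NULL

#' Map corresponding Calpha atoms across systems through the MSA
#'
#' Selects the alignment columns that are ungapped in every requested system
#' and, for each system, the Calpha atom of the residue at each such column.
#' All downstream cross-system PCA comparisons run on this common core, so
#' every system shares the same coordinate dimension.
#'
#' @param msa an [MSA-class] object.
#' @param structures named list of [Structure-class], one per system id.
#' @param idSubset ids to map (default: all ids present in both inputs).
#' @return an [AlignmentMap-class].
#' @export
commonCoreMap <- function(msa, structures, idSubset = NULL) {
  if (is.null(idSubset)) idSubset <- intersect(msaIds(msa), names(structures))
  if (length(idSubset) < 1L) {
    .err("consistency_error", "no system has both an MSA record and a structure")
  }
  ali <- msa@ali
  for (id in idSubset) {
    if (!id %in% rownames(ali)) {
      .err("consistency_error", sprintf("no MSA record for '%s'", id))
    }
    if (!id %in% names(structures)) {
      .err("consistency_error", sprintf("no structure for '%s'", id))
    }
  }
  atomIdx <- list()
  sub <- ali[idSubset, , drop = FALSE]
  shared <- which(colSums(sub == "-") == 0L)
  if (length(shared) == 0L) {
    .err("empty_core_error", "no alignment column is ungapped in all systems")
  }
  for (id in idSubset) {
    st <- structures[[id]]
    at <- st@atoms
    caIdx <- which(at$elety == "CA")
    nRes <- length(unique(paste(at$chain, at$resno)))
    nSeq <- sum(sub[id, ] != "-")
    if (length(caIdx) != nRes) {
      .err("consistency_error",
           sprintf("'%s': expected one CA per residue (%d CA, %d residues)",
                   id, length(caIdx), nRes))
    }
    if (nSeq != nRes) {
      .err("consistency_error",
           sprintf("'%s': %d non-gap residues in MSA but %d residues in structure",
                   id, nSeq, nRes))
    }
    rank <- cumsum(sub[id, ] != "-")
    atomIdx[[id]] <- caIdx[rank[shared]]
  }
  methods::new("AlignmentMap", columns = as.integer(shared),
               atomIndices = atomIdx, ids = idSubset)
}

# Motif class at the CES/D site from the site residue and the next non-gap
# (+1) residue.  Classes follow the conserved-motif granularity used for the
# E2 superfamily: DP, SP, EP, SA, EA, E (glutamate with any other +1), other.
.motifClass <- function(site, plusOne) {
  if (site == "S" && plusOne == "P") return("SP")
  if (site == "S" && plusOne == "A") return("SA")
  if (site == "D" && plusOne == "P") return("DP")
  if (site == "E") {
    if (plusOne == "P") return("EP")
    if (plusOne == "A") return("EA")
    return("E")
  }
  "other"
}

#' Classify the CES/D site motif for every sequence in an alignment
#'
#' Locates the MSA column holding the given residue of the reference sequence
#' (e.g. hHR6A Ser120, the conserved E2 Ser/Asp site) and reports, for every
#' record: the residue at that column, the next non-gap residue of the same
#' sequence (the +1 position is counted in sequence space, so insertions in
#' other systems cannot break the call), the motif class, and whether the
#' pair conforms to the minimal Cdk phosphorylation consensus (Ser/Thr
#' immediately followed by Pro).
#'
#' Sequences are handled case-insensitively; `X` and gaps classify as
#' `other`.
#'
#' @param msa an [MSA-class] object.
#' @param referenceId id of the reference sequence.
#' @param referenceResidueNumber 1-based residue number in the ungapped
#'   reference sequence.
#' @return `data.frame` with columns `id`, `site`, `plusOne`, `class`,
#'   `cdkConsensus`.
#' @export
classifyCesSite <- function(msa, referenceId, referenceResidueNumber) {
  ali <- msa@ali
  if (!referenceId %in% rownames(ali)) {
    .err("invalid_argument", sprintf("reference id '%s' not in MSA", referenceId))
  }
  refRow <- ali[referenceId, ]
  nonGap <- refRow != "-"
  rank <- cumsum(nonGap)
  hit <- which(nonGap & rank == referenceResidueNumber)
  if (length(hit) != 1L) {
    .err("invalid_argument",
         sprintf("reference residue %d is not a non-gap position of '%s'",
                 referenceResidueNumber, referenceId))
  }
  column <- hit
  res <- lapply(rownames(ali), function(id) {
    row <- ali[id, ]
    site <- toupper(row[column])
    if (site == "-") {
      return(data.frame(id = id, site = "-", plusOne = "-", class = "other",
                        cdkConsensus = FALSE, stringsAsFactors = FALSE))
    }
    after <- row[seq(column + 1L, length.out = max(0L, length(row) - column))]
    after <- after[after != "-"]
    plusOne <- if (length(after)) toupper(after[1L]) else "-"
    cls <- .motifClass(site, plusOne)
    data.frame(id = id, site = site, plusOne = plusOne, class = cls,
               cdkConsensus = site %in% c("S", "T") && plusOne == "P",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "column") <- column
  out
}
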