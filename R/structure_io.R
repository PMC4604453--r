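#' @include AllClasses.R
NULL

# I/O: multi-model PDB (via bio3d), aligned FASTA (via Biostrings), TSV
# reports.  Internal unit is the nanometre; PDB files are Angstrom.

#' Read a multi-model PDB file as an ensemble
#'
#' Each MODEL becomes one frame (a single coordinate set yields a one-frame
#' ensemble); atom order is preserved and coordinates are converted from
#' Angstrom to nm.  Alternate-location indicators other than blank/'A' are
#' dropped (bio3d convention) and the retained atom count is reported.
#'
#' @param path PDB file path.
#' @param system system id for the ensemble (default: file base name).
#' @return a [TrajectoryEnsemble-class] with the first model as topology.
#' @export
readPDBModels <- function(path, system = NULL) {
  if (!file.exists(path)) .err("io_error", sprintf("no such file: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) .err("format_error",
                             sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e))))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(at) || nrow(at) == 0L) {
    .err("format_error", sprintf("no ATOM records found in '%s'", path))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(at)) {
    .err("format_error",
         sprintf("inconsistent atom count across models in '%s'", path))
  }
  if (anyNA(xyz)) {
    .err("format_error", sprintf("unparseable coordinates in '%s'", path))
  }
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  elem[blank] <- .elementFromName(at$elety[blank])
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atomTab <- data.frame(serial = at$eleno, elety = at$elety,
                        element = toupper(elem), resid = at$resid,
                        resno = at$resno, chain = chain,
                        stringsAsFactors = FALSE)
  message(sprintf("readPDBModels: %d atoms x %d model(s) from %s",
                  nrow(atomTab), nrow(xyz), basename(path)))
  top <- Structure(atomTab, .unflatten(xyz[1L, ]) / 10)
  if (is.null(system)) system <- sub("\\.[^.]*$", "", basename(path))
  TrajectoryEnsemble(xyz / 10, topology = top, system = system)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, fixed-column PDB format, coordinates
#' in Angstrom with three decimals.
#'
#' @param ensemble a [TrajectoryEnsemble-class] with a topology.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePDBModels <- function(ensemble, path) {
  top <- topology(ensemble)
  if (is.null(top)) .err("invalid_argument", "ensemble carries no topology")
  a <- top@atoms
  xyz <- .flatCoords(ensemble) * 10
  # bio3d formats the fixed-column ATOM records one frame at a time; the
  # MODEL/ENDMDL framing is written here so single-frame files carry it too
  ok <- tryCatch({
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    for (f in seq_len(nrow(xyz))) {
      suppressWarnings(
        bio3d::write.pdb(file = tmp, xyz = xyz[f, ], eleno = a$serial,
                         elety = a$elety, resid = a$resid, resno = a$resno,
                         chain = a$chain))
      body <- readLines(tmp)
      body <- body[!grepl("^(END|MODEL|ENDMDL)", body)]
      writeLines(c(sprintf("MODEL %8d", f), body, "ENDMDL"), con)
    }
    writeLines("END   ", con)
    TRUE
  }, error = function(e) e)
  if (inherits(ok, "error")) {
    .err("io_error", sprintf("cannot write '%s': %s", path,
                             conditionMessage(ok)))
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Records are kept in file order; the gapped sequences must all have the
#' same length and unique ids (first whitespace-delimited token of the
#' header).  An all-gap row is accepted and flagged via a message.
#'
#' @param path FASTA file path.
#' @return an [MSA-class] object.
#' @export
readMSAFasta <- function(path) {
  if (!file.exists(path)) .err("io_error", sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) .err("format_error",
                                           sprintf("cannot parse '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) < 1L) .err("format_error", "empty FASTA file")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs <- stats::setNames(as.character(set), ids)
  MSA(seqs)  # validates equal width + unique ids
}

#' Write a deterministic delimited report table
#'
#' Writes a header plus rows as TSV (or another delimiter).  Numeric columns
#' are serialized with 6 significant digits; re-running on the same input
#' yields a byte-identical file.
#'
#' @param rows `data.frame` of rows (may have zero rows).
#' @param schema optional character vector of required column names; a
#'   mismatch is an error.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return the path, invisibly.
#' @export
writeReportTable <- function(rows, schema = NULL, path, sep = "\t") {
  rows <- as.data.frame(rows)
  if (!is.null(schema) && !identical(names(rows), as.character(schema))) {
    .err("invalid_argument",
         sprintf("rows do not conform to schema (%s vs %s)",
                 paste(names(rows), collapse = ","),
                 paste(schema, collapse = ",")))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(signif(v, 6L), scientific = FALSE,
                                       trim = TRUE)
      }, character(1L))
    }
  }
  con <- tryCatch(file(path, "wb"), error = function(e)
    .err("io_error", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con), add = TRUE)
  writeLines(paste(names(out), collapse = sep), con)
  if (nrow(out) > 0L) {
    writeLines(apply(out, 1L, paste, collapse = sep), con)
  }
  invisible(path)
}
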