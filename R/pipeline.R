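#' @include AllClasses.R
NULL

# Configuration-driven orchestration of the full comparison: trim/concat ->
# MSA mapping -> per-system PCA -> crossing/RMSIP/class stats/cosine content
# -> SASA -> distances/persistence -> activity fit, with a deterministic
# report bundle.

.stage <- function(name, sysId = NA_character_, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.na(sysId)) "" else sprintf(" (system '%s')", sysId)
    stop(sprintf("stage '%s'%s: %s", name, where, conditionMessage(e)),
         call. = FALSE)
  })
}

.resolveEnsemble <- function(x) {
  if (methods::is(x, "TrajectoryEnsemble")) return(x)
  if (is.character(x)) return(readPDBModels(x))
  .err("invalid_argument", "replicate must be a TrajectoryEnsemble or a path")
}

.resolveSelection <- function(top, sel, sidechainDefault = TRUE) {
  if (is.null(sel)) return(integer())
  idx <- selectAtoms(top,
                     chain = sel$chain, resno = sel$resno,
                     elety = sel$elety,
                     sidechain = if (is.null(sel$sidechain)) {
                       is.null(sel$elety) && sidechainDefault
                     } else isTRUE(sel$sidechain))
  if (length(idx) == 0L) {
    .err("selection_error",
         sprintf("selection (chain=%s resno=%s elety=%s) matches no atom",
                 paste(sel$chain, collapse = ","),
                 paste(sel$resno, collapse = ","),
                 paste(sel$elety, collapse = ",")))
  }
  idx
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return the configuration list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .err("io_error", sprintf("no such file: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    .err("format_error", "configuration must be .yaml/.yml or .json")
  }
}

#' Run the full ensemble-comparison pipeline
#'
#' Executes, on a configuration describing one or more systems with >= 1
#' replicate each: equilibration trimming and macro-trajectory assembly;
#' MSA-based Calpha mapping (when an alignment is given); per-system
#' essential-dynamics PCA on the common core; pairwise RMSIP, the
#' PC1 crossing-over diagnostic against the reference system, class-wise
#' boxplot statistics and per-replicate cosine contents; solvent
#' accessibility of the catalytic cysteine side chain; substrate-lysine
#' distance series with contact persistence; and the exponential
#' activity-distance fit.  Stages whose inputs are absent from the
#' configuration are skipped and logged; with a single system the comparison
#' stages are skipped with a warning.
#'
#' The configuration is a list (or a YAML/JSON file path, see
#' [readRunConfig()]) with entries:
#' \describe{
#'   \item{systems}{list of `list(id, replicates, activity = NULL,
#'     class = id)`, where `replicates` is a list of
#'     [TrajectoryEnsemble-class] objects or multi-model PDB paths.}
#'   \item{msa}{optional [MSA-class] or aligned-FASTA path.}
#'   \item{referenceId}{reference system id (default: first system).}
#'   \item{cesResidue}{optional 1-based CES/D residue number in the reference
#'     sequence, enabling the motif scan.}
#'   \item{selections}{optional list with `catalyticCys`, `substrateLys`,
#'     `cesSite`, each `list(chain, resno, elety = NULL)`.}
#'   \item{D, kMax, trim, cutoff, sasaStride, sasaPoints, cosinePCs, seed}{
#'     analysis parameters; defaults 20, 10, 0, 0.48 nm, 1, 960, 10, 1.}
#' }
#'
#' @param config configuration list or file path.
#' @param outDir optional output directory for the deterministic report
#'   bundle (TSV tables, `activity_fit.json`, `report.json`, `log.txt`);
#'   created if missing.  On error no partial bundle is left behind.
#' @return the report list, invisibly: `subspaces`, `rmsipPairwise`,
#'   `crossing`, `classStats`, `cosineContent`, `sasa`, `distanceSummary`,
#'   `activityFit`, `cesCalls`, `log`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$systems) || length(config$systems) < 1L) {
    .err("invalid_argument", "config must list at least one system")
  }
  D <- if (is.null(config$D)) 20L else as.integer(config$D)
  kMax <- if (is.null(config$kMax)) 10L else as.integer(config$kMax)
  trim <- if (is.null(config$trim)) 0 else config$trim
  cutoff <- if (is.null(config$cutoff)) 0.48 else config$cutoff
  sasaStride <- if (is.null(config$sasaStride)) 1L else as.integer(config$sasaStride)
  sasaPoints <- if (is.null(config$sasaPoints)) 960L else as.integer(config$sasaPoints)
  cosinePCs <- if (is.null(config$cosinePCs)) 10L else as.integer(config$cosinePCs)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  ids <- vapply(config$systems, function(s) s$id, character(1L))
  if (anyDuplicated(ids)) .err("invalid_argument", "duplicate system ids")
  classes <- vapply(config$systems, function(s) {
    if (is.null(s$class)) s$id else s$class
  }, character(1L))
  names(classes) <- ids
  referenceId <- if (is.null(config$referenceId)) ids[1L] else config$referenceId
  if (!referenceId %in% ids) {
    .err("invalid_argument", sprintf("referenceId '%s' is not a system", referenceId))
  }
  logLines <- sprintf("run: systems=%s reference=%s D=%d kMax=%d trim=%s cutoff=%g seed=%d",
                      paste(ids, collapse = ","), referenceId, D, kMax,
                      format(trim), cutoff, seed)
  logIt <- function(...) logLines <<- c(logLines, sprintf(...))

  # --- trim + macro-trajectory --------------------------------------------
  macro <- list()
  for (s in config$systems) {
    macro[[s$id]] <- .stage("macro-trajectory", s$id, {
      repsIn <- s$replicates
      if (methods::is(repsIn, "TrajectoryEnsemble") || is.character(repsIn)) {
        repsIn <- list(repsIn)
      }
      reps <- lapply(repsIn, .resolveEnsemble)
      # a single ensemble may carry several replicates via its frame ids
      m <- if (length(reps) == 1L) {
        preprocessMacroTrajectory(reps[[1L]], trim = trim)
      } else {
        preprocessMacroTrajectory(reps, trim = trim)
      }
      m@system <- s$id
      m
    })
    logIt("stage=macro-trajectory system=%s replicates=%d frames=%d trim=%s",
          s$id, length(unique(replicateIds(macro[[s$id]]))),
          nFrames(macro[[s$id]]), format(trim))
  }

  # --- alignment mapping ---------------------------------------------------
  msa <- NULL
  map <- NULL
  if (!is.null(config$msa)) {
    msa <- if (methods::is(config$msa, "MSA")) config$msa else
      .stage("read-msa", expr = readMSAFasta(config$msa))
  }
  topologies <- lapply(macro, topology)
  if (!is.null(msa) && length(ids) > 1L) {
    map <- .stage("alignment-mapping",
                  expr = commonCoreMap(msa, topologies, ids))
    logIt("stage=alignment-mapping columns=%d systems=%d",
          length(mappedColumns(map)), length(ids))
  }
  atomIdx <- lapply(ids, function(id) {
    if (!is.null(map)) return(mappedAtoms(map, id))
    top <- topologies[[id]]
    ca <- which(top@atoms$elety == "CA")
    if (length(ca)) ca else seq_len(nAtoms(macro[[id]]))
  })
  names(atomIdx) <- ids
  if (is.null(map) && length(ids) > 1L) {
    nm <- vapply(atomIdx, length, integer(1L))
    if (length(unique(nm)) != 1L) {
      .err("consistency_error",
           "without an MSA all systems must share the mapped atom count")
    }
  }

  # --- per-system PCA ------------------------------------------------------
  subspaces <- list()
  for (id in ids) {
    subspaces[[id]] <- .stage("essential-dynamics", id, {
      essentialDynamics(macro[[id]], map = atomIdx[[id]])
    })
    logIt("stage=essential-dynamics system=%s atoms=%d frames=%d var20=%.3f",
          id, length(atomIdx[[id]]), nFrames(macro[[id]]),
          varianceExplained(subspaces[[id]],
                            min(20L, length(eigenvalues(subspaces[[id]])))))
  }
  Duse <- min(D, min(vapply(subspaces, function(s) ncol(eigenvectors(s)),
                            integer(1L))))

  # --- subspace comparison -------------------------------------------------
  rmsipTab <- NULL
  crossing <- list()
  classStats <- NULL
  if (length(ids) > 1L) {
    pairs <- utils::combn(ids, 2L)
    rmsipTab <- .stage("rmsip", expr = {
      data.frame(
        systemA = pairs[1L, ], systemB = pairs[2L, ],
        rmsip = apply(pairs, 2L, function(p) {
          rmsip(subspaces[[p[1L]]], subspaces[[p[2L]]], D = Duse)
        }), stringsAsFactors = FALSE)
    })
    logIt("stage=rmsip pairs=%d D=%d", ncol(pairs), Duse)
    refPc1 <- eigenvectors(subspaces[[referenceId]])[, 1L]
    for (id in setdiff(ids, referenceId)) {
      crossing[[id]] <- .stage("crossing", id, {
        bestMatchPC(refPc1, subspaces[[id]],
                    kMax = min(kMax, ncol(eigenvectors(subspaces[[id]]))))
      })
      logIt("stage=crossing system=%s bestMatch=%d overlap=%.3f", id,
            crossing[[id]]$bestMatch, crossing[[id]]$bestOverlap)
    }
    refClass <- classes[referenceId]
    wt <- ids[classes == refClass]
    labels <- character(0)
    vals <- numeric(0)
    for (k in seq_len(nrow(rmsipTab))) {
      a <- rmsipTab$systemA[k]; b <- rmsipTab$systemB[k]
      if (a %in% wt && b %in% wt) {
        labels <- c(labels, refClass); vals <- c(vals, rmsipTab$rmsip[k])
      } else if (a %in% wt || b %in% wt) {
        other <- if (a %in% wt) b else a
        labels <- c(labels, classes[other]); vals <- c(vals, rmsipTab$rmsip[k])
      }
    }
    classStats <- .stage("class-stats", expr = {
      withCallingHandlers(
        groupBoxplotStats(vals, factor(labels, levels = unique(c(refClass, classes)))),
        warning = function(w) {
          logIt("stage=class-stats note=%s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    })
    logIt("stage=class-stats groups=%d", nrow(classStats))
  } else {
    warning("single system: comparison stages skipped")
    logIt("stage=comparison skipped=single-system")
  }

  # --- cosine content per replicate ---------------------------------------
  cosTab <- .stage("cosine-content", expr = {
    rows <- list()
    for (id in ids) {
      ens <- macro[[id]]
      reps <- replicateIds(ens)
      for (r in unique(reps)) {
        sub <- ens[which(reps == r), ]
        if (nFrames(sub) < 4L) next
        sd_r <- essentialDynamics(sub, map = atomIdx[[id]])
        kk <- min(cosinePCs, ncol(eigenvectors(sd_r)), nFrames(sub) - 1L)
        pr <- projectOnto(sub, sd_r, k = kk)
        for (i in seq_len(kk)) {
          if (all(pr[, i] == 0)) next
          rows[[length(rows) + 1L]] <-
            data.frame(system = id, replicate = r, pc = i,
                       cosineContent = cosineContent(pr[, i], i = i),
                       stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  logIt("stage=cosine-content rows=%d", if (is.null(cosTab)) 0L else nrow(cosTab))

  # --- SASA of the catalytic cysteine side chain --------------------------
  sasaTab <- NULL
  sel <- config$selections
  if (!is.null(sel$catalyticCys)) {
    rows <- list()
    for (id in ids) {
      res <- .stage("sasa", id, {
        idx <- .resolveSelection(topologies[[id]], sel$catalyticCys)
        sasaSeries(macro[[id]], idx, nPoints = sasaPoints,
                   stride = sasaStride)
      })
      rows[[id]] <- cbind(system = id, res$byReplicate)
      logIt("stage=sasa system=%s frames=%d stride=%d", id,
            nrow(res$perFrame), sasaStride)
    }
    sasaTab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    logIt("stage=sasa skipped=no-selection")
  }

  # --- distances + persistence --------------------------------------------
  distTab <- NULL
  persTab <- NULL
  if (!is.null(sel$substrateLys) &&
      (!is.null(sel$catalyticCys) || !is.null(sel$cesSite))) {
    drows <- list(); prows <- list()
    for (id in ids) {
      top <- topologies[[id]]
      lysIdx <- .stage("distances", id, .resolveSelection(top, sel$substrateLys))
      pairsDef <- list()
      if (!is.null(sel$catalyticCys)) {
        pairsDef$cysLys <- .resolveSelection(top, sel$catalyticCys)
      }
      if (!is.null(sel$cesSite)) {
        pairsDef$cesLys <- .resolveSelection(top, sel$cesSite)
      }
      for (pairName in names(pairsDef)) {
        ser <- .stage("distances", id, {
          mode <- if (length(pairsDef[[pairName]]) == 1L &&
                      length(lysIdx) == 1L) "named-pair" else "min-heavy"
          distanceSeries(macro[[id]], pairsDef[[pairName]], lysIdx, mode = mode)
        })
        pers <- contactPersistence(ser, cutoff = cutoff)
        reps <- replicateIds(macro[[id]])
        repMeans <- tapply(distances(ser), reps, mean)
        drows[[paste(id, pairName)]] <- data.frame(
          system = id, pair = pairName, mode = ser@mode,
          meanDistance = mean(distances(ser)),
          sdAcrossReplicates = if (length(repMeans) > 1L)
            stats::sd(repMeans) else NA_real_,
          stringsAsFactors = FALSE)
        prows[[paste(id, pairName)]] <- data.frame(
          system = id, pair = pairName, cutoff = cutoff,
          persistence = persistence(pers), stringsAsFactors = FALSE)
        logIt("stage=distances system=%s pair=%s mode=%s frames=%d persistence=%.3f",
              id, pairName, ser@mode, length(distances(ser)),
              persistence(pers))
      }
    }
    distTab <- do.call(rbind, c(drows, list(make.row.names = FALSE)))
    persTab <- do.call(rbind, c(prows, list(make.row.names = FALSE)))
  } else {
    logIt("stage=distances skipped=no-selection")
  }

  # --- activity fit --------------------------------------------------------
  activityFit <- NULL
  activities <- vapply(config$systems, function(s) {
    if (is.null(s$activity)) NA_real_ else as.numeric(s$activity)
  }, numeric(1L))
  names(activities) <- ids
  if (!is.null(distTab)) {
    cys <- distTab[distTab$pair == "cysLys", ]
    have <- cys$system[!is.na(activities[cys$system])]
    if (length(have) >= 3L) {
      activityFit <- .stage("activity-fit", expr = {
        fitExponentialActivity(
          cys$meanDistance[match(have, cys$system)], activities[have],
          uncertainties = cys$sdAcrossReplicates[match(have, cys$system)])
      })
      logIt("stage=activity-fit n=%d b=%.4f c=%.4f r=%.3f", length(have),
            activityFit@b, activityFit@c, activityFit@correlation)
    } else {
      logIt("stage=activity-fit skipped=fewer-than-3-systems-with-activity")
    }
  }

  # --- CES/D motif scan ----------------------------------------------------
  cesCalls <- NULL
  if (!is.null(msa) && !is.null(config$cesResidue)) {
    cesCalls <- .stage("ces-scan", expr = {
      classifyCesSite(msa, referenceId, config$cesResidue)
    })
    logIt("stage=ces-scan sequences=%d column=%d", nrow(cesCalls),
          attr(cesCalls, "column"))
  }

  report <- list(schemaVersion = "1.0",
                 systems = data.frame(id = ids, class = unname(classes),
                                      activity = unname(activities),
                                      stringsAsFactors = FALSE),
                 referenceId = referenceId, D = Duse, kMax = kMax,
                 subspaces = subspaces, rmsipPairwise = rmsipTab,
                 crossing = crossing, classStats = classStats,
                 cosineContent = cosTab, sasa = sasaTab,
                 distanceSummary = distTab, persistence = persTab,
                 activityFit = activityFit, cesCalls = cesCalls,
                 log = logLines)

  if (!is.null(outDir)) .writeBundle(report, outDir)
  invisible(report)
}

# Write the TSV/JSON report bundle; remove partial output on failure.
.writeBundle <- function(report, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character(0)
  wr <- function(fun, name) {
    path <- file.path(outDir, name)
    fun(path)
    written <<- c(written, path)
  }
  tryCatch({
    if (!is.null(report$rmsipPairwise)) {
      wr(function(p) writeReportTable(report$rmsipPairwise, path = p),
         "rmsip_pairwise.tsv")
    }
    if (length(report$crossing)) {
      tab <- do.call(rbind, lapply(names(report$crossing), function(id) {
        cbind(system = id, report$crossing[[id]]$profile)
      }))
      wr(function(p) writeReportTable(tab, path = p), "crossing_pc1.tsv")
    }
    if (!is.null(report$classStats)) {
      wr(function(p) writeReportTable(report$classStats, path = p),
         "class_stats.tsv")
    }
    if (!is.null(report$cosineContent)) {
      wr(function(p) writeReportTable(report$cosineContent, path = p),
         "cosine_content.tsv")
    }
    if (!is.null(report$sasa)) {
      wr(function(p) writeReportTable(report$sasa, path = p),
         "sasa_replicates.tsv")
    }
    if (!is.null(report$distanceSummary)) {
      wr(function(p) writeReportTable(report$distanceSummary, path = p),
         "distances.tsv")
    }
    if (!is.null(report$persistence)) {
      wr(function(p) writeReportTable(report$persistence, path = p),
         "persistence.tsv")
    }
    if (!is.null(report$activityFit)) {
      f <- report$activityFit
      wr(function(p) jsonlite::write_json(
        list(b = f@b, c = f@c, correlation = f@correlation,
             residuals = f@residuals, degenerate = f@degenerate),
        p, auto_unbox = TRUE, digits = 10), "activity_fit.json")
    }
    if (!is.null(report$cesCalls)) {
      wr(function(p) writeReportTable(report$cesCalls, path = p),
         "ces_calls.tsv")
    }
    wr(function(p) jsonlite::write_json(
      list(schemaVersion = report$schemaVersion,
           systems = report$systems, referenceId = report$referenceId,
           D = report$D, kMax = report$kMax), p,
      auto_unbox = TRUE, digits = 10), "report.json")
    wr(function(p) writeLines(report$log, p), "log.txt")
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(outDir)
}
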