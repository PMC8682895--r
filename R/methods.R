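#' Accessors for KinomeSignal objects
#'
#' @param x a [KinomeSignal].
#' @return `signalRecords`: the long-form record table; `sampleInfo`: the
#'   well/sample metadata; `peptideInfo`: the peptide annotation;
#'   `quantType`: the declared quantification type; `sourceMeta`: the
#'   verbatim header metadata; `qcReport`: a [QcReport].
#' @name KinomeSignal-accessors
NULL

#' @rdname KinomeSignal-accessors
#' @export
setMethod("signalRecords", "KinomeSignal", function(x) x@records)

#' @rdname KinomeSignal-accessors
#' @export
setMethod("sampleInfo", "KinomeSignal", function(x) x@samples)

#' @rdname KinomeSignal-accessors
#' @export
setMethod("peptideInfo", "KinomeSignal", function(x) x@peptides)

#' @rdname KinomeSignal-accessors
#' @export
setMethod("quantType", "KinomeSignal", function(x) x@quantType)

#' @rdname KinomeSignal-accessors
#' @export
setMethod("sourceMeta", "KinomeSignal", function(x) x@sourceMeta)

#' @rdname KinomeSignal-accessors
#' @export
setMethod("qcReport", "KinomeSignal", function(x) {
  qc <- x@qc
  num <- function(field) as.integer(qc[[field]] %||% 0L)
  new("QcReport",
      nNegativeRescaled = num("nNegativeRescaled"),
      nSaturatedRemoved = num("nSaturatedRemoved"),
      nLowSignalRemoved = num("nLowSignalRemoved"),
      nReferenceRemoved = num("nReferenceRemoved"),
      nNonlinearRemoved = num("nNonlinearRemoved"),
      survivingPeptides = as.character(x@peptides$peptideId),
      thresholds = qc[["thresholds"]] %||% list())
})

setMethod("show", "KinomeSignal", function(object) {
  rec <- object@records
  cat("KinomeSignal (", object@quantType, ")\n", sep = "")
  cat("  ", nrow(object@peptides), " peptides x ", nrow(object@samples),
      " wells on ", length(unique(object@samples$barcode)), " chip(s)\n",
      sep = "")
  cat("  ", nrow(rec), " signal points; cycles: ",
      paste(sort(unique(rec$cycle)), collapse = ", "),
      "; exposures (ms): ",
      paste(sort(unique(rec$exposureTime)), collapse = ", "), "\n", sep = "")
  grp <- object@samples$group
  if (all(!is.na(grp)))
    cat("  groups: ", paste(sprintf("%s (n=%d)", names(table(grp)),
                                    as.integer(table(grp))),
                            collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "QcReport", function(object) {
  cat("Kinome-array QC report\n")
  cat("  negative points rescaled to baseline:", object@nNegativeRescaled, "\n")
  cat("  saturated points removed:            ", object@nSaturatedRemoved, "\n")
  cat("  undetectable peptides removed:       ", object@nLowSignalRemoved, "\n")
  cat("  reference peptides removed:          ", object@nReferenceRemoved, "\n")
  cat("  non-linear peptides removed (R2):    ", object@nNonlinearRemoved, "\n")
  cat("  surviving peptides:                  ",
      length(object@survivingPeptides), "\n")
  if (length(object@thresholds)) {
    th <- vapply(object@thresholds, function(v) paste(format(v), collapse = ","),
                 character(1))
    cat("  thresholds:", paste(names(th), th, sep = "=", collapse = "; "), "\n")
  }
  invisible(object)
})

#' Accessors for KinomeModel objects
#' @param x a [KinomeModel].
#' @return the per-well fit table, the chip-normalized table, or the
#'   per-group mean table.
#' @name KinomeModel-accessors
NULL

#' @rdname KinomeModel-accessors
#' @export
setMethod("modelFits", "KinomeModel", function(x) x@fits)

#' @rdname KinomeModel-accessors
#' @export
setMethod("normalizedFits", "KinomeModel", function(x) x@normalized)

#' @rdname KinomeModel-accessors
#' @export
setMethod("groupedSignals", "KinomeModel", function(x) x@grouped)

setMethod("show", "KinomeModel", function(object) {
  cat("KinomeModel: ", length(unique(object@fits$peptideId)), " peptides x ",
      length(unique(object@fits$sampleId)), " wells (chip norm: ",
      object@chipNorm, ")\n", sep = "")
  invisible(object)
})

#' Accessors for KinomeDiff objects
#' @param x a [KinomeDiff].
#' @return `diffTable`: the per-peptide log2-fold-change table.
#' @name KinomeDiff-accessors
NULL

#' @rdname KinomeDiff-accessors
#' @export
setMethod("diffTable", "KinomeDiff", function(x) x@table)

setMethod("show", "KinomeDiff", function(object) {
  cat("KinomeDiff (", object@mode, "): ", object@comparison, " vs ",
      object@baseline, " baseline; ", nrow(object@table), " peptides\n",
      sep = "")
  cat("  LFC range: [", round(min(object@table$lfc), 3), ", ",
      round(max(object@table$lfc), 3), "]\n", sep = "")
  invisible(object)
})

setMethod("show", "PeptideSet", function(object) {
  cat("PeptideSet: |LFC| >= ", object@cutoff, " (", object@direction, "), ",
      length(object@peptides), " peptides\n", sep = "")
  invisible(object)
})

#' Accessors for KinaseMapping objects
#' @param x a [KinaseMapping].
#' @return `peptidePool`: the peptide universe the null samples from;
#'   `kinaseNames`: all kinase-family names.
#' @name KinaseMapping-accessors
NULL

#' @rdname KinaseMapping-accessors
#' @export
setMethod("peptidePool", "KinaseMapping", function(x) x@pool)

#' @rdname KinaseMapping-accessors
#' @export
setMethod("kinaseNames", "KinaseMapping", function(x) x@kinases)

setMethod("show", "KinaseMapping", function(object) {
  cat("KinaseMapping: ", length(unique(object@entries$peptideId)),
      " mapped peptides (pool ", length(object@pool), ") -> ",
      length(object@kinases), " kinase families\n", sep = "")
  invisible(object)
})

#' Accessors for KinaseScores objects
#' @param x a [KinaseScores].
#' @return `scoreTable`: one row per (kinase, cutoff) with observed count,
#'   sampling mean/SD and Z; `averagedScores`: one row per kinase with the
#'   cutoff-averaged Z.
#' @name KinaseScores-accessors
NULL

#' @rdname KinaseScores-accessors
#' @export
setMethod("scoreTable", "KinaseScores", function(x) x@scores)

#' @rdname KinaseScores-accessors
#' @export
setMethod("averagedScores", "KinaseScores", function(x) x@averaged)

setMethod("show", "KinaseScores", function(object) {
  cutoffs <- sort(unique(object@scores$cutoff))
  cat("KinaseScores: ", length(unique(object@scores$kinase)),
      " kinase families x ", length(cutoffs), " cutoff set(s) [",
      paste(cutoffs, collapse = ", "), "], B = ", object@iterations,
      " iterations, seed ", object@seed, "\n", sep = "")
  top <- object@averaged[order(-abs(object@averaged$meanZ)), ]
  top <- utils::head(top, 5)
  cat("  top |meanZ|: ",
      paste(sprintf("%s (%.2f)", top$kinase, top$meanZ), collapse = ", "),
      "\n", sep = "")
  invisible(object)
})

#' Accessors for KinaseNetwork objects
#' @param x a [KinaseNetwork].
#' @return `networkNodes`: node table with degree, hit flag and averaged Z;
#'   `networkEdges`: edge table with the hit-incidence class.
#' @name KinaseNetwork-accessors
NULL

#' @rdname KinaseNetwork-accessors
#' @export
setMethod("networkNodes", "KinaseNetwork", function(x) x@nodes)

#' @rdname KinaseNetwork-accessors
#' @export
setMethod("networkEdges", "KinaseNetwork", function(x) x@edges)

setMethod("show", "KinaseNetwork", function(object) {
  cat("KinaseNetwork: ", nrow(object@nodes), " kinases (",
      sum(object@nodes$isHit), " hits), ", nrow(object@edges), " edges (",
      sum(object@edges$class == "hit_incident"), " hit-incident)\n", sep = "")
  invisible(object)
})
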