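#' @import methods
NULL

SUPPORTED_QUANT_TYPES <- c("Median_SigmBg", "Mean_SigmBg")

#' Container for PamChip kinome-array signal data
#'
#' `KinomeSignal` holds the long-form signal records of a PamStation12 run
#' together with well/sample metadata and reporter-peptide annotation. It is
#' the object every downstream stage (QC, kinetic modeling, differential
#' phosphorylation, upstream-kinase scoring) consumes. One record is the
#' background-subtracted signal of one peptide in one well at one pump cycle
#' and one camera exposure time.
#'
#' @slot records data.frame with columns `sampleId`, `peptideId`, `cycle`,
#'   `exposureTime` (ms) and `signal`. Signals may be negative before QC.
#' @slot samples data.frame with columns `sampleId`, `sampleName`, `barcode`
#'   (chip identifier), `well` and `group` (NA until [assignGroups()]).
#' @slot peptides data.frame with columns `peptideId`, `sequence`,
#'   `uniprotAcc` and `isReference` (control peptides destined for removal).
#' @slot quantType quantification declared in the file header, one of
#'   `"Median_SigmBg"` or `"Mean_SigmBg"`.
#' @slot sourceMeta named list of verbatim header metadata (software
#'   version, export date, ...); preserved, never interpreted.
#' @slot qc named list of accumulated QC counters and thresholds; retrieve
#'   with [qcReport()].
#'
#' @seealso [readCrosstab()], [assignGroups()], [extractEndpoint()],
#'   [scaleNegatives()], [filterLowPeptides()]
#' @export
setClass("KinomeSignal",
  representation(
    records    = "data.frame",
    samples    = "data.frame",
    peptides   = "data.frame",
    quantType  = "character",
    sourceMeta = "list",
    qc         = "list"
  ),
  prototype(
    quantType = "Median_SigmBg",
    sourceMeta = list(),
    qc = list()
  )
)

setValidity("KinomeSignal", function(object) {
  msg <- character()
  rec <- object@records
  needRec <- c("sampleId", "peptideId", "cycle", "exposureTime", "signal")
  if (!all(needRec %in% names(rec)))
    msg <- c(msg, paste("records must have columns:",
                        paste(needRec, collapse = ", ")))
  needSam <- c("sampleId", "sampleName", "barcode", "well", "group")
  if (!all(needSam %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns:",
                        paste(needSam, collapse = ", ")))
  needPep <- c("peptideId", "sequence", "uniprotAcc", "isReference")
  if (!all(needPep %in% names(object@peptides)))
    msg <- c(msg, paste("peptides must have columns:",
                        paste(needPep, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(object@peptides$peptideId))
    msg <- c(msg, "duplicated peptideId in peptide annotation")
  if (anyDuplicated(object@samples$sampleId))
    msg <- c(msg, "duplicated sampleId in sample metadata")
  if (any(!nzchar(object@samples$barcode)) || anyNA(object@samples$barcode))
    msg <- c(msg, "every sample needs a non-empty chip barcode")
  if (nrow(rec)) {
    if (!all(rec$sampleId %in% object@samples$sampleId))
      msg <- c(msg, "records reference unknown sampleId")
    if (!all(rec$peptideId %in% object@peptides$peptideId))
      msg <- c(msg, "records reference unknown peptideId")
    if (any(rec$exposureTime <= 0, na.rm = TRUE))
      msg <- c(msg, "exposure times must be strictly positive")
    if (any(rec$cycle <= 0, na.rm = TRUE))
      msg <- c(msg, "cycles must be positive integers")
    key <- paste(rec$sampleId, rec$peptideId, rec$cycle, rec$exposureTime,
                 sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(sample, peptide, cycle, exposure) keys must be unique")
  }
  if (length(object@quantType) != 1L ||
      !object@quantType %in% SUPPORTED_QUANT_TYPES)
    msg <- c(msg, paste("quantType must be one of:",
                        paste(SUPPORTED_QUANT_TYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Quality-control report for a kinome-array run
#'
#' Records how many data points or peptides each QC step touched, the
#' surviving peptide panel, and the thresholds used. Built incrementally by
#' the QC functions and retrieved from a [KinomeSignal] with [qcReport()].
#'
#' @slot nNegativeRescaled points clamped to the baseline.
#' @slot nSaturatedRemoved points removed at/above the saturation ceiling.
#' @slot nLowSignalRemoved peptides removed as undetectable.
#' @slot nReferenceRemoved reference/control peptides removed.
#' @slot nNonlinearRemoved peptides removed by the R-squared filter.
#' @slot survivingPeptides identifiers of the retained peptide panel.
#' @slot thresholds named list of QC parameters (baseline, minSignal,
#'   detection fraction, saturation limit, r2Min).
#' @export
setClass("QcReport",
  representation(
    nNegativeRescaled = "integer",
    nSaturatedRemoved = "integer",
    nLowSignalRemoved = "integer",
    nReferenceRemoved = "integer",
    nNonlinearRemoved = "integer",
    survivingPeptides = "character",
    thresholds        = "list"
  ),
  prototype(
    nNegativeRescaled = 0L, nSaturatedRemoved = 0L, nLowSignalRemoved = 0L,
    nReferenceRemoved = 0L, nNonlinearRemoved = 0L,
    survivingPeptides = character(), thresholds = list()
  )
)

setValidity("QcReport", function(object) {
  counts <- c(object@nNegativeRescaled, object@nSaturatedRemoved,
              object@nLowSignalRemoved, object@nReferenceRemoved,
              object@nNonlinearRemoved)
  if (any(counts < 0L)) "QC counts must be non-negative" else TRUE
})

#' Kinetic model bundle: per-well fits, chip-normalized and grouped signals
#'
#' Result of [scaleModel()]: the per-(peptide, well) linear exposure-time
#' fits with the log2 final signal, the same table after per-chip centering,
#' and the per-(peptide, group) means. The three tables share one peptide
#' panel.
#'
#' @slot fits data.frame: `peptideId`, `sampleId`, `barcode`, `group`,
#'   `slope`, `intercept`, `rSquared`, `nPoints`, `signal` (log2 of 100
#'   times the slope), `clamped` (TRUE when 100*slope fell below the
#'   baseline and was clamped before the log).
#' @slot normalized like `fits` but `signal` is chip-centered.
#' @slot grouped data.frame: `peptideId`, `group`, `signal` (mean of the
#'   chip-normalized signals), `n`.
#' @slot chipNorm centering statistic used: "median", "mean" or "none".
#' @export
setClass("KinomeModel",
  representation(
    fits       = "data.frame",
    normalized = "data.frame",
    grouped    = "data.frame",
    chipNorm   = "character"
  )
)

setValidity("KinomeModel", function(object) {
  p1 <- sort(unique(object@fits$peptideId))
  p2 <- sort(unique(object@normalized$peptideId))
  p3 <- sort(unique(object@grouped$peptideId))
  if (!identical(p1, p2) || (nrow(object@grouped) && !identical(p1, p3)))
    return("fits, normalized and grouped tables must share one peptide panel")
  if (any(object@fits$rSquared < -1e-9 | object@fits$rSquared > 1 + 1e-9,
          na.rm = TRUE))
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' Per-peptide differential phosphorylation table
#'
#' Log2 fold changes of the chip-normalized final signal,
#' comparison minus baseline. In within-chip mode the per-chip group-mean
#' differences are kept and `lfc` is their mean across chips.
#'
#' @slot table data.frame: `peptideId`, `lfc`; within-chip mode adds one
#'   `lfc.<barcode>` column per chip.
#' @slot mode "across_chip" or "within_chip".
#' @slot baseline,comparison group labels; positive `lfc` means higher
#'   phosphorylation in the comparison group.
#' @export
setClass("KinomeDiff",
  representation(
    table      = "data.frame",
    mode       = "character",
    baseline   = "character",
    comparison = "character"
  )
)

setValidity("KinomeDiff", function(object) {
  if (!all(c("peptideId", "lfc") %in% names(object@table)))
    return("table needs columns peptideId, lfc")
  if (any(!is.finite(object@table$lfc)))
    return("all log2 fold changes must be finite")
  if (!object@mode %in% c("across_chip", "within_chip"))
    return("mode must be 'across_chip' or 'within_chip'")
  TRUE
})

#' Cutoff-thresholded differential peptide set
#'
#' @slot cutoff absolute log2-fold-change threshold (inclusive).
#' @slot peptides member identifiers.
#' @slot direction "both", "up" or "down".
#' @export
setClass("PeptideSet",
  representation(cutoff = "numeric", peptides = "character",
                 direction = "character")
)

#' Peptide-to-upstream-kinase-family mapping
#'
#' Maps each reporter peptide to the set of kinase families predicted to
#' phosphorylate it, restricted to a peptide pool (the QC-passing,
#' non-reference panel). The pool defines the universe the sampling null
#' draws from; pool peptides with no annotated family stay in the pool with
#' an empty family set.
#'
#' @slot entries data.frame with columns `peptideId`, `kinase` (long form;
#'   a peptide mapped to m families has m rows).
#' @slot pool peptide universe the null samples from.
#' @slot kinases all kinase-family names (the score-table rows).
#' @export
setClass("KinaseMapping",
  representation(entries = "data.frame", pool = "character",
                 kinases = "character")
)

setValidity("KinaseMapping", function(object) {
  if (!all(c("peptideId", "kinase") %in% names(object@entries)))
    return("entries needs columns peptideId, kinase")
  if (nrow(object@entries) &&
      !all(object@entries$peptideId %in% object@pool))
    return("every mapped peptide must belong to the pool")
  if (any(!nzchar(object@kinases)))
    return("kinase family names must be non-empty")
  if (anyDuplicated(object@pool))
    return("pool peptide identifiers must be unique")
  TRUE
})

#' Upstream-kinase random-sampling scores
#'
#' Per-cutoff and cutoff-averaged kinase-family Z scores from the
#' random-sampling null. `scores` holds one row per (kinase, cutoff) with
#' the observed mapped-peptide count, the sampling mean and standard
#' deviation across iterations, and Z = (observed - mean)/sd. `averaged`
#' carries the arithmetic mean of Z across cutoff sets, the final score of
#' each kinase family.
#'
#' @slot scores data.frame: `kinase`, `cutoff`, `setSize`, `observed`,
#'   `samplingAvg`, `sd`, `z`.
#' @slot averaged data.frame: `kinase`, `meanZ`, `nCutoffs`.
#' @slot iterations number of random draws per set.
#' @slot seed master seed the per-set streams were derived from.
#' @slot draws per-cutoff matrix of per-iteration counts (kinases x
#'   iterations), kept only when `returnDraws = TRUE` (needed by
#'   [samplingHistogramData()]).
#' @export
setClass("KinaseScores",
  representation(
    scores     = "data.frame",
    averaged   = "data.frame",
    iterations = "integer",
    seed       = "integer",
    draws      = "list"
  ),
  prototype(draws = list())
)

setValidity("KinaseScores", function(object) {
  s <- object@scores
  need <- c("kinase", "cutoff", "setSize", "observed", "samplingAvg",
            "sd", "z")
  if (!all(need %in% names(s)))
    return(paste("scores needs columns:", paste(need, collapse = ", ")))
  if (any(s$sd < 0, na.rm = TRUE)) return("sampling SD must be >= 0")
  if (any(s$observed > s$setSize, na.rm = TRUE))
    return("observed count cannot exceed the differential-set size")
  TRUE
})

#' Hit-seeded kinase interaction network
#'
#' Kinase hits grown with their protein-protein-interaction neighbours.
#' Nodes carry the averaged Z score (NA for interactors that were not
#' scored), the hit flag and the degree; edges are classed
#' `hit_incident` when at least one endpoint is a hit, else `other`.
#'
#' @slot graph the underlying [igraph::igraph] object.
#' @slot nodes data.frame: `kinase`, `meanZ`, `isHit`, `degree`.
#' @slot edges data.frame: `from`, `to`, `class`.
#' @export
setClass("KinaseNetwork",
  representation(graph = "ANY", nodes = "data.frame", edges = "data.frame")
)

setValidity("KinaseNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$kinase))
      return("every edge endpoint must appear as a node")
    hit <- nd$isHit[match(ed$from, nd$kinase)] |
           nd$isHit[match(ed$to, nd$kinase)]
    if (!all(ed$class == ifelse(hit, "hit_incident", "other")))
      return("edge class must be hit_incident iff an endpoint is a hit")
  }
  deg <- table(factor(c(ed$from, ed$to), levels = nd$kinase))
  if (nrow(nd) && !all(nd$degree == as.integer(deg[nd$kinase])))
    return("node degree must equal the incident edge count")
  TRUE
})
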