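#' Reporter-peptide ID patterns for PamChip control peptides
#'
#' Reference/control peptides (assay artifacts, calibration spots) carry
#' characteristic ID prefixes on PamChip arrays. Peptides whose IDs match
#' any of these regular expressions are flagged `isReference` on read and
#' removed by [removeReferencePeptides()]. The list is configurable because
#' chip layouts differ.
#'
#' @return character vector of regular expressions.
#' @export
referencePeptidePatterns <- function() {
  c("^ART_", "^pVASP", "^pTY", "^REF_")
}

isReferencePeptide <- function(ids, patterns = referencePeptidePatterns()) {
  Reduce(`|`, lapply(patterns, grepl, x = ids),
         init = rep(FALSE, length(ids)))
}

#' Rescale negative signals to the baseline
#'
#' Background-subtracted signals can be negative; they are clamped up to a
#' small positive baseline so that later log2 transforms stay finite.
#' Non-negative signals at or above the baseline are unchanged. The number
#' of rescaled points is recorded in the QC report.
#'
#' @param ds a [KinomeSignal].
#' @param baseline clamp value in signal units (default 1).
#' @return the dataset with no signal below `baseline`.
#' @export
scaleNegatives <- function(ds, baseline = 1) {
  low <- ds@records$signal < baseline
  ds@records$signal[low] <- baseline
  ds <- bumpQc(ds, "nNegativeRescaled", sum(low))
  recordThreshold(ds, baseline = baseline)
}

#' Remove saturated data points
#'
#' Optionally drops individual data points at or above the camera
#' saturation ceiling, which fall outside the linear dynamic range. Off by
#' default (`limit = Inf`).
#'
#' @param ds a [KinomeSignal].
#' @param limit signal ceiling (> 0); points with `signal >= limit` are
#'   removed.
#' @return the filtered dataset; the removal count lands in [qcReport()].
#' @export
filterSaturated <- function(ds, limit = Inf) {
  stopifnot(is.numeric(limit), length(limit) == 1L, limit > 0)
  sat <- ds@records$signal >= limit
  ds@records <- ds@records[!sat, , drop = FALSE]
  rownames(ds@records) <- NULL
  ds <- bumpQc(ds, "nSaturatedRemoved", sum(sat))
  recordThreshold(ds, saturationLimit = limit)
}

#' Filter out undetectable (low-signal) peptides
#'
#' A peptide is considered detectable when its end-point max-exposure signal
#' exceeds `minSignal` in at least `fraction` of the samples of at least one
#' group (all samples count as one group when groups are unassigned).
#' Undetectable peptides are removed panel-wide, i.e. from every well, so
#' all wells keep an identical peptide panel.
#'
#' @param ds a [KinomeSignal]; detection is judged on its end-point
#'   max-exposure records ([extractEndpoint()] is applied internally).
#' @param minSignal detection threshold in signal units (default 5).
#' @param fraction required proportion of samples above threshold within a
#'   group, boundary inclusive (default 1 = all samples of some group).
#' @return the filtered dataset.
#' @export
filterLowPeptides <- function(ds, minSignal = 5, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  ep <- extractEndpoint(ds, maxExposureOnly = TRUE)@records
  sam <- ds@samples
  grp <- sam$group
  if (anyNA(grp)) grp <- rep("all", nrow(sam))
  grp <- grp[match(ep$sampleId, sam$sampleId)]

  detected <- ep$signal > minSignal
  keepTab <- tapply(detected, list(ep$peptideId, grp), mean)
  keep <- apply(keepTab >= fraction, 1L, any, na.rm = TRUE)
  keepIds <- rownames(keepTab)[keep]

  dropped <- setdiff(ds@peptides$peptideId, keepIds)
  if (length(keepIds) == 0L)
    stop("all peptides fall below the detection threshold (minSignal = ",
         minSignal, "); empty panel", call. = FALSE)
  ds <- subsetPeptides(ds, keepIds)
  ds <- bumpQc(ds, "nLowSignalRemoved", length(dropped))
  recordThreshold(ds, minSignal = minSignal, detectionFraction = fraction)
}

#' Remove reference/control peptides
#'
#' Drops peptides flagged `isReference` (see [referencePeptidePatterns()])
#' from the panel before differential analysis.
#'
#' @param ds a [KinomeSignal].
#' @param patterns ID regular expressions overriding the stored flags;
#'   `NULL` (default) uses the `isReference` annotation.
#' @return the filtered dataset.
#' @export
removeReferencePeptides <- function(ds, patterns = NULL) {
  pep <- ds@peptides
  isRef <- if (is.null(patterns)) pep$isReference
           else isReferencePeptide(pep$peptideId, patterns)
  ds <- subsetPeptides(ds, pep$peptideId[!isRef])
  bumpQc(ds, "nReferenceRemoved", sum(isRef))
}

# panel-wide peptide subset (records + annotation)
subsetPeptides <- function(ds, keepIds) {
  ds@peptides <- ds@peptides[ds@peptides$peptideId %in% keepIds, ,
                             drop = FALSE]
  ds@records <- ds@records[ds@records$peptideId %in% keepIds, ,
                           drop = FALSE]
  rownames(ds@peptides) <- rownames(ds@records) <- NULL
  ds
}

#' Standard QC sequence
#'
#' Convenience wrapper running baseline rescaling, the optional saturation
#' filter, reference-peptide removal and the low-signal filter in the
#' conventional order.
#'
#' @param ds a [KinomeSignal].
#' @param baseline clamp value for [scaleNegatives()].
#' @param saturationLimit ceiling for [filterSaturated()] (default off).
#' @param minSignal,fraction parameters of [filterLowPeptides()].
#' @param keepReference skip reference-peptide removal.
#' @return the QC-filtered dataset; inspect [qcReport()] for counts.
#' @export
qcSteps <- function(ds, baseline = 1, saturationLimit = Inf, minSignal = 5,
                    fraction = 1, keepReference = FALSE) {
  ds <- scaleNegatives(ds, baseline = baseline)
  ds <- filterSaturated(ds, limit = saturationLimit)
  if (!keepReference) ds <- removeReferencePeptides(ds)
  ds <- filterLowPeptides(ds, minSignal = minSignal, fraction = fraction)
  stopIfEmpty(ds, "QC filtering")
}

#' Write a QC report
#'
#' Serializes a [QcReport] as a human-readable block plus machine-readable
#' `key<TAB>value` lines.
#'
#' @param report a [QcReport].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeQcReport <- function(report, path) {
  kv <- c(n_negative_rescaled = report@nNegativeRescaled,
          n_saturated_points_removed = report@nSaturatedRemoved,
          n_low_signal_removed = report@nLowSignalRemoved,
          n_reference_removed = report@nReferenceRemoved,
          n_nonlinear_removed = report@nNonlinearRemoved,
          n_surviving_peptides = length(report@survivingPeptides))
  th <- vapply(report@thresholds, function(v)
    paste(format(v, trim = TRUE), collapse = ","), character(1))
  lines <- c("# kinome-array QC report",
             paste(names(kv), kv, sep = "\t"),
             if (length(th)) paste(paste0("threshold_", names(th)), th,
                                   sep = "\t"),
             "# surviving peptides",
             paste("surviving", report@survivingPeptides, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
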