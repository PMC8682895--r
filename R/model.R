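#' Fit the per-peptide exposure-time kinetic model
#'
#' For every (peptide, well) the end-point signal is regressed on camera
#' exposure time by ordinary least squares. The slope is the peptide's
#' phosphorylation-rate summary; the fit quality (R-squared) feeds the
#' linearity filter. R-squared is defined as 0 when the signal has zero
#' variance across exposures (a flat peptide carries no kinetic
#' information).
#'
#' @param ds a [KinomeSignal] restricted to the last cycle
#'   ([extractEndpoint()] is applied internally); needs at least two
#'   distinct exposure times.
#' @param baseline clamp value applied to 100*slope before the log2
#'   transform (kept consistent with [scaleNegatives()]).
#' @return data.frame with one row per (peptide, well): `peptideId`,
#'   `sampleId`, `barcode`, `group`, `slope`, `intercept`, `rSquared`,
#'   `nPoints`, `signal` = log2(100*slope) and `clamped` flagging slopes
#'   whose 100*slope fell below the baseline.
#' @export
fitExposureModel <- function(ds, baseline = 1) {
  ep <- extractEndpoint(ds)
  rec <- ep@records
  if (length(unique(rec$exposureTime)) < 2L)
    stop("need at least two distinct exposure times to fit a slope",
         call. = FALSE)

  f <- interaction(rec$peptideId, rec$sampleId, drop = TRUE)
  idx <- split(seq_len(nrow(rec)), f)
  fit1 <- function(i) {
    x <- rec$exposureTime[i]; y <- rec$signal[i]
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    sxy <- sum((x - mx) * (y - my))
    b <- sxy / sxx
    r2 <- if (syy <= 0) 0 else (sxy * sxy) / (sxx * syy)
    c(slope = b, intercept = my - b * mx, rSquared = r2, nPoints = n)
  }
  res <- t(vapply(idx, fit1, numeric(4)))
  first <- vapply(idx, `[`, 0L, 1L)
  sam <- ds@samples
  j <- match(rec$sampleId[first], sam$sampleId)
  fits <- data.frame(
    peptideId = rec$peptideId[first], sampleId = rec$sampleId[first],
    barcode = sam$barcode[j], group = sam$group[j],
    slope = res[, "slope"], intercept = res[, "intercept"],
    rSquared = res[, "rSquared"], nPoints = as.integer(res[, "nPoints"]),
    stringsAsFactors = FALSE)
  if (any(fits$nPoints < 2L))
    stop("a (peptide, well) series has fewer than two exposure points",
         call. = FALSE)
  fits$signal <- finalSignal(fits$slope, baseline = baseline)
  fits$clamped <- 100 * fits$slope < baseline
  fits <- fits[order(fits$peptideId, fits$sampleId), ]
  rownames(fits) <- NULL
  fits
}

#' Final log2 signal from the kinetic slope
#'
#' The per-peptide activity summary: the exposure-time slope is multiplied
#' by 100 and log2-transformed. Non-positive values of 100*slope are
#' clamped to `baseline` first so the logarithm stays finite.
#'
#' @param slope kinetic slope(s), signal units per ms.
#' @param baseline clamp value (default 1, giving a floor of log2(1) = 0).
#' @return log2(max(100*slope, baseline)); strictly increasing in `slope`
#'   above the clamp.
#' @examples
#' finalSignal(1)      # log2(100) ~ 6.64
#' finalSignal(10.24)  # log2(1024) = 10
#' @export
finalSignal <- function(slope, baseline = 1) {
  log2(pmax(100 * slope, baseline))
}

#' Center final signals per chip
#'
#' Removes additive chip (barcode) batch effects from the log2 final
#' signals by centering each chip at its median (default) or mean. After
#' centering, each chip's summary statistic of the normalized signals is 0.
#'
#' @param fits fit table from [fitExposureModel()].
#' @param method "median" (robust, default), "mean", or "none".
#' @return the fit table with `signal` replaced by its chip-centered value.
#' @export
normalizeByChip <- function(fits, method = c("median", "mean", "none")) {
  method <- match.arg(method)
  if (method == "none") return(fits)
  stat <- if (method == "median") stats::median else mean
  centers <- tapply(fits$signal, fits$barcode, stat)
  oneWell <- tapply(fits$sampleId, fits$barcode,
                    function(s) length(unique(s))) == 1L
  if (any(oneWell))
    warning("chip(s) with a single well: centering degenerates to 0 for ",
            paste(names(oneWell)[oneWell], collapse = ", "))
  fits$signal <- fits$signal - unname(centers[fits$barcode])
  fits
}

#' Filter peptides with a poor linear fit
#'
#' Removes, panel-wide, every peptide whose signal-versus-exposure fit
#' fails the R-squared threshold in any well: a reporter that does not
#' increase linearly with exposure time anywhere is unreliable everywhere.
#' Strict comparison (`rSquared > r2Min` passes).
#'
#' @param fits fit table from [fitExposureModel()].
#' @param r2Min threshold in \[0, 1\] (default 0.9; 0 disables).
#' @return list with `fits` (surviving rows) and `removed` (peptide IDs).
#' @export
filterNonlinear <- function(fits, r2Min = 0.9) {
  stopifnot(r2Min >= 0, r2Min <= 1)
  if (r2Min == 0) return(list(fits = fits, removed = character()))
  fail <- tapply(fits$rSquared <= r2Min, fits$peptideId, any)
  removed <- names(fail)[fail]
  out <- fits[!fits$peptideId %in% removed, , drop = FALSE]
  rownames(out) <- NULL
  list(fits = out, removed = removed)
}

#' Average normalized signals per group
#'
#' @param fits chip-normalized fit table.
#' @return data.frame `peptideId`, `group`, `signal` (mean), `n`.
#' @export
groupModel <- function(fits) {
  if (anyNA(fits$group))
    stop("groups must be assigned before grouping the model", call. = FALSE)
  agg <- stats::aggregate(signal ~ peptideId + group, data = fits,
                          FUN = mean)
  cnt <- stats::aggregate(signal ~ peptideId + group, data = fits,
                          FUN = length)
  agg$n <- cnt$signal
  agg <- agg[order(agg$peptideId, agg$group), c("peptideId", "group",
                                                "signal", "n")]
  rownames(agg) <- NULL
  agg
}

#' Build the full kinetic model bundle
#'
#' Fits the exposure-time model, applies the linearity filter, centers per
#' chip and averages per group, returning the three coupled tables as a
#' [KinomeModel].
#'
#' @param ds a QC-filtered [KinomeSignal] (groups assigned).
#' @param r2Min linearity threshold passed to [filterNonlinear()].
#' @param chipNorm centering statistic passed to [normalizeByChip()].
#' @param baseline clamp value for the log2 transform.
#' @return a [KinomeModel]; the IDs removed by the linearity filter are
#'   available as `attr(modelFits(x), "nonlinearRemoved")`.
#' @export
scaleModel <- function(ds, r2Min = 0.9, chipNorm = c("median", "mean",
                                                     "none"),
                       baseline = 1) {
  chipNorm <- match.arg(chipNorm)
  fits <- fitExposureModel(ds, baseline = baseline)
  flt <- filterNonlinear(fits, r2Min = r2Min)
  fits <- flt$fits
  if (nrow(fits) == 0L)
    stop("no peptides survive the linearity filter (r2Min = ", r2Min, ")",
         call. = FALSE)
  normalized <- normalizeByChip(fits, method = chipNorm)
  grouped <- if (all(!is.na(fits$group))) groupModel(normalized)
             else data.frame(peptideId = character(), group = character(),
                             signal = numeric(), n = integer())
  attr(fits, "nonlinearRemoved") <- flt$removed
  new("KinomeModel", fits = fits, normalized = normalized,
      grouped = grouped, chipNorm = chipNorm)
}

#' Export a model bundle as three delimited tables
#'
#' @param model a [KinomeModel].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("model_fits.tsv", "model_normalized.tsv",
                            "model_grouped.tsv"))
  writeTable(model@fits, paths[1])
  writeTable(model@normalized, paths[2])
  writeTable(model@grouped, paths[3])
  invisible(paths)
}
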