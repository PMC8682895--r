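#' Read a BioNavigator-style crosstab export
#'
#' Parses the delimited "image analysis" crosstab of a PamStation12 run into
#' a [KinomeSignal]. The accepted layout (tab- or comma-delimited,
#' auto-detected from the meta line) is:
#'
#' \preformatted{
#' QuantType=Median_SigmBg  Version=...  Date=...     <- meta line
#' Barcode      . . . .  B001  B001  ...              <- well metadata block
#' Well         . . . .  A1    A2    ...
#' SampleName   . . . .  ctrl1 ctrl2 ...
#' Group        . . . .  F     M     ...              <- optional
#' ID  UniprotAccession  Sequence  Cycle  ExposureTime  <well...>  <- header
#' PEP_001  P12345  RRLIEDAEYAARG  32  10  12.4  9.1 ...           <- data
#' }
#'
#' The five fixed columns identify the reporter peptide and the (cycle,
#' exposure time) grid point; each further column is one chip well. Signal
#' values are passed through unmodified (negatives are preserved; rescaling
#' belongs to QC).
#'
#' @param path path to the crosstab file.
#' @param delimiter field separator; `NULL` (default) auto-detects tab
#'   versus comma from the meta line.
#' @param decimal decimal separator in numeric fields, `"."` (default) or
#'   `","` (only sensible with a tab delimiter).
#' @return a [KinomeSignal].
#' @examples
#' sim <- simulateCrosstab(samplesPerGroup = 2, nPeptides = 12, seed = 7)
#' tf <- tempfile(fileext = ".txt")
#' writeCrosstab(sim$dataset, tf)
#' ds <- readCrosstab(tf)
#' ds
#' @export
readCrosstab <- function(path, delimiter = NULL, decimal = ".") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("parse error: file is empty or truncated (", path, ")",
         call. = FALSE)

  if (is.null(delimiter)) {
    nTab <- lengths(regmatches(lines[1], gregexpr("\t", lines[1])))
    nCom <- lengths(regmatches(lines[1], gregexpr(",", lines[1])))
    delimiter <- if (nTab >= nCom) "\t" else ","
  }
  splitLine <- function(x) strsplit(x, delimiter, fixed = TRUE)[[1]]

  # --- meta line: key=value pairs, must declare a supported QuantType
  metaFields <- splitLine(lines[1])
  kv <- regmatches(metaFields, regexec("^\\s*([^=]+)=(.*)$", metaFields))
  kv <- kv[lengths(kv) == 3L]
  meta <- stats::setNames(lapply(kv, `[`, 3L),
                          trimws(vapply(kv, `[`, "", 2L)))
  qt <- trimws(meta[["QuantType"]] %||% "")
  if (!nzchar(qt))
    stop("malformed header: meta line declares no quantification type ",
         "(expected QuantType=Median_SigmBg or QuantType=Mean_SigmBg)",
         call. = FALSE)
  if (!qt %in% SUPPORTED_QUANT_TYPES)
    stop("unsupported quantification type \"", qt, "\"; supported: ",
         paste(SUPPORTED_QUANT_TYPES, collapse = ", "), call. = FALSE)
  meta[["QuantType"]] <- NULL

  # --- well metadata block: lines keyed in column 1 until the peptide header
  headerIdx <- which(vapply(lines, function(l) splitLine(l)[1] == "ID",
                            logical(1)))[1]
  if (is.na(headerIdx))
    stop("malformed header: no peptide header line starting with \"ID\"",
         call. = FALSE)
  wellMeta <- list()
  for (i in seq(2L, headerIdx - 1L)) {
    f <- splitLine(lines[i])
    wellMeta[[f[1]]] <- f[-seq_len(5L)]
  }
  for (key in c("Barcode", "Well", "SampleName"))
    if (is.null(wellMeta[[key]]))
      stop("malformed header: missing well metadata line \"", key, "\"",
           call. = FALSE)
  nWells <- length(wellMeta$Barcode)
  if (any(vapply(wellMeta, length, 0L) != nWells))
    stop("malformed header: well metadata lines differ in width",
         call. = FALSE)

  header <- splitLine(lines[headerIdx])
  if (length(header) != 5L + nWells)
    stop("parse error at line ", headerIdx, ": header has ",
         length(header), " fields, expected ", 5L + nWells, call. = FALSE)
  fixedCols <- c("ID", "UniprotAccession", "Sequence", "Cycle",
                 "ExposureTime")
  if (!identical(header[1:5], fixedCols))
    stop("malformed header: fixed columns must be ",
         paste(fixedCols, collapse = ", "), call. = FALSE)

  sampleId <- wellMeta$SampleName
  if (anyDuplicated(sampleId))
    sampleId <- paste(wellMeta$Barcode, wellMeta$Well, sep = "_")
  samples <- data.frame(
    sampleId = sampleId,
    sampleName = wellMeta$SampleName,
    barcode = wellMeta$Barcode,
    well = wellMeta$Well,
    group = if (is.null(wellMeta$Group)) NA_character_ else wellMeta$Group,
    stringsAsFactors = FALSE)

  # --- peptide data rows
  dataLines <- lines[seq(headerIdx + 1L, length(lines))]
  fields <- strsplit(dataLines, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) != 5L + nWells)
  if (length(bad))
    stop("parse error at line ", headerIdx + bad[1], ": row has ",
         lengths(fields)[bad[1]], " fields, expected ", 5L + nWells,
         call. = FALSE)
  m <- matrix(unlist(fields), ncol = 5L + nWells, byrow = TRUE)

  parseNum <- function(x, what, col) {
    if (decimal != ".") x <- gsub(decimal, ".", x, fixed = TRUE)
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop("parse error at line ",
           headerIdx + which(is.na(v))[1], ": non-numeric ", what,
           " \"", x[which(is.na(v))[1]], "\"", call. = FALSE)
    v
  }
  cycle <- parseNum(m[, 4], "cycle")
  expo  <- parseNum(m[, 5], "exposure time")

  pepRows <- !duplicated(m[, 1])
  peptides <- data.frame(
    peptideId = m[pepRows, 1], sequence = m[pepRows, 3],
    uniprotAcc = m[pepRows, 2],
    isReference = FALSE, stringsAsFactors = FALSE)

  nr <- nrow(m)
  records <- data.frame(
    sampleId = rep(samples$sampleId, each = nr),
    peptideId = rep(m[, 1], times = nWells),
    cycle = rep(as.integer(cycle), times = nWells),
    exposureTime = rep(expo, times = nWells),
    signal = parseNum(as.vector(m[, -seq_len(5L)]), "signal"),
    stringsAsFactors = FALSE)

  peptides$isReference <- isReferencePeptide(peptides$peptideId)
  new("KinomeSignal", records = records, samples = samples,
      peptides = peptides, quantType = qt, sourceMeta = meta,
      qc = list())
}

#' Write a KinomeSignal back to crosstab text
#'
#' Inverse of [readCrosstab()]; numbers are written with enough digits to
#' round-trip doubles exactly. Mainly used by the synthetic-data generator
#' and the round-trip tests.
#'
#' @param ds a [KinomeSignal].
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeCrosstab <- function(ds, path, delimiter = "\t") {
  rec <- ds@records
  sam <- ds@samples
  meta <- c(list(QuantType = ds@quantType), ds@sourceMeta)
  num <- function(x) {
    out <- sprintf("%.17g", x)
    whole <- x == floor(x) & abs(x) < 1e15
    out[whole] <- sprintf("%.0f", x[whole])
    out
  }
  lines <- paste(paste0(names(meta), "=", unlist(meta)),
                 collapse = delimiter)
  pad <- function(key, values)
    paste(c(key, rep("", 4L), values), collapse = delimiter)
  lines <- c(lines,
             pad("Barcode", sam$barcode),
             pad("Well", sam$well),
             pad("SampleName", sam$sampleName))
  if (all(!is.na(sam$group))) lines <- c(lines, pad("Group", sam$group))
  lines <- c(lines, paste(c("ID", "UniprotAccession", "Sequence", "Cycle",
                            "ExposureTime", sam$sampleId),
                          collapse = delimiter))

  pep <- ds@peptides
  grid <- unique(rec[, c("peptideId", "cycle", "exposureTime")])
  grid <- grid[order(match(grid$peptideId, pep$peptideId), grid$cycle,
                     grid$exposureTime), ]
  key <- function(s, p, c, e) paste(s, p, c, e, sep = "\r")
  sigIdx <- stats::setNames(seq_len(nrow(rec)),
                            key(rec$sampleId, rec$peptideId, rec$cycle,
                                rec$exposureTime))
  rowsOf <- function(sid)
    rec$signal[sigIdx[key(sid, grid$peptideId, grid$cycle,
                          grid$exposureTime)]]
  sigMat <- vapply(sam$sampleId, rowsOf, numeric(nrow(grid)))
  if (anyNA(sigMat))
    stop("cannot write crosstab: the (peptide, cycle, exposure) grid is ",
         "not identical across wells", call. = FALSE)
  ann <- pep[match(grid$peptideId, pep$peptideId), ]
  body <- cbind(grid$peptideId, ann$uniprotAcc, ann$sequence,
                as.character(grid$cycle), num(grid$exposureTime),
                matrix(num(sigMat), nrow = nrow(grid)))
  lines <- c(lines, apply(body, 1L, paste, collapse = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Assign experimental groups to samples
#'
#' @param ds a [KinomeSignal].
#' @param mapping either a named character vector / two-column data.frame
#'   (`sampleId`, `group`) assigning one label per sample, or the name of an
#'   existing sample-metadata column to use verbatim.
#' @return the dataset with the `group` field populated.
#' @export
assignGroups <- function(ds, mapping) {
  sam <- ds@samples
  if (is.character(mapping) && length(mapping) == 1L &&
      is.null(names(mapping))) {
    if (!mapping %in% names(sam))
      stop("no sample-metadata column named \"", mapping, "\"",
           call. = FALSE)
    sam$group <- as.character(sam[[mapping]])
  } else {
    if (is.data.frame(mapping)) {
      if (!all(c("sampleId", "group") %in% names(mapping)))
        stop("mapping data.frame needs columns sampleId, group",
             call. = FALSE)
      mapping <- stats::setNames(as.character(mapping$group),
                                 mapping$sampleId)
    }
    missing <- setdiff(sam$sampleId, names(mapping))
    if (length(missing))
      stop("samples without a group label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    sam$group <- unname(mapping[sam$sampleId])
  }
  if (anyNA(sam$group) || any(!nzchar(sam$group)))
    stop("group labels must be non-empty", call. = FALSE)
  ds@samples <- sam
  validObject(ds)
  ds
}

#' Extract the end-point (last pump cycle) data
#'
#' Keeps only records at the maximal cycle; with `maxExposureOnly = TRUE`
#' additionally only the maximal camera exposure time, giving one signal per
#' (peptide, well). The kinetic model uses the full exposure series of the
#' last cycle; the low-signal filter uses the max-exposure end point.
#'
#' @param ds a [KinomeSignal].
#' @param maxExposureOnly keep only the longest exposure as well.
#' @return the restricted dataset. Idempotent.
#' @export
extractEndpoint <- function(ds, maxExposureOnly = FALSE) {
  stopIfEmpty(ds, "input (cannot extract end point)")
  rec <- ds@records
  rec <- rec[rec$cycle == max(rec$cycle), , drop = FALSE]
  if (maxExposureOnly)
    rec <- rec[rec$exposureTime == max(rec$exposureTime), , drop = FALSE]
  rownames(rec) <- NULL
  ds@records <- rec
  ds
}

#' Export the canonical long-form signal table
#'
#' @param ds a [KinomeSignal].
#' @param path output file (tab-delimited).
#' @return the long-form data.frame, invisibly if written to `path`.
#' @export
exportLongForm <- function(ds, path = NULL) {
  rec <- ds@records
  sam <- ds@samples
  i <- match(rec$sampleId, sam$sampleId)
  out <- data.frame(sample_id = rec$sampleId, barcode = sam$barcode[i],
                    well = sam$well[i], group = sam$group[i],
                    peptide_id = rec$peptideId, cycle = rec$cycle,
                    exposure_time = rec$exposureTime, signal = rec$signal,
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  writeTable(out, path)
  invisible(out)
}
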