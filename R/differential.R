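#' Per-peptide log2 fold change between two groups
#'
#' Computes the differential phosphorylation of every peptide as the log2
#' fold change (LFC) of the chip-normalized final signal, comparison minus
#' baseline. Two modes:
#' \describe{
#'   \item{across_chip}{mean over all comparison wells minus mean over all
#'     baseline wells, pooling chips.}
#'   \item{within_chip}{the group-mean difference inside each chip,
#'     averaged over chips; preferred when every chip carries both groups,
#'     since chip effects cancel exactly.}
#' }
#'
#' @param model a [KinomeModel] with groups assigned.
#' @param baseline,comparison group labels; positive LFC means higher
#'   phosphorylation in `comparison`.
#' @param mode "within_chip" or "across_chip".
#' @return a [KinomeDiff]. Antisymmetric: swapping the two labels negates
#'   every LFC.
#' @export
computeLFC <- function(model, baseline, comparison,
                       mode = c("within_chip", "across_chip")) {
  mode <- match.arg(mode)
  fits <- model@normalized
  groups <- unique(fits$group)
  if (baseline == comparison)
    stop("baseline and comparison groups must differ", call. = FALSE)
  for (g in c(baseline, comparison))
    if (!g %in% groups)
      stop("group \"", g, "\" not present in the model", call. = FALSE)
  fits <- fits[fits$group %in% c(baseline, comparison), , drop = FALSE]
  peps <- sort(unique(fits$peptideId))

  meanBy <- function(d) {
    m <- tapply(d$signal, list(d$peptideId, d$group), mean)
    m[peps, c(baseline, comparison), drop = FALSE]
  }

  if (mode == "across_chip") {
    m <- meanBy(fits)
    if (anyNA(m))
      stop("a peptide is missing signals in one of the groups",
           call. = FALSE)
    tab <- data.frame(peptideId = peps,
                      lfc = unname(m[, comparison] - m[, baseline]),
                      stringsAsFactors = FALSE)
  } else {
    chips <- sort(unique(fits$barcode))
    perChip <- lapply(chips, function(bc) {
      d <- fits[fits$barcode == bc, , drop = FALSE]
      if (!all(c(baseline, comparison) %in% d$group))
        stop("within-chip analysis: chip ", bc,
             " does not contain both groups", call. = FALSE)
      m <- meanBy(d)
      m[, comparison] - m[, baseline]
    })
    mat <- do.call(cbind, perChip)
    colnames(mat) <- chips
    if (anyNA(mat))
      stop("a peptide is missing signals on some chip", call. = FALSE)
    tab <- data.frame(peptideId = peps, lfc = unname(rowMeans(mat)),
                      stringsAsFactors = FALSE)
    per <- as.data.frame(mat)
    names(per) <- paste0("lfc.", chips)
    tab <- cbind(tab, per)
  }
  rownames(tab) <- NULL
  new("KinomeDiff", table = tab, mode = mode, baseline = baseline,
      comparison = comparison)
}

#' Extract cutoff-thresholded differential peptide sets
#'
#' One [PeptideSet] per LFC cutoff. Membership is two-sided by default
#' (`|lfc| >= cutoff`, boundary inclusive); sets are nested, a larger
#' cutoff always yielding a subset of a smaller one. Using several cutoffs
#' and averaging the downstream kinase Z scores removes the arbitrariness
#' of any single threshold.
#'
#' @param diff a [KinomeDiff].
#' @param cutoffs positive log2 thresholds (default `c(0.2, 0.3, 0.4)`).
#' @param direction "both" (default), "up" (lfc >= cutoff) or "down"
#'   (lfc <= -cutoff).
#' @return named list of [PeptideSet] objects (names = cutoff values).
#' @export
peptideSets <- function(diff, cutoffs = c(0.2, 0.3, 0.4),
                        direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(cutoffs), all(cutoffs >= 0))
  tab <- diff@table
  sets <- lapply(cutoffs, function(ct) {
    sel <- switch(direction,
                  both = abs(tab$lfc) >= ct,
                  up   = tab$lfc >= ct,
                  down = tab$lfc <= -ct)
    ids <- tab$peptideId[sel]
    if (length(ids) == 0L)
      warning("no peptides pass cutoff ", ct, call. = FALSE)
    new("PeptideSet", cutoff = ct, peptides = ids, direction = direction)
  })
  names(sets) <- as.character(cutoffs)
  sets
}

#' Export a differential table
#'
#' @param diff a [KinomeDiff].
#' @param path output file (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeDiff <- function(diff, path) {
  tab <- diff@table
  tab$mode <- diff@mode
  tab$baseline <- diff@baseline
  tab$comparison <- diff@comparison
  writeTable(tab, path)
}
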