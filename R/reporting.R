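#' Heatmap matrix with optional scaling and clustering orders
#'
#' Builds the peptide x sample matrix of chip-normalized final signals,
#' optionally standardized per row (peptide) or per column (sample), with
#' row/column orders from agglomerative hierarchical clustering on
#' Euclidean distance. Zero-variance rows under row scaling are imputed as
#' zeros and flagged.
#'
#' @param model a [KinomeModel].
#' @param scale "row", "column" or "none".
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   "complete").
#' @return list: `matrix` (scaled), `rowOrder`, `colOrder`,
#'   `flaggedRows` (zero-variance peptides).
#' @export
heatmapMatrix <- function(model, scale = c("row", "column", "none"),
                          linkage = "complete") {
  scale <- match.arg(scale)
  fits <- model@normalized
  peps <- sort(unique(fits$peptideId))
  sams <- sort(unique(fits$sampleId))
  if (length(peps) < 2L || length(sams) < 2L)
    stop("heatmap needs at least 2 peptides and 2 samples", call. = FALSE)
  m <- matrix(NA_real_, length(peps), length(sams),
              dimnames = list(peps, sams))
  m[cbind(match(fits$peptideId, peps), match(fits$sampleId, sams))] <-
    fits$signal

  flagged <- character()
  std <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  if (scale == "row") {
    flagged <- rownames(m)[apply(m, 1L, stats::sd) == 0]
    m <- t(apply(m, 1L, std))
    colnames(m) <- sams
  } else if (scale == "column") {
    m <- apply(m, 2L, std)
    rownames(m) <- peps
  }
  rowOrder <- stats::hclust(stats::dist(m), method = linkage)$order
  colOrder <- stats::hclust(stats::dist(t(m)), method = linkage)$order
  list(matrix = m, rowOrder = rowOrder, colOrder = colOrder,
       flaggedRows = flagged)
}

#' Global group comparison of per-peptide signal distributions
#'
#' Compares the per-peptide group-mean signal vectors of two groups with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test -- the global-signature
#' test shown alongside grouped violin plots. With more than 20 values per
#' group the normal approximation with tie correction is used; otherwise
#' the exact distribution.
#'
#' @param model a [KinomeModel] with grouped signals.
#' @param groupA,groupB group labels.
#' @return list: `statistic` (rank-sum W), `p.value`, `n` per group.
#' @export
globalGroupTest <- function(model, groupA, groupB) {
  g <- model@grouped
  a <- g$signal[g$group == groupA]
  b <- g$signal[g$group == groupB]
  if (!length(a) || !length(b))
    stop("both groups must be present in the grouped model", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    warning("all signals tied; p = 1", call. = FALSE)
    return(list(statistic = length(a) * length(b) / 2, p.value = 1,
                n = c(length(a), length(b))))
  }
  exact <- max(length(a), length(b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = c(length(a), length(b)))
}

#' Coefficient of variation per peptide and group
#'
#' CV = sample SD / mean of the linear-scale signal (2^log2-signal, i.e.
#' 100*slope after clamping) across the wells of each group; an outlier
#' well inflates the CVs of its group. CV is computed on the linear scale
#' because the CV of log values is not scale-free.
#'
#' @param fits per-well fit table from [modelFits()].
#' @return data.frame `peptideId`, `group`, `cv`, `n`; `cv` is NA
#'   (flagged) where the group mean is 0.
#' @export
cvByGroup <- function(fits) {
  if (anyNA(fits$group))
    stop("groups must be assigned before the CV plot", call. = FALSE)
  lin <- 2^fits$signal
  agg <- stats::aggregate(lin,
                          by = list(peptideId = fits$peptideId,
                                    group = fits$group),
                          FUN = function(v)
                            c(cv = if (mean(v) == 0) NA_real_
                                   else stats::sd(v) / mean(v),
                              n = length(v)))
  out <- data.frame(peptideId = agg$peptideId, group = agg$group,
                    cv = agg$x[, "cv"], n = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$peptideId, out$group), ]
}

#' Waterfall data: peptides ordered by log2 fold change
#'
#' @param diff a [KinomeDiff].
#' @param cutoffs cutoff annotations to carry along (drawn as dashed
#'   +/- lines).
#' @return list: `table` (peptides sorted by LFC, ties keeping input
#'   order) and `cutoffs`.
#' @export
waterfallData <- function(diff, cutoffs = c(0.2, 0.3, 0.4)) {
  tab <- diff@table
  tab <- tab[order(tab$lfc), , drop = FALSE]   # stable sort: ties keep order
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, cutoffs = sort(cutoffs))
}

#' Fitted-curve data for selected peptides
#'
#' Raw end-point signal points plus the stored per-well linear fit, for
#' plotting signal-versus-exposure curves coloured by group.
#'
#' @param ds the end-point [KinomeSignal] the model was fitted on.
#' @param fits per-well fit table.
#' @param peptides peptide IDs to plot.
#' @return list: `points` (raw records with group) and `lines` (one row
#'   per (peptide, well) with slope/intercept/group).
#' @export
curvePlotData <- function(ds, fits, peptides) {
  unknown <- setdiff(peptides, unique(fits$peptideId))
  if (length(unknown))
    stop("unknown peptide(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ep <- extractEndpoint(ds)
  rec <- ep@records[ep@records$peptideId %in% peptides, , drop = FALSE]
  sam <- ds@samples
  rec$group <- sam$group[match(rec$sampleId, sam$sampleId)]
  rownames(rec) <- NULL
  lines <- fits[fits$peptideId %in% peptides,
                c("peptideId", "sampleId", "group", "slope", "intercept")]
  rownames(lines) <- NULL
  list(points = rec, lines = lines)
}

#' Sampling-distribution histogram data for one kinase
#'
#' Bins the per-iteration null counts of one kinase at one cutoff, with
#' the observed count as a marker and the mean +/- 2 SD band -- the
#' per-kinase sampling histogram.
#'
#' @param scores a [KinaseScores] computed with `returnDraws = TRUE`.
#' @param kinase kinase family name.
#' @param cutoff which cutoff set (default: first).
#' @return list: `breaks`, `counts` (summing to the iteration count),
#'   `observed`, `mean`, `band` (mean -/+ 2 SD).
#' @export
samplingHistogramData <- function(scores, kinase, cutoff = NULL) {
  if (length(scores@draws) == 0L)
    stop("null draws were not retained; re-run scoreKinases(..., ",
         "returnDraws = TRUE)", call. = FALSE)
  if (is.null(cutoff)) cutoff <- names(scores@draws)[1]
  draws <- scores@draws[[as.character(cutoff)]]
  if (is.null(draws))
    stop("no draws for cutoff ", cutoff, call. = FALSE)
  if (!kinase %in% rownames(draws))
    stop("unknown kinase ", kinase, call. = FALSE)
  v <- draws[kinase, ]
  s <- scores@scores
  row <- s[s$kinase == kinase & s$cutoff == as.numeric(cutoff), ]
  breaks <- seq(min(v) - 0.5, max(v) + 0.5, by = 1)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, observed = row$observed,
       mean = row$samplingAvg,
       band = c(row$samplingAvg - 2 * row$sd, row$samplingAvg + 2 * row$sd))
}

#' Z-score waterfall data across cutoff sets
#'
#' Per-kinase Z scores for each cutoff set plus the averaged score (drawn
#' as the larger dot), ordered by averaged Z.
#'
#' @param scores a [KinaseScores].
#' @return list: `points` (kinase, cutoff, z) and `averaged` (kinase,
#'   meanZ), both ordered by `meanZ`.
#' @export
zWaterfallData <- function(scores) {
  avg <- scores@averaged[order(scores@averaged$meanZ), ]
  pts <- scores@scores[, c("kinase", "cutoff", "z")]
  pts <- pts[order(match(pts$kinase, avg$kinase)), ]
  rownames(avg) <- rownames(pts) <- NULL
  list(points = pts, averaged = avg)
}

#' PCA embedding of samples
#'
#' Principal component analysis of the samples x peptides matrix of
#' chip-normalized final signals (centered, unscaled), for checking how
#' samples cluster, e.g. by group or chip.
#'
#' @param model a [KinomeModel].
#' @param nComponents number of components to return scores for.
#' @return list: `scores` (samples x PCs, with group/barcode columns) and
#'   `explained` (variance fractions, summing to <= 1).
#' @export
pcaEmbed <- function(model, nComponents = 2L) {
  fits <- model@normalized
  sams <- sort(unique(fits$sampleId))
  if (length(sams) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  peps <- sort(unique(fits$peptideId))
  m <- matrix(NA_real_, length(sams), length(peps),
              dimnames = list(sams, peps))
  m[cbind(match(fits$sampleId, sams), match(fits$peptideId, peps))] <-
    fits$signal
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  info <- unique(fits[, c("sampleId", "group", "barcode")])
  sc <- data.frame(sampleId = rownames(pc$x), pc$x[, seq_len(k),
                                                   drop = FALSE],
                   stringsAsFactors = FALSE)
  sc$group <- info$group[match(sc$sampleId, info$sampleId)]
  sc$barcode <- info$barcode[match(sc$sampleId, info$sampleId)]
  rownames(sc) <- NULL
  list(scores = sc, explained = explained[seq_len(k)])
}

#' Pearson correlation of averaged kinase Z scores between two analyses
#'
#' Pairs the kinase families shared by two averaged score tables (e.g. two
#' cohorts) and returns their Pearson correlation -- the cross-study
#' concordance check for upstream kinase signatures.
#'
#' @param avgA,avgB [KinaseScores] objects or averaged score data.frames
#'   (`kinase`, `meanZ`).
#' @return list: `r`, `p.value`, `n`, and the paired `table`.
#' @export
cohortZCorrelation <- function(avgA, avgB) {
  a <- if (is(avgA, "KinaseScores")) avgA@averaged else avgA
  b <- if (is(avgB, "KinaseScores")) avgB@averaged else avgB
  shared <- intersect(a$kinase, b$kinase)
  if (length(shared) < 3L)
    stop("need at least 3 shared kinases (found ", length(shared), ")",
         call. = FALSE)
  tab <- data.frame(kinase = shared,
                    zA = a$meanZ[match(shared, a$kinase)],
                    zB = b$meanZ[match(shared, b$kinase)],
                    stringsAsFactors = FALSE)
  tab <- tab[stats::complete.cases(tab), ]
  ct <- stats::cor.test(tab$zA, tab$zB, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(tab),
       table = tab)
}
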