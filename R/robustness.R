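#' Inject noise into a differential table at a controlled SNR
#'
#' Perturbs the per-peptide log2 fold changes with additive zero-mean
#' Gaussian noise whose variance is `var(lfc) / snr`, so the
#' signal-to-noise ratio of the between-group differences is exactly the
#' requested value in expectation. Used by the robustness protocol to ask
#' how stable the downstream kinase Z scores are as the group signal is
#' progressively drowned.
#'
#' @param diff a [KinomeDiff] with a non-constant LFC vector.
#' @param snr signal-to-noise ratio (> 0); variance of the LFC vector over
#'   the injected noise variance.
#' @param seed optional seed; seeded runs are bit-reproducible, `NULL`
#'   leaves the RNG stream untouched (unseeded mode).
#' @param distribution "gaussian" (default) or "uniform" (matched
#'   variance).
#' @return a [KinomeDiff] with perturbed LFCs (per-chip columns dropped).
#' @export
injectNoise <- function(diff, snr, seed = NULL,
                        distribution = c("gaussian", "uniform")) {
  distribution <- match.arg(distribution)
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  lfc <- diff@table$lfc
  v <- stats::var(lfc)
  if (!is.finite(v) || v == 0)
    stop("LFC vector has zero variance; SNR undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sdNoise <- sqrt(v / snr)
  noise <- switch(distribution,
                  gaussian = stats::rnorm(length(lfc), 0, sdNoise),
                  uniform = stats::runif(length(lfc),
                                         -sdNoise * sqrt(3),
                                         sdNoise * sqrt(3)))
  tab <- data.frame(peptideId = diff@table$peptideId, lfc = lfc + noise,
                    stringsAsFactors = FALSE)
  new("KinomeDiff", table = tab, mode = diff@mode,
      baseline = diff@baseline, comparison = diff@comparison)
}

#' Signal-to-noise robustness curve of the kinase Z scores
#'
#' For each SNR in the grid (and each replicate), injects noise into the
#' differential table, re-runs the cutoff-set extraction and the
#' random-sampling kinase scoring, and correlates (Pearson) the averaged
#' kinase Z vector against the noiseless reference run. Correlations
#' approach 1 as SNR grows; the median over replicates is expected to be
#' non-decreasing in SNR.
#'
#' @param diff the reference [KinomeDiff] (noiseless).
#' @param mapping a [KinaseMapping].
#' @param snrGrid SNR values (default `c(1, 2, 4, 8, 16, 32)`).
#' @param cutoffs LFC cutoffs for the peptide sets.
#' @param iterations,seed passed to [scoreKinases()]; per-(SNR, replicate)
#'   noise seeds are derived from `seed`, so the curve is reproducible.
#'   `seed = NULL` gives unseeded noise.
#' @param replicates noise replicates per SNR (default 1).
#' @param workers parallelism degree for the scoring step.
#' @return data.frame `snr`, `replicate`, `r` (Pearson correlation vs the
#'   reference), `nKinases`.
#' @export
robustnessCurve <- function(diff, mapping, snrGrid = c(1, 2, 4, 8, 16, 32),
                            cutoffs = c(0.2, 0.3, 0.4),
                            iterations = 2000L, seed = 123L,
                            replicates = 1L, workers = 1L) {
  refSets <- peptideSets(diff, cutoffs)
  ref <- scoreKinases(mapping, refSets, iterations = iterations,
                      seed = seed %||% 123L, workers = workers)
  refZ <- ref@averaged

  rows <- list()
  for (si in seq_along(snrGrid)) {
    for (rep in seq_len(replicates)) {
      noiseSeed <- if (is.null(seed)) NULL
                   else deriveSeed(seed, si * 1000L + rep)
      noisy <- injectNoise(diff, snr = snrGrid[si], seed = noiseSeed)
      sets <- suppressWarnings(peptideSets(noisy, cutoffs))
      sc <- scoreKinases(mapping, sets, iterations = iterations,
                         seed = seed %||% 123L, workers = workers)
      cz <- cohortZCorrelation(refZ, sc@averaged)
      rows[[length(rows) + 1L]] <-
        data.frame(snr = snrGrid[si], replicate = rep, r = cz$r,
                   nKinases = cz$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
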