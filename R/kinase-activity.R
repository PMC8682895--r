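#' Load a peptide-to-kinase-family mapping
#'
#' Reads (or accepts) a long-format two-column table mapping reporter
#' peptides to the upstream kinase families predicted to phosphorylate
#' them, and restricts it to a peptide pool -- the QC-passing,
#' non-reference panel the differential sets were drawn from. The sampling
#' null must draw from the same pool the observed set came from, so
#' entries for peptides outside the pool are dropped (with a warning
#' count); pool peptides without any annotated family stay in the pool
#' with an empty family set.
#'
#' @param mapping path to a delimited file (header required; first two
#'   columns peptide ID, kinase family; tab or comma) or an equivalent
#'   data.frame.
#' @param pool character vector of pool peptide IDs.
#' @return a [KinaseMapping].
#' @export
loadMapping <- function(mapping, pool) {
  if (is.character(mapping) && length(mapping) == 1L) {
    first <- readLines(mapping, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    mapping <- utils::read.table(mapping, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE)
  }
  if (!is.data.frame(mapping) || ncol(mapping) < 2L || nrow(mapping) == 0L)
    stop("mapping must be a non-empty two-column (peptide, kinase) table",
         call. = FALSE)
  ent <- data.frame(peptideId = trimws(as.character(mapping[[1]])),
                    kinase = trimws(as.character(mapping[[2]])),
                    stringsAsFactors = FALSE)
  pool0 <- as.character(pool)
  pool <- trimws(pool0)
  if (anyDuplicated(pool))
    stop("pool peptide IDs collide after whitespace normalization",
         call. = FALSE)
  outside <- !(ent$peptideId %in% pool)
  if (any(outside))
    warning(sum(outside), " mapping entries refer to peptides outside ",
            "the pool and were dropped", call. = FALSE)
  ent <- unique(ent[!outside, , drop = FALSE])
  rownames(ent) <- NULL
  new("KinaseMapping", entries = ent, pool = pool,
      kinases = sort(unique(ent$kinase)))
}

# kinase x pool logical membership matrix
membershipMatrix <- function(mapping) {
  M <- matrix(FALSE, nrow = length(mapping@kinases),
              ncol = length(mapping@pool),
              dimnames = list(mapping@kinases, mapping@pool))
  if (nrow(mapping@entries))
    M[cbind(match(mapping@entries$kinase, mapping@kinases),
            match(mapping@entries$peptideId, mapping@pool))] <- TRUE
  M
}

#' Observed mapped-peptide counts per kinase family
#'
#' For each kinase family, the number of peptides of the given set that the
#' family is mapped to. A peptide mapped to m families contributes 1 to
#' each of them, so summing counts over kinases conserves the total mapping
#' multiplicity of the set.
#'
#' @param mapping a [KinaseMapping].
#' @param peptides a [PeptideSet] or character vector of peptide IDs; must
#'   be a subset of the pool.
#' @return named integer vector over all kinase families.
#' @export
observedCounts <- function(mapping, peptides) {
  if (is(peptides, "PeptideSet")) peptides <- peptides@peptides
  if (!all(peptides %in% mapping@pool))
    stop("peptide set contains IDs outside the mapping pool: ",
         paste(utils::head(setdiff(peptides, mapping@pool), 3),
               collapse = ", "), call. = FALSE)
  ent <- mapping@entries
  hit <- ent$kinase[ent$peptideId %in% peptides]
  tab <- table(factor(hit, levels = mapping@kinases))
  stats::setNames(as.integer(tab), mapping@kinases)
}

#' Random-sampling null distribution of mapped-peptide counts
#'
#' Draws `iterations` random peptide sets of size `setSize` uniformly
#' without replacement from the pool and tallies, for each kinase family,
#' the mapped-peptide count of every draw. The per-kinase mean and sample
#' standard deviation (B-1 denominator) over iterations form the null
#' against which the observed count is standardized. For a family mapped
#' to k of N pool peptides the draw count is hypergeometric with mean
#' n*k/N, which the empirical mean approaches as iterations grow.
#'
#' @param mapping a [KinaseMapping].
#' @param setSize n, the differential-set size (0 < n <= pool size).
#' @param iterations B, number of random draws (>= 2; default 2000).
#' @param seed RNG seed; the same seed reproduces the draws bit-exactly.
#' @param returnDraws keep the kinases x iterations count matrix
#'   (attribute `"draws"`), needed for sampling histograms.
#' @return data.frame `kinase`, `samplingAvg`, `sd`; optionally with the
#'   draw matrix attached.
#' @export
sampleNullCounts <- function(mapping, setSize, iterations = 2000L, seed,
                             returnDraws = FALSE) {
  N <- length(mapping@pool)
  if (setSize > N)
    stop("set size (", setSize, ") exceeds the pool size (", N, ")",
         call. = FALSE)
  stopifnot(setSize > 0, iterations >= 2)
  M <- membershipMatrix(mapping)
  storage.mode(M) <- "double"
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  draws <- matrix(0, nrow = N, ncol = iterations)
  for (b in seq_len(iterations))
    draws[sample.int(N, setSize), b] <- 1
  counts <- M %*% draws                       # kinases x iterations
  mu <- rowMeans(counts)
  sdv <- apply(counts, 1L, stats::sd)
  out <- data.frame(kinase = mapping@kinases, samplingAvg = unname(mu),
                    sd = unname(sdv), stringsAsFactors = FALSE)
  if (returnDraws) attr(out, "draws") <- counts
  out
}

#' Kinase Z score
#'
#' Standardizes the observed mapped-peptide count against the sampling
#' null: Z = (observed - samplingAvg) / SD, i.e. how many null standard
#' deviations the observation lies from the null mean. Undefined (NA) when
#' the SD is zero; such kinases are excluded from hit calling.
#'
#' @param observed observed mapped-peptide count(s).
#' @param mu sampling mean(s).
#' @param sigma sampling standard deviation(s) (>= 0).
#' @return numeric Z score(s); NA where `sigma` is 0, with a warning.
#' @examples
#' kinaseZ(11, 19.19, 2.75)   # -2.98
#' kinaseZ(3, 1.16, 0.84)     #  2.19
#' @export
kinaseZ <- function(observed, mu, sigma) {
  if (any(sigma < 0, na.rm = TRUE))
    stop("sampling SD must be non-negative", call. = FALSE)
  z <- (observed - mu) / sigma
  zero <- !is.na(sigma) & sigma == 0
  if (any(zero)) {
    warning(sum(zero), " kinase(s) with zero sampling SD: Z undefined",
            call. = FALSE)
    z[zero] <- NA_real_
  }
  z
}

#' Score upstream kinase families by random sampling
#'
#' The core analysis: for every differential peptide set (one per LFC
#' cutoff) the observed per-kinase mapped-peptide counts are standardized
#' against the random-sampling null of [sampleNullCounts()], and the
#' per-cutoff Z scores are averaged (unweighted arithmetic mean) into the
#' final score of each kinase family.
#'
#' Each cutoff set gets its own RNG stream derived deterministically from
#' the master seed, so results are a pure function of (inputs, seed) and
#' identical whether sets are processed serially or in parallel.
#'
#' @param mapping a [KinaseMapping].
#' @param sets list of [PeptideSet] objects (from [peptideSets()]) or of
#'   character vectors.
#' @param iterations random draws per set (default 2000).
#' @param seed master seed (default 123).
#' @param workers parallelism degree; values > 1 use
#'   [parallel::mclapply()] where available. Affects wall-clock only.
#' @param returnDraws keep per-iteration counts for histogram plots.
#' @return a [KinaseScores].
#' @export
scoreKinases <- function(mapping, sets, iterations = 2000L, seed = 123L,
                         workers = 1L, returnDraws = FALSE) {
  if (length(sets) == 0L) stop("no peptide sets supplied", call. = FALSE)
  seed <- as.integer(seed)
  setNames0 <- names(sets) %||% rep(NA_character_, length(sets))
  cutoffs <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is(s, "PeptideSet")) s@cutoff
    else suppressWarnings(as.numeric(setNames0[i]))
  }, numeric(1))
  cutoffs[is.na(cutoffs)] <- seq_along(sets)[is.na(cutoffs)]

  scoreOne <- function(i) {
    s <- sets[[i]]
    ids <- if (is(s, "PeptideSet")) s@peptides else as.character(s)
    obs <- observedCounts(mapping, ids)
    null <- sampleNullCounts(mapping, setSize = length(ids),
                             iterations = iterations,
                             seed = deriveSeed(seed, i),
                             returnDraws = returnDraws)
    df <- data.frame(kinase = null$kinase, cutoff = cutoffs[i],
                     setSize = length(ids),
                     observed = unname(obs[null$kinase]),
                     samplingAvg = null$samplingAvg, sd = null$sd,
                     stringsAsFactors = FALSE)
    df$z <- suppressWarnings(kinaseZ(df$observed, df$samplingAvg, df$sd))
    list(scores = df, draws = attr(null, "draws"))
  }

  workers <- max(1L, as.integer(workers))
  res <- if (workers > 1L &&
             requireNamespace("parallel", quietly = TRUE) &&
             .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(sets), scoreOne, mc.cores = workers)
  } else {
    lapply(seq_along(sets), scoreOne)
  }

  scores <- do.call(rbind, lapply(res, `[[`, "scores"))
  rownames(scores) <- NULL
  kin <- mapping@kinases
  zmat <- vapply(res, function(r)
    r$scores$z[match(kin, r$scores$kinase)], numeric(length(kin)))
  zmat <- matrix(zmat, nrow = length(kin))
  averaged <- data.frame(
    kinase = kin, meanZ = rowMeans(zmat),
    nCutoffs = ncol(zmat), stringsAsFactors = FALSE)
  rownames(averaged) <- NULL
  draws <- if (returnDraws) {
    d <- lapply(res, `[[`, "draws")
    names(d) <- as.character(cutoffs)
    d
  } else list()
  new("KinaseScores", scores = scores, averaged = averaged,
      iterations = as.integer(iterations), seed = seed, draws = draws)
}

#' Select kinase hits from averaged Z scores
#'
#' A kinase family is a hit when the absolute value of its cutoff-averaged
#' Z score reaches the threshold (boundary inclusive; default 2, i.e. two
#' null standard deviations). The sign labels the family over- or
#' under-represented among differentially phosphorylated peptides.
#' Kinases with undefined Z (zero sampling SD) are never called.
#'
#' @param scores a [KinaseScores] or its `averagedScores()` data.frame.
#' @param zThreshold absolute mean-Z threshold (default 2).
#' @return data.frame `kinase`, `meanZ`, `direction`
#'   ("overrepresented"/"underrepresented"), ordered by |meanZ|.
#' @export
selectHits <- function(scores, zThreshold = 2) {
  avg <- if (is(scores, "KinaseScores")) scores@averaged else scores
  sel <- !is.na(avg$meanZ) & abs(avg$meanZ) >= zThreshold
  hits <- avg[sel, c("kinase", "meanZ")]
  hits$direction <- ifelse(hits$meanZ >= 0, "overrepresented",
                           "underrepresented")
  hits <- hits[order(-abs(hits$meanZ)), ]
  rownames(hits) <- NULL
  hits
}

#' Export kinase score tables
#'
#' Writes the per-cutoff score table with the conventional column layout
#' `Kinase, Observed, SamplingAvg, SD, Z` (one file per cutoff suffix) and
#' the averaged table.
#'
#' @param scores a [KinaseScores].
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
writeScores <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- scores@scores
  paths <- character()
  for (ct in unique(s$cutoff)) {
    d <- s[s$cutoff == ct, ]
    out <- data.frame(Kinase = d$kinase, Observed = d$observed,
                      SamplingAvg = round(d$samplingAvg, 2),
                      SD = round(d$sd, 2), Z = round(d$z, 2))
    p <- file.path(dir, sprintf("kinase_scores_cutoff_%s.tsv", ct))
    writeTable(out, p)
    paths <- c(paths, p)
  }
  avg <- scores@averaged
  p <- file.path(dir, "kinase_scores_averaged.tsv")
  writeTable(data.frame(Kinase = avg$kinase, MeanZ = round(avg$meanZ, 4),
                        nCutoffs = avg$nCutoffs), p)
  invisible(c(paths, p))
}
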