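#' Simulate a PamChip crosstab run with a known-truth manifest
#'
#' Generates a complete synthetic kinome-array experiment in the crosstab
#' format [readCrosstab()] accepts, together with a manifest recording
#' every planted truth, so the whole pipeline is testable without any
#' instrument data. The emulation covers: a serine-threonine-like reporter
#' panel with reference/control peptides, a (cycle, exposure time) signal
#' grid, linear end-point kinetics with Gaussian noise, planted group
#' effects on the log2 final signal, multiplicative chip batch offsets,
#' flat undetectable peptides, step-shaped non-linear peptides, negative
#' points and saturated points.
#'
#' For each well the signal at (cycle c, exposure t) is
#' `intercept + slope * t * c/max(c) + noise`, so at the last cycle the
#' fitted exposure slope recovers the planted per-well slope. Planted
#' slopes are `2^s / 100` with `s` the target log2 final signal; group
#' effects and chip offsets act additively on `s` (multiplicatively on
#' the slope).
#'
#' @param nPeptides total reporter panel size (default 144).
#' @param nReference control peptides (`ART_*` IDs; default 11).
#' @param nUndetectable flat low-signal peptides (default 12).
#' @param nNonlinear step-shaped peptides failing the R-squared filter
#'   (default 2).
#' @param samplesPerGroup wells per group (default 3).
#' @param groups two group labels; the first is the baseline (default
#'   `c("Female", "Male")`).
#' @param nDifferential peptides with a planted group effect (default 20);
#'   ignored when `differentialPeptides` is given.
#' @param differentialPeptides explicit peptide IDs to plant the effect
#'   on (must be regular panel peptides).
#' @param lfc planted log2 fold change, comparison vs baseline (scalar or
#'   one value per differential peptide; default 0.5).
#' @param chipOffsets log2 offsets per chip, recycled over chips (default
#'   `c(0.25, -0.25)`).
#' @param cycles pump-cycle grid (default `c(32, 54, 76, 93, 124)`).
#' @param exposures exposure-time grid in ms (default
#'   `c(10, 20, 50, 100, 200)`).
#' @param baseRange range of baseline log2 final signals (default
#'   `c(4, 8)`).
#' @param noiseSd Gaussian signal noise SD in signal units (default 1).
#' @param nNegative points at the first cycle forced negative (default 10).
#' @param nSaturated end-point points forced to `saturationValue`
#'   (default 0).
#' @param saturationValue camera ceiling (default 4095).
#' @param seed RNG seed; the manifest plus seed fully determine the data.
#' @param path optional file path; when given the crosstab is written
#'   there via [writeCrosstab()].
#' @return list with `dataset` (a [KinomeSignal]), `file` (path or NULL)
#'   and `manifest` (planted truths: peptide categories, per-well slopes,
#'   true LFCs, chip offsets, counts, grids, seed).
#' @export
simulateCrosstab <- function(nPeptides = 144L, nReference = 11L,
                             nUndetectable = 12L, nNonlinear = 2L,
                             samplesPerGroup = 3L,
                             groups = c("Female", "Male"),
                             nDifferential = 20L,
                             differentialPeptides = NULL,
                             lfc = 0.5,
                             chipOffsets = c(0.25, -0.25),
                             cycles = c(32L, 54L, 76L, 93L, 124L),
                             exposures = c(10, 20, 50, 100, 200),
                             baseRange = c(4, 8), noiseSd = 1,
                             nNegative = 10L, nSaturated = 0L,
                             saturationValue = 4095, seed = 1L,
                             path = NULL) {
  stopifnot(length(groups) == 2L, samplesPerGroup >= 1L,
            nPeptides > nReference + nUndetectable + nNonlinear,
            length(cycles) >= 1L, length(exposures) >= 2L, noiseSd >= 0)
  set.seed(as.integer(seed))

  # --- peptide panel
  nRegular <- nPeptides - nReference
  pepIds <- c(sprintf("PEP_%03d", seq_len(nRegular)),
              sprintf("ART_%03d", seq_len(nReference)))
  refIds <- pepIds[grepl("^ART_", pepIds)]
  regIds <- setdiff(pepIds, refIds)
  undetIds <- sample(regIds, nUndetectable)
  nonlinIds <- sample(setdiff(regIds, undetIds), nNonlinear)
  normalIds <- setdiff(regIds, c(undetIds, nonlinIds))
  if (is.null(differentialPeptides)) {
    stopifnot(nDifferential <= length(normalIds))
    diffIds <- sample(normalIds, nDifferential)
  } else {
    diffIds <- differentialPeptides
    if (!all(diffIds %in% normalIds))
      stop("differentialPeptides must be regular (detectable, linear) ",
           "panel peptides", call. = FALSE)
  }
  lfcVec <- stats::setNames(rep_len(lfc, length(diffIds)), diffIds)

  aa <- c("A", "R", "N", "D", "E", "G", "K", "L", "S", "T", "Y", "P")
  sequences <- vapply(seq_along(pepIds), function(i)
    paste(sample(aa, 13, replace = TRUE), collapse = ""), character(1))
  peptides <- data.frame(peptideId = pepIds, sequence = sequences,
                         uniprotAcc = sprintf("P%05d",
                                              sample.int(99999,
                                                         length(pepIds))),
                         isReference = pepIds %in% refIds,
                         stringsAsFactors = FALSE)

  # --- wells: groups interleaved so every 4-well chip holds both groups
  nWells <- 2L * samplesPerGroup
  group <- rep(groups, times = samplesPerGroup)
  sampleName <- paste0(substr(group, 1, 1), rep(seq_len(samplesPerGroup),
                                                each = 2L))
  chipIdx <- (seq_len(nWells) - 1L) %/% 4L + 1L
  barcode <- sprintf("B%03d", chipIdx)
  well <- paste0("A", ((seq_len(nWells) - 1L) %% 4L) + 1L)
  offs <- rep_len(chipOffsets, max(chipIdx))
  samples <- data.frame(sampleId = sampleName, sampleName = sampleName,
                        barcode = barcode, well = well, group = group,
                        stringsAsFactors = FALSE)

  # --- planted kinetics
  baseLog2 <- stats::setNames(stats::runif(length(pepIds), baseRange[1],
                                           baseRange[2]), pepIds)
  intercepts <- stats::setNames(stats::runif(length(pepIds), 10, 50),
                                pepIds)
  wellLog2 <- sapply(seq_len(nWells), function(w) {
    s <- baseLog2
    if (group[w] == groups[2]) s[diffIds] <- s[diffIds] + lfcVec
    s + offs[chipIdx[w]]
  })
  slopes <- 2^wellLog2 / 100              # peptides x wells, signal/ms
  rownames(slopes) <- pepIds

  # --- signal grid
  grid <- expand.grid(peptideId = pepIds, cycle = cycles,
                      exposureTime = exposures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$peptideId, pepIds), grid$cycle,
                     grid$exposureTime), ]
  rownames(grid) <- NULL
  cyc <- grid$cycle / max(cycles)
  recList <- lapply(seq_len(nWells), function(w) {
    mu <- intercepts[grid$peptideId] +
      slopes[cbind(match(grid$peptideId, pepIds), w)] *
        grid$exposureTime * cyc
    sig <- mu + stats::rnorm(nrow(grid), 0, noiseSd)

    isU <- grid$peptideId %in% undetIds
    sig[isU] <- stats::runif(sum(isU), 1.5, 3)

    isN <- grid$peptideId %in% nonlinIds
    jump <- isN & grid$exposureTime == max(exposures)
    sig[isN] <- 30 + stats::rnorm(sum(isN), 0, 0.5)
    sig[jump] <- 800 + stats::rnorm(sum(jump), 0, 0.5)

    data.frame(sampleId = samples$sampleId[w], peptideId = grid$peptideId,
               cycle = grid$cycle, exposureTime = grid$exposureTime,
               signal = sig, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recList)
  rownames(records) <- NULL

  # planted negatives live at the first cycle so the end-point model
  # never sees them
  firstCyc <- which(records$cycle == min(cycles) &
                    records$peptideId %in% normalIds)
  negIdx <- sample(firstCyc, min(nNegative, length(firstCyc)))
  records$signal[negIdx] <- -stats::runif(length(negIdx), 1, 20)

  satIdx <- integer()
  if (nSaturated > 0L) {
    lastPts <- which(records$cycle == max(cycles) &
                     records$exposureTime == max(exposures) &
                     records$peptideId %in% normalIds)
    satIdx <- sample(lastPts, min(nSaturated, length(lastPts)))
    records$signal[satIdx] <- saturationValue
  }

  ds <- new("KinomeSignal", records = records, samples = samples,
            peptides = peptides, quantType = "Median_SigmBg",
            sourceMeta = list(Version = "SimKin 1.0",
                              Date = "2026-09-19"),
            qc = list())
  if (!is.null(path)) writeCrosstab(ds, path)

  manifest <- list(
    seed = as.integer(seed),
    groups = groups, baseline = groups[1], comparison = groups[2],
    samples = samples,
    referencePeptides = refIds, undetectablePeptides = undetIds,
    nonlinearPeptides = nonlinIds, normalPeptides = normalIds,
    differentialPeptides = diffIds, trueLfc = lfcVec,
    chipOffsets = stats::setNames(offs, sprintf("B%03d",
                                                seq_along(offs))),
    baseLog2 = baseLog2, intercepts = intercepts, slopes = slopes,
    nNegative = length(negIdx), nSaturated = length(satIdx),
    saturationValue = saturationValue,
    cycles = cycles, exposures = exposures, noiseSd = noiseSd)
  list(dataset = ds, file = path, manifest = manifest)
}

#' Simulate a peptide-to-kinase-family mapping
#'
#' Each kinase family is mapped to a fixed or randomly drawn number of
#' pool peptides; peptides may be substrates of several families (draws
#' are independent across kinases).
#'
#' @param peptides pool peptide IDs.
#' @param nKinases number of kinase families (default 20); ignored when
#'   `kPerKinase` is a named vector.
#' @param kPerKinase substrates per kinase: a single range `c(min, max)`
#'   to draw from, or a (optionally named) vector of exact counts.
#' @param disjoint when TRUE families share no substrates (each peptide
#'   maps to at most one family); requires `sum(k) <= length(peptides)`.
#' @param seed RNG seed.
#' @param path optional TSV output (columns `peptideId`, `kinase`).
#' @return list with `mapping` (a [KinaseMapping] over `peptides`),
#'   `file`, and `manifest` (per-kinase substrate sets and counts).
#' @export
simulateMapping <- function(peptides, nKinases = 20L,
                            kPerKinase = c(3L, 30L), disjoint = FALSE,
                            seed = 1L, path = NULL) {
  set.seed(as.integer(seed))
  N <- length(peptides)
  if (length(kPerKinase) == 2L && is.null(names(kPerKinase))) {
    kin <- sprintf("KIN%02d", seq_len(nKinases))
    k <- sample(seq(kPerKinase[1], kPerKinase[2]), nKinases,
                replace = TRUE)
  } else {
    kin <- names(kPerKinase) %||% sprintf("KIN%02d",
                                          seq_along(kPerKinase))
    k <- as.integer(kPerKinase)
  }
  if (any(k > N))
    stop("kPerKinase exceeds the number of pool peptides (", N, ")",
         call. = FALSE)
  if (disjoint) {
    if (sum(k) > N)
      stop("disjoint families need sum(kPerKinase) <= pool size",
           call. = FALSE)
    shuffled <- sample(peptides)
    ends <- cumsum(k)
    subs <- mapply(function(a, b) shuffled[seq(a, b)],
                   c(1L, utils::head(ends, -1L) + 1L), ends,
                   SIMPLIFY = FALSE)
  } else {
    subs <- lapply(k, function(ki) sample(peptides, ki))
  }
  names(subs) <- kin
  entries <- data.frame(
    peptideId = unlist(subs, use.names = FALSE),
    kinase = rep(kin, times = k), stringsAsFactors = FALSE)
  if (!is.null(path)) writeTable(entries, path)
  mapping <- suppressWarnings(loadMapping(entries, pool = peptides))
  list(mapping = mapping, file = path,
       manifest = list(seed = as.integer(seed),
                       substrates = subs,
                       k = stats::setNames(k, kin)))
}

#' Simulate a kinase-kinase PPI edge list
#'
#' Simple undirected Erdos-Renyi graph over the given kinase names: each
#' unordered pair is an edge independently with probability `density`; no
#' self-loops.
#'
#' @param kinases node names.
#' @param density edge probability in \[0, 1\].
#' @param seed RNG seed.
#' @param path optional TSV output (columns `from`, `to`).
#' @return data.frame `from`, `to`.
#' @export
simulatePPI <- function(kinases, density = 0.15, seed = 1L, path = NULL) {
  if (density < 0 || density > 1)
    stop("density must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  pairs <- t(utils::combn(kinases, 2L))
  keep <- stats::runif(nrow(pairs)) < density
  edges <- data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                      stringsAsFactors = FALSE)
  if (!is.null(path)) writeTable(edges, path)
  edges
}
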