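# Shared in-code fixtures for the test suite.

# Build a KinomeSignal straight from a long-form record table; sample and
# peptide metadata are derived (overridable via barcodes/groups keyed by
# sampleId).
makeSignal <- function(records, barcodes = NULL, groups = NULL,
                       isReference = NULL) {
  sampleIds <- unique(records$sampleId)
  pepIds <- unique(records$peptideId)
  if (is.null(barcodes))
    barcodes <- stats::setNames(rep("B001", length(sampleIds)), sampleIds)
  grp <- if (is.null(groups)) rep(NA_character_, length(sampleIds))
         else unname(groups[sampleIds])
  ref <- if (is.null(isReference)) rep(FALSE, length(pepIds))
         else pepIds %in% isReference
  records <- as.data.frame(records)
  rownames(records) <- NULL
  new("KinomeSignal",
      records = records,
      samples = data.frame(sampleId = sampleIds, sampleName = sampleIds,
                           barcode = unname(barcodes[sampleIds]),
                           well = paste0("A", seq_along(sampleIds)),
                           group = grp, stringsAsFactors = FALSE),
      peptides = data.frame(peptideId = pepIds,
                            sequence = strrep("A", 13),
                            uniprotAcc = paste0("P", seq_along(pepIds)),
                            isReference = ref, stringsAsFactors = FALSE),
      quantType = "Median_SigmBg", sourceMeta = list(), qc = list())
}

# Long-form grid records with signal = f(peptideId, sampleId, cycle, expo)
gridRecords <- function(peptides, samples, cycles, exposures, f) {
  g <- expand.grid(sampleId = samples, peptideId = peptides,
                   cycle = cycles, exposureTime = exposures,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$signal <- mapply(f, g$peptideId, g$sampleId, g$cycle, g$exposureTime)
  g
}

# A minimal valid crosstab file as text lines (tab-delimited)
tinyCrosstabLines <- function(quantType = "Median_SigmBg") {
  c(paste0("QuantType=", quantType, "\tVersion=x\tDate=2026-01-01"),
    "Barcode\t\t\t\t\tB001\tB001",
    "Well\t\t\t\t\tA1\tA2",
    "SampleName\t\t\t\t\ts1\ts2",
    "Group\t\t\t\t\tF\tM",
    "ID\tUniprotAccession\tSequence\tCycle\tExposureTime\ts1\ts2",
    "PEP_001\tP1\tAAA\t124\t50\t10.5\t-2.25",
    "PEP_001\tP1\tAAA\t124\t100\t20\t30",
    "PEP_002\tP2\tCCC\t124\t50\t5\t6",
    "PEP_002\tP2\tCCC\t124\t100\t7\t8")
}

writeTempLines <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

# Exact two-sided rank-sum p value by enumeration over all group
# assignments of the pooled observations (no ties assumed); independent
# oracle for the Mann-Whitney test at small n.
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  wAll <- apply(combs, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  pLow <- mean(wAll <= wObs)
  pHigh <- mean(wAll >= wObs)
  min(1, 2 * min(pLow, pHigh))
}

# Brute-force neighbourhood expansion oracle for the network module
bruteExpand <- function(hits, edges, depth) {
  nodes <- hits
  for (i in seq_len(depth)) {
    nb <- c(edges$to[edges$from %in% nodes],
            edges$from[edges$to %in% nodes])
    nodes <- union(nodes, nb)
  }
  sort(nodes)
}
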