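modelFixture <- function(seed = 23, ...) {
  sim <- simulateCrosstab(seed = seed, ...)
  ds <- qcSteps(assignGroups(sim$dataset, "group"))
  list(model = scaleModel(extractEndpoint(ds)), sim = sim, ds = ds)
}

test_that("heatmap scaling and clustering orders behave as declared", {
  fx <- modelFixture(nPeptides = 30, nReference = 3, nUndetectable = 2,
                     nNonlinear = 0, samplesPerGroup = 2,
                     nDifferential = 5)
  hm <- heatmapMatrix(fx$model, scale = "none")
  nf <- normalizedFits(fx$model)
  p0 <- rownames(hm$matrix)[1]
  s0 <- nf$sampleId[nf$peptideId == p0][1]
  expect_equal(hm$matrix[p0, s0],
               nf$signal[nf$peptideId == p0 & nf$sampleId == s0])
  hmr <- heatmapMatrix(fx$model, scale = "row")
  expect_equal(unname(rowMeans(hmr$matrix)),
               rep(0, nrow(hmr$matrix)), tolerance = 1e-9)
  expect_equal(unname(apply(hmr$matrix, 1, stats::sd)),
               rep(1, nrow(hmr$matrix)), tolerance = 1e-9)
  expect_setequal(hmr$rowOrder, seq_len(nrow(hmr$matrix)))
  # orders come from hierarchical clustering with the named linkage
  ref <- stats::hclust(stats::dist(hmr$matrix), method = "average")$order
  expect_equal(heatmapMatrix(fx$model, "row", "average")$rowOrder, ref)
  expect_error(heatmapMatrix(fx$model, scale = "nope"))
})

test_that("zero-variance rows under row scaling are flagged and zeroed", {
  fits <- data.frame(peptideId = rep(c("P1", "P2", "P3"), each = 3),
                     sampleId = rep(c("s1", "s2", "s3"), 3),
                     barcode = "B1", group = "g",
                     signal = c(1, 2, 3, 5, 5, 5, 2, 4, 8))
  model <- new("KinomeModel", fits = fits, normalized = fits,
               grouped = data.frame(peptideId = character(),
                                    group = character(),
                                    signal = numeric(), n = integer()),
               chipNorm = "none")
  hm <- heatmapMatrix(model, scale = "row")
  expect_equal(hm$flaggedRows, "P2")
  expect_equal(unname(hm$matrix["P2", ]), c(0, 0, 0))
})

test_that("global group test reproduces the rank-sum oracle", {
  # identical distributions -> p essentially 1
  g <- data.frame(peptideId = rep(paste0("p", 1:30), 2),
                  group = rep(c("A", "B"), each = 30),
                  signal = rep(stats::rnorm(30, 5), 2), n = 3L)
  model <- new("KinomeModel",
               fits = data.frame(peptideId = g$peptideId[1:30],
                                 signal = 1),
               normalized = data.frame(peptideId = g$peptideId[1:30],
                                       signal = 1),
               grouped = g, chipNorm = "none")
  res <- globalGroupTest(model, "A", "B")
  expect_gt(res$p.value, 0.9)

  # fully separated distributions at n = 84 each
  g2 <- g
  g2$peptideId <- rep(paste0("p", 1:84), length.out = nrow(g2))
  set.seed(1)
  g2 <- data.frame(peptideId = rep(paste0("p", 1:84), 2),
                   group = rep(c("A", "B"), each = 84),
                   signal = c(stats::rnorm(84, 0, 0.2),
                              stats::rnorm(84, 10, 0.2)), n = 3L)
  model2 <- model; model2@grouped <- g2
  expect_lt(globalGroupTest(model2, "A", "B")$p.value, 1e-10)

  # exact enumeration oracle at small n (no ties)
  set.seed(42)
  for (i in 1:5) {
    a <- stats::runif(sample(3:4, 1)); b <- stats::runif(sample(3:4, 1))
    gg <- data.frame(peptideId = c(seq_along(a), seq_along(b)),
                     group = rep(c("A", "B"), c(length(a), length(b))),
                     signal = c(a, b), n = 1L)
    m <- model; m@grouped <- gg
    expect_equal(globalGroupTest(m, "A", "B")$p.value,
                 enumRankSumP(a, b), tolerance = 1e-12)
  }

  # all-tied data warns and returns p = 1
  gt <- g; gt$signal <- 1
  mt <- model; mt@grouped <- gt
  expect_warning(rt <- globalGroupTest(mt, "A", "B"), "tied")
  expect_equal(rt$p.value, 1)
})

test_that("coefficient of variation works on the linear signal scale", {
  fits <- data.frame(peptideId = "P1", sampleId = c("s1", "s2"),
                     barcode = "B1", group = "A",
                     signal = log2(c(1, 3)))
  cv <- cvByGroup(fits)
  expect_equal(cv$cv, sqrt(2) / 2, tolerance = 1e-12)
  # identical replicates give zero CV
  fits2 <- transform(fits, signal = log2(c(4, 4)))
  expect_equal(cvByGroup(fits2)$cv, 0)
  # an outlier well inflates its group's CVs
  fx <- modelFixture(seed = 71, samplesPerGroup = 3)
  nf <- modelFits(fx$model)
  out <- nf
  bad <- out$sampleId == out$sampleId[1]
  out$signal[bad] <- out$signal[bad] + 4
  cvClean <- cvByGroup(nf); cvOut <- cvByGroup(out)
  grp <- nf$group[bad][1]
  expect_gt(mean(cvOut$cv[cvOut$group == grp]),
            mean(cvClean$cv[cvClean$group == grp]) * 2)
})

test_that("waterfall ordering is a stable sort of the fold changes", {
  tab <- data.frame(peptideId = c("a", "b", "c", "d"),
                    lfc = c(0.4, -0.2, 0.4, 0))
  d <- new("KinomeDiff", table = tab, mode = "across_chip",
           baseline = "A", comparison = "B")
  wf <- waterfallData(d, cutoffs = c(0.2, 0.3))
  expect_setequal(wf$table$peptideId, tab$peptideId)
  expect_equal(wf$table$lfc, sort(tab$lfc))
  # ties keep input order: a before c
  expect_equal(wf$table$peptideId[3:4], c("a", "c"))
  expect_equal(wf$cutoffs, c(0.2, 0.3))
})

test_that("curve plot data passes raw points and stored fits through", {
  fx <- modelFixture(seed = 37, nPeptides = 20, nReference = 2,
                     nUndetectable = 1, nNonlinear = 0,
                     samplesPerGroup = 2, nDifferential = 3)
  fits <- modelFits(fx$model)
  pick <- unique(fits$peptideId)[1:2]
  cp <- curvePlotData(fx$ds, fits, pick)
  expect_setequal(unique(cp$lines$peptideId), pick)
  # line parameters equal the stored fits
  l1 <- cp$lines[1, ]
  f1 <- fits[fits$peptideId == l1$peptideId &
             fits$sampleId == l1$sampleId, ]
  expect_equal(l1$slope, f1$slope)
  expect_equal(l1$intercept, f1$intercept)
  # raw points are endpoint records, unmodified
  ep <- extractEndpoint(fx$ds)
  expect_true(all(cp$points$signal %in% signalRecords(ep)$signal))
  expect_error(curvePlotData(fx$ds, fits, "NO_SUCH"), "NO_SUCH")
})

test_that("sampling histogram bins sum to the iteration count", {
  pool <- sprintf("PEP_%03d", 1:40)
  m <- simulateMapping(pool, nKinases = 5, seed = 3)
  sets <- list(new("PeptideSet", cutoff = 0.2,
                   peptides = pool[1:15], direction = "both"))
  s <- scoreKinases(m$mapping, sets, iterations = 500, seed = 8,
                    returnDraws = TRUE)
  kin <- kinaseNames(m$mapping)[1]
  hd <- samplingHistogramData(s, kin)
  expect_equal(sum(hd$counts), 500)
  expect_equal(diff(hd$band), 4 * scoreTable(s)$sd[
    scoreTable(s)$kinase == kin], tolerance = 1e-12)
  expect_equal(hd$observed, scoreTable(s)$observed[
    scoreTable(s)$kinase == kin])
  # without retained draws the helper instructs to re-run
  s2 <- scoreKinases(m$mapping, sets, iterations = 100, seed = 8)
  expect_error(samplingHistogramData(s2, kin), "returnDraws")
})

test_that("z waterfall layers are consistent with the score object", {
  pool <- sprintf("PEP_%03d", 1:40)
  m <- simulateMapping(pool, nKinases = 6, seed = 5)
  set.seed(4)
  sets <- peptideSetsFromIds <- list(
    new("PeptideSet", cutoff = 0.2, peptides = sample(pool, 20),
        direction = "both"),
    new("PeptideSet", cutoff = 0.3, peptides = sample(pool, 12),
        direction = "both"))
  s <- scoreKinases(m$mapping, sets, iterations = 300, seed = 2)
  zw <- zWaterfallData(s)
  agg <- tapply(zw$points$z, zw$points$kinase, mean)
  expect_equal(zw$averaged$meanZ, as.vector(agg[zw$averaged$kinase]))
  one <- scoreKinases(m$mapping, sets[1], iterations = 300, seed = 2)
  zw1 <- zWaterfallData(one)
  expect_equal(zw1$averaged$meanZ,
               zw1$points$z[match(zw1$averaged$kinase,
                                  zw1$points$kinase)])
})

test_that("PCA embeds samples with planted group structure", {
  fx <- modelFixture(seed = 55, nDifferential = 30, lfc = 1)
  pc <- pcaEmbed(fx$model)
  expect_equal(nrow(pc$scores), 6)
  expect_true(all(pc$explained >= 0) && sum(pc$explained) <= 1 + 1e-9)
  # groups separate on PC1
  byGroup <- split(pc$scores$PC1, pc$scores$group)
  expect_true(max(byGroup$Female) < min(byGroup$Male) ||
              max(byGroup$Male) < min(byGroup$Female))

  # duplicated samples land on coincident scores
  nf <- normalizedFits(fx$model)
  dup <- rbind(nf, transform(nf, sampleId = paste0(sampleId, "_copy")))
  model2 <- fx$model; model2@fits <- dup; model2@normalized <- dup
  pc2 <- pcaEmbed(model2)
  sc <- pc2$scores
  orig <- sc[!grepl("_copy", sc$sampleId), ]
  copy <- sc[grepl("_copy", sc$sampleId), ]
  copy$sampleId <- sub("_copy", "", copy$sampleId)
  copy <- copy[match(orig$sampleId, copy$sampleId), ]
  expect_equal(orig$PC1, copy$PC1, tolerance = 1e-9)

  # two samples: PC1 explains all between-sample variance
  two <- nf[nf$sampleId %in% unique(nf$sampleId)[1:2], ]
  model3 <- fx$model; model3@fits <- two; model3@normalized <- two
  pc3 <- pcaEmbed(model3)
  expect_equal(pc3$explained[1], 1, tolerance = 1e-9)
})

test_that("cohort Z correlation matches its closed form", {
  avg <- data.frame(kinase = paste0("K", 1:10),
                    meanZ = stats::rnorm(10))
  self <- cohortZCorrelation(avg, avg)
  expect_equal(self$r, 1, tolerance = 1e-12)
  neg <- transform(avg, meanZ = -meanZ)
  expect_equal(cohortZCorrelation(avg, neg)$r, -1, tolerance = 1e-12)

  set.seed(7)
  b <- transform(avg, meanZ = meanZ + stats::rnorm(10))
  got <- cohortZCorrelation(avg, b)
  x <- avg$meanZ; y <- b$meanZ
  closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, closed, tolerance = 1e-12)
  expect_equal(got$n, 10)
  expect_error(cohortZCorrelation(avg[1:2, ], avg), "at least 3")
})
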