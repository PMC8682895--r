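test_that("exposure-model slopes match closed forms on exact data", {
  expos <- c(10, 20, 50, 100, 200)
  rec <- gridRecords(c("LIN", "FLAT"), "s1", 124L, expos,
                     function(p, s, c, e) if (p == "LIN") e else 42)
  fits <- fitExposureModel(makeSignal(rec))
  lin <- fits[fits$peptideId == "LIN", ]
  expect_equal(lin$slope, 1, tolerance = 1e-12)
  expect_equal(lin$rSquared, 1, tolerance = 1e-12)
  flat <- fits[fits$peptideId == "FLAT", ]
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$rSquared, 0)  # zero total variance convention

  # a single exposure time cannot define a slope
  one <- makeSignal(rec[rec$exposureTime == 10, ])
  expect_error(fitExposureModel(one), "two distinct exposure")
})

test_that("OLS fits agree with stats::lm to 1e-10 relative tolerance", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    x <- sort(stats::runif(n, 5, 300))
    y <- stats::rnorm(n, 2 + 0.3 * x, 4)
    rec <- data.frame(sampleId = "s1", peptideId = "P", cycle = 1L,
                      exposureTime = x, signal = y)
    fit <- fitExposureModel(makeSignal(rec))
    ref <- stats::lm(y ~ x)
    expect_equal(fit$slope, unname(stats::coef(ref)[2]),
                 tolerance = 1e-10)
    expect_equal(fit$intercept, unname(stats::coef(ref)[1]),
                 tolerance = 1e-10)
    expect_equal(fit$rSquared, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("planted slopes are recovered within OLS sampling error", {
  expos <- c(10, 20, 50, 100, 200)
  set.seed(11)
  rec <- gridRecords("P1", "s1", 1L, expos,
                     function(p, s, c, e) 5 + 0.8 * e + stats::rnorm(1))
  fit <- fitExposureModel(makeSignal(rec))
  se <- 1 / sqrt(sum((expos - mean(expos))^2))
  expect_lt(abs(fit$slope - 0.8), 3 * se)
})

test_that("final signal transform is log2 of 100 x slope with clamping", {
  expect_equal(finalSignal(1), log2(100))
  expect_equal(finalSignal(0.01), 0)
  expect_equal(finalSignal(10.24), 10)
  # non-positive slopes clamp to the baseline floor
  expect_equal(finalSignal(-2), 0)
  expect_equal(finalSignal(0, baseline = 2), 1)
  # strictly increasing above the clamp
  s <- sort(stats::runif(50, 0.02, 5))
  expect_true(all(diff(finalSignal(s)) > 0))
})

test_that("chip centering removes additive chip offsets", {
  fits <- data.frame(
    peptideId = rep(paste0("P", 1:4), 2),
    sampleId = rep(c("s1", "s2"), each = 4),
    barcode = rep(c("B1", "B2"), each = 4),
    group = "g",
    signal = c(5:8 + 1, 5:8 - 1))
  med <- suppressWarnings(normalizeByChip(fits, "median"))
  expect_equal(med$signal[1:4], med$signal[5:8])
  expect_equal(as.vector(tapply(med$signal, med$barcode, stats::median)),
               c(0, 0))
  mn <- suppressWarnings(normalizeByChip(fits, "mean"))
  expect_equal(as.vector(tapply(mn$signal, mn$barcode, mean)), c(0, 0))
  expect_identical(normalizeByChip(fits, "none"), fits)

  # single-chip data only shifts by a constant
  one <- fits[fits$barcode == "B1", ]
  shifted <- suppressWarnings(normalizeByChip(one, "median"))
  expect_equal(as.vector(diff(shifted$signal)),
               as.vector(diff(one$signal)))

  # planted chip batch effect disappears from the between-chip contrast
  sim <- simulateCrosstab(chipOffsets = c(0.6, -0.6), samplesPerGroup = 4,
                          seed = 21)
  ds <- qcSteps(assignGroups(sim$dataset, "group"))
  model <- scaleModel(extractEndpoint(ds), chipNorm = "median")
  nf <- normalizedFits(model)
  gap <- diff(unname(tapply(nf$signal, nf$barcode, mean)))
  raw <- modelFits(model)
  rawGap <- diff(unname(tapply(raw$signal, raw$barcode, mean)))
  expect_lt(abs(gap), 0.05)
  expect_gt(abs(rawGap), 1)   # 1.2 log2 units were planted
})

test_that("linearity filter removes failing peptides panel-wide", {
  fits <- data.frame(
    peptideId = rep(c("GOOD", "BAD"), each = 2),
    sampleId = rep(c("s1", "s2"), 2),
    barcode = "B1", group = "g",
    rSquared = c(0.99, 0.97, 0.95, 0.85),
    signal = 1)
  flt <- filterNonlinear(fits, 0.9)
  expect_equal(flt$removed, "BAD")
  expect_setequal(unique(flt$fits$peptideId), "GOOD")
  # r2Min = 0 is the identity
  expect_equal(nrow(filterNonlinear(fits, 0)$fits), 4)
  # threshold is strict: rSquared == r2Min fails
  flt2 <- filterNonlinear(fits, 0.97)
  expect_setequal(flt2$removed, c("GOOD", "BAD"))
  # removed set grows monotonically with the threshold
  sim <- simulateCrosstab(seed = 15)
  f <- fitExposureModel(extractEndpoint(
    qcSteps(assignGroups(sim$dataset, "group"))))
  sizes <- vapply(c(0, 0.5, 0.9, 0.99, 1),
                  function(r) length(filterNonlinear(f, r)$removed), 0L)
  expect_true(all(diff(sizes) >= 0))
  # the two planted step-shaped peptides are exactly what 0.9 removes
  expect_setequal(filterNonlinear(f, 0.9)$removed,
                  sim$manifest$nonlinearPeptides)
})

test_that("group averaging reduces to the per-well values when n = 1", {
  fits <- data.frame(peptideId = rep(c("P1", "P2"), 2),
                     sampleId = rep(c("s1", "s2"), each = 2),
                     barcode = "B1",
                     group = rep(c("A", "B"), each = 2),
                     signal = c(1, 2, 5, 6))
  g <- groupModel(fits)
  expect_equal(g$signal[g$group == "A"], c(1, 2))
  expect_equal(g$signal[g$group == "B"], c(5, 6))
  # duplicated wells average to the common value
  dup <- rbind(fits, transform(fits, sampleId = paste0(sampleId, "b")))
  g2 <- groupModel(dup)
  expect_equal(g2$signal, g$signal)
  expect_equal(g2$n, rep(2L, 4))
})

test_that("model bundle shares one peptide panel across its tables", {
  sim <- simulateCrosstab(seed = 6)
  model <- scaleModel(extractEndpoint(
    qcSteps(assignGroups(sim$dataset, "group"))))
  expect_s4_class(model, "KinomeModel")
  expect_setequal(unique(modelFits(model)$peptideId),
                  unique(groupedSignals(model)$peptideId))
  expect_true(all(modelFits(model)$rSquared > 0.9))
})
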