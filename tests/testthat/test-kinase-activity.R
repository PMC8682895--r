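poolOf <- function(n) sprintf("PEP_%03d", seq_len(n))

test_that("mapping loads restricted to the pool with warnings for strays", {
  pool <- poolOf(10)
  df <- data.frame(peptideId = c(pool[1:4], "OUTSIDE_1", "OUTSIDE_2"),
                   kinase = c("K1", "K1", "K2", "K2", "K1", "K3"))
  expect_warning(map <- loadMapping(df, pool), "2 mapping entries")
  expect_setequal(kinaseNames(map), c("K1", "K2"))
  expect_length(peptidePool(map), 10)
  # unmapped pool peptides stay in the pool with empty family sets
  expect_true(all(pool %in% peptidePool(map)))

  expect_error(loadMapping(df[0, ], pool), "non-empty")
  expect_error(loadMapping(df, c("a ", "a")), "collide")

  # file round trip (tab and comma)
  tf <- tempfile(); write.table(df[1:4, ], tf, sep = "\t",
                                quote = FALSE, row.names = FALSE)
  expect_setequal(kinaseNames(loadMapping(tf, pool)), c("K1", "K2"))
})

test_that("observed counts respect mapping multiplicity", {
  pool <- poolOf(6)
  df <- data.frame(
    peptideId = c("PEP_001", "PEP_001", "PEP_002", "PEP_003", "PEP_004"),
    kinase = c("K1", "K2", "K1", "K2", "K3"))
  map <- loadMapping(df, pool)

  expect_equal(observedCounts(map, character()),
               c(K1 = 0L, K2 = 0L, K3 = 0L))
  expect_equal(observedCounts(map, pool), c(K1 = 2L, K2 = 2L, K3 = 1L))
  obs <- observedCounts(map, c("PEP_001", "PEP_004"))
  expect_equal(obs, c(K1 = 1L, K2 = 1L, K3 = 1L))
  # conservation: total counts = mapping multiplicity within the set
  expect_equal(sum(obs), sum(df$peptideId %in% c("PEP_001", "PEP_004")))
  expect_error(observedCounts(map, "NOT_IN_POOL"), "outside")
})

test_that("sampling null matches the hypergeometric closed form", {
  pool <- poolOf(84)
  m <- simulateMapping(pool, nKinases = 12, kPerKinase = c(4, 60),
                       seed = 19)
  null <- sampleNullCounts(m$mapping, setSize = 56, iterations = 2000,
                           seed = 5)
  k <- m$manifest$k[null$kinase]
  N <- 84; n <- 56; B <- 2000
  muH <- n * k / N
  sdH <- sqrt(n * (k / N) * (1 - k / N) * (N - n) / (N - 1))
  expect_true(all(abs(null$samplingAvg - muH) < 3 * sdH / sqrt(B)))
  expect_true(all(abs(null$sd - sdH) / sdH < 0.10))
})

test_that("degenerate draw of the whole pool has zero variance", {
  pool <- poolOf(12)
  m <- simulateMapping(pool, nKinases = 4, kPerKinase = c(2, 8), seed = 2)
  null <- sampleNullCounts(m$mapping, setSize = 12, iterations = 50,
                           seed = 1)
  expect_equal(null$sd, rep(0, 4))
  expect_equal(null$samplingAvg, unname(m$manifest$k[null$kinase]))
  expect_error(sampleNullCounts(m$mapping, 13, 100, 1), "exceeds")
})

test_that("null sampling is bit-reproducible under a fixed seed", {
  pool <- poolOf(40)
  m <- simulateMapping(pool, nKinases = 6, seed = 4)
  a <- sampleNullCounts(m$mapping, 20, 500, seed = 42)
  b <- sampleNullCounts(m$mapping, 20, 500, seed = 42)
  expect_identical(a, b)
  c <- sampleNullCounts(m$mapping, 20, 500, seed = 43)
  expect_false(identical(a$samplingAvg, c$samplingAvg))
})

test_that("Z arithmetic matches published worked examples", {
  expect_equal(round(kinaseZ(11, 19.19, 2.75), 2), -2.98)
  expect_equal(round(kinaseZ(15, 28.05, 3.00), 2), -4.35)
  expect_equal(kinaseZ(5, 5, 1.7), 0)
  expect_warning(z <- kinaseZ(3, 2, 0), "zero sampling SD")
  expect_true(is.na(z))
  expect_error(kinaseZ(1, 1, -0.5), "non-negative")
})

test_that("scoring averages per-cutoff Z and is parallel-invariant", {
  pool <- poolOf(60)
  m <- simulateMapping(pool, nKinases = 8, seed = 7)
  set.seed(1)
  sets <- list(
    new("PeptideSet", cutoff = 0.2, peptides = sample(pool, 30),
        direction = "both"),
    new("PeptideSet", cutoff = 0.3, peptides = sample(pool, 20),
        direction = "both"),
    new("PeptideSet", cutoff = 0.4, peptides = sample(pool, 10),
        direction = "both"))

  one <- scoreKinases(m$mapping, sets[1], iterations = 400, seed = 11)
  expect_equal(averagedScores(one)$meanZ,
               scoreTable(one)$z[match(averagedScores(one)$kinase,
                                       scoreTable(one)$kinase)])

  s1 <- scoreKinases(m$mapping, sets, iterations = 400, seed = 11)
  s4 <- scoreKinases(m$mapping, sets, iterations = 400, seed = 11,
                     workers = 4)
  expect_identical(scoreTable(s1), scoreTable(s4))
  expect_identical(averagedScores(s1), averagedScores(s4))

  # averaged Z is the arithmetic mean across cutoffs
  st <- scoreTable(s1)
  manual <- tapply(st$z, st$kinase, mean)
  avg <- averagedScores(s1)
  expect_equal(avg$meanZ, as.vector(manual[avg$kinase]))

  # a pure function of (inputs, seed)
  expect_identical(scoreTable(scoreKinases(m$mapping, sets, 400, 11)),
                   scoreTable(s1))
})

test_that("Z scores are invariant under consistent peptide relabeling", {
  pool <- poolOf(30)
  m <- simulateMapping(pool, nKinases = 5, seed = 3)
  set.seed(2)
  ids <- sample(pool, 12)
  s1 <- scoreKinases(m$mapping, list(ids), iterations = 300, seed = 9)

  relabel <- stats::setNames(sprintf("XX_%03d", seq_along(pool)), pool)
  ent <- m$mapping@entries
  ent$peptideId <- unname(relabel[ent$peptideId])
  map2 <- loadMapping(ent, unname(relabel[pool]))
  s2 <- scoreKinases(map2, list(unname(relabel[ids])),
                     iterations = 300, seed = 9)
  expect_equal(scoreTable(s1)$z, scoreTable(s2)$z)
})

test_that("hit calling is inclusive at the threshold and signed", {
  avg <- data.frame(kinase = c("A", "B", "C", "D", "E"),
                    meanZ = c(2.0, -2.5, 1.99, 0, NA))
  hits <- selectHits(avg, 2)
  expect_setequal(hits$kinase, c("A", "B"))
  expect_equal(hits$direction[hits$kinase == "A"], "overrepresented")
  expect_equal(hits$direction[hits$kinase == "B"], "underrepresented")
  # threshold 0 calls every finite-Z kinase
  expect_setequal(selectHits(avg, 0)$kinase, c("A", "B", "C", "D"))
  # overlap between two analyses is plain set algebra
  avg2 <- data.frame(kinase = c("A", "B", "F"), meanZ = c(3, 1, -4))
  h1 <- selectHits(avg, 2)$kinase
  h2 <- selectHits(avg2, 2)$kinase
  expect_setequal(intersect(h1, h2), "A")
  expect_setequal(setdiff(h1, h2), "B")
  expect_setequal(setdiff(h2, h1), "F")
})

test_that("score export uses the conventional table layout", {
  pool <- poolOf(20)
  m <- simulateMapping(pool, nKinases = 4, kPerKinase = c(3, 10),
                       seed = 6)
  s <- scoreKinases(m$mapping, list(pool[1:8]), iterations = 100,
                    seed = 2)
  dir <- tempfile(); dir.create(dir)
  writeScores(s, dir)
  tab <- read.delim(list.files(dir, "cutoff", full.names = TRUE)[1])
  expect_named(tab, c("Kinase", "Observed", "SamplingAvg", "SD", "Z"))
})
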