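# Probability of identity, genotype matching, capture histories.

test_that("pidUnrelated and pidSib match enumeration oracles to 1e-12", {
  set.seed(21)
  for (rep in 1:10) {
    fr <- randomFreqs(1, minA = 2, maxA = 5)
    p <- unname(fr[[1]])
    ft <- makeFrequencyTable(fr)
    expect_equal(pidUnrelated(ft), pidUnrelatedOracle(p), tolerance = 1e-12)
    expect_equal(pidSib(ft), pidSibOracle(p), tolerance = 1e-12)
  }
  # multi-locus values multiply across loci
  fr <- randomFreqs(3, seed = 22)
  ft <- makeFrequencyTable(fr)
  expect_equal(
    pidUnrelated(ft),
    prod(vapply(fr, function(p) pidUnrelatedOracle(unname(p)), 1.0)),
    tolerance = 1e-12
  )
})

test_that("pidSib >= pidUnrelated and both shrink as loci are added", {
  fr <- randomFreqs(6, seed = 23)
  ft <- makeFrequencyTable(fr)
  expect_gte(pidSib(ft), pidUnrelated(ft))
  subsets <- lapply(1:6, function(k) names(fr)[seq_len(k)])
  pu <- vapply(subsets, function(s) pidUnrelated(ft, s), 1.0)
  ps <- vapply(subsets, function(s) pidSib(ft, s), 1.0)
  expect_true(all(diff(pu) < 0))
  expect_true(all(diff(ps) < 0))
  expect_error(pidSib(ft, character(0)), "empty")
  expect_error(pidSib(ft, "nope"), "nope")
})

test_that("bestLociSubset ranks loci by ascending single-locus PIDsib", {
  fr <- list(
    weak = c(a = 0.9, b = 0.1), # least informative
    strong = setNames(rep(1 / 8, 8), letters[1:8]), # most informative
    mid = c(a = 0.5, b = 0.3, c = 0.2)
  )
  ft <- makeFrequencyTable(fr)
  expect_equal(bestLociSubset(ft), c("strong", "mid", "weak"))
  expect_equal(bestLociSubset(ft, 2), c("strong", "mid"))
})

test_that("allele frequency tables count copies and skip missing calls", {
  g <- rbind(
    c(120L, 124L, 200L, 200L),
    c(120L, 120L, NA, NA),
    c(124L, 124L, 200L, 204L)
  )
  rownames(g) <- paste0("I", 1:3)
  ft <- alleleFrequencyTable(mkCatalog(g, c("L1", "L2")))
  expect_equal(alleleFreqs(ft, "L1"), c("120" = 0.5, "124" = 0.5))
  expect_equal(alleleFreqs(ft, "L2"), c("200" = 0.75, "204" = 0.25))
  expect_equal(unname(alleleCopies(ft)), c(6L, 4L))
  expect_error(
    alleleFrequencyTable(g),
    "lociNames"
  )
})

test_that("matching merges exact duplicates and splits >= 2 mismatches", {
  lociNames <- c("L1", "L2")
  mk <- function(a1, b1, a2, b2) {
    list(L1 = repPair(a1, b1, 3), L2 = repPair(a2, b2, 3))
  }
  reps <- list(
    mk(120, 124, 200, 204), # s01
    mk(120, 124, 200, 204), # s02 identical -> same individual
    mk(132, 136, 208, 212) # s03 many mismatches -> distinct
  )
  m <- matchGenotypes(callConsensus(mkScatSamples(reps, lociNames)),
    minLoci = 2
  )
  expect_equal(nIndividuals(m$catalog), 2L)
  expect_equal(nrow(m$reviewQueue), 0L)
  cap <- captures(m$catalog)
  expect_equal(sort(cap$sample[cap$individual == "IND001"]), c("s01", "s02"))
})

test_that("one-mismatch pairs follow the review protocol", {
  lociNames <- c("L1", "L2")
  mk <- function(a1, b1, a2, b2) {
    list(L1 = repPair(a1, b1, 3), L2 = repPair(a2, b2, 3))
  }
  reps <- list(
    mk(120, 124, 200, 204),
    mk(120, 128, 200, 204) # one mismatching allele at L1
  )
  x <- callConsensus(mkScatSamples(reps, lociNames))

  # unreviewed: conservative split
  m0 <- matchGenotypes(x, minLoci = 2)
  expect_equal(nIndividuals(m0$catalog), 2L)
  expect_equal(m0$reviewQueue$resolved, "unreviewed-split")

  # review confirms a genuine difference: stays split
  m1 <- matchGenotypes(x, minLoci = 2, review = function(s1, s2) TRUE)
  expect_equal(nIndividuals(m1$catalog), 2L)
  expect_equal(m1$reviewQueue$resolved, "confirmed-different")

  # review attributes the difference to error: merged
  m2 <- matchGenotypes(x, minLoci = 2, review = function(s1, s2) FALSE)
  expect_equal(nIndividuals(m2$catalog), 1L)
  expect_equal(m2$reviewQueue$resolved, "merged")

  # data.frame review form
  rv <- data.frame(sample1 = "s01", sample2 = "s02", different = FALSE)
  m3 <- matchGenotypes(x, minLoci = 2, review = rv)
  expect_equal(nIndividuals(m3$catalog), 1L)
})

test_that("mismatch counting uses the allele multiset per locus", {
  # (120,124) vs (124,128): one shared allele -> 1 mismatch, review pair;
  # (120,120) vs (124,128): no shared -> 2 mismatches, distinct
  lociNames <- "L1"
  reps <- list(
    list(L1 = repPair(120, 124, 3)),
    list(L1 = repPair(124, 128, 3)),
    list(L1 = repPair(132, 132, 3))
  )
  m <- matchGenotypes(callConsensus(mkScatSamples(reps, lociNames)),
    minLoci = 1
  )
  expect_equal(nIndividuals(m$catalog), 3L)
  expect_equal(nrow(m$reviewQueue), 1L)
  expect_setequal(
    c(m$reviewQueue$sample1, m$reviewQueue$sample2), c("s01", "s02")
  )
})

test_that("matching recovers the true partition on an error-free dataset", {
  cfg <- simConfig(
    nIndividuals = 60L, dropout = 0, falseAllele = 0, missingLocus = 0
  )
  ds <- simulateDataset(cfg, seed = 301)
  m <- matchGenotypes(callConsensus(ds$samples))
  truthPart <- ds$sampleIndividual[sampleInfo(ds$samples)$sample[m$usable]]
  estPart <- captures(m$catalog)$individual[
    match(names(truthPart), captures(m$catalog)$sample)
  ]
  ari <- mclust::adjustedRandIndex(truthPart, estPart)
  expect_equal(ari, 1)
  expect_equal(ariOracle(truthPart, estPart), 1) # oracle agreement
})

test_that("individual ids are ordered by first capture date", {
  lociNames <- "L1"
  reps <- list(
    list(L1 = repPair(120, 124, 3)),
    list(L1 = repPair(132, 136, 3))
  )
  # s02 (allele 132) captured before s01
  x <- callConsensus(mkScatSamples(reps, lociNames,
    dates = as.Date(c("2015-06-01", "2015-04-01"))
  ))
  m <- matchGenotypes(x, minLoci = 1)
  cap <- captures(m$catalog)
  expect_equal(cap$sample[cap$individual == "IND001"], "s02")
  expect_equal(cap$sample[cap$individual == "IND002"], "s01")
})

test_that("capture histories bin dates into occasions and keep totals", {
  g <- rbind(c(120L, 124L), c(128L, 132L))
  rownames(g) <- c("A", "B")
  cap <- data.frame(
    individual = c("A", "A", "A", "B", "B", "A"),
    sample = paste0("s", 1:6),
    date = as.Date("2015-03-01") + c(0, 10, 40, 5, 70, 85),
    x = c(0, 100, 0, 500, 500, 50),
    y = rep(0, 6),
    cell = c("c1", "c1", "c1", "c2", "c2", "c1"),
    stringsAsFactors = FALSE
  )
  catA <- IndividualCatalog(g, "L1", cap)
  ch <- buildCaptureHistory(catA, occasions = 3)
  expect_equal(sort(unname(captureTotals(ch))), c(2L, 4L))
  expect_equal(sum(ch@counts$n), 6L)
  expect_true(all(ch@counts$occasion %in% 1:3))
  expect_equal(length(ch@occasionBreaks), 4L)
  expect_setequal(detectors(ch)$detector, c("c1", "c2"))
  # one occasion also works
  ch1 <- buildCaptureHistory(catA, occasions = 1)
  expect_true(all(ch1@counts$occasion == 1L))
  expect_error(buildCaptureHistory(catA, occasions = 0), "positive")
})
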