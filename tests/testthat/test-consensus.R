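# Multi-tubes consensus rules, replicate error rates, null-allele EM,
# sample usability.

test_that("consensus acceptance thresholds follow the multi-tubes rules", {
  # homozygote needs >= 3 identical replicates
  expect_equal(
    callConsensusLocus(repPair(120, 120, 3))$status, "accepted"
  )
  expect_equal(
    callConsensusLocus(repPair(120, 120, 2))$status, "pending"
  )
  # heterozygote needs >= 2 identical replicates, order-insensitive
  hit <- callConsensusLocus(rbind(c(120, 124), c(124, 120)))
  expect_equal(hit$status, "accepted")
  expect_equal(hit$alleles, c(120L, 124L))
  expect_equal(hit$support, 2L)
  expect_equal(
    callConsensusLocus(rbind(c(120, 124)))$status, "pending"
  )
  # all replicates failed -> missing
  expect_equal(
    callConsensusLocus(rbind(c(NA, NA), c(NA, NA)))$status, "missing"
  )
  expect_error(callConsensusLocus(matrix(integer(), 0, 2)), "replicate")
})

test_that("a qualifying heterozygote beats a qualifying homozygote", {
  # dropout explains spurious homozygotes; 3 homs + 2 hets -> het wins
  m <- rbind(
    c(120, 120), c(120, 120), c(120, 120),
    c(120, 124), c(120, 124)
  )
  hit <- callConsensusLocus(m)
  expect_equal(hit$alleles, c(120L, 124L))
  # ties among qualifying profiles resolve by support then allele order,
  # deterministically
  m2 <- rbind(c(120, 124), c(120, 124), c(128, 132), c(128, 132), c(128, 132))
  expect_equal(callConsensusLocus(m2)$alleles, c(128L, 132L))
  m3 <- rbind(c(120, 124), c(120, 124), c(128, 132), c(128, 132))
  expect_equal(callConsensusLocus(m3)$alleles, c(120L, 124L))
})

test_that("callConsensus fills consensus and status for every sample x locus", {
  lociNames <- c("L1", "L2")
  reps <- list(
    list(L1 = repPair(120, 124, 2), L2 = repPair(88, 88, 3)),
    list(L1 = repPair(120, 120, 2), L2 = matrix(NA_integer_, 2, 2))
  )
  x <- callConsensus(mkScatSamples(reps, lociNames))
  st <- consensusStatus(x)
  expect_equal(unname(st[1, ]), c("accepted", "accepted"))
  expect_equal(unname(st[2, ]), c("pending", "missing"))
  g <- consensusGenotypes(x)
  expect_equal(unname(g[1, ]), c(120L, 124L, 88L, 88L))
  expect_true(all(is.na(g[2, ])))
  fl <- flaggedSamples(x)
  expect_equal(fl$sample, "s02")
  expect_equal(fl$locus, "L1")
})

test_that("error rates count dropout and false alleles exactly", {
  lociNames <- "L1"
  # sample 1: consensus het 120/124; replicates show one dropout homozygote
  # sample 2: consensus het 120/124; replicates contain one foreign allele
  reps <- list(
    list(L1 = rbind(c(120, 124), c(120, 124), c(120, 120))),
    list(L1 = rbind(c(120, 124), c(120, 124), c(120, 128)))
  )
  x <- callConsensus(mkScatSamples(reps, lociNames))
  er <- estimateErrorRates(x)
  expect_equal(er$dropout[er$locus == "pooled"], 1 / 6)
  expect_equal(er$falseAllele[er$locus == "pooled"], 1 / 6)
  expect_equal(er$nDropoutReps[er$locus == "pooled"], 6L)
  # per-locus row agrees with the pool for a single locus
  expect_equal(er$dropout[er$locus == "L1"], 1 / 6)
})

test_that("error rates are NA without an informative comparison", {
  # only homozygote consensus: no dropout denominator
  reps <- list(list(L1 = repPair(120, 120, 3)))
  x <- callConsensus(mkScatSamples(reps, "L1"))
  er <- estimateErrorRates(x)
  expect_true(is.na(er$dropout[1]))
  expect_equal(er$falseAllele[1], 0)
  expect_error(estimateErrorRates(mkScatSamples(reps, "L1")), "callConsensus")
})

test_that("null-allele EM recovers a planted null frequency", {
  set.seed(42)
  # alleles 1..4 visible at 0.2 each plus a null allele at 0.2
  pTrue <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  n <- 3000
  draws <- matrix(sample.int(5, 2 * n, replace = TRUE, prob = pTrue), n, 2)
  isNull <- draws == 5L
  blank <- isNull[, 1] & isNull[, 2]
  obs <- draws[!blank, , drop = FALSE]
  oneNull <- xor(obs[, 1] == 5L, obs[, 2] == 5L)
  vis <- ifelse(obs[, 1] == 5L, obs[, 2], obs[, 1])
  obs[oneNull, 1] <- vis[oneNull]
  obs[oneNull, 2] <- vis[oneNull] # null heterozygote reads as homozygote
  est <- estimateNullAlleleFreq(obs, nBlank = sum(blank))
  expect_lt(abs(est - 0.2), 0.03)
})

test_that("null-allele EM stays near zero without null alleles", {
  set.seed(43)
  g <- drawHweGenotypes(randomFreqs(1, minA = 5, maxA = 5, seed = 5), 2000)
  est <- estimateNullAlleleFreq(g[, 1:2])
  expect_lt(est, 0.02)
  # monomorphic locus: 0 with a note
  mono <- matrix(7L, 20, 2)
  est2 <- estimateNullAlleleFreq(mono)
  expect_equal(as.numeric(est2), 0)
  expect_match(attr(est2, "note"), "monomorphic")
  expect_error(estimateNullAlleleFreq(matrix(1:8, 4, 2)), ">= 10")
})

test_that("null-allele estimate is invariant to allele relabeling", {
  set.seed(44)
  g <- drawHweGenotypes(randomFreqs(1, minA = 4, maxA = 4, seed = 9), 400)[, 1:2]
  e1 <- estimateNullAlleleFreq(g)
  relab <- g * 3L + 7L # order-preserving relabeling
  e2 <- estimateNullAlleleFreq(relab)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("nullAlleleFrequencies covers the catalog loci", {
  set.seed(45)
  g <- drawHweGenotypes(randomFreqs(3, seed = 6), 60)
  cat <- mkCatalog(g, c("L1", "L2", "L3"))
  nf <- nullAlleleFrequencies(cat)
  expect_equal(names(nf), c("L1", "L2", "L3"))
  expect_true(all(is.finite(nf)))
  expect_true(all(nf >= 0 & nf < 1))
})

test_that("usableSamples applies the locus minimum and distance rescue", {
  lociNames <- paste0("L", 1:3)
  okRep <- function() repPair(120, 124, 2)
  badRep <- function() matrix(NA_integer_, 2, 2)
  reps <- list(
    list(L1 = okRep(), L2 = okRep(), L3 = okRep()), # 3 loci: usable
    list(L1 = okRep(), L2 = okRep(), L3 = badRep()), # 2 loci, near s1
    list(L1 = okRep(), L2 = okRep(), L3 = badRep()) # 2 loci, isolated
  )
  x <- callConsensus(mkScatSamples(reps, lociNames,
    x = c(0, 100, 9000), y = c(0, 0, 0)
  ))
  u <- usableSamples(x, minLoci = 3, rescueLoci = 2, rescueDistance = 2000)
  expect_equal(u, c(TRUE, FALSE, TRUE))
  # stricter rescue distance drops the isolated sample too
  u2 <- usableSamples(x, minLoci = 3, rescueLoci = 2, rescueDistance = 20000)
  expect_equal(u2, c(TRUE, FALSE, FALSE))
})
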