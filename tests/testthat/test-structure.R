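# FST, permutation tests, Nm, PCoA, admixture Gibbs, migrant detection.

test_that("theta is ~0 under panmixia and 1 for fixed differences", {
  set.seed(41)
  fr <- randomFreqs(6, minA = 4, maxA = 6, seed = 42)
  g <- drawHweGenotypes(fr, 80)
  cat <- mkCatalog(g, names(fr))
  labels <- rep(c("a", "b"), 40)
  th <- fstWeirCockerham(cat, labels)$theta
  expect_lt(abs(th), 0.02)

  # fixed differences at every locus
  gf <- rbind(
    matrix(rep(c(1L, 1L), 5 * 10), 10, 10, byrow = TRUE),
    matrix(rep(c(2L, 2L), 5 * 10), 10, 10, byrow = TRUE)
  )
  rownames(gf) <- sprintf("I%02d", 1:20)
  catf <- mkCatalog(gf, paste0("L", 1:5))
  thf <- fstWeirCockerham(catf, rep(c("a", "b"), each = 10))
  expect_equal(thf$theta, 1)
  expect_true(all(thf$perLocus == 1))
})

test_that("theta recovers the Balding-Nichols divergence on average", {
  set.seed(43)
  ths <- vapply(1:50, function(i) {
    truth <- simulatePopulation(
      simConfig("twodeme", nIndividuals = 100L),
      seed = 5000 + i
    )
    cat <- mkCatalog(truth$genotypes, truth$config$loci)
    fstWeirCockerham(cat, as.character(truth$deme))$theta
  }, 1.0)
  expect_lt(abs(mean(ths) - 0.1), 0.02)
})

test_that("labels can be named or positional and are validated", {
  g <- drawHweGenotypes(randomFreqs(3, seed = 44), 12)
  cat <- mkCatalog(g, paste0("L", 1:3))
  labPos <- rep(c("a", "b"), 6)
  labNamed <- setNames(labPos, rownames(g))
  expect_equal(
    fstWeirCockerham(cat, labPos)$theta,
    fstWeirCockerham(cat, sample(labNamed))$theta
  )
  expect_error(fstWeirCockerham(cat, labPos[1:3]), "named or match")
  expect_error(fstWeirCockerham(cat, rep("a", 12)), "2 populations")
})

test_that("permutation p matches the exhaustive 3v3 oracle", {
  set.seed(45)
  g <- drawHweGenotypes(randomFreqs(4, minA = 3, maxA = 4, seed = 46), 6)
  cat <- mkCatalog(g, paste0("L", 1:4))
  labels <- rep(c("a", "b"), each = 3)
  obs <- fstWeirCockerham(cat, labels)$theta
  # exhaustive: theta depends only on which 3 individuals are labeled "a"
  splits <- combn(6, 3)
  thetas <- apply(splits, 2, function(ii) {
    lab <- rep("b", 6)
    lab[ii] <- "a"
    fstWeirCockerham(cat, lab)$theta
  })
  pStar <- mean(thetas >= obs - 1e-15)
  pt <- fstPermutationTest(cat, labels, nPerm = 3000, seed = 47)
  expect_equal(pt$theta, obs)
  expect_lt(abs(pt$p - pStar), 0.04)
})

test_that("permutation p is not small under the null", {
  set.seed(48)
  ps <- vapply(1:40, function(i) {
    g <- drawHweGenotypes(randomFreqs(4, seed = 100 + i), 40)
    cat <- mkCatalog(g, paste0("L", 1:4))
    fstPermutationTest(cat, rep(c("a", "b"), 20), nPerm = 150)$p
  }, 1.0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("Nm conversion matches hand-computed values", {
  expect_equal(nmFromFst(0.021), 11.6547619, tolerance = 1e-6)
  expect_equal(nmFromFst(0.2), 1)
  expect_equal(nmFromFst(0.5), 0.25)
  expect_equal(nmFromFst(1), 0)
  expect_warning(nm <- nmFromFst(0), "undefined")
  expect_true(is.na(nm))
  expect_error(nmFromFst(NA_real_), "finite")
})

test_that("PCoA squared distance codes follow the genotype relations", {
  g <- rbind(
    c(1L, 1L), # hom 11
    c(1L, 2L), # het sharing an allele with both others? no: shares 1 with I1
    c(3L, 4L) # het disjoint from both
  )
  rownames(g) <- c("I1", "I2", "I3")
  pc <- genotypePcoa(mkCatalog(g, "L1"))
  expect_equal(pc$D2["I1", "I2"], 1) # one shared allele
  expect_equal(pc$D2["I1", "I3"], 3) # hom vs het, no shared
  expect_equal(pc$D2["I2", "I3"], 2) # het vs het, no shared
  # hom vs other hom = 4
  g2 <- rbind(c(1L, 1L), c(2L, 2L), c(1L, 2L))
  rownames(g2) <- c("a", "b", "c")
  expect_equal(genotypePcoa(mkCatalog(g2, "L1"))$D2["a", "b"], 4)
})

test_that("PCoA eigenvalues agree with the cmdscale oracle", {
  set.seed(49)
  g <- drawHweGenotypes(randomFreqs(6, seed = 50), 12)
  cat <- mkCatalog(g, paste0("L", 1:6))
  pc <- genotypePcoa(cat)
  cm <- cmdscale(as.dist(sqrt(pc$D2)), k = 11, eig = TRUE)
  cmPos <- cm$eig[cm$eig > 1e-9 * max(abs(cm$eig))]
  expect_equal(pc$eig, cmPos, tolerance = 1e-8)
  expect_equal(sum(pc$percentVar), 100)
  # points reproduce the positive-definite part of the distances
  expect_error(genotypePcoa(mkCatalog(g[1:2, ], paste0("L", 1:6))), "at least 3")
})

test_that("admixture with K=1 is the trivial clustering", {
  g <- drawHweGenotypes(randomFreqs(4, seed = 51), 15)
  cat <- mkCatalog(g, paste0("L", 1:4))
  res <- admixtureGibbs(cat, K = 1, burnin = 50, sweeps = 200, seed = 1)
  expect_equal(res@K, 1L)
  expect_true(all(res@Q == 1))
  expect_true(is.finite(res@lnP))
  expect_error(admixtureGibbs(cat, K = 0), "K must")
  expect_error(admixtureGibbs(cat, K = 2, burnin = 10, sweeps = 5), "exceed")
})

test_that("admixture separates strongly differentiated demes", {
  set.seed(52)
  nLoci <- 12
  frA <- lapply(1:nLoci, function(i) c("1" = 0.95, "2" = 0.05))
  frB <- lapply(1:nLoci, function(i) c("1" = 0.05, "2" = 0.95))
  names(frA) <- names(frB) <- paste0("L", 1:nLoci)
  g <- rbind(
    drawHweGenotypes(frA, 30),
    drawHweGenotypes(frB, 30)
  )
  rownames(g) <- sprintf("I%03d", 1:60)
  cat <- mkCatalog(g, names(frA))
  res <- admixtureGibbs(cat, K = 2, burnin = 300, sweeps = 1200, seed = 2)
  cl <- max.col(res@Q)
  truthLab <- rep(c("A", "B"), each = 30)
  expect_gte(mclust::adjustedRandIndex(cl, truthLab), 0.9)
  expect_gt(mean(apply(res@Q, 1, max)), 0.85)
  # a K=2 model should beat K=1 on structured data
  res1 <- admixtureGibbs(cat, K = 1, burnin = 300, sweeps = 1200, seed = 2)
  expect_gt(res@lnP, res1@lnP)
})

test_that("Evanno delta-K matches hand arithmetic", {
  # mean lnP: -100, -50, -48, -47; runs at K=2 are -49/-51 so sd = sqrt(2)
  m <- cbind(
    "1" = c(-100, -100), "2" = c(-49, -51),
    "3" = c(-48, -48), "4" = c(-47, -47)
  )
  dk <- evannoDeltaK(m)
  expect_equal(dk$K, 1:4)
  # |(-48) - 2(-50) + (-100)| / sqrt(2) = 48 / sqrt(2)
  expect_equal(dk$deltaK[2], 48 / sqrt(2))
  expect_true(is.na(dk$deltaK[1]) && is.na(dk$deltaK[4]))
  expect_true(is.na(dk$deltaK[3])) # sd 0 at K=3
  # data.frame input agrees
  df <- data.frame(K = rep(1:4, each = 2), lnP = as.vector(m))
  expect_equal(evannoDeltaK(df), dk)
  expect_error(evannoDeltaK(m[, 1:2]), ">= 3")
})

test_that("an individual with foreign alleles is flagged as a migrant", {
  set.seed(53)
  nLoci <- 8
  frA <- lapply(1:nLoci, function(i) c("1" = 0.5, "2" = 0.5))
  frB <- lapply(1:nLoci, function(i) c("11" = 0.5, "12" = 0.5))
  names(frA) <- names(frB) <- paste0("L", 1:nLoci)
  g <- rbind(
    drawHweGenotypes(frA, 15),
    drawHweGenotypes(frB, 15),
    drawHweGenotypes(frB, 1) # true B genotype labeled as A below
  )
  rownames(g) <- sprintf("I%03d", 1:31)
  cat <- mkCatalog(g, names(frA))
  labels <- c(rep("A", 15), rep("B", 15), "A")
  mig <- detectFirstGenMigrants(cat, labels, nSim = 500, alpha = 0.01, seed = 54)
  expect_true(mig$migrant[31])
  expect_equal(sum(mig$migrant[1:30]), 0)
  expect_gt(mig$stat[31], 1)
})

test_that("migrant detection false-positive rate is near alpha", {
  # The simulated null assumes the two reference samples describe genuinely
  # distinct populations, so calibration is assessed in that regime (between
  # two Dirichlet-perturbed demes), not under panmixia with arbitrary labels
  # where "first-generation migrant" is undefined. Bound: twice the nominal
  # alpha plus slack for within-dataset correlation of flags.
  fpRates <- vapply(1:6, function(rep) {
    set.seed(600 + rep)
    frBase <- randomFreqs(6, minA = 4, maxA = 6, seed = 700 + rep)
    perturb <- function(p, c = 8) {
      q <- rgamma(length(p), c * p)
      setNames(q / sum(q), names(p))
    }
    frA <- lapply(frBase, perturb)
    frB <- lapply(frBase, perturb)
    names(frA) <- names(frB) <- names(frBase)
    g <- rbind(drawHweGenotypes(frA, 25), drawHweGenotypes(frB, 25))
    rownames(g) <- sprintf("I%03d", 1:50)
    catFp <- mkCatalog(g, names(frBase))
    mig <- detectFirstGenMigrants(catFp, rep(c("A", "B"), each = 25),
      nSim = 400, alpha = 0.05, seed = 800 + rep
    )
    expect_true(all(mig$p > 0 & mig$p <= 1))
    mean(mig$migrant)
  }, 1.0)
  expect_lte(mean(fpRates), 0.12)
})
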