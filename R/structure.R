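## Differentiation, clustering, ordination and migrant detection between two
## labeled populations.

# Precompute integer allele arrays per locus for fast repeated theta
# evaluation under label permutation.
.fstPrep <- function(catalog) {
  g <- genotypes(catalog)
  lociNames <- loci(catalog)
  lapply(seq_along(lociNames), function(li) {
    al <- .locusGeno(g, li)
    keep <- !is.na(al[, 1])
    alleles <- sort(unique(as.vector(al[keep, , drop = FALSE])))
    list(
      keep = keep,
      i1 = match(al[, 1], alleles),
      i2 = match(al[, 2], alleles),
      A = length(alleles)
    )
  })
}

# Weir & Cockerham (1984) variance components summed over alleles of one
# locus; pops is an integer vector 1..r over individuals.
.fstLocusComponents <- function(prep, pops, r) {
  keep <- prep$keep
  pp <- pops[keep]
  i1 <- prep$i1[keep]
  i2 <- prep$i2[keep]
  A <- prep$A
  ni <- tabulate(pp, nbins = r)
  use <- ni > 0
  if (sum(use) < 2 || A < 2) {
    return(c(a = 0, b = 0, c = 0))
  }
  ni <- ni[use]
  rEff <- length(ni)
  nbar <- mean(ni)
  nc <- (rEff * nbar - sum(ni^2) / (rEff * nbar)) / (rEff - 1)

  # per-pop allele counts and heterozygote-carrier counts
  popIdx <- match(pp, which(use))
  aSum <- bSum <- cSum <- 0
  countMat <- matrix(0, rEff, A)
  hetMat <- matrix(0, rEff, A)
  for (al in seq_len(A)) {
    cnt <- tabulate(popIdx[i1 == al], nbins = rEff) + tabulate(popIdx[i2 == al], nbins = rEff)
    hetc <- tabulate(popIdx[i1 == al & i1 != i2], nbins = rEff) +
      tabulate(popIdx[i2 == al & i1 != i2], nbins = rEff)
    countMat[, al] <- cnt
    hetMat[, al] <- hetc
  }
  for (al in seq_len(A)) {
    p_i <- countMat[, al] / (2 * ni)
    h_i <- hetMat[, al] / ni
    pbar <- sum(ni * p_i) / (rEff * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((rEff - 1) * nbar)
    hbar <- sum(ni * h_i) / (rEff * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((rEff - 1) / rEff) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((rEff - 1) / rEff) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    aSum <- aSum + a
    bSum <- bSum + b
    cSum <- cSum + cc
  }
  c(a = aSum, b = bSum, c = cSum)
}

.thetaFromPrep <- function(prepList, pops, r) {
  comp <- rowSums(vapply(prepList, .fstLocusComponents, numeric(3), pops = pops, r = r))
  denom <- sum(comp)
  if (denom == 0) {
    return(0)
  }
  comp[[1]] / denom
}

#' Weir-Cockerham F-statistics between labeled populations
#'
#' Multi-locus theta with variance components summed over alleles and loci
#' before the ratio; slightly negative estimates are reported as-is.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param labels named character/factor vector of population labels per
#'   individual (names matching catalog individual ids), or an unnamed
#'   vector in catalog order.
#' @return list with `theta`, per-locus estimates and variance components.
#' @export
fstWeirCockerham <- function(catalog, labels) {
  g <- genotypes(catalog)
  labels <- .alignLabels(labels, rownames(g))
  f <- factor(labels)
  if (nlevels(f) < 2) .stopf("need at least 2 populations")
  pops <- as.integer(f)
  prepList <- .fstPrep(catalog)
  perLocus <- vapply(prepList, function(p) {
    comp <- .fstLocusComponents(p, pops, nlevels(f))
    if (sum(comp) == 0) NA_real_ else comp[1] / sum(comp)
  }, 1.0)
  comp <- rowSums(vapply(prepList, .fstLocusComponents, numeric(3), pops = pops, r = nlevels(f)))
  if (sum(comp) == 0) .stopf("no polymorphic co-typed loci between the populations")
  list(
    theta = comp[["a"]] / sum(comp),
    perLocus = setNames(perLocus, loci(catalog)),
    components = comp,
    populations = levels(f)
  )
}

.alignLabels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) .stopf("no population label for individual %s", miss[1])
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    .stopf("labels must be named or match the number of individuals")
  }
  as.character(labels)
}

#' Permutation test of population differentiation
#'
#' Individuals' population labels are permuted `nPerm` times;
#' `p = (1 + #{theta_perm >= theta_obs}) / (1 + nPerm)`.
#'
#' @inheritParams fstWeirCockerham
#' @param nPerm number of permutations.
#' @param seed optional RNG seed.
#' @return list with `theta`, `p`, `nPerm` and the permutation distribution.
#' @export
fstPermutationTest <- function(catalog, labels, nPerm = 10000L, seed = NULL) {
  if (nPerm < 100) .warnf("fewer than 100 permutations gives poor p-value resolution")
  g <- genotypes(catalog)
  labels <- .alignLabels(labels, rownames(g))
  f <- factor(labels)
  pops <- as.integer(f)
  r <- nlevels(f)
  prepList <- .fstPrep(catalog)
  obs <- .thetaFromPrep(prepList, pops, r)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(b) {
    .thetaFromPrep(prepList, sample(pops), r)
  }, 1.0)
  list(
    theta = obs,
    p = (1 + sum(perm >= obs - 1e-15)) / (1 + nPerm),
    nPerm = as.integer(nPerm),
    permuted = perm
  )
}

#' Effective migrants per generation from theta
#'
#' Wright island-model conversion `Nm = (1 - Fst) / (4 Fst)`.
#'
#' @param theta differentiation estimate in (0, 1).
#' @return effective number of migrants; NA with a warning when theta <= 0,
#'   0 when theta >= 1.
#' @export
nmFromFst <- function(theta) {
  if (!is.finite(theta)) .stopf("theta must be finite")
  if (theta <= 0) {
    .warnf("theta <= 0: island-model Nm undefined")
    return(NA_real_)
  }
  if (theta >= 1) {
    return(0)
  }
  (1 - theta) / (4 * theta)
}

## PCoA ----------------------------------------------------------------------

# squared genetic distance codes between two single-locus genotypes
# (Smouse-Peakall): identical 0; one shared allele 1; het vs het no shared 2;
# hom vs het no shared 3; hom vs other hom 4.
.locusDist2 <- function(a1, b1, a2, b2) {
  if (a1 == a2 && b1 == b2) {
    return(0)
  }
  shared <- (a1 == a2) || (b1 == b2) || (a1 == b2) || (b1 == a2)
  hom1 <- a1 == b1
  hom2 <- a2 == b2
  if (shared) {
    return(1)
  }
  if (!hom1 && !hom2) {
    return(2)
  }
  if (hom1 && hom2) {
    return(4)
  }
  3
}

#' Principal coordinates analysis of individual genetic distances
#'
#' Squared multivariate genetic distances are summed over co-typed loci,
#' double-centered (Gower) and eigendecomposed; axes with positive
#' eigenvalues are kept.
#'
#' @param catalog an [IndividualCatalog-class] object with >= 3 individuals.
#' @return list with `points` (individuals x axes), `eig` (positive
#'   eigenvalues), `percentVar` and the squared distance matrix `D2`.
#' @export
genotypePcoa <- function(catalog) {
  g <- genotypes(catalog)
  n <- nrow(g)
  if (n < 3) .stopf("need at least 3 individuals for PCoA")
  L <- length(loci(catalog))
  D2 <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 0
      for (li in seq_len(L)) {
        a1 <- g[i, 2L * li - 1L]
        b1 <- g[i, 2L * li]
        a2 <- g[j, 2L * li - 1L]
        b2 <- g[j, 2L * li]
        if (is.na(a1) || is.na(a2)) next
        d <- d + .locusDist2(a1, b1, a2, b2)
      }
      D2[i, j] <- D2[j, i] <- d
    }
  }
  # Gower double-centering: J (-D2/2) J
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% (-0.5 * D2) %*% J
  ev <- eigen(G, symmetric = TRUE)
  keep <- ev$values > 1e-9 * max(1, abs(ev$values[1]))
  if (!any(keep)) {
    return(list(points = matrix(0, n, 0), eig = numeric(0), percentVar = numeric(0), D2 = D2))
  }
  lam <- ev$values[keep]
  pts <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), nrow = length(lam))
  rownames(pts) <- rownames(g)
  list(points = pts, eig = lam, percentVar = 100 * lam / sum(lam), D2 = D2)
}

## Admixture Gibbs sampler ---------------------------------------------------

#' Admixture-model Gibbs sampler for multilocus genotypes
#'
#' A finite-mixture admixture model: each allele copy has a latent cluster of
#' origin z drawn from the individual's membership proportions q; cluster
#' allele frequencies get independent Dirichlet(lambda) priors and q a
#' symmetric Dirichlet(alpha) prior. The sampler alternates categorical
#' updates of z with conjugate Dirichlet updates of p and q. The model
#' log-probability is estimated as `mean(lnL) - var(lnL)/2` over
#' post-burn-in sweeps, and Q is the posterior mean of q.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param K number of clusters.
#' @param burnin,sweeps burn-in and total Gibbs sweeps.
#' @param alpha Dirichlet parameter of the admixture proportions.
#' @param lambda Dirichlet parameter of the cluster allele frequencies.
#' @param seed RNG seed of the run.
#' @return An [AdmixtureResult-class] object.
#' @export
admixtureGibbs <- function(catalog, K, burnin = 2000L, sweeps = 10000L,
                           alpha = 1.0, lambda = 1.0, seed = 1L) {
  g <- genotypes(catalog)
  n <- nrow(g)
  if (K < 1) .stopf("K must be >= 1")
  if (K > n) .stopf("K exceeds the number of individuals")
  if (sweeps <= burnin) .stopf("sweeps must exceed burnin")
  lociNames <- loci(catalog)
  set.seed(seed)

  # flatten allele copies
  ci <- cl <- ca <- integer(0)
  alleleSets <- list()
  for (li in seq_along(lociNames)) {
    al <- .locusGeno(g, li)
    alleles <- sort(unique(as.vector(al[!is.na(al)])))
    alleleSets[[li]] <- alleles
    for (col in 1:2) {
      ok <- which(!is.na(al[, col]))
      ci <- c(ci, ok)
      cl <- c(cl, rep(li, length(ok)))
      ca <- c(ca, match(al[ok, col], alleles))
    }
  }
  nc <- length(ci)
  locusRows <- split(seq_len(nc), cl)

  if (K == 1L) {
    # single cluster: closed-form multinomial sampling of p only
    lnL <- numeric(sweeps - burnin)
    for (s in seq_len(sweeps - burnin)) {
      v <- 0
      for (li in seq_along(lociNames)) {
        rows <- locusRows[[as.character(li)]]
        cnt <- tabulate(ca[rows], nbins = length(alleleSets[[li]]))
        p <- as.vector(.rdirichlet(1, lambda + cnt))
        v <- v + sum(cnt * log(p))
      }
      lnL[s] <- v
    }
    Q <- matrix(1, n, 1, dimnames = list(rownames(g), "k1"))
    return(new("AdmixtureResult",
      K = 1L, Q = Q, lnLTrace = lnL,
      lnP = mean(lnL) - var(lnL) / 2, seed = as.integer(seed)
    ))
  }

  q <- matrix(1 / K, n, K)
  p <- lapply(alleleSets, function(alleles) {
    .rdirichlet(K, rep(lambda, length(alleles)))
  })
  z <- sample.int(K, nc, replace = TRUE)

  keep <- sweeps - burnin
  lnL <- numeric(keep)
  Qsum <- matrix(0, n, K)

  for (s in seq_len(sweeps)) {
    # z | p, q and the data log-likelihood sum_copies log sum_k q p
    W <- matrix(0, nc, K)
    for (li in seq_along(lociNames)) {
      rows <- locusRows[[as.character(li)]]
      W[rows, ] <- q[ci[rows], , drop = FALSE] * t(p[[li]])[ca[rows], , drop = FALSE]
    }
    rs <- rowSums(W)
    cs <- W
    for (k in 2:K) cs[, k] <- cs[, k - 1] + W[, k]
    u <- runif(nc) * rs
    z <- max.col(u <= cs, ties.method = "first")

    # p | z
    for (li in seq_along(lociNames)) {
      rows <- locusRows[[as.character(li)]]
      A <- length(alleleSets[[li]])
      cnt <- matrix(tabulate((z[rows] - 1L) * A + ca[rows], nbins = K * A), K, A, byrow = TRUE)
      gam <- matrix(rgamma(K * A, shape = lambda + cnt), K, A)
      p[[li]] <- gam / rowSums(gam)
    }

    # q | z
    cntQ <- matrix(tabulate((ci - 1L) * K + z, nbins = n * K), n, K, byrow = TRUE)
    gam <- matrix(rgamma(n * K, shape = alpha + cntQ), n, K)
    q <- gam / rowSums(gam)

    if (s > burnin) {
      lnL[s - burnin] <- sum(log(rs))
      Qsum <- Qsum + q
    }
  }
  Q <- Qsum / keep
  Q <- Q / rowSums(Q)
  dimnames(Q) <- list(rownames(g), paste0("k", seq_len(K)))
  new("AdmixtureResult",
    K = as.integer(K), Q = Q, lnLTrace = lnL,
    lnP = mean(lnL) - var(lnL) / 2, seed = as.integer(seed)
  )
}

#' Evanno delta-K from model log-probability estimates
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined for interior K only.
#'
#' @param lnP numeric matrix (runs x K values) with column names giving the
#'   K values, or a data.frame with columns `K` and `lnP`.
#' @return data.frame with columns K, meanLnP, sdLnP, deltaK (NA at the
#'   boundary and where sd is 0).
#' @export
evannoDeltaK <- function(lnP) {
  if (is.data.frame(lnP)) {
    ks <- sort(unique(lnP$K))
    meanL <- vapply(ks, function(k) mean(lnP$lnP[lnP$K == k]), 1.0)
    sdL <- vapply(ks, function(k) sd(lnP$lnP[lnP$K == k]), 1.0)
  } else {
    ks <- as.integer(colnames(lnP))
    if (anyNA(ks)) .stopf("lnP matrix needs K values as column names")
    meanL <- unname(colMeans(lnP))
    sdL <- unname(apply(lnP, 2, sd))
  }
  if (length(ks) < 3) .stopf("need >= 3 consecutive K values for delta-K")
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    if (is.na(sdL[i]) || sdL[i] == 0) next
    dk[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1]) / sdL[i]
  }
  data.frame(K = ks, meanLnP = meanL, sdLnP = sdL, deltaK = dk)
}

## Migrant detection ---------------------------------------------------------

.popCounts <- function(g, lociNames, alleleUniverse) {
  lapply(seq_along(lociNames), function(li) {
    al <- as.vector(.locusGeno(g, li))
    al <- al[!is.na(al)]
    cnt <- setNames(rep(0, length(alleleUniverse[[li]])), alleleUniverse[[li]])
    tb <- table(al)
    cnt[names(tb)] <- as.numeric(tb)
    cnt
  })
}

#' Detect first-generation migrants between two populations
#'
#' For each individual the genotype likelihood is computed against both
#' populations (leave-one-out in its home population) with a Dirichlet(1/A)
#' posterior-predictive smoother; the statistic is
#' `-log10(L_home / L_max)`. The null distribution comes from `nSim`
#' genotypes drawn from the home population's Dirichlet posterior-predictive
#' (Polya urn over the smoothed allele counts, matching the likelihood), and
#' `p = (1 + #{null >= obs}) / (1 + nSim)`; individuals with `p < alpha`
#' are flagged.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param labels population labels per individual (two populations).
#' @param nSim simulated individuals per population for the null.
#' @param alpha flagging threshold.
#' @param seed optional RNG seed.
#' @return data.frame with columns individual, home, lHome, lMax, stat, p,
#'   migrant.
#' @export
detectFirstGenMigrants <- function(catalog, labels, nSim = 10000L,
                                   alpha = 0.01, seed = NULL) {
  g <- genotypes(catalog)
  labels <- .alignLabels(labels, rownames(g))
  f <- factor(labels)
  if (nlevels(f) != 2) .stopf("exactly two populations required")
  popNames <- levels(f)
  if (any(table(f) < 10)) .warnf("a population has fewer than 10 individuals; assignment power is low")
  if (!is.null(seed)) set.seed(seed)
  lociNames <- loci(catalog)
  L <- length(lociNames)

  alleleUniverse <- lapply(seq_along(lociNames), function(li) {
    al <- as.vector(.locusGeno(g, li))
    sort(unique(al[!is.na(al)]))
  })
  tauByLocus <- vapply(alleleUniverse, function(u) 1 / max(1, length(u)), 1.0)
  countsByPop <- lapply(popNames, function(p) {
    .popCounts(g[labels == p, , drop = FALSE], lociNames, alleleUniverse)
  })
  names(countsByPop) <- popNames

  llik <- function(gInd, counts) {
    v <- 0
    for (li in seq_len(L)) {
      a <- gInd[2L * li - 1L]
      b <- gInd[2L * li]
      if (is.na(a)) next
      cnt <- counts[[li]]
      tau <- tauByLocus[li]
      tot <- sum(cnt) + length(cnt) * tau
      ca <- cnt[as.character(a)] + tau
      if (a == b) {
        v <- v + log10(ca * (ca + 1) / (tot * (tot + 1)))
      } else {
        cb <- cnt[as.character(b)] + tau
        v <- v + log10(2 * ca * cb / (tot * (tot + 1)))
      }
    }
    v
  }

  # null distributions per home population
  nullStats <- list()
  for (p in popNames) {
    cntHome <- countsByPop[[p]]
    other <- setdiff(popNames, p)
    cntOther <- countsByPop[[other]]
    # Polya-urn (Dirichlet posterior-predictive) draws, matching the
    # smoothed likelihood used for the observed statistic; drawing from
    # point-estimate frequencies instead ignores frequency-estimation
    # uncertainty and makes the null anti-conservative
    smoothed <- lapply(seq_len(L), function(li) cntHome[[li]] + tauByLocus[li])
    stats <- numeric(nSim)
    for (s in seq_len(nSim)) {
      gSim <- integer(2L * L)
      for (li in seq_len(L)) {
        cnt <- smoothed[[li]]
        a1 <- sample(names(cnt), 1, prob = cnt)
        cnt[a1] <- cnt[a1] + 1
        a2 <- sample(names(cnt), 1, prob = cnt)
        al <- as.integer(c(a1, a2))
        gSim[2L * li - 1L] <- min(al)
        gSim[2L * li] <- max(al)
      }
      lh <- llik(gSim, cntHome)
      lo <- llik(gSim, cntOther)
      stats[s] <- max(lh, lo) - lh
    }
    nullStats[[p]] <- stats
  }

  out <- data.frame(
    individual = rownames(g), home = labels,
    lHome = NA_real_, lMax = NA_real_, stat = NA_real_, p = NA_real_,
    migrant = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(g))) {
    home <- labels[i]
    other <- setdiff(popNames, home)
    # leave-one-out in the home population
    cntHome <- .popCounts(
      g[labels == home & rownames(g) != rownames(g)[i], , drop = FALSE],
      lociNames, alleleUniverse
    )
    lh <- llik(g[i, ], cntHome)
    lo <- llik(g[i, ], countsByPop[[other]])
    stat <- max(lh, lo) - lh
    pv <- (1 + sum(nullStats[[home]] >= stat - 1e-12)) / (1 + nSim)
    out$lHome[i] <- lh
    out$lMax[i] <- max(lh, lo)
    out$stat[i] <- stat
    out$p[i] <- pv
    out$migrant[i] <- pv < alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "nSim") <- as.integer(nSim)
  out
}
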