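## Diversity statistics, Hardy-Weinberg testing, maximum-likelihood
## inbreeding and Queller-Goodnight relatedness.

#' Per-locus diversity summary
#'
#' Computes, per locus: the number of genotyped individuals (N), allele count
#' (A), observed heterozygosity (Ho), unbiased expected heterozygosity
#' He = 2n/(2n-1) (1 - sum p_i^2), polymorphic information content
#' PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2, a Monte Carlo exact
#' Hardy-Weinberg p-value and its Bonferroni flag at family alpha
#' `bonferroniAlpha` over the tested loci. The final row holds unweighted
#' means across loci.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param hwePerms permutations for the Hardy-Weinberg test (0 skips it).
#' @param bonferroniAlpha family-wise alpha for the Bonferroni flag.
#' @param seed optional RNG seed for the permutation test.
#' @return data.frame with columns locus, N, A, Ho, He, HeRaw, PIC, hweP,
#'   hweSignif.
#' @export
diversitySummary <- function(catalog, hwePerms = 2000L, bonferroniAlpha = 0.01,
                             seed = NULL) {
  g <- genotypes(catalog)
  lociNames <- loci(catalog)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (li in seq_along(lociNames)) {
    al <- .locusGeno(g, li)
    al <- al[!is.na(al[, 1]) & !is.na(al[, 2]), , drop = FALSE]
    if (nrow(al) == 0) next
    if (nrow(al) < 2) .stopf("locus %s has fewer than 2 genotypes", lociNames[li])
    nInd <- nrow(al)
    tab <- table(as.vector(al))
    p <- as.numeric(tab) / sum(tab)
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    ho <- mean(al[, 1] != al[, 2])
    heRaw <- 1 - s2
    he <- (2 * nInd) / (2 * nInd - 1) * heRaw
    pic <- 1 - s2 - (s2^2 - s4)
    hweP <- if (hwePerms > 0) {
      if (length(p) < 2) 1 else hweTest(al, nPerm = hwePerms)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      locus = lociNames[li], N = nInd, A = length(p),
      Ho = ho, He = he, HeRaw = heRaw, PIC = pic, hweP = hweP,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  nTested <- sum(!is.na(out$hweP))
  out$hweSignif <- !is.na(out$hweP) & out$hweP < bonferroniAlpha / max(1, nTested)
  means <- data.frame(
    locus = "mean", N = NA_integer_, A = mean(out$A), Ho = mean(out$Ho),
    He = mean(out$He), HeRaw = mean(out$HeRaw), PIC = mean(out$PIC),
    hweP = NA_real_, hweSignif = NA, stringsAsFactors = FALSE
  )
  rbind(out, means)
}

# log conditional probability of a genotype array given its allele counts
# (Levene / Guo-Thompson): log[ n! 2^h prod(n_a!) / ((2n)! prod(n_ij!)) ]
.hweLogProb <- function(i1, i2, A) {
  n <- length(i1)
  het <- sum(i1 != i2)
  alleleCounts <- tabulate(c(i1, i2), nbins = A)
  genoKey <- (pmin(i1, i2) - 1L) * A + pmax(i1, i2)
  genoCounts <- tabulate(genoKey, nbins = A * A)
  lfactorial(n) + het * log(2) + sum(lfactorial(alleleCounts)) -
    lfactorial(2 * n) - sum(lfactorial(genoCounts))
}

#' Monte Carlo exact test of Hardy-Weinberg proportions
#'
#' The test statistic is the conditional probability of the observed genotype
#' array given its allele counts; the null distribution is generated by
#' randomly re-pairing the 2n allele copies. The p-value uses the add-one
#' estimator `(1 + #{perm <= obs}) / (1 + nPerm)`.
#'
#' @param genotypes integer matrix (individuals x 2) at one locus.
#' @param nPerm number of permutations.
#' @param seed optional RNG seed.
#' @return p-value; a monomorphic locus returns 1 with attribute `note`.
#' @export
hweTest <- function(genotypes, nPerm = 10000L, seed = NULL) {
  m <- matrix(as.integer(genotypes), ncol = 2)
  m <- m[!is.na(m[, 1]) & !is.na(m[, 2]), , drop = FALSE]
  if (nrow(m) < 5) .stopf("need >= 5 genotypes for the Hardy-Weinberg test")
  alleles <- sort(unique(as.vector(m)))
  if (length(alleles) < 2) {
    return(structure(1, note = "monomorphic locus"))
  }
  if (!is.null(seed)) set.seed(seed)
  A <- length(alleles)
  i1 <- match(m[, 1], alleles)
  i2 <- match(m[, 2], alleles)
  obs <- .hweLogProb(i1, i2, A)
  pool <- c(i1, i2)
  n <- length(i1)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    perm <- sample(pool)
    p1 <- perm[seq_len(n)]
    p2 <- perm[n + seq_len(n)]
    if (.hweLogProb(p1, p2, A) <= obs + 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + nPerm)
}

#' Maximum-likelihood individual inbreeding coefficient
#'
#' Maximizes over f in [0, 1] the likelihood of the multilocus genotype
#' where a homozygote ii has probability \eqn{f p_i + (1-f) p_i^2} and a
#' heterozygote ij has \eqn{(1-f) 2 p_i p_j}, using Brent optimization with
#' explicit endpoint checks.
#'
#' @param genotype integer vector (2 values per locus, NA for missing loci)
#'   or a 1-row genotype matrix.
#' @param freqs an [AlleleFrequencyTable-class] covering the alleles.
#' @return estimated f in [0, 1].
#' @export
inbreedingF <- function(genotype, freqs) {
  g <- as.integer(genotype)
  lociNames <- loci(freqs)
  if (length(g) != 2L * length(lociNames)) {
    .stopf("genotype length must be 2 x number of loci in the frequency table")
  }
  homP <- c()
  hetP <- list()
  for (li in seq_along(lociNames)) {
    a <- g[2L * li - 1L]
    b <- g[2L * li]
    if (is.na(a) || is.na(b)) next
    p <- alleleFreqs(freqs, lociNames[li])
    pa <- p[as.character(a)]
    pb <- p[as.character(b)]
    if (is.na(pa) || is.na(pb)) .stopf("allele %s at %s absent from frequency table", a, lociNames[li])
    if (a == b) homP <- c(homP, as.numeric(pa)) else hetP[[length(hetP) + 1L]] <- as.numeric(c(pa, pb))
  }
  if (!length(homP) && !length(hetP)) .stopf("individual typed at 0 loci: f undefined")
  ll <- function(f) {
    v <- 0
    for (pa in homP) v <- v + log(f * pa + (1 - f) * pa^2)
    for (pp in hetP) v <- v + log((1 - f) * 2 * pp[1] * pp[2])
    v
  }
  cand <- c(0, if (!length(hetP)) 1)
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(cand, opt$maximum)
  vals <- vapply(cand, ll, 1.0)
  f <- cand[which.max(vals)]
  min(max(f, 0), 1)
}

#' Per-individual inbreeding coefficients for a catalog
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param freqs optional frequency table (defaults to frequencies estimated
#'   from the catalog itself).
#' @return named numeric vector of f estimates.
#' @export
inbreedingCoefficients <- function(catalog, freqs = alleleFrequencyTable(catalog)) {
  g <- genotypes(catalog)
  setNames(
    vapply(seq_len(nrow(g)), function(i) inbreedingF(g[i, ], freqs), 1.0),
    rownames(g)
  )
}

# Queller & Goodnight (1989) single-orientation numerator/denominator sums
.qgSums <- function(gx, gy, freqs, lociNames) {
  num <- 0
  den <- 0
  for (li in seq_along(lociNames)) {
    a <- gx[2L * li - 1L]
    b <- gx[2L * li]
    c_ <- gy[2L * li - 1L]
    d <- gy[2L * li]
    if (is.na(a) || is.na(c_)) next
    p <- alleleFreqs(freqs, lociNames[li])
    pa <- as.numeric(p[as.character(a)])
    pb <- as.numeric(p[as.character(b)])
    if (is.na(pa) || is.na(pb)) next
    sim <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
    num <- num + sim - pa - pb
    den <- den + 1 + (a == b) - pa - pb
  }
  c(num = num, den = den)
}

#' Queller-Goodnight pairwise relatedness
#'
#' Moment estimator of pairwise relatedness, locus-pooled by summing
#' numerators and denominators across loci and symmetrized by averaging the
#' two focal-individual orientations.
#'
#' @param g1,g2 genotype vectors (2 values per locus).
#' @param freqs an [AlleleFrequencyTable-class] object.
#' @return relatedness estimate (may fall outside [-1, 1]; NA when both
#'   orientations have zero denominators).
#' @export
quellerGoodnightR <- function(g1, g2, freqs) {
  lociNames <- loci(freqs)
  s1 <- .qgSums(as.integer(g1), as.integer(g2), freqs, lociNames)
  s2 <- .qgSums(as.integer(g2), as.integer(g1), freqs, lociNames)
  ok1 <- abs(s1["den"]) > 1e-12
  ok2 <- abs(s2["den"]) > 1e-12
  if (!ok1 && !ok2) {
    return(NA_real_)
  }
  if (ok1 && ok2) {
    return(as.numeric((s1["num"] / s1["den"] + s2["num"] / s2["den"]) / 2))
  }
  s <- if (ok1) s1 else s2
  as.numeric(s["num"] / s["den"])
}

#' Pairwise relatedness matrix for a catalog
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param freqs optional frequency table (defaults to catalog frequencies).
#' @param clamp clamp estimates into [-1, 1] (the raw value is kept in
#'   attribute `raw`).
#' @return symmetric numeric matrix with NA diagonal.
#' @export
relatednessMatrix <- function(catalog, freqs = alleleFrequencyTable(catalog),
                              clamp = TRUE) {
  g <- genotypes(catalog)
  n <- nrow(g)
  r <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r[i, j] <- r[j, i] <- quellerGoodnightR(g[i, ], g[j, ], freqs)
    }
  }
  raw <- r
  if (clamp) r[] <- pmin(1, pmax(-1, r))
  attr(r, "raw") <- raw
  r
}

#' Bin values into low / moderate / high classes
#'
#' Bins follow the conventions `[0, t1)`, `[t1, t2)`, `[t2, Inf)`; the
#' default thresholds 0.125 and 0.25 are the usual inbreeding cutoffs.
#'
#' @param values numeric vector (NA dropped).
#' @param thresholds two increasing bin boundaries.
#' @return list with `proportions` (named length-3), `counts`, `mean` and
#'   `n`.
#' @export
binSummary <- function(values, thresholds = c(0.125, 0.25)) {
  v <- values[is.finite(values)]
  if (!length(v)) .stopf("no finite values to bin")
  lab <- c("low", "moderate", "high")
  cls <- cut(v, c(-Inf, thresholds, Inf), labels = lab, right = FALSE)
  counts <- table(cls)
  list(
    proportions = setNames(as.numeric(counts) / length(v), lab),
    counts = setNames(as.integer(counts), lab),
    mean = mean(v), n = length(v)
  )
}
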