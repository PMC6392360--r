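## Multi-tubes consensus genotyping: replicate PCR calls are accepted into a
## single-locus consensus only when they repeat often enough to rule out
## allelic dropout and false alleles.

#' Call the consensus genotype of one locus from replicate PCRs
#'
#' A homozygote is accepted only after `minHomReps` identical homozygote
#' replicates; a heterozygote after `minHetReps` identical heterozygote
#' replicates. When both a qualifying homozygote and a qualifying
#' heterozygote are present the heterozygote wins: allelic dropout readily
#' produces spurious homozygote replicates from a true heterozygote, while
#' the reverse would require recurrent identical false alleles.
#'
#' @param replicates integer matrix (replicates x 2) of allele calls; rows
#'   containing NA are failed amplifications and are ignored.
#' @param minHomReps,minHetReps acceptance thresholds.
#' @return list with `status` (`accepted`, `pending` or `missing`), `alleles`
#'   (sorted pair or NA) and `support` (count of the accepted profile).
#' @examples
#' callConsensusLocus(rbind(c(120, 120), c(120, 120), c(120, 120)))
#' callConsensusLocus(rbind(c(120, 124), c(124, 120)))
#' @export
callConsensusLocus <- function(replicates, minHomReps = 3L, minHetReps = 2L) {
  if (is.null(replicates) || !nrow(replicates)) {
    .stopf("at least one replicate is required")
  }
  m <- matrix(as.integer(replicates), ncol = 2)
  ok <- !is.na(m[, 1]) & !is.na(m[, 2])
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) {
    return(list(status = "missing", alleles = c(NA_integer_, NA_integer_), support = 0L))
  }
  lo <- pmin(m[, 1], m[, 2])
  hi <- pmax(m[, 1], m[, 2])
  key <- paste(lo, hi)
  tab <- table(key)
  isHet <- vapply(strsplit(names(tab), " "), function(p) p[1] != p[2], TRUE)

  pick <- function(counts) {
    # deterministic: highest support first, then lowest allele pair
    nm <- names(counts)[order(-as.integer(counts), names(counts))][1]
    list(
      alleles = as.integer(strsplit(nm, " ")[[1]]),
      support = as.integer(counts[nm])
    )
  }
  hets <- tab[isHet & tab >= minHetReps]
  homs <- tab[!isHet & tab >= minHomReps]
  if (length(hets)) {
    hit <- pick(hets)
    return(list(status = "accepted", alleles = hit$alleles, support = hit$support))
  }
  if (length(homs)) {
    hit <- pick(homs)
    return(list(status = "accepted", alleles = hit$alleles, support = hit$support))
  }
  list(status = "pending", alleles = c(NA_integer_, NA_integer_), support = 0L)
}

#' Call consensus genotypes for every sample and locus
#'
#' @param x a [ScatSamples-class] object.
#' @param minHomReps,minHetReps per-locus acceptance thresholds (see
#'   [callConsensusLocus()]).
#' @return `x` with the `consensus` and `status` slots filled.
#' @export
callConsensus <- function(x, minHomReps = 3L, minHetReps = 2L) {
  loci <- x@loci
  n <- nrow(x@samples)
  cons <- matrix(NA_integer_, n, 2L * length(loci), dimnames = list(NULL, .locusCols(loci)))
  status <- matrix("missing", n, length(loci), dimnames = list(NULL, loci))
  for (i in seq_len(n)) {
    for (li in seq_along(loci)) {
      m <- x@replicates[[i]][[li]]
      if (is.null(m) || !nrow(m)) next
      cc <- callConsensusLocus(m, minHomReps, minHetReps)
      status[i, li] <- cc$status
      if (cc$status == "accepted") {
        cons[i, 2L * li - 1L] <- cc$alleles[1]
        cons[i, 2L * li] <- cc$alleles[2]
      }
    }
  }
  x@consensus <- cons
  x@status <- status
  validObject(x)
  x
}

#' Estimate allelic dropout and false-allele rates from replicates
#'
#' Replicates are compared against the accepted consensus of their sample.
#' The dropout rate of a locus is the fraction of replicates of
#' heterozygote-consensus samples that show exactly one consensus allele as a
#' homozygote; the false-allele rate is the fraction of replicates of
#' accepted samples containing an allele absent from the consensus.
#'
#' @param x a [ScatSamples-class] object after [callConsensus()].
#' @return data.frame with one row per locus plus a pooled row; `NA` rates
#'   mark loci without an informative comparison.
#' @export
estimateErrorRates <- function(x) {
  if (nrow(x@status) == 0) .stopf("run callConsensus() first")
  loci <- x@loci
  out <- data.frame(
    locus = c(loci, "pooled"), dropout = NA_real_, falseAllele = NA_real_,
    nDropoutReps = 0L, nFalseReps = 0L, stringsAsFactors = FALSE
  )
  doNum <- doDen <- faNum <- faDen <- integer(length(loci))
  for (li in seq_along(loci)) {
    for (i in seq_len(nrow(x@samples))) {
      if (x@status[i, li] != "accepted") next
      a <- x@consensus[i, 2L * li - 1L]
      b <- x@consensus[i, 2L * li]
      m <- x@replicates[[i]][[li]]
      m <- m[!is.na(m[, 1]) & !is.na(m[, 2]), , drop = FALSE]
      if (!nrow(m)) next
      faDen[li] <- faDen[li] + nrow(m)
      faNum[li] <- faNum[li] + sum(!(m[, 1] %in% c(a, b)) | !(m[, 2] %in% c(a, b)))
      if (a != b) {
        doDen[li] <- doDen[li] + nrow(m)
        isDrop <- (m[, 1] == m[, 2]) & (m[, 1] == a | m[, 1] == b)
        doNum[li] <- doNum[li] + sum(isDrop)
      }
    }
    if (doDen[li] > 0) out$dropout[li] <- doNum[li] / doDen[li]
    if (faDen[li] > 0) out$falseAllele[li] <- faNum[li] / faDen[li]
    out$nDropoutReps[li] <- doDen[li]
    out$nFalseReps[li] <- faDen[li]
  }
  pl <- length(loci) + 1L
  if (sum(doDen) > 0) out$dropout[pl] <- sum(doNum) / sum(doDen)
  if (sum(faDen) > 0) out$falseAllele[pl] <- sum(faNum) / sum(faDen)
  out$nDropoutReps[pl] <- sum(doDen)
  out$nFalseReps[pl] <- sum(faDen)
  out
}

#' EM estimate of the null-allele frequency at one locus
#'
#' Treats the observed homozygote excess as a mixture of true homozygotes and
#' heterozygotes carrying a non-amplifying (null) allele under random mating,
#' in the style of the Dempster expectation-maximization estimators used by
#' FreeNA-type tools. When the number of completely non-amplifying (blank)
#' individuals at the locus is known it sharpens the estimate; without it the
#' estimator conditions on observable genotypes and is slightly conservative.
#'
#' @param genotypes integer matrix (individuals x 2) of accepted genotypes at
#'   one locus (no NA rows).
#' @param nBlank number of individuals that failed to amplify at this locus
#'   (candidate null homozygotes), if known.
#' @param minN minimum number of genotyped individuals required.
#' @param tol convergence tolerance on successive estimates.
#' @param maxIter iteration cap.
#' @return estimated null-allele frequency in `[0, 1)`; a monomorphic locus
#'   returns 0 with attribute `note`.
#' @export
estimateNullAlleleFreq <- function(genotypes, nBlank = 0L, minN = 10L,
                                   tol = 1e-8, maxIter = 10000L) {
  m <- matrix(as.integer(genotypes), ncol = 2)
  m <- m[!is.na(m[, 1]) & !is.na(m[, 2]), , drop = FALSE]
  if (nrow(m) < minN) .stopf("need >= %d genotyped individuals, got %d", minN, nrow(m))
  alleles <- sort(unique(as.vector(m)))
  if (length(alleles) < 2 && nBlank == 0) {
    return(structure(0, note = "monomorphic locus"))
  }
  A <- length(alleles)
  i1 <- match(m[, 1], alleles)
  i2 <- match(m[, 2], alleles)
  hom <- i1 == i2
  nInd <- nrow(m) + nBlank
  copies <- 2 * nInd

  # visible-allele copy counts fixed by the heterozygotes; homozygotes split
  # between true homozygote (2 copies) and null heterozygote (1 copy + null)
  hetCount <- tabulate(c(i1[!hom], i2[!hom]), nbins = A)
  homCount <- tabulate(i1[hom], nbins = A) # individuals, not copies

  pn <- 0.05
  p <- (hetCount + 2 * homCount) / sum(hetCount + 2 * homCount) * (1 - pn)
  for (it in seq_len(maxIter)) {
    h <- ifelse(homCount > 0, 2 * pn / (p[seq_len(A)] + 2 * pn), 0)
    nullCopies <- sum(homCount * h) + 2 * nBlank
    visCopies <- hetCount + homCount * (2 - h)
    pNew <- visCopies / copies
    pnNew <- nullCopies / copies
    if (max(abs(c(pNew, pnNew) - c(p, pn))) < tol) {
      return(pnNew)
    }
    p <- pNew
    pn <- pnNew
  }
  .stopf("null-allele EM did not converge within %d iterations", maxIter)
}

#' Null-allele frequency estimates for every locus of a catalog
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param minN minimum genotyped individuals per locus.
#' @return named numeric vector of per-locus estimates (NA where undefined).
#' @export
nullAlleleFrequencies <- function(catalog, minN = 10L) {
  g <- genotypes(catalog)
  out <- setNames(rep(NA_real_, length(catalog@loci)), catalog@loci)
  for (li in seq_along(catalog@loci)) {
    al <- .locusGeno(g, li)
    al <- al[!is.na(al[, 1]) & !is.na(al[, 2]), , drop = FALSE]
    if (nrow(al) >= minN) {
      out[li] <- as.numeric(estimateNullAlleleFreq(al, minN = minN))
    }
  }
  out
}

#' Samples usable for individual identification
#'
#' A sample is usable when at least `minLoci` loci have an accepted
#' consensus. Samples with exactly `rescueLoci` accepted loci are rescued
#' when their nearest usable sample lies further than `rescueDistance`
#' meters, mirroring the treatment of spatially isolated low-coverage
#' samples.
#'
#' @param x a [ScatSamples-class] object after [callConsensus()].
#' @param minLoci minimum accepted loci.
#' @param rescueLoci accepted-locus count eligible for distance rescue.
#' @param rescueDistance rescue distance in meters.
#' @return logical vector over samples.
#' @export
usableSamples <- function(x, minLoci = 6L, rescueLoci = 5L, rescueDistance = 2000) {
  if (nrow(x@status) == 0) .stopf("run callConsensus() first")
  nAcc <- rowSums(x@status == "accepted")
  usable <- nAcc >= minLoci
  cand <- which(nAcc == rescueLoci)
  if (length(cand) && any(usable)) {
    ux <- x@samples$x[usable]
    uy <- x@samples$y[usable]
    for (i in cand) {
      dmin <- sqrt(min((ux - x@samples$x[i])^2 + (uy - x@samples$y[i])^2))
      if (dmin > rescueDistance) usable[i] <- TRUE
    }
  } else if (length(cand) && !any(usable)) {
    usable[cand] <- TRUE
  }
  usable
}

#' Samples flagged for re-amplification
#'
#' Lists samples with pending locus calls, the in-silico stand-in for
#' requesting additional PCR replicates in the lab.
#'
#' @param x a [ScatSamples-class] object after [callConsensus()].
#' @return data.frame with columns `sample`, `locus`, `nReplicates`.
#' @export
flaggedSamples <- function(x) {
  if (nrow(x@status) == 0) .stopf("run callConsensus() first")
  idx <- which(x@status == "pending", arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(sample = character(), locus = character(), nReplicates = integer()))
  }
  data.frame(
    sample = x@samples$sample[idx[, 1]],
    locus = x@loci[idx[, 2]],
    nReplicates = mapply(function(i, l) nrow(x@replicates[[i]][[l]]), idx[, 1], idx[, 2]),
    stringsAsFactors = FALSE
  )
}
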