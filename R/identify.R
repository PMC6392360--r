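## Probability of identity, genotype matching into individuals, capture
## histories.

#' Build an allele frequency table from an individual catalog
#'
#' @param catalog an [IndividualCatalog-class] object (or an integer genotype
#'   matrix with 2 columns per locus and locus names via `lociNames`).
#' @param lociNames locus names when `catalog` is a bare matrix.
#' @return An [AlleleFrequencyTable-class] object.
#' @export
alleleFrequencyTable <- function(catalog, lociNames = NULL) {
  if (is(catalog, "IndividualCatalog")) {
    g <- genotypes(catalog)
    lociNames <- loci(catalog)
  } else {
    g <- catalog
    if (is.null(lociNames)) .stopf("lociNames required for a bare genotype matrix")
  }
  freqs <- list()
  nCopies <- integer(length(lociNames))
  for (li in seq_along(lociNames)) {
    al <- as.vector(.locusGeno(g, li))
    al <- al[!is.na(al)]
    if (!length(al)) .stopf("locus %s has no genotypes", lociNames[li])
    tab <- table(al)
    freqs[[lociNames[li]]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
    nCopies[li] <- length(al)
  }
  new("AlleleFrequencyTable", freqs = freqs, nCopies = setNames(nCopies, lociNames))
}

#' Construct an AlleleFrequencyTable from explicit frequencies
#'
#' @param freqs named list per locus of named numeric frequency vectors.
#' @param nCopies allele copies counted per locus (defaults to a nominal
#'   large sample when frequencies are theoretical).
#' @return An [AlleleFrequencyTable-class] object.
#' @export
makeFrequencyTable <- function(freqs, nCopies = NULL) {
  if (is.null(nCopies)) nCopies <- setNames(rep(1000L, length(freqs)), names(freqs))
  freqs <- lapply(freqs, function(p) p / sum(p))
  new("AlleleFrequencyTable", freqs = freqs, nCopies = setNames(as.integer(nCopies), names(freqs)))
}

.pidLocusUnrelated <- function(p) {
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  2 * s2^2 - s4
}

.pidLocusSib <- function(p) {
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Probability of identity for unrelated individuals
#'
#' Probability that two unrelated individuals drawn from Hardy-Weinberg
#' proportions share an identical multilocus genotype:
#' per locus \eqn{2(\sum p_i^2)^2 - \sum p_i^4}, multiplied across loci.
#'
#' @param freqs an [AlleleFrequencyTable-class] object.
#' @param lociSubset loci to include (default all).
#' @return probability in (0, 1].
#' @export
pidUnrelated <- function(freqs, lociSubset = loci(freqs)) {
  if (!length(lociSubset)) .stopf("empty locus subset")
  missing <- setdiff(lociSubset, loci(freqs))
  if (length(missing)) .stopf("locus %s not in frequency table", missing[1])
  prod(vapply(lociSubset, function(l) .pidLocusUnrelated(alleleFreqs(freqs, l)), 1.0))
}

#' Probability of identity for full siblings
#'
#' Per locus \eqn{0.25 + 0.5\sum p_i^2 + 0.5(\sum p_i^2)^2 - 0.25\sum p_i^4},
#' multiplied across loci; always at least as large as [pidUnrelated()] on
#' the same input.
#'
#' @inheritParams pidUnrelated
#' @return probability in (0, 1].
#' @export
pidSib <- function(freqs, lociSubset = loci(freqs)) {
  if (!length(lociSubset)) .stopf("empty locus subset")
  missing <- setdiff(lociSubset, loci(freqs))
  if (length(missing)) .stopf("locus %s not in frequency table", missing[1])
  prod(vapply(lociSubset, function(l) .pidLocusSib(alleleFreqs(freqs, l)), 1.0))
}

#' Rank loci by single-locus sibling probability of identity
#'
#' Loci are ordered most-informative first (ascending per-locus PIDsib),
#' giving a deterministic "best k loci" convention.
#'
#' @param freqs an [AlleleFrequencyTable-class] object.
#' @param k number of loci to return (default all, ranked).
#' @return character vector of locus names.
#' @export
bestLociSubset <- function(freqs, k = length(loci(freqs))) {
  v <- vapply(loci(freqs), function(l) .pidLocusSib(alleleFreqs(freqs, l)), 1.0)
  head(names(sort(v)), k)
}

# mismatching alleles between two genotype rows over co-typed loci:
# per locus 2 - |multiset intersection|
.pairMismatch <- function(g1, g2, L) {
  mm <- 0L
  co <- 0L
  for (li in seq_len(L)) {
    a1 <- g1[2L * li - 1L]
    b1 <- g1[2L * li]
    a2 <- g2[2L * li - 1L]
    b2 <- g2[2L * li]
    if (is.na(a1) || is.na(a2)) next
    co <- co + 1L
    # pairs are stored sorted, so the multiset intersection size reduces to:
    inter <- if (a1 == a2 && b1 == b2) {
      2L
    } else if (a1 == a2 || b1 == b2 || a1 == b2 || b1 == a2) 1L else 0L
    mm <- mm + (2L - inter)
  }
  c(mismatch = mm, cotyped = co)
}

#' Match consensus genotypes into individuals
#'
#' Samples whose consensus genotypes agree at every co-typed locus are merged
#' into one individual. Pairs differing by exactly one allele are placed on a
#' review queue requesting replicate confirmation: a `review` answer of
#' `TRUE` (difference confirmed) keeps them distinct, `FALSE` merges them;
#' without an answer the pair stays split, which biases abundance upward in a
#' predictable, conservative direction. Pairs differing by two or more
#' alleles are always distinct.
#'
#' @param x a [ScatSamples-class] object after [callConsensus()].
#' @param minLoci,rescueLoci,rescueDistance usability rules, see
#'   [usableSamples()].
#' @param review either `NULL` (split all one-mismatch pairs), a function
#'   `function(sample1, sample2) -> logical` (TRUE = confirmed different), or
#'   a data.frame with columns `sample1`, `sample2`, `different`.
#' @return list with `catalog` (an [IndividualCatalog-class]), `reviewQueue`
#'   (data.frame of one-mismatch pairs and their resolution) and `usable`
#'   (logical vector over samples).
#' @export
matchGenotypes <- function(x, minLoci = 6L, rescueLoci = 5L,
                           rescueDistance = 2000, review = NULL) {
  usable <- usableSamples(x, minLoci, rescueLoci, rescueDistance)
  idx <- which(usable)
  if (!length(idx)) .stopf("no usable samples (>= %d accepted loci)", minLoci)
  g <- x@consensus[idx, , drop = FALSE]
  ids <- x@samples$sample[idx]
  n <- length(idx)
  L <- length(x@loci)

  # pairwise mismatch counts
  mm <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pm <- .pairMismatch(g[i, ], g[j, ], L)
      mm[i, j] <- mm[j, i] <- if (pm["cotyped"] == 0L) 99L else pm[["mismatch"]]
    }
  }

  # union-find over exact matches (rule a)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mm[i, j] == 0L) unite(i, j)
    }
  }

  # one-mismatch pairs across clusters -> review queue (rule b)
  queue <- data.frame(
    sample1 = character(), sample2 = character(),
    different = logical(), resolved = character(), stringsAsFactors = FALSE
  )
  answer <- function(s1, s2) {
    if (is.null(review)) return(NA)
    if (is.function(review)) return(isTRUE(review(s1, s2)))
    hit <- which((review$sample1 == s1 & review$sample2 == s2) |
                   (review$sample1 == s2 & review$sample2 == s1))
    if (!length(hit)) return(NA)
    isTRUE(review$different[hit[1]])
  }
  pairs <- which(mm == 1L & upper.tri(mm), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      if (find(i) == find(j)) next
      ans <- answer(ids[i], ids[j])
      res <- if (is.na(ans)) {
        "unreviewed-split"
      } else if (ans) "confirmed-different" else "merged"
      if (!is.na(ans) && !ans) {
        # merging is only applied when it creates no >= 2 mismatch conflict
        ci <- which(vapply(seq_len(n), function(k) find(k) == find(i), TRUE))
        cj <- which(vapply(seq_len(n), function(k) find(k) == find(j), TRUE))
        conflict <- any(mm[ci, cj, drop = FALSE] >= 2L & mm[ci, cj, drop = FALSE] != 99L)
        if (conflict) {
          res <- "merge-conflict-split"
        } else {
          unite(i, j)
        }
      }
      queue <- rbind(queue, data.frame(
        sample1 = ids[i], sample2 = ids[j],
        different = if (is.na(ans)) NA else ans, resolved = res,
        stringsAsFactors = FALSE
      ))
    }
  }

  roots <- vapply(seq_len(n), find, 1L)
  clusters <- split(seq_len(n), roots)

  # individual consensus genotype: per locus the most supported accepted call
  dates <- x@samples$date[idx]
  firstDate <- vapply(clusters, function(cl) min(as.numeric(dates[cl])), 1.0)
  ord <- order(firstDate, vapply(clusters, function(cl) min(ids[cl]), ""))
  clusters <- clusters[ord]
  indIds <- sprintf("IND%03d", seq_along(clusters))

  gm <- matrix(NA_integer_, length(clusters), 2L * L)
  capRows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    for (li in seq_len(L)) {
      calls <- g[cl, c(2L * li - 1L, 2L * li), drop = FALSE]
      calls <- calls[!is.na(calls[, 1]), , drop = FALSE]
      if (!nrow(calls)) next
      key <- paste(calls[, 1], calls[, 2])
      best <- names(sort(table(key), decreasing = TRUE))[1]
      gm[ci, c(2L * li - 1L, 2L * li)] <- as.integer(strsplit(best, " ")[[1]])
    }
    si <- idx[cl]
    capRows[[ci]] <- data.frame(
      individual = indIds[ci],
      sample = x@samples$sample[si],
      date = x@samples$date[si],
      x = x@samples$x[si], y = x@samples$y[si],
      cell = x@samples$cell[si],
      stringsAsFactors = FALSE
    )
  }
  rownames(gm) <- indIds
  catalog <- IndividualCatalog(gm, x@loci, do.call(rbind, capRows))
  list(catalog = catalog, reviewQueue = queue, usable = usable)
}

#' Build capture histories from a catalog
#'
#' Occasions are equal-count quantile bins of the capture dates; detectors
#' default to the survey cells of the samples (falling back to one nominal
#' detector when no cells are recorded).
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param occasions number of sampling occasions.
#' @param detectorCoords optional data.frame with columns `detector`, `x`,
#'   `y` giving detector (survey-cell centroid) coordinates; defaults to the
#'   mean capture location per cell.
#' @return A [CaptureHistory-class] object.
#' @export
buildCaptureHistory <- function(catalog, occasions = 30L, detectorCoords = NULL) {
  cap <- captures(catalog)
  if (anyNA(cap$date)) {
    .stopf(
      "undated capture events: %s",
      paste(head(cap$sample[is.na(cap$date)], 5), collapse = ", ")
    )
  }
  if (!.isCount(occasions)) .stopf("occasions must be a positive integer")
  occasions <- as.integer(occasions)

  dnum <- as.numeric(cap$date)
  if (occasions == 1L) {
    brks <- c(min(dnum) - 0.5, max(dnum) + 0.5)
  } else {
    qs <- quantile(dnum, probs = seq(0, 1, length.out = occasions + 1L), type = 1)
    qs[1] <- qs[1] - 0.5
    qs[length(qs)] <- qs[length(qs)] + 0.5
    brks <- cummax(qs + seq(0, 1e-6, length.out = length(qs)))
  }
  occ <- cut(dnum, breaks = brks, labels = FALSE, include.lowest = TRUE)

  det <- cap$cell
  if (all(is.na(det))) det <- rep("D1", nrow(cap))
  det[is.na(det)] <- "unplaced"
  if (is.null(detectorCoords)) {
    detectorCoords <- aggregate(cbind(x, y) ~ det, data = data.frame(det = det, x = cap$x, y = cap$y), FUN = mean)
    names(detectorCoords) <- c("detector", "x", "y")
  }

  counts <- aggregate(
    list(n = rep(1L, nrow(cap))),
    by = list(individual = cap$individual, occasion = occ, detector = det),
    FUN = sum
  )
  tot <- table(cap$individual)
  totals <- setNames(as.integer(tot), names(tot))
  new("CaptureHistory",
    totals = totals, counts = counts,
    occasionBreaks = as.Date(brks, origin = "1970-01-01"),
    detectors = detectorCoords
  )
}
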