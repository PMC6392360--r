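## Generics and accessors. Slot access from user code should go through these.

#' Locus names
#' @param x a scatCMR data object
#' @return character vector of locus names
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname loci
#' @export
setMethod("loci", "ScatSamples", function(x) x@loci)

#' @rdname loci
#' @export
setMethod("loci", "IndividualCatalog", function(x) x@loci)

#' @rdname loci
#' @export
setMethod("loci", "AlleleFrequencyTable", function(x) names(x@freqs))

#' Number of samples
#' @param x a [ScatSamples-class] object
#' @return integer
#' @export
nSamples <- function(x) nrow(x@samples)

#' Sample metadata table
#' @param x a [ScatSamples-class] object
#' @return data.frame of per-sample metadata
#' @export
sampleInfo <- function(x) x@samples

#' Replicate allele calls of one sample
#' @param x a [ScatSamples-class] object
#' @param sample sample id
#' @return named list over loci of integer matrices (replicates x 2)
#' @export
sampleReplicates <- function(x, sample) {
  i <- match(sample, x@samples$sample)
  if (is.na(i)) .stopf("unknown sample id '%s'", sample)
  x@replicates[[i]]
}

#' Consensus genotype matrix of a ScatSamples object
#' @param x a [ScatSamples-class] object after [callConsensus()]
#' @return integer matrix (samples x 2*loci)
#' @export
consensusGenotypes <- function(x) {
  if (nrow(x@consensus) == 0) .stopf("consensus has not been called yet; run callConsensus()")
  g <- x@consensus
  rownames(g) <- x@samples$sample
  g
}

#' Per-locus consensus status matrix
#' @param x a [ScatSamples-class] object after [callConsensus()]
#' @return character matrix (samples x loci) of accepted/pending/missing
#' @export
consensusStatus <- function(x) {
  if (nrow(x@status) == 0) .stopf("consensus has not been called yet; run callConsensus()")
  s <- x@status
  dimnames(s) <- list(x@samples$sample, x@loci)
  s
}

#' Number of individuals in a catalog
#' @param x an [IndividualCatalog-class] object
#' @return integer
#' @export
nIndividuals <- function(x) nrow(x@genotypes)

#' Genotype matrix of a catalog
#' @param x an [IndividualCatalog-class] object
#' @return integer matrix (individuals x 2*loci), rownames individual ids
#' @export
genotypes <- function(x) x@genotypes

#' Capture events of a catalog
#' @param x an [IndividualCatalog-class] or [CaptureHistory-class] object
#' @return data.frame of capture events / counts
#' @export
captures <- function(x) {
  if (is(x, "IndividualCatalog")) return(x@captures)
  if (is(x, "CaptureHistory")) return(x@counts)
  .stopf("no captures for class %s", class(x))
}

#' Allele frequencies of one locus
#' @param x an [AlleleFrequencyTable-class] object
#' @param locus locus name (omit for the full list)
#' @return named numeric vector of frequencies, or the full list
#' @export
alleleFreqs <- function(x, locus = NULL) {
  if (is.null(locus)) return(x@freqs)
  if (!locus %in% names(x@freqs)) .stopf("unknown locus '%s'", locus)
  x@freqs[[locus]]
}

#' Allele copies counted per locus (2n)
#' @param x an [AlleleFrequencyTable-class] object
#' @return named integer vector
#' @export
alleleCopies <- function(x) x@nCopies

#' Per-individual capture totals
#' @param x a [CaptureHistory-class] object
#' @return named integer vector
#' @export
captureTotals <- function(x) x@totals

#' Detector coordinates of a capture history
#' @param x a [CaptureHistory-class] object
#' @return data.frame with columns detector, x, y
#' @export
detectors <- function(x) x@detectors

#' Density raster values
#' @param x a [DensitySurface-class] object
#' @return numeric matrix (per square meter)
#' @export
surfaceValues <- function(x) x@values

#' Tier raster of a density surface
#' @param x a [DensitySurface-class] object after [classifyTiers()]
#' @return character matrix with values none/low/medium/high
#' @export
surfaceTiers <- function(x) {
  if (nrow(x@tiers) == 0) .stopf("tiers not classified yet; run classifyTiers()")
  x@tiers
}

## show methods -------------------------------------------------------------

setMethod("show", "ScatSamples", function(object) {
  cat(sprintf(
    "ScatSamples: %d samples, %d loci (%s)\n",
    nrow(object@samples), length(object@loci),
    paste(head(object@loci, 4), collapse = ", ")
  ))
  if (nrow(object@status) > 0) {
    acc <- mean(object@status == "accepted")
    cat(sprintf("  consensus called: %.1f%% locus calls accepted\n", 100 * acc))
  } else {
    cat("  consensus not yet called\n")
  }
})

setMethod("show", "IndividualCatalog", function(object) {
  tot <- table(object@captures$individual)
  cat(sprintf(
    "IndividualCatalog: %d individuals from %d samples (mean %.2f captures)\n",
    nrow(object@genotypes), nrow(object@captures),
    if (length(tot)) mean(tot) else NA_real_
  ))
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  a <- vapply(object@freqs, length, 1L)
  cat(sprintf(
    "AlleleFrequencyTable: %d loci, %d-%d alleles per locus\n",
    length(a), if (length(a)) min(a) else 0L, if (length(a)) max(a) else 0L
  ))
})

setMethod("show", "CaptureHistory", function(object) {
  cat(sprintf(
    "CaptureHistory: %d individuals, %d captures over %d occasions, %d detectors\n",
    length(object@totals), sum(object@totals),
    length(object@occasionBreaks) - 1L, nrow(object@detectors)
  ))
  cat(sprintf(
    "  recaptured >= 2 times: %d (%.0f%%); mean captures %.2f\n",
    sum(object@totals >= 2L),
    100 * mean(object@totals >= 2L), mean(object@totals)
  ))
})

setMethod("show", "DensitySurface", function(object) {
  cat(sprintf(
    "DensitySurface: %d x %d cells of %.0f m; integral %.2f kernels\n",
    nrow(object@values), ncol(object@values), object@cellSize,
    sum(object@values) * object@cellSize^2
  ))
})

setMethod("show", "EcmFit", function(object) {
  cat(sprintf(
    "Equal-capture-model fit: N = %d (95%% CI %d-%d)%s\n  k = %d individuals, %d captures\n",
    object@N, object@ci[1], object@ci[2],
    if (object@capped) " [capped at search bound]" else "",
    object@k, object@captures
  ))
})

setMethod("show", "SecrFit", function(object) {
  cat(sprintf(
    "SECR fit (half-normal Poisson count detectors):\n  D = %.4f /km2 (%.4f-%.4f), lambda0 = %.4f, sigma = %.0f m\n  mask %.0f km2 -> N = %.1f\n",
    object@D, object@ci[1, 1], object@ci[1, 2], object@lambda0, object@sigma,
    object@maskArea, object@N
  ))
})

setMethod("show", "AdmixtureResult", function(object) {
  cat(sprintf(
    "AdmixtureResult: K = %d, %d individuals, lnP = %.1f\n",
    object@K, nrow(object@Q), object@lnP
  ))
})
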