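#' @import methods
NULL

## ---------------------------------------------------------------------------
## ScatSamples: one row per fecal sample, replicate PCR calls per locus.
##
## Genotypes throughout the package are stored as integer allele sizes (base
## pairs) in a 2-column-per-locus layout; within a locus the pair is kept
## sorted so that (a,b) and (b,a) are the same genotype. NA marks a missing
## allele call.
## ---------------------------------------------------------------------------

#' Container for replicated fecal-sample genotypes
#'
#' One row per fecal sample with collection metadata, the per-locus replicate
#' PCR allele calls, and (after [callConsensus()]) the consensus genotype and
#' per-locus acceptance status.
#'
#' @slot samples data.frame with columns `sample`, `date` (Date), `x`, `y`
#'   (projected meters) and optional `cell` (survey-cell id).
#' @slot loci character vector of locus names.
#' @slot replicates list, one element per sample; each element is a named list
#'   over loci holding an integer matrix (replicates x 2) of allele calls,
#'   `NA` rows marking failed amplifications.
#' @slot consensus integer matrix (samples x 2*loci) of consensus allele
#'   pairs; zero rows until [callConsensus()] has run.
#' @slot status character matrix (samples x loci) with values `accepted`,
#'   `pending` or `missing`; zero rows until consensus has been called.
#'
#' @seealso [readSampleTable()], [callConsensus()], [matchGenotypes()]
#' @export
setClass("ScatSamples",
  slots = c(
    samples = "data.frame",
    loci = "character",
    replicates = "list",
    consensus = "matrix",
    status = "matrix"
  )
)

setValidity("ScatSamples", function(object) {
  s <- object@samples
  msgs <- character()
  need <- c("sample", "date", "x", "y")
  if (!all(need %in% names(s))) {
    msgs <- c(msgs, paste("samples needs columns", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(s$sample)) msgs <- c(msgs, "duplicate sample ids")
    if (!all(is.finite(s$x)) || !all(is.finite(s$y))) {
      msgs <- c(msgs, "coordinates must be finite")
    }
  }
  if (length(object@replicates) != nrow(s)) {
    msgs <- c(msgs, "one replicate set per sample required")
  }
  if (nrow(object@consensus) > 0 &&
      (nrow(object@consensus) != nrow(s) ||
       ncol(object@consensus) != 2L * length(object@loci))) {
    msgs <- c(msgs, "consensus matrix dimensions inconsistent")
  }
  if (nrow(object@status) > 0 &&
      (nrow(object@status) != nrow(s) || ncol(object@status) != length(object@loci))) {
    msgs <- c(msgs, "status matrix dimensions inconsistent")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScatSamples object
#'
#' @param samples data.frame with columns `sample`, `date`, `x`, `y` and
#'   optionally `cell`.
#' @param loci character vector of locus names.
#' @param replicates list parallel to `samples` rows; each element a named
#'   list over `loci` of integer matrices (replicates x 2).
#' @return A [ScatSamples-class] object.
#' @export
ScatSamples <- function(samples, loci, replicates) {
  samples$sample <- as.character(samples$sample)
  if (!inherits(samples$date, "Date")) samples$date <- as.Date(samples$date)
  if (is.null(samples$cell)) samples$cell <- NA_character_
  replicates <- lapply(replicates, function(rl) {
    rl <- rl[loci]
    names(rl) <- loci
    lapply(rl, function(m) {
      if (is.null(m)) m <- matrix(integer(), 0, 2)
      m <- matrix(as.integer(m), ncol = 2)
      if (nrow(m)) {
        lo <- pmin(m[, 1], m[, 2])
        hi <- pmax(m[, 1], m[, 2])
        m <- cbind(lo, hi)
      }
      dimnames(m) <- NULL
      m
    })
  })
  new("ScatSamples",
    samples = samples, loci = loci, replicates = replicates,
    consensus = matrix(integer(), 0, 2L * length(loci)),
    status = matrix(character(), 0, length(loci))
  )
}

## ---------------------------------------------------------------------------
## IndividualCatalog: individuals with consensus multilocus genotypes and
## date-ordered capture events.
## ---------------------------------------------------------------------------

#' Catalog of identified individuals
#'
#' Produced by [matchGenotypes()]: each row of `genotypes` is the multilocus
#' consensus genotype of one individual; `captures` lists the samples assigned
#' to each individual as date-ordered capture events.
#'
#' @slot genotypes integer matrix (individuals x 2*loci), rownames are
#'   individual ids; NA pairs mark untyped loci.
#' @slot loci character vector of locus names.
#' @slot captures data.frame with columns `individual`, `sample`, `date`,
#'   `x`, `y`, `cell`, sorted by individual then date.
#' @export
setClass("IndividualCatalog",
  slots = c(genotypes = "matrix", loci = "character", captures = "data.frame")
)

setValidity("IndividualCatalog", function(object) {
  msgs <- character()
  if (ncol(object@genotypes) != 2L * length(object@loci)) {
    msgs <- c(msgs, "genotype matrix must have 2 columns per locus")
  }
  if (is.null(rownames(object@genotypes))) {
    msgs <- c(msgs, "genotypes must have individual ids as rownames")
  }
  cap <- object@captures
  need <- c("individual", "sample", "date", "x", "y")
  if (!all(need %in% names(cap))) {
    msgs <- c(msgs, paste("captures needs columns", paste(need, collapse = ", ")))
  } else {
    if (!all(cap$individual %in% rownames(object@genotypes))) {
      msgs <- c(msgs, "capture events refer to unknown individuals")
    }
    if (anyDuplicated(cap$sample)) {
      msgs <- c(msgs, "a sample may be assigned to only one individual")
    }
    unsortedWithin <- tapply(as.numeric(cap$date), cap$individual, is.unsorted)
    if (any(unlist(unsortedWithin))) {
      msgs <- c(msgs, "capture events must be date-sorted within individuals")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IndividualCatalog
#'
#' @param genotypes integer matrix (individuals x 2*loci) with rownames.
#' @param loci locus names.
#' @param captures data.frame of capture events (see class docs).
#' @return An [IndividualCatalog-class] object.
#' @export
IndividualCatalog <- function(genotypes, loci, captures) {
  genotypes <- .sortPairs(genotypes, loci)
  colnames(genotypes) <- .locusCols(loci)
  if (is.null(captures$cell)) captures$cell <- NA_character_
  captures <- captures[order(captures$individual, captures$date), , drop = FALSE]
  rownames(captures) <- NULL
  new("IndividualCatalog", genotypes = genotypes, loci = loci, captures = captures)
}

## ---------------------------------------------------------------------------
## AlleleFrequencyTable
## ---------------------------------------------------------------------------

#' Per-locus allele frequency table
#'
#' @slot freqs named list, one element per locus: a named numeric vector of
#'   relative allele frequencies (names are allele sizes).
#' @slot nCopies named integer, allele copies counted per locus (2n).
#' @export
setClass("AlleleFrequencyTable",
  slots = c(freqs = "list", nCopies = "integer")
)

setValidity("AlleleFrequencyTable", function(object) {
  msgs <- character()
  for (l in names(object@freqs)) {
    p <- object@freqs[[l]]
    if (any(p <= 0)) msgs <- c(msgs, sprintf("non-positive frequency at %s", l))
    if (abs(sum(p) - 1) > 1e-9) msgs <- c(msgs, sprintf("frequencies at %s do not sum to 1", l))
  }
  if (!identical(names(object@freqs), names(object@nCopies))) {
    msgs <- c(msgs, "freqs and nCopies must cover the same loci")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## CaptureHistory
## ---------------------------------------------------------------------------

#' Capture histories for abundance estimation
#'
#' Holds per-individual total capture counts (equal-capture model input) and
#' the individual x occasion x detector counts used by the SECR likelihood.
#'
#' @slot totals named integer vector of capture counts per individual.
#' @slot counts data.frame with columns `individual`, `occasion`, `detector`,
#'   `n` (sparse representation; absent combinations are zero).
#' @slot occasionBreaks Date vector of occasion bin boundaries (length
#'   occasions + 1).
#' @slot detectors data.frame with columns `detector`, `x`, `y`.
#' @export
setClass("CaptureHistory",
  slots = c(
    totals = "integer", counts = "data.frame",
    occasionBreaks = "Date", detectors = "data.frame"
  )
)

setValidity("CaptureHistory", function(object) {
  msgs <- character()
  if (any(object@totals < 1L)) msgs <- c(msgs, "every individual must have >= 1 capture")
  if (sum(object@counts$n) != sum(object@totals)) {
    msgs <- c(msgs, "occasion/detector counts must sum to the totals")
  }
  if (!all(object@counts$detector %in% object@detectors$detector)) {
    msgs <- c(msgs, "counts refer to unknown detectors")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## DensitySurface
## ---------------------------------------------------------------------------

#' Gridded kernel space-use density surface
#'
#' @slot values numeric matrix of density (per square meter); rows index y
#'   from the bottom up, columns index x left to right.
#' @slot xmin,ymin numeric, coordinates of the lower-left corner of the grid.
#' @slot cellSize numeric, cell edge length in meters.
#' @slot tiers character matrix of the same shape with values `none`, `low`,
#'   `medium`, `high`; zero rows until [classifyTiers()] has run.
#' @export
setClass("DensitySurface",
  slots = c(
    values = "matrix", xmin = "numeric", ymin = "numeric",
    cellSize = "numeric", tiers = "matrix"
  )
)

setValidity("DensitySurface", function(object) {
  msgs <- character()
  if (any(!is.finite(object@values)) || any(object@values < 0)) {
    msgs <- c(msgs, "density values must be finite and non-negative")
  }
  if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be positive")
  if (nrow(object@tiers) > 0 && !identical(dim(object@tiers), dim(object@values))) {
    msgs <- c(msgs, "tier raster must match the density raster")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Model fits
## ---------------------------------------------------------------------------

#' Equal-capture-model abundance fit
#'
#' @slot N integer maximum-likelihood population size.
#' @slot ci integer vector (lower, upper) percentile bootstrap interval.
#' @slot logLik numeric log-likelihood over the integer grid `Ngrid`.
#' @slot Ngrid integer grid of candidate population sizes.
#' @slot capped logical, TRUE when the MLE hit the upper search bound.
#' @slot k integer number of observed individuals.
#' @slot captures integer total number of captures.
#' @slot boot numeric vector of bootstrap point estimates.
#' @export
setClass("EcmFit",
  slots = c(
    N = "integer", ci = "integer", logLik = "numeric", Ngrid = "integer",
    capped = "logical", k = "integer", captures = "integer", boot = "numeric"
  )
)

#' Spatially explicit capture-recapture fit
#'
#' Half-normal Poisson count-detector model with homogeneous density.
#'
#' @slot D numeric density estimate (individuals per km^2).
#' @slot lambda0 numeric expected detections per occasion at distance zero.
#' @slot sigma numeric spatial decay parameter (meters).
#' @slot ci numeric 3 x 2 matrix of Wald intervals (rows D, lambda0, sigma).
#' @slot maskArea numeric mask area in km^2.
#' @slot N numeric derived abundance D * maskArea.
#' @slot logLik numeric maximized log-likelihood.
#' @slot convergence integer optimizer convergence code (0 = ok).
#' @export
setClass("SecrFit",
  slots = c(
    D = "numeric", lambda0 = "numeric", sigma = "numeric", ci = "matrix",
    maskArea = "numeric", N = "numeric", logLik = "numeric",
    convergence = "integer"
  )
)

setValidity("SecrFit", function(object) {
  msgs <- character()
  if (object@D <= 0 || object@lambda0 <= 0 || object@sigma <= 0) {
    msgs <- c(msgs, "D, lambda0 and sigma must be positive")
  }
  if (abs(object@N - object@D * object@maskArea) > 1e-9 * max(1, object@N)) {
    msgs <- c(msgs, "N must equal D * maskArea")
  }
  if (length(msgs)) msgs else TRUE
})

#' Admixture-model Gibbs sampler result
#'
#' @slot K integer number of clusters.
#' @slot Q numeric matrix (individuals x K) of posterior mean membership
#'   proportions; rows sum to 1.
#' @slot lnLTrace numeric per-recorded-sweep data log-likelihood.
#' @slot lnP numeric model log-probability estimate
#'   (mean lnL - var(lnL) / 2 over post-burn-in sweeps).
#' @slot seed integer RNG seed of the run.
#' @export
setClass("AdmixtureResult",
  slots = c(
    K = "integer", Q = "matrix", lnLTrace = "numeric",
    lnP = "numeric", seed = "integer"
  )
)

setValidity("AdmixtureResult", function(object) {
  if (nrow(object@Q) > 0 && any(abs(rowSums(object@Q) - 1) > 1e-9)) {
    return("Q rows must sum to 1")
  }
  TRUE
})
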