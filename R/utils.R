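# Internal helpers shared across modules.

#' @importFrom stats rgamma runif rnorm rpois rbinom optimize optim quantile
#'   var sd setNames na.omit aggregate
#' @importFrom utils head tail read.table write.table
NULL

# Dirichlet draws via normalized gammas; alpha may be a vector (one draw per
# row when n > 1).
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  sw <- rowSums(x)
  # guard against all-zero rows for very small alpha
  bad <- sw == 0
  if (any(bad)) {
    x[bad, ] <- .rdirichlet(sum(bad), pmax(alpha, 1e-3))
    sw[bad] <- 1
    return(x / ifelse(rowSums(x) == 0, 1, rowSums(x)))
  }
  x / sw
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# column names of the 2-column-per-locus genotype matrix layout
.locusCols <- function(loci) {
  as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
}

# sort each allele pair so storage is order-independent; g is n x 2L
.sortPairs <- function(g, loci) {
  for (l in seq_along(loci)) {
    c1 <- 2L * l - 1L
    a <- g[, c1]
    b <- g[, c1 + 1L]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    g[, c1] <- lo
    g[, c1 + 1L] <- hi
  }
  g
}

# extract the n x 2 allele matrix of one locus from an n x 2L genotype matrix
.locusGeno <- function(g, locusIndex) {
  g[, c(2L * locusIndex - 1L, 2L * locusIndex), drop = FALSE]
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
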