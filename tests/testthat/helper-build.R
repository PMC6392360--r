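# Shared builders for small, fully controlled test objects.

# replicate matrix: the pair (a, b) repeated n times
repPair <- function(a, b, n = 1L) {
  matrix(rep(c(a, b), each = n), ncol = 2)
}

# ScatSamples from a list of per-sample replicate sets
# reps: list, one element per sample; each a named list over loci of
# (replicates x 2) matrices
mkScatSamples <- function(reps, loci, dates = NULL, x = NULL, y = NULL,
                          cell = NULL) {
  n <- length(reps)
  if (is.null(dates)) dates <- as.Date("2015-04-01") + seq_len(n)
  if (is.null(x)) x <- 1000 * seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  df <- data.frame(
    sample = sprintf("s%02d", seq_len(n)), date = dates, x = x, y = y,
    cell = if (is.null(cell)) NA_character_ else cell,
    stringsAsFactors = FALSE
  )
  ScatSamples(df, loci, reps)
}

# IndividualCatalog with one capture per individual (unless capture details
# are supplied)
mkCatalog <- function(g, lociNames, dates = NULL, x = NULL, y = NULL,
                      cell = NULL) {
  n <- nrow(g)
  if (is.null(rownames(g))) rownames(g) <- sprintf("I%03d", seq_len(n))
  if (is.null(dates)) dates <- as.Date("2015-04-01") + seq_len(n)
  if (is.null(x)) x <- 1000 * seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  cap <- data.frame(
    individual = rownames(g), sample = sprintf("cs%03d", seq_len(n)),
    date = dates, x = x, y = y,
    cell = if (is.null(cell)) NA_character_ else cell,
    stringsAsFactors = FALSE
  )
  IndividualCatalog(g, lociNames, cap)
}

# genotypes drawn under Hardy-Weinberg from explicit per-locus frequencies
# freqs: named list per locus; each a named numeric vector (names = allele
# sizes)
drawHweGenotypes <- function(freqs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  g <- matrix(NA_integer_, n, 2L * L)
  for (li in seq_len(L)) {
    p <- freqs[[li]]
    al <- as.integer(names(p))
    pairs <- matrix(sample(al, 2L * n, replace = TRUE, prob = p), n, 2)
    g[, 2L * li - 1L] <- pmin(pairs[, 1], pairs[, 2])
    g[, 2L * li] <- pmax(pairs[, 1], pairs[, 2])
  }
  rownames(g) <- sprintf("I%03d", seq_len(n))
  g
}

# random allele frequency vectors (named by allele size)
randomFreqs <- function(nLoci, minA = 2L, maxA = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (li in seq_len(nLoci)) {
    A <- sample(minA:maxA, 1)
    p <- rgamma(A, 1)
    p <- p / sum(p)
    out[[paste0("L", li)]] <- setNames(p, 100 + 4 * seq_len(A))
  }
  out
}
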