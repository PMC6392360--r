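# Independent oracle implementations used only by the tests.

# enumerate single-locus genotypes with Hardy-Weinberg probabilities
enumGenotypes <- function(p) {
  A <- length(p)
  out <- list()
  for (i in seq_len(A)) {
    for (j in i:A) {
      pr <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      out[[length(out) + 1L]] <- list(a = i, b = j, pr = pr)
    }
  }
  out
}

# P(two unrelated HWE individuals share a genotype), by enumeration
pidUnrelatedOracle <- function(p) {
  sum(vapply(enumGenotypes(p), function(g) g$pr^2, 1.0))
}

# P(two full siblings share a genotype): enumerate both parents' genotypes
# and the child genotype distribution given the parents
pidSibOracle <- function(p) {
  gl <- enumGenotypes(p)
  tot <- 0
  for (gm in gl) {
    for (gf in gl) {
      keys <- character(0)
      for (am in c(gm$a, gm$b)) {
        for (af in c(gf$a, gf$b)) {
          keys <- c(keys, paste(min(am, af), max(am, af)))
        }
      }
      pk <- as.numeric(table(keys)) / 4
      tot <- tot + gm$pr * gf$pr * sum(pk^2)
    }
  }
  tot
}

# naive integer grid search for the equal-capture MLE
naiveEcm <- function(counts, nmax) {
  k <- length(counts)
  Tcap <- sum(counts)
  best <- k
  bestll <- -Inf
  for (N in k:nmax) {
    ll <- sum(log(seq(N - k + 1, N))) - Tcap * log(N)
    if (ll > bestll) {
      bestll <- ll
      best <- N
    }
  }
  best
}

# crossings from a side-label sequence, skipping ON
scanCrossings <- function(sides) {
  s <- sides[sides != "ON"]
  if (length(s) < 2) {
    return(0L)
  }
  sum(s[-1] != s[-length(s)])
}

# adjusted Rand index between two labelings (Hubert & Arabie), written out
# directly from the contingency-table formula
ariOracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) {
    return(1)
  }
  (sumij - expected) / (maxidx - expected)
}
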