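## One-call orchestration: consensus -> identify -> abundance -> diversity ->
## structure -> space, with a structured JSON-able report.

#' Default pipeline configuration
#'
#' @param ... named overrides.
#' @return config list understood by [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    minHomReps = 3L, minHetReps = 2L,
    minLoci = 6L, rescueLoci = 5L, rescueDistance = 2000,
    occasions = 30L,
    ecm = TRUE, secr = TRUE, nmaxMult = 20L, bootstrap = 500L,
    hwePerms = 2000L, bonferroniAlpha = 0.01,
    fstPerms = 1000L, assignSims = 2000L, migrantAlpha = 0.01,
    admixture = FALSE, kRange = 1:3, admixRuns = 2L,
    admixBurnin = 500L, admixSweeps = 2500L,
    kdeRadius = 3000, kdeCell = 250,
    relatedness = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) .stopf("unknown pipeline config field '%s'", nm)
    cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; a stage failure halts with an error named
#' after the stage. The returned report collects the summary numbers of
#' every stage and is reproducible given `seed` (timestamps excluded).
#'
#' @param samples a [ScatSamples-class] object (or a path plus `tableConfig`
#'   to read one).
#' @param road optional road polyline matrix (enables side labeling, FST /
#'   migrant analyses and crossing detection).
#' @param config from [pipelineConfig()].
#' @param seed integer seed driving every stochastic stage.
#' @param tableConfig sample-table layout when `samples` is a file path.
#' @param review optional review input for [matchGenotypes()].
#' @param outDir optional directory for report.json and per-stage TSV files.
#' @return a pipeline report list.
#' @export
runPipeline <- function(samples, road = NULL, config = pipelineConfig(),
                        seed = 1L, tableConfig = NULL, review = NULL,
                        outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  report <- list(provenance = list(seed = as.integer(seed), config = config))

  if (is.character(samples)) {
    if (is.null(tableConfig)) .stopf("tableConfig required when samples is a path")
    samples <- stage("read", readSampleTable(samples, tableConfig))
  }
  report$input <- list(nSamples = nSamples(samples), loci = loci(samples))

  samples <- stage("consensus", callConsensus(samples, config$minHomReps, config$minHetReps))
  err <- stage("consensus", estimateErrorRates(samples))
  report$consensus <- list(
    errorRates = err,
    flagged = nrow(flaggedSamples(samples)),
    acceptedCallRate = mean(consensusStatus(samples) == "accepted")
  )

  m <- stage("identify", matchGenotypes(
    samples,
    minLoci = config$minLoci, rescueLoci = config$rescueLoci,
    rescueDistance = config$rescueDistance, review = review
  ))
  catalog <- m$catalog
  freqs <- alleleFrequencyTable(catalog)
  ch <- stage("identify", buildCaptureHistory(catalog, occasions = config$occasions))
  tot <- captureTotals(ch)
  report$identify <- list(
    nUsable = sum(m$usable),
    nIndividuals = nIndividuals(catalog),
    meanCaptures = mean(tot),
    nRecaptured = sum(tot >= 2L),
    reviewQueue = nrow(m$reviewQueue),
    pid7 = pidUnrelated(freqs),
    pidSib7 = pidSib(freqs),
    pidSibBest6 = pidSib(freqs, bestLociSubset(freqs, 6)),
    nullAlleleFreqs = nullAlleleFrequencies(catalog)
  )

  report$abundance <- list()
  if (isTRUE(config$ecm)) {
    ecm <- stage("abundance", fitEcm(tot,
      nmaxMult = config$nmaxMult,
      bootstrap = config$bootstrap, seed = seed
    ))
    report$abundance$ecm <- list(N = ecm@N, ci = ecm@ci, capped = ecm@capped)
  }
  if (isTRUE(config$secr)) {
    secr <- tryCatch(fitSecr(ch, seed = seed), error = function(e) e)
    report$abundance$secr <- if (inherits(secr, "error")) {
      list(error = conditionMessage(secr))
    } else {
      list(
        D = secr@D, lambda0 = secr@lambda0, sigma = secr@sigma,
        maskArea = secr@maskArea, N = secr@N, ciD = secr@ci[1, ]
      )
    }
  }

  div <- stage("diversity", diversitySummary(catalog,
    hwePerms = config$hwePerms,
    bonferroniAlpha = config$bonferroniAlpha, seed = seed
  ))
  fvals <- stage("diversity", inbreedingCoefficients(catalog, freqs))
  report$diversity <- list(
    table = div,
    inbreedingBins = binSummary(fvals)
  )
  if (isTRUE(config$relatedness)) {
    r <- stage("diversity", relatednessMatrix(catalog, freqs))
    rv <- r[upper.tri(r)]
    report$diversity$relatedness <- list(
      mean = mean(rv, na.rm = TRUE),
      propBelow0.125 = mean(rv < 0.125, na.rm = TRUE)
    )
  }

  if (!is.null(road)) {
    cap <- captures(catalog)
    firstCap <- cap[!duplicated(cap$individual), , drop = FALSE]
    sides <- sideOfRoad(firstCap$x, firstCap$y, road = road)
    names(sides) <- firstCap$individual
    onRoad <- sides == "ON"
    if (any(onRoad)) sides[onRoad] <- "A"
    labels <- sides[rownames(genotypes(catalog))]
    structureRes <- list(sideCounts = table(labels))
    if (length(unique(labels)) == 2) {
      fp <- stage("structure", fstPermutationTest(catalog, labels,
        nPerm = config$fstPerms, seed = seed
      ))
      structureRes$fst <- fp$theta
      structureRes$fstP <- fp$p
      structureRes$Nm <- if (fp$theta > 0) nmFromFst(fp$theta) else NA_real_
      mig <- stage("structure", detectFirstGenMigrants(catalog, labels,
        nSim = config$assignSims, alpha = config$migrantAlpha, seed = seed
      ))
      structureRes$migrants <- mig$individual[mig$migrant]
      structureRes$nMigrants <- sum(mig$migrant)
    }
    if (isTRUE(config$admixture)) {
      lnP <- list()
      for (K in config$kRange) {
        for (run in seq_len(config$admixRuns)) {
          res <- stage("structure", admixtureGibbs(catalog, K,
            burnin = config$admixBurnin, sweeps = config$admixSweeps,
            seed = seed + 100L * K + run
          ))
          lnP[[length(lnP) + 1L]] <- data.frame(K = K, lnP = res@lnP)
        }
      }
      lnP <- do.call(rbind, lnP)
      structureRes$lnP <- lnP
      structureRes$deltaK <- tryCatch(evannoDeltaK(lnP), error = function(e) NULL)
    }
    pc <- stage("structure", genotypePcoa(catalog))
    structureRes$pcoaPercentVar <- head(pc$percentVar, 3)
    report$structure <- structureRes

    cr <- stage("space", detectRoadCrossings(catalog, road))
    report$space <- list(crossings = cr$total, crossingIndividuals = names(cr$counts))
  }

  surf <- stage("space", classifyTiers(kernelDensitySurface(
    firstCaptureLocations(catalog),
    radius = config$kdeRadius, cellSize = config$kdeCell
  )))
  report$space$kdeIntegral <- sum(surfaceValues(surf)) * config$kdeCell^2
  report$space$tierCounts <- as.list(attr(surf, "counts"))

  report$objects <- list(samples = samples, catalog = catalog, captureHistory = ch, surface = surf)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    body <- report[setdiff(names(report), "objects")]
    jsonlite::write_json(
      body, file.path(outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE
    )
    write.table(div, file.path(outDir, "diversity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(captures(catalog), file.path(outDir, "captures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  report
}
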