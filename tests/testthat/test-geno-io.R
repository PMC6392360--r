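# Sample-table and GenePop I/O, road geometry.

test_that("readSampleTable parses the long dialect and groups replicates", {
  cfg <- sampleTableConfig(loci = c("L1", "L2"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample,date,x,y,cell,L1_1,L1_2,L2_1,L2_2",
    "s1,2015-04-01,1000,2000,c1,120,124,88,88",
    "s1,2015-04-01,1000,2000,c1,124,120,88,92",
    "s2,2015-05-02,1500,2500,c2,120,120,0,0"
  ), f)
  x <- readSampleTable(f, cfg)
  expect_s4_class(x, "ScatSamples")
  expect_equal(nSamples(x), 2L)
  expect_equal(loci(x), c("L1", "L2"))
  r1 <- sampleReplicates(x, "s1")
  # pairs are stored sorted, so (124,120) becomes (120,124)
  expect_equal(r1$L1, rbind(c(120L, 124L), c(120L, 124L)))
  expect_equal(r1$L2, rbind(c(88L, 88L), c(88L, 92L)))
  # "0" tokens are missing: the whole replicate is a failed amplification
  r2 <- sampleReplicates(x, "s2")
  expect_true(all(is.na(r2$L2)))
  expect_equal(sampleInfo(x)$date, as.Date(c("2015-04-01", "2015-05-02")))
})

test_that("readSampleTable errors name the offending column and row", {
  cfg <- sampleTableConfig(loci = c("L1", "L2"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample,date,x,y,L1_1,L1_2",
    "s1,2015-04-01,1,2,120,124"
  ), f)
  expect_error(readSampleTable(f, cfg), "L2_1")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample,date,x,y,L1_1,L1_2,L2_1,L2_2",
    "s1,2015-04-01,1,2,120,124,88,88",
    "s2,2015-04-02,1,2,12x,124,88,88"
  ), f2)
  expect_error(readSampleTable(f2, cfg), "12x")
  expect_error(readSampleTable(f2, cfg), "row 3")

  expect_error(readSampleTable("/nonexistent/file.csv", cfg), "not found")
})

test_that("wide dialect reads replicate column groups", {
  cfg <- sampleTableConfig(loci = "L1", dialect = "wide")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample,date,x,y,L1_r1_1,L1_r1_2,L1_r2_1,L1_r2_2",
    "s1,2015-04-01,10,20,120,124,120,120"
  ), f)
  x <- readSampleTable(f, cfg)
  expect_equal(sampleReplicates(x, "s1")$L1, rbind(c(120L, 124L), c(120L, 120L)))
})

test_that("writeSampleTable round-trips through readSampleTable", {
  lociNames <- c("L1", "L2")
  reps <- list(
    list(L1 = repPair(120, 124, 3), L2 = repPair(88, 88, 2)),
    list(L1 = rbind(c(120, 120), c(NA, NA)), L2 = repPair(92, 96, 4))
  )
  x <- mkScatSamples(reps, lociNames, cell = c("c1", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSampleTable(x, f)
  y <- readSampleTable(f, sampleTableConfig(loci = lociNames))
  expect_equal(sampleInfo(y)$sample, sampleInfo(x)$sample)
  expect_equal(sampleInfo(y)$date, sampleInfo(x)$date)
  expect_equal(sampleInfo(y)$x, sampleInfo(x)$x)
  for (s in sampleInfo(x)$sample) {
    expect_equal(sampleReplicates(y, s), sampleReplicates(x, s))
  }
})

test_that("GenePop write/read round-trips genotypes, pops and missing loci", {
  lociNames <- c("L1", "L2")
  g <- rbind(
    c(120L, 124L, 200L, 200L),
    c(120L, 120L, NA, NA),
    c(124L, 128L, 204L, 208L)
  )
  rownames(g) <- c("A1", "A2", "B1")
  cat <- mkCatalog(g, lociNames)
  pops <- c(A1 = "east", A2 = "east", B1 = "west")
  f <- withr::local_tempfile(fileext = ".gen")
  mapping <- writeGenepop(cat, pops, f)
  expect_true(all(c("locus", "code", "allele") %in% names(mapping)))
  back <- readGenepop(f)
  expect_equal(back$loci, lociNames)
  expect_equal(unname(back$genotypes), unname(genotypes(cat)))
  expect_equal(rownames(back$genotypes), rownames(g))
  # population separators preserved the grouping
  expect_equal(as.character(back$pops), c("pop1", "pop1", "pop2"))
})

test_that("sideOfRoad splits a vertical road and labels on-road points", {
  road <- cbind(x = c(0, 0), y = c(-100, 100))
  lab <- sideOfRoad(c(-5, 5, 0, -1, 2), c(0, 0, 30, 90, -90), road = road)
  expect_equal(lab[3], "ON")
  expect_equal(lab[1], lab[4]) # both x < 0
  expect_equal(lab[2], lab[5]) # both x > 0
  expect_true(lab[1] != lab[2])
})

test_that("sideOfRoad partition is invariant under rigid motions", {
  set.seed(11)
  road <- cbind(x = c(0, 200, 150, 400), y = c(0, 300, 700, 1000))
  pts <- cbind(runif(40, -500, 900), runif(40, -200, 1200))
  lab <- sideOfRoad(pts, road = road)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(12345, -6789)
  ptsT <- sweep(pts %*% t(R), 2, shift, "+")
  roadT <- sweep(road %*% t(R), 2, shift, "+")
  labT <- sideOfRoad(ptsT, road = roadT)
  # the induced two-set partition must be identical (labels may swap)
  expect_true(identical(lab == "A", labT == "A") ||
    identical(lab == "A", labT == "B"))
})

test_that("sideOfRoad matches an x-offset oracle on a zig-zag road", {
  # road with x a piecewise-linear function of y: oracle side is
  # sign(x - roadX(y))
  road <- cbind(x = c(0, 500, 0, 500), y = c(0, 1000, 2000, 3000))
  roadX <- approxfun(road[, 2], road[, 1])
  set.seed(7)
  y <- runif(200, 50, 2950)
  x <- runif(200, -800, 1300)
  off <- x - roadX(y)
  keep <- abs(off) > 1 # skip points essentially on the road
  lab <- sideOfRoad(x[keep], y[keep], road = road)
  oracle <- ifelse(off[keep] > 0, "R", "L")
  expect_true(identical(lab == "A", oracle == "R") ||
    identical(lab == "A", oracle == "L"))
})

test_that("road validation rejects degenerate input", {
  expect_error(sideOfRoad(1, 1, road = cbind(1, 1)), "road")
  expect_error(
    sideOfRoad(1, 1, road = rbind(c(0, 0), c(0, 0))),
    "degenerate"
  )
  expect_error(sideOfRoad(NaN, 1, road = cbind(c(0, 0), c(0, 1))), "finite")
})

test_that("readRoadLine reads a two-column coordinate file", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "100 250", "200 600"), f)
  m <- readRoadLine(f)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[2, ], c(x = 100, y = 250))
})

test_that("sample-table config round-trips through YAML", {
  cfg <- sampleTableConfig(loci = c("L1", "L2"), dialect = "wide", sep = ";")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  cfg2 <- readSampleTableConfig(f)
  expect_equal(cfg2$loci, cfg$loci)
  expect_equal(cfg2$dialect, "wide")
  expect_equal(cfg2$sep, ";")
})
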