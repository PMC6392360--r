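## Sample-table and GenePop I/O, road geometry.

#' Describe the layout of a delimited sample table
#'
#' The reader is dialect-configurable because field datasets differ in how
#' replicate PCRs are laid out. In the `long` dialect each row is one
#' replicate (rows sharing a sample id are grouped) with two allele columns
#' per locus, `<locus>_1` / `<locus>_2`. In the `wide` dialect each sample is
#' one row and replicate `k` of a locus sits in `<locus>_r<k>_1` /
#' `<locus>_r<k>_2`.
#'
#' @param loci character vector of locus names, in the desired order.
#' @param dialect `"long"` or `"wide"`.
#' @param sep field separator.
#' @param idCol,dateCol,xCol,yCol,cellCol column names for sample id, date,
#'   projected x/y (meters) and optional survey cell (`cellCol = NULL` when
#'   absent).
#' @param missingTokens character tokens accepted as missing allele calls.
#' @param dateFormat primary date format; `dateFallback` is tried for values
#'   the primary format cannot parse.
#' @param dateFallback fallback date format.
#' @return A config list for [readSampleTable()].
#' @export
sampleTableConfig <- function(loci,
                              dialect = c("long", "wide"),
                              sep = ",",
                              idCol = "sample", dateCol = "date",
                              xCol = "x", yCol = "y", cellCol = "cell",
                              missingTokens = c("0", "", "NA"),
                              dateFormat = "%Y-%m-%d",
                              dateFallback = "%d/%m/%Y") {
  list(
    loci = loci, dialect = match.arg(dialect), sep = sep,
    idCol = idCol, dateCol = dateCol, xCol = xCol, yCol = yCol,
    cellCol = cellCol, missingTokens = missingTokens,
    dateFormat = dateFormat, dateFallback = dateFallback
  )
}

#' Read a sample-table config from a YAML file
#' @param path path to a YAML key-value file with the fields of
#'   [sampleTableConfig()].
#' @return config list
#' @export
readSampleTableConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sampleTableConfig, cfg)
}

.parseAllele <- function(tok, missingTokens, rowIdx, path) {
  tok <- trimws(as.character(tok))
  out <- rep(NA_integer_, length(tok))
  miss <- tok %in% missingTokens | is.na(tok)
  num <- suppressWarnings(as.integer(tok))
  bad <- !miss & (is.na(num) | num <= 0)
  if (any(bad)) {
    .stopf(
      "unparseable allele token '%s' at row %d of %s",
      tok[which(bad)[1]], rowIdx[which(bad)[1]], path
    )
  }
  out[!miss] <- num[!miss]
  out
}

.parseDates <- function(x, cfg) {
  d <- as.Date(as.character(x), format = cfg$dateFormat)
  retry <- is.na(d) & !is.na(x) & nzchar(as.character(x))
  if (any(retry)) d[retry] <- as.Date(as.character(x)[retry], format = cfg$dateFallback)
  if (anyNA(d)) .stopf("unparseable date value '%s'", as.character(x)[which(is.na(d))[1]])
  d
}

#' Read a delimited table of replicated fecal-sample genotypes
#'
#' @param path path to a delimited text file.
#' @param config layout description from [sampleTableConfig()] (or a path to a
#'   YAML file accepted by [readSampleTableConfig()]).
#' @return A [ScatSamples-class] object with one record per distinct sample id.
#' @examples
#' cfg <- sampleTableConfig(loci = c("L1", "L2"))
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "sample,date,x,y,cell,L1_1,L1_2,L2_1,L2_2",
#'   "s1,2015-04-01,1000,2000,c1,120,124,88,88",
#'   "s1,2015-04-01,1000,2000,c1,120,124,88,92"
#' ), f)
#' readSampleTable(f, cfg)
#' @export
readSampleTable <- function(path, config) {
  if (is.character(config)) config <- readSampleTableConfig(config)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- read.table(path,
    sep = config$sep, header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character"
  )
  meta <- c(config$idCol, config$dateCol, config$xCol, config$yCol)
  missingCols <- setdiff(meta, names(tab))
  if (length(missingCols)) .stopf("missing mandatory column '%s' in %s", missingCols[1], path)

  loci <- config$loci
  if (config$dialect == "long") {
    cols <- .locusCols(loci)
    missingCols <- setdiff(cols, names(tab))
    if (length(missingCols)) .stopf("missing mandatory column '%s' in %s", missingCols[1], path)
    repCols <- lapply(loci, function(l) list(paste0(l, "_1"), paste0(l, "_2")))
  } else {
    repCols <- lapply(loci, function(l) {
      pat <- paste0("^", l, "_r([0-9]+)_([12])$")
      hits <- grep(pat, names(tab), value = TRUE)
      if (!length(hits)) .stopf("missing mandatory column group '%s_r*_1/2' in %s", l, path)
      ks <- sort(unique(as.integer(sub(pat, "\\1", hits))))
      list(paste0(l, "_r", ks, "_1"), paste0(l, "_r", ks, "_2"))
    })
  }

  ids <- as.character(tab[[config$idCol]])
  ord <- !duplicated(ids)
  uids <- ids[ord]
  first <- match(uids, ids)
  cellCol <- config$cellCol
  samples <- data.frame(
    sample = uids,
    date = .parseDates(tab[[config$dateCol]][first], config),
    x = as.numeric(tab[[config$xCol]][first]),
    y = as.numeric(tab[[config$yCol]][first]),
    cell = if (!is.null(cellCol) && cellCol %in% names(tab)) {
      as.character(tab[[cellCol]][first])
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(samples$x)) || any(!is.finite(samples$y))) {
    .stopf("non-finite coordinates in %s", path)
  }

  rowIdx <- seq_len(nrow(tab)) + 1L # +1 for the header line
  replicates <- lapply(uids, function(id) {
    rows <- which(ids == id)
    rl <- vector("list", length(loci))
    names(rl) <- loci
    for (li in seq_along(loci)) {
      c1 <- repCols[[li]][[1]]
      c2 <- repCols[[li]][[2]]
      r1 <- unlist(lapply(c1, function(cc) tab[[cc]][rows]))
      r2 <- unlist(lapply(c2, function(cc) tab[[cc]][rows]))
      a1 <- unlist(lapply(c1, function(cc) .parseAllele(tab[[cc]][rows], config$missingTokens, rowIdx[rows], path)))
      a2 <- unlist(lapply(c2, function(cc) .parseAllele(tab[[cc]][rows], config$missingTokens, rowIdx[rows], path)))
      m <- cbind(a1, a2)
      # a replicate with one missing allele is treated as failed
      m[is.na(m[, 1]) | is.na(m[, 2]), ] <- NA_integer_
      # rows where both cells are empty mark padding (the locus has fewer
      # replicates than the sample's longest locus), not a failed replicate
      blank <- function(v) is.na(v) | trimws(v) == ""
      rl[[li]] <- m[!(blank(r1) & blank(r2)), , drop = FALSE]
    }
    rl
  })
  ScatSamples(samples, loci, replicates)
}

#' Write a ScatSamples object as a long-dialect sample table
#'
#' The written file round-trips through [readSampleTable()] with a `long`
#' dialect config over the same loci.
#'
#' @param x a [ScatSamples-class] object.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(x, path, sep = ",") {
  loci <- x@loci
  rows <- list()
  for (i in seq_len(nrow(x@samples))) {
    nrep <- max(c(1L, vapply(x@replicates[[i]], nrow, 1L)))
    block <- data.frame(
      sample = rep(x@samples$sample[i], nrep),
      date = rep(format(x@samples$date[i], "%Y-%m-%d"), nrep),
      x = rep(x@samples$x[i], nrep),
      y = rep(x@samples$y[i], nrep),
      cell = rep(ifelse(is.na(x@samples$cell[i]), "", x@samples$cell[i]), nrep),
      stringsAsFactors = FALSE
    )
    for (l in loci) {
      m <- x@replicates[[i]][[l]]
      # failed replicates are written as "0"; padding rows (beyond the
      # locus's replicate count) are written empty so they read back as absent
      a1 <- rep("", nrep)
      a2 <- rep("", nrep)
      if (nrow(m)) {
        a1[seq_len(nrow(m))] <- ifelse(is.na(m[, 1]), "0", as.character(m[, 1]))
        a2[seq_len(nrow(m))] <- ifelse(is.na(m[, 2]), "0", as.character(m[, 2]))
      }
      block[[paste0(l, "_1")]] <- a1
      block[[paste0(l, "_2")]] <- a2
    }
    rows[[i]] <- block
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

## GenePop ------------------------------------------------------------------

#' Write an individual catalog as a GenePop file
#'
#' Alleles are ranked within each locus and encoded as 3-digit codes
#' `001..n`; the code-to-allele-size mapping is written alongside as
#' `<path>.alleles` so the paired reader can restore exact allele sizes.
#' Missing loci are encoded `000000`.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param pops named character vector mapping every individual id to a
#'   population label.
#' @param path output path.
#' @param title title line for the file.
#' @return data.frame of the allele code mapping, invisibly.
#' @export
writeGenepop <- function(catalog, pops, path, title = "scatCMR export") {
  g <- genotypes(catalog)
  ids <- rownames(g)
  if (!all(ids %in% names(pops))) .stopf("every individual must have a population label")
  lociNames <- loci(catalog)
  mapping <- list()
  codes <- matrix(NA_integer_, nrow(g), ncol(g))
  for (li in seq_along(lociNames)) {
    al <- .locusGeno(g, li)
    sizes <- sort(unique(as.vector(al[!is.na(al)])))
    if (length(sizes) > 999) .stopf("locus %s has more than 999 allele codes", lociNames[li])
    mapping[[li]] <- data.frame(
      locus = lociNames[li], code = seq_along(sizes), allele = sizes,
      stringsAsFactors = FALSE
    )
    codes[, 2L * li - 1L] <- match(al[, 1], sizes)
    codes[, 2L * li] <- match(al[, 2], sizes)
  }
  mapping <- do.call(rbind, mapping)

  lines <- c(title, lociNames)
  for (p in unique(pops[ids])) {
    lines <- c(lines, "Pop")
    for (i in which(pops[ids] == p)) {
      toks <- vapply(seq_along(lociNames), function(li) {
        a <- codes[i, 2L * li - 1L]
        b <- codes[i, 2L * li]
        if (is.na(a) || is.na(b)) "000000" else sprintf("%03d%03d", a, b)
      }, "")
      lines <- c(lines, paste0(ids[i], " , ", paste(toks, collapse = " ")))
    }
  }
  writeLines(lines, path)
  write.table(mapping, paste0(path, ".alleles"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(mapping)
}

#' Read a GenePop file written by [writeGenepop()]
#'
#' @param path path to the GenePop file; when `<path>.alleles` exists the
#'   3-digit codes are decoded back to allele sizes.
#' @return list with `genotypes` (integer matrix, 2 columns per locus),
#'   `pops` (named character vector) and `loci`.
#' @export
readGenepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) .stopf("not a GenePop file: %s", path)
  popIdx <- which(tolower(trimws(lines)) == "pop")
  if (!length(popIdx)) .stopf("no 'Pop' separator found in %s", path)
  lociNames <- trimws(lines[2:(popIdx[1] - 1L)])
  # loci may alternatively be comma-separated on one line
  if (length(lociNames) == 1 && grepl(",", lociNames)) {
    lociNames <- trimws(strsplit(lociNames, ",")[[1]])
  }
  mapFile <- paste0(path, ".alleles")
  mapping <- if (file.exists(mapFile)) {
    read.table(mapFile, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else NULL

  ids <- character()
  popLab <- character()
  rows <- list()
  popNo <- 0L
  for (i in seq(popIdx[1], length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (tolower(ln) == "pop") {
      popNo <- popNo + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) .stopf("malformed GenePop row: %s", ln)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(toks) != length(lociNames)) {
      .stopf("row for '%s' has %d genotypes, expected %d", id, length(toks), length(lociNames))
    }
    g <- integer(2L * length(lociNames))
    for (li in seq_along(toks)) {
      a <- as.integer(substr(toks[li], 1, 3))
      b <- as.integer(substr(toks[li], 4, 6))
      if (a == 0L || b == 0L) {
        g[c(2L * li - 1L, 2L * li)] <- NA_integer_
      } else {
        if (!is.null(mapping)) {
          mm <- mapping[mapping$locus == lociNames[li], ]
          a <- mm$allele[match(a, mm$code)]
          b <- mm$allele[match(b, mm$code)]
        }
        g[2L * li - 1L] <- min(a, b)
        g[2L * li] <- max(a, b)
      }
    }
    ids <- c(ids, id)
    popLab <- c(popLab, paste0("pop", popNo))
    rows[[length(rows) + 1L]] <- g
  }
  gm <- do.call(rbind, rows)
  rownames(gm) <- ids
  colnames(gm) <- .locusCols(lociNames)
  list(genotypes = gm, pops = setNames(popLab, ids), loci = lociNames)
}

## Road geometry ------------------------------------------------------------

#' Read a road polyline from a 2-column x,y text file
#' @param path path to a whitespace- or comma-delimited 2-column file of
#'   projected coordinates (meters).
#' @return numeric matrix with columns x, y.
#' @export
readRoadLine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE, sep = "", col.names = c("x", "y")))
  .validRoad(m)
  m
}

.validRoad <- function(road) {
  if (!is.matrix(road) || ncol(road) != 2 || nrow(road) < 2) {
    .stopf("road must be a matrix of >= 2 vertices with columns x, y")
  }
  if (nrow(unique(road)) < 2) .stopf("degenerate road: fewer than 2 distinct vertices")
  if (any(!is.finite(road))) .stopf("road vertices must be finite")
  invisible(TRUE)
}

.pointSegDist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / pmax(L2, .Machine$double.xmin)))
  t[L2 == 0] <- 0
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

.distToRoad <- function(px, py, road) {
  n <- nrow(road)
  min(.pointSegDist(
    px, py,
    road[-n, 1], road[-n, 2], road[-1, 1], road[-1, 2]
  ))
}

# Count proper crossings of segment p0->p with the segments of `ext`.
# Returns NA when a near-degenerate intersection is met (caller retries with
# a different anchor).
.crossingCount <- function(p0, p, ext, eps) {
  n <- nrow(ext)
  ax <- ext[-n, 1]; ay <- ext[-n, 2]
  bx <- ext[-1, 1]; by <- ext[-1, 2]
  rx <- p[1] - p0[1]; ry <- p[2] - p0[2]
  sx <- bx - ax; sy <- by - ay
  denom <- rx * sy - ry * sx
  qpx <- ax - p0[1]; qpy <- ay - p0[2]
  tnum <- qpx * sy - qpy * sx
  unum <- qpx * ry - qpy * rx
  t <- tnum / ifelse(denom == 0, NA, denom)
  u <- unum / ifelse(denom == 0, NA, denom)
  par <- abs(denom) < eps * (abs(rx) + abs(ry)) * (abs(sx) + abs(sy) + 1)
  # parallel and collinear overlap would be degenerate; parallel disjoint is fine
  if (any(par & abs(tnum) < eps * (abs(qpx) + abs(qpy) + 1))) return(NA_integer_)
  t[par] <- NA; u[par] <- NA
  inT <- !is.na(t) & t > 0 & t < 1
  inU <- !is.na(u) & u > 0 & u < 1
  nearEdge <- !is.na(t) & !is.na(u) &
    (pmin(abs(t), abs(t - 1)) < eps | pmin(abs(u), abs(u - 1)) < eps) &
    t > -eps & t < 1 + eps & u > -eps & u < 1 + eps
  if (any(nearEdge)) return(NA_integer_)
  sum(inT & inU)
}

#' Label points by the side of a road polyline
#'
#' The polyline is extended far beyond both ends and divides the plane in
#' two; a point's label is the crossing parity of a path from a fixed
#' off-road anchor to the point. Points lying exactly on the polyline get
#' `"ON"`. Labels are deterministic and invariant under rigid motions applied
#' jointly to points and road.
#'
#' @param x,y numeric coordinate vectors (or `x` a 2-column matrix and
#'   `y = NULL`).
#' @param road 2-column matrix of polyline vertices (projected meters).
#' @param tol absolute distance below which a point counts as on the road.
#' @return character vector of labels `"A"`, `"B"` or `"ON"`.
#' @export
sideOfRoad <- function(x, y = NULL, road, tol = 1e-9) {
  if (is.null(y)) {
    pts <- as.matrix(x)
  } else {
    pts <- cbind(x, y)
  }
  .validRoad(road)
  if (any(!is.finite(pts))) .stopf("points must be finite")

  # drop consecutive duplicate vertices, then extend both ends
  keep <- c(TRUE, rowSums(abs(diff(road))) > 0)
  road <- road[keep, , drop = FALSE]
  n <- nrow(road)
  bb <- rbind(road, pts)
  diag <- max(1, sqrt(diff(range(bb[, 1]))^2 + diff(range(bb[, 2]))^2))
  L <- 1e3 * diag
  d1 <- road[1, ] - road[2, ]
  d1 <- d1 / sqrt(sum(d1^2))
  dn <- road[n, ] - road[n - 1, ]
  dn <- dn / sqrt(sum(dn^2))
  ext <- rbind(road[1, ] + L * d1, road, road[n, ] + L * dn)

  # One fixed off-road anchor defines side "A"; all points are labeled by
  # crossing parity against the same anchor. Degenerate intersections are
  # resolved by jittering the anchor by amounts far smaller than its distance
  # to the extended polyline, which cannot change its side.
  candidates <- lapply(0:19, function(k) {
    ang <- 0.7853 + 0.37 * k
    c(
      min(bb[, 1]) - (7.3 + 0.91 * k) * diag * cos(ang) - 3.1 * diag,
      min(bb[, 2]) - (11.7 + 1.13 * k) * diag * sin(ang) - 2.3 * diag
    )
  })
  clear <- 0.01 * diag
  a0 <- NULL
  for (cand in candidates) {
    if (.distToRoad(cand[1], cand[2], ext) > clear) {
      a0 <- cand
      break
    }
  }
  if (is.null(a0)) .stopf("could not place a side anchor clear of the road")
  jitters <- lapply(0:19, function(k) {
    if (k == 0) c(0, 0) else 1e-5 * diag * c(cos(0.37 + 0.61 * k), sin(1.13 + 0.83 * k))
  })
  eps <- 1e-12

  out <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (.distToRoad(p[1], p[2], road) <= tol) {
      out[i] <- "ON"
      next
    }
    cnt <- NA_integer_
    for (j in jitters) {
      cnt <- .crossingCount(a0 + j, p, ext, eps)
      if (!is.na(cnt)) break
    }
    if (is.na(cnt)) .stopf("side labeling failed for point %d (degenerate geometry)", i)
    out[i] <- if (cnt %% 2L == 0L) "A" else "B"
  }
  out
}
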