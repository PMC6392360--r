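## Kernel space-use density, tier classification, road crossings.

#' Kernel space-use density surface
#'
#' Sums a quartic (biweight) kernel of bandwidth `radius` over the supplied
#' points (conventionally the first-capture location of each individual);
#' each kernel integrates to one, so the raster integral equals the number
#' of points up to edge truncation. The raster extent is the point bounding
#' box buffered by the radius.
#'
#' @param points 2-column matrix or data.frame of x,y coordinates (meters).
#' @param radius kernel radius in meters (3 km reflects the upper end of
#'   reported home-range diameters).
#' @param cellSize raster cell edge in meters (must be <= radius / 5).
#' @param kernel `"quartic"` (default) or `"uniform"` (uniform disc).
#' @return A [DensitySurface-class] object (values per square meter).
#' @export
kernelDensitySurface <- function(points, radius = 3000, cellSize = 250,
                                 kernel = c("quartic", "uniform")) {
  kernel <- match.arg(kernel)
  pts <- as.matrix(points)
  if (!nrow(pts)) .stopf("no points supplied")
  if (radius <= 0) .stopf("radius must be positive")
  if (cellSize > radius / 5) .stopf("cellSize must be <= radius / 5")

  xmin <- min(pts[, 1]) - radius
  ymin <- min(pts[, 2]) - radius
  nx <- ceiling((max(pts[, 1]) + radius - xmin) / cellSize) + 1L
  ny <- ceiling((max(pts[, 2]) + radius - ymin) / cellSize) + 1L
  xs <- xmin + (seq_len(nx) - 0.5) * cellSize
  ys <- ymin + (seq_len(ny) - 0.5) * cellSize
  vals <- matrix(0, ny, nx)

  h2 <- radius^2
  for (i in seq_len(nrow(pts))) {
    jx <- which(abs(xs - pts[i, 1]) <= radius)
    jy <- which(abs(ys - pts[i, 2]) <= radius)
    if (!length(jx) || !length(jy)) next
    d2 <- outer(ys[jy] - pts[i, 2], xs[jx] - pts[i, 1], function(a, b) a^2 + b^2)
    if (kernel == "quartic") {
      k <- 3 / (pi * h2) * (1 - d2 / h2)^2
    } else {
      k <- matrix(1 / (pi * h2), nrow(d2), ncol(d2))
    }
    k[d2 > h2] <- 0
    vals[jy, jx] <- vals[jy, jx] + k
  }
  new("DensitySurface",
    values = vals, xmin = xmin, ymin = ymin, cellSize = cellSize,
    tiers = matrix(character(), 0, 0)
  )
}

#' Classify a density surface into low / medium / high tiers
#'
#' Zero cells are labeled `none`; positive cells are split at the tertiles
#' (33.3 and 66.7 percentiles) of their percentile ranks, with tied values
#' sharing the minimum rank so that ties fall deterministically into the
#' lower tier (a surface of equal positive values is entirely `low`, while a
#' single positive cell is `high`).
#'
#' @param surface a [DensitySurface-class] object.
#' @return the surface with the `tiers` slot filled; tier counts in
#'   attribute `counts`.
#' @export
classifyTiers <- function(surface) {
  v <- surface@values
  posIdx <- which(v > 0)
  tiers <- matrix("none", nrow(v), ncol(v))
  if (length(posIdx)) {
    frac <- rank(v[posIdx], ties.method = "min") / length(posIdx)
    lab <- ifelse(frac <= 1 / 3, "low", ifelse(frac <= 2 / 3, "medium", "high"))
    tiers[posIdx] <- lab
  }
  surface@tiers <- tiers
  tab <- table(factor(tiers, levels = c("none", "low", "medium", "high")))
  attr(surface, "counts") <- setNames(as.integer(tab), names(tab))
  surface
}

#' First-capture location per individual
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @return matrix of x,y coordinates, one row per individual (earliest
#'   capture).
#' @export
firstCaptureLocations <- function(catalog) {
  cap <- captures(catalog)
  first <- cap[!duplicated(cap$individual), , drop = FALSE] # captures are date-sorted
  m <- cbind(x = first$x, y = first$y)
  rownames(m) <- first$individual
  m
}

#' Detect road crossings from repeated captures
#'
#' Each individual's captures are date-sorted and labeled by
#' [sideOfRoad()]; every adjacent pair of captures on opposite sides is one
#' crossing. `ON` labels carry the previous side forward.
#'
#' @param catalog an [IndividualCatalog-class] object.
#' @param road 2-column matrix of road vertices.
#' @return list with `events` (data.frame individual, fromSample, toSample,
#'   fromSide, toSide, date) and `counts` (named integer per individual,
#'   individuals with >= 1 crossing).
#' @export
detectRoadCrossings <- function(catalog, road) {
  cap <- captures(catalog)
  if (anyNA(cap$date)) {
    .warnf("excluding %d undated captures", sum(is.na(cap$date)))
    cap <- cap[!is.na(cap$date), , drop = FALSE]
  }
  sides <- sideOfRoad(cap$x, cap$y, road = road)
  events <- list()
  counts <- integer(0)
  for (ind in unique(cap$individual)) {
    rows <- which(cap$individual == ind) # already date-sorted
    lab <- sides[rows]
    prev <- NA_character_
    prevRow <- NA_integer_
    cnt <- 0L
    for (r in seq_along(lab)) {
      s <- lab[r]
      if (s == "ON") next
      if (!is.na(prev) && s != prev) {
        cnt <- cnt + 1L
        events[[length(events) + 1L]] <- data.frame(
          individual = ind,
          fromSample = cap$sample[rows[prevRow]],
          toSample = cap$sample[rows[r]],
          fromSide = prev, toSide = s,
          date = cap$date[rows[r]],
          stringsAsFactors = FALSE
        )
      }
      prev <- s
      prevRow <- r
    }
    if (cnt > 0) counts[ind] <- cnt
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(
      individual = character(), fromSample = character(), toSample = character(),
      fromSide = character(), toSide = character(), date = as.Date(character()),
      stringsAsFactors = FALSE
    )
  }
  ev <- ev[order(ev$date, ev$individual), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, counts = counts, total = sum(counts))
}
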