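## Abundance estimation: equal-capture multinomial-occupancy MLE and a
## spatially explicit capture-recapture likelihood with Poisson count
## detectors and half-normal detection.

#' Equal-capture-model population size estimate
#'
#' Under equal capture probabilities, the probability that T captures
#' distributed uniformly over N individuals hit exactly the k observed ones
#' is proportional to \eqn{N!/(N-k)! \cdot N^{-T}}. The MLE is found by an
#' exact integer search of the log-likelihood over `[k, nmax]`; the
#' confidence interval is a parametric percentile bootstrap that re-simulates
#' T uniform captures over the fitted N and refits.
#'
#' @param counts integer vector of per-individual capture totals (all >= 1).
#' @param nmax upper search bound (default `nmaxMult * k`).
#' @param nmaxMult multiplier for the default bound.
#' @param bootstrap number of bootstrap replicates (0 skips the CI).
#' @param level confidence level.
#' @param seed optional RNG seed for the bootstrap.
#' @return An [EcmFit-class] object.
#' @examples
#' fitEcm(c(2, 1), bootstrap = 0)
#' @export
fitEcm <- function(counts, nmax = NULL, nmaxMult = 20L, bootstrap = 500L,
                   level = 0.95, seed = NULL) {
  counts <- as.integer(counts)
  if (any(counts < 1L)) .stopf("capture counts must all be >= 1")
  k <- length(counts)
  if (k < 2L) .stopf("need at least 2 observed individuals")
  Tcap <- sum(counts)
  if (is.null(nmax)) nmax <- nmaxMult * k
  nmax <- as.integer(nmax)

  mle <- function(k, Tcap) {
    Ngrid <- k:nmax
    ll <- lfactorial(Ngrid) - lfactorial(Ngrid - k) - Tcap * log(Ngrid)
    list(N = Ngrid[which.max(ll)], ll = ll, Ngrid = Ngrid)
  }
  fit <- mle(k, Tcap)
  capped <- fit$N == nmax
  if (capped && all(counts == 1L)) {
    .warnf("all individuals captured once: likelihood is monotone, estimate capped at nmax = %d", nmax)
  }

  boot <- numeric(0)
  ci <- c(NA_integer_, NA_integer_)
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(bootstrap), function(b) {
      tab <- tabulate(sample.int(fit$N, Tcap, replace = TRUE), nbins = fit$N)
      cnt <- tab[tab > 0L]
      mle(length(cnt), Tcap)$N
    }, 1.0)
    alpha <- (1 - level) / 2
    ci <- as.integer(round(quantile(boot, c(alpha, 1 - alpha), type = 1)))
  }

  new("EcmFit",
    N = as.integer(fit$N), ci = ci, logLik = fit$ll, Ngrid = fit$Ngrid,
    capped = capped, k = as.integer(k), captures = as.integer(Tcap),
    boot = boot
  )
}

## SECR ----------------------------------------------------------------------

#' Build a habitat mask for the SECR likelihood
#'
#' Rectangular grid of habitat points covering the detector array buffered on
#' every side, discretized at `pitch` meters.
#'
#' @param detectorCoords data.frame with columns `x`, `y` (meters).
#' @param buffer buffer width in meters (4 x the expected sigma is standard).
#' @param pitch mask cell edge length in meters.
#' @return list with `x`, `y` (cell centers) and `cellAreaKm2`.
#' @export
makeMask <- function(detectorCoords, buffer, pitch) {
  xs <- seq(min(detectorCoords$x) - buffer, max(detectorCoords$x) + buffer, by = pitch)
  ys <- seq(min(detectorCoords$y) - buffer, max(detectorCoords$y) + buffer, by = pitch)
  gg <- expand.grid(x = xs, y = ys)
  list(x = gg$x, y = gg$y, cellAreaKm2 = (pitch / 1000)^2)
}

# collapse a CaptureHistory (or pass-through list) to the n x J count matrix
# used by the likelihood; occasions are exchangeable under a constant hazard,
# so total counts per individual x detector are sufficient.
.secrCounts <- function(ch) {
  if (is(ch, "CaptureHistory")) {
    det <- detectors(ch)
    cnt <- ch@counts
    inds <- names(captureTotals(ch))
    Y <- matrix(0L, length(inds), nrow(det),
      dimnames = list(inds, det$detector)
    )
    for (r in seq_len(nrow(cnt))) {
      Y[cnt$individual[r], as.character(cnt$detector[r])] <-
        Y[cnt$individual[r], as.character(cnt$detector[r])] + cnt$n[r]
    }
    list(Y = Y, detectors = det, occasions = length(ch@occasionBreaks) - 1L)
  } else {
    ch
  }
}

#' Fit a spatially explicit capture-recapture model
#'
#' Poisson count-detector model with half-normal detection: the expected
#' number of detections of an individual with activity center s at detector
#' j per occasion is \eqn{\lambda_0 \exp(-d_{sj}^2 / 2\sigma^2)}. Activity
#' centers follow a homogeneous Poisson process of density D over a
#' discretized habitat mask; the full likelihood integrates over the mask.
#' Optimization is quasi-Newton on log-scale parameters from `nStarts`
#' jittered starts; Wald intervals are computed on the log scale and
#' back-transformed.
#'
#' @param ch a [CaptureHistory-class] object, or a list with elements `Y`
#'   (individual x detector count matrix), `detectors` (data.frame `detector`,
#'   `x`, `y`) and `occasions`.
#' @param mask optional mask from [makeMask()]; defaults to the detectors
#'   buffered by 4 x the starting sigma at the detector pitch.
#' @param maskPitch mask discretization in meters (defaults to the median
#'   nearest-neighbor detector spacing).
#' @param nStarts number of jittered optimizer starts.
#' @param level confidence level for the Wald intervals.
#' @param seed optional RNG seed controlling the start jitter.
#' @return A [SecrFit-class] object.
#' @export
fitSecr <- function(ch, mask = NULL, maskPitch = NULL, nStarts = 3L,
                    level = 0.95, seed = NULL) {
  dat <- .secrCounts(ch)
  Y <- dat$Y
  det <- dat$detectors
  Tocc <- dat$occasions
  n <- nrow(Y)
  if (n == 0 || sum(Y) == 0) .stopf("no detections: cannot fit SECR")
  detPerInd <- rowSums(Y > 0)
  usedDet <- colSums(Y) > 0
  if (all(detPerInd <= 1L) && sum(usedDet) <= 1L) {
    .stopf("all detections at a single detector: sigma is not identifiable; use coarser occasions or more data")
  }
  if (n < 2L || sum(usedDet) < 2L) {
    .stopf("need >= 2 individuals detected at >= 2 distinct detectors for sigma identifiability")
  }

  # starting values: sigma from the pooled within-individual detector spread,
  # lambda0 from the mean detection count, D from n over the buffered area
  sigma0 <- {
    sp <- c()
    for (i in seq_len(n)) {
      j <- which(Y[i, ] > 0)
      if (length(j) >= 2) {
        w <- Y[i, j]
        cx <- sum(det$x[j] * w) / sum(w)
        cy <- sum(det$y[j] * w) / sum(w)
        sp <- c(sp, rep(sqrt((det$x[j] - cx)^2 + (det$y[j] - cy)^2), w))
      }
    }
    s <- if (length(sp) >= 2) sqrt(mean(sp^2) * 2) else NA
    if (!is.finite(s) || s <= 0) s <- diff(range(det$x, det$y)) / 10
    s
  }
  if (is.null(maskPitch)) {
    dx <- sort(unique(det$x))
    maskPitch <- if (length(dx) > 1) min(diff(dx)) else sigma0
  }
  if (is.null(mask)) mask <- makeMask(det, buffer = 4 * sigma0, pitch = maskPitch)
  a <- mask$cellAreaKm2
  S <- length(mask$x)
  if (S == 0) .stopf("empty mask")

  d2 <- outer(mask$x, det$x, "-")^2 + outer(mask$y, det$y, "-")^2 # S x J
  areaKm2 <- S * a
  D0 <- max(n / areaKm2, 1e-6)
  lambda00 <- max(sum(Y) / (n * Tocc * pi * 2 * (sigma0 / maskPitch)^2), 1e-4)

  lgamY <- sum(lfactorial(Y))
  Yt <- t(Y) # J x n
  negll <- function(par) {
    D <- exp(par[1])
    lambda0 <- exp(par[2])
    sigma <- exp(par[3])
    lam <- lambda0 * exp(-d2 / (2 * sigma^2)) # S x J, per occasion
    lamTot <- Tocc * rowSums(lam) # S
    pdot <- 1 - exp(-lamTot)
    Lambda <- D * a * sum(pdot)
    # computed on the log scale directly so distant cells never yield -Inf
    loglam <- log(Tocc * lambda0) - d2 / (2 * sigma^2) # S x J
    M <- loglam %*% Yt # S x n: sum_j y_ij log(T lam_sj)
    M <- M - lamTot
    mx <- apply(M, 2, max)
    intS <- log(colSums(exp(sweep(M, 2, mx, "-")))) + mx + log(a)
    ll <- sum(log(D) + intS) - Lambda - lgamY
    if (!is.finite(ll)) 1e10 else -ll
  }

  if (!is.null(seed)) set.seed(seed)
  base <- log(c(D0, lambda00, sigma0))
  best <- NULL
  for (s in seq_len(nStarts)) {
    start <- if (s == 1) base else base + rnorm(3, 0, 0.4)
    fit <- tryCatch(
      optim(start, negll, method = "BFGS", control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) .stopf("SECR optimization failed from every start")

  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- matrix(NA_real_, 3, 2, dimnames = list(c("D", "lambda0", "sigma"), c("lower", "upper")))
  if (!is.null(hess)) {
    se <- tryCatch(sqrt(diag(solve(hess))), error = function(e) rep(NA_real_, 3))
    ci[, 1] <- exp(best$par - z * se)
    ci[, 2] <- exp(best$par + z * se)
  }
  est <- exp(best$par)
  new("SecrFit",
    D = est[1], lambda0 = est[2], sigma = est[3], ci = ci,
    maskArea = areaKm2, N = est[1] * areaKm2, logLik = -best$value,
    convergence = as.integer(best$convergence)
  )
}

#' SECR log-likelihood at given parameter values
#'
#' Exposes the likelihood used by [fitSecr()] so the fitted maximum can be
#' checked against perturbed parameter values.
#'
#' @inheritParams fitSecr
#' @param D,lambda0,sigma parameter values (density per km^2, detections per
#'   occasion at distance zero, meters).
#' @param mask mask from [makeMask()].
#' @return log-likelihood value.
#' @export
secrLogLik <- function(ch, D, lambda0, sigma, mask) {
  dat <- .secrCounts(ch)
  Y <- dat$Y
  det <- dat$detectors
  Tocc <- dat$occasions
  a <- mask$cellAreaKm2
  d2 <- outer(mask$x, det$x, "-")^2 + outer(mask$y, det$y, "-")^2
  lam <- lambda0 * exp(-d2 / (2 * sigma^2))
  lamTot <- Tocc * rowSums(lam)
  pdot <- 1 - exp(-lamTot)
  Lambda <- D * a * sum(pdot)
  M <- (log(Tocc * lambda0) - d2 / (2 * sigma^2)) %*% t(Y) - lamTot
  mx <- apply(M, 2, max)
  intS <- log(colSums(exp(sweep(M, 2, mx, "-")))) + mx + log(a)
  sum(log(D) + intS) - Lambda - sum(lfactorial(Y))
}
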