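#' Detect rings by circular Hough transform
#'
#' Background-subtracted intensity votes for circle centers: for each
#' candidate radius the image is correlated with a zero-mean Gaussian
#' annulus template (a matched filter whose response estimates the ring
#' amplitude at that center and radius). Local maxima of the
#' radius-maximized accumulator are thresholded and reduced by greedy
#' non-maximum suppression with a minimum center separation.
#'
#' @param image intensity matrix (preprocessed: averaged/filtered).
#' @param radiusRangePx numeric length-2, candidate radii in px.
#' @param radiusStepPx radius sampling step, px.
#' @param minSepPx minimum center separation for suppression; defaults to
#'   the minimum radius.
#' @param scoreFrac detection threshold as a fraction of the robust
#'   intensity range (0.999 quantile minus median) of the image.
#' @param profileSigmaPx Gaussian radial cross-section width of the
#'   annulus template, px (roughly the PSF + filtering width).
#' @param refine logical; refine each detection with [fitCircle] on a
#'   +/- 1.5 px grid.
#' @return list of [RingROI-class] objects (possibly empty), sorted by
#'   decreasing accumulator score.
#' @export
detectRings <- function(image, radiusRangePx = c(3, 12), radiusStepPx = 0.5,
                        minSepPx = NULL, scoreFrac = 0.4, refine = TRUE,
                        profileSigmaPx = 2) {
  stopifnot(is.matrix(image), length(radiusRangePx) == 2L,
            radiusRangePx[1] >= 2, radiusRangePx[2] >= radiusRangePx[1])
  if (is.null(minSepPx)) minSepPx <- radiusRangePx[1]
  # signed residuals: annulus means of pure noise then average to ~0
  img0 <- image - median(image)
  radii <- seq(radiusRangePx[1], radiusRangePx[2], by = radiusStepPx)

  acc <- matrix(-Inf, nrow(image), ncol(image))
  accR <- matrix(radii[1], nrow(image), ncol(image))
  for (r in radii) {
    # matched filter: zero-mean Gaussian annulus template, scaled so the
    # response estimates the ring amplitude in image units. A full ring
    # matches the whole template; a straight bright line or an isolated
    # blob only overlaps part of it and scores much lower.
    half <- ceiling(r + 3 * profileSigmaPx)
    d <- sqrt(outer((-half:half)^2, (-half:half)^2, "+"))
    tmpl <- exp(-(d - r)^2 / (2 * profileSigmaPx^2))
    tmpl <- tmpl - mean(tmpl)
    tmpl <- tmpl / sum(tmpl[tmpl > 0])
    a <- as.matrix(EBImage::filter2(EBImage::Image(img0), tmpl))
    upd <- a > acc
    acc[upd] <- a[upd]
    accR[upd] <- r
  }

  thr <- scoreFrac * max(quantile(img0, 0.999), .Machine$double.eps)
  # 3x3 local maxima above threshold, excluding a border where the
  # annulus kernel was truncated
  border <- ceiling(radiusRangePx[2] + 2 * profileSigmaPx)
  nr <- nrow(acc); nc <- ncol(acc)
  cand <- which(acc >= thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > border & cand[, 1] <= nr - border &
               cand[, 2] > border & cand[, 2] <= nc - border, , drop = FALSE]
  isMax <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    isMax[i] <- acc[y, x] >= max(acc[(y - 1):(y + 1), (x - 1):(x + 1)])
  }
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())

  sc <- acc[cand]
  o <- order(sc, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; sc <- sc[o]
  # greedy NMS: disjoint rings have centers at least r1 + r2 apart, so a
  # weaker candidate closer than that to an accepted center is a duplicate
  # response of the same ring
  kept <- matrix(numeric(), 0, 2); keptR <- numeric(); keptIdx <- integer()
  for (i in seq_len(nrow(cand))) {
    ri <- accR[cand[i, 1], cand[i, 2]]
    if (nrow(kept)) {
      dd <- sqrt((kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2)
      if (any(dd <= pmax(minSepPx, keptR + ri))) next
    }
    kept <- rbind(kept, cand[i, ])
    keptR <- c(keptR, ri)
    keptIdx <- c(keptIdx, i)
  }

  rois <- vector("list", length(keptIdx))
  for (j in seq_along(keptIdx)) {
    i <- keptIdx[j]
    ctr <- as.numeric(cand[i, ]); r <- accR[cand[i, 1], cand[i, 2]]
    if (refine) {
      roi <- tryCatch(
        fitCircle(image, ctr + c(0, -r), ctr + c(0, r),
                  gridHalfWidthPx = 1.5, gridStepPx = 0.25, nAngles = 48L),
        error = function(e) NULL)
      if (!is.null(roi) && !roi@lowConfidence) { rois[[j]] <- roi; next }
    }
    rois[[j]] <- RingROI(ctr, r, score = sc[i])
  }
  rois
}

#' Ring surface density
#'
#' Number of detected rings per unit membrane area.
#'
#' @param detections list of [RingROI-class] (or an integer count).
#' @param areaUm2 field area in square micrometers (> 0).
#' @return density in rings per um^2.
#' @export
ringDensity <- function(detections, areaUm2) {
  if (areaUm2 <= 0) stop("area must be > 0")
  n <- if (is.numeric(detections)) detections else length(detections)
  n / areaUm2
}

#' Gaussian fit to a histogram of ring diameters (or velocities)
#'
#' Histograms the values at the stated bin width and fits a Gaussian curve
#' to the bin counts by least squares -- the plotted-curve convention of
#' ring-size and velocity distribution figures (curve on histogram, not a
#' maximum-likelihood fit to the samples).
#'
#' @param values numeric vector (e.g. diameters in um), or a list of
#'   [RingROI-class] together with `pixelSizeNm` to convert fitted radii
#'   to diameters in um.
#' @param binWidth histogram bin width (same units as values); 0.1 um is
#'   the diameter default, 2 nm/s suits velocities.
#' @param pixelSizeNm needed only when `values` is a list of ROIs.
#' @return A [GaussianFit-class] (mean/sd in the units of the input).
#' @export
diameterHistogramFit <- function(values, binWidth = 0.1, pixelSizeNm = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    stopifnot(!is.null(pixelSizeNm))
    values <- vapply(values, function(r) 2 * ringRadius(r) * pixelSizeNm / 1000,
                     numeric(1))
  }
  values <- values[is.finite(values)]
  if (length(values) < 30L)
    warning("fewer than 30 values: histogram fit will be unstable")
  if (sd(values) == 0) stop("degenerate input: all values identical")
  edges <- seq(floor(min(values) / binWidth) * binWidth,
               ceiling(max(values) / binWidth) * binWidth + binWidth / 2,
               by = binWidth)
  h <- hist(values, breaks = edges, plot = FALSE)
  x <- h$mids; counts <- h$counts
  mu0 <- mean(values); sd0 <- sd(values); a0 <- max(counts)
  fit <- minpack.lm::nlsLM(counts ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                           start = list(a = a0, mu = mu0, s = sd0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(fit)
  new("GaussianFit", mean = unname(p[["mu"]]), sd = abs(unname(p[["s"]])),
      amplitude = unname(p[["a"]]), binEdges = edges)
}

# Kasa algebraic circle fit: least squares of x^2+y^2 = a x + b y + c.
# Returns radius (same units as the points) or Inf for collinear windows.
kasaRadius <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  z <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, z, tol = 1e-12), error = function(e) NULL)
  if (is.null(sol)) return(Inf)
  r2 <- sol[3] + sol[1]^2 / 4 + sol[2]^2 / 4
  if (!is.finite(r2) || r2 <= 0) return(Inf)
  sqrt(r2)
}

#' Curvature profile along a filament centerline
#'
#' For each interior point, a circle is fitted algebraically (Kasa fit) to
#' the sliding window of points centered there; the local curvature is the
#' reciprocal of the fitted radius (unsigned: curvature magnitudes are
#' reported). Collinear windows get curvature 0 (infinite radius), and the
#' profile is padded at the ends with the nearest interior value.
#'
#' @param trace n x 2 matrix of ordered centerline points, columns x/y in
#'   nm (n >= 5).
#' @param windowPts sliding window length (odd, >= 5).
#' @return numeric vector of curvatures in 1/um, one per centerline point.
#' @examples
#' th <- seq(0, pi, length.out = 60)
#' arc <- cbind(1250 * cos(th), 1250 * sin(th))   # R = 1.25 um in nm
#' range(curvatureProfile(arc))                   # ~0.8 1/um throughout
#' @export
curvatureProfile <- function(trace, windowPts = 7L) {
  trace <- as.matrix(trace)
  stopifnot(ncol(trace) == 2L)
  n <- nrow(trace)
  if (n < 5L) stop("need >= 5 centerline points")
  w <- as.integer(windowPts)
  if (w %% 2L == 0L || w < 5L) stop("window must be odd and >= 5")
  w <- min(w, if (n %% 2L) n else n - 1L)
  h <- (w - 1L) %/% 2L
  kap <- rep(NA_real_, n)
  for (i in (h + 1L):(n - h)) {
    R <- kasaRadius(trace[(i - h):(i + h), , drop = FALSE])
    kap[i] <- if (is.finite(R)) 1000 / R else 0     # nm -> 1/um
  }
  kap[seq_len(h)] <- kap[h + 1L]
  kap[(n - h + 1L):n] <- kap[n - h]
  kap
}

#' Extreme-value (Gumbel) fit to a curvature histogram
#'
#' Histograms the curvature magnitudes and fits a scaled Gumbel (type-I
#' extreme value) density to the bin counts by least squares, the
#' "extreme fit" convention used for filament curvature distributions.
#' A Weibull alternative is selectable; its scale parameter is reported in
#' the `location` slot and its shape in `scale`.
#'
#' @param curvatures numeric vector, 1/um (>= 100 values recommended).
#' @param binWidth histogram bin width, 1/um.
#' @param family `"gumbel"` (default) or `"weibull"`.
#' @return An [ExtremeFit-class]; `flagged` is TRUE when the optimizer
#'   ended at a non-positive scale.
#' @export
curvatureHistogramFit <- function(curvatures, binWidth = 0.25,
                                  family = c("gumbel", "weibull")) {
  family <- match.arg(family)
  curvatures <- curvatures[is.finite(curvatures)]
  if (length(curvatures) < 100L)
    warning("fewer than 100 values: extreme-value histogram fit will be unstable")
  edges <- seq(floor(min(curvatures) / binWidth) * binWidth,
               ceiling(max(curvatures) / binWidth) * binWidth + binWidth / 2,
               by = binWidth)
  h <- hist(curvatures, breaks = edges, plot = FALSE)
  x <- h$mids; counts <- h$counts
  n <- length(curvatures)
  if (family == "gumbel") {
    b0 <- sd(curvatures) * sqrt(6) / pi
    mu0 <- mean(curvatures) - 0.5772156649 * b0
    a0 <- n * binWidth
    fit <- minpack.lm::nlsLM(
      counts ~ a / b * exp(-((x - mu) / b + exp(-(x - mu) / b))),
      start = list(a = a0, mu = mu0, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- coef(fit)
    new("ExtremeFit", location = unname(p[["mu"]]), scale = unname(p[["b"]]),
        amplitude = unname(p[["a"]]), binEdges = edges,
        flagged = !(is.finite(p[["b"]]) && p[["b"]] > 0))
  } else {
    lam0 <- mean(curvatures); k0 <- 1.5; a0 <- n * binWidth
    fit <- minpack.lm::nlsLM(
      counts ~ a * (k / lam) * pmax(x / lam, 1e-12)^(k - 1) *
        exp(-pmax(x / lam, 0)^k),
      start = list(a = a0, lam = lam0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- coef(fit)
    new("ExtremeFit", location = unname(p[["lam"]]), scale = unname(p[["k"]]),
        amplitude = unname(p[["a"]]), binEdges = edges,
        flagged = !(is.finite(p[["k"]]) && p[["k"]] > 0))
  }
}

#' Percent difference relative to a reference
#'
#' 100 * (reference - value) / reference: e.g. the reduction of the mean
#' ring diameter of a halogenated variant relative to the wild type.
#'
#' @param reference reference value (e.g. wild-type mean).
#' @param value comparison value.
#' @return signed percent difference (positive = reduction).
#' @examples
#' percentDifference(0.80, 0.62)   # 22.5
#' @export
percentDifference <- function(reference, value) {
  100 * (reference - value) / reference
}
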