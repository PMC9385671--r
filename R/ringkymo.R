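#' Fit a circle to a ring from two seed points
#'
#' The two seeds are taken as (approximately) diametrically opposite points
#' on the ring: the initial guess is their midpoint (center) and half their
#' distance (radius). The geometry is then refined by maximizing the mean
#' ring-path intensity over a local grid (center +/- `gridHalfWidthPx` and
#' radius +/- `gridHalfWidthPx`, step `gridStepPx`), with a final 3-point
#' parabolic sub-step interpolation on each axis. The image supplied should
#' be the frame-averaged, mean-filtered still (see [averageFrames],
#' [meanFilter]).
#'
#' @param image preprocessed image matrix.
#' @param seedA,seedB numeric (row, col) seed points, px.
#' @param gridHalfWidthPx half-width of the refinement grid, px.
#' @param gridStepPx refinement grid step, px.
#' @param nAngles number of path samples used in the intensity objective.
#' @param blurCorrect logical. The radius of maximal path intensity of a
#'   blurred thin ring sits inside the true fluorophore circle (the
#'   azimuthally averaged image of a ring of radius r blurred with total
#'   width sigma peaks near sqrt(r^2 - sigma^2)). When TRUE (default) the
#'   effective blur width is measured from a Gaussian fit to the radial
#'   intensity profile and the reported radius is corrected to
#'   sqrt(rho*^2 + sigma^2).
#' @return A [RingROI-class]. `lowConfidence` is set when the intensity
#'   landscape is flat and the initial guess is returned unrefined.
#' @export
fitCircle <- function(image, seedA, seedB, gridHalfWidthPx = 3,
                      gridStepPx = 0.25, nAngles = 72L, blurCorrect = TRUE) {
  stopifnot(is.matrix(image), length(seedA) == 2L, length(seedB) == 2L)
  if (all(seedA == seedB)) stop("seed points must be distinct")
  inField <- function(p) all(p >= 1) && p[1] <= nrow(image) && p[2] <= ncol(image)
  if (!inField(seedA) || !inField(seedB)) stop("seed points outside the field")
  center0 <- (seedA + seedB) / 2
  radius0 <- sqrt(sum((seedA - seedB)^2)) / 2
  seeds <- rbind(seedA, seedB)

  offs <- seq(-gridHalfWidthPx, gridHalfWidthPx, by = gridStepPx)
  cand <- expand.grid(dr = offs, dc = offs, drad = offs)
  cand$rad <- radius0 + cand$drad
  cand <- cand[cand$rad >= 2, , drop = FALSE]
  # candidate circles of radius rad+1 must stay inside the field
  keep <- (center0[1] + cand$dr - cand$rad - 1) >= 1 &
          (center0[1] + cand$dr + cand$rad + 1) <= nrow(image) &
          (center0[2] + cand$dc - cand$rad - 1) >= 1 &
          (center0[2] + cand$dc + cand$rad + 1) <= ncol(image)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no candidate circle of radius >= 2 fits inside the field")

  th <- seq(0, 2 * pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
  rows <- outer(center0[1] + cand$dr, rep(1, nAngles)) -
    cand$rad %o% sin(th)
  cols <- outer(center0[2] + cand$dc, rep(1, nAngles)) +
    cand$rad %o% cos(th)
  vals <- matrix(bilinearSample(image, as.vector(rows), as.vector(cols)),
                 nrow(cand), nAngles)
  score <- rowMeans(vals)

  if (diff(range(score)) <= 1e-9 * max(abs(score), 1))
    return(RingROI(center0, max(radius0, 2), seeds, score = score[1],
                   lowConfidence = TRUE))

  best <- which.max(score)
  bdr <- cand$dr[best]; bdc <- cand$dc[best]; brad <- cand$rad[best]
  # parabolic sub-step refinement, one axis at a time
  ringScore <- function(cy, cx, r) {
    mean(bilinearSample(image, cy - r * sin(th), cx + r * cos(th)))
  }
  s <- gridStepPx
  bdr <- bdr + s * parabolicPeak(ringScore(center0[1] + bdr - s, center0[2] + bdc, brad),
                                 score[best],
                                 ringScore(center0[1] + bdr + s, center0[2] + bdc, brad))
  bdc <- bdc + s * parabolicPeak(ringScore(center0[1] + bdr, center0[2] + bdc - s, brad),
                                 ringScore(center0[1] + bdr, center0[2] + bdc, brad),
                                 ringScore(center0[1] + bdr, center0[2] + bdc + s, brad))
  brad <- brad + s * parabolicPeak(ringScore(center0[1] + bdr, center0[2] + bdc, brad - s),
                                   ringScore(center0[1] + bdr, center0[2] + bdc, brad),
                                   ringScore(center0[1] + bdr, center0[2] + bdc, brad + s))
  center <- center0 + c(bdr, bdc)
  if (blurCorrect) {
    # measure the effective blur width from the radial profile and undo
    # the inward bias of the intensity-peak radius
    rGrid <- seq(max(1, brad - 3), brad + 3, by = 0.25)
    rGrid <- rGrid[center[1] + rGrid + 1 <= nrow(image) &
                   center[1] - rGrid - 1 >= 1 &
                   center[2] + rGrid + 1 <= ncol(image) &
                   center[2] - rGrid - 1 >= 1]
    prof <- vapply(rGrid, function(r) ringScore(center[1], center[2], r),
                   numeric(1))
    gf <- tryCatch(
      minpack.lm::nlsLM(prof ~ b0 + a * exp(-(rGrid - m)^2 / (2 * s^2)),
                        start = list(b0 = min(prof), a = diff(range(prof)),
                                     m = brad, s = 1.5),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(gf)) {
      p <- coef(gf)
      if (is.finite(p[["s"]]) && abs(p[["s"]]) < 3.5 && abs(p[["m"]] - brad) < 1.5)
        brad <- sqrt(max(p[["m"]], 2)^2 + p[["s"]]^2)
    }
  }
  if (center[1] - brad - 1 < 1 || center[1] + brad + 1 > nrow(image) ||
      center[2] - brad - 1 < 1 || center[2] + brad + 1 > ncol(image))
    stop("refined circle (radius + 1) leaves the field")
  RingROI(center, brad, seeds,
          score = ringScore(center[1], center[2], brad), lowConfidence = FALSE)
}

#' Three concentric circular sampling trajectories
#'
#' Ordered (row, col) sub-pixel sample points along circles of radius
#' r - 1, r and r + 1 px around the ROI center. The middle circle is
#' sampled at an arc step of 1 px (M = round(2 pi r) samples); the inner
#' and outer circles are sampled at the same M angles so that the three
#' trajectories can be averaged coherently point by point. The angular
#' origin is at 3 o'clock and the orientation counter-clockwise.
#'
#' @param roi a [RingROI-class] with radius >= 2 px.
#' @param arcStepPx arc step on the middle circle, px.
#' @return list with elements `inner`, `middle`, `outer` (M x 2 matrices of
#'   row/col), `angles` and `arcStepPx`.
#' @export
concentricTrajectories <- function(roi, arcStepPx = 1) {
  r <- ringRadius(roi)
  if (r < 2) stop("ring radius must be >= 2 px (inner circle needs r - 1 >= 1)")
  M <- max(8L, round(2 * pi * r / arcStepPx))
  th <- seq(0, 2 * pi, length.out = M + 1L)[-(M + 1L)]
  ctr <- ringCenter(roi)
  path <- function(rad)
    cbind(row = ctr[1] - rad * sin(th), col = ctr[2] + rad * cos(th))
  list(inner = path(r - 1), middle = path(r), outer = path(r + 1),
       angles = th, arcStepPx = 2 * pi * r / M)
}

#' Extract a circumferential kymograph
#'
#' For each frame, intensity is sampled by bilinear interpolation at every
#' point of the three concentric trajectories; the three are averaged
#' pointwise. Rows of the result are frames, columns angular positions.
#'
#' @param movie an [FtsZMovie-class].
#' @param roi a [RingROI-class]; the outer trajectory (r + 1) must lie
#'   inside the field.
#' @param arcStepPx arc step on the middle circle, px.
#' @return A [Kymograph-class] carrying the movie's physical metadata and
#'   the ROI radius.
#' @export
extractKymograph <- function(movie, roi, arcStepPx = 1) {
  traj <- concentricTrajectories(roi, arcStepPx)
  d <- dim(movie@stack)
  pts <- rbind(traj$inner, traj$middle, traj$outer)
  if (min(pts) < 1 || max(pts[, 1]) > d[2] || max(pts[, 2]) > d[3])
    stop("sampling trajectories leave the field")
  M <- nrow(traj$middle)
  K <- matrix(NA_real_, d[1], M)
  for (t in seq_len(d[1])) {
    img <- movie@stack[t, , ]
    v <- bilinearSample(img, pts[, 1], pts[, 2])
    if (any(is.na(v)))
      stop(sprintf("NaN pixels under the trajectory in frame %d", t))
    K[t, ] <- (v[seq_len(M)] + v[M + seq_len(M)] + v[2 * M + seq_len(M)]) / 3
  }
  Kymograph(K, arcStepPx = traj$arcStepPx, frameIntervalS = movie@frameIntervalS,
            radiusPx = ringRadius(roi), pixelSizeNm = movie@pixelSizeNm)
}
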