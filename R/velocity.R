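#' Savitzky-Golay smoothing of a kymograph
#'
#' Order-2 Savitzky-Golay polynomial smoothing applied along the arclength
#' (angular) axis of every time row, with circular (wrap-around) boundary:
#' the circumference is periodic, so each row is extended by wrapping before
#' filtering. Order-2 smoothing preserves locally quadratic intensity
#' profiles exactly.
#'
#' @param kymo a [Kymograph-class].
#' @param window filter window length; odd, >= 5, <= number of angular
#'   samples.
#' @param order polynomial order.
#' @return smoothed [Kymograph-class].
#' @export
smoothKymograph <- function(kymo, window = 7L, order = 2L) {
  K <- kymoData(kymo)
  N <- ncol(K)
  w <- as.integer(window)
  if (w %% 2L == 0L) stop("window must be odd")
  if (w < 5L || w > N) stop(sprintf("window must be in [5, %d]", N))
  out <- K
  for (t in seq_len(nrow(K))) {
    xw <- c(K[t, (N - w + 1L):N], K[t, ], K[t, seq_len(w)])
    sm <- signal::sgolayfilt(xw, p = order, n = w)
    out[t, ] <- sm[(w + 1L):(w + N)]
  }
  initialize(kymo, data = out)
}

#' Contrast-limited adaptive histogram equalization of a kymograph
#'
#' CLAHE applied to the kymograph (default 8 x 8 tiles, clipped to the
#' array size), rescaled to [0, 1]. A contrast aid for weak stripe
#' patterns; it distorts amplitudes, so phase tracking prefers the raw
#' kymograph when the spectral SNR is already high. A constant input is
#' returned unchanged with attribute `flatInput = TRUE`.
#'
#' @param kymo a [Kymograph-class].
#' @param tiles requested tile count per dimension.
#' @param clipLimit normalized clip limit (fraction of tile pixels per
#'   histogram bin).
#' @param bins histogram bins.
#' @return enhanced [Kymograph-class] with values in [0, 1].
#' @export
enhanceContrast <- function(kymo, tiles = 8L, clipLimit = 0.01, bins = 256L) {
  K <- kymoData(kymo)
  rng <- range(K)
  if (diff(rng) == 0) {
    out <- initialize(kymo, data = K)
    attr(out@data, "flatInput") <- TRUE
    return(out)
  }
  K01 <- (K - rng[1]) / diff(rng)
  nx <- max(2L, min(as.integer(tiles), ncol(K) %/% 2L))
  ny <- max(2L, min(as.integer(tiles), nrow(K) %/% 2L))
  limit <- max(1, clipLimit * bins)
  enh <- EBImage::imageData(EBImage::clahe(EBImage::Image(K01), nx = nx,
                                           ny = ny, bins = bins,
                                           limit = limit))
  enh <- matrix(pmin(pmax(as.numeric(enh), 0), 1), nrow(K), ncol(K))
  initialize(kymo, data = enh)
}

#' Characteristic spatial frequency of a kymograph
#'
#' Per-row discrete Fourier transform along the arclength axis; power
#' spectra are averaged over rows (time) and the integer frequency k* with
#' maximal mean power over the search band k in [1, N/4] is returned,
#' together with the spectral peak SNR (peak power / median band power).
#'
#' @param kymo a [Kymograph-class] with >= 8 angular samples.
#' @param kMax upper edge of the search band (defaults to floor(N/4)).
#' @return list with `kStar` (cycles per circumference), `snr`, and the
#'   mean `power` over the band.
#' @export
characteristicFrequency <- function(kymo, kMax = NULL) {
  K <- kymoData(kymo)
  N <- ncol(K)
  if (N < 8L) stop("need >= 8 angular samples")
  if (is.null(kMax)) kMax <- N %/% 4L
  kMax <- max(1L, min(as.integer(kMax), N %/% 2L - 1L))
  Kc <- K - rowMeans(K)
  P <- matrix(0, nrow(K), kMax)
  for (t in seq_len(nrow(K))) {
    ft <- fft(Kc[t, ])
    P[t, ] <- Mod(ft[2:(kMax + 1L)])^2
  }
  meanP <- colMeans(P)
  kStar <- which.max(meanP)
  snr <- if (kMax > 1L) meanP[kStar] / median(meanP) else 1
  list(kStar = as.integer(kStar), snr = snr, power = meanP)
}

#' Treadmilling velocity from the Fourier phase slope
#'
#' Extracts the complex Fourier coefficient at the characteristic frequency
#' k* for each time row, unwraps its phase over time, and fits phase versus
#' time by least squares. Rows whose phase increment deviates from the
#' median increment by more than `jumpTol` are flagged as unwrap jumps and
#' excluded from the fit. The angular rate of the rotating pattern is
#' omega = (dphi/dt) / k*, and the speed is |omega| * r * pixel size
#' (nm/s). The quality gate ([qualityGate]) is applied with its default
#' thresholds to set the `accepted` flag.
#'
#' @param kymo a [Kymograph-class] with >= 5 rows and physical metadata
#'   (radius, pixel size) set, or supplied via `radiusPx` / `pixelSizeNm`.
#' @param kStar characteristic frequency from [characteristicFrequency].
#' @param snr spectral peak SNR to carry into the quality gate.
#' @param radiusPx,pixelSizeNm,frameIntervalS overrides for the kymograph
#'   metadata.
#' @param jumpTol phase-jump tolerance, rad.
#' @return A [VelocityEstimate-class].
#' @export
phaseSlopeVelocity <- function(kymo, kStar, snr = NA_real_,
                               radiusPx = NULL, pixelSizeNm = NULL,
                               frameIntervalS = NULL, jumpTol = pi) {
  K <- kymoData(kymo)
  if (nrow(K) < 5L) stop("need >= 5 kymograph rows for the phase fit")
  if (is.null(radiusPx)) radiusPx <- kymo@radiusPx
  if (is.null(pixelSizeNm)) pixelSizeNm <- kymo@pixelSizeNm
  if (is.null(frameIntervalS)) frameIntervalS <- kymo@frameIntervalS
  stopifnot(is.finite(radiusPx), is.finite(pixelSizeNm))
  k <- as.integer(kStar)
  phi <- apply(K, 1, function(row) Arg(fft(row - mean(row))[k + 1L]))
  phi <- signal::unwrap(phi)
  tt <- (seq_len(nrow(K)) - 1L) * frameIntervalS
  # flag rows at unwrap jumps: increments far from the running consensus
  inc <- diff(phi)
  medInc <- median(inc)
  bad <- c(FALSE, abs(inc - medInc) > jumpTol)
  keep <- !bad
  rowFraction <- mean(keep)
  if (sum(keep) < 3L) keep <- rep(TRUE, length(phi))
  tk <- tt[keep]; pk <- phi[keep]
  slope <- sum((tk - mean(tk)) * (pk - mean(pk))) / sum((tk - mean(tk))^2)
  ssTot <- sum((pk - mean(pk))^2)
  ssRes <- sum((pk - mean(pk) - slope * (tk - mean(tk)))^2)
  r2 <- if (ssTot > 1e-20) max(0, 1 - ssRes / ssTot) else 1
  omega <- slope / k                               # rad/s of the pattern
  speedNm <- abs(omega) * radiusPx * pixelSizeNm   # nm/s
  est <- new("VelocityEstimate", speedNmPerS = speedNm,
             angularRateRadPerS = omega, kStar = as.numeric(k),
             phaseSlope = slope, r2 = r2, snr = as.numeric(snr),
             rowFraction = rowFraction, accepted = NA)
  est@accepted <- qualityGate(est)
  est
}

#' Quality gate for velocity estimates
#'
#' A kymograph region is accepted when the spectral peak SNR, the phase-fit
#' R-squared and the fraction of rows surviving phase-jump filtering all
#' clear their thresholds. Estimates from low-quality kymograph regions
#' (noise-dominated spectra, unstable phase tracks) are thereby rejected.
#'
#' @param estimate a [VelocityEstimate-class].
#' @param snrMin minimum spectral peak SNR.
#' @param r2Min minimum phase-fit R-squared.
#' @param rowFractionMin minimum fraction of retained rows.
#' @return logical acceptance flag. An NA SNR (not measured) passes the
#'   SNR criterion.
#' @export
qualityGate <- function(estimate, snrMin = 2, r2Min = 0.8,
                        rowFractionMin = 0.8) {
  snrOk <- is.na(estimate@snr) || estimate@snr >= snrMin
  isTRUE(snrOk && estimate@r2 >= r2Min &&
         estimate@rowFraction >= rowFractionMin)
}

#' Full treadmilling-velocity pipeline for one ring
#'
#' Runs the complete chain on a raw movie: per-frame box mean filtering,
#' drift correction, frame averaging, two-seed circle fitting, kymograph
#' extraction along three concentric trajectories, Savitzky-Golay
#' smoothing, characteristic-frequency detection and phase-slope
#' velocimetry. Phase is tracked on the raw smoothed kymograph when the
#' spectral SNR is >= `claheBelowSnr`, and on the CLAHE-enhanced kymograph
#' otherwise (CLAHE rescues weak stripe patterns but distorts amplitudes).
#'
#' @param movie raw [FtsZMovie-class].
#' @param seedA,seedB two (row, col) seed points on the ring.
#' @param meanRadiusPx box mean-filter half-width, px.
#' @param avgFrames number of frames averaged for the circle-fit still;
#'   NULL (default) averages the whole movie, which for a treadmilling ring
#'   approximates rotational averaging and makes the ring-path objective
#'   insensitive to the instantaneous azimuthal profile.
#' @param sgWindow Savitzky-Golay window.
#' @param correctDrift logical; register frames before extraction.
#' @param claheBelowSnr SNR threshold under which CLAHE is applied before
#'   phase tracking.
#' @return list with `roi`, `kymo` (smoothed), `freq`, and `estimate`
#'   (a [VelocityEstimate-class]).
#' @export
estimateTreadmilling <- function(movie, seedA, seedB, meanRadiusPx = 2L,
                                 avgFrames = NULL, sgWindow = 7L,
                                 correctDrift = TRUE, claheBelowSnr = 5) {
  stack <- movie@stack
  for (t in seq_len(dim(stack)[1]))
    stack[t, , ] <- meanFilter(stack[t, , ], meanRadiusPx)
  prepped <- FtsZMovie(stack, movie@pixelSizeNm, movie@frameIntervalS)
  drift <- NULL
  if (correctDrift) {
    # linear drift model: robust to the tangential correlation pull of the
    # rotating azimuthal pattern (see driftCorrect)
    dc <- driftCorrect(prepped, model = "linear")
    prepped <- dc$movie
    drift <- dc$drift
  }
  if (is.null(avgFrames)) avgFrames <- nFrames(prepped)
  still <- averageFrames(prepped, min(avgFrames, nFrames(prepped)))
  roi <- fitCircle(still, seedA, seedB)
  kymo <- extractKymograph(prepped, roi)
  kymo <- smoothKymograph(kymo, sgWindow)
  freq <- characteristicFrequency(kymo)
  kForPhase <- if (freq$snr >= claheBelowSnr) kymo else enhanceContrast(kymo)
  est <- phaseSlopeVelocity(kForPhase, freq$kStar, snr = freq$snr)
  list(roi = roi, kymo = kymo, freq = freq, estimate = est, drift = drift)
}
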