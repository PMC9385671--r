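#' @import methods
#' @importFrom stats coef fft lm median quantile resid rnorm rpois runif sd var setNames
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv write.table tail
NULL

#' FtsZMovie: a TIRF time-lapse stack with physical metadata
#'
#' Container for a fluorescence time-lapse acquisition: a 3-D intensity
#' array ordered time x rows x cols, together with the pixel size (nm/px)
#' and the frame interval (s) that convert image-space measurements into
#' physical treadmilling speeds.
#'
#' @slot stack numeric array, dim = c(frames, rows, cols), intensities in
#'   arbitrary units (AU), non-negative.
#' @slot pixelSizeNm pixel size in nm per pixel (scalar, > 0).
#' @slot frameIntervalS time between consecutive frames in seconds (> 0).
#' @export
setClass("FtsZMovie",
  slots = c(stack = "array", pixelSizeNm = "numeric", frameIntervalS = "numeric"))

setValidity("FtsZMovie", function(object) {
  msg <- character()
  if (length(dim(object@stack)) != 3L)
    msg <- c(msg, "stack must be a 3-D array (time x rows x cols)")
  if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
      object@pixelSizeNm <= 0)
    msg <- c(msg, "pixelSizeNm must be a positive scalar")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a positive scalar")
  if (any(!is.finite(object@stack)))
    msg <- c(msg, "stack contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an FtsZMovie
#'
#' @param stack 3-D numeric array (time x rows x cols).
#' @param pixelSizeNm pixel size, nm per pixel.
#' @param frameIntervalS frame interval, seconds.
#' @return An [FtsZMovie-class] object.
#' @export
FtsZMovie <- function(stack, pixelSizeNm, frameIntervalS) {
  new("FtsZMovie", stack = stack, pixelSizeNm = as.numeric(pixelSizeNm),
      frameIntervalS = as.numeric(frameIntervalS))
}

#' RingROI: a fitted circular region of interest
#'
#' A ring's sampling geometry: sub-pixel circle center (row, col) and
#' radius in pixels, with the two seed points it was derived from and a
#' confidence flag set when refinement could not improve on the seeds
#' (flat intensity landscape).
#'
#' @slot center numeric length-2, (row, col) in pixels, sub-pixel.
#' @slot radiusPx circle radius in pixels (>= 2).
#' @slot seeds 2 x 2 matrix of the two seed points (rows = points,
#'   cols = row/col), or a 0 x 2 matrix when constructed without seeds.
#' @slot score mean ring-path intensity at the fitted geometry (AU).
#' @slot lowConfidence TRUE when the refinement objective was flat and the
#'   initial guess was returned unrefined.
#' @export
setClass("RingROI",
  slots = c(center = "numeric", radiusPx = "numeric", seeds = "matrix",
            score = "numeric", lowConfidence = "logical"))

setValidity("RingROI", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be finite (row, col)")
  if (length(object@radiusPx) != 1L || !is.finite(object@radiusPx) ||
      object@radiusPx < 2)
    msg <- c(msg, "radiusPx must be a scalar >= 2 px")
  if (ncol(object@seeds) != 2L)
    msg <- c(msg, "seeds must be an n x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a RingROI
#'
#' @param center numeric (row, col) center in px.
#' @param radiusPx radius in px (>= 2).
#' @param seeds optional 2 x 2 matrix of seed points.
#' @param score mean ring-path intensity (AU), NA when not evaluated.
#' @param lowConfidence logical degenerate-fit flag.
#' @return A [RingROI-class] object.
#' @export
RingROI <- function(center, radiusPx, seeds = matrix(numeric(), 0, 2),
                    score = NA_real_, lowConfidence = FALSE) {
  new("RingROI", center = as.numeric(center), radiusPx = as.numeric(radiusPx),
      seeds = seeds, score = as.numeric(score), lowConfidence = lowConfidence)
}

#' Kymograph: intensity sampled along a circular trajectory over time
#'
#' Rows are frames, columns are angular positions along the ring
#' circumference (arc step fixed on the middle of the three concentric
#' sampling circles). Physical metadata is carried along so downstream
#' velocimetry can convert a phase slope into nm/s.
#'
#' @slot data numeric matrix, time x arclength samples.
#' @slot arcStepPx arc step along the middle circle, px per sample.
#' @slot frameIntervalS frame interval, s.
#' @slot radiusPx radius of the middle sampling circle, px.
#' @slot pixelSizeNm pixel size, nm/px.
#' @export
setClass("Kymograph",
  slots = c(data = "matrix", arcStepPx = "numeric", frameIntervalS = "numeric",
            radiusPx = "numeric", pixelSizeNm = "numeric"))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (any(!is.finite(object@data))) msg <- c(msg, "kymograph values must be finite")
  if (object@arcStepPx <= 0) msg <- c(msg, "arcStepPx must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Kymograph
#'
#' @param data time x arclength numeric matrix.
#' @param arcStepPx arc step, px/sample.
#' @param frameIntervalS frame interval, s.
#' @param radiusPx middle-circle radius, px.
#' @param pixelSizeNm pixel size, nm/px.
#' @return A [Kymograph-class] object.
#' @export
Kymograph <- function(data, arcStepPx = 1, frameIntervalS = 1,
                      radiusPx = NA_real_, pixelSizeNm = NA_real_) {
  new("Kymograph", data = as.matrix(data), arcStepPx = as.numeric(arcStepPx),
      frameIntervalS = as.numeric(frameIntervalS),
      radiusPx = as.numeric(radiusPx), pixelSizeNm = as.numeric(pixelSizeNm))
}

#' VelocityEstimate: treadmilling speed with quality diagnostics
#'
#' @slot speedNmPerS treadmilling speed, nm/s (absolute value).
#' @slot angularRateRadPerS signed angular rate of the rotating pattern, rad/s.
#' @slot kStar characteristic spatial frequency, cycles per circumference.
#' @slot phaseSlope phase-vs-time slope at kStar, rad/s.
#' @slot r2 coefficient of determination of the phase-vs-time line.
#' @slot snr spectral peak signal-to-noise ratio (peak power / band median).
#' @slot rowFraction fraction of kymograph rows surviving phase-jump filtering.
#' @slot accepted quality-gate verdict.
#' @export
setClass("VelocityEstimate",
  slots = c(speedNmPerS = "numeric", angularRateRadPerS = "numeric",
            kStar = "numeric", phaseSlope = "numeric", r2 = "numeric",
            snr = "numeric", rowFraction = "numeric", accepted = "logical"))

#' ExpFit: mono-exponential recovery fit
#'
#' Parameters of the recovery model Y = A e^(-k t) + B with signed
#' amplitude A (negative for upward FRAP recovery), and the derived
#' half-time t1/2 = ln 2 / k.
#'
#' @slot A signed amplitude.
#' @slot k rate constant, 1/s (> 0 on success).
#' @slot B plateau.
#' @slot tHalf half-time ln2/k, s.
#' @slot rss residual sum of squares.
#' @slot converged TRUE when the optimizer converged with k > 0.
#' @export
setClass("ExpFit",
  slots = c(A = "numeric", k = "numeric", B = "numeric", tHalf = "numeric",
            rss = "numeric", converged = "logical"))

#' HHFit: Henderson-Hasselbalch titration fit
#'
#' @slot pKa fitted side-chain pKa.
#' @slot deltaHA chemical shift of the protonated plateau, ppm.
#' @slot deltaA chemical shift of the deprotonated plateau, ppm.
#' @slot residSd residual standard deviation, ppm.
#' @slot ciHalfWidth half-width of the 95% confidence interval on pKa.
#' @export
setClass("HHFit",
  slots = c(pKa = "numeric", deltaHA = "numeric", deltaA = "numeric",
            residSd = "numeric", ciHalfWidth = "numeric"))

#' GaussianFit: least-squares Gaussian curve on a histogram
#'
#' @slot mean fitted mean (same units as the data).
#' @slot sd fitted standard deviation (> 0).
#' @slot amplitude fitted peak height (counts).
#' @slot binEdges histogram bin edges used for the fit.
#' @export
setClass("GaussianFit",
  slots = c(mean = "numeric", sd = "numeric", amplitude = "numeric",
            binEdges = "numeric"))

#' ExtremeFit: least-squares Gumbel (type-I extreme value) curve on a histogram
#'
#' @slot location Gumbel location (mode).
#' @slot scale Gumbel scale (> 0).
#' @slot amplitude area scaling of the fitted density (counts x bin width).
#' @slot binEdges histogram bin edges used for the fit.
#' @slot flagged TRUE when the optimizer ended at a non-positive scale.
#' @export
setClass("ExtremeFit",
  slots = c(location = "numeric", scale = "numeric", amplitude = "numeric",
            binEdges = "numeric", flagged = "logical"))

#' FRAPTrace: a photobleaching recovery experiment
#'
#' Bleached-spot and reference-spot intensity traces on a common clock.
#' Negative times are pre-bleach samples; the first sample at t >= 0 is the
#' first post-bleach frame. Pre-bleach means over both channels anchor the
#' double normalization.
#'
#' @slot time time in s, strictly increasing; bleach at t = 0.
#' @slot bleached bleached-ROI intensity, AU.
#' @slot reference reference-ROI intensity, AU.
#' @slot preBleached pre-bleach mean of the bleached ROI, AU (> 0).
#' @slot preReference pre-bleach mean of the reference ROI, AU (> 0).
#' @export
setClass("FRAPTrace",
  slots = c(time = "numeric", bleached = "numeric", reference = "numeric",
            preBleached = "numeric", preReference = "numeric"))

setValidity("FRAPTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@bleached) ||
      length(object@time) != length(object@reference))
    msg <- c(msg, "time, bleached, reference must have equal length")
  if (any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!is.finite(object@preBleached) || object@preBleached <= 0 ||
      !is.finite(object@preReference) || object@preReference <= 0)
    msg <- c(msg, "pre-bleach means must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a FRAPTrace
#'
#' When pre-bleach means are omitted they are computed from the samples at
#' time < 0; at least one pre-bleach sample is then required.
#'
#' @param time time vector, s; bleach at t = 0.
#' @param bleached bleached-ROI intensities, AU.
#' @param reference reference-ROI intensities, AU.
#' @param preBleached,preReference pre-bleach channel means, AU.
#' @return A [FRAPTrace-class] object.
#' @export
FRAPTrace <- function(time, bleached, reference,
                      preBleached = NULL, preReference = NULL) {
  pre <- time < 0
  if (is.null(preBleached)) {
    if (!any(pre)) stop("no pre-bleach samples (time < 0) and no preBleached mean given")
    preBleached <- mean(bleached[pre])
  }
  if (is.null(preReference)) {
    if (!any(pre)) stop("no pre-bleach samples (time < 0) and no preReference mean given")
    preReference <- mean(reference[pre])
  }
  new("FRAPTrace", time = as.numeric(time), bleached = as.numeric(bleached),
      reference = as.numeric(reference), preBleached = as.numeric(preBleached),
      preReference = as.numeric(preReference))
}
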