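#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("frameData", function(x, i) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setGeneric("ringCenter", function(x) standardGeneric("ringCenter"))
#' @rdname accessors
#' @export
setGeneric("ringRadius", function(x) standardGeneric("ringRadius"))
#' @rdname accessors
#' @export
setGeneric("kymoData", function(x) standardGeneric("kymoData"))
#' @rdname accessors
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))
#' @rdname accessors
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))

#' Half-time of a mono-exponential recovery
#'
#' t1/2 = ln 2 / k: the time at which the recovery has covered half the
#' distance from the bleach level to the plateau.
#'
#' @param fit an [ExpFit-class] or a positive rate constant k (1/s).
#' @return half-time in seconds.
#' @examples
#' halfLife(log(2))   # 1 s
#' @export
setGeneric("halfLife", function(fit) standardGeneric("halfLife"))

#' Accessors for FtsZQuant containers
#'
#' Small accessor family: number of frames, physical metadata, frame and
#' kymograph matrices, ring geometry, velocity results.
#'
#' @param x a container object.
#' @param i frame index.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nFrames", "FtsZMovie", function(x) dim(x@stack)[1L])
#' @rdname accessors
#' @export
setMethod("pixelSize", "FtsZMovie", function(x) x@pixelSizeNm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pixelSizeNm)
#' @rdname accessors
#' @export
setMethod("frameInterval", "FtsZMovie", function(x) x@frameIntervalS)
#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@frameIntervalS)
#' @rdname accessors
#' @export
setMethod("frameData", "FtsZMovie", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@stack)[1L])
  x@stack[i, , , drop = TRUE]
})
#' @rdname accessors
#' @export
setMethod("ringCenter", "RingROI", function(x) x@center)
#' @rdname accessors
#' @export
setMethod("ringRadius", "RingROI", function(x) x@radiusPx)
#' @rdname accessors
#' @export
setMethod("ringRadius", "Kymograph", function(x) x@radiusPx)
#' @rdname accessors
#' @export
setMethod("kymoData", "Kymograph", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("speed", "VelocityEstimate", function(x) x@speedNmPerS)
#' @rdname accessors
#' @export
setMethod("accepted", "VelocityEstimate", function(x) x@accepted)

#' @rdname halfLife
#' @export
setMethod("halfLife", "ExpFit", function(fit) {
  if (!is.finite(fit@k) || fit@k <= 0) stop("half-life undefined: k <= 0")
  log(2) / fit@k
})
#' @rdname halfLife
#' @export
setMethod("halfLife", "numeric", function(fit) {
  if (length(fit) != 1L || !is.finite(fit) || fit <= 0)
    stop("half-life undefined: k must be a positive scalar")
  log(2) / fit
})

setMethod("show", "FtsZMovie", function(object) {
  d <- dim(object@stack)
  cat(sprintf("FtsZMovie: %d frames, %d x %d px, %.1f nm/px, dt = %.2f s\n",
              d[1], d[2], d[3], object@pixelSizeNm, object@frameIntervalS))
  cat(sprintf("  intensity range [%.1f, %.1f] AU\n",
              min(object@stack), max(object@stack)))
})

setMethod("show", "RingROI", function(object) {
  cat(sprintf("RingROI: center (%.2f, %.2f) px, radius %.2f px%s\n",
              object@center[1], object@center[2], object@radiusPx,
              if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d frames x %d angular samples, arc step %.2f px\n",
              nrow(object@data), ncol(object@data), object@arcStepPx))
})

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf(
    "VelocityEstimate: %.2f nm/s (k* = %d, SNR = %.1f, R2 = %.3f, rows %.0f%%) -> %s\n",
    object@speedNmPerS, round(object@kStar), object@snr, object@r2,
    100 * object@rowFraction, if (object@accepted) "accepted" else "rejected"))
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit: Y = %.4g exp(-%.4g t) + %.4g, t1/2 = %.3f s%s\n",
              object@A, object@k, object@B, object@tHalf,
              if (!object@converged) " [not converged]" else ""))
})

setMethod("show", "HHFit", function(object) {
  cat(sprintf("HHFit: pKa = %.2f (dHA = %.3f, dA = %.3f ppm, resid sd %.2g)\n",
              object@pKa, object@deltaHA, object@deltaA, object@residSd))
})
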