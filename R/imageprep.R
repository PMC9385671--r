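#' Average the leading frames of a movie
#'
#' Pixel-wise arithmetic mean of a window of frames, the standard way to
#' obtain a still image of the ring pattern from a time series (typically
#' 5-10 frames). A rotating ring averaged over a full treadmilling period
#' becomes an azimuthally uniform annulus.
#'
#' @param movie an [FtsZMovie-class].
#' @param n number of frames to average.
#' @param start first frame of the window (default 1: leading window).
#' @return averaged image matrix.
#' @export
averageFrames <- function(movie, n, start = 1L) {
  nf <- nFrames(movie)
  if (n < 1 || n > nf) stop(sprintf("n must be in [1, %d]", nf))
  if (start < 1 || start + n - 1 > nf) stop("window exceeds movie length")
  idx <- seq.int(start, start + n - 1L)
  colMeans(movie@stack[idx, , , drop = FALSE], dims = 1)
}

#' Box mean filter with reflection padding
#'
#' Square box mean of half-width `radiusPx` (a radius-2 filter is the 5x5
#' box, the standard "mean filter (2 pixel)" of typical image-processing
#' workflows). Borders are handled by symmetric reflection, which avoids
#' the dark-edge bias that zero padding would introduce into ring-path
#' intensities near the field edge.
#'
#' @param image numeric matrix.
#' @param radiusPx filter half-width in pixels (>= 1).
#' @return filtered matrix of the same size.
#' @export
meanFilter <- function(image, radiusPx = 2L) {
  stopifnot(is.matrix(image))
  r <- as.integer(radiusPx)
  if (r < 1) stop("radiusPx must be >= 1")
  pad <- reflectPad(image, r)
  w <- 2L * r + 1L
  kern <- matrix(1 / (w * w), w, w)
  f <- EBImage::imageData(EBImage::filter2(EBImage::Image(pad), kern))
  # interior of the padded result equals reflection-padded filtering
  out <- f[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image)), drop = FALSE]
  matrix(as.numeric(out), nrow(image), ncol(image))
}

# One round of phase cross-correlation: integer peak on the regularized
# (whitened) correlation surface, then sub-pixel refinement on a +/- 1 px
# neighbourhood at 1/upsample resolution via an explicit matrix-multiply
# DFT of the raw cross spectrum (whitening amplifies empty frequencies and
# spoils the sub-pixel peak on smooth scenes).
phaseCorrOnce <- function(ref, img, upsample = 10L, eps = 1e-3) {
  nr <- nrow(ref); nc <- ncol(ref)
  # Hann window against wrap-around edge artifacts of the periodic DFT
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  W <- outer(wy, wx)
  FR <- fft((ref - mean(ref)) * W); FI <- fft((img - mean(img)) * W)
  cross <- Conj(FR) * FI
  denom <- Mod(cross) + eps * max(Mod(cross))
  cc <- Re(fft(cross / denom, inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  u <- as.integer(upsample)
  offs <- seq(-1, 1, by = 1 / u)
  ky <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  kx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  Ey <- exp(2i * pi * outer(dy + offs, ky))          # |offs| x nr
  Ex <- exp(2i * pi * outer(kx, dx + offs))          # nc x |offs|
  patch <- Re(Ey %*% cross %*% Ex)
  pk <- arrayInd(which.max(patch), dim(patch))
  c(dy = dy + offs[pk[1]], dx = dx + offs[pk[2]])
}

# Sub-pixel displacement of img relative to ref. Window truncation biases
# a single correlation pass toward zero for large displacements, so the
# estimate is iterated: counter-shift img by the current estimate and
# re-measure the residual until it is below half the refinement step.
phaseCorrShift <- function(ref, img, upsample = 10L, maxIter = 3L) {
  total <- c(dy = 0, dx = 0)
  cur <- img
  for (i in seq_len(maxIter)) {
    d <- phaseCorrOnce(ref, cur, upsample)
    total <- total + d
    if (max(abs(d)) <= 0.5 / upsample) break
    cur <- shiftImage(img, -total[1], -total[2])
  }
  total
}

#' Translation-only drift correction by phase cross-correlation
#'
#' Two-pass translation registration with sub-pixel (0.1 px) precision.
#' Pass 1 registers consecutive frames by phase cross-correlation with
#' upsampled-DFT refinement and accumulates the shifts (robust when the
#' scene itself evolves, e.g. a treadmilling ring whose azimuthal pattern
#' rotates between distant frames). Pass 2 re-registers every frame to the
#' temporal mean of the pass-1-aligned stack -- for a rotating ring that
#' mean is an azimuthally uniform annulus, so the refinement is blind to
#' the rotating pattern and removes any residual wander. Shifts are
#' reported relative to frame 1 (which gets (0, 0)) and each original
#' frame is resampled once, by bilinear interpolation, with its total
#' shift. Featureless (zero-variance) frames get a (0, 0) increment and a
#' warning.
#'
#' @param movie an [FtsZMovie-class] with >= 2 frames.
#' @param upsample sub-pixel refinement factor (10 = 0.1 px resolution).
#' @param passes 1 = consecutive-frame registration only; 2 (default)
#'   adds the align-to-mean refinement pass.
#' @param meanIters iterations of the align-to-mean pass (the reference
#'   mean is recomputed from the re-aligned stack each round).
#' @param model `"free"` keeps the raw per-frame shifts; `"linear"`
#'   replaces them with a constant-velocity drift whose per-frame step is
#'   the 25%-trimmed mean of the per-frame shift increments. Stage drift
#'   over a few minutes is smooth and near-linear, whereas registration
#'   artifacts from an evolving scene (e.g. the rotating azimuthal
#'   pattern of a treadmilling ring, which pulls the correlation peak
#'   tangentially and traces a closed loop over each revolution)
#'   contribute symmetric oscillating increments that the trimmed mean
#'   rejects; unlike a plain median it also interpolates between the
#'   0.1 px registration quantization steps.
#' @return list with `movie` (drift-corrected [FtsZMovie-class]) and
#'   `drift` (data.frame of per-frame `dy`, `dx` displacements in px of
#'   each frame relative to frame 1; row 1 is (0, 0); subtracting them,
#'   i.e. shifting frame t by (-dy[t], -dx[t]), aligns the stack).
#' @export
driftCorrect <- function(movie, upsample = 10L, passes = 2L, meanIters = 3L,
                         model = c("free", "linear")) {
  model <- match.arg(model)
  nf <- nFrames(movie)
  if (nf < 2) stop("drift correction needs >= 2 frames")
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in 2:nf) {
    a <- movie@stack[t - 1, , ]; b <- movie@stack[t, , ]
    if (var(as.vector(a)) == 0 || var(as.vector(b)) == 0) {
      warning(sprintf("featureless frame at %d: zero shift increment", t))
      shifts[t, ] <- shifts[t - 1, ]
      next
    }
    # phaseCorrShift(ref, img) is the displacement of img relative to ref
    shifts[t, ] <- shifts[t - 1, ] + phaseCorrShift(a, b, upsample)
  }
  if (passes >= 2L && model == "free") {
    for (it in seq_len(meanIters)) {
      aligned <- movie@stack
      for (t in seq_len(nf))
        aligned[t, , ] <- shiftImage(movie@stack[t, , ], -shifts[t, 1], -shifts[t, 2])
      ref <- colMeans(aligned, dims = 1)
      if (var(as.vector(ref)) == 0) break
      resid <- matrix(0, nf, 2)
      for (t in seq_len(nf)) {
        fr <- aligned[t, , ]
        if (var(as.vector(fr)) == 0) next
        resid[t, ] <- phaseCorrShift(ref, fr, upsample)
      }
      shifts <- shifts + resid
      if (max(abs(resid)) <= 0.5 / upsample) break
    }
    shifts <- sweep(shifts, 2, shifts[1, ])   # frame 1 defines the origin
  }
  if (model == "linear") {
    tt <- seq_len(nf) - 1L
    shifts[, 1] <- mean(diff(shifts[, 1]), trim = 0.25) * tt
    shifts[, 2] <- mean(diff(shifts[, 2]), trim = 0.25) * tt
  }
  out <- movie@stack
  for (t in seq_len(nf))
    if (any(shifts[t, ] != 0))
      out[t, , ] <- shiftImage(movie@stack[t, , ], -shifts[t, 1], -shifts[t, 2])
  list(movie = FtsZMovie(pmax(out, 0), movie@pixelSizeNm, movie@frameIntervalS),
       drift = as.data.frame(shifts))
}

#' Apply a known per-frame translation to a movie
#'
#' Shifts frame t by (dy[t], dx[t]) px with bilinear resampling. Used to
#' impose a synthetic drift whose inversion by [driftCorrect] can be
#' verified.
#'
#' @param movie an [FtsZMovie-class].
#' @param dy,dx per-frame shifts in px (length = frames).
#' @return shifted [FtsZMovie-class].
#' @export
applyDrift <- function(movie, dy, dx) {
  nf <- nFrames(movie)
  stopifnot(length(dy) == nf, length(dx) == nf)
  out <- movie@stack
  for (t in seq_len(nf))
    if (dy[t] != 0 || dx[t] != 0)
      out[t, , ] <- shiftImage(movie@stack[t, , ], dy[t], dx[t])
  FtsZMovie(out, movie@pixelSizeNm, movie@frameIntervalS)
}

#' Find the synchronization frame (time zero)
#'
#' Time-lapse acquisitions are synchronized on the frame at which the mean
#' surface intensity first reaches a threshold (around 200 AU in the
#' reference workflow), i.e. when enough protein has accumulated on the
#' membrane.
#'
#' @param movie an [FtsZMovie-class].
#' @param thresholdAU intensity threshold, AU (> 0).
#' @return 1-based index of the first frame whose spatial mean is >= the
#'   threshold, or `NA_integer_` when never reached.
#' @export
findTimeZero <- function(movie, thresholdAU = 200) {
  if (thresholdAU <= 0) stop("threshold must be > 0")
  means <- apply(movie@stack, 1, mean)
  idx <- which(means >= thresholdAU)
  if (length(idx)) idx[1] else NA_integer_
}
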