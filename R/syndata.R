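#' Synthetic treadmilling-ring movie with known ground truth
#'
#' Renders one or more FtsZ-like rings on a noisy membrane background. Each
#' ring is an annulus of Gaussian radial cross-section whose smooth,
#' non-uniform azimuthal intensity profile (a sum of wrapped Gaussian blobs)
#' rotates rigidly at the angular rate omega = 2 V / D implied by the
#' requested treadmilling speed V and diameter D. Frames are rasterized on a
#' super-sampled grid, binned down, convolved with a Gaussian PSF, and
#' optionally degraded with Poisson shot noise and Gaussian read noise.
#'
#' Defaults reflect the imaging conditions the analysis is designed for:
#' 65 nm pixels (100x objective, 6.5 um camera pixels) and a 3 s frame
#' interval.
#'
#' @param rings data.frame with one row per ring: columns `row`, `col`
#'   (center, px), `diameterNm`, `speedNmPerS`.
#' @param fieldPx field side length in pixels.
#' @param pixelSizeNm pixel size, nm/px.
#' @param frameIntervalS frame interval, s.
#' @param nFrames number of frames.
#' @param ringSigmaNm Gaussian radial cross-section sd of the annulus, nm.
#' @param psfSigmaNm Gaussian PSF sd, nm.
#' @param amplitude peak azimuthal-blob intensity, AU.
#' @param background constant background level, AU.
#' @param azimuthalContrast scaling of the azimuthal blob pattern relative
#'   to the uniform annulus baseline; 0 is rejected (velocity would be
#'   unobservable).
#' @param nBlobs range (length-2) of the number of wrapped Gaussian blobs
#'   per ring profile.
#' @param azimuthal `"blobs"` (default): smooth random non-uniform
#'   azimuthal profile that makes rotation observable. `"uniform"`:
#'   azimuthally constant annuli -- the time-averaged limit of a
#'   treadmilling ring over a full revolution, appropriate for static
#'   morphometric fields (ring detection, diameter statistics) where the
#'   instantaneous blob pattern is irrelevant.
#' @param poissonScale photons per AU for shot noise; 0 disables.
#' @param readNoiseSd Gaussian read noise sd, AU; 0 disables.
#' @param oversample super-sampling factor for rasterization.
#' @param seed RNG seed; fixes the output bit-exactly.
#' @return list with `movie` ([FtsZMovie-class]) and `truth` (data.frame of
#'   per-ring ground truth: center, `radiusPx`, `diameterNm`, `speedNmPerS`,
#'   `angularRateRadPerS` = 2 V / D).
#' @examples
#' rr <- data.frame(row = 32, col = 32, diameterNm = 800, speedNmPerS = 21.63)
#' sim <- makeRingMovie(rr, fieldPx = 64, nFrames = 10, seed = 1)
#' sim$truth$angularRateRadPerS    # 2 * 21.63 / 800
#' @export
makeRingMovie <- function(rings, fieldPx = 64, pixelSizeNm = 65,
                          frameIntervalS = 3, nFrames = 40,
                          ringSigmaNm = 50, psfSigmaNm = 110,
                          amplitude = 1000, background = 100,
                          azimuthalContrast = 1, nBlobs = c(3L, 8L),
                          azimuthal = c("blobs", "uniform"),
                          poissonScale = 1, readNoiseSd = 20,
                          oversample = 4L, seed = 1L) {
  azimuthal <- match.arg(azimuthal)
  stopifnot(is.data.frame(rings), nrow(rings) >= 1,
            all(c("row", "col", "diameterNm", "speedNmPerS") %in% names(rings)))
  if (any(rings$diameterNm <= 0)) stop("ring diameter must be > 0")
  if (any(rings$speedNmPerS < 0)) stop("treadmilling speed must be >= 0")
  if (psfSigmaNm <= 0 || ringSigmaNm <= 0) stop("PSF and ring sigma must be > 0")
  if (poissonScale < 0 || readNoiseSd < 0) stop("noise parameters must be >= 0")
  if (azimuthal == "blobs" && azimuthalContrast <= 0)
    stop("zero azimuthal contrast: ring rotation would be unobservable")

  rPx <- rings$diameterNm / 2 / pixelSizeNm
  sigPx <- ringSigmaNm / pixelSizeNm
  margin <- rPx + 4 * sigPx + 2
  if (any(rings$row - margin < 1 | rings$row + margin > fieldPx |
          rings$col - margin < 1 | rings$col + margin > fieldPx))
    stop("ring (including its rendered halo) extends outside the field")

  omega <- 2 * rings$speedNmPerS / rings$diameterNm  # rad/s
  os <- as.integer(oversample)

  withSeed(seed, {
    profiles <- lapply(seq_len(nrow(rings)), function(i) {
      nb <- sample(seq(nBlobs[1], nBlobs[2]), 1L)
      list(mu = runif(nb, 0, 2 * pi), s = runif(nb, 0.15, 0.5),
           w = runif(nb, 0.5, 1))
    })

    stack <- array(background, dim = c(nFrames, fieldPx, fieldPx))
    for (i in seq_len(nrow(rings))) {
      # polar geometry on the super-sampled grid, restricted to a bounding box
      b <- ceiling(margin)
      r0 <- max(1L, floor(rings$row[i] - b)); r1 <- min(fieldPx, ceiling(rings$row[i] + b))
      c0 <- max(1L, floor(rings$col[i] - b)); c1 <- min(fieldPx, ceiling(rings$col[i] + b))
      subr <- (seq((r0 - 1) * os + 1, r1 * os) - 0.5) / os + 0.5
      subc <- (seq((c0 - 1) * os + 1, c1 * os) - 0.5) / os + 0.5
      dy <- -(outer(subr, rep(1, length(subc))) - rings$row[i])  # +y up
      dx <- t(outer(subc, rep(1, length(subr)))) - rings$col[i]
      rho <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, dx)                     # CCW from 3 o'clock
      radial <- exp(-(rho - rPx[i])^2 / (2 * sigPx^2))
      pf <- profiles[[i]]
      for (t in seq_len(nFrames)) {
        if (azimuthal == "uniform") {
          az <- 1
        } else {
          th <- theta - omega[i] * (t - 1) * frameIntervalS
          az <- 0.25
          for (j in seq_along(pf$mu)) {
            d <- ((th - pf$mu[j] + pi) %% (2 * pi)) - pi
            az <- az + azimuthalContrast * pf$w[j] * exp(-d^2 / (2 * pf$s[j]^2))
          }
        }
        patch <- binMatrix(amplitude * az * radial, os)
        stack[t, r0:r1, c0:c1] <- stack[t, r0:r1, c0:c1] + patch
      }
    }

    psfPx <- psfSigmaNm / pixelSizeNm
    for (t in seq_len(nFrames))
      stack[t, , ] <- as.matrix(EBImage::gblur(EBImage::Image(stack[t, , ]),
                                               sigma = psfPx))
    if (poissonScale > 0)
      stack[] <- rpois(length(stack), pmax(stack, 0) * poissonScale) / poissonScale
    if (readNoiseSd > 0)
      stack[] <- stack + rnorm(length(stack), 0, readNoiseSd)
    stack[] <- pmax(stack, 0)

    truth <- data.frame(row = rings$row, col = rings$col,
                        radiusPx = rPx, diameterNm = rings$diameterNm,
                        speedNmPerS = rings$speedNmPerS,
                        angularRateRadPerS = omega)
    list(movie = FtsZMovie(stack, pixelSizeNm, frameIntervalS), truth = truth)
  })
}

# Block-average a matrix by integer factor s (dimensions must be multiples).
binMatrix <- function(m, s) {
  if (s == 1L) return(m)
  nr <- nrow(m) %/% s; nc <- ncol(m) %/% s
  a <- rowsum(m, rep(seq_len(nr), each = s), reorder = FALSE)
  t(rowsum(t(a), rep(seq_len(nc), each = s), reorder = FALSE)) / (s * s)
}

#' Synthetic curved-filament image with exact centerlines
#'
#' Renders a static field of filaments, each a circular arc or straight
#' segment of Gaussian cross-section, emulating the fiber-like meshed
#' patterns formed by ring-incompetent FtsZ variants. Alongside the image it
#' returns the exact sub-pixel centerline coordinates (in nm) and the true
#' curvature (1/um) at every centerline point, for validating curvature
#' estimators.
#'
#' @param segments list of segments; each is a list with `type = "arc"`
#'   (fields `center` = c(row, col) px, `radiusUm`, `thetaFrom`, `thetaTo`
#'   rad, CCW from 3 o'clock) or `type = "line"` (fields `from`, `to` =
#'   c(row, col) px).
#' @param fieldPx,pixelSizeNm,psfSigmaNm,amplitude,background,poissonScale,readNoiseSd,oversample,seed
#'   as in [makeRingMovie].
#' @param widthSigmaNm Gaussian cross-section sd of the filament, nm.
#' @param sampleStepPx arc-length step between returned centerline points, px.
#' @return list with `image` (matrix), `centerlines` (list of n x 2 matrices,
#'   columns x/y in nm), and `truth` (list of curvature vectors, 1/um, one
#'   value per centerline point).
#' @export
makeFilamentImage <- function(segments, fieldPx = 128, pixelSizeNm = 65,
                              widthSigmaNm = 60, psfSigmaNm = 110,
                              amplitude = 800, background = 100,
                              poissonScale = 1, readNoiseSd = 20,
                              oversample = 4L, seed = 1L,
                              sampleStepPx = 0.5) {
  stopifnot(is.list(segments), length(segments) >= 1)
  os <- as.integer(oversample)
  sigPx <- widthSigmaNm / pixelSizeNm

  sub <- (seq_len(fieldPx * os) - 0.5) / os + 0.5
  rowg <- matrix(sub, length(sub), length(sub))
  colg <- t(rowg)
  img <- matrix(0, length(sub), length(sub))
  centerlines <- list(); truth <- list()

  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    if (identical(sg$type, "arc")) {
      rpx <- sg$radiusUm * 1000 / pixelSizeNm
      if (rpx < 2 * sigPx)
        stop("arc radius smaller than the filament width: self-intersecting render")
      dy <- -(rowg - sg$center[1]); dx <- colg - sg$center[2]
      th <- atan2(dy, dx)
      span <- (sg$thetaTo - sg$thetaFrom) %% (2 * pi)
      if (span == 0) span <- 2 * pi
      rel <- (th - sg$thetaFrom) %% (2 * pi)
      onArc <- rel <= span
      d <- abs(sqrt(dx^2 + dy^2) - rpx)
      # off the angular span, distance to the nearer endpoint
      for (te in c(sg$thetaFrom, sg$thetaFrom + span)) {
        pr <- sg$center[1] - rpx * sin(te); pc <- sg$center[2] + rpx * cos(te)
        de <- sqrt((rowg - pr)^2 + (colg - pc)^2)
        d[!onArc] <- pmin(d[!onArc], de[!onArc])
      }
      d[!onArc & d > 4 * sigPx] <- Inf
      img <- img + amplitude * exp(-d^2 / (2 * sigPx^2))
      nPts <- max(5L, ceiling(span * rpx / sampleStepPx))
      tt <- sg$thetaFrom + span * seq(0, 1, length.out = nPts)
      cl <- cbind(x = (sg$center[2] + rpx * cos(tt)) * pixelSizeNm,
                  y = (sg$center[1] - rpx * sin(tt)) * pixelSizeNm)
      kap <- rep(1 / sg$radiusUm, nPts)
    } else if (identical(sg$type, "line")) {
      a <- sg$from; b <- sg$to
      vr <- b[1] - a[1]; vc <- b[2] - a[2]; L2 <- vr^2 + vc^2
      tpar <- pmin(pmax(((rowg - a[1]) * vr + (colg - a[2]) * vc) / L2, 0), 1)
      d <- sqrt((rowg - (a[1] + tpar * vr))^2 + (colg - (a[2] + tpar * vc))^2)
      img <- img + amplitude * exp(-d^2 / (2 * sigPx^2))
      L <- sqrt(L2)
      nPts <- max(5L, ceiling(L / sampleStepPx))
      tt <- seq(0, 1, length.out = nPts)
      cl <- cbind(x = (a[2] + tt * vc) * pixelSizeNm,
                  y = (a[1] + tt * vr) * pixelSizeNm)
      kap <- rep(0, nPts)
    } else stop("segment type must be 'arc' or 'line'")
    centerlines[[i]] <- cl; truth[[i]] <- kap
  }

  out <- binMatrix(img, os) + background
  out <- as.matrix(EBImage::gblur(EBImage::Image(out),
                                  sigma = psfSigmaNm / pixelSizeNm))
  withSeed(seed, {
    if (poissonScale > 0)
      out[] <- rpois(length(out), pmax(out, 0) * poissonScale) / poissonScale
    if (readNoiseSd > 0) out[] <- out + rnorm(length(out), 0, readNoiseSd)
  })
  out[] <- pmax(out, 0)
  list(image = out, centerlines = centerlines, truth = truth)
}

#' Synthetic FRAP trace from the mono-exponential model
#'
#' Generates an intensity trace Y(t) = A e^(-k t) + B on the post-bleach
#' time grid, with optional pre-bleach samples, common-mode photobleaching
#' applied to both the bleached and the reference channel, and Gaussian
#' noise. A negative amplitude A produces the upward fluorescence recovery
#' of a FRAP experiment; a positive A produces a plain decay.
#'
#' @param A signed amplitude (negative for recovery toward the plateau B).
#' @param k rate constant, 1/s (> 0).
#' @param B plateau level (>= 0).
#' @param tGrid strictly increasing post-bleach time grid, s (t = 0 is the
#'   first post-bleach frame).
#' @param noiseSd Gaussian noise sd added to both channels.
#' @param seed RNG seed.
#' @param preBleachN number of pre-bleach samples prepended at the
#'   pre-bleach level (1.0 before bleaching in model units).
#' @param bleachRate common-mode acquisition photobleaching rate, 1/s,
#'   multiplying both channels by exp(-bleachRate * (t - t_min)).
#' @param refLevel reference-channel level in model units.
#' @return list with `trace` ([FRAPTrace-class]) and `truth` (list A, k, B,
#'   tHalf = ln2/k).
#' @examples
#' tr <- makeFrapTrace(A = -0.6, k = 0.13946, B = 0.9, tGrid = seq(0, 30, 0.5))
#' tr$truth$tHalf    # ln(2)/k = 4.97 s
#' @export
makeFrapTrace <- function(A, k, B, tGrid, noiseSd = 0, seed = 1L,
                          preBleachN = 5L, bleachRate = 0, refLevel = 1) {
  if (k <= 0) stop("rate constant k must be > 0")
  if (B < 0) stop("plateau B must be >= 0")
  if (any(diff(tGrid) <= 0)) stop("tGrid must be strictly increasing")
  dt <- if (length(tGrid) > 1) tGrid[2] - tGrid[1] else 1
  tPre <- if (preBleachN > 0) tGrid[1] - dt * rev(seq_len(preBleachN)) else numeric()
  tAll <- c(tPre, tGrid)
  ideal <- c(rep(1, length(tPre)), B + A * exp(-k * tGrid))
  g <- exp(-bleachRate * (tAll - tAll[1]))
  withSeed(seed, {
    noiseB <- if (noiseSd > 0) rnorm(length(tAll), 0, noiseSd) else 0
    noiseR <- if (noiseSd > 0) rnorm(length(tAll), 0, noiseSd) else 0
    bleached <- ideal * g + noiseB
    reference <- refLevel * g + noiseR
    preB <- if (length(tPre)) mean(bleached[seq_along(tPre)]) else g[1]
    preR <- if (length(tPre)) mean(reference[seq_along(tPre)]) else refLevel * g[1]
    trace <- FRAPTrace(tAll, bleached, reference,
                       preBleached = preB, preReference = preR)
    list(trace = trace, truth = list(A = A, k = k, B = B, tHalf = log(2) / k))
  })
}

#' Synthetic two-state NMR titration
#'
#' Chemical shift versus pH following the Henderson-Hasselbalch relation
#' delta(pH) = delta_HA + (delta_A - delta_HA) / (1 + 10^(pKa - pH)),
#' optionally with Gaussian noise. The returned ground truth carries a
#' warning flag when the pH grid does not span pKa +/- 1.5 (the transition
#' would be under-sampled for fitting).
#'
#' @param pKa true acid dissociation constant.
#' @param deltaHA chemical shift of the protonated form, ppm.
#' @param deltaA chemical shift of the deprotonated form, ppm.
#' @param pHGrid pH sampling points.
#' @param noiseSd Gaussian noise sd, ppm.
#' @param seed RNG seed.
#' @return list with `pH`, `delta` (observed shifts, ppm) and `truth`
#'   (pKa, deltaHA, deltaA, `spanWarning`).
#' @examples
#' tit <- makeTitration(6.52, 7.10, 6.70, seq(4, 10, 0.25))
#' @export
makeTitration <- function(pKa, deltaHA, deltaA, pHGrid, noiseSd = 0, seed = 1L) {
  stopifnot(all(pHGrid >= 0 & pHGrid <= 14))
  delta <- deltaHA + (deltaA - deltaHA) / (1 + 10^(pKa - pHGrid))
  spanWarning <- !(min(pHGrid) <= pKa - 1.5 && max(pHGrid) >= pKa + 1.5)
  withSeed(seed, {
    if (noiseSd > 0) delta <- delta + rnorm(length(pHGrid), 0, noiseSd)
    list(pH = pHGrid, delta = delta,
         truth = list(pKa = pKa, deltaHA = deltaHA, deltaA = deltaA,
                      spanWarning = spanWarning))
  })
}
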