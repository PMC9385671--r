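# Shared fixtures, all generated in code.

# Standard wild-type-like single-ring movie: D = 800 nm, V = 21.63 nm/s,
# 65 nm px, 3 s frames.
wtRingMovie <- function(seed, nFrames = 40, fieldPx = 64, speed = 21.63,
                        ...) {
  rr <- data.frame(row = fieldPx / 2, col = fieldPx / 2,
                   diameterNm = 800, speedNmPerS = speed)
  makeRingMovie(rr, fieldPx = fieldPx, nFrames = nFrames, seed = seed, ...)
}

wtSeeds <- function(fieldPx = 64, rPx = 800 / 2 / 65) {
  c0 <- fieldPx / 2
  list(a = c(c0, c0 - rPx), b = c(c0, c0 + rPx))
}

# Field of non-overlapping uniform annuli on a jittered grid; diameters
# drawn from N(meanUm, sdUm) truncated symmetrically around the mean.
ringField <- function(seed, nRings = 25, spacingPx = 44, marginPx = 30,
                      meanUm = 0.80, sdUm = 0.18) {
  set.seed(seed)
  side <- ceiling(sqrt(nRings))
  rows <- marginPx + spacingPx * (0:(side - 1))
  g <- expand.grid(row = rows, col = rows)[seq_len(nRings), ]
  d <- pmin(pmax(rnorm(nRings, meanUm, sdUm), meanUm - 0.5), meanUm + 0.5)
  rings <- data.frame(row = g$row + runif(nRings, -3, 3),
                      col = g$col + runif(nRings, -3, 3),
                      diameterNm = d * 1000, speedNmPerS = 0)
  fieldPx <- 2 * marginPx + spacingPx * (side - 1)
  sim <- makeRingMovie(rings, fieldPx = fieldPx, nFrames = 1,
                       azimuthal = "uniform", seed = seed + 7000)
  list(rings = rings, fieldPx = fieldPx,
       image = meanFilter(sim$movie@stack[1, , ], 2))
}

# Two tangent arcs (R = 1 um then R = 2 um) with a continuous tangent at
# the junction; coordinates in nm.
sCurveTrace <- function(n1 = 60, n2 = 30) {
  th1 <- seq(pi / 2, -pi / 2, length.out = n1)
  arc1 <- cbind(1000 * cos(th1), 1000 * sin(th1))
  phi <- seq(pi / 2, 0, length.out = n2)
  arc2 <- cbind(2000 * cos(phi), -3000 + 2000 * sin(phi))
  rbind(arc1, arc2[-1, ])
}

# Analytic pure-transport kymograph K(t, s) = cos(2 pi k (s - u t) / N)
# on a circle whose circumference is exactly N samples.
transportKymo <- function(N = 64, nT = 20, k = 3, u = 0.7,
                          pixelSizeNm = 65, frameIntervalS = 3) {
  K <- outer(0:(nT - 1), 0:(N - 1),
             function(t, s) cos(2 * pi * k * (s - u * t) / N))
  Kymograph(K, arcStepPx = 1, frameIntervalS = frameIntervalS,
            radiusPx = N / (2 * pi), pixelSizeNm = pixelSizeNm)
}

rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
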