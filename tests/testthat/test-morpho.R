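test_that("ring detection finds a field of disjoint rings", {
  f <- ringField(seed = 11, nRings = 25)
  det <- detectRings(f$image, c(2.5, 10.5))
  expect_equal(length(det), 25L)
  ctrs <- t(sapply(det, ringCenter))
  dmat <- as.matrix(dist(rbind(as.matrix(f$rings[, 1:2]), ctrs)))
  dmat <- dmat[1:25, 26:(25 + length(det)), drop = FALSE]
  expect_lt(max(apply(dmat, 1, min)), 1)
})

test_that("blank images yield no detections", {
  expect_equal(length(detectRings(matrix(100, 128, 128), c(3, 10))), 0L)
  set.seed(1)
  noisy <- meanFilter(matrix(rnorm(128^2, 100, 20), 128), 2)
  expect_equal(length(detectRings(noisy, c(3, 10))), 0L)
})

test_that("non-maximum suppression merges overlapping responses", {
  rings <- data.frame(row = c(60, 64), col = c(60, 63),
                      diameterNm = c(800, 780), speedNmPerS = 0)
  sim <- makeRingMovie(rings, fieldPx = 120, nFrames = 1,
                       azimuthal = "uniform", seed = 3)
  det <- detectRings(meanFilter(sim$movie@stack[1, , ], 2), c(2.5, 10.5))
  expect_equal(length(det), 1L)
})

test_that("ring density is count per area and unbiased on synthetic fields", {
  expect_equal(ringDensity(50, 10), 5)
  expect_equal(ringDensity(list(), 10), 0)
  expect_error(ringDensity(5, 0), "> 0")
  dens <- sapply(1:50, function(s) {
    f <- ringField(seed = 100 + s, nRings = 4, spacingPx = 44, marginPx = 26)
    areaUm2 <- (f$fieldPx * 65 / 1000)^2
    ringDensity(detectRings(f$image, c(2.5, 10.5)), areaUm2) /
      (4 / areaUm2)
  })
  expect_lt(abs(mean(dens) - 1), 0.05)
})

test_that("Gaussian histogram fit recovers diameter distributions", {
  set.seed(3)
  d <- rnorm(1e4, 0.80, 0.18)
  fit <- diameterHistogramFit(d, binWidth = 0.1)
  expect_lt(abs(fit@mean - 0.80) / 0.80, 0.02)
  expect_lt(abs(fit@sd - 0.18) / 0.18, 0.05)
  # half-bin origin shift does not move the fit materially
  fit2 <- diameterHistogramFit(d + 0.05, binWidth = 0.1)
  expect_lt(abs((fit2@mean - 0.05) - fit@mean), 0.01)
  expect_error(diameterHistogramFit(rep(0.8, 100)), "degenerate")
  expect_warning(diameterHistogramFit(rnorm(10, 0.8, 0.1)), "30")
})

test_that("curvature of a sampled circle equals 1/R", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- cbind(1250 * cos(th), 1250 * sin(th))   # R = 1.25 um in nm
  k <- curvatureProfile(circ)
  expect_lt(max(abs(k - 0.8)) / 0.8, 0.01)
  line <- cbind(seq(0, 5000, length.out = 50), seq(0, 2500, length.out = 50))
  expect_true(all(curvatureProfile(line) == 0))
})

test_that("curvature profile resolves the two halves of a tangent-arc S-curve", {
  tr <- sCurveTrace()
  k <- curvatureProfile(tr, windowPts = 7)
  expect_lt(abs(median(k[1:55]) - 1.0) / 1.0, 0.03)
  expect_lt(abs(median(k[65:89]) - 0.5) / 0.5, 0.03)
})

test_that("curvature is rigid-motion invariant and scale equivariant", {
  tr <- sCurveTrace()
  k0 <- curvatureProfile(tr)
  a <- 0.7
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
  moved <- t(R %*% t(tr)) + matrix(c(500, -900), nrow(tr), 2, byrow = TRUE)
  expect_equal(curvatureProfile(moved), k0, tolerance = 1e-8)
  expect_equal(curvatureProfile(tr * 2), k0 / 2, tolerance = 1e-8)
})

test_that("Gumbel histogram fit inverts sampled extreme-value data", {
  set.seed(2)
  x <- rgumbel(1e5, loc = 1.0, scale = 0.3)
  fit <- curvatureHistogramFit(x, binWidth = 0.05)
  expect_false(fit@flagged)
  expect_lt(abs(fit@location - 1.0) / 1.0, 0.02)
  expect_lt(abs(fit@scale - 0.3) / 0.3, 0.05)
  # location/scale equivariance
  fitShift <- curvatureHistogramFit(x + 2, binWidth = 0.05)
  expect_lt(abs(fitShift@location - (fit@location + 2)), 0.02)
  fitScale <- curvatureHistogramFit(x * 2, binWidth = 0.1)
  expect_lt(abs(fitScale@scale - 2 * fit@scale) / (2 * fit@scale), 0.02)
  # Weibull alternative runs and returns a positive shape
  fw <- curvatureHistogramFit(x[x > 0], binWidth = 0.05, family = "weibull")
  expect_false(fw@flagged)
})

test_that("percent difference reports reduction relative to the reference", {
  expect_equal(percentDifference(0.80, 0.62), 22.5)
  expect_equal(percentDifference(10, 12), -20)
})
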