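test_that("order-2 Savitzky-Golay smoothing preserves quadratics and constants", {
  N <- 48
  s <- 0:(N - 1)
  quad <- 2 + 0.3 * s - 0.01 * s^2
  kym <- Kymograph(rbind(quad, quad), 1, 3, 8, 65)
  sm <- kymoData(smoothKymograph(kym, 7))
  interior <- 8:(N - 8)     # away from the wrap seam, where the profile is C2
  expect_lt(max(abs(sm[1, interior] - quad[interior])), 1e-9)
  cst <- Kymograph(matrix(5, 4, 32), 1, 3, 8, 65)
  expect_equal(kymoData(smoothKymograph(cst, 7)), matrix(5, 4, 32))
})

test_that("Savitzky-Golay smoothing shrinks white-noise variance", {
  set.seed(8)
  shrunk <- replicate(20, {
    row <- rnorm(64)
    kym <- Kymograph(rbind(row, row), 1, 3, 8, 65)
    var(kymoData(smoothKymograph(kym, 7))[1, ]) < var(row)
  })
  expect_true(all(shrunk))
})

test_that("smoothing window contract is enforced", {
  kym <- Kymograph(matrix(rnorm(64), 2, 32), 1, 3, 8, 65)
  expect_error(smoothKymograph(kym, 6), "odd")
  expect_error(smoothKymograph(kym, 3), "\\[5")
  expect_error(smoothKymograph(kym, 41), "\\[5")
})

test_that("CLAHE maps into [0,1], no-ops on constants, and amplifies weak stripes", {
  cst <- enhanceContrast(Kymograph(matrix(5, 10, 32), 1, 3, 8, 65))
  expect_true(isTRUE(attr(kymoData(cst), "flatInput")))
  expect_true(all(kymoData(cst) == 5))
  set.seed(9)
  rnd <- enhanceContrast(Kymograph(matrix(rnorm(40 * 64, 100, 10), 40), 1, 3, 8, 65))
  expect_true(all(kymoData(rnd) >= 0 & kymoData(rnd) <= 1))
  # 1% amplitude sinusoid on a flat background
  N <- 64
  stripes <- outer(rep(1, 40), 100 + cos(2 * pi * 4 * (0:(N - 1)) / N))
  kw <- Kymograph(stripes, 1, 3, 8, 65)
  relAmp <- function(k) {
    row <- kymoData(k)[1, ]
    Mod(fft(row - mean(row))[5]) / mean(row)
  }
  expect_gt(relAmp(enhanceContrast(kw)) / relAmp(kw), 10)
})

test_that("characteristic frequency finds the dominant integer tone", {
  N <- 64
  tone <- function(k, a = 1) a * cos(2 * pi * k * (0:(N - 1)) / N)
  k3 <- Kymograph(outer(rep(1, 10), tone(3)), 1, 3, 8, 65)
  expect_equal(characteristicFrequency(k3)$kStar, 3L)
  two <- Kymograph(outer(rep(1, 10), tone(2) + tone(5, 0.3)), 1, 3, 8, 65)
  expect_equal(characteristicFrequency(two)$kStar, 2L)
  expect_error(characteristicFrequency(Kymograph(matrix(1, 3, 6), 1, 3, 8, 65)),
               ">= 8")
})

test_that("white-noise kymographs are flagged and rejected", {
  set.seed(6)
  flags <- replicate(100, {
    kn <- Kymograph(matrix(rnorm(20 * 64), 20, 64), 1, 3, 10, 65)
    fn <- characteristicFrequency(kn)
    en <- phaseSlopeVelocity(kn, fn$kStar, snr = fn$snr)
    c(lowSnr = fn$snr < 2, rejected = !accepted(en))
  })
  expect_gt(mean(flags["lowSnr", ]), 0.9)
  expect_gt(mean(flags["rejected", ]), 0.9)
})

test_that("phase slope recovers the analytic transport velocity exactly", {
  u <- 0.7; px <- 65; dt <- 3
  kym <- transportKymo(N = 64, nT = 20, k = 3, u = u,
                       pixelSizeNm = px, frameIntervalS = dt)
  f <- characteristicFrequency(kym)
  expect_equal(f$kStar, 3L)
  est <- phaseSlopeVelocity(kym, f$kStar, snr = f$snr)
  expect_lt(abs(speed(est) - u * px / dt) / (u * px / dt), 1e-6)
  expect_true(accepted(est))
  # the full smooth -> frequency -> phase chain stays exact
  sm <- smoothKymograph(kym, 7)
  f2 <- characteristicFrequency(sm)
  est2 <- phaseSlopeVelocity(sm, f2$kStar, snr = f2$snr)
  expect_lt(abs(speed(est2) - u * px / dt) / (u * px / dt), 1e-6)
})

test_that("a static kymograph yields zero speed", {
  Ks <- outer(rep(1, 10), cos(2 * pi * 3 * (0:63) / 64))
  est <- phaseSlopeVelocity(Kymograph(Ks, 1, 3, 10, 65), 3)
  expect_lt(speed(est), 1e-9)
  expect_error(phaseSlopeVelocity(Kymograph(Ks[1:4, ], 1, 3, 10, 65), 3),
               ">= 5")
})

test_that("speed is invariant to intensity scaling and angular origin", {
  kym <- transportKymo(N = 64, nT = 16, k = 2, u = 0.9)
  base <- speed(phaseSlopeVelocity(kym, 2))
  scaled <- initialize(kym, data = 7 * kymoData(kym))
  expect_equal(speed(phaseSlopeVelocity(scaled, 2)), base, tolerance = 1e-9)
  rot <- initialize(kym, data = kymoData(kym)[, c(21:64, 1:20)])
  expect_equal(speed(phaseSlopeVelocity(rot, 2)), base, tolerance = 1e-9)
})

test_that("quality gate applies threshold semantics", {
  mk <- function(r2, snr, frac = 1) new("VelocityEstimate",
    speedNmPerS = 10, angularRateRadPerS = 0.05, kStar = 3,
    phaseSlope = 0.1, r2 = r2, snr = snr, rowFraction = frac, accepted = NA)
  expect_false(qualityGate(mk(0.79, 10)))
  expect_true(qualityGate(mk(0.95, 10)))
  expect_false(qualityGate(mk(0.95, 1.5)))
  expect_false(qualityGate(mk(0.95, 10, frac = 0.5)))
})

test_that("velocity recovery error does not grow with generator SNR", {
  errAt <- function(noiseSd, seeds) {
    sapply(seeds, function(s) {
      sim <- wtRingMovie(seed = s, readNoiseSd = noiseSd)
      sd0 <- wtSeeds()
      est <- tryCatch(
        estimateTreadmilling(sim$movie, sd0$a, sd0$b)$estimate,
        error = function(e) NULL)
      if (is.null(est)) 1 else abs(speed(est) - 21.63) / 21.63
    })
  }
  seeds <- 1:20
  eLow <- mean(errAt(500, seeds))    # SNR ~ 2
  eMid <- mean(errAt(200, seeds))    # SNR ~ 5
  eHigh <- mean(errAt(50, seeds))    # SNR ~ 20
  expect_gte(eLow + 1e-3, eMid)
  expect_gte(eMid + 1e-3, eHigh)
})
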