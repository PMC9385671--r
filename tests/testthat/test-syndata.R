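test_that("ring movies are bit-identical under the same seed", {
  a <- wtRingMovie(seed = 42, nFrames = 6)
  b <- wtRingMovie(seed = 42, nFrames = 6)
  c <- wtRingMovie(seed = 43, nFrames = 6)
  expect_identical(a$movie@stack, b$movie@stack)
  expect_false(identical(a$movie@stack, c$movie@stack))
})

test_that("a static noiseless scene renders identical frames", {
  sim <- wtRingMovie(seed = 1, nFrames = 5, speed = 0,
                     poissonScale = 0, readNoiseSd = 0)
  for (t in 2:5)
    expect_equal(sim$movie@stack[t, , ], sim$movie@stack[1, , ])
})

test_that("pattern autocorrelation peaks at the full-revolution period", {
  # D = 800 nm at V = 21.63 nm/s: period pi D / V = 116.2 s = 38.7 frames
  sim <- wtRingMovie(seed = 3, nFrames = 45, poissonScale = 0, readNoiseSd = 0)
  s <- sim$movie@stack
  cors <- sapply(30:45, function(t) cor(as.vector(s[1, , ]), as.vector(s[t, , ])))
  peakFrame <- (30:45)[which.max(cors)]
  expect_true(peakFrame %in% 39:41)   # lag 38-40 frames = 114-120 s
})

test_that("total rendered intensity is conserved over frames before noise", {
  sim <- wtRingMovie(seed = 7, nFrames = 10, poissonScale = 0, readNoiseSd = 0)
  tot <- apply(sim$movie@stack, 1, sum)
  expect_lt(sd(tot) / mean(tot), 1e-3)
})

test_that("ground-truth manifest is internally consistent", {
  rings <- data.frame(row = c(40, 90), col = c(40, 90),
                      diameterNm = c(800, 620), speedNmPerS = c(21.63, 12.5))
  sim <- makeRingMovie(rings, fieldPx = 128, nFrames = 2, seed = 2)
  expect_equal(sim$truth$angularRateRadPerS * sim$truth$diameterNm / 2,
               sim$truth$speedNmPerS)
  tr <- makeFrapTrace(A = -0.5, k = 0.2, B = 0.9, tGrid = seq(0, 20, 0.5))
  expect_equal(tr$truth$tHalf, log(2) / 0.2)
})

test_that("invalid ring scenes are rejected", {
  out <- data.frame(row = 5, col = 5, diameterNm = 800, speedNmPerS = 10)
  expect_error(makeRingMovie(out, fieldPx = 64, nFrames = 2, seed = 1),
               "outside the field")
  rr <- data.frame(row = 32, col = 32, diameterNm = 800, speedNmPerS = 10)
  expect_error(makeRingMovie(rr, fieldPx = 64, nFrames = 2, seed = 1,
                             azimuthalContrast = 0),
               "contrast")
  expect_silent(makeRingMovie(rr, fieldPx = 64, nFrames = 2, seed = 1,
                              azimuthalContrast = 0, azimuthal = "uniform"))
})

test_that("filament generator returns exact centerlines and curvature truth", {
  arc <- list(list(type = "arc", center = c(64, 64), radiusUm = 1.25,
                   thetaFrom = 0, thetaTo = pi))
  fi <- makeFilamentImage(list(arc[[1]]), fieldPx = 128, seed = 3)
  expect_true(all(fi$truth[[1]] == 0.8))
  # centerline radius in nm is exact
  ctr <- c(64, 64) * 65
  rad <- sqrt((fi$centerlines[[1]][, "x"] - ctr[2])^2 +
              (fi$centerlines[[1]][, "y"] - ctr[1])^2)
  expect_equal(rad, rep(1250, length(rad)), tolerance = 1e-10)

  ln <- list(type = "line", from = c(20, 20), to = c(100, 60))
  fl <- makeFilamentImage(list(ln), fieldPx = 128, seed = 4)
  expect_true(all(fl$truth[[1]] == 0))

  sArcs <- list(
    list(type = "arc", center = c(60, 40), radiusUm = 1.0,
         thetaFrom = pi / 2, thetaTo = 3 * pi / 2),
    list(type = "arc", center = c(60, 90), radiusUm = 2.0,
         thetaFrom = 0, thetaTo = pi / 2))
  fs <- makeFilamentImage(sArcs, fieldPx = 160, seed = 5)
  expect_equal(unique(fs$truth[[1]]), 1.0)
  expect_equal(unique(fs$truth[[2]]), 0.5)

  tiny <- list(list(type = "arc", center = c(64, 64), radiusUm = 0.001,
                    thetaFrom = 0, thetaTo = pi))
  expect_error(makeFilamentImage(list(tiny[[1]]), fieldPx = 128, seed = 1),
               "self-intersecting")
})

test_that("FRAP generator satisfies the exponential-model identities", {
  k <- 0.13946
  tg <- sort(c(seq(0, 60, 0.25), log(2) / k))
  tr <- makeFrapTrace(A = 0.5, k = k, B = 0.2, tGrid = tg, preBleachN = 0)
  y <- tr$trace@bleached
  expect_equal(y[1], 0.7)                        # A + B at t = 0
  expect_lt(abs(y[length(y)] - 0.2), 1e-3)       # asymptote -> B
  iHalf <- which(tr$trace@time == log(2) / k)
  expect_equal(y[iHalf], 0.2 + 0.5 / 2)          # half-recovery identity
  expect_error(makeFrapTrace(0.5, k, 0.2, tGrid = c(0, 1, 1)), "increasing")
})

test_that("titration generator follows the two-state curve", {
  tit <- makeTitration(6.52, 7.10, 6.70, seq(4, 10, 0.25))
  iMid <- which(tit$pH == 6.5)
  expect_equal(tit$delta[which.min(abs(tit$pH - 6.52))],
               (7.10 + 6.70) / 2, tolerance = 0.01)
  expect_equal(tit$delta[1], 7.10, tolerance = 1e-2)   # protonated limit
  expect_true(all(diff(tit$delta) < 0))                # monotone plateaus
  expect_false(tit$truth$spanWarning)
  narrow <- makeTitration(6.52, 7.10, 6.70, seq(6.2, 6.8, 0.1))
  expect_true(narrow$truth$spanWarning)
})
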