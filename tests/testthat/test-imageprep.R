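test_that("averageFrames is the arithmetic mean and commutes with scaling", {
  st <- array(0, c(2, 4, 4)); st[1, , ] <- 0; st[2, , ] <- 2
  m <- FtsZMovie(st, 65, 3)
  expect_true(all(averageFrames(m, 2) == 1))
  cst <- array(7, c(3, 5, 5))
  expect_true(all(averageFrames(FtsZMovie(cst, 65, 3), 3) == 7))
  expect_error(averageFrames(m, 3), "\\[1, 2\\]")
  sim <- wtRingMovie(seed = 9, nFrames = 4)
  m2 <- FtsZMovie(3 * sim$movie@stack, 65, 3)
  expect_equal(averageFrames(m2, 4), 3 * averageFrames(sim$movie, 4))
})

test_that("averaging a rotating ring over a full period is azimuthally uniform", {
  # V chosen so one revolution = 40 frames x 3 s exactly
  sim <- wtRingMovie(seed = 5, nFrames = 40, speed = pi * 800 / 120,
                     poissonScale = 0, readNoiseSd = 0)
  avg <- averageFrames(sim$movie, 40)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  r <- 800 / 2 / 65
  vals <- sapply(th, function(a) avg[round(32 - r * sin(a)) +
                                     (round(32 + r * cos(a)) - 1) * 64])
  expect_lt(sd(vals) / mean(vals), 0.02)
})

test_that("meanFilter matches a direct reflection-padded convolution oracle", {
  expect_true(all(meanFilter(matrix(3, 8, 8), 2) == 3))
  # impulse: total mass conserved under reflection padding
  imp <- matrix(0, 9, 9); imp[5, 5] <- 10
  expect_equal(sum(meanFilter(imp, 2)), 10)
  impEdge <- matrix(0, 9, 9); impEdge[1, 2] <- 10
  expect_equal(sum(meanFilter(impEdge, 2)), 10)
  # brute-force oracle on a checkerboard and a random image
  oracle <- function(img, r) {
    n <- nrow(img); m <- ncol(img)
    refl <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
    out <- img
    for (i in seq_len(n)) for (j in seq_len(m)) {
      acc <- 0
      for (di in -r:r) for (dj in -r:r)
        acc <- acc + img[refl(i + di, n), refl(j + dj, m)]
      out[i, j] <- acc / (2 * r + 1)^2
    }
    out
  }
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  expect_equal(meanFilter(chk, 2), oracle(chk, 2), tolerance = 1e-10)
  set.seed(4)
  rnd <- matrix(runif(81), 9, 9)
  expect_equal(meanFilter(rnd, 2), oracle(rnd, 2), tolerance = 1e-10)
})

test_that("drift correction leaves an aligned stack untouched", {
  sim <- wtRingMovie(seed = 2, nFrames = 6, speed = 0,
                     poissonScale = 0, readNoiseSd = 0)
  dc <- driftCorrect(sim$movie)
  expect_lt(max(abs(as.matrix(dc$drift))), 0.11)
  expect_equal(dc$drift$dy[1], 0)
  expect_equal(dc$drift$dx[1], 0)
})

test_that("drift correction inverts a known applied drift within 0.2 px", {
  sim <- makeRingMovie(
    data.frame(row = 70, col = 70, diameterNm = 800, speedNmPerS = 0),
    fieldPx = 160, nFrames = 8, poissonScale = 0, readNoiseSd = 0, seed = 2)
  dyI <- 3 * (0:7); dxI <- -2 * (0:7)
  dcI <- driftCorrect(applyDrift(sim$movie, dyI, dxI))
  expect_lt(max(abs(dcI$drift$dy - dyI), abs(dcI$drift$dx - dxI)), 0.2)
  dyS <- 0.4 * (0:7); dxS <- -0.25 * (0:7)
  dcS <- driftCorrect(applyDrift(sim$movie, dyS, dxS))
  expect_lt(max(abs(dcS$drift$dy - dyS), abs(dcS$drift$dx - dxS)), 0.2)
})

test_that("velocity from a drift-corrected drifting ring matches the drift-free movie", {
  sim <- makeRingMovie(
    data.frame(row = 48, col = 48, diameterNm = 800, speedNmPerS = 21.63),
    fieldPx = 96, nFrames = 40, seed = 5)
  sd0 <- wtSeeds(96)
  v0 <- speed(estimateTreadmilling(sim$movie, sd0$a, sd0$b,
                                   correctDrift = FALSE)$estimate)
  dy <- cumsum(c(0, rep(0.4, 39))); dx <- cumsum(c(0, rep(-0.25, 39)))
  vD <- speed(estimateTreadmilling(applyDrift(sim$movie, dy, dx),
                                   sd0$a, sd0$b)$estimate)
  expect_lt(abs(vD - v0) / v0, 0.02)
})

test_that("featureless frames get a zero shift and a warning", {
  st <- array(5, c(3, 16, 16)); st[2, , ] <- 5
  st[1, 8, 8] <- 50; st[3, 9, 8] <- 50
  w <- capture_warnings(dc <- driftCorrect(FtsZMovie(st, 65, 3), passes = 1))
  expect_true(any(grepl("featureless", w)))
  expect_equal(dc$drift$dy[2], dc$drift$dy[1])
})

test_that("time zero is the first frame reaching the intensity threshold", {
  mk <- function(means) {
    st <- array(0, c(length(means), 4, 4))
    for (t in seq_along(means)) st[t, , ] <- means[t]
    FtsZMovie(st, 65, 3)
  }
  expect_equal(findTimeZero(mk(c(50, 150, 250, 350))), 3L)
  expect_true(is.na(findTimeZero(mk(c(10, 20, 30)))))
  expect_equal(findTimeZero(mk(c(300, 310))), 1L)
  expect_error(findTimeZero(mk(c(10)), thresholdAU = -1), "> 0")
})
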