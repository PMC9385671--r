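# Internal numerical helpers shared across modules.

# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Bilinear interpolation of matrix img at sub-pixel positions (rows, cols),
# 1-based continuous coordinates. Points outside the grid are clamped to the
# border (callers are expected to keep trajectories inside the field).
bilinearSample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(rows, 1), nr)
  cc <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  i00 <- (c0 - 1L) * nr + r0
  v00 <- img[i00];       v10 <- img[i00 + 1L]
  v01 <- img[i00 + nr];  v11 <- img[i00 + nr + 1L]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Reflection-pad a matrix by p pixels on every side (half-sample symmetric:
# the edge pixel is mirrored too, so a box mean conserves total intensity
# for any impulse position).
reflectPad <- function(img, p) {
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(rev(seq_len(p)), seq_len(nr), nr + 1L - seq_len(p))
  cidx <- c(rev(seq_len(p)), seq_len(nc), nc + 1L - seq_len(p))
  img[ridx, cidx, drop = FALSE]
}

# Translate an image by (dy, dx) pixels (sub-pixel) via bilinear resampling;
# content moves by +dy rows / +dx cols, borders filled by edge clamping.
shiftImage <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) - dy
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  matrix(bilinearSample(img, as.vector(rows), as.vector(cols)), nr, nc)
}

# Parabolic (3-point) sub-step refinement of a grid maximum. Returns the
# offset in grid-step units, clipped to [-0.5, 0.5].
parabolicPeak <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (ym1 - yp1) / den))
}
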