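# FtsZQuant

Quantification of FtsZ self-organization dynamics from in vitro
reconstitution experiments. FtsZ — the bacterial tubulin homologue of the
cell-division ring — self-organizes on supported lipid bilayers into
treadmilling ring patterns whose geometry and dynamics respond sensitively
to single-site chemical perturbations of the protein (e.g. tyrosine
halogenation). This package provides, for researchers analyzing TIRF
time-lapse data of such systems:

* **Treadmilling velocimetry**: circular-kymograph extraction along fitted
  ring trajectories and Fourier phase-slope estimation. For a ring of
  diameter *D* treadmilling at speed *V*, the pattern rotates at
  ω = 2*V*/*D*; the phase of the kymograph's dominant spatial frequency
  *k*\* advances as φ(t) = φ₀ − *k*\* ω t, so a least-squares line
  through the unwrapped phase gives ω and hence *V* = |ω| · r · pixel
  size. Includes Savitzky–Golay smoothing, CLAHE for weak patterns, and a
  spectral/phase-fit quality gate.
* **Image preparation**: frame averaging, 5×5 box mean filtering,
  sub-pixel (0.1 px) translation drift correction by phase
  cross-correlation, and threshold-based time-zero synchronization.
* **FRAP kinetics**: double normalization and the mono-exponential
  recovery fit Y = A·e^(−kt) + B with half-time t½ = ln 2 / k.
* **Morphometrics**: matched-filter circular Hough ring detection, ring
  surface density, Gaussian histogram fits of diameter/velocity
  distributions, and sliding-window (Kåsa) filament curvature with
  extreme-value (Gumbel) histogram fits.
* **Side-chain chemistry**: Henderson–Hasselbalch pKa fits of NMR pH
  titrations, closed-form logD(pH) profiles, and halogen mass-shift
  calculation.
* **A synthetic-data generator** (treadmilling ring movies, curved
  filament fields, FRAP traces, titrations) with exact ground truth, used
  throughout the test suite for parameter-recovery validation.

## Worked example

Simulate a wild-type-like ring (D = 0.80 µm treadmilling at 21.63 nm/s,
65 nm pixels, one frame per 3 s) and recover its speed through the full
chain — mean filtering, drift correction, two-seed circle fitting,
three-trajectory kymograph extraction, smoothing and phase-slope
velocimetry:

```r
library(FtsZQuant)

rr  <- data.frame(row = 32, col = 32, diameterNm = 800, speedNmPerS = 21.63)
sim <- makeRingMovie(rr, fieldPx = 64, nFrames = 40, seed = 1)
sim$movie
#> FtsZMovie: 40 frames, 64 x 64 px, 65.0 nm/px, dt = 3.00 s
#>   intensity range [1.0, 547.3] AU

res <- estimateTreadmilling(sim$movie, seedA = c(32, 25.8), seedB = c(32, 38.2))
res$roi
#> RingROI: center (32.22, 31.68) px, radius 6.20 px
res$estimate
#> VelocityEstimate: 21.80 nm/s (k* = 1, SNR = 311.7, R2 = 0.999, rows 100%) -> accepted
```

The fitted ring diameter is 2 · 6.20 px · 65 nm = 0.806 µm and the
recovered speed 21.80 nm/s — both within 1% of the generator truth. The
`accepted` flag is the quality gate (spectral SNR ≥ 2, phase-fit
R² ≥ 0.8, ≥ 80% of rows surviving phase-jump filtering).

FRAP and titration fits work the same way:

```r
frap <- makeFrapTrace(A = -0.6, k = 0.13946, B = 0.9,
                      tGrid = seq(0, 30, 0.5), noiseSd = 0.01, seed = 2)
fitRecovery(frap$trace)
#> ExpFit: Y = -0.5884 exp(-0.1412 t) + 0.8904, t1/2 = 4.910 s

tit <- makeTitration(pKa = 6.52, deltaHA = 7.10, deltaA = 6.70,
                     pHGrid = seq(4, 10, 0.25))
fitPka(tit$pH, tit$delta)
#> HHFit: pKa = 6.52 (dHA = 7.100, dA = 6.700 ppm, resid sd 0)
```

The half-time reported above is ln 2 / k of the *fitted* rate on a noisy
trace; on a noiseless trace the generator parameters are recovered to
better than 10⁻⁶ relative error (see `tests/testthat/test-frap.R`).

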