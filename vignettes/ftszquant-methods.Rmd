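---
title: "Quantifying FtsZ self-organization: models, estimators and synthetic validation"
author: "FtsZQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FtsZ self-organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FtsZQuant)
```

# The system and the measurements

FtsZ, the bacterial tubulin homologue at the heart of the cell-division
machinery, self-organizes on supported lipid bilayers into dynamic ring
("vortex") patterns. Although individual subunits do not move, GTP-driven
polymerization at one filament end and depolymerization at the other make
the pattern *treadmill*: in TIRF time-lapse movies each ring appears to
rotate. Single-site chemical perturbations of the protein — for example
halogenation of a surface tyrosine — shift the ring diameter, the
treadmilling speed, the filament curvature, the subunit turnover rate and
the side-chain acidity. This package implements the quantitative pipeline
that turns raw observations into those five numbers:

1. **Treadmilling velocimetry** — circular-kymograph extraction and
   Fourier phase-slope estimation (`estimateTreadmilling` and the
   operations it composes).
2. **FRAP recovery kinetics** — double normalization and a
   mono-exponential fit, `Y = A e^{-kt} + B`, with half-time
   `t½ = ln 2 / k`.
3. **Morphometrics** — ring detection, diameter and density statistics
   with Gaussian histogram fits; filament curvature with extreme-value
   (Gumbel) histogram fits.
4. **Side-chain chemistry** — Henderson–Hasselbalch pKa fits of NMR pH
   titrations, a closed-form logD(pH) model, and halogen mass-shift
   arithmetic.
5. **A synthetic-data generator** that renders all of the above with
   known ground truth, because the raw microscopy data underlying the
   published numbers are not deposited in a reusable form. Every
   estimator in the package is validated as a parameter-recovery
   experiment against this generator.

# The velocimetry model

A treadmilling ring of diameter $D$ whose pattern advances at speed $V$
(nm/s along the circumference) rotates rigidly at angular rate

$$\omega = \frac{2V}{D}.$$

Sampling the movie along a circle of radius $r$ (pixels) concentric with
the ring produces a kymograph $K(t, s)$ (rows = frames, columns = angular
positions at 1 px arc steps). Rigid rotation makes the kymograph a pure
transport pattern, $K(t, s) = K(0, s - r\omega t)$, i.e. stripes of
constant slope. For any spatial frequency $k$ (cycles per circumference)
the complex Fourier coefficient of row $t$ has phase
$\varphi_t = \varphi_0 - k\,\omega\, t$, so the slope of the unwrapped
phase–time line at the dominant frequency $k^\*$ gives
$\omega = -\,\mathrm{d}\varphi/\mathrm{d}t \,/\, k^\*$ and
$V = |\omega|\, r\, p$ with $p$ the pixel size. On analytic transport
kymographs the implementation recovers $V$ to better than $10^{-6}$
relative error (tested).

The processing chain mirrors the standard workflow for these data:

* per-frame **box mean filter** of half-width 2 px (5×5), reflection
  padded;
* **drift correction** (below);
* **two-seed circle fit**: the user clicks two roughly diametrical points;
  the circle is refined by maximizing mean ring-path intensity over a
  local grid (center and radius ±3 px, 0.25 px steps) with parabolic
  sub-step interpolation;
* kymograph extraction along **three concentric circles** ($r-1, r, r+1$)
  sampled at the same angles and averaged pointwise — averaging the three
  trajectories is our choice; fitting each separately and pooling slopes
  is the main alternative and gives the same estimator in the noiseless
  limit;
* **Savitzky–Golay smoothing** (order 2, window 7, circular boundary)
  along the arclength axis. The reference workflow states the order but
  neither the window nor the axis; 7 is the smallest window that gives
  meaningful order-2 smoothing at 1 px arc steps, and smoothing along
  arclength (not time) avoids biasing the phase–time slope that carries
  the velocity. Both are parameters.
* **CLAHE** contrast enhancement (8×8 tiles, normalized clip limit 0.01)
  is applied *only* when the spectral SNR is below 5: it rescues weak
  stripe patterns (measured ≥ 10× amplification of 1% stripes) but
  distorts amplitudes, so strong patterns are phase-tracked raw.
* **quality gate**: spectral peak SNR ≥ 2, phase-fit R² ≥ 0.8, and ≥ 80%
  of rows surviving phase-jump filtering (rows whose phase increment
  deviates from the median by more than π are excluded). White-noise
  kymographs are rejected in > 90% of Monte-Carlo trials.

## Circle-fit radius: blur correction

The azimuthally averaged radial profile of a thin fluorescent ring blurred
by the PSF (plus filtering) of total width $\sigma$ peaks near
$\sqrt{r^2 - \sigma^2}$, *inside* the true fluorophore circle — for a
0.8 µm ring imaged at 65 nm/px with a ~110 nm PSF and a 5×5 mean filter
the bias is ≈ 8% of the radius, which would propagate linearly into the
reported speed. `fitCircle` therefore measures $\sigma$ from a Gaussian
fit to the radial intensity profile and reports
$\sqrt{\rho_{\mathrm{peak}}^2 + \sigma^2}$ (option `blurCorrect`,
default on; widths beyond 3.5 px are treated as fit failures and left
uncorrected).

## Drift correction

Registration is translation-only phase cross-correlation with upsampled
sub-pixel (0.1 px) refinement, run consecutively between neighbouring
frames and accumulated, followed by an align-to-the-temporal-mean pass.
Two non-obvious choices:

* The sub-pixel peak is refined on the *raw* cross spectrum
  (Guizar–Sicairos-style matrix DFT): whitening amplifies frequencies
  with no signal and destroys the sub-pixel peak on smooth scenes. The
  integer peak uses the regularized whitened spectrum, and the estimate
  is iterated (measure, counter-shift, re-measure) because windowing
  biases single-pass estimates of large shifts toward zero.
* For movies dominated by a single rotating ring, the evolving azimuthal
  pattern drags the correlation peak tangentially; over one revolution
  this artifact traces a closed loop of several pixels. The pipeline
  therefore uses a **constant-velocity drift model**: the per-frame step
  is the 25%-trimmed mean of the shift increments, which rejects the
  zero-mean oscillating artifact, captures genuine smooth stage drift,
  and interpolates below the 0.1 px registration quantization. The raw
  per-frame mode (`model = "free"`) remains available and is what the
  sub-pixel registration tests exercise. On synthetic drifting rings the
  corrected movie's velocity matches the drift-free movie within 2%.

# FRAP model

The recovery is fitted as printed, $Y = A e^{-kt} + B$, with the
amplitude *signed*: upward fluorescence recovery corresponds to $A < 0$,
the plateau is $B$, and the half-time $t_{1/2} = \ln 2 / k$ depends only
on $k$. Traces are double normalized,
$N(t) = [I_{\mathrm{bleach}}(t)/I_{\mathrm{ref}}(t)] \big/
[I_{\mathrm{bleach}}^{\mathrm{pre}}/I_{\mathrm{ref}}^{\mathrm{pre}}]$,
which cancels any photobleaching common to both channels exactly
(tested as an invariant). Initialization takes $B_0$ from the last three
points, $A_0 = Y(0) - B_0$, and $k_0$ from the empirical half-recovery
time; optimization is Levenberg–Marquardt with 1e-10 tolerances. Both the
normalized and the raw-trace paths are exposed (`fitRecovery(...,
normalized = )`) since published half-times do not state which was used;
for noiseless synthetic data both recover the generator parameters to
$10^{-6}$.

# Morphometrics

**Ring detection** is a circular Hough transform implemented as a matched
filter: for each candidate radius the background-subtracted image is
correlated with a zero-mean Gaussian-annulus template whose response
estimates the ring amplitude. Candidates are thresholded (default 40% of
the robust intensity range), reduced by greedy non-maximum suppression
using the disjointness constraint (two ring centers cannot be closer than
the sum of their radii), and refined with the intensity circle fit. On
synthetic fields the detector finds 25/25 disjoint rings with sub-pixel
centers and leaves blank (flat or pure-noise) images empty.

**Distribution fits** follow the plotted-curve convention of the figures
they reproduce: a least-squares Gaussian (diameters, velocities; default
bins 0.1 µm and 2 nm/s) or Gumbel (curvatures; 0.25 µm⁻¹ bins) curve
fitted to histogram *counts*, not a maximum-likelihood fit to samples.
"Extreme fit" is interpreted as the type-I extreme-value (Gumbel) family,
the default "Extreme" function of the plotting software used for the
original figures; a Weibull alternative is selectable. Curvature signs
are discarded (magnitudes are reported).

**Filament curvature** is estimated on centerline points (e.g. SOAX snake
exports — the tracer itself is out of scope) by sliding-window algebraic
(Kåsa) circle fits; collinear windows get curvature 0 by the
infinite-radius convention. The estimator is exact on circles (1/R to
1%), rigid-motion invariant and scale equivariant.

# Side-chain chemistry

NMR titrations are fitted with the two-state fast-exchange form of the
Henderson–Hasselbalch equation,
$\delta(\mathrm{pH}) = \delta_{HA} + (\delta_A - \delta_{HA})/(1 +
10^{pK_a - \mathrm{pH}})$. Monte-Carlo recovery at 0.005 ppm noise on a
pH 4–11 grid is within 0.05 pKa units — comfortably inside the ±0.15
experimental error quoted for such measurements. Each ionizable site
(phenol, ammonium) is fitted as an independent series; no coupled
two-site model. The logD profile uses first-order neutral-species-only
partitioning, $\log D = \log P - \log_{10}(1 + 10^{\mathrm{pH} - pK_a})$,
a deliberate simplification that ignores ion-pair partitioning; it is a
model utility for exploring the lipophilicity/acidity interplay of
halogenated tyrosines, not a claimed reproduction of measured logD
tables. Mass shifts use IUPAC standard (or monoisotopic) atomic masses.

# The synthetic-data generator

`makeRingMovie` renders rings as annuli of Gaussian radial cross-section
(default 50 nm sd) whose azimuthal intensity profile — a sum of 3–8
wrapped Gaussian blobs with random positions, widths and weights —
rotates rigidly at $\omega = 2V/D$. Rendering is 4× super-sampled then
binned, convolved with a Gaussian PSF (default 110 nm sd), and degraded
with Poisson shot noise plus Gaussian read noise; a seed fixes the output
bit-exactly. Defaults reflect the instrument class of the source data:
65 nm pixels (100× objective, 6.5 µm camera pixels) and 3 s frame
intervals. The blob profile guarantees a non-degenerate characteristic
frequency; requesting zero azimuthal contrast in a movie is an error
because rotation would be unobservable. The `azimuthal = "uniform"` mode
renders azimuthally constant annuli — the time-average limit of a
treadmilling ring over a full revolution — and is what the static
morphometric fields use, matching the experimental practice of detecting
rings on frame-averaged images.

What the generator deliberately does **not** emulate: the
depth-dependent TIRF excitation profile, any mechanistic polymerization
kinetics (no GTP hydrolysis, no monomer exchange, no filament-level
structure inside the ring), membrane background texture, and camera
fixed-pattern noise. Passing the recovery tests therefore demonstrates
that the estimators are correct and well-conditioned under realistic
geometry, sampling and noise — not that they are robust to every
real-data pathology (overlapping rings, partial rings, heterogeneous
backgrounds).

Ring-field diameters are drawn from the normal distribution of the study
conditions (mean 0.80 µm, sd 0.18 µm) truncated symmetrically at
±0.5 µm around the mean, which keeps every ring physically renderable
(radius ≥ 2 px) without biasing the mean.

# Problem sizes and numerical choices

Validation experiments run at deliberately desk-scale sizes, chosen as
the smallest that exercise the estimators meaningfully: single-ring
movies of 64×64 px × 40 frames (≈ one full revolution at the wild-type
speed), velocity recovery averaged over 20 seeds, morphometric fields of
56 rings × 20 fields, 100-seed Monte-Carlo runs for the scalar fits.
Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with
moment-based/plateau initializations stated above; histogram fits start
from sample moments. Degenerate inputs are contracts, not crashes: flat
intensity landscapes return low-confidence ROIs, constant kymographs
pass CLAHE untouched with a flag, flat FRAP traces and transition-free
titrations are flagged or rejected with descriptive errors.

# Known limitations

* The intensity circle fit assumes a locally Gaussian radial profile for
  its blur correction; heavily saturated or strongly asymmetric rings
  would need a different profile model.
* The trimmed-mean drift model assumes stage drift is near-linear over
  the acquisition; strongly curved drift paths need `model = "free"` on
  feature-rich fields.
* Velocity estimation reports a single dominant rotation; mixed-polarity
  or multi-speed flux within one ring is out of scope.
* The matched-filter detector assumes approximately circular, disjoint
  rings; merged or strongly elliptical patterns are not resolved.
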