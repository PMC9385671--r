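Package: FtsZQuant
Title: Quantification of FtsZ Ring Self-Organization, Treadmilling and
    Turnover Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the self-organization of the bacterial
    cell-division protein FtsZ on supported lipid bilayers from TIRF
    time-lapse data: circular-kymograph extraction along fitted ring
    trajectories, treadmilling velocimetry by Fourier phase-slope
    estimation with spectral quality gating, mono-exponential FRAP
    recovery fitting, ring and filament morphometrics (Hough ring
    detection, sliding-window curvature, Gaussian and extreme-value
    histogram fits), and Henderson-Hasselbalch pKa analysis of NMR
    titrations. Includes a synthetic-data generator that renders
    treadmilling ring movies, curved filament images, FRAP traces and
    titration curves with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    EBImage,
    signal,
    minpack.lm,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
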