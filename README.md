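# matricell

Image-based stromal matrix models and cell migration analysis.

`matricell` reimplements, as a tested and reusable R pipeline, the
computational methods behind studies of cancer cell migration on
image-based collagen scaffolds: second-harmonic-generation-like images of
fibrous stroma are discretized into fabrication blueprints and modulated
raster scan plans, simulated "fabricated" readouts are scored for fidelity
by colocalization, cell trajectories are reduced to motility parameters
through the persistent-random-walk model, and cell morphology, stress-fiber
orientation, focal adhesions and fluorescence are quantified with the
field's standard metrics. Because no microscopy data are deposited with
such studies, the package ships a first-class synthetic-data module:
seeded phantoms for the four ovarian stromal morphology classes (normal
mesh-like stroma, thicker benign-tumor fibers, aligned high-risk fibers,
aligned wavy high-grade tumor fibers), persistent-random-walk trajectories
with known parameters, elliptical cell masks, and punctate focal-adhesion
images — so every stage is testable end to end without any download.

It is aimed at quantitative cell biologists and biomedical engineers who
want the analysis half of an image-based scaffold experiment — or a fully
synthetic rehearsal of one — in a handful of pipeable functions.

## The models at the core

**Fiber discretization and fidelity.** Bright curvilinear structures are
enhanced with a multiscale Hessian ridge (tubeness) response — the
magnitude of the most negative Hessian eigenvalue, scale-normalized and
maximized over scales — thresholded by Otsu's method, and small objects
removed. The graded map (original intensities on the mask, rescaled to
[0, 1]) maps linearly to the per-pixel shutter "open" fraction of a
modulated raster scan plan, so exposure tracks relative collagen
concentration. Blueprint-to-readout fidelity combines the Dice coefficient
of the two support masks with the Pearson correlation of graded
intensities on their union.

**Persistent random walk (PRW).** Cell velocity follows a stationary
Ornstein–Uhlenbeck process; the ensemble mean squared displacement is the
Fürth formula

    ⟨d²(t)⟩ = 2 n_d μ [ t − P (1 − e^(−t/P)) ],    n_d = 2,

with motility coefficient μ (µm²/min) and persistence time P (min),
estimated by bounded nonlinear least squares on the time-averaged,
pair-count-weighted ensemble MSD.

**Axial orientation statistics.** Local fiber and stress-fiber orientation
comes from the structure tensor (axis of least intensity variation, with
coherence (λ₁−λ₂)/(λ₁+λ₂)). Orientations are axial (mod 180°): statistics
double the angles, apply circular statistics, and halve — mean direction,
alignment index (mean resultant length), Pearson correlation between
binned distributions, and a permutation-based two-sample Watson's U² test.

**Morphometry.** Circularity 4πA/p² (chain-code perimeter with Kulpa's
correction), cell-to-fiber alignment angle folded into [0°, 90°],
difference-of-Gaussians focal-adhesion detection with a robust background
threshold, and corrected total cell fluorescence
CTCF = integrated density − cell area × mean background.

## Worked example

```r
library(matricell)

# a high-grade tumor stroma phantom: aligned, crimped fibers + ground truth
phantom <- generate_fiber_image(morphology_params("high_grade"), seed = 7)
phantom$image
#> <fiber_image> 400 x 400 px (200.0 x 200.0 um at 0.5 um/px), intensity [0, 421]

# discretize into a fabrication blueprint and a 3 x 3 tiled scan plan
blueprint <- discretize_fibers(phantom$image, scales_um = c(0.5, 1))
blueprint
#> <blueprint> 400 x 400 px, tile 200 x 200 um, fiber coverage 15.8%
build_scan_plan(blueprint, dwell_us = 10, tiles = c(3, 3))
#> <scan_plan> 400 x 400 px, dwell 10 us, 3 x 3 tiles, overall 600 x 600 um

# simulate imaging the fabricated scaffold and score the fidelity
fabricated <- simulate_fabrication(blueprint, psf_fwhm_um = 0.6,
                                   noise = "poisson", snr = 20, seed = 8)
fidelity_score(blueprint, fabricated)
#> Fidelity: 97.4% (spatial overlap 98.3%, intensity correlation 0.965)

# simulate 500 cells tracked every 30 min for 72 h and fit the PRW model
tracks <- generate_trajectories(prw_params(mu_um2_per_min = 10, P_min = 30),
                                seed = 9)
fit <- fit_motility(tracks)
tidy(fit)
#> # A tibble: 2 × 3
#>   term           estimate std.error
#>   <chr>             <dbl>     <dbl>
#> 1 mu_um2_per_min     9.86    0.0135
#> 2 P_min             26.9     1.15

# orientation distribution of the scaffold fibers
field <- orientation_field(phantom$image, sigma_um = 2)
angular_distribution(field, n_bins = 36, mask = blueprint$mask)
#> <angular_distribution> 36 bins over [0,180), n_eff = 1.913e+04, alignment index = 0.683

# do two samples of stress-fiber orientations share a distribution?
a <- sample_axial_vonmises(50, 0, 4)
b <- sample_axial_vonmises(50, 90, 4)
watson_u2(a, b, seed = 10)
#> Two-sample Watson's U2 (axial data): U2 = 2.0850, p = 0.001 (n1 = 50, n2 = 50, 999 permutations)
```

The fidelity line reads: after blurring the blueprint with the
instrument's ~0.6 µm point-spread function and adding photon noise, 98% of
the fiber support is recovered and graded intensities correlate at 0.965,
for a combined fidelity of 97.4% — comfortably above the 90% design
threshold for faithful fabrication. The PRW fit recovers the generating
parameters (μ = 10 µm²/min, P = 30 min) within sampling error, and the
Watson U² test cleanly rejects equality of two orientation distributions
whose axes differ by 90°.

`run_pipeline(run_config(seed = 1))` chains all of the above for the four
morphology classes and writes a JSON report plus a text summary.

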