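---
title: "Methods: image-based stromal models and migration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based stromal models and migration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matricell)
```

`matricell` packages the computational half of an image-based scaffold
experiment: from a grayscale image of fibrous stroma to a fabrication
blueprint and scan plan, from time-lapse cell trajectories to motility
parameters, and from stained-cell images to orientation, shape, adhesion
and fluorescence metrics. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
phantoms do and do not establish about real data.

## The synthetic phantoms and what they emulate

Studies of this kind rarely deposit raw microscopy, so the package treats
synthetic data as a first-class module rather than a test fixture. Four
morphology presets emulate the stromal classes seen in second-harmonic
generation (SHG) images of ovarian tissue:

| class        | alignment (κ on doubled angles) | crimp | width |
|--------------|--------------------------------|-------|-------|
| `normal`     | 0 (isotropic)                  | none  | 1.5 µm |
| `benign`     | 0                              | none  | 3 µm (thicker, fibrotic) |
| `high_risk`  | 8 (aligned)                    | none  | 1.5 µm |
| `high_grade` | 8 (aligned)                    | 3 µm amplitude, 25 µm wavelength | 1.5 µm |

Each fiber is a curve with a Gaussian cross-section whose orientation is
drawn from a von Mises law on doubled angles — the standard construction
for axial data, in which an axis and its opposite are the same
observation. Waviness is a sinusoidal lateral displacement
`A sin(2πs/λ)` in the fiber frame: two interpretable parameters (amplitude,
wavelength) reproduce the periodic crimping characteristic of high-grade
tumor stroma. Images are 400 × 400 px at 0.5 µm/px — a 200 × 200 µm
field matching the single-tile pattern extent — with Poisson noise scaled
to a peak of 400 counts (photon-limited imaging at SNR ≈ 20).

The class presets fix what the source imagery constrains qualitatively
(alignment present/absent, crimp present/absent, relative width); absolute
fiber widths, lengths and the crimp wavelength are plausible placeholders
at the scale of such images, not calibrated measurements — no per-class
quantification exists to calibrate against. Likewise the phantoms make no
attempt to reproduce SHG speckle, depth attenuation, or 3D structure:
patterns are 2D with nominal 10 µm height metadata. Passing tests on
phantoms therefore establish that the estimators recover known ground
truth under realistic noise and geometry; they do not certify performance
on real SHG images, where fiber crossings, intensity heterogeneity and
out-of-plane structure are harsher.

## Discretization, scan plans, and fidelity

`discretize_fibers()` enhances bright curvilinear structure with a
multiscale Hessian ridge ("tubeness") response: at each scale the image is
Gaussian-smoothed, and the response is the magnitude of the most negative
Hessian eigenvalue (zero where that eigenvalue is positive), normalized by
scale² and maximized over scales. Defaults use scales of 0.5 and 1 µm,
bracketing the preset fiber widths. The response — not the raw image — is
thresholded by Otsu's method, which is parameter-free and reproducible;
objects under 1 µm² are removed. The graded map carries the original
intensities on the mask rescaled to [0, 1], standing for relative collagen
concentration.

`build_scan_plan()` is deliberately a bit-exact copy of the graded map
into a per-pixel shutter open fraction (default dwell 10 µs), because the
fabrication principle being modeled is precisely that linearity; the
tiling layout (default 3 × 3 of a 200 × 200 µm tile, i.e. 600 × 600 µm
overall) is metadata the scan plan must report exactly.

`simulate_fabrication()` stands in for imaging a fabricated scaffold:
Gaussian PSF blur plus noise. One modeling choice deserves note: the
graded map is already a pixel-sampled object, so the simulator applies
only the optical blur *in excess of* the pixel size, subtracting the two
in quadrature (`FWHM_eff² = FWHM² − px²`). A PSF at the sampling limit is
then exactly the identity, and the default 0.6 µm FWHM — the lateral
resolution of the fabrication/imaging instrument being modeled — applies
a mild sub-pixel blur at 0.5 µm/px.

`fidelity_score()` answers "how faithful is the readout to the design"
with two colocalization components: the Dice coefficient between the
blueprint mask and an Otsu mask of the (background-subtracted, rescaled)
readout, and the Pearson correlation of graded intensities over the union
of the masks. How the two should combine into one number is genuinely
open — published descriptions name both ingredients without a formula —
so the package reports both components plus their arithmetic mean (with
the correlation floored at zero), which is transparent and monotone in
each. On the high-grade phantom with default settings the combined score
is ~97%, comfortably above the 90% benchmark for faithful fabrication;
all three numbers are invariant to global rescaling of the readout.

## The persistent random walk

Trajectory analysis rests on the persistent random walk: velocity is a
stationary zero-mean Ornstein–Uhlenbeck (OU) process with per-component
variance μ/P and correlation time P, giving the Fürth ensemble MSD

$$\langle d^2(t)\rangle = 2 n_d \mu \left[t - P\left(1 - e^{-t/P}\right)\right],
\qquad n_d = 2,$$

ballistic (`n_d (μ/P) t²`) for t ≪ P and diffusive (`2 n_d μ t`) for
t ≫ P. The simulator uses the exact OU velocity update at substeps of
dt/50 — decay `e^(−δ/P)`, innovation variance `(μ/P)(1 − e^(−2δ/P))` —
with trapezoidal position integration, and draws the initial velocity
from the stationary law so the process is stationary from frame 0. This
avoids the bias of naive Euler stepping; at the default study sampling
(30-min frames over 72 h, i.e. 145 frames) the simulated ensemble MSD of
500 cells agrees with the Fürth formula to within a few percent at every
retained lag, the residual being Monte-Carlo noise that scales as
1/√n_cells.

Estimation mirrors standard practice. `ensemble_msd()` computes each
track's time-averaged MSD over all overlapping pairs, then averages
across tracks weighted by pair counts — the lowest-variance standard
estimator. Lags are cut at 1/3 of track duration: the long-lag tail of
time-averaged MSD has few effectively independent pairs and would
otherwise dominate the fit's variance; with this guard the motility
estimate is biased by well under 5% in recovery simulations. Tracks
shorter than 10 frames are excluded (with a message) since their pair
counts are too small to contribute stably. `fit_prw()` then runs bounded
nonlinear least squares (Levenberg–Marquardt) on the retained lags,
unweighted by default, initialized from the diffusive-limit slope
(μ₀ = slope/2n_d) and P₀ at the first lag, with restarts from two
alternative starting points.

Persistence time is structurally weakly identified: a near-ballistic
curve constrains only μ/P. The fit flags `identifiable_P = FALSE` when
the estimate sits at its bound, exceeds the largest observed lag (the
data never leave the ballistic regime), or carries a standard error
larger than itself. Whether to fit one ensemble curve or fit per cell and
average is not settled practice; both are provided
(`fit_motility(mode = "ensemble")`, the default, and `"per_cell"`).

Contact guidance departs from the Fürth model by design. With
`guidance_strength` g > 0 the simulator (i) rotates the velocity toward
the local fiber axis by g times the axial angular difference each frame,
and (ii) gives the axis-parallel velocity component a longer persistence
time and proportionally larger stationary variance (both scaled by
1 + g). The rotation alone aligns headings but provably leaves long-time
motility unchanged — it redistributes direction onto an axis without
suppressing reversals along it — whereas enhanced persistence along
fibers is the accepted mechanism by which aligned matrices raise
motility. With both ingredients, fitted μ̂ increases monotonically with g,
reproducing the qualitative ordering seen across stromal classes of
increasing alignment, while headings concentrate on the fiber axis.

## Axial orientation statistics

All orientation quantities treat angles as axial (mod 180°), doubling
angles before any circular computation. Angles are measured from the
image +x axis with y pointing down (the raster convention used
throughout, including trajectory headings: a step in −y is 270°).

`orientation_field()` uses the structure tensor: gradients of the
1-px-presmoothed image, tensor components smoothed at an integration
scale `sigma_um` (default 2 µm in the pipeline — large enough to average
over a fiber cross-section, small enough not to mix neighboring fibers),
orientation as the axis of least intensity variation and coherence as
(λ₁−λ₂)/(λ₁+λ₂). A curvelet-based tool is sometimes used for this in the
field; the structure tensor is the parameter-light standard that delivers
the same angular distributions, which is all the downstream statistics
consume. Constant images are flagged and given zero coherence.

Distributions are histograms on [0, 180), default 36 bins of 5° — a
balance of angular resolution against per-bin counts; nothing downstream
depends on the exact width, but comparisons require identical binning and
`pearson_between()` refuses to rebin silently. The alignment index is the
mean resultant length of the doubled bin centers under the binned density
(0 for isotropy, 1 for a single bin; for a von Mises sample with
concentration κ it estimates the Bessel ratio I₁(κ)/I₀(κ)).

Watson's two-sample U² is computed on doubled angles from the combined
ranked sample; because the statistic depends on the data only through the
group interleaving, p-values come from random permutation of group labels
(default 999), exact under exchangeability at any sample size — asymptotic
U² tables would add nothing and fail at small n. Calibration checks show
the test holds its nominal 5% size under the null and has high power
against 90°-rotated von Mises alternatives at n = 50.

One caution for interpreting the Pearson correlation between two binned
distributions: under the null of unrelated distributions its standard
deviation is ≈ 1/√(k−1) for k bins (≈ 0.17 at 36 bins) *regardless of the
sample sizes behind the histograms*, so modest correlations are expected
by chance and published correlation tables of this kind should be read
with that yardstick.

## Morphometry and fluorescence

Circularity is 4πA/p², 1 for a circle. The perimeter estimator matters
more than the formula: counting boundary pixel edges inflates p by
10–20% and deflates circularity correspondingly. The package walks the
ordered 8-connected boundary chain and applies Kulpa's corrected step
weights (0.948 per axis-parallel step, 0.948√2 per diagonal step), which
brings a digitized r = 100 px circle to circularity 1.00 and a 4:1
ellipse within a few percent of its Ramanujan-perimeter analytic value.
Values are clipped at 1 to absorb residual digitization bias. Orientation
and aspect ratio come from second central moments; the cell-to-fiber
alignment angle is the axial difference between the cell's major axis and
the fiber axis folded into [0°, 90°], so lower means more aligned.

Focal adhesions are detected as difference-of-Gaussians puncta (scales
σ and 1.6σ) above `mean + k·sd` of the in-mask background response, with
the background moments estimated by iterative 3σ clipping so the spots
themselves do not inflate the threshold. The default k = 5 is higher than
a naive per-pixel argument would suggest, deliberately: the band-passed
noise field is spatially correlated, and its excursion sets form
multi-pixel blobs often enough that a 3σ cut produces spurious
"adhesions" even on spot-free images. k = 5 yields zero detections on
spot-free phantoms while keeping ≥ 95% recall and precision at
signal-to-noise 10, and makes counts robust to doubling the spot
amplitude. Components are filtered to [0.25, 25] µm², bracketing
resolvable adhesion sizes and rejecting single-pixel exceedances.

CTCF is the classical corrected total cell fluorescence,
`integrated density − cell area × mean background`, with the background
region supplied by the caller (mirroring manual ROI practice — automatic
background selection would hide a consequential choice). It is exactly
invariant to constant offsets, and `ctcf_ratio()` forms the
area-normalized on-pattern/off-pattern expression ratio used for relative
cadherin quantification.

## Pipeline and group statistics

`run_pipeline()` chains phantom → blueprint → scan plan → simulated
readout → fidelity → trajectories → motility fit → orientation summaries
for each configured class, with per-class sub-seeds derived
deterministically from the master seed; a run is reproducible from the
config plus seed alone, and the JSON report is byte-identical across
reruns. `compare_groups()` performs one-way ANOVA followed by all
pairwise Welch t-tests — Welch because equal variances across conditions
are rarely defensible for cell-level metrics; the pooled test is
available. No multiplicity correction is applied by default, mirroring
common reporting practice in the field; Holm's correction is one flag
away and recommended for confirmatory analyses.

## Problem sizes, tolerances, and limitations

The test suite exercises the stated study conditions where they are
cheap — 500 cells × 145 frames for the Fürth oracle and parameter
recovery (50 replicates; median |μ̂ − μ|/μ ≤ 10%, |P̂ − P|/P ≤ 20%),
1000 null replicates × 999 permutations for Watson U² calibration —
and smaller phantoms (tens of fibers, tens of cells) for unit-level
properties, sizes chosen so the full suite runs in a couple of minutes on
a laptop. Pointwise MSD tolerances follow the Monte-Carlo scaling
1/√n_cells rather than wishful thinking: at 500 cells the largest
retained lags fluctuate by a few percent, so the curve is held to a 3%
mean error and an 8% pointwise bound in unit tests, with the 5%-at-all-
lags check reserved for the full stated conditions.

Known limitations: phantoms are 2D and geometric, not radiometric
emulations of SHG; discretization assumes pre-registered images (no
alignment search); the contact-guidance simulator is a phenomenological
two-parameter mechanism, not a mechanistic adhesion model, and the Fürth
formula deliberately does not hold under guidance; trajectory tracking
itself (linking detections across frames) is out of scope — tables of
tracked positions are the input; and segmentation of cells from
phase-contrast video is likewise assumed done upstream, with masks as
inputs.
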