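---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind each stage:
the models and their assumptions, the parameters that matter (with units
and defaults), what the phantom generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate conventions

One convention is used everywhere: matrices are `[row = y, column = x]`;
pixels are 0-based; pixel `(i, j)` of a plane with pitch `p` nm has its
centre at physical `((j + 0.5) p, (i + 0.5) p)` nm. Stage arithmetic is in
µm (the stage's native unit), pixel sizes in nm, with a fixed factor of
1000 between them. Tile offsets are the stage positions of each tile's
pixel-origin *corner* (the corner convention is asserted by the retrieval
round-trip tests). All registration transforms live in physical nm, which
is what lets a 65 nm/px widefield image, a 160 nm/px relay-lens image and
a 10 nm/px super-resolution rendering be overlaid without pixel bookkeeping.

## Image cytometry

**Preprocessing.** Flat-field correction divides by the illumination
reference normalised to unit mean (so a constant reference is the
identity). Background is then removed by a rolling-ball estimate: the
grayscale morphological opening of the plane with a disc of radius
`radius_px` (default 25 px at 325 nm/px, i.e. about twice the nucleus
radius). Two practical details matter on shot-noise-limited images, and
both follow classic rolling-ball implementations: the estimate is computed
on a lightly smoothed copy (otherwise the erosion tracks the lower
envelope of the noise, not the background level — on the phantom this
biased the G2/G1 DNA-content ratio from 2.0 down to 1.8), and for large
radii the opening runs on a block-shrunk copy and is re-expanded. The
opening itself is implemented in-package (disc decomposed into row runs,
each a van Herk running minimum), since the installed image library
provides only binary morphology; the test suite checks it against a direct
brute-force opening.

**Segmentation.** A global threshold on the DNA channel, hole filling,
optional watershed splitting on the distance transform, a size filter, and
removal of border-touching objects (their area and intensity are biased;
a flag retains them). The default threshold is Otsu computed on
`log10(1 + I)` after a 1 px Gaussian smooth: fluorescence nuclei span a
wide intensity range, and linear-space Otsu tends to land above the
dimmest G1 nuclei (measurably: it lost about one cell in fifty on the
phantom). Both the log transform and the smoothing are parameters;
`method = "manual"` bypasses them.

**Measurement.** Per label: area (px and µm²), centroid, circularity
`4πA/P²` with the perimeter estimated from the oriented contour using
Kulpa step weights (0.948 straight, 1.340 diagonal) and the result clamped
to 1 — a digitised disc of radius 20 px stays above 0.95, which a naive
pixel-edge perimeter does not achieve; and per channel the mean and
integrated intensity. Integrated intensity is additive under label splits
by construction (it is a plain sum), which the tests assert exactly.

**Spots.** Difference-of-Gaussians band-pass (defaults 1 and 4 px),
threshold at `k = 6` MADs above the median of the band-passed image,
watershed splitting of touching spots seeded at band-pass maxima (minimum
peak-to-saddle: half the detection threshold, so noise ripple inside one
spot does not shatter it), size filter, then the same measurements as
cells; each spot is assigned to the cell containing its centroid.

## Cell-cycle classification

The classifier works on the distribution of per-cell integrated DNA
intensity. The G1 peak `P` is the lowest local maximum of a kernel
density estimate (Silverman bandwidth) reaching at least 25% of the global
mode — the "lowest" rule guards against G2-dominant samples. All windows
are multiples of `P`, so classification is invariant to any uniform
rescaling of intensity (tested): G1 `[0.8, 1.25]·P`, G2 `[1.6, 2.5]·P`,
sub-G1 debris below `0.5·P` unclassified. In EdU mode, S-phase is called
first from the EdU channel (threshold: config value, or an Otsu split of
log EdU); in DNA-only mode S is everything between the windows. Mitosis is
overlaid on G2-window cells by DNA condensation (mean DNA intensity above
1.5× the interphase median), reduced area (below 0.8× the median) and
near-circular shape (circularity above 0.9), OR a mitosis-marker mean
above threshold (default: median + 5 MAD). The window and morphology
constants are config-exposed; the defaults are the package's own, since
the underlying logic (content windows around a G1 peak, condensation +
morphology for mitosis) fixes their meaning but not their values.

## The phantom population

The generator emulates exactly what the cytometry stage measures: nuclei
as rough ellipses (radius 4.2 µm ± 8%, ellipticity up to 1.25, 4%
boundary roughness) placed without contact on 512 px tiles at 325 nm/px,
50 per tile; DNA integrals Normal(20000, CV 0.07) photons for G1, twice
that for G2/M, EdU and mitosis-marker channels bright only in their
phases; mitotic nuclei at 55% area and circular, which doubles their mean
DNA intensity (condensation) without changing content; a foci channel with
Poisson(5) diffraction-scale spots per nucleus and one large bright focus
in 10% of G1 cells; camera noise as Poisson photons plus Gaussian read
noise (sd 2) over a 10 photon background at gain 1.

Two generative choices deserve their reasoning spelled out:

* **S-phase DNA content occupies the mid-band 1.30–1.60 G1-equivalents**
  rather than the full 1–2 range. Real mid-S cells do sit between the G1
  and G2 peaks, but a population whose S compartment extends into the G1
  and G2 windows is *inherently* ambiguous to any DNA-content gate — no
  classifier can attribute a cell at 1.1× G1 content to S rather than G1
  from DNA alone. The phantom is built to be separable so that classifier
  defects are attributable: with the default band, DNA-only and EdU modes
  must both recover every phase, and failures indicate bugs, not
  ambiguity. The band is a config entry (`s_band`); widening it to
  `c(1.0, 2.0)` produces the realistic overlap regime, in which only EdU
  mode retains full S sensitivity.
* **Foci are placed with a 6 px minimum separation** and the truth table
  records the realised count. Spots closer than the optical scale are one
  spot to any detector; recoverable truth is what makes count-recovery a
  meaningful test. The same reasoning puts ordinary foci outside the
  exclusion zone of the large central focus.

What the phantom does **not** emulate: touching or overlapping cells (so
segmentation correctness is tested separately from under-segmentation
robustness), intensity gradients across tiles, chromatic aberration,
spectral bleed-through, out-of-focus light, or cell-to-cell DNA staining
variability beyond the stated CVs. A pass on the phantom therefore
validates the measurement and decision logic, not robustness to those
real-data pathologies.

## SMLM: fitting, drift, rendering

**Localization fitting** is the standard open chain: per-frame candidate
detection (local maxima above the frame median + `k = 6` robust sigmas,
non-maximum suppression at the fit-window scale), least-squares fit of a
*pixel-integrated* 2D Gaussian (offset, total photons, centre, sigma) in a
7×7 window, and a Thompson-style precision
`σ_loc² = s²/N + a²/(12N) + 8π s⁴ b²/(a² N²)` (s: fitted PSF sigma, N:
photons, a: pixel size, b: background noise). Fits failing convergence,
the sigma bounds (50–400 nm) or a 100-photon floor are discarded and
counted. The pixel-integrated model matters at 160 nm pixels: it recovers
a noiseless emitter to well under 0.1 nm where the point-sampled model
does not. On Poisson-noise phantoms the per-axis RMSE runs about 1.3× the
reported precision — the known inefficiency of unweighted least squares
relative to the information bound — which the tests bound at 1.5×.

**Drift.** Fiducials sampled once every `cadence_K = 1000` frames (anchors
`0, K, …, frames`, bracketing the acquisition) are linked across anchors
by nearest neighbour within 500 nm of their drift-predicted positions;
drift per anchor is the mean displacement of linked fiducials relative to
the first anchor, so independent per-fiducial noise averages down.
Correction subtracts the piecewise-linearly interpolated drift at each
record's frame (clamped outside the anchor range). Note the estimator's
intrinsic floor: with 3 fiducials of 2 nm jitter, the endpoint estimate
carries the anchor-0 and endpoint noise of a 3-marker mean — about 2.3 nm
RMS in 2D — so single-seed endpoint errors of 3 nm are within its sampling
distribution, not a defect.

**Rendering** accumulates a unit-integral, pixel-integrated Gaussian per
molecule (fixed 10 nm sigma by default, or the per-molecule precision),
scaled by photons or by 1. Rendering is exactly linear in the molecule
set, and the canvas integral equals the summed weights of in-field
molecules to 0.1% (5-sigma truncation of each kernel). Unit weighting is
the default input for correlation analysis: photon weighting makes ICCS
amplitudes bright-molecule-weighted, which biases the fractions.

**Long drift studies** use `generate_smlm_movie(emit = "localizations")`,
which emits the observed localization tables (drift plus emulated
precision noise) without rendering camera frames; movie rendering is
exercised at a few hundred to a few thousand frames where the fitter is
under test. The problem sizes in the suite — 500-cell (one pass) and
2000-cell (classification) populations, a 15000-frame drift study at
table level, 100-seed oracle sweeps at up to 500 points, 10-seed ICCS at
1000 points — were chosen as the smallest sizes at which the statistical
bands above are meaningful.

## Registration

Transforms form the translation ⊂ rigid ⊂ similarity hierarchy, stored in
physical nm and composed in closed form. Landmark fitting is the
closed-form Procrustes solution (SVD rotation, variance-ratio scale): on
noiseless constructions it is exact to numerical precision, and it is
deterministic — no iterative optimiser. Image-to-image translation uses
phase correlation with a Hann window and parabolic sub-pixel refinement.
When the two planes were sampled at different pixel sizes, the coarser is
first resampled (bilinear) onto the finer grid over the physical overlap,
and spatial frequencies beyond the *coarser* sampling's Nyquist limit are
excluded from the correlation: the coarse plane carries no signal there,
and phase correlation — which whitens the spectrum — would otherwise give
those noise-only bands equal weight (on the 65/160 nm phantom pair this
mask is the difference between ~1 px and ~0.1 px errors). Localization
tables are transformed exactly; images by inverse-map bilinear
interpolation with out-of-frame set to 0.

## Colocalization

**ICCS.** Fluctuation correlation surfaces are computed by FFT (circular
boundary — appropriate for statistically homogeneous point fields), each
central peak is fitted with a 2D Gaussian plus offset within an 8 px lag
radius, the auto-correlation zero lag excluded as the shot-noise spike.
Colocalized fractions are the fitted amplitude ratios
`f1 = Gcc(0)/G22(0)` and `f2 = Gcc(0)/G11(0)`, clamped to [0, 1]. For
equal-size channels rendered with a common PSF this estimator's expected
value is the paired fraction; the adopted normalisation is documented here
precisely because fluctuation-correlation estimators differ in their
amplitude conventions.

**Object-based.** Clusters are single-linkage connected components at an
inclusive 50 nm linking distance ("50 nm size" read as linking distance,
with the radius of gyration reported so users can filter by extent
instead); the implementation uses a spatial grid plus graph components and
is tested for exact agreement with a brute-force union-find over the full
distance matrix. Matching between channels is greedy by ascending
centroid distance (ties broken by lowest ids) with mutual exclusivity —
deterministic, and within ±0.05 of truth on 1000-cluster phantoms; optimal
bipartite matching was rejected as an unverifiable complication given the
adjacency radii in use. Adjacency defaults: 50 nm (STORM-scale), 250 nm
(TIRF-scale). Distances are centroid-to-centroid (config-documented
choice). Compartment splits label a cluster on-mask iff its distance to a
confocal-derived mask (registered to the rendering grid, Otsu threshold,
morphological closing) is at most `tolerance_nm` (default 0: centroid
inside).

## Degenerate inputs and tie-breaks

Empty segmentations, empty localization tables, empty gates and empty
cluster sets are all valid values, not errors; errors are reserved for
contract violations (negative photons, missing calibration, unresolvable
gate references, no linkable fiducial). Boolean gates are evaluated
without short-circuiting in dependency order with cycle detection. The
phase-correlation peak uses the first maximum in column-major order when
exactly tied; greedy matching breaks distance ties by lowest cluster id;
watershed tolerance defaults prevent noise-driven splits rather than
resolve genuine ties. Numeric round trips are bounded at 1e-9 relative for
text formats and scaled 32-bit images, exact for 16-bit integer images.

## Known limitations

2D only (no astigmatic 3D localization, no volumetric registration — the
correlative overlay is plane-into-stack placement by user-chosen z-index);
single-emitter fitting only (dense frames lose molecules to the
non-maximum suppression and fit-window contamination); no deformable
registration; the phantom's optics are Gaussian-PSF throughout (no
vectorial PSF, no depth aberrations); ICCS assumes statistical
homogeneity within the analysed region.
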