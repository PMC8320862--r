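---
title: "Enhancement and segmentation of the embryonic vasculature in 3D light-sheet stacks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vascuseg)
```

## The imaging problem

Light-sheet fluorescence microscopy of transgenic endothelial reporter
zebrafish produces large anisotropic stacks (in-plane spacing ~0.334 µm,
axial ~0.69 µm, ~2000² pixels, hundreds of slices) in which vessels are
bright tubes on a dark, artefact-laden background. Two properties make
standard vessel analysis inapplicable:

1. **Cross-vessel profile shape.** Membrane-localised reporters label the
   vessel wall, so a lumenised vessel shows a *double-peak* profile across
   its diameter — two wall maxima and a lumen dip — while small or
   non-lumenised vessels are single-peaked. Threshold- or ridge-based
   methods built for filled vessels split a double-peak vessel into two
   structures.
2. **Anisotropy and artefacts.** Axial sampling is about twice as coarse
   as lateral; stripes (light-sheet shadowing), autofluorescence gradients
   and scattering add structured background.

The package therefore works throughout in *physical* coordinates: every
`image_volume` carries its `voxel_spacing`, filters convert physical scales
to per-axis voxel units, and measurements (profiles, volumes, ROI
geometry) are in µm. Voxel `i` (0-based) has its centre at
`(i + 0.5) * spacing`.

## The phantom generator: what it emulates, and what it does not

Because no public reference stacks exist for this workflow, validation
runs on a synthetic phantom generator (`phantom_scene()`,
`render_scene()`, `render_series()`, catalogued in `standard_scenes()`).
A scene renders in four stages:

1. **Geometry.** Tubes are polyline axes with a diameter, rendered by
   physical distance to the axis, so they are circular in µm and
   elliptical in voxels under anisotropic spacing. *Cytosolic* tubes are
   filled with a soft (Gaussian, sd 0.4 µm) edge; *membrane* tubes are
   radial Gaussian shells centred on the wall radius with sd
   `wall_fraction * radius` (default 0.2, i.e. a ~1 µm wall on a 10 µm
   vessel, a realistic endothelial thickness). The ground-truth mask is
   all voxels within `diameter/2` of the axis.
2. **Optics.** The ideal image is low-pass filtered with a PSF-like
   Gaussian, 0.5 µm lateral and 1.0 µm axial. This reproduces the
   double-peak shape and its diameter dependence without optics
   simulation: a 3 µm membrane vessel retains a >20% lumen dip, while
   ~2 µm vessels fill in — matching the observation that the double peak
   is pronounced only in larger vessels.
3. **Artefacts.** A flat background level, an optional linear intensity
   ramp across the field, and optional multiplicative attenuation bands
   along x (shadow stripes).
4. **Noise.** Poisson shot noise, then Gaussian read noise, then rounding
   and clamping to the declared bit depth. All randomness derives from the
   single scene seed; identical seeds give identical bytes.

Time series render the scene on a canvas padded beyond the field of view
and crop a drifting window from it, so content genuinely slides in at the
edges the way a real acquisition drifts, with fresh noise per frame. A
naive implementation that shifts the field and back-fills with flat
background biases every intensity-based registration estimate and was
deliberately avoided.

The catalogue fixes four study conditions: `membrane10` (a 10 µm
membrane-labelled vessel at the acquisition spacing, read noise set so
the nominal CNR is ~48, the level of the best membrane reporter line),
`bright+dim` (a bright 10 µm vessel and a dim 2.5 µm vessel at 20%
intensity — dim vessels in these reporters are typically newly formed
small-calibre vessels), `bifurcation` (a Y-junction), and `noisy16`
(a 16-bit cytosolic vessel calibrated to CNR ≈ 48).

**What the phantom does not emulate.** Real variability between embryos
(vessel diameters, expression levels, anatomy) is absent: repeated
renderings of one scene differ only in noise realisation. Consequently,
across-seed coefficients of variation of recovered volumes are orders of
magnitude smaller than across-animal CoV in real studies, and passing
robustness checks on phantoms demonstrates *numerical* stability, not
biological reproducibility. Optical effects beyond a fixed Gaussian PSF
(depth-dependent scattering, refraction by the sample) are also out of
scope.

## Quality control: contrast-to-noise ratio

`compute_cnr()` implements
`CNR = (mu_v - mu_nv) / sigma_bg`,
with `mu_v` the mean over a vessel ROI, `mu_nv` the mean over a
non-vascular tissue ROI and `sigma_bg` the standard deviation of a
background region outside the sample. The protocol ROI — the whole
vascular cross-section over a 5 µm axial length — is produced by
`cylinder_roi()` from an axis point, direction and diameter; arbitrary
mask ROIs are accepted so the measure generalises beyond named vessels.
CNR is reported signed (a negative value is a meaningful QC failure), it
is invariant under affine intensity maps `a*I + b` (a > 0), and the
background ROI must contain at least 100 voxels (the count is reported)
because the sd estimate is otherwise too unstable to standardise.

## Motion correction

Embedded embryos drift slowly in the mounting agarose; the damage is
between-frame misalignment, measured as the mean Pearson correlation of
successive frames. `register_series()` corrects each frame against the
previous *corrected* frame (chained, so slow drift accumulates into the
estimate; a fixed-first-frame reference is available). Estimation is
intensity-based rather than feature-based: the acceptance readout is the
correlation itself, and an intensity estimator validated against that
readout is far simpler than a keypoint pipeline. Design choices that
matter, all of which were forced by measurable failure modes:

* **Windowed FFT for the integer peak.** Structure crossing the field
  edge wraps around in circular correlation and drags the peak; a Hann
  window suppresses this.
* **Overlap-normalised refinement.** The FFT covariance peak is biased
  when content slides in and out of the field. The subvoxel stage
  therefore maximises the Pearson correlation over the actual overlap by
  hierarchical direct search (steps 0.5 → 0.1 → 0.02 voxels).
* **Symmetric interpolation.** Scoring a candidate shift by resampling
  only the moving image prefers integer shifts (bilinear interpolation
  blurs fractional shifts). Both images are shifted by half the candidate
  each, after a mild common pre-smoothing, so interpolation blur is equal
  for every candidate.
* **Valid-region bookkeeping.** Resampled frames carry a `valid` mask;
  zero-filled voxels are mean-filled for the FFT stage, excluded from all
  correlations, and never treated as content.

Frames whose estimated shift exceeds `max_shift` (default a fifth of the
field; capped below a quarter) are flagged and left uncorrected rather
than silently clipped. Rotation search is available but off by default:
agarose drift is predominantly translational, and the rotation path is
not validated against any reference data. Registration is idempotent on
phantoms: re-registering a corrected series moves transforms by less than
0.1 voxel. Whether the correlation readout should be computed on whole
frames or masked sub-regions is unspecified in the field; the package
computes whole frames minus invalid fill and records that convention.

## Enhancement

**General Filtering (GF)** is the composition median-then-rolling-ball
with defaults radius 6 voxels (a 13 × 13 disc) and ball radius 200. The
median is computed over the true disc with mirrored edges. The rolling
ball is the *exact* grayscale opening with a non-flat spherical-cap
element — not the common paraboloid/downsampling approximation — because
exactness is testable against a brute-force oracle; the price is O(N·W)
cost, noticeable only at large radii. Both operations are strictly 2D
per slice, so processing a z-slab of interest gives bit-identical results
for those slices.

**Tubular Filtering (TF)** enhances bright tubes from the eigenvalues of
the scale-space Hessian. At Gaussian sd σ (µm, converted per axis to
voxels), second derivatives are taken in physical units and multiplied by
σ² so responses are comparable across scales — without that
normalisation a scale sweep is meaningless. With eigenvalues
`l1 <= l2 <= l3`, the response is `sqrt(l1*l2)` where both are negative
(geometric mean of the two cross-section curvatures; the along-axis
eigenvalue is near zero for a tube), else 0. The sign gate makes the
response zero for dark tubes, and responses below a float-noise floor are
zeroed exactly so constants and ramps give 0.

**Scale semantics.** The user-facing scale `tf_sigma` is the *diameter*
of the vessels to enhance; the derivative kernel uses sd `tf_sigma/2`,
the matched vessel radius. This convention is calibrated to the
observable that drives scale selection: on membrane phantoms of diameter
7, 10 and 13 µm the cross-vessel response profile converts from
double-peak to single-peak at a scale approximately equal to the vessel
diameter (the package's scale sweep reproduces this transition, and the
conversion point is how practitioners choose the working scale). With a
raw-sd convention the conversion would occur at ~0.45 d, which
contradicts how the scale parameter is used and reported in this field.
The default scale is 10.5 µm because most embryonic cranial vessels fall
in the 7–13 µm range: one scale enhances most vessels acceptably while
avoiding the edge blurring of oversized scales (the sweep reports edge
width growing monotonically beyond the conversion point). Raw Gaussian-sd
semantics remain available through `hessian_at_scale()`/`tubeness()`.
Multi-scale response fusion is explicitly out of scope.

The TF response is linearly rescaled to the input bit-depth range and
rounded, because the downstream segmentation methods operate on integer
images.

**Known limitation — accuracy versus precision.** At the matched scale the
response of a vessel is a smooth blob wider than the vessel: on the
isolated 10 µm membrane phantom, TF followed by global Otsu overestimates
the true cylinder volume by roughly 75% (the benchmark in
`scripts/acceptance.R` computes this number). The global threshold lands
on the flank of the response, and no threshold recovers the true wall
position from a single-scale response. The recovered volume is therefore
a *precise, repeatable index* of vascular volume rather than an unbiased
estimate — sufficient for comparisons between groups measured identically,
not for absolute morphometry. GF preserves sharp edges and can land
closer to truth on an isolated clean vessel, at the cost of erasing
thin-walled and small structures.

**Dim vessels.** Both GF and TF are linear in intensity at a vessel axis,
so for equal-diameter vessels the dim/bright response ratio after either
path equals the intensity ratio; neither path can amplify a dim vessel
*relative* to a bright one. For small-calibre dim vessels the comparison
actually favours GF at the axis: a single 10.5 µm scale suppresses a
2.5 µm vessel quadratically in diameter, more strongly than the 13 × 13
median does. What TF does deliver for dim vessels is background
suppression: non-tubular structure and noise map to (near) zero, so a dim
vessel stands clear of the floor after display normalisation. The
benchmark reports the measured axis-response ratios for both paths rather
than asserting a superiority the physics does not support.

## Segmentation

* **Otsu** (`otsu_threshold()`): histogram with 256 bins between the
  observed min and max (the common reference behaviour even for 16-bit
  data; full-resolution binning by argument), threshold at the bin
  boundary maximising between-class variance, ties toward the lower
  boundary, vessel = strictly above. Verified against an exhaustive
  oracle.
* **k-means** (`kmeans_segment()`): Lloyd iterations over the intensity
  histogram, k-means++ initialisation driven by a fixed seed (default 48),
  centre tolerance 1e-4, k = 4 read as one background plus three vessel
  clusters of varying brightness; the vessel mask is the union of the
  three brightest clusters. Operating on the histogram rather than the
  voxel list makes the algorithm exactly deterministic for a given seed
  and fast at any stack size.
* **SRM** (`srm_segment()`): single-voxel regions, 6-connected edges in
  ascending |intensity difference|, merge when
  `(mean_i - mean_j)^2 <= b2(R_i) + b2(R_j)` with
  `b(R) = g sqrt(ln(2/delta)/(2 Q |R|))`, `g = 256`,
  `delta = 1/(6 N^2)`; larger Q merges less (region count non-increasing
  in 1/Q). Input is 8-bit; 16-bit data are rescaled with a warning,
  matching the usual implementation constraint. Q defaults to 25. Since
  no convention exists for turning SRM regions into a vessel mask, the
  region-mean image is binarised by Otsu; a single surviving region is
  reported as degenerate with an empty mask rather than guessed at.

`vascular_volume()` implements `Vol = N_vasc * V_voxel` exactly, counting
only voxels inside the quantification ROI (an input mask, never computed:
anatomical ROI drawing is out of scope). `coefficient_of_variation()`
uses the sample (n−1) standard deviation.

On phantom noise seeds all three methods are numerically very stable
(CoV well below 1%; the acceptance script reports the exact values), with
SRM the most variable — consistent with its rank as the least robust
method on real data. Because phantom seeds vary only the noise, these
CoVs compress real-world differences; they are reported, not interpreted
as biological robustness.

## Numerical choices and degenerate inputs

* Gaussian smoothing is separable with mirrored boundaries; kernels are
  truncated at 4 sd. Second derivatives are central differences with
  edge replication (interior values are what the invariants are tested
  on).
* 3 × 3 symmetric eigenvalues use the closed-form trigonometric solution,
  vectorised across voxels and verified against `eigen()` to 1e-8.
* Profile classification smooths with a 1 µm FWHM Gaussian and counts
  maxima with topographic prominence at least 5% of the smoothed range
  (defaults; both exposed). Zero prominent peaks is `none`, one `single`,
  two `double`; more than two is reported as `none` with a warning.
  Flat profiles (up to float dust) are `none`. The lumen dip depth is
  `(mean(peaks) - dip) / mean(peaks)`; the edge width is the mean 80%→20%
  fall distance on the two outer flanks.
* Otsu on a constant image, CNR with an empty or overlapping ROI, volumes
  with an empty ROI, CoV of fewer than two values or zero mean — all are
  errors with explicit messages, never silent defaults.
* TIFF I/O stores intensities at the declared bit depth; spacing metadata
  is read from embedded resolution tags plus ImageJ-style description
  strings when present, else from the plain-text sidecar written
  alongside, and an explicit override always wins. Masks binarise on
  read (any nonzero voxel is 1).

## Problem sizes used in the test-bed

The shipped tests and the acceptance script run phantoms of
48 × 144 × 144 voxels (≈33 × 48 × 48 µm at the acquisition spacing) for
enhancement and segmentation, 20-frame 96 × 96 series for motion
correction, and 10 noise seeds for robustness summaries. These sizes were
chosen so every geometric regime of interest (vessel diameters 2.5–13 µm,
scales 2.5–24 µm, drifts up to 5 voxels) is represented while a full
validation run completes in minutes; all operations scale to
acquisition-size stacks, with the exact rolling ball at radius 200 the
only step whose cost is worth planning around (about a second per
144 × 144 slice).
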