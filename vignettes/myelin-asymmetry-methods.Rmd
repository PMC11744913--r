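---
title: "Methods: quantifying myelin orientation asymmetry and columnar organisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying myelin orientation asymmetry and columnar organisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`myelotrace`, the assumptions behind them, the tunable parameters and their
defaults, and the design choices made where the underlying methodology left
the design genuinely open. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The measurement problem

Cleared-tissue light-sheet stacks of mouse cortex carry two structural
readouts relevant to hemispheric specialisation: the spatial arrangement of
neuronal somata (microcolumns) and the orientation of myelinated axons
relative to the cortical surface. Both must be extracted from strongly
anisotropic volumes (0.54 × 0.54 × 4 µm voxels), and the orientation data
are *axial* — a fibre at θ and θ + 180° is the same fibre — which shapes
all the statistics downstream.

## Cell annotation with the Gabor spherical-shell kernel

Somata appear as hollow, lens-shaped bright shells. The detection kernel is
a Gaussian envelope of width σ offset by radius r₀ from the origin and
modulated by a radial plane wave (frequency f₀, phase φ), with the kernel's
z axis compressed to mirror the data's Z anisotropy. The real part is
convolved with the soma channel by zero-padded FFT ("same" extent;
`convolve_fft3()` is tested against direct spatial convolution at 1e−8
relative error). Detections are 3D local maxima of the response subject to
a minimum separation and a relative height threshold.

Numerical choices:

* **Support truncation** at r′ = r₀ + 4σ (odd box): the envelope is below
  e^(−16π) outside. The printed amplitude prefactor 1/(2πσr₀) is constant
  and kept as written; detection uses relative maxima, so it cannot change
  results.
* **Mean subtraction.** The volume mean is subtracted before convolution,
  making the response a pure local-contrast signal; a background-only
  volume yields exactly zero response and no detections.
* **Phase and matched radius.** The kernel's phase shifts the radius of its
  positive crest away from r₀: a bright shell correlates maximally at the
  radius returned by `kernel_matched_radius_px()`, not at r₀ itself (for
  the published parameter set r₀ = 22 px, σ = 12, f₀ = 0.1, φ = 3.7 the
  matched radius is ≈ 25.7 px). The synthetic soma generator renders shells
  at that matched radius, on a grid whose anisotropy equals the kernel's
  compression factor, so that local-maxima detection is well posed.
* **Defaults the source left open:** minimum separation = r₀ in XY-pixel
  units (configurable; duplicate suppression across z planes may warrant
  ~half the known soma spacing), relative threshold 0.3, scoring match
  radius 5 µm (about a soma radius). Maxima within half a kernel width of
  the border are flagged, not dropped.

Detection accuracy is scored by greedy one-to-one nearest matching:
accuracy % = matched/truth, false positives as a share of detections,
false negatives as a share of truth.

## Neighbourhood statistics

For each reference cell at least d = 54 µm from every volume edge, a cube
of edge d with 1 µm isotropic bins (choice: the source does not state the
bin geometry) counts the surrounding centres; p = counts/d³ is the local
density field. Fields are averaged over the stride-5 subset of cells. The
reference cell is excluded from its own field (including it would only add
a delta at the origin). Radial distance distributions up to d/2 = 27 µm are
normalised by the number of *imaging-grid voxels* whose centre falls in
each radial shell — an anisotropy-aware normalisation under which a uniform
point field on that grid is flat, so microcolumn structure appears as
peaks (~6 and ~12 µm for 6 µm intra-column spacing). The depth axis of the
field is the image y axis (pia up).

## Orientation quantification

Per plane, the myelin channel is median-filtered, ridge-enhanced and
min–max normalised. The ridge filter is a multiscale Hessian tubeness
operator (scale-normalised negative minimum eigenvalue, maximum over
σ ∈ {1, 2} px) written in-package; it enhances bright curvilinear
structures the way Sato-style filters do.

Windows of 24 × 24 px tile the plane without overlap. Storing one record
per window (rather than per pixel) keeps records approximately independent
for the regression; the alternative reading — one value per pixel from a
sliding window — would only duplicate records ~576-fold without adding
information. Per window,

* φ = ½·atan2(2J₁₂, J₂₂ − J₁₁), implemented in the two-argument form to
  resolve the quadrant ambiguity of the half-angle arctangent, and reported
  as the *ridge* direction (gradient direction + 90°) so that fibres along
  the depth axis read 90°;
* E = trace(J), zero for homogeneous windows;
* C = (λmax − λmin)/(λmax + λmin) ∈ [0, 1], defined as 0 when E = 0.

Gradients are central differences with replicated borders; no pre-window
Gaussian weighting (plain window averaging). The analysis is strictly
in-plane: at 4 µm plane spacing a 3D tensor would mix scales.

**Gating.** Records with E·C below a threshold are rejected. The threshold
was "predefined" but unpublished; the package default is the 60th
percentile of E·C — taken over *in-cortex* windows (after surface fitting
and layer assignment), because background windows above the pial surface
would otherwise dilute the quantile and let sparse, incoherent windows
through. An absolute override is available.

**Surface correction and layers.** The autofluorescence plane is Otsu-
thresholded; the tissue boundary is extracted per column with subpixel
interpolation of the threshold crossing and fitted with a quadratic
row = a·x² + b·x + c. The package computes the distance field to the
*fitted continuous curve* (vectorised Newton projection) and applies the
gradient filter to that field; a binarised discrete transform would
quantise the shallow curvatures typical at this field of view into
staircase artefacts several degrees large. The gradient direction is the
local surface normal — equivalently, the direction to the nearest surface
point — and the tangent is its 90° rotation. Corrected angles are
(φ − tangent) mod 180. Layers are assigned from the window centre's depth
below the surface; a depth exactly on a boundary goes to the deeper layer;
windows above the surface or beyond the L5 boundary (layer 6, unusable in
the source assay due to poor antibody penetration) are dropped with
counts. Layer boundaries are configuration; the defaults, as fractions of
cortical depth, are L1 0–0.10, L2/3 0.10–0.35, L4 0.35–0.50, L5 0.50–0.75,
L6 0.75–1 (mouse-cortex-plausible values; expert annotations in the source
are not numeric).

## Projected-normal circular regression

Axial angles are doubled onto the full circle (the standard embedding;
without it, moments of 0–180° data are ill-defined), fitted there, and
halved back everywhere a result is reported. The observed direction is
modelled as θᵢ = atan2(yᵢ₂, yᵢ₁) with latent yᵢ ~ N₂(B·xᵢ, I). Identity
latent covariance is the standard identifiability constraint; coefficients
get diffuse N(0, 10⁴) priors.

**Design parameterisation.** The design is cell-means: one latent mean
vector per covariate cell — the two hemispheres for model 1, the
hemisphere × layer crossing for model 2. The crossing (rather than an
additive side + layer structure) was chosen because the quantities of
interest are per-layer left/right differences, which are not additive
across layers; the cell-means model nests the additive one and reads those
contrasts off directly.

**Sampler.** A Gibbs sampler alternates (i) the latent vector lengths
rᵢ from their full conditional ∝ r·exp(−(r − tᵢ)²/2), r > 0 — sampled
*exactly* by slice sampling: a uniform slice height bounds an interval on
which the density is linear in r, inverted in closed form — and (ii) the
cell mean vectors from conjugate normal updates (with indicator designs
the posterior precision is diagonal, so no linear algebra is needed). The
core loop is Rcpp using R's RNG, so `set.seed()` fixes runs. Defaults:
2 chains × 5,000 iterations, 1,000 burn-in, no thinning. Effective sample
sizes use an initial-positive-sequence estimator; cells below ESS 100
trigger a warning.

**Summaries.** Per cell: circular posterior mean direction, circular
posterior sd, and the 95% highest-posterior-density interval — computed as
the shortest arc over sorted draws on the doubled circle, wrapped safely.
Two effects are called distinct when their 95% HPD intervals do not
overlap (`hpd_overlap()`). For group contrasts the posterior means are
differenced on the axial scale. Posterior sd and across-bootstrap sd are
distinct quantities; both are reported and labelled, since a "mean ± sd"
convention alone does not disambiguate them.

**Model comparison.** DIC = D̄ + p_D with p_D = D̄ − D(posterior mean)
(Spiegelhalter's form — the convention of the reference implementations of
this model family). The projected-normal log-density uses a numerically
stable large-t branch for the angular integral term.

**Bootstrap.** Where the full data exceed what one fit should carry, the
stratified bootstrap draws equal-size subsamples per design cell (default
5,000; 25 repetitions), refits, and aggregates posterior means with their
across-repetition circular sd. Each subsample is compared with its full
stratum by a two-sample Kuiper test (rotation-invariant; α = 0.01),
operationalising the requirement that subsamples recover the full
distribution.

## The synthetic-data generators

The generators define the simulated study conditions:

* `gen_cell_volume()` — microcolumns along the depth axis: 6 µm
  intra-column spacing, 20 µm column pitch, 0.5 µm positional jitter,
  somata as hollow shells (default radius 3.2 µm, rim 1.3 µm) or solid
  blobs, Poisson shot noise plus Gaussian read noise at snr 10. The
  soma radius default is a realistic mouse soma matched to a
  correspondingly scaled detection kernel; shells matched to the
  published full-scale kernel parameters are exercised explicitly in the
  acceptance tests.
* `gen_fibre_volume()` — per-layer fibre segments whose angle *relative to
  the local surface tangent* is sampled from a wrapped normal; L1 defaults
  to 0° (parallel to the surface), L2/3–L5 to 90° (radial). All angles are
  drawn before any placement, so the exported truth angles depend only on
  (design, seed) and are identical between flat and curved surfaces.
  Fibres are placed at their depth *along the surface normal*, making the
  generator's layer geometry exactly the analysis's distance-to-surface.
  Per-layer angular dispersions are free parameters (the source constrains
  only the spread of *means*); 5° is the default, a realistic value for
  dominant-direction spread within a layer.
* `gen_af_surface()` — a smooth intensity step across the quadratic
  surface, identical in every plane.
* `gen_orientation_samples()` — direct projected-normal sampling per
  stratum with mean direction 2μ and concentration κ (axial circular sd
  ≈ 1/(2κ) radians for large κ); κ = 10 is used in the recovery
  simulations ("small dispersion").

What the generators deliberately do **not** emulate: light-sheet PSF,
stripe artefacts, depth-dependent attenuation, staining chemistry, fibre
crossings or curvature within a segment. Passing tests therefore
demonstrate correctness of the measurement and inference chain under the
stated geometric and noise assumptions, not robustness to every optical
artefact of real acquisitions.

## Simulated cohorts and problem sizes

`run_cohort()` chains the stages for a cohort mirroring the study design
(defaults scaled to 2 + 2 animals, two hemispheres each; the full study
used 6 female and 5 male). A run is a pure function of (config, seed); the
master seed fans out into per-sample, per-stage sub-seeds drawn once up
front. Desk-scale volume defaults are 400 × 160 × 2 voxel hemispheres —
chosen so that each cortical layer is thicker than one 24 px analysis
window (with shallower stacks, L1 becomes thinner than a window and its
horizontal fibres contaminate L2/3 windows). Surface curvature is drawn so
the radius of curvature stays above 2.5× the frame depth, as for real
cortex at this field of view; tighter curvatures put deep tissue beyond
the curve's evolute, where "nearest surface point" (and hence the tangent
correction) is ill-defined. Test and acceptance simulations use 10⁴
observations per design cell for the regression recoveries, 5 seeds each,
and cohorts of 3 animals for the image-level recovery; these sizes hold
every recovery check comfortably inside its stated tolerance.

The package's functions, the test-suite and `scripts/acceptance.R` are the
interface; no shell wrapper is shipped, since every documented workflow is
a handful of R calls.

## Known limitations

* Orientation is measured per window, weighting thick fibres more than
  thin ones; segment-level statistics would need single-fibre
  segmentation, which the source resolution rules out.
* The quadratic surface model cannot follow strongly folded cortex; it is
  adequate for the near-planar patches this pipeline targets.
* No hierarchical (per-animal random-effect) model: per-sample fits and
  pooled fits are both supported, matching the source analysis, but
  between-animal variance is not partitioned.
* The tonotopic axis is deliberately not a covariate.
* DIC magnitudes depend on the data scale; only comparisons between models
  fitted to the same records are meaningful.
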