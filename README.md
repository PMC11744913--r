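# myelotrace

Quantifying hemispheric asymmetry of intracortical myelin orientation and
columnar neuronal organisation in 3D cleared-tissue light-sheet volumes of
mouse cortex.

Left and right auditory cortex (AC) differ functionally, but the
microstructure behind that lateralisation is hard to measure. `myelotrace`
implements a complete quantitative pipeline for two complementary readouts
from multi-channel light-sheet stacks (somata, myelin, autofluorescence;
voxels 0.54 × 0.54 × 4 µm XYZ):

1. **Columnar cell organisation.** Somata are annotated by FFT convolution
   with a complex 3D *Gabor spherical-shell* kernel

   K(x,y,z) = 1/(2πσr₀) · e^(−π((r′−r₀)/σ)²) · e^(i(2πf₀(r′−r₀)+φ)),

   where r′ is the radial distance with z scaled by a compression factor
   matching the Z anisotropy, followed by 3D local-maxima marking. Around
   the detected centres the package computes local density fields
   (pᵢ = cᵢ/d³ on a d = 54 µm grid, stride-5 reference subset, edge
   exclusion), averaged neighbourhoods, volume-normalised radial distance
   distributions, and paired left/right densities. Microcolumns appear as
   radial-profile peaks at ~6 and ~12 µm.

2. **Myelin fibre orientation.** Per image plane, the myelin channel is
   median- and ridge-filtered, then tiled into 24 × 24 px windows. The
   structure tensor J of each window yields the dominant orientation
   φ = ½·atan2(2J₁₂, J₂₂−J₁₁), energy E = trace(J) and coherence
   C = (λmax−λmin)/(λmax+λmin); records are gated on E·C. The cortical
   surface is fitted with a quadratic on the autofluorescence channel; a
   gradient filter over the distance field to the fitted surface gives the
   local tangent, so orientations become tangent-relative (90° = radial)
   and each window gets a cortical layer (L1, L2/3, L4, L5; L6 excluded).

   The resulting axial angles θ ∈ [0°, 180°) are modelled with Bayesian
   **projected-normal circular GLMs**: θ is the direction of a latent
   bivariate normal vector whose mean depends on hemisphere (model 1) or
   hemisphere × layer (model 2). A Gibbs sampler (Rcpp) with slice-sampled
   latent lengths produces circular posterior means, 95% HPD intervals,
   DIC for model comparison, and a stratified 25× bootstrap for large data.

A synthetic-data module generates microcolumnar soma volumes, layered
fibre volumes under a curved cortical surface, autofluorescence surfaces,
and direct projected-normal samples — all with exported ground truth — so
every stage is testable without microscopy data.

## Worked example

```r
library(myelotrace)

# simulate a two-group orientation dataset at a 0.7-degree asymmetry
design <- pn_group_design(data.frame(side = c("L", "R"),
                                     mu_deg = c(90.9, 90.2),
                                     kappa = 10, n = 10000), seed = 7)
dat <- gen_orientation_samples(design)
fit <- fit_pn_glm(dat, "side", seed = 11, track_loglik = FALSE)
fit
#> Projected-normal circular GLM (side), 20000 observations
#>  cell mean_deg sd_deg hpd_lower hpd_upper     ess n_obs
#>     L    90.88   0.03     90.82     90.93 7740.86 10000
#>     R    90.20   0.03     90.15     90.26 7434.78 10000
posterior_mean_diff(fit, "L", "R")
#> [1] 0.6744604
```

The posterior mean directions recover the injected group means (90.9° and
90.2°), their 95% HPD intervals do not overlap, and the left-minus-right
contrast reproduces the injected 0.7° asymmetry within sampling error.

An end-to-end simulated cohort (render → detect/orient → regress):

```r
rep <- run_cohort(run_config(n_female = 2, n_male = 1, seed = 44))
rep$fit_side_layer$summary      # per side x layer circular posterior means
dic(rep$fit_side)               # side-only model
dic(rep$fit_side_layer)         # side x layer model (lower = better)
```

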