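---
title: "Quantifying fibrosis in phase-contrast microCT: models and methods"
author: "fibroCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrosis in phase-contrast microCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroCT)
```

## The problem

Fibrotic remodelling of soft tissue — the hallmark of uterine leiomyoma, where
excess extracellular matrix stiffens the myometrium — is a three-dimensional
phenomenon, but routine histology only sees it in 2D sections. Propagation-based
phase-contrast micro computed tomography (PhC-microCT) images unstained soft
tissue in 3D: contrast comes from the refractive-index decrement $\delta$ of
$n = 1 - \delta + i\beta$, which for non-mineralized tissue is orders of
magnitude larger than the absorption index $\beta$. Collagen
(≈1.41 g/cm³) and smooth muscle (≈1.06–1.11 g/cm³) differ only slightly in
mass density, so the $\delta$-proportional grey levels of a phase-retrieved
reconstruction are the workable contrast channel.

fibroCT implements the complete quantitative chain for such volumes:

1. **Reconstruction** — flat/dark correction, single-distance Paganin phase
   retrieval, parallel-beam filtered back-projection (FBP).
2. **Segmentation** — two-Gaussian mixture modelling of the grey histogram;
   the threshold is the intersection of the two fitted Gaussians.
3. **Morphometry** — the seven trabecular-style indices of the collagen
   network: CollV/TV, CollS/CollV, Th, Nr, Sp, DA, Conn.D.
4. **Relative mass-density distribution (MDDr)** — Roschger-style histogram
   descriptors (peak, mean, fwhm, low, high) against a pooled control
   reference range.
5. **Reporting** — per-subvolume tables, group mean ± SD and quartiles.

Because no public biopsy scans exist for this application, the package ships a
synthetic phantom generator with exact ground truth; every stage is validated
against closed-form oracles or the generator's known truth.

## Reconstruction model

### Paganin single-distance phase retrieval

Under the homogeneous-object assumption (fixed $\delta/\beta$), a
flat-corrected projection at propagation distance $D$ relates to the projected
thickness $T$ through a single low-pass filter:

$$T = -\frac{1}{\mu}\,\ln\!\left(\mathcal{F}^{-1}\!\left[
\frac{\mathcal{F}[I/I_0]}{1 + \frac{D\delta}{\mu}\,|k|^2}\right]\right),
\qquad \mu = \frac{4\pi\beta}{\lambda}.$$

The filter coefficient needs only the ratio:
$D\delta/\mu = (\delta/\beta)\, D \lambda/(4\pi)$. Shipped defaults follow the
synchrotron soft-tissue protocol the package targets: 19 keV
($\lambda \approx 0.0653$ nm), $D = 100$ mm, 1 µm detector pixels,
$\delta/\beta = 100$. At these values the filter's real-space scale is
$\sqrt{(\delta/\beta) D\lambda/4\pi} \approx 7$ µm.

$\mu$ defaults to unset: retrieved maps (and everything downstream) are then
in thickness-proportional *arbitrary units*. This is deliberate — a constant
$\delta/\beta$ biases absolute values, so the pipeline works with relative
quantities throughout; all cross-sample comparisons are made on a shared
8-bit rescale (below).

### The forward model and why retrieval round-trips exactly

The phantom generator's `forward_project()` uses the linearized
single-material transfer function — multiplication by
$1 + (D\delta/\mu)|k|^2$ applied to the contact image $C = e^{-\mu T}$ —
which is the exact algebraic inverse of the Paganin filter on the same FFT
grid. This makes the retrieval stage *verifiable*: a noiseless forward
projection followed by retrieval reproduces the input thickness map to
machine precision. Full Fresnel wave propagation is intentionally out of
scope; the linearized model is the regime in which Paganin retrieval is exact,
so the round trip tests the implementation rather than the model error.

Two padding conventions are provided. The forward model is defined on the
periodic (unpadded) FFT grid, and `paganin_retrieve(..., pad = "none")` is its
exact inverse. For measured (non-periodic) data, retrieval defaults to
symmetric mirror padding to the next power of two of at least twice the image
extent, which suppresses wrap-around at the cost of exact invertibility.

### Filtered back-projection

Slice-by-slice parallel-beam FBP: projections are zero-padded to ≥2× the
detector width, filtered with the band-limited Ram–Lak kernel (the discrete
spatial-domain form, which handles the DC term correctly), and
back-projected with linear interpolation. No apodization is applied by
default ("FBP" plain); a cosine window is available. A manual
centre-of-rotation offset is exposed but defaults to zero since simulated
data are centred. On a 256² grid with 360 angles the reconstruction of an
analytic disk sinogram recovers the interior value to well under 2% (see
`test-acceptance.R`).

## Segmentation: two-Gaussian mixture thresholding

The grey histogram of an 8-bit volume is modelled as a two-component Gaussian
mixture: the left component is smooth muscle, the right is collagen. The fit
follows the classic histogram-partition algorithm rather than EM: for every
candidate split $s \in [1, 254]$ the two sub-histograms are summarized by
moment-matched Gaussians, the implied mixture is scored by summed squared
error against the empirical frequencies, and the best split wins. (EM is
available behind `method = "em"` as a comparison route; it is never used as
the default because the partition algorithm is the behaviour the pipeline is
designed to mirror.) The threshold is the analytic intersection of the two
weighted Gaussians — the quadratic root between the means, linear closed form
when the standard deviations tie, and an error-minimizing grid fallback (with
a warning) when extreme weight imbalance leaves no crossing between the means.

Conventions chosen for bit-reproducibility:

* thresholds are rounded to integer grey levels after averaging;
* voxels *equal* to the threshold go to muscle (collagen is strictly `> t`);
* per-volume thresholds are the arithmetic mean of fits on 12 axial slices
  uniformly spaced in z ("a dozen slices"), skipping slices whose fit fails;
* control samples never contribute to threshold estimation — their collagen
  content is too low for a reliable two-component fit — so the threshold
  estimated on fibrotic samples (or phantoms) is applied batch-wide;
* bright (blood-clot-like) voxels are not excluded before fitting; a config
  flag allows capping the top 0.1% for sensitivity analysis.

A unimodality check warns when the empirical histogram shows no dip at the
threshold (the two-Gaussian model is then unreliable).

Thresholded masks of noisy volumes carry salt-and-pepper misclassifications:
isolated foreground specks in muscle and background pinholes inside bundles.
A single interior pinhole collapses the distance-transform thickness around
it, so the pipeline purifies masks before morphometry (`clean_mask()`):
foreground components and enclosed background components smaller than 27
voxels (a 3×3×3 neighbourhood) are removed/filled; background connected to
the ROI border is never filled.

### Cross-sample comparability

One threshold can only be applied across independently reconstructed samples
if their grey scales are commensurable. `rescale_to_grey8()` maps the window
between the 0.01 and 99.99 percentiles linearly onto [0, 255] and returns the
mapping so an entire batch can be rescaled with a *single shared* mapping.
Percentile (rather than min–max) clipping keeps rare hyperdense voxels —
residual blood-clot spots occur in real biopsies — from compressing the
tissue range. How the original study made its scans commensurable is not
documented; the shared-mapping batch rescale is this package's explicit
substitute and is flagged as such.

## Morphometry

All indices operate on a binary collagen mask, per subvolume (default
600 × 600 × 400 µm³, tiled from the volume origin; partial edge tiles are
discarded so every analyzed subvolume lies fully inside the sample), and are
aggregated as mean ± sample SD.

* **CollV/TV** — foreground voxel fraction, in percent.
* **CollS/CollV** — isosurface area per foreground volume (mm⁻¹). The
  surface is a marching-tetrahedra triangulation of the 0.5 level of the
  binary field after one pass of a separable [1,2,1]/4 smoothing kernel; the
  sub-voxel vertex interpolation removes most of the staircase bias that
  makes voxel-face counting overestimate smooth surfaces by ~50%, and a
  digitized sphere of radius 25 voxels reproduces $3/r$ to about 1%. The
  denominator volume is the integral of the trilinear interpolant of the
  mask over the same cell grid, so boundary-spanning structures (whose
  boundary-touching faces are deliberately left open) keep a consistent
  ratio. Foreground touching the ROI boundary sets a `truncated` flag.
* **Th** — Hildebrand–Rüegsegger model-free thickness: distance transform →
  distance ridge → sphere painting; the value at a voxel is the diameter of
  the largest inscribed sphere containing it, measured to the structure
  surface (half a voxel beyond the outermost foreground centre). Painting
  prunes spheres whose centre is already covered with a diameter ≥ 6 voxels
  larger (`paint_margin`); this caps the cost in wide open regions at the
  price of a small negative bias there (about −4% on the sparsest phantom's
  spacing at the default margin, none on slabs/cylinders/spheres);
  `paint_margin = Inf` paints exactly.
* **Sp** — Th of the complement within the ROI.
* **Nr** — rod-model structure count `1000/(Th + Sp)` per mm. The original
  tool names no formula; the rod model is adopted as the documented
  convention (consistent with the fibrotic-tissue values it is compared to),
  with the plate model `(CollV/TV)/Th` available via `model = "plate"`.
* **DA** — mean-intercept-length anisotropy: 60 quasi-uniform directions
  (Fibonacci hemisphere), 100 random parallel lines each, nearest-neighbour
  sampling at 0.5-voxel steps; `MIL(ω)` = intercepted length / intercept
  count; the fabric tensor is fit by least squares on `1/MIL²` and DA is its
  eigenvalue ratio `λ_min/λ_max`. The default ("paper") convention reports
  1 = perfect isotropy, 0 = all structure on a single axis/plane; this is
  the *opposite* of the common bone-software convention, which is available
  as `convention = "complement"`. Directions without crossings are dropped;
  fewer than 9 usable directions is an error.
* **Conn.D** — the mask is purged to its largest 26-connected component and
  enclosed cavities are filled, after which the Euler characteristic of the
  cubical complex (`χ = V − E + F − C`, additive cell counting) gives the
  loop count `β₁ = 1 − χ`; Conn.D = β₁ per ROI voxel (pixel⁻³). Whether the
  original analysis purged before counting is undocumented; purging is this
  package's default and `purge = FALSE` keeps all components
  (`β₁ = β₀ − χ`), which makes Conn.D intensive under structure duplication.
  A second, independent Euler route (inclusion–exclusion over voxel-cube
  subsets, reduced to a 256-entry window table) is exposed for
  cross-validation and agrees exactly with the additive count on
  exhaustively enumerated and random volumes.

Structures touching subvolume faces are included as-is — no edge correction.
This biases Sp downward when spacing approaches the subvolume size.

## Relative mass-density distribution (MDDr)

Grey levels of the phase-retrieved reconstruction are proportional to mass
density up to the unknown $\delta/\beta$ bias, so only *relative* density
descriptors are meaningful. The MDDr is the grey histogram of the overall
tissue domain (not collagen only), normalized to unit area. Five descriptors
are extracted:

* **peak** — argmax of the smoothed profile (cubic smoothing spline on the
  normalized histogram, evaluated on a 10× finer grid, negatives clipped and
  re-normalized; smoothness chosen by generalized cross-validation unless a
  `spar` value is given; `smoothing = 0` interpolates);
* **mean** — trapezoidal $\int x f(x)\,dx$ of the *raw* normalized
  histogram;
* **fwhm** — distance between the outermost half-maximum crossings of the
  smoothed profile (multimodal profiles use the outermost crossings and are
  flagged);
* **low / high** — percent of the sample's distribution below/above the
  reference-range cuts, with linear interpolation inside the cut bin.

The reference range pools the control group's profiles (average of
normalized frequencies) and places cuts at the $P$ and $1-P$ quantiles,
$P = 0.005$ by default — i.e. the 0.5th/99.5th percentiles. The percentile
level is a config knob (`mdd_reference_P`). The reference population is the
study's own control group; that, too, is a convention of this package since
no external reference exists for this tissue. Quantiles and tail areas use
the same piecewise-uniform-within-bin distribution function, so a profile
scored against its own reference yields low = high = 100·P exactly, a
property the tests assert.

Peak and fwhm are measured on the smoothed profile, the mean on the raw
histogram — the usual practice for bone-mineralization histograms, applied
here unchanged; all three sources are fixed, not configurable.

## The synthetic phantom generator

`generate_fiber_phantom()` emulates the two-phase tissue: a smooth-muscle
background and collagen bundles built as a union of straight capsules with
von Mises–Fisher distributed directions (κ = 0 isotropic), Gaussian radii,
and centre lines spanning the volume. Capsules are added until the realized
volume fraction is within 0.01 of the target (capsule length shrinks
adaptively near the target so the band cannot be overshot); the realized
fraction in the ground truth is *defined by counting*, so it is exact. Grey
levels are class-conditionally Gaussian (defaults: muscle 90 ± 12, collagen
140 ± 14 on the 8-bit scale), clipped to [0, 255]; saturated spherical
bright spots are added at a default rate of 50/mm³ (radius 3 ± 1 µm) and
recorded separately in the ground truth; optional additive noise defaults
off.

Straight capsules were chosen over curved bundles deliberately: curvature
affects none of the implemented indices' oracles, and straight capsules
admit exact projected-thickness reasoning. Class-conditional Gaussians match
the segmentation model's assumption; heavier-tailed options exist for
robustness experiments but default off.

**What passing tests do and do not show.** The phantoms share the
segmentation model's assumptions (two Gaussian classes) and have piecewise-
constant density inside each phase. Real tissue has texture below the
resolution limit, partial-volume mixing at interfaces, reconstruction
artefacts and spatially varying illumination; none of these are emulated.
Passing the synthetic suite therefore validates the *computations*, not the
biological interpretation of any particular scan.

### Study conditions for the two-group cohort

`simulate_cohort()` fixes the synthetic study design: per seed, four
control samples (Ctr: 5% collagen, bundle radius 6 ± 1.5 µm) and four
fibrotic samples (L: 40%, 15 ± 3 µm), each a 300 × 300 × 200 µm phantom at
2.5 µm voxels — one subvolume-scale specimen per sample, sized so a full
cohort analysis (segmentation at the slice-averaged threshold, all seven
indices, MDDr against the pooled Ctr reference) runs on a single CPU in
about half a minute per seed. The expected directional findings — CollV/TV,
Th, Nr, MDDr fwhm and high all higher in L; Sp and CollS/CollV lower in L —
are asserted across five seeds in the acceptance tests.

## Numerical choices and degenerate inputs

* FFT padding: mirror reflection to the next power of two ≥ 2× extent
  (retrieval); zero padding (FBP filtering). Padding, windowing and
  interpolation are places where reconstruction software differs silently —
  the choices here are documented defaults, not reproductions of any
  specific tool.
* Histograms are exact integer counts; bin i is grey value i.
* Constant volumes: grey8 rescale errors out (degenerate range); MDD flags
  a degenerate single-bin profile and refuses to smooth it.
* Empty masks: surface area 0; thickness errors; spacing of an all-empty
  mask returns the ROI's smallest extent (the largest inscribable gap).
* Mixture fit requires mass in ≥ 3 distinct bins and at least 2 voxels and
  positive variance on each side of a candidate split.
* All randomized steps (phantoms, MIL line offsets, cohort) take explicit
  integer seeds; a fixed seed makes the whole pipeline byte-reproducible,
  which the tests assert on the CSV outputs.

## Known limitations

* Absolute mass density is out of scope by construction — only relative
  comparisons on a shared grey mapping are supported.
* The forward model is linearized (no Fresnel fringes beyond the Laplacian
  term, no partial coherence, no ring artefacts); reconstruction robustness
  to such effects is untested.
* Sub-voxel texture analysis is explicitly not implemented (it requires
  roughly 2× finer sampling than the tissue imaging this targets).
* DA's line-sampling estimator has Monte-Carlo noise; with the default 60
  directions × 100 lines it is deterministic given a seed but not
  grid-converged for very sparse masks.
* Th/Sp standard deviations can be reported per-voxel or across subvolumes;
  both are produced because the convention in published tables is ambiguous.
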