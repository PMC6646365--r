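# fibroCT

Quantitative 3D analysis of fibrotic soft tissue in propagation-based
phase-contrast micro computed tomography (PhC-microCT), for researchers who
need numbers — not just renderings — out of reconstructed tissue volumes:
how much collagen a sample contains, how thick, how densely packed, how
oriented and how interconnected its bundles are, and how its relative mass
density is distributed compared to healthy controls. The motivating
application is uterine leiomyoma (fibroid) versus adjacent myometrium, where
fibrosis shows up as excess, stiff extracellular matrix.

## What it computes

**Reconstruction.** Flat/dark correction; single-distance Paganin phase
retrieval under the homogeneous-object assumption,

    T = -(1/mu) ln( F^-1[ F(I/I0) / (1 + (D*delta/mu) |k|^2) ] ),
    mu = 4*pi*beta/lambda,

with shipped defaults 19 keV, D = 100 mm, 1 um pixels, delta/beta = 100; and
slice-by-slice parallel-beam filtered back-projection (Ram-Lak filter,
linear-interpolation back-projection).

**Segmentation.** The grey histogram (8-bit scale) is modelled as two
Gaussians — muscle left, collagen right — fitted by exhaustive split search
with moment matching; the threshold is the analytic intersection of the two
weighted Gaussians, averaged over a dozen axial slices.

**Collagen morphometry** on the binary mask, per subvolume (default
600 x 600 x 400 um^3) with mean +/- SD aggregation:

| index | meaning | units |
|---|---|---|
| CollV/TV | collagen volume fraction | % |
| CollS/CollV | specific surface (marching-tetrahedra isosurface) | mm^-1 |
| Th | mean bundle thickness (maximal inscribed spheres) | um |
| Nr | bundle number, rod model 1000/(Th+Sp) | mm^-1 |
| Sp | mean bundle spacing (thickness of the gap phase) | um |
| DA | mean-intercept-length anisotropy (1 = isotropy) | – |
| Conn.D | connectivity density, beta1 per ROI voxel | voxel^-3 |

**Relative mass-density distribution (MDDr).** The unit-area grey histogram
of the whole tissue domain, summarized Roschger-style by `peak`, `mean`,
`fwhm`, and the tail areas `low`/`high` outside a reference range pooled
from the control group (P = 0.005, i.e. 0.5th/99.5th percentiles).

**Synthetic phantoms.** Ground-truth-known two-phase fiber phantoms (capsule
unions with von Mises-Fisher orientations, class-conditional Gaussian greys,
saturated blood-clot-like spots) plus a physically consistent forward
projection model whose Paganin retrieval round-trips exactly — every stage
is testable without any scan data.

## Worked example

```r
library(fibroCT)

# a fibrotic-tissue phantom: 300 x 300 x 200 um at 2.5 um voxels,
# 40% collagen in 15 um bundles
spec <- phantom_spec(shape_um = c(300, 300, 200), voxel_size_um = 2.5,
                     target_coll_fraction = 0.40,
                     bundle_radius_um = c(15, 3), seed = 42)
ph <- generate_fiber_phantom(spec)
ph$truth
#> <phantom_ground_truth> collagen fraction 0.3992, 52 bundles, mean radius 14.8 um

t <- slice_averaged_threshold(ph$volume, 12)   # mixture fit on 12 slices
t
#> [1] 116
mask <- clean_mask(apply_threshold(ph$volume, t))
compute_morphometry(mask)
#> <morphometry_result>
#>   CollS/CollV:     95.7 mm^-1
#>   CollV/TV:       39.67 %
#>   Th:             28.68 um (+/- 7.03)
#>   Nr:             13.36 mm^-1
#>   Sp:             46.19 um (+/- 24.81)
#>   DA:             0.805
#>   Conn.D:      0.000257 voxel^-3

prof <- smooth_profile(compute_mdd(ph$volume))
ref  <- compute_reference_range(list(prof), P = 0.005)
extract_mdd_parameters(prof, ref)
#> <mdd_parameters> peak 90.08, mean 109.96, fwhm 71.48, low 0.500%, high 0.500% [multimodal]
```

Reading: the segmented mask recovers the generated 40% fraction
(CollV/TV 39.7%) and the 30 um bundle diameter (Th 28.7 um vs. 2 x 14.8 um
generated); specific surface is close to the thin-rod value 2/r = 135 mm^-1
reduced by bundle overlap; DA near 0.8 reflects the isotropic orientation
distribution. The MDDr profile of this two-phase sample peaks at the muscle
grey (90), its mean sits between the phases, and scored against its own
reference range it leaves exactly 0.5% in each tail.

A full pipeline run (phantom or TIFF stack in, CSV reports out):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "fibroCT"),
             seed = 1, out_dir = "demo_out")
```

or from the shell, via the thin CLI:

```sh
Rscript inst/cli/fibroct.R pipeline --config inst/extdata/demo_config.yaml --seed 1 --out demo_out
```

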