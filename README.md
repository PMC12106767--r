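# hepavasc

Quantitative 3D analysis of the liver micro-vasculature in X-ray
phase-contrast CT volumes.

Liver lobules perfuse through sinusoids — a dense bed of ~3 µm capillaries
draining into central veins — and metastatic colorectal-cancer nodules
remodel that bed: vessel density collapses in the distal parenchyma while a
dense vascular band forms immediately around each nodule. Propagation-based
phase-contrast CT of paraffin-embedded liver resolves sinusoids without
staining; `hepavasc` turns such volumes into numbers:

- **Vessel segmentation** — multiscale Hessian (Frangi) vesselness for the
  sinusoids (scales 1–10, α = β = 0.5, c = 0.013, threshold V > 0.16),
  intensity thresholding for large vessels, voxelwise merge, and an
  inscribed-sphere local-thickness split at a 15 µm diameter.
- **Vascular volume fraction (VVF)** — vessel voxels over tissue voxels
  (vessels above 10 µm excluded), on random 5·10⁻³ mm³ ROIs, on a sliding
  50-voxel cube (a spatial VVF map), and in radial shells around a nodule
  boundary plotted against the best-fit ellipsoid semi-axis.
- **Skeleton statistics** — 3D curve thinning with AnalyzeSkeleton-style
  branch classification; spline-interpolated branch lengths, branch
  diameters from the distance transform, and nearest-neighbour distances
  between per-branch curve midpoints.
- **RMS texture classification** — per-slice sliding-window RMS of
  mean-subtracted grey values (30 px windows, vessels excluded) and a
  healthy/metastatic classifier from mean ± 1.5 SD training bands.
- **CD31 histology** — 2D vascular fraction by colour-range segmentation of
  stained RGB images.
- **Synthetic liver phantoms** — a forward model with ground-truth masks
  whose presets are calibrated to the reported control and metastatic
  statistics (VVF 1.65% / 0.45%, NND 17.8 / 32.5 µm, branch-length modes
  5 / 12 µm, RMS 0.004 / 0.010), so every estimator is testable by
  parameter recovery.

The heavy primitives (separable Gaussian scale space, Hessian eigenvalues,
exact 3D Euclidean distance transform, 3D thinning, box sums) are compiled
(Rcpp).

## Worked example

```r
library(hepavasc)

# a control-liver phantom: 128^3 voxels at 0.7 um, truth masks included
ph <- generate_phantom("control", seed = 11, shape = c(128, 128, 128))
ph
#> <liver_phantom> 128 x 128 x 128 voxels at 0.7 um
#>   truth VVF 1.66% (small vessels), 0 nodule voxels, seed 11

# full pipeline: segmentation, VVF, skeleton statistics, RMS map
met <- run_specimen(phantom_config(ph), volume = ph$volume)
met
#> <specimen_metrics> mean ROI VVF 1.43%; 109 branches
#>   NND weighted mean 14.2 um; length mode 5.5 um; diameter mode 2.25 um
```

The ground-truth VVF of 1.66% is recovered at 1.43% — within the
segmentation's accuracy, biased low here because the central vein and its
exclusion margin occupy a larger share of this reduced volume — and the
branch-length mode recovers the 5 µm design target. At the full validation
size (256³ voxels) the recovered VVF, diameter mode and weighted-mean NND
sit at about 1.7–1.8%, 2.75 µm and 16.3 µm against design targets of
1.65%, 3 µm and 17.8 µm.

A specimen volume on disk runs the same way:

```r
cfg <- run_config(input = "specimen.tif", voxel_size = 0.7,
                  output_dir = "out/")
met <- run_specimen(cfg)   # writes CSV tables + manifest into out/
```

A thin command-line front end is installed with the package
(`system.file("cli", "hepavasc", package = "hepavasc")`) with `phantom`,
`run` and `validate` subcommands.

See the methods vignette (`vignettes/hepavasc-methods.Rmd`) for the models,
parameter defaults, phantom design and known limitations.

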