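---
title: "Quantifying the hepatic sinusoid network in phase-contrast CT: models and methods"
author: "hepavasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the hepatic sinusoid network in phase-contrast CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Liver lobules drain blood through a dense bed of specialized capillaries —
the sinusoids, about 3 um across — toward a central vein tens of micrometres
wide. Colorectal-cancer metastases remodel this bed: the sinusoid network
thins out in the distal parenchyma while a dense perivascular band forms
immediately around each nodule. Propagation-based X-ray phase-contrast CT of
paraffin-embedded tissue resolves the sinusoids without staining, so the
remodeling can be quantified in 3D. `hepavasc` implements the quantification
chain: vessel segmentation, vascular volume fraction (VVF) in several forms,
skeleton-based branch statistics, a texture (RMS) classifier for
low-resolution scans, and a 2D colour-range vascular fraction for CD31
histology, plus a calibrated synthetic phantom generator used to validate
every estimator by parameter recovery.

## Segmentation model

Small vessels are extracted with the multiscale Hessian vesselness of
Frangi: at each voxel and scale $s$ the Hessian of the Gaussian-smoothed
volume is gamma-normalized ($s^2 \partial^2$), its eigenvalues
$|\lambda_1| \le |\lambda_2| \le |\lambda_3|$ feed the ratios
$R_A = |\lambda_2|/|\lambda_3|$ (plate vs line),
$R_B = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}$ (blob deviation) and the
second-order energy $S$, and

$$
V = \left(1 - e^{-R_A^2/2\alpha^2}\right) e^{-R_B^2/2\beta^2}
    \left(1 - e^{-S^2/2c^2}\right),
$$

taking the maximum over scales. Defaults are scales 1–10 voxels,
$\alpha = \beta = 0.5$, $c = 0.013$ (calibrated for grey values normalized
to $[0,1]$), and a mask threshold of $V > 0.16$ (strict). Vessels are dark
in these reconstructions, so the volume is negated internally; a
`dark_vessels` flag selects the polarity. Boundaries are mirror-reflected.
Internally the filter runs in single precision: properties that are exact
in real arithmetic (e.g. invariance under adding a constant) hold to about
$10^{-3}$ in the response.

Large vessels are segmented by a grey threshold (Otsu by default,
overridable — Otsu fails by design when a bright nodule dominates the
histogram, so phantom pipelines pass the midpoint between vessel and
parenchyma grey) and filtered to structures with local diameter of at least
15 um. The two masks are merged voxelwise.

### Diameter split and cleanup

The small/large split assigns every mask voxel a local diameter by the
inscribed-sphere (local-thickness) convention: each centerline voxel of the
mask skeleton carries the sphere of its distance-transform radius, and a
voxel takes the largest covering sphere's diameter. An earlier
nearest-centerline variant misassigned the surface of thick vessels to
nearby thin-vessel centerlines and was replaced. Two cutoffs coexist on
purpose: 15 um separates sinusoids from large vessels in the network
analyses, while VVF reporting excludes vessels above 10 um; both are config
keys.

Two cleanup steps, both standard morphological practice and both exposed as
configuration with defaults chosen from the geometry (not fitted to any
outcome): a margin of 4 um around the large-vessel mask is removed from the
sinusoid masks, because the vesselness filter rings the rim of thick dark
structures; and merged-mask components smaller than 27 voxels (a 3-voxel
cube — below the minimal resolvable sinusoid fragment) are despeckled.

### Skeleton and branch statistics

The mask is thinned to a 26-connected curve skeleton by iterative removal
of simple border points (Malandain–Bertrand characterization, six
directional subiterations, endpoints preserved). Voxels are classified as
in ImageJ's AnalyzeSkeleton: slab (2 neighbours), end (1), junction (3+,
with adjacent junction voxels clustered); a branch is a maximal slab path
between non-slab voxels. Terminal branches shorter than 3 um (one sinusoid
diameter) hanging off a junction are pruned as voxelization spurs, and
chains re-merge through the vacated junctions. A caveat worth recording:
curve thinning of *exactly* grid-symmetric synthetic cylinders (axis
centred between voxel columns) collapses — the reference implementations
behave the same way — so the phantom never places a vessel in that
measure-zero configuration; real scans cannot.

Branch length is the arc length of a natural cubic spline through the path
voxel centres (chord-length parameterization). Spline knots are thinned to
every third voxel (endpoints kept): interpolating every voxel centre tracks
the half-voxel digitization zigzag and inflates curved lengths by tens of
percent, while knot thinning recovers a digital quarter-circle's length to
better than 5% and leaves straight paths exact. Branch diameter is twice
the median distance-transform radius along the path; on digital cylinders
the median skeleton EDT matches the generating radius to about 0.1 voxel
across radii 1–30 voxels (off-axis skeleton placement and the half-voxel
EDT overshoot cancel), so no offset is applied. The per-vessel
representative point for nearest-neighbour distances is the skeleton voxel
at half the branch's cumulative length — a centre of mass taken along the
curve so that it lies inside the vessel — and the reported "weighted
average" NND is the plain mean over branches, i.e. the mean of the
distribution normalized to the total number of vessels.

## VVF in three forms

VVF is vessel voxels over tissue voxels (tissue = region voxels not flagged
vessel), reported as a percent. Vessels above the exclusion diameter are
removed from the *mask* first, so their voxels count as tissue; the phantom
generator uses the same convention when calibrating its ground truth.
Summary VVF averages five random cubic ROIs of $5\times10^{-3}$ mm$^3$;
the local map evaluates every 50-voxel cube via 3D box sums (stride 1); the
radial profile bins voxels by Euclidean distance from the nodule boundary
(distance transform of the nodule complement, so shells follow nodule
shape) in 10 um shells, reporting each shell's VVF against the major
semi-axis of a second-moment ellipsoid fit to the shell's outer surface
(for a sphere of radius $R$ the fit returns exactly $R$). Shells whose
outer bound exceeds the smallest nodule-to-face distance are flagged
incomplete; trailing empty shells truncate the profile with a warning.

## RMS texture classification

For low-resolution scans the in-plane roughness map is the population SD of
the mean-subtracted grey values in 30-pixel windows, per slice, excluding
vessel/nodule/damage pixels; windows under 10% valid pixels are undefined.
The default stride tiles the slice — the classification statistics are the
same in expectation as the stride-1 sliding map at a small fraction of the
cost; `stride = "slide"` restores the dense map. A window is assigned to
the healthy or metastatic class when its RMS falls within that class's
mean ± 1.5 SD training band (inclusive); in both bands, the nearer mean in
SD units wins and an exact tie is unclassified (the tie rule is a package
choice; the band rule itself is fixed). Class fractions are reported over
classified windows only and sum to 100 exactly.

## The synthetic phantom

No volumes are deposited with the study this package operationalizes, so
validation is by parameter recovery on phantoms whose generator targets are
the reported values: control VVF 1.65%, sinusoid diameter 3 um,
branch-length mode 5 um, weighted-mean NND 17.8 um, low-resolution RMS
amplitude 0.004 (within the reported "below 0.006"); metastatic VVF 0.45%,
length mode 12 um, NND 32.5 um, RMS 0.010 (midpoint of the reported 0.008 to
0.012); a half-and-half texture mixture for the chemotherapy-treated
condition; and a nodule phantom with a vessel-free ellipsoidal nodule, a 6%
perinodular density plateau decaying linearly to a 0.5% far field, and a
bright desmoplastic-style rim shell.

The generator places finite tubes (3-point polylines with a slight bow) of
sinusoid calibre: a sharp short length component at the target mode plus a
long uniform tail that carries most of the vascular volume, with midpoints
proposed on a jittered grid at the `min_centerline_spacing` pitch and
accepted under hard constraints (midpoint spacing, 2.5 um surface
clearance, clearance from the central vein). Orientations follow a smooth
field so neighbouring tubes run locally parallel; around a nodule they wrap
in hoop directions. These choices are not cosmetic: a bed of 3 um tubes can
only reach percent-level volume fractions at 15–20 um spacing if neighbours
are nearly parallel — randomly oriented tubes jam well below the target —
and the same holds for the 6% perinodular band. Tubes are rasterized
incrementally and accepted until the voxel-counted truth reaches the
target; in the nodule case a separate quota per 10 um distance band stops a
crowded rim from being compensated by overfilling the far field. An
unreachable density/spacing pair fails with an error naming both
parameters; a shortfall within 0.06 VVF percentage points of the target is
accepted as jammed-but-in-contract. Grey levels are normalized to $[0,1]$:
parenchyma 0.5, vessels darker at 0.435, nodule interior 0.60 with a 0.72
rim shell. The texture is white Gaussian noise smoothed with a 1-voxel
Gaussian (correlation length about 2 voxels) and rescaled to the target
SD. Identical spec and seed reproduce a phantom bit-exactly.

Two calibration notes, both decided on oracle geometry during development
and committed as constants. First, the vessel grey contrast (0.065) is the
value at which the vesselness mask of an ideal rasterized sinusoid has
approximately unit volume ratio against truth — at the reported filter
settings the mask width is a steep function of contrast, and a
physically-arbitrary grey scale is the one free parameter the phantom owns.
Second, the reported RMS amplitudes describe the low-resolution scans on
which the texture analysis runs, so only phantoms at low-resolution voxel
sizes (≥ 2 um) carry the metastatic 0.010 amplitude; high-resolution
phantoms of any condition carry the quiet 0.004, since the high-resolution
texture is otherwise unconstrained and amplitudes near 0.010 would seed the
vesselness filter with false positives that the study's own
high-resolution scans evidently did not exhibit.

What the phantom does *not* model: connected network topology (tubes are
disjoint — branch statistics on real data reflect junction-to-junction
segments of a connected bed), X-ray physics (propagation fringes, phase
retrieval, ring artefacts), lobule-scale grey variations, and anatomical
tortuosity or branching order. Passing recovery tests therefore validates
the estimator chain's geometry and counting conventions, not its behaviour
under reconstruction artefacts.

## Problem sizes and reproducibility

The validation conditions are 256³ voxels at 0.7 um for the two
high-resolution conditions (three seeds each) and 320³ at 1.4 um for the
nodule phantom, with 256×256×48 at 3.1 um for the low-resolution RMS
stage; unit tests exercise the same code on smaller grids. All randomness
derives from explicit seeds; `run_specimen()` reruns bit-identically for a
fixed config and input, and writes a manifest with the config hash and
seed. The sliding-cube map, box-filtered RMS maps, distance transforms,
thinning and vesselness run in compiled code; a full 256³ pipeline takes
on the order of a minute on one core.

## Known limitations

- The vesselness mask dilates or erodes with contrast; VVF recovered from
  segmentation is accurate to ~10% relative, not exactly the truth count.
- NND calibration interacts with packing: at the control density the
  phantom operates near the parallel-bundle packing limit, so the recovered
  NND sits in the lower half of its tolerance band.
- The CD31 stage validates against synthetic truth only; no stain
  deconvolution is attempted, matching the plain colour-range definition.
- The "probability" thresholded at 0.16 is read as the raw vesselness
  value; no additional calibration of the response is applied.
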