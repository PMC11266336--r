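---
title: "Anatomy-based partial volume correction on synthetic kidney-IEC phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-based partial volume correction on synthetic kidney-IEC phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative 177Lu SPECT underestimates the activity concentration of
kidney-sized objects because the imaging chain's point spread function (PSF,
FWHM on the order of 9-11 mm) redistributes counts across region boundaries —
the partial volume effect (PVE). For kidney dosimetry in radionuclide therapy
this bias reaches tens of percent and scales with the organ's
surface-to-volume ratio (S:V). Anatomy-based partial volume correction (PVC)
uses a high-resolution segmentation (from CT) plus the measured PSF to undo
the exchange of activity between regions.

`kidneypvc` provides (i) a synthetic digital analogue of a modified IEC body
phantom carrying a pair of parametric kidney surrogates, (ii) a forward model
(anisotropic Gaussian PSF, optional Poisson count noise), (iii) from-scratch
implementations of seven anatomy-based PVC methods, and (iv) the evaluation
metrics and robustness sweeps used to characterize them. Everything is
deterministic unless noise is explicitly enabled with a seed.

## The correction model

Let $s_i$ be the indicator of region $i$ (of $N$ mutually exclusive regions
covering the body), $h$ the PSF kernel, and $I$ the observed image. The
spill-over matrix is built with one convolution per region:

* GTM mode: $G_{ij} = \sum (s_i \circledast h)\, s_j \,/\, \sum s_j$,
  uncorrected means $A_i = \operatorname{mean}_{s_i}(I)$;
* Labbé mode: $G_{ij} = \sum (s_i \circledast h)(s_j \circledast h) / \sum s_j$,
  uncorrected means $A_i = \sum (s_i \circledast h)\, I \,/\, \sum s_i$.

`G[i, j]` is the fraction of region $i$'s blurred mass landing in region $j$,
normalized by the *receiving* region size. With that orientation a
piecewise-constant object with true means $C$ satisfies $A = G^{\top} C$ for
both estimators (an exact algebraic identity, not an approximation), so
`solve_corrected_means()` solves the transposed system by LU factorization
with an explicit residual check. This is a deliberate reading of the usual
"$C = G^{-1} A$" shorthand: solving the non-transposed system is *not* exact
for either estimator, and exact recovery in the matched, noise-free limit is
the property the whole family is built on. The test suite pins this down to
0.1% for all seven methods on the full phantom.

The voxel-based methods reuse the same cached blurred masks:

* MTC corrects each region in turn,
  $I_c = \sum_j s_j \big(I - \sum_{i \ne j} C_i (s_i \circledast h)\big) / (s_j \circledast h)$;
* RBV corrects all regions at once, $I_c = I \cdot S / (S \circledast h)$
  with $S = \sum_j C_j s_j$;
* Iterative Yang applies the RBV ratio with means bootstrapped from the
  image itself, re-estimated each iteration (default 10 iterations, with an
  additional relative-change stop at `tol = 1e-5`).

Denominator guard: voxels where $s_j \circledast h$ (MTC) or
$S \circledast h$ (RBV/IY) falls below $10^{-3}$ times the within-region
maximum of that denominator are left uncorrected and counted in the
`guarded` attribute. The equations divide by blurred masks that vanish away
from the region; without a guard a handful of far-edge voxels would dominate
the corrected image. Voxels outside every region (air, label 0) are never
corrected and never enter any mean.

Region-based methods report corrected means; for voxel-based methods
`pvc_region_means()` re-measures means from the corrected image over the
crisp masks, which is what makes e.g. Labbé+RBV behave differently from
plain Labbé under perturbations.

## The phantom generator

The generator emulates the study conditions of a physical phantom series:
three modified IEC body phantoms, each with six spheres (10, 13, 17, 22, 28,
37 mm) on a 57 mm ring, a cold central lung insert (51 mm), a cold 10 mm
holder plate, and a pair of kidney inserts, imaged at six decreasing
target-to-background ratios (TBR ~12 down to ~2) obtained by adding
background activity. Concentrations are ingested in MBq/L (the tabulated
unit) and converted once to the canonical Bq/mL; `iec_activity_table()` and
`kidney_geometry_table()` carry the study's printed concentration and
geometry tables.

**Kidney surrogates.** The printed kidneys are only characterized by volume,
surface, and S:V, which are also the quantities that govern the PVE, so the
surrogates are parametric solids matched on volume and S:V within 2%. The
base shape is an ellipsoid with anatomical aspect ratio 1:0.55:0.35 minus a
hilum indentation sphere. Fitting exploits exact self-similarity in the
isotropic scale (the shape factor $\text{S:V} \cdot V^{1/3}$ is
scale-invariant), so the volume stage is a closed-form update and only the
S:V knob needs a bisection. The indentation alone saturates near 1.9x the
equal-volume-sphere S:V, while the smallest printed kidney (56.3 cm^3 at
2.8 cm^-1) sits at 2.22x — no smooth bean reaches it. The fitter therefore
engages a second, saturating knob: a smooth cosine surface lobulation
(amplitude up to 0.25 of the local radius, 5 waves per semi-axis),
emulating the surface roughness/lobulation that CT-segmented printed kidneys
actually have. Medium and large pairs fit with the indentation alone; the
small pair uses lobulation amplitudes of about 0.10-0.16.

**Layout.** The defaults place the kidneys laterally (centers at
(±75, 0, −35) mm) with long axes anterior-posterior, the sphere ring in the
axial plane z = +45 mm with the large spheres on the ±y axis, and the holder
at z in [−78, −68] mm with a hole clearing the lung insert. This is the
arrangement that keeps every structure at least 10 mm from every other
structure and from the body shell with the largest (~160 cm^3) kidney pair
inside the 180 mm IEC interior; the clearance is verified numerically on the
rasterized masks at assembly and violations are errors, not warnings.

**Truth vs labels.** Rasterization produces fractional occupancy
(supersampled 3^3 per voxel); the truth image mixes concentrations by
occupancy at boundaries, while the analysis label map thresholds occupancy
at 0.5. This separates "physical truth" from "segmentation" the way CT-based
segmentation of a continuous object does. `truth_mode = "binary"` instead
makes the truth piecewise-constant on the label partition — the idealized
premise under which all seven methods are provably exact, used by the
exactness tests. With the default fractional truth the residual kidney-mean
errors at TBR ~12 are about 0.1-0.4% depending on the method.

**Noise.** Off by default. When enabled, expected voxel counts are
`concentration x voxel volume x kappa` with Poisson sampling under an
explicit seed. The default `kappa = 0.043824 counts/Bq` anchors the count
density to a tomographic sensitivity of 18.26 counts/s/MBq over a 60 x 40 s
projection acquisition (about 16 counts per background voxel at 33.8 MBq/L).
No per-voxel count density is published for the reference acquisition, so
this is a documented modeling choice, chosen once.

**What the generator does not emulate.** The forward model is a stationary
Gaussian convolution. It reproduces none of the reconstruction-induced
effects of an iterative OSEM chain — in particular the near TBR-independence
of measured uncorrected RCs that resolution modeling inside the
reconstruction produces. Consequently the package treats the published
low-TBR recovery losses and exact robustness bias percentages as directional
references only: passing tests show the algorithms behave correctly under
the stated model, not that they reproduce acquisition-specific magnitudes.
Distance-variant PSFs, attenuation, scatter, and dead time are likewise out
of scope.

## Numerical choices

* **Convolution** is separable, zero-padded (the phantom is surrounded by
  air; periodic wrap-around would create spurious spill-in), with per-axis
  Gaussian taps truncated at 4 sigma and renormalized to sum exactly 1. It
  matches a direct triple-sum oracle to 1e-10 on small grids.
* **Morphology** (erosion by a physical distance, k-voxel Euclidean shells)
  thresholds counts against an exact Euclidean-ball indicator computed by
  FFT convolution — equivalent to exact-EDT thresholding, with no chamfer
  approximation; an erosion that empties a mask raises an explicit error.
* **Surface area** is a marching-tetrahedra triangulation of the 0.5
  isosurface (6-tet cube decomposition, linear edge interpolation). The
  field is pre-smoothed with a sigma = 0.6 voxel Gaussian: the triangulation
  of a sharp one-voxel transition overestimates area by ~5-6% (staircase
  zigzag), while the smoothing's curvature shrinkage stays below ~1% for
  radii above ~6 voxels. Digitized-sphere checks (37 mm within 3%, 13 mm
  within 5%) pin the estimator.
* **Resampling** is nearest-neighbor in physical coordinates for both
  images and label maps (never introducing new labels); the acquisition
  grid (4.42 mm) is resampled to the 2.21 mm working grid before PVC so
  shell thicknesses and mask shifts are expressed in 2.21 mm voxels.
* **Surrogate fitting** bisects the S:V knob to 0.4% relative and polishes
  scale and knob jointly at the final size (discretization breaks exact
  self-similarity at the 1-2% level for lobulated shapes).
* **Conditioning**: the spill-over solve refuses condition numbers >= 1e8
  and names the most strongly coupled region pair; the residual check
  (1e-8) turns silent numerical failure into an error.

## Robustness sweeps

All three sweeps follow the same design: perturb exactly one assumption of
the correction (never the simulated observation), rerun all methods, and
report the kidney RC bias relative to the *matched* reference run of the
same observation — not relative to RC = 1 — so the sweep isolates the
perturbation even under noise or boundary-mixing effects. The null
perturbation is therefore exactly zero bias by construction, which the tests
assert at 0.1%.

* PSF mismatch: correction FWHM shifted by −6..+6 mm (2 mm steps) on all
  three axes simultaneously; negative resulting FWHMs are skipped with a
  record.
* Registration mismatch: kidney labels translated ±1..3 voxels per axis
  (both kidneys jointly by default; vacated voxels become background,
  entered voxels are overwritten, shifts beyond the body support are
  clipped with a warning).
* Background heterogeneity: the lung label is merged into the background
  and uniform activity is added inside the (former) lung voxels of the
  observed image so that the merged-background mean rises by the target
  ratio (solved exactly from the linear relation); ratios 1..4 in 0.25
  steps.

Sweep summaries report signed and absolute means; the published study does
not state which of the two its averages use, so both are kept.

On the synthetic phantoms these sweeps reproduce the qualitative findings of
the physical study: PSF overestimation biases all methods upward and more
strongly than registration errors of the same magnitude; Labbé is the least
sensitive to PSF and registration mismatch but the most sensitive to
background heterogeneity (its extra convolution in both the means and the
matrix couples it more strongly to the background assumption); heterogeneity
bias is negative and linear in the ratio; and both uncorrected RC and
PSF-mismatch bias are linear in kidney S:V.

## Problem sizes

The default working grid is 2.21 mm isotropic over a 350 x 260 x 220 mm
field of view (159 x 118 x 100 voxels), chosen so the whole phantom keeps at
least 3 PSF sigmas of margin and kernel mass is conserved. Surrogates are
fitted on a 1 mm grid with 3^3 supersampling. The test suite runs the full
phantom for the exactness and robustness properties and reduced sweep
samplings (offsets 1-3 along one axis, PSF deltas 0/2/4/6 mm, seven
heterogeneity ratios); the analysis scripts run the full sweep grids.

## Known limitations

* Quantitative agreement with a physical acquisition is out of scope: no
  OSEM reconstruction, scatter, attenuation, dead time, or distance-variant
  resolution. Magnitudes such as uncorrected RC levels agree only
  qualitatively.
* The surrogate family matches volume and S:V, not kidney shape beyond the
  bean-with-hilum motif; peripheral-shell metrics depend on local curvature
  and should be read as model properties.
* The Labbé mean normalization follows the printed form (sum over the
  blurred mask divided by the crisp mask size); `normalization = "blurred"`
  exposes the alternative, and the two coincide for interior regions.
* Erosion/shell operations assume the isotropic working grid for their
  voxel-unit contracts; physical-distance erosion works on anisotropic
  grids.
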