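# kidneypvc

Anatomy-based partial volume correction (PVC) for quantitative SPECT,
evaluated on synthetic digital analogues of kidney-bearing IEC body phantoms.

## The problem

Post-therapy 177Lu SPECT is the basis of kidney dosimetry in radionuclide
therapy, but the imaging chain's point spread function (FWHM ~9–11 mm)
smears activity across organ boundaries — the partial volume effect — and
biases kidney activity concentration low by 20–35%, the more so the higher
the organ's surface-to-volume ratio (S:V). Anatomy-based PVC uses a CT-derived
segmentation plus the measured PSF to undo this exchange. This package is for
physicists and method developers who want a fully controlled, reproducible
test bed: it generates the ground truth, degrades it with a known PSF, runs
seven PVC algorithms implemented from scratch, and measures what each one
recovers.

## The methods

With region indicators `s_i` (N mutually exclusive regions), PSF kernel `h`,
and observed image `I`, the spill-over matrix and uncorrected means are

* GTM: `G[i,j] = sum((s_i ⊛ h) · s_j) / sum(s_j)`, `A_i = mean_{s_i}(I)`
* Labbé: `G[i,j] = sum((s_i ⊛ h) · (s_j ⊛ h)) / sum(s_j)`,
  `A_i = sum((s_i ⊛ h) · I) / sum(s_i)`

and the corrected means `C` solve the spill-over system `t(G) C = A`
(a piecewise-constant object satisfies this identity exactly, so the whole
family is exact in the matched, noise-free limit). The voxel-based methods
reuse `C`: MTC divides each region's spill-in-subtracted image by its blurred
mask, RBV multiplies by `S / (S ⊛ h)` with `S = Σ C_j s_j`, and iterative
Yang bootstraps the means from the image itself (10 iterations). All seven —
GTM, Labbé, GTM+MTC, Labbé+MTC, GTM+RBV, Labbé+RBV, IY — run off one set of
N cached convolutions.

The phantom generator reproduces the study conditions of a printed-kidney
IEC phantom series: six spheres (10–37 mm), a cold lung insert and holder
plate, and a pair of parametric kidney surrogates fitted to each printed
kidney's volume and S:V within 2% (1.5–2.8 cm⁻¹), on a 2.21 mm isotropic
grid, at six target-to-background ratios (TBR ~12 down to ~2).

## Worked example

```r
library(kidneypvc)

# fit a surrogate to the smallest printed kidney: 56.3 cm^3 at 2.8 cm^-1
s <- make_kidney_surrogate(56.3, 2.8)
print(s)
#> kidney_surrogate: V 56.5 cm^3 (target 56.3), S:V 2.80 cm^-1 (target 2.80)

# assemble the IEC-1 analogue at TBR ~12 and simulate the observation
surr <- fit_all_kidney_surrogates()
spec <- phantom_spec(kidneys = surr[c("Small-R", "Small-L")],
                     background_conc = 33.8, target_conc = 378.7)  # MBq/L
asm <- assemble_phantom(spec)
psf <- psf_model(c(8.8, 11.0, 9.2))  # measured FWHM, mm
obs <- simulate_observation(asm$truth, psf)

recovery_coefficient(obs, region_mask(asm$labels, "kidney_R"), 378700)$RC
#> [1] 0.688          # uncorrected: ~31% of the kidney signal smeared away

r <- run_pvc(obs, asm$labels, psf, method = "gtm")
r$means[["kidney_R"]]
#> [1] 377091         # corrected mean, Bq/mL; true value 378700 (RC 0.996)
r$means[["background"]]
#> [1] 33596          # background recovered too (true 33800)
```

The uncorrected kidney RC of 0.688 is the partial volume effect; GTM (and
the other six methods) bring the kidney mean back to within ~0.5% of truth
under matched PSF and masks. The `analysis/` scripts run the full study:
`01_fit_kidneys.R` (surrogate geometry), `02_rc_vs_tbr.R` (RC tables over
3 phantoms × 6 TBRs × 7 methods), `03_robustness.R` (PSF-mismatch,
registration, heterogeneity sweeps), `04_figures.R` (plots). Tables land in
`results/`.

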