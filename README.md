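# tmquant

Quantitative image analysis for multi-channel two-photon z-stacks of human
trabecular meshwork (TM) — the porous drainage tissue whose actomyosin tone
regulates intraocular pressure. Given paired (vehicle-control vs.
actin-depolymerised) stacks with a green channel (structural-ECM
autofluorescence + Hoechst nuclei) and a red channel (phalloidin F-actin),
or calcein/propidium-iodide viability channels, `tmquant` computes:

* **F-actin adjusted fluorescence intensity** — per-ROI mean red grey value
  over sampled sections, normalised by the ROI's nuclear count:
  `AFI = mean_i ( mean_z ( Σ_k G_k / P_x )_i / N_i )` over five 3 230 µm²
  ROIs replicated across sections;
* **F-actin adjusted fluorescence distribution** — the volume of the
  thresholded red channel (voxels strictly inside the window
  (10 025, 65 540), 26-connected components) per 82 × 82 × 38 µm subvolume
  of a 3 × 3 partition, normalised by the subvolume's nuclear count;
* **structural-ECM pore morphometry** — 2D elliptical cross-sections
  `A = π (d_short/2)(d_long/2)` of interior pores, and 3D void volume by
  subtracting the segmented autofluorescence foreground from a solid mask
  of the crop (negative imprint);
* **autofluorescence intensity** and **cell viability** (calcein-positive
  live vs. PI-positive dead, pooled two-proportion z-test);
* **paired statistics** — one-tailed paired t-tests on natural-log values,
  per-pair and group-mean percent change, CSV report tables.

Because the donor-tissue images behind the published TM measurements are
not publicly deposited, the package ships a synthetic stack generator
(`generate_tissue_pair()`, `generate_viability_stack()`) that renders
beam lattices with pores, cortical vs. aggregated actin, ellipsoidal
nuclei and photon noise with full ground truth, so every pipeline is
validated by parameter recovery. See the methods vignette
(`vignettes/tmquant-methods.Rmd`) for the model, parameter defaults and
what the synthetic scenes do and do not emulate.

## Worked example

Three simulated donor pairs with a programmed 50 % F-actin reduction:

```r
library(tmquant)
vals <- sapply(1:3, function(s) {
  p <- synth_params(seed = s, actin_effect = 0.5)
  pair <- generate_tissue_pair(p)
  rois <- place_rois(p$ny, p$nx, 5, cal = p$cal)
  c(adjusted_intensity(pair$control$red, pair$control$green, rois)$adjusted_intensity,
    adjusted_intensity(pair$treated$red, pair$treated$green, rois)$adjusted_intensity)
})
round(vals, 1)
#>       [,1]  [,2]  [,3]
#> [1,] 208.5 228.3 215.9   # control adjusted intensity per pair
#> [2,] 108.6 119.0 112.8   # treated
paired_comparison(vals[1, ], vals[2, ], label = "factin_density")
#> <paired_comparison> factin_density: control 217.6 +/- 10.01, treated 113.5 +/- 5.229 (n = 3)
#>   per-pair change -47.9% +/- 0.1%; group-mean change -47.9% (-48%)
#>   paired log t = 811, one-tailed p = 7.601e-07 (control_gt_treated)
```

The recovered reduction sits ~2 points below the programmed 50 % because
the constant background offset is shared between conditions; the adjusted
intensity is the mean ROI grey value divided by the ~10–12 nuclei each ROI
samples. The same pattern holds for the 3D distribution measure, where
thresholding amplifies the loss (aggregated actin stays above the window,
the dimmed shell falls below it).

A thin command-line front end over the same functions is installed at
`inst/scripts/tmquant.R` (subcommands `simulate`, `density`,
`distribution`, `pores`, `viability`, `report`), reading the plain-text
YAML config and multi-page TIFFs that `write_tissue_pair()` emits.

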