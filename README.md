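# dectquant

Quantitative dual-energy CT (DECT) analysis of gold-nanoparticle (AuNP)
contrast agents, as an R package plus a reproducible analysis workflow.

Gold's strongly energy-dependent X-ray attenuation (k-edge 80.7 keV) lets
two co-registered CT acquisitions at different tube potentials (80 and
140 kVp) be inverted, voxel by voxel, into material concentration maps.
This is the non-destructive counterpart of excising organs and measuring
gold by ICP-MS, and the basis for imaging folate-targeted AuNP uptake in
folate-receptor-overexpressing tumours. The package is aimed at imaging
scientists who want a tested, ground-truth-validated implementation of
the full chain: phantom simulation, sensitivity calibration, per-voxel
decomposition, organ quantification, and the haemolysis assay statistic
used for probe haemocompatibility.

## The model

Each voxel's shifted CT number (CT' = HU + 1000, so water reads 1000 and
the water coefficient is nonzero) responds linearly to the two basis
materials at each energy *E*:

    CT'_E = e_w,E · C_w + e_Au,E · C_Au        [mg/ml, HU'·ml/mg]

Stacking both energies gives a 2×2 system per voxel,

    [C_w, C_Au]' = M⁻¹ [CT'_80, CT'_140]',   M = [[e_w,80, e_Au,80],
                                                  [e_w,140, e_Au,140]]

solved in closed form. The gold slopes e_Au,E are calibrated by ordinary
least squares of mean vial CT' against concentration on a five-vial
phantom (250–2000 µg/ml); e_w is fixed at 1 by the shifted-CT
convention. Per-energy noise σ propagates into the gold map with
standard deviation σ·√2/|e_Au,140 − e_Au,80|, the closed form the test
suite checks empirically.

Module map: `phantom_spec()`/`build_phantom()` and
`mouse_scenario()`/`build_mouse()` (synthetic ground truth),
`forward_project()` (two-energy simulation), `measure_vials()` /
`fit_sensitivity()` / `validate_calibration()` (calibration),
`decompose_voxel()`/`decompose_volume()` (inversion),
`quantify_rois()` / `compare_with_reference()` / `targeting_contrast()`
(biodistribution), `hemolysis_fraction()` (assay statistic),
`run_pipeline()` (all stages with a checksummed manifest). Volumes are
NIfTI (conventional HU on disk), tables CSV/JSON, configs YAML/JSON.

## Worked example

The noiseless calibration-phantom round trip (simulate → calibrate →
decompose → measure):

```r
library(dectquant)
spec <- phantom_spec()                     # vials at 250..2000 ug/ml
maps <- build_phantom(spec)
img  <- forward_project(maps, default_sensitivity(),
                        scan_protocol(noise_sd = 0))
ser  <- measure_vials(img, maps$labels, spec$vial_concentrations)
fit  <- fit_sensitivity(ser$low, ser$high)
fit
#> <sensitivity_matrix> HU' per (mg/ml)
#>   low : e_w 1  e_au 22  intercept 1000  r2 1
#>   high: e_w 1  e_au 27  intercept 1000  r2 1
#>   condition number: 243
dec <- decompose_volume(img, fit)
sapply(1:5, function(i) mean(dec$maps$c_au[maps$labels == i]) * 1000)
#> [1]  250  500 1000 1500 2000
```

The fitted slopes are the generating sensitivity coefficients (22 and
27 HU'·ml/mg at 80 and 140 kVp) and every vial's recovered mean equals
its nominal concentration in µg/ml.

The full study-scale analysis is the numbered workflow under
`analysis/` (run in order from the repository root after installing):

```sh
Rscript analysis/01_simulate.R     # phantom + targeted/non-targeted mouse
Rscript analysis/02_calibrate.R    # vial OLS fits -> fit.json
Rscript analysis/03_decompose.R    # per-voxel concentration maps
Rscript analysis/04_quantify.R     # organ ROI report + uptake ratio
Rscript analysis/05_hemolysis.R    # haemolysis fractions 200-600 uM
```

On the default scenario (organ panel tumour/kidneys/lungs/spleen/heart/
liver, 5 HU per-energy noise, 0.25 mm grid) stage 04 prints an
organ-vs-reference correlation of 0.9993, a mean absolute relative error
of 1.5%, and a tumour uptake ratio of 1.92 for the targeted vs
non-targeted probe (ground truth 2.0); stage 05 reports haemolysis below
3.6% at every tested concentration, i.e. haemocompatible. Outputs land
under `results/`.

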