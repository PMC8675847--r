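---
title: "Quantifying gold nanoparticle concentrations with dual-energy CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gold nanoparticle concentrations with dual-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectquant)
```

## The problem

Gold nanoparticles (AuNPs) are attractive CT contrast agents: gold's high
atomic number (Z = 79) gives it a strong, strongly energy-dependent X-ray
attenuation, with a k-edge at 80.7 keV. Conjugated to folic acid, AuNPs
accumulate preferentially in folate-receptor-overexpressing tumours
(e.g. nasopharyngeal KB xenografts). Dual-energy CT (DECT) — two
co-registered acquisitions at different tube potentials, here 80 and
140 kVp — can turn that energy dependence into a *quantitative* per-voxel
estimate of gold concentration, offering a non-destructive alternative to
excising organs and measuring gold by ICP-MS.

`dectquant` implements the full image-domain analysis as a tested
pipeline on synthetic data with known ground truth: simulate two-energy
volumes from water/gold concentration maps, calibrate sensitivity
coefficients from a vial phantom, invert the per-voxel two-material
system, and score organ-level recovery against the reference
concentrations. A small separate module computes the normalized
haemolysis fraction used to establish haemocompatibility of the probe.

## The two-material model

Post-reconstruction, image-domain decomposition assumes each voxel's CT
number at energy $E$ responds linearly to the two basis materials, water
and gold:

$$\mathrm{CT}'_E = e_{w,E}\, C_w + e_{Au,E}\, C_{Au},$$

with concentrations in mg/ml and sensitivity coefficients $e$ in HU per
(mg/ml). Written for both energies this is a $2\times2$ linear system per
voxel,

$$\begin{bmatrix} C_w \\ C_{Au} \end{bmatrix} =
  \begin{bmatrix} e_{w,80} & e_{Au,80} \\ e_{w,140} & e_{Au,140}
  \end{bmatrix}^{-1}
  \begin{bmatrix} \mathrm{CT}'_{80} \\ \mathrm{CT}'_{140} \end{bmatrix},$$

solved in closed form by `decompose_voxel()` / `decompose_volume()`.

**The shifted-CT convention.** In true Hounsfield units water reads 0 HU
at every energy, which would force $e_w = 0$ and make the matrix
singular. All internal arithmetic therefore uses shifted CT numbers
$\mathrm{CT}' = \mathrm{HU} + 1000$ (air 0, water 1000), under which
$e_w = 1$ HU$'$·ml/mg at both energies and the system is invertible
exactly when the gold slopes differ between energies — which they do,
because of the k-edge. The offset is metadata: NIfTI files hold
conventional HU and the shift is applied/removed at the I/O boundary.

**Intercepts.** Calibration fits a line
$\mathrm{CT}'_E = b_E + e_{Au,E} c_{Au}$ through the vial means. Since
the vials are aqueous, $b_E = e_{w,E}\cdot 1000$; the decomposition
subtracts $b_E$ before inverting (so background offset cannot leak into
$C_{Au}$) and adds the implied water baseline $b_E/e_{w,E}$ (averaged
over energies) back onto the recovered water map. On noiseless data the
round trip simulate → calibrate → decompose is the identity to numerical
precision. The forward model itself carries no intercept.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| tube potentials | 80 / 140 | kVp | the standard dual-energy pair for gold imaging |
| `e_Au,80`, `e_Au,140` | 22, 27 | HU$'$·ml/mg | anchored to reported liver enhancements of ~22 and 27 HU per unit gold concentration at 80/140 kVp on a hospital CT; configuration values, replaced by any phantom calibration |
| `e_w` (both energies) | 1 | HU$'$·ml/mg | the shifted-CT water convention |
| vial concentrations | 250–2000 | µg/ml | the five-vial calibration design |
| phantom geometry | body r = 20 mm, vials r = 4 mm on a 12 mm ring | mm | no canonical geometry exists; chosen once as a plausible small-animal phantom |
| PMMA background | 1120 | mg/ml water-equivalent | PMMA reads ≈ +120 HU |
| `noise_sd` | 10 (stress tests), 5 (in vivo scenario) | HU | see below |
| condition cap | 10^6 | — | hard error instead of silent noise amplification |
| targeting ratio | 2 | — | targeted vs non-targeted tumour uptake |
| voxel size | 0.5×0.5×0.625 (phantom), 0.25 iso (mouse) | mm | phantom matches a 0.625 mm clinical slice; the mouse grid is finer so the 0.1 cm³ tumour contains ~6500 voxels |

Units: every external interface (specs, CSV/JSON reports, NIfTI maps)
uses µg/ml, the customary reporting unit; all internal math is mg/ml.
The factor-1000 conversion is applied exactly once, at ingestion or at
the report boundary.

## What the synthetic generator emulates — and what it does not

`build_phantom()` and `build_mouse()` produce voxelized ground-truth
maps: axis-aligned cylindrical vials in a PMMA cylinder, and ellipsoidal
organs (tumour, both kidneys, lungs, spleen, heart, liver) in an
ellipsoidal torso sized after a ~20 g mouse. Organ gold concentrations
default to a realistic 3 h post-injection biodistribution
(reticuloendothelial organs highest: liver 1500, spleen 1200 µg/ml;
kidneys 700; lungs 500; heart 400; tumour 400, doubled under the
targeted probe; 100 µg/ml residual blood pool elsewhere). The tumour
volume is 0.1 cm³, the size at which imaging starts.

`forward_project()` applies the bilinear response and adds independent
per-voxel, per-energy Gaussian HU noise — the standard post-reconstruction
approximation. Deliberately *not* modelled: polychromatic spectra, beam
hardening, scatter, partial-volume blurring beyond voxelization, spatial
noise correlation from the reconstruction kernel, and motion. Passing
tests therefore demonstrate that the estimator chain is correct and
well-calibrated under its own assumptions, not that those assumptions
hold on scanner data; on real volumes the linearity of HU in
concentration and the noise level must be established by the physical
calibration phantom.

Because decomposition is linear, per-energy noise $\sigma$ propagates
into the gold map with standard deviation
$\sigma\,\lVert \text{row}_2 M^{-1}\rVert_2 = \sigma\sqrt2/|e_{Au,140}-e_{Au,80}|$
(≈ 0.28 mg/ml per HU at the default slopes) — `noise_amplification()`
gives the closed form, and the test suite verifies the empirical noise
against it within 5% on >10⁵ voxels. This amplification is why the
per-voxel maps look noisy while organ ROI means (thousands of voxels)
are accurate to a few percent.

**Noise levels.** The stress tests use σ = 10 HU per energy, a harsh
setting for thin-slice imaging. The in vivo scenario uses σ = 5 HU, a
moderate level representative of a quiet high-mAs abdominal protocol;
with the tumour's ~6500 voxels this puts the seed-to-seed spread of the
recovered uptake ratio near 4%, so the 2× targeting contrast is
measurable from a single simulated animal, mirroring the study design.
Both values were fixed when the scenarios were defined.

## Numerical choices and degenerate inputs

- The solver is the closed-form adjugate inverse of the 2×2 system, not
  an iterative or least-squares routine; a generic `solve()` serves only
  as an independent oracle in the tests (agreement ≤ 1e-9 over 1000
  random well-conditioned systems).
- Degeneracy is decided solely by the exact 2-norm condition number:
  equal slopes give an infinite condition number at construction, and
  `decompose_*` refuses anything above the cap (default 10⁶) with a hard
  error.
- Negative recovered gold concentrations are retained by default: they
  are the zero-mean tail of the propagated noise (≈45% of body voxels at
  background concentrations), and clipping before averaging would bias
  ROI means upward. `clip_negative = TRUE` floors the map for display
  only; the pre-clip negatives fraction is always recorded.
- Calibration uses unweighted OLS by default, matching the minimal
  linear-correlation procedure; `weighted = TRUE` applies the obvious
  1/sd² refinement. A fitted negative slope warns but does not abort
  (it signals an unusable energy pair, which the condition cap will
  catch downstream).
- Vial/organ geometry is validated before painting (vials inside the
  body and pairwise disjoint; organs non-overlapping, every organ with
  ≥1 voxel at the chosen resolution); violations are errors, not silent
  clipping.
- Reproducibility: all randomness flows through the protocol seed via
  `withr::with_seed` (low-energy volume drawn first), so identical
  (maps, coefficients, protocol) triples give bit-identical volumes;
  `run_pipeline()` derives per-stage substreams from one master seed and
  writes MD5 checksums for every artifact into its manifest.

## Design choices where the design was open

- **e_w determination.** How water coefficients are obtained is not
  prescribed anywhere; we fix them at the convention value (1) with an
  override argument for a water-dilution series. This makes the gold
  channel depend only on the *difference* of the fitted slopes.
- **ICP-MS emulation.** Reference organ concentrations are the scenario
  ground truth; an optional mean-preserving multiplicative lognormal
  perturbation (`icpms_noise_cv`) emulates reference-assay error and is
  off by default, so agreement statistics isolate the imaging chain.
- **Tissue mass vs voxel mean.** Physical reference assays report gold
  per weighed tissue; the synthetic comparison uses the voxel-volume
  weighted organ mean as the mass proxy, exact for uniform organs.
- **Agreement statistics.** Organ-wise paired relative error, Pearson
  correlation across organs, and mean bias replace omnibus significance
  testing: on synthetic data with configurable noise, effect sizes are
  design choices and p-values would only restate them.
- **Haemolysis.** The statistic is kept as the pure normalized fraction
  (percentage at the report boundary); sub-zero fractions are flagged
  and reported as computed. The positive control is conventionally fully
  lysed blood; no numeric assumption about it enters the computation.

## Problem sizes

The packaged analyses run at desk scale: phantom 96×96×16 voxels
(0.5×0.5×0.625 mm), mouse 256×112×96 voxels (0.25 mm isotropic,
~2.7×10⁶ voxels), noise-propagation checks on 1.3×10⁵-voxel uniform
blocks, and 1000-system solver comparisons. The whole test suite and the
five analysis scripts each complete in well under a minute on one CPU.

## Worked example

```{r phantom-roundtrip}
spec <- phantom_spec()
maps <- build_phantom(spec)
img <- forward_project(maps, default_sensitivity(),
                       scan_protocol(noise_sd = 0))
series <- measure_vials(img, maps$labels, spec$vial_concentrations)
fit <- fit_sensitivity(series$low, series$high)
fit
dec <- decompose_volume(img, fit)
sapply(1:5, function(i) mean(dec$maps$c_au[maps$labels == i]) * 1000)
```

The noiseless round trip returns the five nominal concentrations
(250–2000 µg/ml) to machine precision; with per-energy noise the same
chain recovers organ means to a few percent, which is the package's
acceptance bar.

## Known limitations

- Two basis materials only; no k-edge three-bin or multi-contrast
  decomposition, and no separation of two simultaneously injected
  agents.
- No projection-domain physics: spectra, beam hardening and scatter are
  out of scope, so absolute sensitivity coefficients on real scanners
  must come from the physical phantom, not from these defaults.
- No spatial regularization or denoising: per-voxel maps carry the full
  amplified noise by design.
- Organ labels are inputs (ground truth here, segmentations on real
  data); segmentation error is not modelled.
- The haemolysis module reads single-wavelength (540 nm) absorbances
  only; no spectral curve processing.
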