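# cinephase

Automated cardiac phase selection and ejection-fraction estimation for
rodent short-axis cine MRI.

Preclinical cardiac studies in rats estimate left-ventricular (LV) function
from cine MRI: 11–13 three-dimensional image stacks acquired 8 ms apart over
one cardiac cycle, typically 12 × 86 × 98 voxels at 1.5 × 0.5 × 0.5 mm. Once
each phase has an LV cavity segmentation — from a CNN, a human operator, or
any other backend — two steps separate the masks from a reported ejection
fraction (EF): identifying end-diastole (ED) and end-systole (ES), and
turning masks into volumes. `cinephase` automates both and ships the
apparatus around them, so segmentation backends can be developed, stress
tested and benchmarked end to end without proprietary data.

The core quantity is

```
EF = 100 · (EDV − ESV) / EDV
```

with EDV and ESV the cavity volumes (µL) at ED and ES. The package describes
each cardiac cycle by one scalar metric per phase — cavity volume, maximum-
variance slice area, or marching-tetrahedra iso-surface area — fits the
resulting curve with either a fourth-degree polynomial or a Gaussian process
(constant × RBF kernel, hyperparameters by marginal-likelihood maximisation),
selects ES/ED as the fitted curve's extrema anchored at observed phases, and
reads EDV/ESV from the masks at the selected phases.

Also included, as first-class tested components:

* **Training losses** — soft Dice (ε-smoothed, two-sided), border-weighted
  soft Dice with a Ronneberger-style weight map (w₀ = 2, σ = 1), binary
  cross-entropy and the hybrid loss, as pure framework-free functions.
* **MRI noise models** — Gaussian, Rician, Rayleigh and mixed, calibrated to
  a target SNR (mean foreground signal / noise sd).
* **Augmentation** — elastic, shift, rotation, scaling, blur, gamma; ×10
  dataset inflation, seeded and deterministic.
* **Agreement statistics** — mean absolute EF difference, Bland–Altman bias
  and limits of agreement with 95% CIs, proportional-bias check, paired TOST
  equivalence test with a 2% EF margin.
* **Synthetic cine generator** — ellipsoidal cavity + myocardial shell with
  physiological radial-dominant contraction and exact voxel-level ground
  truth (EDV, ESV, EF, extreme phases).

## Worked example

Generate a synthetic cine series with known truth, then run the automated
pipeline on its masks:

```r
library(cinephase)

res <- generate_synthetic_cine(synthetic_cine_spec(n_phases = 13, ef_pct = 62, seed = 42))
res
#> <synthetic_cine_result> 13 phases, truth EF 61.92% (EDV 500.2, ESV 190.5 uL), ED phase 11, ES phase 5

out <- auto_ef(res$series, metric = "slice_area", spec = fit_spec("gp", seed = 1))
out$selection
#> <phase_selection> gp fit on slice_area: diastole phase 11, systole phase 5
out$ef
#> <ef_estimate> EF 61.92% (EDV 500.2 uL @ phase 11, ESV 190.5 uL @ phase 5)
```

The GP fit of the mid-slice area curve (mm² per phase: 46.5, 42.2, 35.0,
28.2, 23.0, 22.5, 24.5, 31.2, 37.2, 44.2, 48.0, 49.8, 46.5) bottoms out at
phase 5 and peaks at phase 11; the volumes at those phases reproduce the
generator's EF exactly because the masks are the ground truth.

Agreement between two EF raters:

```r
p <- paired_ef(sprintf("rat%02d", 1:6),
               c(52.1, 60.4, 44.9, 66.2, 57.0, 48.3),   # estimated
               c(53.0, 61.8, 45.2, 65.0, 58.1, 50.1))   # reference
bland_altman(p)
#> <agreement_report> n = 6
#>   MD  1.117 +/- 0.504
#>   bias -0.717 +/- 1.065 (95% CI -1.834 to 0.401)
#>   LoA  -2.804 / 1.370
#>   proportional-bias slope p = 0.389
tost_equivalence(p, margin = 2)$p_value
#> 0.0159  (equivalent at the 2% EF margin)
```

## Command line

A thin CLI over the same functions lives at `inst/cli/cinephase.R`:

```sh
Rscript inst/cli/cinephase.R synth --ef 55 --phases 13 --seed 7 --out demo/
Rscript inst/cli/cinephase.R auto-ef --in demo/masks.nii.gz --metric slice_area --fit gp --out demo/ef.json
Rscript inst/cli/cinephase.R benchmark --n-series 50 --seed 1 --out bench/
```

Subcommands: `synth`, `metrics`, `auto-ef`, `corrupt`, `augment`, `agree`,
`benchmark`, `noise-robustness`. Every run writes a `manifest.json` with the
configuration, seed and package versions.

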