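# boldcv

Fluctuation-amplitude analysis of resting-state BOLD fMRI.

The amplitude of spontaneous low-frequency (f < 0.1 Hz) BOLD fluctuations —
not just their spatial correlation structure — carries information about
cerebrovascular reactivity, and changes with vascular ageing and disease.
`boldcv` measures it as the per-voxel **coefficient of variation**

    CV_i = sd_t( S_i ) / mean_t( S_i )

of each voxel's time series after nuisance removal, and carries the analysis
from raw 4D NIfTI to cohort-level inference:

* **Preprocessing**: regression of the 6 rigid-body motion parameter time
  courses, first-order detrending, and optional **RETROICOR** physiological
  correction (2nd-order Fourier model in cardiac/respiratory phase, built
  per slice from photoplethysmograph and respiratory-belt recordings).
* **CV mapping**: full band, or within frequency bands (defaults
  0.01–0.014, 0.014–0.025, 0.025–0.1 Hz) via an exact zero-phase DFT-mask
  filter, so band variances partition the total.
* **Tissue aggregation**: partial-volume-weighted mean
  `sum(PVE*CV)/sum(PVE)`, strict-threshold mean (PVE > 0.8), and
  template/ROI masks.
* **Cohort statistics**: exact Wilcoxon rank-sum tests (dynamic-programming
  null distribution, permutation fallback under ties), group summaries,
  WM~GM least-squares fit, framewise-displacement comparison.
* **A calibrated synthetic phantom**: 4D BOLD subjects with known intrinsic
  tissue CV, power-law fluctuation spectra, scanner drift, quasi-periodic
  cardiac (1.13 Hz) and respiratory components with ground-truth phases, and
  thermal noise — the package's end-to-end validation harness.

Audience: neuroimaging researchers who want a tested, scriptable CV pipeline
or a ground-truth phantom for validating their own fluctuation-amplitude
analyses.

## Worked example

Simulate a two-cohort phantom study — a control-analog group generated at
gray/white-matter intrinsic CVs of 4.6/3.0 × 10⁻³ and an elevated-fluctuation
group at 7.9/4.2 × 10⁻³ — run the full pipeline on every subject, and compare
the cohorts:

```r
library(boldcv)

ctrl <- phantom_spec(grid_shape = c(24L, 24L, 24L),
                     tissue_cv = c(GM = 4.6e-3, WM = 3.0e-3, CSF = 9e-3))
ckd  <- phantom_spec(grid_shape = c(24L, 24L, 24L),
                     tissue_cv = c(GM = 7.9e-3, WM = 4.2e-3, CSF = 1.2e-2))
study <- phantom_study(control_spec = ctrl, ckd_spec = ckd,
                       n_per_group = 4L, seed = 42L,
                       cfg = pipeline_config(bands = list()))
print(study$report)
```

```
Cohort comparison: control vs ckd (Wilcoxon rank-sum, alpha = 0.05)
# A tibble: 4 × 11
  tissue method band  mean_control sd_control mean_ckd    sd_ckd n_control n_ckd
  <chr>  <chr>  <chr>        <dbl>      <dbl>    <dbl>     <dbl>     <int> <int>
1 GM     pve    full       0.00445 0.00000890  0.00753 0.0000121         4     4
2 GM     strict full       0.00453 0.00000872  0.00770 0.0000123         4     4
3 WM     pve    full       0.00332 0.0000128   0.00479 0.0000120         4     4
4 WM     strict full       0.00313 0.0000133   0.00438 0.0000120         4     4

WM ~ GM per-subject CV: OLS fit: y = 0.3939 x + 0.001345, R^2 = 1.000 (n = 8)
```

The strict-threshold means recover the generating values (4.53 vs 4.6 × 10⁻³
in control GM, 7.70 vs 7.9 × 10⁻³ in the elevated group) within a few
percent: the residual bias is thermal noise plus the small amount of genuine
signal RETROICOR's 8 regressors absorb. The WM~GM slope ≈ 0.39 is the WM:GM
amplitude ratio the cohorts were generated with; R² ≈ 1 here because phantom
subjects differ only by realization noise (real cohorts add true
between-subject spread). Each `tidy()`-able result has an `autoplot()`
method: `autoplot(cv_map(...))` renders a CV slice, `autoplot(study$report)`
the group comparison.

Per-subject processing of your own data:

```r
bold   <- read_bold("bold.nii.gz", slice_offsets_s = offsets)
physio <- read_physio("cardiac.tsv", "resp.tsv", scan_duration_s = 360)
clean  <- bold |>
  regress_confounds(retroicor_regressors(physio, bold)) |>
  regress_confounds(regressor_set(read_motion("motion.par"))) |>
  detrend_linear()
cv     <- cv_map(clean, read_mask("brain_mask.nii.gz"))
strict_threshold_mean(cv, read_pve("pve_gm.nii.gz", "GM"))
```

A thin command-line wrapper lives at `inst/cli/boldcv`
(`boldcv phantom|phantom-study|subject|run --config FILE --out DIR`).

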