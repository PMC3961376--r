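---
title: "Fluctuation-amplitude (CV) analysis of resting-state BOLD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-amplitude (CV) analysis of resting-state BOLD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The quantity being measured

Resting-state BOLD time series show spontaneous low-frequency (f < 0.1 Hz)
fluctuations whose *amplitude* — not just their spatial correlation — carries
physiological information about vasomotor reactivity. The package's core
statistic is the per-voxel coefficient of variation

$$\mathrm{CV}_i = \frac{\sigma_i}{\mu_i},$$

the temporal standard deviation of a voxel's signal divided by its temporal
mean, computed after nuisance removal. CV is dimensionless and scale
invariant, which is what makes it comparable across scanners, coils and
subjects. Typical cortical values are a few parts per thousand: around
4–5 × 10⁻³ in gray matter and 3 × 10⁻³ in white matter for young healthy
adults, rising substantially with vascular ageing and disease.

Throughout the package the *sample* standard deviation (n − 1 denominator) is
used; the choice is arbitrary at n = 180 (a 0.3% effect) but is fixed and
documented so results reproduce bit for bit.

## The processing chain

Per subject the chain is:

1. **RETROICOR** (optional): cardiac and respiratory phases are evaluated at
   each slice's acquisition time and expanded in a 2nd-order Fourier basis
   (8 regressors); the fitted component is removed by per-voxel OLS.
2. **Motion regression**: the 6 rigid-body realignment parameter time courses
   are regressed out (as-is: no derivatives or squares).
3. **First-order detrending**: the least-squares line is removed, leaving the
   temporal mean intact.
4. **CV mapping**: full band, and optionally within frequency bands.
5. **Tissue aggregation** to per-subject scalars.
6. **Cohort comparison** by exact Wilcoxon rank-sum tests.

Every confound-removal step uses mean-centred regressors plus an intercept,
so the voxel's temporal mean — the CV denominator — is preserved exactly, the
residual is orthogonal to the regressors, and temporal variance can only
decrease. This also settles an ambiguity that the chain's description leaves
open: the CV denominator is the same before and after detrending, because
detrending preserves the mean.

The stage order (RETROICOR first, then motion regression, then detrending)
follows the usual reading of the processing narrative: physiological
correction is applied to reconstructed images before the standard nuisance
chain. Because all three stages are linear projections the composition is
deterministic and idempotent, and toggling any stage off reduces the chain
exactly to the remaining projections.

### RETROICOR details

* Cardiac phase is piecewise linear between detected pulse peaks:
  $\phi_c(t) = 2\pi (t - t_k)/(t_{k+1} - t_k)$.
* Respiratory phase uses amplitude histogram equalization (100 bins) with the
  sign of the smoothed derivative, giving $\phi_r \in (-\pi, \pi]$: belt
  amplitude does not advance linearly in time, so phase is defined through
  the run-wide amplitude distribution.
* Harmonic order is fixed at 2 (the standard "low-order" model), giving
  8 regressors per slice.
* Peak detection: 100 ms moving-average smoothing, adaptive threshold
  (rolling median plus half the rolling 2 s amplitude range), 0.25 s
  refractory period (a 240 bpm ceiling), and parabolic sub-sample refinement
  of each maximum.

### A known limitation: spurious removal at TR = 2 s

With 8 regressors against 180 samples, OLS removes a small amount of genuine
signal even when no physiological component is present. Two mechanisms make
this worse than the naive dof count suggests: realistic cardiac RR jitter
(±0.13 Hz around 1.13 Hz) spreads the cardiac regressors' spectrum into the
0.01–0.1 Hz band, and at TR = 2 s the *second respiratory harmonic*
(2 × 0.3 Hz = 0.6 Hz) aliases to ≈ 0.1 Hz — directly into the band of
interest. Measured on phantoms, the median spurious per-voxel CV change is
≈ 1–2% under these conditions, and below 1% only when the cardiac trace is
nearly regular and the respiratory rate avoids the aliasing collision. This
is a property of RETROICOR at long TR, not of the implementation; it is far
below the ≈ 70% group difference the statistic is used to detect.

## Frequency-band decomposition

Band-limited CVs use a zero-phase ideal (DFT-mask) filter: the mean-removed
series is Fourier transformed, bins whose alias-folded frequency falls
outside the half-open interval (low, high] are zeroed, and the filtered
series' standard deviation is divided by the *original* mean. The ideal
filter was chosen over an IIR design because it makes the band decomposition
exact: over any partition of (0, Nyquist] the band variances sum to the total
detrended variance to ~1e-10 relative (Parseval), and widening a band can
never decrease the band CV. The cost is the absence of tapering: for short
series, spectral leakage between *off-grid* frequencies and bin edges is not
controlled. The default bands (0.01–0.014, 0.014–0.025, 0.025–0.1 Hz) target
the fast initial decay of the resting-state spectrum; at 180 volumes and
TR 2 s they hold 2, 4 and 27 DFT bins respectively.

## Tissue aggregation

Three estimators reduce a CV map to a per-subject tissue scalar:

* **PVE-weighted** (method a): $\sum_i \mathrm{PVE}_i \mathrm{CV}_i / \sum_i
  \mathrm{PVE}_i$ over brain voxels — no threshold to choose; the weight sum
  is the effective voxel count.
* **Strict threshold** (method b): plain mean over voxels with PVE strictly
  greater than 0.8 (a voxel at exactly 0.8 is excluded). A warning fires
  below 2000 surviving voxels, the scale at which subject means start to
  look undersampled.
* **Template / ROI** (method c): plain mean over a pre-aligned binary mask
  (standard-space tissue template, or a manually drawn ROI such as a
  periventricular region).

Voxels whose temporal mean falls below 10⁻⁶ × the in-mask median are flagged
invalid and carry zero weight in *every* aggregator: a near-zero denominator
makes CV numerically meaningless, and such voxels (background bleed,
vessels) must not poison tissue means. The registration that would align
templates to subject space is out of scope — masks must arrive on the
analysis grid, and mismatched grids are a hard error rather than a silent
resample.

## Cohort statistics

Group comparisons use a two-sample Wilcoxon rank-sum test with the two-sided
p-value defined as $2\min(P(W \le w), P(W \ge w))$ capped at 1. The null
distribution is exact wherever feasible: a dynamic-programming enumeration of
rank-sum counts for untied samples up to n = 12 per group (equivalent to — and
property-tested against — brute-force enumeration of all label assignments),
full permutation enumeration for tied pooled samples up to N = 20, and a
tie-corrected, continuity-corrected normal approximation beyond. At the
study's n = 10 + 10 the exact and approximate p agree to well under 0.01.
P-values across tissue × method × band strata are reported unadjusted, and
0.05 is the annotated significance threshold.

The across-subject WM-versus-GM relationship is summarised by an OLS fit
with R²; the caller chooses the axis orientation (the package regresses WM
on GM in cohort reports, matching the convention in which the fitted slope
is the WM:GM amplitude ratio, ≈ 1:3).

## The synthetic phantom

No imaging data accompanies the analysis, so validation rests on a
signal-level phantom with known ground truth. Per voxel,

$$S_i(t) = S_{0,i}\,[1 + f_i(t) + d\,t + p_i(t)] + \varepsilon_i(t)$$

* **Geometry**: concentric ellipsoids — GM shell, WM core, two ventricular
  CSF bodies — with hard labels softened by a small Gaussian kernel
  (σ = 0.6 voxel) and renormalised so PVE fractions sum to exactly 1 inside
  the brain envelope. A 32³ grid yields >2000 voxels above PVE 0.8 in each
  tissue, matching the adequacy the analysis assumes; tests run mostly at
  20³ × 120 volumes for speed, with run-length-sensitive checks at 180.
* **Intrinsic fluctuations** $f_i$: Fourier synthesis on the run's exact DFT
  grid with deterministic power-law amplitudes and independent random phases
  per voxel. Because every component sits on a DFT bin, the sample SD equals
  the target CV up to the n/(n−1) factor — the generator is *calibrated*, so
  parameter-recovery tests measure pipeline error, not Monte-Carlo luck.
  The spectral exponent defaults to −2.5: with the three analysis bands'
  very unequal widths, the integrated band variance only decreases across
  bands (the observed pattern — most power below 0.025 Hz) for slopes
  steeper than about −2; a 1/f spectrum would let the wide 0.025–0.1 Hz band
  dominate. The exponent is a configuration knob, as the true spectrum is
  known only through its band contributions.
* **Drift** d·t: 1% of baseline over the 6-minute run, removed exactly by
  detrending.
* **Physiology** $p_i$: built from the ground-truth cardiac phase as a
  2-harmonic series plus the respiratory oscillator cosine, sampled at each
  voxel's slice time (interleaved acquisition, evenly spaced offsets). BOLD
  pulsatility is smoother than the photoplethysmogram waveform, and a
  low-order phase model is exactly the structure RETROICOR assumes — the
  phantom tests whether the pipeline removes what the noise model says is
  there. Amplitudes are largest in CSF (0.6%), intermediate in GM (0.2%),
  smallest in WM (0.1%), mirroring where pulsatility concentrates.
* **Thermal noise**: white Gaussian at 0.05% of baseline, keeping thermal
  variance below 5% of fluctuation variance even at the WM level — the
  regime in which CV recovery is meaningful.
* **Cardiac trace**: Gaussian pulse train with RR intervals jittered at
  11.5% relative SD around 1.13 Hz (the reported 1.13 ± 0.13 Hz);
  respiratory belt: amplitude-modulated quasi-sinusoid at 0.3 Hz
  (18 breaths/min). Note that the *mean of 1/RR* exceeds the nominal rate by
  ≈ jitter² (Jensen's inequality), ~1.3% at the default jitter — rate-recovery
  checks therefore use low-jitter traces.

The slow components (intrinsic, drift) are evaluated at volume times; only
the fast physiological component sees per-slice timing. Sub-TR offsets are
negligible below 0.1 Hz, and this keeps the CV calibration exact.

What the phantom deliberately does **not** emulate: k-space/MR physics (T2*
decay, EPI distortion), spatially correlated noise, true between-subject
variability of the intrinsic CV (subjects within a phantom cohort differ
only by realization noise, so cohort SDs are far smaller than in vivo and
across-subject R² values are near 1), non-rigid brain motion, and white
matter hyperintensities. Passing recovery tests therefore demonstrates that
the pipeline is unbiased under the assumed signal model, not that the model
captures every feature of real data.

## Problem sizes and numerical choices

* Recovery studies run 10 subjects per cohort at 32³ × 180, the protocol's
  run length on a desk-scale grid.
* The rank-sum DP is O(n₁ n₂ N) and exact; enumeration fallbacks are capped
  at C(20, 10) ≈ 1.8 × 10⁵ subsets.
* Degenerate inputs: constant traces error in phase estimators; all-zero
  voxels pass through confound removal unchanged; empty masks, empty bands,
  sub-Nyquist violations and rank-deficient designs (pruned, with warning)
  are all explicit errors or warnings rather than silent propagation.
* All randomness flows from a single integer seed per subject; identical
  specs reproduce subjects bit for bit.
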