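#' Specification of a synthetic BOLD phantom subject
#'
#' Collects every knob of the signal-level phantom: acquisition geometry and
#' timing, per-tissue intrinsic fluctuation amplitude (as a coefficient of
#' variation), the spectral shape of the intrinsic fluctuations, scanner
#' drift, quasi-periodic cardiac and respiratory components, and thermal
#' noise. Defaults mirror a 6-minute resting-state protocol (TR 2 s, 180
#' volumes) on a desk-scale 32^3 grid; `tissue_cv` defaults to the young
#' healthy control levels (GM 4.6e-3, WM 3.0e-3).
#'
#' @param grid_shape Integer length-3 voxel grid, each dimension >= 16.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param tr_s Repetition time, seconds.
#' @param n_timepoints Number of volumes (>= 2).
#' @param n_slices Number of slices; defaults to `grid_shape[3]`.
#' @param tissue_cv Named numeric: target intrinsic CV per tissue (GM, WM, CSF),
#'   dimensionless.
#' @param fluct_band_hz Length-2: low/high cutoff of the intrinsic fluctuation
#'   spectrum, Hz. Upper cutoff must not exceed Nyquist `1/(2 tr_s)`.
#' @param spectral_exponent Power-law slope of the intrinsic fluctuation power
#'   spectrum inside the band (power ~ f^exponent). The default -2.5 makes the
#'   band-limited CVs decrease across the three analysis bands — the fast
#'   initial spectral decay seen in resting-state BOLD, where most fluctuation
#'   power sits below 0.025 Hz. Shallower slopes (e.g. -1) concentrate *per-bin*
#'   power at low frequency but let the much wider 0.025-0.1 Hz band win on
#'   integrated variance.
#' @param drift_slope_frac_per_scan Linear scanner drift as a signal fraction
#'   accumulated over the whole run.
#' @param cardiac_freq_hz Mean cardiac frequency, Hz.
#' @param cardiac_jitter_frac Relative standard deviation of RR intervals.
#' @param resp_freq_hz Respiratory frequency, Hz.
#' @param physio_amp_frac Named numeric: fractional amplitude of the combined
#'   cardiac+respiratory BOLD component per tissue; largest in CSF (ventricle
#'   boundaries carry the strongest pulsatility), smallest in WM.
#' @param thermal_sd_frac Thermal (white) noise SD as a fraction of baseline.
#' @param physio_sample_hz Sampling rate of the synthetic physio traces, Hz.
#' @param smooth_sigma_vox Gaussian sigma (voxels) used to soften the hard
#'   tissue labels into partial-volume fractions; 0 gives binary labels.
#' @param seed RNG seed driving all randomness of this subject.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size_mm = c(3.5, 3.5, 3.5),
                         tr_s = 2,
                         n_timepoints = 180L,
                         n_slices = grid_shape[3],
                         tissue_cv = c(GM = 4.6e-3, WM = 3.0e-3, CSF = 9.0e-3),
                         fluct_band_hz = c(0.01, 0.1),
                         spectral_exponent = -2.5,
                         drift_slope_frac_per_scan = 0.01,
                         cardiac_freq_hz = 1.13,
                         cardiac_jitter_frac = 0.115,
                         resp_freq_hz = 0.3,
                         physio_amp_frac = c(GM = 2e-3, WM = 1e-3, CSF = 6e-3),
                         thermal_sd_frac = 5e-4,
                         physio_sample_hz = 100,
                         smooth_sigma_vox = 0.6,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               tr_s = tr_s, n_timepoints = as.integer(n_timepoints),
               n_slices = as.integer(n_slices),
               tissue_cv = tissue_cv, fluct_band_hz = as.numeric(fluct_band_hz),
               spectral_exponent = spectral_exponent,
               drift_slope_frac_per_scan = drift_slope_frac_per_scan,
               cardiac_freq_hz = cardiac_freq_hz,
               cardiac_jitter_frac = cardiac_jitter_frac,
               resp_freq_hz = resp_freq_hz,
               physio_amp_frac = physio_amp_frac,
               thermal_sd_frac = thermal_sd_frac,
               physio_sample_hz = physio_sample_hz,
               smooth_sigma_vox = smooth_sigma_vox,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 1))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (s$tr_s <= 0) stop("tr_s must be > 0", call. = FALSE)
  if (s$n_timepoints < 2L) stop("n_timepoints must be >= 2", call. = FALSE)
  tis <- c("GM", "WM", "CSF")
  if (!all(tis %in% names(s$tissue_cv)))
    stop("tissue_cv must name GM, WM and CSF", call. = FALSE)
  if (any(s$tissue_cv < 0) || any(s$physio_amp_frac < 0) || s$thermal_sd_frac < 0)
    stop("CVs and fractional amplitudes must be nonnegative", call. = FALSE)
  nyq <- 1 / (2 * s$tr_s)
  if (length(s$fluct_band_hz) != 2L || s$fluct_band_hz[1] <= 0 ||
      s$fluct_band_hz[2] <= s$fluct_band_hz[1])
    stop("fluct_band_hz must be 0 < low < high", call. = FALSE)
  if (s$fluct_band_hz[2] > nyq + 1e-12)
    stop(sprintf("fluct_band_hz upper cutoff %g exceeds Nyquist %g",
                 s$fluct_band_hz[2], nyq), call. = FALSE)
  if (s$physio_sample_hz < 10 * s$cardiac_freq_hz)
    stop("physio_sample_hz must be at least 10x the cardiac frequency", call. = FALSE)
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, TR %g s x %d volumes, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$tr_s, x$n_timepoints, x$seed))
  cat(sprintf("  tissue CV: GM %.3g, WM %.3g, CSF %.3g; band %g-%g Hz, exponent %g\n",
              x$tissue_cv[["GM"]], x$tissue_cv[["WM"]], x$tissue_cv[["CSF"]],
              x$fluct_band_hz[1], x$fluct_band_hz[2], x$spectral_exponent))
  invisible(x)
}

# separable 3D Gaussian smoothing with zero padding (kernel radius 3 sigma)
gauss_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    pad <- matrix(0, r, ncol(m))
    f <- stats::filter(rbind(pad, m, pad), k, sides = 2)
    m2 <- matrix(f[(r + 1):(r + d[axis]), ], nrow = d[axis])
    aperm(array(m2, d[perm]), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Build the phantom head geometry
#'
#' Concentric-ellipsoid head model: an outer gray-matter shell, an inner
#' white-matter core and two small central ventricular CSF compartments.
#' Hard labels are softened with a small Gaussian kernel and renormalised to
#' fractional partial-volume maps that sum to 1 inside the brain envelope and
#' are 0 outside. With `smooth_sigma_vox = 0` the maps are exactly binary.
#'
#' @param spec A [phantom_spec()]; each grid dimension must be >= 16.
#' @return Named list of [pve_map()]s (`GM`, `WM`, `CSF`) plus a logical
#'   attribute-free brain envelope under `$brain` (a [tissue_mask()]).
#' @export
build_geometry <- function(spec) {
  g <- spec$grid_shape
  if (any(g < 16L))
    stop("grid too small to contain GM shell, WM core and ventricles (need >= 16 per axis)",
         call. = FALSE)
  ctr <- (g + 1) / 2
  ax <- function(frac) frac * g / 2
  idx <- lapply(1:3, function(i) (seq_len(g[i]) - ctr[i]))
  # normalized squared radius for an ellipsoid with semi-axes `semi`
  rho2 <- function(semi, offset = c(0, 0, 0)) {
    u <- lapply(1:3, function(i) ((idx[[i]] - offset[i]) / semi[i])^2)
    outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`)
  }
  brain <- rho2(ax(0.88)) <= 1
  wm <- rho2(ax(0.62)) <= 1
  vent_semi <- pmax(ax(c(0.10, 0.30, 0.16)), 1)
  csf <- (rho2(vent_semi, c(+ax(0.14)[1], 0, 0)) <= 1) |
         (rho2(vent_semi, c(-ax(0.14)[1], 0, 0)) <= 1)
  lab_csf <- brain & csf
  lab_wm <- brain & wm & !lab_csf
  lab_gm <- brain & !wm & !lab_csf
  if (!any(lab_gm) || !any(lab_wm) || !any(lab_csf))
    stop("grid too small: an empty tissue compartment was produced", call. = FALSE)
  s_gm <- gauss_smooth_3d(lab_gm + 0, spec$smooth_sigma_vox)
  s_wm <- gauss_smooth_3d(lab_wm + 0, spec$smooth_sigma_vox)
  s_csf <- gauss_smooth_3d(lab_csf + 0, spec$smooth_sigma_vox)
  tot <- s_gm + s_wm + s_csf          # = smoothed brain indicator
  envelope <- tot > 0.5
  norm <- ifelse(envelope, tot, Inf)
  z <- array(0, g)
  pve <- list(GM = ifelse(envelope, s_gm / norm, z),
              WM = ifelse(envelope, s_wm / norm, z),
              CSF = ifelse(envelope, s_csf / norm, z))
  # guard against fp dust just outside [0,1]
  pve <- lapply(pve, function(p) array(pmin(pmax(p, 0), 1), g))
  out <- lapply(names(pve), function(t) pve_map(pve[[t]], t))
  names(out) <- names(pve)
  out$brain <- tissue_mask(array(envelope + 0, g), "threshold")
  out
}

#' Synthesize cardiac and respiratory recordings
#'
#' Cardiac trace: a train of pulse-like (Gaussian) waveforms whose peak-to-peak
#' (RR) intervals are drawn around `1/cardiac_freq_hz` with the configured
#' relative jitter. Respiratory trace: a quasi-sinusoid at `resp_freq_hz` with
#' slow amplitude modulation. Both cover the full scan and carry their ground
#' truth (true cardiac peak times, true respiratory oscillator phase) as
#' attributes for validation.
#'
#' @param spec A [phantom_spec()].
#' @param duration_s Trace duration; defaults to the scan duration.
#' @param noise_frac Additive white noise SD as a fraction of the cardiac pulse
#'   amplitude (also applied to the respiratory trace).
#' @return A [physio_trace()] with attributes `peak_times_s` (true cardiac
#'   peaks) and `resp_phase0` (respiratory phase at t = 0).
#' @export
synth_physio <- function(spec, duration_s = spec$tr_s * spec$n_timepoints,
                         noise_frac = 0) {
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed + 1000L, {
    mu <- 1 / spec$cardiac_freq_hz
    n_beats <- ceiling(duration_s / mu * 1.3) + 8L
    rr <- stats::rnorm(n_beats, mu, spec$cardiac_jitter_frac * mu)
    rr <- pmax(rr, 0.35 * mu)           # physiological floor
    first <- stats::runif(1, 0.1, 0.9) * mu
    peaks <- first + cumsum(c(0, rr))
    peaks <- peaks[peaks < duration_s + 2 * mu]
    tt <- seq(0, duration_s, by = 1 / spec$physio_sample_hz)
    card <- rep(0, length(tt))
    width <- 0.09 * mu
    for (p in peaks) {
      sel <- which(abs(tt - p) < 4 * width)
      card[sel] <- card[sel] + exp(-0.5 * ((tt[sel] - p) / width)^2)
    }
    phase0 <- stats::runif(1, 0, 2 * pi)
    resp <- (1 + 0.15 * sin(2 * pi * 0.015 * tt + phase0 / 3)) *
      sin(2 * pi * spec$resp_freq_hz * tt + phase0)
    if (noise_frac > 0) {
      card <- card + stats::rnorm(length(tt), 0, noise_frac)
      resp <- resp + stats::rnorm(length(tt), 0, noise_frac)
    }
    out <- physio_trace(card, spec$physio_sample_hz, resp, spec$physio_sample_hz)
    attr(out, "peak_times_s") <- peaks[peaks >= 0 & peaks <= duration_s]
    attr(out, "resp_phase0") <- phase0
    out
  })
}

# ground-truth cardiac phase at arbitrary times, from the true peak train
truth_cardiac_phase <- function(physio, t) {
  pk <- attr(physio, "peak_times_s")
  cardiac_phase(cardiac_peaks(pk), t)
}

#' Synthesize a 4D BOLD phantom subject
#'
#' Per voxel i the generated signal is
#' `S_i(t) = S0_i * (1 + f_i(t) + d*t + p_i(t)) + eps_i(t)`:
#' a baseline `S0` mixed from tissue baselines by partial volume, a zero-mean
#' band-limited intrinsic fluctuation `f_i` whose temporal standard deviation
#' equals the PVE-mixed target tissue CV (Fourier synthesis of a power-law
#' spectrum on the run's exact DFT frequency grid, with independent random
#' phases per voxel), a linear scanner drift, a cardiac+respiratory component
#' `p_i` evaluated at each voxel's slice acquisition time with tissue-dependent
#' amplitude, and white thermal noise. The slow intrinsic and drift components
#' are evaluated at volume times (sub-TR slice offsets are negligible below
#' 0.1 Hz); only the fast physiological component sees per-slice timing.
#'
#' Because the intrinsic component uses deterministic spectral amplitudes with
#' random phases on the exact DFT grid, the per-voxel sample CV equals the
#' target CV up to the `n/(n-1)` sample-variance factor, making the generator a
#' calibrated ground truth for parameter-recovery tests.
#'
#' @param spec A [phantom_spec()].
#' @param pve Tissue PVE maps from [build_geometry()] (regenerated if omitted).
#' @param physio A [physio_trace()] from [synth_physio()] (regenerated if
#'   omitted).
#' @param motion Optional [motion_params()] to inject; when supplied, a small
#'   motion-correlated signal component is added so motion regression has
#'   something to remove. `NULL` (default) injects zero motion.
#' @return A `phantom_subject`: list with elements `bold` ([bold_series()]),
#'   `pve` (list of [pve_map()]s + brain mask), `physio`, `motion`,
#'   `truth_cv` (3D array of the intrinsic CV used in generation) and `spec`.
#' @export
synth_bold <- function(spec, pve = NULL, physio = NULL, motion = NULL) {
  validate_phantom_spec(spec)
  if (is.null(pve)) pve <- build_geometry(spec)
  if (is.null(physio)) physio <- synth_physio(spec)
  g <- spec$grid_shape
  nt <- spec$n_timepoints
  tr <- spec$tr_s
  if (!identical(dim(pve$GM$data), g))
    stop("PVE maps and phantom grid have different shapes", call. = FALSE)

  # per-voxel mixes
  base_au <- c(GM = 1000, WM = 850, CSF = 1300)
  s0 <- base_au[["GM"]] * pve$GM$data + base_au[["WM"]] * pve$WM$data +
    base_au[["CSF"]] * pve$CSF$data
  truth_cv <- spec$tissue_cv[["GM"]] * pve$GM$data +
    spec$tissue_cv[["WM"]] * pve$WM$data + spec$tissue_cv[["CSF"]] * pve$CSF$data
  truth_cv[s0 == 0] <- 0
  amp_phys <- spec$physio_amp_frac[["GM"]] * pve$GM$data +
    spec$physio_amp_frac[["WM"]] * pve$WM$data +
    spec$physio_amp_frac[["CSF"]] * pve$CSF$data

  # intrinsic fluctuation frequency grid: exact DFT bins inside the band
  freqs <- seq_len(floor(nt / 2)) / (nt * tr)
  inband <- freqs >= spec$fluct_band_hz[1] - 1e-12 &
    freqs <= spec$fluct_band_hz[2] + 1e-12
  if (!any(inband))
    stop("fluctuation band contains no resolvable frequency for this run length",
         call. = FALSE)
  fb <- freqs[inband]
  a <- fb^(spec$spectral_exponent / 2)
  a <- a / sqrt(sum(a^2) / 2)           # unit process SD before scaling by CV

  brain_idx <- which(s0 > 0)
  nv <- length(brain_idx)
  t_vol <- (seq_len(nt) - 1) * tr

  # interleaved slice acquisition (odd slices first), evenly spaced offsets
  n_sl <- g[3]
  acq_order <- c(seq(1, n_sl, by = 2), seq(2, n_sl, by = 2))
  offsets <- numeric(n_sl)
  offsets[acq_order] <- (seq_len(n_sl) - 1) / n_sl * tr

  withr::with_seed(spec$seed + 2000L, {
    fl <- matrix(0, nv, nt)
    for (j in seq_along(fb)) {
      ph <- stats::runif(nv, 0, 2 * pi)
      fl <- fl + a[j] * cos(outer(rep(2 * pi * fb[j], nv), t_vol) + ph)
    }
    fl <- fl * truth_cv[brain_idx]

    drift <- spec$drift_slope_frac_per_scan * t_vol / (nt * tr)

    # physiological component from ground-truth phases, per slice time
    phase0 <- attr(physio, "resp_phase0")
    rel <- fl + matrix(drift, nv, nt, byrow = TRUE)
    flat <- matrix(0, prod(g), nt)
    flat[brain_idx, ] <- rel
    zidx <- slice.index(array(0L, g), 3)
    for (z in seq_len(n_sl)) {
      ts <- t_vol + offsets[z]
      pc <- truth_cardiac_phase(physio, ts)
      card <- (cos(pc) + 0.3 * cos(2 * pc)) / 1.3
      resp <- cos(2 * pi * spec$resp_freq_hz * ts + phase0)
      pwave <- 0.6 * card + 0.4 * resp
      sl <- which(zidx == z & s0 > 0)
      if (length(sl))
        flat[sl, ] <- flat[sl, ] + outer(amp_phys[sl], pwave)
    }
    sig <- array(as.vector(s0) * (1 + flat), c(g, nt))
    if (!is.null(motion)) {
      motion <- motion_params(motion)
      if (nrow(motion) != nt)
        stop("injected motion must have one row per timepoint", call. = FALSE)
      mw <- scale(motion, scale = FALSE) %*% stats::rnorm(6, 0, 1)
      sens <- array(stats::runif(prod(g), 0.5, 1.5), g)
      sig <- sig + as.vector(s0 * sens * 2e-3) *
        rep(as.vector(mw) / max(abs(mw), 1e-12), each = prod(g))
    }
    if (spec$thermal_sd_frac > 0)
      sig <- sig + as.vector(s0) * spec$thermal_sd_frac *
        array(stats::rnorm(length(sig)), dim(sig))
  })

  if (is.null(motion)) motion <- motion_params(matrix(0, nt, 6))
  structure(
    list(bold = bold_series(sig, tr, slice_axis = 3L, slice_offsets_s = offsets),
         pve = pve, physio = physio, motion = motion,
         truth_cv = truth_cv, spec = spec),
    class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> seed %d, %s grid x %d volumes\n",
              x$spec$seed, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$n_timepoints))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Produces `n` phantom subjects sharing one geometry and parameter set but
#' with independent seeds (derived as `seed_base + subject index`).
#'
#' @param n Number of subjects.
#' @param spec Template [phantom_spec()]; its seed field is overridden per
#'   subject.
#' @param seed_base Base seed; subject k uses `seed_base + k`.
#' @param motion Optional function `(spec) -> motion_params` supplying injected
#'   motion per subject; default none.
#' @return List of `phantom_subject`s.
#' @export
phantom_cohort <- function(n, spec = phantom_spec(), seed_base = spec$seed,
                           motion = NULL) {
  geo <- build_geometry(spec)
  lapply(seq_len(n), function(k) {
    sk <- spec
    sk$seed <- as.integer(seed_base + k)
    mo <- if (is.null(motion)) NULL else motion(sk)
    synth_bold(sk, pve = geo, physio = synth_physio(sk), motion = mo)
  })
}

#' Write a phantom subject to disk in the package's on-disk formats
#'
#' BOLD as 4D NIfTI, PVE maps / brain mask / ground-truth CV as 3D NIfTI,
#' physio as two 2-column TSVs and motion as 6-column whitespace text.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the files written.
#' @export
write_phantom_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    bold = file.path(dir, "bold.nii.gz"),
    gm = file.path(dir, "pve_gm.nii.gz"),
    wm = file.path(dir, "pve_wm.nii.gz"),
    csf = file.path(dir, "pve_csf.nii.gz"),
    brain = file.path(dir, "brain_mask.nii.gz"),
    truth = file.path(dir, "truth_cv.nii.gz"),
    cardiac = file.path(dir, "cardiac.tsv"),
    resp = file.path(dir, "respiratory.tsv"),
    motion = file.path(dir, "motion.par"))
  write_bold(subject$bold, paths$bold)
  write_volume(subject$pve$GM$data, paths$gm)
  write_volume(subject$pve$WM$data, paths$wm)
  write_volume(subject$pve$CSF$data, paths$csf)
  write_volume(subject$pve$brain$data + 0, paths$brain)
  write_volume(subject$truth_cv, paths$truth)
  write_physio(subject$physio, paths$cardiac, paths$resp)
  write_motion(subject$motion, paths$motion)
  invisible(paths)
}
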