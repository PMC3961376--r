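test_that("geometry with zero smoothing gives exactly binary labels", {
  sp <- small_spec(smooth_sigma_vox = 0)
  geo <- build_geometry(sp)
  for (t in c("GM", "WM", "CSF"))
    expect_true(all(geo[[t]]$data %in% c(0, 1)))
})

test_that("PVE fractions partition unity inside the brain and vanish outside", {
  geo <- small_geometry()
  tot <- geo$GM$data + geo$WM$data + geo$CSF$data
  brain <- geo$brain$data
  expect_lt(max(abs(tot[brain] - 1)), 1e-9)
  expect_identical(unique(as.vector(tot[!brain])), 0)
})

test_that("a 32^3 grid supplies enough high-PVE voxels for stable tissue means", {
  geo <- build_geometry(phantom_spec())
  expect_gte(sum(geo$GM$data > 0.8), 2000)
  expect_gte(sum(geo$WM$data > 0.8), 2000)
})

test_that("too-small grids are rejected", {
  expect_error(build_geometry(phantom_spec(grid_shape = c(8L, 8L, 8L))),
               "too small")
})

test_that("zero RR jitter gives perfectly regular cardiac peaks", {
  sp <- small_spec(cardiac_jitter_frac = 0)
  ph <- synth_physio(sp)
  rr <- diff(attr(ph, "peak_times_s"))
  expect_equal(rr, rep(1 / sp$cardiac_freq_hz, length(rr)), tolerance = 1e-12)
})

test_that("generated RR intervals average to the requested cardiac frequency", {
  sp <- small_spec()
  ph <- synth_physio(sp, duration_s = 360)
  # oracle: direct average of the ground-truth intervals
  rate <- mean(1 / diff(attr(ph, "peak_times_s")))
  expect_lt(abs(rate / sp$cardiac_freq_hz - 1), 0.02)
})

test_that("the degenerate generator produces a time-constant series with zero CV", {
  sp <- small_spec(tissue_cv = c(GM = 0, WM = 0, CSF = 0),
                   drift_slope_frac_per_scan = 0,
                   physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                   thermal_sd_frac = 0)
  sub <- synth_bold(sp, pve = small_geometry())
  rng <- apply(matrix(sub$bold$data, ncol = sp$n_timepoints), 1, function(x) diff(range(x)))
  expect_equal(max(rng), 0)
  cv <- cv_map(sub$bold, small_geometry()$brain)
  expect_equal(max(cv$data), 0)
})

test_that("a single-bin fluctuation band reduces to a sinusoid with CV a/sqrt(2)", {
  # with one DFT bin the process is a pure sinusoid of amplitude a = cv*sqrt(2);
  # its sample SD over whole periods is exactly (a/sqrt(2)) * sqrt(n/(n-1))
  nt <- 120L
  sp <- small_spec(n_timepoints = nt, fluct_band_hz = c(0.0200, 0.0215),
                   drift_slope_frac_per_scan = 0,
                   physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                   thermal_sd_frac = 0)
  # 0.0208 Hz = 5 / (120 * 2 s) is the only bin inside the band
  sub <- synth_bold(sp, pve = small_geometry())
  cv <- cv_map(sub$bold, small_geometry()$brain)
  sel <- small_geometry()$GM$data > 0.99
  expected <- sub$truth_cv[sel] * sqrt(nt / (nt - 1))
  expect_lt(max(abs(cv$data[sel] / expected - 1)), 1e-9)
})

test_that("the same seed reproduces a subject bit for bit", {
  sp <- small_spec(seed = 99L)
  a <- synth_bold(sp, pve = small_geometry())
  b <- synth_bold(sp, pve = small_geometry())
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(attr(a$physio, "peak_times_s"), attr(b$physio, "peak_times_s"))
})

test_that("intrinsic fluctuation power is confined to the configured band", {
  sub <- clean_subject()
  sp <- sub$spec
  nt <- sp$n_timepoints
  geo <- small_geometry()
  i <- which(geo$GM$data > 0.99)[1]
  ijk <- arrayInd(i, dim(geo$GM$data))
  x <- sub$bold$data[ijk[1], ijk[2], ijk[3], ]
  x <- x / mean(x) - 1
  pw <- abs(stats::fft(x))^2
  f <- (0:(nt - 1)) / (nt * sp$tr_s)
  fa <- pmin(f, 1 / sp$tr_s - f)
  inband <- fa >= sp$fluct_band_hz[1] - 1e-9 & fa <= sp$fluct_band_hz[2] + 1e-9
  inband[1] <- FALSE
  expect_lt(sum(pw[!inband][-1]) / sum(pw[-1]), 0.01)
})

test_that("sample CV of clean voxels matches the generation target closely", {
  sp <- small_spec(n_timepoints = 512L, drift_slope_frac_per_scan = 0,
                   physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                   thermal_sd_frac = 0)
  sub <- synth_bold(sp, pve = small_geometry())
  cv <- cv_map(sub$bold, small_geometry()$brain)
  sel <- cv$valid & sub$truth_cv > 0
  rel_bias <- mean(cv$data[sel] / sub$truth_cv[sel]) - 1
  expect_lt(abs(rel_bias), 0.02)
})

test_that("truth CV is zero wherever the baseline is zero", {
  sub <- clean_subject()
  s0 <- sub$bold$data[, , , 1]
  expect_true(all(sub$truth_cv[s0 == 0] == 0))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(tr_s = 0), "tr_s")
  expect_error(phantom_spec(fluct_band_hz = c(0.01, 0.3)), "Nyquist")
  expect_error(phantom_spec(tissue_cv = c(GM = -1e-3, WM = 0, CSF = 0)),
               "nonnegative")
  expect_error(phantom_spec(physio_sample_hz = 5), "10x")
  sp <- small_spec()
  sp$fluct_band_hz <- c(0.0201, 0.0205)   # between bins 4 and 5 of a 120 x 2 s run
  expect_error(synth_bold(sp, pve = small_geometry()), "no resolvable frequency")
})
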