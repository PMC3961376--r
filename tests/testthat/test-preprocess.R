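test_that("a perfect confound regresses to a constant at the voxel mean", {
  set.seed(1)
  x <- 100 + sin(2 * pi * (0:119) / 40) * 3
  s <- voxel_series(x)
  out <- regress_confounds(s, regressor_set(cbind(conf = x)))
  expect_equal(as.vector(out$data[1, 1, 1, ]), rep(100, 120), tolerance = 1e-9)
  cv <- cv_map(out, all_mask())
  expect_lt(max(cv$data), 1e-12)
})

test_that("orthogonal regressors leave the series unchanged", {
  tt <- 0:119
  x <- 100 + cos(2 * pi * 5 * tt / 120)          # bin-5 cosine
  reg <- cbind(sin(2 * pi * 7 * tt / 120))       # orthogonal bin-7 sine
  s <- voxel_series(x)
  out <- regress_confounds(s, regressor_set(reg))
  expect_equal(out$data, s$data, tolerance = 1e-10)
})

test_that("confound regression matches an explicit normal-equations oracle", {
  set.seed(42)
  n <- 180
  y <- rnorm(n, 500, 4)
  X <- matrix(rnorm(n * 6), n, 6)
  s <- voxel_series(y)
  out <- regress_confounds(s, regressor_set(X))
  got <- as.vector(out$data[1, 1, 1, ])
  # oracle: solve the normal equations directly for [1, centered X]
  Xd <- cbind(1, scale(X, center = TRUE, scale = FALSE))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  oracle <- y - Xd[, -1, drop = FALSE] %*% beta[-1]
  expect_equal(got, as.vector(oracle), tolerance = 1e-10)
  # residual orthogonal to every regressor column, variance not increased
  resid <- got - mean(got)
  expect_lt(max(abs(t(scale(X, scale = FALSE)) %*% resid)), 1e-8)
  expect_lte(var(got), var(y))
  expect_equal(mean(got), mean(y), tolerance = 1e-12)
})

test_that("confound regression is idempotent and ignores all-zero voxels", {
  set.seed(3)
  arr <- array(rnorm(2 * 2 * 2 * 60, 100, 2), c(2, 2, 2, 60))
  arr[2, 2, 2, ] <- 0
  s <- bold_series(arr, tr_s = 2)
  rs <- regressor_set(matrix(rnorm(60 * 3), 60, 3))
  once <- regress_confounds(s, rs)
  twice <- regress_confounds(once, rs)
  expect_equal(twice$data, once$data, tolerance = 1e-9)
  expect_equal(once$data[2, 2, 2, ], rep(0, 60))
})

test_that("rank-deficient designs are pruned with a warning", {
  set.seed(4)
  X <- matrix(rnorm(60 * 2), 60, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  s <- voxel_series(rnorm(60, 100, 1))
  expect_warning(out <- regress_confounds(s, regressor_set(X)), "rank-deficient")
  clean <- regress_confounds(s, regressor_set(X[, 1:2]))
  expect_equal(out$data, clean$data, tolerance = 1e-9)
})

test_that("linear detrending removes an exact ramp and is idempotent", {
  tt <- 0:119
  s <- voxel_series(100 * (1 + 0.01 * tt / 119))
  out <- detrend_linear(s)
  expect_equal(as.vector(out$data[1, 1, 1, ]),
               rep(mean(100 * (1 + 0.01 * tt / 119)), 120), tolerance = 1e-9)
  again <- detrend_linear(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
})

test_that("detrending a sinusoid-plus-ramp matches a polynomial-fit oracle", {
  tt <- (0:119) * 2
  y <- 200 + 0.05 * tt + 3 * sin(2 * pi * tt / 97)
  out <- detrend_linear(voxel_series(y))
  fit <- lm(y ~ tt)                               # independent polyfit oracle
  oracle <- y - coef(fit)[2] * (tt - mean(tt))
  expect_equal(as.vector(out$data[1, 1, 1, ]), as.vector(oracle),
               tolerance = 1e-10)
})

test_that("cardiac peaks are recovered at the generated heart rate", {
  # near-noiseless trace: mean(1/RR) is only unbiased for the nominal rate
  # when the RR jitter is small (E[1/RR] ~ f*(1 + jitter^2))
  sp <- small_spec(cardiac_jitter_frac = 0.02)
  ph <- synth_physio(sp, duration_s = 360)
  det <- detect_cardiac_peaks(ph)
  rate <- mean(1 / diff(det$peak_times_s))
  expect_lt(abs(rate / sp$cardiac_freq_hz - 1), 0.01)
})

test_that("peak detection matches ground truth within one sample under 5% noise", {
  sp <- small_spec(seed = 21L)
  ph <- synth_physio(sp, duration_s = 120, noise_frac = 0.05)
  truth <- attr(ph, "peak_times_s")
  det <- detect_cardiac_peaks(ph)$peak_times_s
  # every true peak matched by a detection within about one sample; the
  # sub-sample parabolic refinement is noise-limited, so allow half a sample
  # of slack on top of the 10 ms grid
  matched <- vapply(truth,
                    function(p) min(abs(det - p)) <= 1.5 / sp$physio_sample_hz,
                    logical(1))
  expect_true(all(matched))
  expect_equal(length(det), length(truth))
})

test_that("flat traces yield no usable peaks", {
  expect_error(detect_cardiac_peaks(rep(1, 1000), sample_hz = 100), "unusable")
})

test_that("cardiac phase is 0 at peaks, pi at interval midpoints, linear between", {
  pk <- cardiac_peaks(c(1, 1.9, 3.1, 4.0))
  expect_equal(cardiac_phase(pk, c(1, 1.9, 3.1)), c(0, 0, 0))
  expect_equal(cardiac_phase(pk, c(1.45, 2.5, 3.55)), c(pi, pi, pi))
  # jittered intervals: piecewise-linear oracle per interval
  tq <- c(1.2, 2.2, 3.3, 3.9)
  oracle <- c(2 * pi * (1.2 - 1) / 0.9, 2 * pi * (2.2 - 1.9) / 1.2,
              2 * pi * (3.3 - 3.1) / 0.9, 2 * pi * (3.9 - 3.1) / 0.9)
  expect_equal(cardiac_phase(pk, tq), oracle, tolerance = 1e-12)
})

test_that("respiratory phase follows histogram equalization of a sinusoid", {
  fs <- 100
  tt <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * tt)
  # |phase| at the amplitude maximum reaches the top of the cumulative histogram
  t_max <- 2                                       # sin peak at t = 1/(4*0.25) + k/0.25
  ph_max <- resp_phase(x, 1 + 4 * (0:5), sample_hz = fs)
  expect_true(all(abs(abs(ph_max) - pi) < 0.15))
  # monotone within a half-cycle (here: rising limb between trough and peak)
  tq <- seq(3.05, 4.95, by = 0.05)
  ph <- resp_phase(x, tq, sample_hz = fs)
  expect_true(all(diff(ph) >= -1e-9))
  # analytic oracle: equalized phase of a sinusoid is arcsine-distributed in
  # amplitude, so phi(t) ~ pi * (0.5 + asin(sin(theta))/pi) on the rising limb
  theta <- 2 * pi * 0.25 * tq
  oracle <- pi * (0.5 + asin(sin(theta)) / pi)
  expect_lt(max(abs(ph - oracle)), 0.2)
  # inverting the trace flips the sign pattern consistently: on a rising limb
  # of R, -R is falling with complementary amplitude rank, so the equalized
  # phase shifts by -pi: signs flip and |phi| + |phi_inv| ~ pi
  ph_inv <- resp_phase(-x, tq, sample_hz = fs)
  mid <- abs(abs(ph) - pi) > 0.2 & abs(ph) > 0.2   # away from wrap points
  expect_true(all(sign(ph[mid]) == -sign(ph_inv[mid])))
  expect_true(all(abs(abs(ph[mid]) + abs(ph_inv[mid]) - pi) < 0.3))
})

test_that("constant respiratory traces are rejected", {
  expect_error(resp_phase(rep(2, 500), 1, sample_hz = 100), "constant")
})

test_that("RETROICOR designs have 4*order columns and collapse for zero offsets", {
  sp <- small_spec()
  ph <- synth_physio(sp)
  arr <- array(rnorm(4 * 4 * 3 * 120, 100), c(4, 4, 3, 120))
  s0 <- bold_series(arr, tr_s = 2)                     # zero offsets
  rs0 <- retroicor_regressors(ph, s0)
  expect_equal(dim(rs0$matrix)[2], 8)
  expect_true(rs0$slice_specific)
  expect_equal(rs0$matrix[, , 1], rs0$matrix[, , 3])
  s1 <- bold_series(arr, tr_s = 2, slice_offsets_s = c(0, 0.5, 1.0))
  rs1 <- retroicor_regressors(ph, s1)
  expect_gt(max(abs(rs1$matrix[, , 1] - rs1$matrix[, , 2])), 0.1)
})

test_that("RETROICOR removes most injected physiological variance", {
  sp <- small_spec(seed = 31L, tissue_cv = c(GM = 0, WM = 0, CSF = 0),
                   drift_slope_frac_per_scan = 0, thermal_sd_frac = 0,
                   physio_amp_frac = c(GM = 5e-3, WM = 2e-3, CSF = 1e-2))
  geo <- small_geometry()
  sub <- synth_bold(sp, geo, synth_physio(sp))
  clean <- regress_confounds(sub$bold,
                             retroicor_regressors(sub$physio, sub$bold))
  vvar <- function(b) {
    d <- dim(b$data)
    Y <- matrix(b$data, prod(d[1:3]))
    rowSums(sweep(Y, 1, rowMeans(Y))^2) / (d[4] - 1)
  }
  hi <- which(geo$GM$data > 0.9)      # high-physio voxels
  removed <- 1 - vvar(clean)[hi] / vvar(sub$bold)[hi]
  expect_gt(median(removed), 0.9)
})

test_that("RETROICOR removes little real signal from a physio-free phantom", {
  # clean regressors (low cardiac jitter, respiratory harmonics clear of the
  # band after aliasing): spurious per-voxel CV change stays below 1%
  geo <- small_geometry()
  sp_clean <- small_spec(seed = 33L, n_timepoints = 180L,
                         cardiac_jitter_frac = 0.02, resp_freq_hz = 0.23,
                         physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                         thermal_sd_frac = 0, drift_slope_frac_per_scan = 0)
  sub <- synth_bold(sp_clean, geo, synth_physio(sp_clean))
  cv0 <- cv_map(sub$bold, geo$brain)
  cv1 <- cv_map(regress_confounds(sub$bold,
                                  retroicor_regressors(sub$physio, sub$bold)),
                geo$brain)
  rel <- abs(cv1$data[cv0$valid] / cv0$data[cv0$valid] - 1)
  expect_lt(median(rel), 0.01)
  # under jittered cardiac + 0.3 Hz respiration the 2nd respiratory harmonic
  # aliases into the fluctuation band at TR 2 s; removal grows but stays small
  sp_real <- small_spec(seed = 34L, n_timepoints = 180L,
                        physio_amp_frac = c(GM = 0, WM = 0, CSF = 0),
                        thermal_sd_frac = 0, drift_slope_frac_per_scan = 0)
  sub2 <- synth_bold(sp_real, geo, synth_physio(sp_real))
  cv0b <- cv_map(sub2$bold, geo$brain)
  cv1b <- cv_map(regress_confounds(sub2$bold,
                                   retroicor_regressors(sub2$physio, sub2$bold)),
                 geo$brain)
  relb <- abs(cv1b$data[cv0b$valid] / cv0b$data[cv0b$valid] - 1)
  expect_lt(median(relb), 0.03)
})

test_that("mean displacement handles zero, single-step and random-walk motion", {
  expect_equal(mean_displacement(matrix(0, 180, 6)), 0)
  m <- matrix(0, 180, 6)
  m[100:180, 4] <- 1                       # one 1 mm x-translation step
  expect_equal(mean_displacement(m), 1 / 179)
  # 5-frame fixture, hand-computed framewise displacement
  m5 <- rbind(c(0, 0, 0, 0, 0, 0),
              c(0.001, 0, 0, 0.1, 0, 0),
              c(0.001, -0.002, 0, 0.1, 0.2, 0),
              c(0, -0.002, 0.001, 0, 0.2, -0.1),
              c(0, 0, 0.001, 0, 0, -0.1))
  # steps: |drot|*50 + |dtrans| per row
  fd <- c(50 * 0.001 + 0.1,
          50 * 0.002 + 0.2,
          50 * (0.001 + 0.001) + (0.1 + 0.1),
          50 * 0.002 + 0.2)
  expect_equal(mean_displacement(m5), mean(fd), tolerance = 1e-12)
})
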