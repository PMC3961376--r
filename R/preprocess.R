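#' Nuisance regressor set
#'
#' A time-by-k design matrix of confound regressors, optionally slice-specific
#' (one design per slice, as RETROICOR requires).
#'
#' @param matrix Numeric time-by-k matrix, or a 3D array time-by-k-by-slice
#'   when `slice_specific`.
#' @param labels Column names.
#' @param slice_specific Logical.
#' @return A `regressor_set` object.
#' @export
regressor_set <- function(matrix, labels = NULL, slice_specific = FALSE) {
  if (slice_specific) {
    stopifnot(is.array(matrix), length(dim(matrix)) == 3L)
    k <- dim(matrix)[2]
  } else {
    matrix <- as.matrix(matrix)
    k <- ncol(matrix)
  }
  if (k < 1L) stop("need at least one regressor column", call. = FALSE)
  if (is.null(labels)) labels <- paste0("reg", seq_len(k))
  stopifnot(length(labels) == k)
  # a constant-zero column carries no information and breaks pruning logic
  flat <- if (slice_specific) apply(matrix, 2, function(m) all(m == 0))
          else apply(matrix, 2, function(m) all(m == 0))
  if (any(flat))
    stop("regressor column(s) identically zero: ", paste(labels[flat], collapse = ", "),
         call. = FALSE)
  structure(list(matrix = matrix, labels = labels,
                 slice_specific = slice_specific),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  d <- dim(x$matrix)
  cat(sprintf("<regressor_set> %d timepoints x %d columns%s: %s\n", d[1], d[2],
              if (x$slice_specific) sprintf(" x %d slices", d[3]) else "",
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# OLS removal of centered regressors from a time-by-voxel matrix.
# Mean is preserved because the fitted nuisance component is exactly the
# projection of the centered data onto centered regressors.
project_out <- function(Y, X, labels = NULL) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    warning(sprintf("rank-deficient design: dropping %d dependent column(s)%s",
                    ncol(Xc) - qrx$rank,
                    if (!is.null(labels))
                      paste0(" (kept: ", paste(labels[sort(keep)], collapse = ", "), ")")
                    else ""),
            call. = FALSE)
    Xc <- Xc[, sort(keep), drop = FALSE]
    qrx <- qr(Xc)
  }
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  Y - qr.fitted(qrx, Yc)
}

#' Remove confound regressors from a BOLD series by linear regression
#'
#' Per voxel, fits the mean-centered regressors plus an intercept by ordinary
#' least squares and subtracts the fitted nuisance component. The voxel's
#' temporal mean is preserved, the residual is orthogonal to every regressor
#' column, and temporal variance never increases. All-zero voxels pass through
#' unchanged. Rank-deficient designs are pruned with a warning.
#'
#' @param series A [bold_series()].
#' @param regressors A [regressor_set()]; when slice-specific, each slice is
#'   regressed against its own design.
#' @return A [bold_series()] of identical shape.
#' @export
regress_confounds <- function(series, regressors) {
  stopifnot(inherits(series, "bold_series"), inherits(regressors, "regressor_set"))
  nt <- n_timepoints(series)
  d <- dim(series$data)
  if (dim(regressors$matrix)[1] != nt)
    stop("regressor rows must match the number of timepoints", call. = FALSE)
  out <- series$data
  if (regressors$slice_specific) {
    if (series$slice_axis != 3L)
      stop("slice-specific regression supports slice_axis = 3 only", call. = FALSE)
    if (dim(regressors$matrix)[3] != d[3])
      stop("slice-specific design must have one slab per slice", call. = FALSE)
    for (z in seq_len(d[3])) {
      Y <- t(matrix(series$data[, , z, ], nrow = d[1] * d[2]))
      res <- project_out(Y, regressors$matrix[, , z], regressors$labels)
      out[, , z, ] <- array(t(res), c(d[1], d[2], 1, nt))
    }
  } else {
    Y <- t(matrix(series$data, nrow = prod(d[1:3])))      # time x voxel
    res <- project_out(Y, regressors$matrix, regressors$labels)
    out <- array(t(res), d)
  }
  series$data <- out
  series
}

#' Remove first-order (linear) scanner drift
#'
#' Per voxel, the least-squares straight line `a + b t` is fitted and the slope
#' component `b (t - mean(t))` subtracted, preserving the temporal mean. The
#' residual has zero least-squares slope, so the operation is idempotent.
#'
#' @param series A [bold_series()] with at least 3 timepoints.
#' @return Detrended [bold_series()].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  nt <- n_timepoints(series)
  if (nt < 3L) stop("detrending needs at least 3 timepoints", call. = FALSE)
  tt <- frame_times(series)
  tc <- tt - mean(tt)
  d <- dim(series$data)
  Y <- matrix(series$data, nrow = prod(d[1:3]))            # voxel x time
  b <- (Y %*% tc) / sum(tc^2)
  series$data <- array(Y - b %*% t(tc), d)
  series
}

#' Detected cardiac peak times
#'
#' @param peak_times_s Strictly increasing numeric vector of peak times
#'   (seconds).
#' @param refractory_s Minimum allowed peak separation used at construction.
#' @return A `cardiac_peaks` object.
#' @export
cardiac_peaks <- function(peak_times_s, refractory_s = 0.25) {
  p <- as.numeric(peak_times_s)
  if (length(p) < 2L || any(diff(p) <= 0))
    stop("peak times must be strictly increasing (>= 2 peaks)", call. = FALSE)
  structure(list(peak_times_s = p, refractory_s = refractory_s),
            class = "cardiac_peaks")
}

#' @export
print.cardiac_peaks <- function(x, ...) {
  rr <- diff(x$peak_times_s)
  cat(sprintf("<cardiac_peaks> %d peaks over %.4g s, mean rate %.4g Hz\n",
              length(x$peak_times_s), diff(range(x$peak_times_s)), mean(1 / rr)))
  invisible(x)
}

#' Detect cardiac peaks in a photoplethysmograph trace
#'
#' Local maxima exceeding an adaptive threshold built from a rolling median
#' plus a fraction of the rolling amplitude range, with a refractory period
#' rejecting implausibly close peaks (the smaller of two conflicting peaks is
#' dropped).
#'
#' @param trace A [physio_trace()] (its cardiac channel is used) or a numeric
#'   vector with `sample_hz` supplied.
#' @param sample_hz Sampling rate when `trace` is a bare vector.
#' @param refractory_s Minimum peak separation, seconds (default 0.25 s,
#'   i.e. a 240 bpm ceiling).
#' @param window_s Rolling window for the adaptive threshold, seconds.
#' @param threshold_frac Fraction of the rolling amplitude range (above the
#'   rolling median) a peak must exceed.
#' @param smooth_s Moving-average pre-smoothing window, seconds; suppresses
#'   sample-to-sample sensor noise before the argmax search. Peak times are
#'   refined to sub-sample precision by a parabola through the three samples
#'   around each maximum.
#' @return A [cardiac_peaks()] object. Errors if fewer than 3 peaks are found
#'   (an unusable trace, e.g. flat or arrhythmic beyond recognition).
#' @export
detect_cardiac_peaks <- function(trace, sample_hz = NULL, refractory_s = 0.25,
                                 window_s = 2, threshold_frac = 0.5,
                                 smooth_s = 0.1) {
  if (inherits(trace, "physio_trace")) {
    x <- trace$cardiac
    fs <- trace$cardiac_hz
    t0 <- trace$t0_offset_s
  } else {
    if (is.null(sample_hz)) stop("supply `sample_hz` for a bare vector", call. = FALSE)
    x <- as.numeric(trace); fs <- sample_hz; t0 <- 0
  }
  n <- length(x)
  ws <- max(1L, round(smooth_s * fs))
  if (ws %% 2 == 0) ws <- ws + 1L
  if (ws > 1) x <- as.numeric(zoo::rollmean(zoo::zoo(x), ws, fill = "extend"))
  w <- max(3L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  med <- zoo::rollmedian(zoo::zoo(x), w, fill = "extend")
  hi <- zoo::rollapply(zoo::zoo(x), w, max, fill = "extend")
  lo <- zoo::rollapply(zoo::zoo(x), w, min, fill = "extend")
  thr <- as.numeric(med + threshold_frac * (hi - lo))
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_max & x > thr)
  if (length(cand) >= 2) {
    keep <- cand[1]
    for (i in cand[-1]) {
      if ((i - keep[length(keep)]) / fs >= refractory_s) keep <- c(keep, i)
      else if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    }
    cand <- keep
  }
  if (length(cand) < 3L)
    stop("fewer than 3 cardiac peaks detected; trace unusable", call. = FALSE)
  # sub-sample refinement: vertex of the parabola through the 3 samples
  frac <- vapply(cand, function(i) {
    if (i <= 1L || i >= n) return(0)
    den <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (x[i - 1] - x[i + 1]) / den))
  }, numeric(1))
  cardiac_peaks(t0 + (cand - 1 + frac) / fs, refractory_s)
}

#' Cardiac phase at arbitrary times
#'
#' Linear phase within each RR interval: `2*pi*(t - t_k)/(t_{k+1} - t_k)` for
#' the bracketing peaks. Times before the first (after the last) peak are
#' extrapolated with the first (last) interval, wrapped into `[0, 2*pi)`.
#'
#' @param peaks A [cardiac_peaks()].
#' @param t Numeric vector of query times, seconds.
#' @return Phases in `[0, 2*pi)`.
#' @export
cardiac_phase <- function(peaks, t) {
  p <- peaks$peak_times_s
  np <- length(p)
  k <- findInterval(t, p)
  k <- pmin(pmax(k, 1L), np - 1L)
  frac <- (t - p[k]) / (p[k + 1L] - p[k])
  2 * pi * (frac %% 1)
}

#' Respiratory phase by amplitude histogram equalization
#'
#' The belt amplitude does not advance linearly in time, so respiratory phase
#' is defined through the run-wide amplitude distribution:
#' `phi(t) = pi * sign(dR/dt) * H(R(t)) / n`, where `H` is the cumulative
#' amplitude histogram (default 100 bins) of the smoothed trace and the
#' derivative comes from centered differences on the smoothed trace. Phase
#' lies in `(-pi, pi]`, increasing through inhalation.
#'
#' @param trace A [physio_trace()] (respiratory channel) or numeric vector.
#' @param t Query times, seconds.
#' @param sample_hz Sampling rate for a bare vector.
#' @param n_bins Histogram bins.
#' @param smooth_s Moving-average smoothing window, seconds.
#' @return Phases in `(-pi, pi]`.
#' @export
resp_phase <- function(trace, t, sample_hz = NULL, n_bins = 100, smooth_s = 1) {
  if (inherits(trace, "physio_trace")) {
    x <- trace$respiratory; fs <- trace$respiratory_hz; t0 <- trace$t0_offset_s
  } else {
    if (is.null(sample_hz)) stop("supply `sample_hz` for a bare vector", call. = FALSE)
    x <- as.numeric(trace); fs <- sample_hz; t0 <- 0
  }
  if (diff(range(x)) == 0)
    stop("constant respiratory trace: phase undefined", call. = FALSE)
  w <- max(1L, round(smooth_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  xs <- if (w > 1) as.numeric(zoo::rollmean(zoo::zoo(x), w, fill = "extend")) else x
  n <- length(xs)
  br <- seq(min(xs), max(xs), length.out = n_bins + 1L)
  ct <- graphics::hist(xs, breaks = br, plot = FALSE)$counts
  cum <- cumsum(ct)
  deriv <- c(xs[2] - xs[1], (xs[3:n] - xs[1:(n - 2)]) / 2, xs[n] - xs[n - 1]) * fs
  ts <- t0 + (seq_len(n) - 1) / fs
  rt <- stats::approx(ts, xs, xout = t, rule = 2)$y
  dt <- stats::approx(ts, deriv, xout = t, rule = 2)$y
  bin <- pmin(pmax(findInterval(rt, br, rightmost.closed = TRUE), 1L), n_bins)
  sgn <- ifelse(dt < 0, -1, 1)
  ph <- pi * sgn * cum[bin] / n
  # map -pi exactly onto +pi to honour the (-pi, pi] convention
  ifelse(ph <= -pi, pi, ph)
}

#' Build RETROICOR Fourier regressors
#'
#' For each slice and volume, the cardiac and respiratory phases are evaluated
#' at that slice's acquisition time and expanded in a low-order Fourier basis:
#' `cos(m*phi_c), sin(m*phi_c), cos(m*phi_r), sin(m*phi_r)` for harmonics
#' `m = 1..order` (order 2 gives the standard 8 columns).
#'
#' @param physio A [physio_trace()] covering the scan.
#' @param series A [bold_series()] supplying TR, volume count and per-slice
#'   offsets.
#' @param order Harmonic order (default 2).
#' @param peaks Optional precomputed [cardiac_peaks()]; detected from the
#'   trace when omitted.
#' @return A slice-specific [regressor_set()] with `4*order` columns.
#' @export
retroicor_regressors <- function(physio, series, order = 2L, peaks = NULL) {
  stopifnot(inherits(physio, "physio_trace"), inherits(series, "bold_series"))
  if (is.null(peaks)) peaks <- detect_cardiac_peaks(physio)
  nt <- n_timepoints(series)
  n_sl <- dim(series$data)[series$slice_axis]
  k <- 4L * order
  labels <- c(paste0(rep(c("card_cos", "card_sin"), order),
                     rep(seq_len(order), each = 2)),
              paste0(rep(c("resp_cos", "resp_sin"), order),
                     rep(seq_len(order), each = 2)))
  X <- array(0, c(nt, k, n_sl))
  for (z in seq_len(n_sl)) {
    ts <- frame_times(series, slice = z)
    pc <- cardiac_phase(peaks, ts)
    pr <- resp_phase(physio, ts)
    cols <- list()
    for (m in seq_len(order)) cols <- c(cols, list(cos(m * pc), sin(m * pc)))
    for (m in seq_len(order)) cols <- c(cols, list(cos(m * pr), sin(m * pr)))
    X[, , z] <- do.call(cbind, cols)
  }
  regressor_set(X, labels = labels, slice_specific = TRUE)
}

#' Mean framewise head displacement
#'
#' Framewise displacement per step is the sum of absolute translation changes
#' plus `radius_mm` times the sum of absolute rotation changes (rotations
#' converted to arc length on a 50 mm head-radius sphere); the mean over steps
#' is returned.
#'
#' @param motion A [motion_params()] (or 6-column matrix) with >= 2 rows.
#' @param radius_mm Rotation-to-displacement conversion radius.
#' @return Mean displacement in mm.
#' @export
mean_displacement <- function(motion, radius_mm = 50) {
  m <- unclass(motion_params(motion))
  if (nrow(m) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  d <- abs(diff(m))
  fd <- rowSums(d[, 4:6, drop = FALSE]) + radius_mm * rowSums(d[, 1:3, drop = FALSE])
  mean(fd)
}
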