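# two-pass sample statistics over a voxel-by-time matrix
row_mean_sd <- function(Y) {
  n <- ncol(Y)
  m <- rowMeans(Y)
  s <- sqrt(rowSums(sweep(Y, 1, m)^2) / (n - 1))
  list(mean = m, sd = s)
}

#' Per-voxel coefficient of variation map
#'
#' For every in-mask voxel, CV = sample standard deviation over time (n-1
#' denominator) divided by the temporal mean. Voxels whose absolute mean falls
#' below a relative floor (default `1e-6` times the in-mask median absolute
#' mean) are marked invalid and excluded from all downstream aggregation; the
#' ratio is numerically meaningless there.
#'
#' @param series A [bold_series()] (preprocessed or raw, the caller's choice).
#' @param brain_mask A [tissue_mask()] on the same grid.
#' @param mean_floor_rel Relative low-signal floor.
#' @return A [new_cv_map()] object; `provenance` records `"cv"`.
#' @export
cv_map <- function(series, brain_mask, mean_floor_rel = 1e-6) {
  stopifnot(inherits(series, "bold_series"), inherits(brain_mask, "tissue_mask"))
  check_same_grid(series$data, brain_mask$data, "BOLD and mask")
  mask <- brain_mask$data
  if (!any(mask)) stop("empty brain mask", call. = FALSE)
  d <- dim(series$data)
  Y <- matrix(series$data, nrow = prod(d[1:3]))
  st <- row_mean_sd(Y)
  floor_abs <- mean_floor_rel * stats::median(abs(st$mean[as.vector(mask)]))
  valid <- as.vector(mask) & abs(st$mean) > floor_abs
  cv <- numeric(length(valid))
  cv[valid] <- st$sd[valid] / st$mean[valid]
  cv[valid] <- abs(cv[valid])
  new_cv_map(array(cv, d[1:3]), array(valid, d[1:3]),
             provenance = "cv", affine = series$affine)
}

# frequency of DFT bin k (0-based) for an n-point series sampled every tr_s
dft_freqs <- function(n, tr_s) (seq_len(n) - 1) / (n * tr_s)

#' Band-limited coefficient of variation map
#'
#' The fluctuation component (series minus its temporal mean) is filtered with
#' a zero-phase ideal (discrete-Fourier mask) band-pass retaining bins with
#' frequency in the half-open interval `(low, high]`; the band CV is the
#' sample standard deviation of the filtered component divided by the
#' *original* temporal mean. DC is never included, and the ideal mask makes
#' band variances over an exact partition of the frequency axis add up to the
#' total detrended variance (Parseval).
#'
#' @param series A [bold_series()].
#' @param band A [band_spec()] with `high <= Nyquist`.
#' @param brain_mask A [tissue_mask()].
#' @param mean_floor_rel Relative low-signal floor, as in [cv_map()].
#' @return A [new_cv_map()] with `band_hz` set.
#' @export
bandpass_cv <- function(series, band, brain_mask, mean_floor_rel = 1e-6) {
  stopifnot(inherits(series, "bold_series"), inherits(band, "band_spec"),
            inherits(brain_mask, "tissue_mask"))
  check_same_grid(series$data, brain_mask$data, "BOLD and mask")
  nyq <- 1 / (2 * series$tr_s)
  if (band$high_hz > nyq + 1e-12)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", band$high_hz, nyq),
         call. = FALSE)
  mask <- brain_mask$data
  if (!any(mask)) stop("empty brain mask", call. = FALSE)
  d <- dim(series$data)
  nt <- d[4]
  Y <- matrix(series$data, nrow = prod(d[1:3]))
  m <- rowMeans(Y)
  Yc <- sweep(Y, 1, m)
  f <- dft_freqs(nt, series$tr_s)
  fa <- pmin(f, 1 / series$tr_s - f)        # alias-folded frequency per bin
  keep <- fa > band$low_hz + 1e-12 & fa <= band$high_hz + 1e-12
  keep[1] <- FALSE                          # DC stays out, always
  if (!any(keep))
    stop("band contains no resolvable frequency for this run length", call. = FALSE)
  Z <- stats::mvfft(t(Yc))
  Z[!keep, ] <- 0
  Yf <- t(Re(stats::mvfft(Z, inverse = TRUE))) / nt
  s <- sqrt(rowSums(Yf^2) / (nt - 1))
  floor_abs <- mean_floor_rel * stats::median(abs(m[as.vector(mask)]))
  valid <- as.vector(mask) & abs(m) > floor_abs
  cv <- numeric(length(valid))
  cv[valid] <- s[valid] / abs(m[valid])
  new_cv_map(array(cv, d[1:3]), array(valid, d[1:3]),
             band_hz = c(band$low_hz, band$high_hz),
             provenance = c("cv", sprintf("bandpass_%g_%g", band$low_hz, band$high_hz)),
             affine = series$affine)
}
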