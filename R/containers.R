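#' 4D BOLD time series container
#'
#' Wraps a 4D voxel-by-time array together with the acquisition timing metadata
#' the pipeline needs: repetition time, which spatial axis indexes slices, the
#' per-slice acquisition offsets within a TR, and the voxel-to-world affine.
#'
#' @param data 4D numeric array, spatial dims first, time last.
#' @param tr_s Repetition time in seconds (> 0).
#' @param slice_axis Spatial axis (1-3) along which slices were acquired.
#' @param slice_offsets_s Per-slice acquisition offset within the TR, seconds,
#'   each in `[0, tr_s)`. Defaults to all-zero offsets.
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr_s, slice_axis = 3L, slice_offsets_s = NULL,
                        affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a single positive number", call. = FALSE)
  if (dim(data)[4L] < 2L)
    stop("a BOLD series needs at least 2 timepoints", call. = FALSE)
  if (anyNA(data) || !all(is.finite(data)))
    stop("BOLD data contains non-finite voxels", call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  n_slices <- dim(data)[slice_axis]
  if (is.null(slice_offsets_s)) slice_offsets_s <- rep(0, n_slices)
  if (length(slice_offsets_s) != n_slices)
    stop("`slice_offsets_s` must have one entry per slice", call. = FALSE)
  if (any(slice_offsets_s < 0 | slice_offsets_s >= tr_s))
    stop("slice offsets must lie in [0, tr_s)", call. = FALSE)
  structure(
    list(data = data, tr_s = tr_s, slice_axis = slice_axis,
         slice_offsets_s = as.numeric(slice_offsets_s), affine = affine),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels x %d timepoints, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_timepoints <- function(series) dim(series$data)[4L]

#' Volume acquisition times of a BOLD series
#'
#' @param series A [bold_series()].
#' @param slice Optional slice index; when given, per-slice acquisition times
#'   (volume time + slice offset) are returned.
#' @return Numeric vector of times in seconds, first volume at 0.
#' @export
frame_times <- function(series, slice = NULL) {
  t0 <- (seq_len(n_timepoints(series)) - 1) * series$tr_s
  if (is.null(slice)) t0 else t0 + series$slice_offsets_s[slice]
}

#' Tissue partial-volume map
#'
#' Per-voxel tissue fraction in `[0, 1]` for one tissue class.
#'
#' @param data 3D numeric array of fractions in `[0, 1]`.
#' @param tissue One of `"GM"`, `"WM"`, `"CSF"`.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `pve_map` object.
#' @export
pve_map <- function(data, tissue = c("GM", "WM", "CSF"), affine = diag(4)) {
  tissue <- match.arg(tissue)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("PVE map must be a 3D array", call. = FALSE)
  if (anyNA(data) || any(data < 0) || any(data > 1))
    stop("PVE fractions must lie in [0, 1] with no missing values", call. = FALSE)
  structure(list(data = data, tissue = tissue, affine = affine),
            class = "pve_map")
}

#' @export
print.pve_map <- function(x, ...) {
  cat(sprintf("<pve_map> %s, %s voxels, total weight %.1f\n", x$tissue,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Binary tissue / ROI mask
#'
#' @param data 3D array coercible to strictly binary (0/1 or logical).
#' @param provenance How the mask was made: `"threshold"` (PVE cut),
#'   `"template"` (standard-space template), or `"manual_roi"`.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `tissue_mask` object.
#' @export
tissue_mask <- function(data, provenance = c("threshold", "template", "manual_roi"),
                        affine = diag(4)) {
  provenance <- match.arg(provenance)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  v <- as.numeric(data)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("mask must be strictly binary (0/1)", call. = FALSE)
  structure(list(data = array(v != 0, dim(data)), provenance = provenance,
                 affine = affine),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %s, %d of %s voxels\n", x$provenance,
              sum(x$data), paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Cardiac and respiratory recordings
#'
#' Uniformly sampled cardiac (photoplethysmograph) and respiratory (belt)
#' amplitude traces, with their sampling rates and the trace start time
#' relative to the first BOLD volume.
#'
#' @param cardiac,respiratory Numeric amplitude vectors.
#' @param cardiac_hz,respiratory_hz Sampling rates in Hz.
#' @param t0_offset_s Trace start relative to the first volume (seconds;
#'   negative when recording started before the scan).
#' @return A `physio_trace` object.
#' @export
physio_trace <- function(cardiac, cardiac_hz, respiratory, respiratory_hz,
                         t0_offset_s = 0) {
  stopifnot(is.numeric(cardiac), is.numeric(respiratory),
            cardiac_hz > 0, respiratory_hz > 0)
  if (anyNA(cardiac) || anyNA(respiratory))
    stop("physio traces must not contain missing samples", call. = FALSE)
  structure(list(cardiac = as.numeric(cardiac), cardiac_hz = cardiac_hz,
                 respiratory = as.numeric(respiratory),
                 respiratory_hz = respiratory_hz,
                 t0_offset_s = t0_offset_s),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> cardiac %.4g s @ %g Hz, respiratory %.4g s @ %g Hz\n",
              length(x$cardiac) / x$cardiac_hz, x$cardiac_hz,
              length(x$respiratory) / x$respiratory_hz, x$respiratory_hz))
  invisible(x)
}

# times (s, relative to first volume) of the cardiac / respiratory samples
physio_times <- function(trace, which = c("cardiac", "respiratory")) {
  which <- match.arg(which)
  hz <- if (which == "cardiac") trace$cardiac_hz else trace$respiratory_hz
  n <- length(trace[[which]])
  trace$t0_offset_s + (seq_len(n) - 1) / hz
}

#' Rigid-body motion parameters
#'
#' @param mat Numeric matrix with one row per timepoint and 6 columns:
#'   3 rotations (radians) then 3 translations (mm), the common
#'   realignment-output convention.
#' @return A `motion_params` object (a classed matrix).
#' @export
motion_params <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 6L)
    stop("motion parameters must have 6 columns (3 rotations rad, 3 translations mm)",
         call. = FALSE)
  if (anyNA(mat)) stop("motion parameters contain missing values", call. = FALSE)
  colnames(mat) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  structure(mat, class = c("motion_params", "matrix", "array"))
}

#' Per-voxel CV map
#'
#' @param data 3D array of coefficients of variation (dimensionless).
#' @param valid 3D logical array marking voxels where the CV is defined
#'   (in-mask, mean above the low-signal floor).
#' @param band_hz Optional length-2 numeric `(low, high)` when band-limited.
#' @param provenance Character vector naming the preprocessing steps applied.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `cv_map` object.
#' @export
new_cv_map <- function(data, valid, band_hz = NULL, provenance = character(),
                       affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            identical(dim(data), dim(valid)))
  if (any(!is.finite(data[valid])) || any(data[valid] < 0))
    stop("CV must be finite and nonnegative over valid voxels", call. = FALSE)
  structure(list(data = data, valid = valid, band_hz = band_hz,
                 provenance = provenance, affine = affine),
            class = "cv_map")
}

#' @export
print.cv_map <- function(x, ...) {
  band <- if (is.null(x$band_hz)) "full band"
          else sprintf("%.3g-%.3g Hz", x$band_hz[1], x$band_hz[2])
  cat(sprintf("<cv_map> %s voxels (%d valid), %s; median CV %.3g\n",
              paste(dim(x$data), collapse = "x"), sum(x$valid), band,
              stats::median(x$data[x$valid])))
  invisible(x)
}

#' Frequency band specification
#'
#' A half-open frequency interval `(low, high]` Hz used for band-limited CV.
#' The half-open convention makes a set of contiguous bands an exact partition
#' of the discrete frequency axis, so band variances add up to the total.
#'
#' @param low_hz,high_hz Band edges with `0 < low < high`.
#' @return A `band_spec` object.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

#' @export
format.band_spec <- function(x, ...) sprintf("%g-%g Hz", x$low_hz, x$high_hz)

#' @export
print.band_spec <- function(x, ...) {
  cat("<band_spec>", format(x), "\n"); invisible(x)
}

#' The three analysis bands used for the band-contribution breakdown
#'
#' 0.01-0.014, 0.014-0.025 and 0.025-0.1 Hz, chosen to capture the fast
#' initial decay of the resting-state BOLD spectrum.
#'
#' @return List of three [band_spec()] objects.
#' @export
default_bands <- function() {
  list(band_spec(0.010, 0.014), band_spec(0.014, 0.025), band_spec(0.025, 0.100))
}

# shared grid check used by everything that combines images
check_same_grid <- function(a, b, what = "inputs") {
  da <- if (is.array(a)) dim(a) else dim(a$data)
  db <- if (is.array(b)) dim(b) else dim(b$data)
  if (!identical(da[1:3], db[1:3]))
    stop(sprintf("%s are on different grids (%s vs %s); resampling is out of scope",
                 what, paste(da[1:3], collapse = "x"), paste(db[1:3], collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}
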