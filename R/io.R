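#' Read a 4D BOLD NIfTI file
#'
#' @param path Path to a 4D NIfTI-1 image (`.nii` / `.nii.gz`).
#' @param tr_s Optional TR override (seconds). Required when the header does
#'   not carry a usable TR.
#' @param slice_offsets_s Optional per-slice acquisition offsets (seconds);
#'   when missing, all-zero offsets are assumed with a warning, since NIfTI
#'   headers rarely encode slice timing reliably.
#' @param slice_axis Spatial axis indexing slices (default 3).
#' @return A validated [bold_series()].
#' @export
read_bold <- function(path, tr_s = NULL, slice_offsets_s = NULL, slice_axis = 3L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  if (length(dim(a)) != 4L)
    stop(sprintf("expected a 4D BOLD image, got %dD: %s", length(dim(a)), path),
         call. = FALSE)
  if (anyNA(a) || !all(is.finite(a)))
    stop("BOLD image contains non-finite voxels: ", path, call. = FALSE)
  if (is.null(tr_s)) {
    pd <- attr(img, "pixdim")
    tr_s <- if (length(pd) >= 4) pd[4] else 0
    if (!is.finite(tr_s) || tr_s <= 0)
      stop("header carries no usable TR; pass `tr_s` explicitly", call. = FALSE)
  }
  if (is.null(slice_offsets_s)) {
    warning("no slice timing supplied; assuming all-zero slice offsets",
            call. = FALSE)
    slice_offsets_s <- rep(0, dim(a)[slice_axis])
  }
  bold_series(a, tr_s = tr_s, slice_axis = slice_axis,
              slice_offsets_s = slice_offsets_s, affine = nifti_affine(img))
}

nifti_affine <- function(img) {
  x <- try(structure(RNifti::xform(img), class = NULL), silent = TRUE)
  if (inherits(x, "try-error") || !is.matrix(x)) diag(4) else unclass(x)
}

#' Write a BOLD series as 4D NIfTI
#'
#' @param series A [bold_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(1, 1, 1, series$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D volume as NIfTI
#'
#' @param data 3D numeric array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(dim(a)), path),
         call. = FALSE)
  list(data = a, affine = nifti_affine(img))
}

#' Read a tissue partial-volume map from NIfTI
#'
#' @param path 3D NIfTI with per-voxel fractions in `[0, 1]`.
#' @param tissue Tissue label (`"GM"`, `"WM"`, `"CSF"`).
#' @return A [pve_map()]. Values outside `[0, 1]` or missing are rejected, not
#'   clipped: a negative PVE signals a corrupted input.
#' @export
read_pve <- function(path, tissue) {
  v <- read_volume(path)
  if (anyNA(v$data) || any(v$data < 0) || any(v$data > 1))
    stop("PVE map has values outside [0, 1]: ", path, call. = FALSE)
  pve_map(v$data, tissue, affine = v$affine)
}

#' Read a binary mask from NIfTI
#'
#' @param path 3D NIfTI containing only 0/1.
#' @param provenance Mask provenance (`"threshold"`, `"template"`,
#'   `"manual_roi"`).
#' @return A [tissue_mask()].
#' @export
read_mask <- function(path, provenance = "template") {
  v <- read_volume(path)
  tissue_mask(v$data, provenance, affine = v$affine)
}

read_physio_tsv <- function(path, target_hz) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) < 2L) stop("physio file has fewer than 2 samples: ", path, call. = FALSE)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("physio TSV needs columns time_s and amplitude: ", path, call. = FALSE)
  tt <- df$time_s
  if (anyNA(tt) || anyNA(df$amplitude))
    stop("physio file contains missing values: ", path, call. = FALSE)
  if (any(diff(tt) <= 0))
    stop("physio time column must be strictly increasing: ", path, call. = FALSE)
  # resample to a uniform grid (identity when already uniform at target_hz)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_hz)
  amp <- stats::approx(tt, df$amplitude, xout = grid)$y
  list(amplitude = amp, sample_hz = target_hz, t0 = tt[1],
       span = tt[length(tt)] - tt[1])
}

#' Read cardiac and respiratory traces from TSV
#'
#' Each file holds two tab-separated columns, `time_s` and `amplitude`, with a
#' strictly increasing time column. Unevenly sampled traces are linearly
#' interpolated onto a uniform grid at `sample_hz`.
#'
#' @param cardiac_path,resp_path TSV paths.
#' @param sample_hz Uniform internal sampling rate (default 100 Hz).
#' @param scan_duration_s Optional scan duration; when supplied, traces that do
#'   not cover it are rejected.
#' @return A [physio_trace()].
#' @export
read_physio <- function(cardiac_path, resp_path, sample_hz = 100,
                        scan_duration_s = NULL) {
  card <- read_physio_tsv(cardiac_path, sample_hz)
  resp <- read_physio_tsv(resp_path, sample_hz)
  if (!is.null(scan_duration_s)) {
    for (tr in list(card, resp))
      if (tr$t0 > 0 || tr$t0 + tr$span < scan_duration_s)
        stop(sprintf("physio trace covers [%g, %g] s but the scan needs [0, %g] s",
                     tr$t0, tr$t0 + tr$span, scan_duration_s), call. = FALSE)
  }
  physio_trace(card$amplitude, sample_hz, resp$amplitude, sample_hz,
               t0_offset_s = card$t0)
}

#' Write a physio trace as two 2-column TSVs
#'
#' @param physio A [physio_trace()].
#' @param cardiac_path,resp_path Output TSV paths (`time_s`, `amplitude`).
#' @return Invisibly, the two paths.
#' @export
write_physio <- function(physio, cardiac_path, resp_path) {
  w <- function(amp, hz, path) {
    df <- data.frame(time_s = physio$t0_offset_s + (seq_along(amp) - 1) / hz,
                     amplitude = amp)
    utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(physio$cardiac, physio$cardiac_hz, cardiac_path)
  w(physio$respiratory, physio$respiratory_hz, resp_path)
  invisible(c(cardiac_path, resp_path))
}

#' Read rigid-body motion parameters
#'
#' Whitespace-delimited text, one row per timepoint, 6 columns: 3 rotations
#' (radians) then 3 translations (mm).
#'
#' @param path Input path.
#' @return A [motion_params()].
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop(sprintf("motion file must have 6 columns, found %d: %s", ncol(m), path),
         call. = FALSE)
  motion_params(m)
}

#' Write motion parameters as 6-column whitespace text
#'
#' @param motion A [motion_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a per-subject results table
#'
#' Tab-separated with header `subject  group  tissue  method  band  cv  n`;
#' values round-trip to at least 12 significant digits.
#'
#' @param tbl Tibble of per-subject tissue CV rows.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_results_table <- function(tbl, path) {
  df <- as.data.frame(tbl)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read a run configuration file (YAML or JSON)
#'
#' Keys mirror the [phantom_spec()] and [pipeline_config()] argument lists.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
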