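tissue_cv_row <- function(subject_id, tissue, method, band, value, n) {
  tibble::tibble(
    subject = subject_id, tissue = tissue, method = method,
    band = if (is.null(band)) "full" else format(band),
    cv = value, n = n)
}

band_label <- function(band) if (is.null(band)) "full" else format(band)

# valid-voxel weights: invalid (low-mean) CV voxels carry zero weight everywhere
valid_weights <- function(cv, w) {
  w[!cv$valid] <- 0
  w
}

#' Partial-volume-weighted mean CV (method a)
#'
#' `sum(PVE_i * CV_i) / sum(PVE_i)` over valid brain voxels: every voxel
#' contributes in proportion to how much of the tissue it contains, so no
#' threshold has to be chosen. The sum of weights is recorded as the effective
#' sample size.
#'
#' @param cv A [cv_map()] result.
#' @param pve A [pve_map()] on the same grid.
#' @param subject_id Subject label for the output row.
#' @param band Optional [band_spec()] recorded in the output.
#' @return One-row tibble: `subject, tissue, method, band, cv, n`.
#' @export
pve_weighted_mean <- function(cv, pve, subject_id = "subject", band = NULL) {
  stopifnot(inherits(cv, "cv_map"), inherits(pve, "pve_map"))
  check_same_grid(cv$data, pve$data, "CV map and PVE map")
  w <- valid_weights(cv, pve$data)
  sw <- sum(w)
  if (sw <= 0) stop("PVE weights sum to zero over valid voxels", call. = FALSE)
  tissue_cv_row(subject_id, pve$tissue, "pve", band, sum(w * cv$data) / sw, sw)
}

#' Strict-threshold mean CV (method b)
#'
#' Arithmetic mean of CV over voxels whose partial-volume estimate strictly
#' exceeds the threshold (default 0.8); a voxel at exactly the threshold is
#' excluded. Warns when fewer than 2000 voxels survive, the count below which
#' a subject-level mean starts to look undersampled.
#'
#' @param cv A [cv_map()] result.
#' @param pve A [pve_map()].
#' @param threshold PVE cut in (0, 1).
#' @param subject_id,band As in [pve_weighted_mean()].
#' @return One-row tibble.
#' @export
strict_threshold_mean <- function(cv, pve, threshold = 0.8,
                                  subject_id = "subject", band = NULL) {
  stopifnot(inherits(cv, "cv_map"), inherits(pve, "pve_map"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  check_same_grid(cv$data, pve$data, "CV map and PVE map")
  sel <- pve$data > threshold & cv$valid
  n <- sum(sel)
  if (n == 0)
    stop(sprintf("no voxel has %s PVE > %g", pve$tissue, threshold), call. = FALSE)
  if (n < 2000)
    warning(sprintf("only %d %s voxels above PVE %g; mean may be undersampled",
                    n, pve$tissue, threshold), call. = FALSE)
  tissue_cv_row(subject_id, pve$tissue, "strict", band, mean(cv$data[sel]), n)
}

#' Template / ROI mean CV (method c and the periventricular ROI)
#'
#' Arithmetic mean of CV over a pre-aligned binary mask: a standard-space
#' tissue template or a manually drawn region of interest.
#'
#' @param cv A [cv_map()] result.
#' @param mask A [tissue_mask()] on the same grid.
#' @param tissue Tissue/ROI label for the output row.
#' @param subject_id,band As in [pve_weighted_mean()].
#' @return One-row tibble; `method` is `"template"` or `"roi"` depending on the
#'   mask's provenance.
#' @export
template_mean <- function(cv, mask, tissue = "GM", subject_id = "subject",
                          band = NULL) {
  stopifnot(inherits(cv, "cv_map"), inherits(mask, "tissue_mask"))
  check_same_grid(cv$data, mask$data, "CV map and mask")
  sel <- mask$data & cv$valid
  if (!any(sel)) stop("empty mask after removing invalid voxels", call. = FALSE)
  method <- if (mask$provenance == "manual_roi") "roi" else "template"
  tissue_cv_row(subject_id, tissue, method, band, mean(cv$data[sel]), sum(sel))
}
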