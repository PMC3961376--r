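#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test of equal population medians. Midranks are assigned
#' (ties averaged) and the statistic is the rank-sum of `x`. The null
#' distribution is computed exactly whenever feasible:
#'
#' * no ties and both samples at most `exact_limit`: dynamic-programming
#'   enumeration of the rank-sum distribution (counts of k-subsets of
#'   `1..N` by sum);
#' * ties present and `n1 + n2 <= 20`: full enumeration of all
#'   `choose(N, n1)` group assignments of the midranks;
#' * otherwise: normal approximation with tie-corrected variance and
#'   continuity correction.
#'
#' The two-sided p-value is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param exact_limit Largest per-group size for the no-ties exact path.
#' @return A `ranksum_test` object with fields `statistic` (rank-sum of `x`),
#'   `p_two_sided`, `n1`, `n2`, `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    r <- rank(pooled)
    return(new_ranksum(sum(r[seq_len(n1)]), 1, n1, n2, "exact"))
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  ties <- any(duplicated(pooled))
  N <- n1 + n2
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    p <- ranksum_exact_p(round(w), n1, n2)
    method <- "exact"
  } else if (ties && N <= 20L) {
    p <- ranksum_perm_p(w, r, n1)
    method <- "exact"
  } else {
    p <- ranksum_normal_p(w, r, n1, n2)
    method <- "normal_approx"
  }
  new_ranksum(w, p, n1, n2, method)
}

new_ranksum <- function(statistic, p, n1, n2, method) {
  structure(list(statistic = statistic, p_two_sided = min(max(p, 0), 1),
                 n1 = n1, n2 = n2, method = method),
            class = "ranksum_test")
}

# counts of subsets of {1..N} of size n1 by rank-sum, via DP over items
ranksum_null_counts <- function(n1, n2) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1):N)
  # cnt[[k]][s+1] = number of k-subsets with sum s
  cnt <- matrix(0, n1 + 1L, smax + 1L)
  cnt[1L, 1L] <- 1
  for (item in seq_len(N)) {
    for (k in rev(seq_len(min(item, n1)))) {
      shifted <- c(rep(0, item), cnt[k, seq_len(smax + 1L - item)])
      cnt[k + 1L, ] <- cnt[k + 1L, ] + shifted
    }
  }
  cnt[n1 + 1L, ]      # index s+1 holds count of subsets summing to s
}

ranksum_exact_p <- function(w, n1, n2) {
  counts <- ranksum_null_counts(n1, n2)
  total <- choose(n1 + n2, n1)
  s <- seq_along(counts) - 1L
  lo <- sum(counts[s <= w]) / total
  hi <- sum(counts[s >= w]) / total
  min(1, 2 * min(lo, hi))
}

ranksum_perm_p <- function(w, ranks, n1) {
  idx <- utils::combn(length(ranks), n1)
  sums <- colSums(matrix(ranks[idx], nrow = n1))
  eps <- 1e-9
  lo <- mean(sums <= w + eps)
  hi <- mean(sums >= w - eps)
  min(1, 2 * min(lo, hi))
}

ranksum_normal_p <- function(w, ranks, n1, n2) {
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_tab <- table(ranks)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  z_lo <- (w - mu + 0.5) / sqrt(sigma2)
  z_hi <- (w - mu - 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z_lo), stats::pnorm(z_hi, lower.tail = FALSE)))
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, n = %d/%d, two-sided p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ranksum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_two_sided,
                 n1 = x$n1, n2 = x$n2, method = x$method)
}

#' @exportS3Method generics::glance
glance.ranksum_test <- function(x, ...) tidy(x)

#' Ordinary least-squares fit of one per-subject CV measure on another
#'
#' Used for the WM-versus-GM fluctuation-amplitude relationship across
#' subjects. The caller chooses which measure is `x` and which is `y`; the
#' function does not guess an orientation.
#'
#' @param x,y Numeric vectors (>= 3 points, `x` not constant).
#' @return A `cv_linfit` object with `slope`, `intercept`, `r_squared` and the
#'   underlying [stats::lm()] fit.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
                 fit = fit, n = length(x)),
            class = "cv_linfit")
}

#' @export
print.cv_linfit <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4g x + %.4g, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_linfit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.cv_linfit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n)
}

#' Compare two cohorts stratum by stratum
#'
#' For every tissue x method x band stratum present in the table, computes the
#' per-group mean and SD of the subject-level CVs and a two-sided exact
#' Wilcoxon rank-sum p-value. Adds a mean-displacement comparison when a
#' `displacement` column is present, and a WM-on-GM least-squares fit over all
#' subjects (strict-threshold full-band values) when both tissues are present.
#' Strata with fewer than 2 subjects in either group are listed as incomplete
#' and skipped. P-values are reported unadjusted.
#'
#' @param table Tibble with columns `subject, group, tissue, method, band, cv`
#'   and optionally `displacement` (one value per subject); `group` must have
#'   exactly two levels.
#' @param alpha Significance threshold annotated in the report (default 0.05).
#' @param fit_method Aggregation method used for the WM~GM fit.
#' @return A `cohort_report`: list with tibble `strata`, tibble or NULL
#'   `displacement`, `cv_linfit` or NULL `gm_wm_fit`, character vector
#'   `incomplete`, and `groups` (the two labels, reference first).
#' @export
compare_cohorts <- function(table, alpha = 0.05, fit_method = "strict") {
  tbl <- tibble::as_tibble(table)
  need <- c("subject", "group", "tissue", "method", "band", "cv")
  if (!all(need %in% names(tbl)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  groups <- unique(as.character(tbl$group))
  if (length(groups) != 2L)
    stop("cohort table must contain exactly two groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  dup <- tbl |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0)
    stop("subject(s) appear in both groups: ",
         paste(dup$subject, collapse = ", "), call. = FALSE)

  incomplete <- character()
  one_stratum <- function(d) {
    g1 <- d$cv[d$group == groups[1]]
    g2 <- d$cv[d$group == groups[2]]
    if (length(g1) < 2L || length(g2) < 2L) {
      incomplete <<- c(incomplete,
                       sprintf("%s/%s/%s", d$tissue[1], d$method[1], d$band[1]))
      return(NULL)
    }
    p <- suppressWarnings(wilcoxon_ranksum(g1, g2)$p_two_sided)
    tibble::tibble(
      tissue = d$tissue[1], method = d$method[1], band = d$band[1],
      mean_1 = mean(g1), sd_1 = stats::sd(g1),
      mean_2 = mean(g2), sd_2 = stats::sd(g2),
      n_1 = length(g1), n_2 = length(g2),
      p = p, significant = p < alpha)
  }
  strata <- tbl |>
    dplyr::group_by(.data$tissue, .data$method, .data$band) |>
    dplyr::group_map(~ one_stratum(.x |> dplyr::mutate(tissue = .y$tissue,
                                                       method = .y$method,
                                                       band = .y$band))) |>
    purrr::compact() |>
    dplyr::bind_rows()
  names(strata)[names(strata) %in% c("mean_1", "sd_1", "n_1")] <-
    paste0(c("mean_", "sd_", "n_"), groups[1])
  names(strata)[names(strata) %in% c("mean_2", "sd_2", "n_2")] <-
    paste0(c("mean_", "sd_", "n_"), groups[2])

  disp <- NULL
  if ("displacement" %in% names(tbl)) {
    dsub <- tbl |> dplyr::distinct(.data$subject, .data$group, .data$displacement)
    d1 <- dsub$displacement[dsub$group == groups[1]]
    d2 <- dsub$displacement[dsub$group == groups[2]]
    if (length(d1) >= 2L && length(d2) >= 2L) {
      dp <- suppressWarnings(wilcoxon_ranksum(d1, d2)$p_two_sided)
      disp <- tibble::tibble(mean_1 = mean(d1), mean_2 = mean(d2),
                             mean_difference = mean(d2) - mean(d1), p = dp)
      names(disp)[1:2] <- paste0("mean_", groups)
    }
  }

  fit <- NULL
  wide <- tbl |>
    dplyr::filter(.data$method == fit_method, .data$band == "full",
                  .data$tissue %in% c("GM", "WM")) |>
    dplyr::select("subject", "tissue", "cv") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "cv")
  if (all(c("GM", "WM") %in% names(wide)) && nrow(wide) >= 3L &&
      stats::var(wide$GM) > 0)
    fit <- linear_fit(wide$GM, wide$WM)

  structure(list(strata = strata, displacement = disp, gm_wm_fit = fit,
                 incomplete = incomplete, groups = groups, alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s vs %s (Wilcoxon rank-sum, alpha = %g)\n",
              x$groups[1], x$groups[2], x$alpha))
  print(x$strata, n = Inf)
  if (!is.null(x$displacement)) {
    cat("\nMean head displacement (mm):\n"); print(x$displacement)
  }
  if (!is.null(x$gm_wm_fit)) {
    cat("\nWM ~ GM per-subject CV: "); print(x$gm_wm_fit)
  }
  if (length(x$incomplete))
    cat("\nIncomplete strata skipped:", paste(x$incomplete, collapse = "; "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) x$strata

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  tibble::tibble(n_strata = nrow(x$strata),
                 n_significant = sum(x$strata$significant),
                 n_incomplete = length(x$incomplete),
                 r_squared_gm_wm = if (is.null(x$gm_wm_fit)) NA_real_
                                   else x$gm_wm_fit$r_squared)
}

#' Write a cohort report to TSV + plain-text summary
#'
#' @param report A `cohort_report`.
#' @param dir Output directory; writes `report.tsv` (strata) and `report.txt`
#'   (human-readable summary).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "report.tsv")
  txt <- file.path(dir, "report.txt")
  write_results_table(report$strata, tsv)
  con <- file(txt, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(c(tsv, txt))
}
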