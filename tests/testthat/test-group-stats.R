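test_that("tiny-sample exact p matches enumeration over all label assignments", {
  # x = {1,2}, y = {3,4}: rank-sum 3, the most extreme of C(4,2)=6 -> p = 2/6
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_two_sided, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
})

test_that("identical multisets across groups give p = 1", {
  r <- wilcoxon_ranksum(c(5, 7, 9), c(9, 5, 7))
  expect_equal(r$p_two_sided, 1)
  expect_warning(wilcoxon_ranksum(c(2, 2), c(2, 2)), "identical")
})

test_that("the rank-sum DP agrees with brute-force enumeration for all n1,n2 <= 6", {
  set.seed(13)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    got <- wilcoxon_ranksum(x, y)
    expect_equal(got$p_two_sided, brute_force_ranksum_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("p at n1=%d n2=%d", n1, n2))
  }
})

test_that("the exact p agrees with the reference implementation on continuous data", {
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(10, 0.5)
    got <- wilcoxon_ranksum(x, y)$p_two_sided
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("exact and normal-approximation p agree within 0.01 at n = 10 per group", {
  set.seed(15)
  for (rep in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.7)
    exact <- wilcoxon_ranksum(x, y)$p_two_sided
    approx <- wilcoxon_ranksum(x, y, exact_limit = 2L)$p_two_sided
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(16)
  x <- rlnorm(7); y <- rlnorm(9, 0.6)
  p0 <- wilcoxon_ranksum(x, y)$p_two_sided
  expect_equal(wilcoxon_ranksum(log(x), log(y))$p_two_sided, p0)
  expect_equal(wilcoxon_ranksum(x^3, y^3)$p_two_sided, p0)
  expect_equal(wilcoxon_ranksum(exp(x), exp(y))$p_two_sided, p0)
})

test_that("tied data goes through permutation enumeration and matches brute force", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  got <- wilcoxon_ranksum(x, y)
  expect_equal(got$method, "exact")
  expect_equal(got$p_two_sided, brute_force_ranksum_p(x, y), tolerance = 1e-12)
  # large tied samples fall back to the tie-corrected normal approximation
  set.seed(17)
  xl <- sample(1:4, 15, TRUE); yl <- sample(2:5, 15, TRUE)
  gotl <- wilcoxon_ranksum(xl, yl)
  expect_equal(gotl$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(xl, yl, correct = TRUE))$p.value
  expect_equal(gotl$p_two_sided, ref, tolerance = 0.01)
})

test_that("statistic stays within its feasible rank-sum range", {
  set.seed(18)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    r <- suppressWarnings(wilcoxon_ranksum(rnorm(n1), rnorm(n2)))
    expect_gte(r$statistic, n1 * (n1 + 1) / 2)
    expect_lte(r$statistic, n1 * (n1 + 2 * n2 + 1) / 2)
    expect_gt(r$p_two_sided, 0)
    expect_lte(r$p_two_sided, 1)
  }
})

test_that("OLS fit matches the closed-form normal-equations solution", {
  x <- c(1, 2, 4, 7, 9)
  y <- c(2.2, 2.9, 5.1, 8.4, 10.1)
  f <- linear_fit(x, y)
  # closed-form oracle
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$slope, slope, tolerance = 1e-12)
  expect_equal(f$intercept, intercept, tolerance = 1e-12)
  expect_equal(f$r_squared, r2, tolerance = 1e-12)
})

test_that("degenerate fits behave: collinear R2 = 1, flat y R2 = 0, flat x errors", {
  f <- linear_fit(1:5, 2 * (1:5) + 3)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  f2 <- linear_fit(c(1, 2, 3, 5), rep(4, 4))
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0)
  expect_error(linear_fit(rep(1, 4), 1:4), "zero variance")
})

test_that("tidy and glance methods return one-row tibbles with the key fields", {
  r <- wilcoxon_ranksum(c(1, 2, 5), c(3, 4, 8))
  expect_s3_class(tidy(r), "tbl_df")
  expect_true(all(c("statistic", "p.value") %in% names(tidy(r))))
  f <- linear_fit(1:4, c(1.1, 2.3, 2.8, 4.2))
  expect_equal(nrow(tidy(f)), 2)
  expect_equal(glance(f)$r.squared, f$r_squared)
})

test_that("identical cohorts compare as indistinguishable", {
  tbl <- tidyr::expand_grid(subject = paste0("s", 1:8),
                            tissue = c("GM", "WM"),
                            method = "strict", band = "full")
  sub_idx <- as.integer(sub("s", "", tbl$subject))
  tbl$group <- ifelse(sub_idx <= 4, "control", "ckd")
  tbl$cv <- rep(c(1, 2, 3, 4), 4)    # same multiset in both groups per stratum
  rep_ <- compare_cohorts(tbl)
  expect_true(all(rep_$strata$p == 1))
  expect_true(all(abs(rep_$strata$mean_control - rep_$strata$mean_ckd) < 1e-12))
})

test_that("a hand-built 4-subject table reproduces hand-computed report numbers", {
  tbl <- tibble::tibble(
    subject = c("a", "b", "c", "d"),
    group = c("control", "control", "ckd", "ckd"),
    tissue = "GM", method = "strict", band = "full",
    cv = c(3, 4, 6, 9),
    displacement = c(0.10, 0.12, 0.15, 0.30))
  rep_ <- compare_cohorts(tbl)
  expect_equal(rep_$strata$mean_control, 3.5)
  expect_equal(rep_$strata$sd_control, sd(c(3, 4)))
  expect_equal(rep_$strata$mean_ckd, 7.5)
  # ranks of control {1,2}: most extreme split -> p = 2/6
  expect_equal(rep_$strata$p, 2 / 6, tolerance = 1e-12)
  expect_equal(rep_$displacement$mean_difference, 0.225 - 0.11, tolerance = 1e-12)
})

test_that("simulated cohorts at the published group levels separate decisively", {
  # subject-level GM CVs drawn at the two groups' reported mean +/- SD
  set.seed(19)
  ps <- replicate(11, {
    ctrl <- rnorm(10, 4.6, 0.6)
    ckd <- rnorm(10, 7.9, 1.8)
    wilcoxon_ranksum(ctrl, ckd)$p_two_sided
  })
  expect_lt(median(ps), 0.01)
})

test_that("malformed cohort tables are rejected", {
  tbl <- tibble::tibble(subject = c("a", "a"), group = c("g1", "g2"),
                        tissue = "GM", method = "strict", band = "full", cv = 1:2)
  expect_error(compare_cohorts(tbl), "both groups")
  tbl2 <- tibble::tibble(subject = "a", group = "g1", tissue = "GM",
                         method = "strict", band = "full", cv = 1)
  expect_error(compare_cohorts(tbl2), "two groups")
})
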