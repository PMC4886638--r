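test_that("balanced neighbourhood selects the N nearest points per side", {
  set.seed(2)
  x <- c(runif(80, 20, 100), runif(11, 1, 19.9))
  sel <- balanced_neighborhood(x, 20)
  expect_equal(sel$n_selected, 11L)
  expect_equal(sel$n_above, 80L)
  expect_equal(sel$n_below, 11L)
  expect_length(c(sel$above, sel$below), 22L)

  # one-sided data give an empty selection
  expect_equal(balanced_neighborhood(runif(30, 50, 60), 20)$n_selected, 0L)

  # brute-force sort-by-distance oracle + ordering invariance
  set.seed(7)
  y <- runif(100, 0, 10)
  lod <- 5
  sel <- balanced_neighborhood(y, lod)
  above <- sort(y[y >= lod]); below <- sort(y[y < lod])
  n <- min(length(above), length(below))
  oracle_above <- above[order(abs(above - lod))][1:n]
  oracle_below <- below[order(abs(below - lod))][1:n]
  expect_setequal(sel$above, oracle_above)
  expect_setequal(sel$below, oracle_below)
  shuffled <- balanced_neighborhood(sample(y), lod)
  expect_equal(sort(shuffled$above), sort(sel$above))
  expect_equal(sort(shuffled$below), sort(sel$below))
})

test_that("coefficient of variation is sd/mean and scale invariant", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(37 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-5, 1)), "positive")
})

test_that("the variance-ratio test is two-sided and scale invariant", {
  x <- rlnorm(20, 1, 0.3)
  same <- cv_ratio_test(x, x)
  expect_equal(same$f_statistic, 1)
  expect_equal(same$f_pvalue, 1)

  set.seed(5)
  a <- rlnorm(15, 2, 0.4); b <- rlnorm(12, 1, 0.2)
  p1 <- cv_ratio_test(a, b)$f_pvalue
  p2 <- cv_ratio_test(a * 100, b * 0.01)$f_pvalue
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_true(cv_ratio_test(rep(2, 5), rlnorm(5))$degenerate)
})

test_that("the variance-ratio test has power against a 4-fold variance ratio", {
  set.seed(12)
  rej <- mean(vapply(1:200, function(i) {
    a <- rlnorm(30, 3, 0.4)   # log2-variance ratio 4 against sd 0.2
    b <- rlnorm(30, 3, 0.2)
    cv_ratio_test(a, b)$f_pvalue < 0.05
  }, logical(1)))
  expect_gt(rej, 0.9)
})

test_that("aggregating the printed CV table reproduces the paired t result", {
  rows <- printed_cv_table()
  agg <- aggregate_cv_comparison(rows)
  expect_equal(round(agg$t_statistic, 2), -0.42)
  expect_equal(agg$df, 16)
  expect_equal(round(agg$p_t, 2), 0.68)

  # rank-sum statistic equals an exhaustive pair-counting U oracle on the
  # printed (rounded) values
  la <- log2(rows$cv_above); lb <- log2(rows$cv_below)
  u <- sum(outer(la, lb, ">")) + 0.5 * sum(outer(la, lb, "=="))
  expect_equal(agg$w_statistic, u)

  # antisymmetry: swapping the columns flips the t sign exactly
  swapped <- aggregate_cv_comparison(
    dplyr::rename(rows, cv_above = "cv_below", cv_below = "cv_above")
  )
  expect_equal(swapped$t_statistic, -agg$t_statistic)

  # identical columns: no difference at all
  same <- aggregate_cv_comparison(
    tibble::tibble(cv_above = rows$cv_above, cv_below = rows$cv_above)
  )
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_t, 1)
})

test_that("rank-difference profiles read off grid spacing exactly", {
  set.seed(3)
  dense <- quantize_fluorescence(runif(4000, 50, 250), 0.5)
  prof <- rank_difference_profile(dense)
  expect_equal(rank_diff_head_mean(prof), -1)

  unit <- rank_difference_profile(quantize_fluorescence(runif(4000, 50, 250), 1))
  expect_equal(rank_diff_head_mean(unit), 0)

  # brute-force oracle on arbitrary unique values + translation invariance
  v <- runif(200, 0, 10)
  prof2 <- rank_difference_profile(v)
  u <- sort(unique(v))
  expect_equal(prof2$log2_diff, log2(diff(u)))
  expect_equal(nrow(prof2), length(u) - 1L)
  shifted <- rank_difference_profile(v + 1234.5)
  expect_equal(shifted$log2_diff, prof2$log2_diff, tolerance = 1e-9)

  expect_error(rank_difference_profile(c(1, 1, 2)), "unique")
})

test_that("the uniformity scan is calibrated on null data and powered on shifts", {
  make_ds <- function(shift_half = FALSE) {
    n_per <- 20L
    grid <- tidyr::crossing(
      analyte = sprintf("A%02d (1)", 1:9),
      tissue = c("plasma", "saliva", "serum", "urine"),
      rep = 1:n_per
    )
    mu <- ifelse(shift_half & grid$analyte <= "A04 (1)" &
                   grid$tissue %in% c("plasma", "serum"), 2, 0)
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(nrow(grid))),
      tissue = grid$tissue, condition = "Normal", plate = "plate1",
      analyte = grid$analyte, well_role = "sample",
      standard_level = NA_integer_,
      fluorescence = 2^(8 + mu + rnorm(nrow(grid), 0, 0.7)),
      concentration = NA_real_, censor_status = "unset"
    )
  }

  set.seed(31)
  scan <- pvalue_uniformity_scan(make_ds())
  expect_equal(nrow(scan$pvalues), 54L)  # 9 analytes x C(4,2) tissue pairs

  # null calibration: the KS statistic rejects near (somewhat above) the
  # nominal 5% rate; the exact rank-sum p-value has discrete support, which
  # biases the KS comparison against a continuous uniform upward
  set.seed(77)
  rej <- mean(vapply(1:200, function(i) {
    pvalue_uniformity_scan(make_ds())$ks_pvalue < 0.05
  }, logical(1)))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.2)

  # true tissue shifts overrepresent the smallest p-values
  set.seed(78)
  null_frac <- pvalue_uniformity_scan(make_ds())$prop_below_05
  shift_frac <- pvalue_uniformity_scan(make_ds(TRUE))$prop_below_05
  expect_gt(shift_frac, null_frac)
})
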