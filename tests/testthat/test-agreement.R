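test_that("pairing intersects image sets and respects selectors", {
  a <- tibble::tibble(image_id = c("img1", "img2", "img3"), count = c(3, 5, 8))
  b <- tibble::tibble(image_id = c("img2", "img3", "img4"), count = c(5, 9, 2))
  p <- pair_counts(a, b)
  expect_equal(nrow(p), 2)
  expect_equal(attr(p, "n_dropped"), 2)
  expect_equal(p$image_id, c("img2", "img3"))

  identical_pair <- pair_counts(a, a)
  expect_equal(identical_pair$x_ref, identical_pair$x_other)

  cohort <- make_small_cohort()
  tool <- simulate_observer_counts(cohort$truth, cohort$design,
                                   default_observer_profile("ExP", "o1"),
                                   mode = "tool", seed = 1, dot_times = FALSE)
  sheet <- simulate_observer_counts(cohort$truth, cohort$design,
                                    default_observer_profile("ExP", "o1"),
                                    mode = "spreadsheet", seed = 2)
  both <- bind_annotations(tool, sheet)
  p_tool <- pair_counts(both, both, select_a = list(mode = "tool"),
                        select_b = list(mode = "tool"))
  expect_equal(nrow(p_tool), nrow(cohort$design))

  expect_error(pair_counts(a, tibble::tibble(image_id = "zzz", count = 1)),
               class = "leafagree_no_overlap")
})

test_that("the agreement report matches hand-computed values", {
  perfect <- agreement_report(make_paired(c(3, 5, 8), c(3, 5, 8)))
  expect_equal(perfect$dic_mean, 0)
  expect_equal(perfect$dic_sd, 0)
  expect_equal(perfect$adic_mean, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$alpha, 1)

  rep <- agreement_report(make_paired(c(5, 6, 7), c(4, 6, 9)))
  expect_equal(rep$dic_mean, -1 / 3)
  expect_equal(rep$dic_sd, 1.527525, tolerance = 1e-6)
  expect_equal(rep$adic_mean, 1)
  expect_equal(rep$mse, 5 / 3)
  expect_equal(rep$r2, 0.9868421, tolerance = 1e-6)
})

test_that("zero-variance references flag R^2 as undefined without erroring", {
  rep <- agreement_report(make_paired(c(4, 4, 4), c(3, 5, 7)))
  expect_true(is.na(rep$r2))
  expect_true(attr(rep, "r2_undefined"))
  expect_false(is.na(rep$mse))
})

test_that("alpha is 1 for identical raters and matches the brute-force oracle", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(krippendorff_alpha(m), 1)

  m2 <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(krippendorff_alpha(m2), alpha_bruteforce(m2), tolerance = 1e-12)

  # permutation of the unit order leaves alpha unchanged
  perm <- m2[c(3, 1, 4, 2), ]
  expect_equal(krippendorff_alpha(perm), krippendorff_alpha(m2))

  # two zero counts agree perfectly under the ratio metric
  m3 <- cbind(c(0, 2, 3), c(0, 2, 4))
  expect_equal(krippendorff_alpha(m3), alpha_bruteforce(m3), tolerance = 1e-12)

  expect_error(krippendorff_alpha(cbind(c(1, NA), c(NA, 2))),
               class = "leafagree_insufficient_data")
  expect_error(krippendorff_alpha(cbind(1:3, 3:1), metric = "interval"),
               class = "leafagree_configuration")
})

test_that("MSE decomposes into squared bias plus population variance", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    p <- make_paired(sample(0:15, n, replace = TRUE),
                     sample(0:15, n, replace = TRUE))
    rep <- agreement_report(p)
    d <- p$x_ref - p$x_other
    pop_var <- mean((d - mean(d))^2)
    expect_equal(rep$mse, rep$dic_mean^2 + pop_var, tolerance = 1e-10)
    expect_gte(rep$adic_mean, abs(rep$dic_mean))
  }
})

test_that("mean absolute difference equals |mean difference| iff one sign", {
  one_sign <- agreement_report(make_paired(c(5, 6, 7), c(4, 5, 6)))
  expect_equal(one_sign$adic_mean, abs(one_sign$dic_mean))
  mixed <- agreement_report(make_paired(c(5, 6, 7), c(6, 6, 6)))
  expect_gt(mixed$adic_mean, abs(mixed$dic_mean))
})

test_that("R^2 is symmetric and invariant to affine rescaling", {
  x <- c(4, 7, 9, 12, 6)
  y <- c(5, 6, 10, 11, 7)
  r2_xy <- agreement_report(make_paired(x, y))$r2
  r2_yx <- agreement_report(make_paired(y, x))$r2
  expect_equal(r2_xy, r2_yx)
  r2_scaled <- cor(2 * x + 3, y)^2
  expect_equal(r2_xy, r2_scaled, tolerance = 1e-12)
})

test_that("within-one-leaf agreement counts pairs with |difference| <= 1", {
  expect_equal(within_one_fraction(make_paired(c(5, 6, 7), c(4, 6, 9))), 2 / 3)
  expect_equal(within_one_fraction(make_paired(c(5, 6), c(5, 6))), 1)
  expect_equal(within_one_fraction(make_paired(c(9, 9), c(4, 4))), 0)
})

test_that("annotation timing summarises durations and excludes outliers", {
  ann <- make_dot_annotations(list(c(0, 3, 10)))
  ts <- timing_summary(ann)
  expect_equal(ts$records$duration_s, 10)
  expect_equal(ts$gap_mean, 5)
  expect_equal(ts$n_excluded, 0)

  ts_out <- timing_summary(make_dot_annotations(list(c(0, 3, 250), c(0, 2, 4))))
  expect_equal(ts_out$n_excluded, 1)
  expect_equal(ts_out$duration_mean, 4)
  expect_equal(ts_out$gap_mean, 2)

  ts_single <- timing_summary(make_dot_annotations(list(5, c(0, 1, 2))))
  expect_equal(nrow(ts_single$records), 1)
})
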