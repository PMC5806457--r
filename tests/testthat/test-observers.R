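noiseless <- function(id = "perfect") {
  observer_profile(id, "ExP", p_miss_young = c(high = 0, low = 0),
                   p_miss_old = 0, p_spurious = 0)
}

test_that("a noiseless observer in tool mode reproduces the truth exactly", {
  cohort <- make_small_cohort()
  ann <- simulate_observer_counts(cohort$truth, cohort$design, noiseless(),
                                  seed = 1)
  expect_equal(ann$count[match(cohort$truth$counts$image_id, ann$image_id)],
               cohort$truth$counts$true_count)
})

test_that("deterministic young-leaf misses remove exactly the young leaves", {
  # slope 1 leaf/day from n0 = 2: at day 8 a plant has 10 leaves of which
  # exactly 2 are younger than 2 days.
  design <- build_design(cultivars = "solo", n_replicates = 1, n_timepoints = 5)
  truth <- simulate_growth(design,
                           growth_params(n0 = 2, rate = c(solo = 1),
                                         plant_effect_sd = 0),
                           seed = 1)
  profile <- observer_profile("harsh", "NExP",
                              p_miss_young = c(high = 1, low = 1),
                              p_miss_old = 0, p_spurious = 0)
  ann <- simulate_observer_counts(truth, design, profile, seed = 2)
  day8 <- ann[grepl("t05", ann$image_id), ]
  expect_equal(truth$counts$true_count[grepl("t05", truth$counts$image_id)], 10)
  expect_equal(day8$count, 8)
})

test_that("observer simulation is reproducible under a fixed seed", {
  cohort <- make_small_cohort()
  profile <- default_observer_profile("NExP")
  a <- simulate_observer_counts(cohort$truth, cohort$design, profile, seed = 5)
  b <- simulate_observer_counts(cohort$truth, cohort$design, profile, seed = 5)
  expect_identical(a, b)
})

test_that("an unknown annotation mode is rejected", {
  cohort <- make_small_cohort()
  expect_error(
    simulate_observer_counts(cohort$truth, cohort$design, noiseless(),
                             mode = "clipboard", seed = 1),
    class = "leafagree_invalid_mode"
  )
})

test_that("miss-only observers never overcount and degrade monotonically", {
  design <- build_design(cultivars = "solo", n_replicates = 1, n_timepoints = 4)
  truth <- simulate_growth(design,
                           growth_params(n0 = 3, rate = c(solo = 0.6),
                                         plant_effect_sd = 0),
                           seed = 2)
  truth_counts <- truth$counts$true_count[match(design$image_id,
                                                truth$counts$image_id)]
  mean_count <- function(p_young, n = 500, seed0 = 1000) {
    totals <- vapply(seq_len(n), function(i) {
      profile <- observer_profile("x", "NExP",
                                  p_miss_young = c(high = p_young, low = p_young),
                                  p_miss_old = 0.05, p_spurious = 0)
      ann <- simulate_observer_counts(truth, design, profile,
                                      seed = seed0 + i, dot_times = FALSE)
      expect_true(all(ann$count <= truth_counts))
      mean(ann$count)
    }, numeric(1))
    mean(totals)
  }
  expect_gt(mean_count(0.1), mean_count(0.5))
  expect_gt(mean_count(0.5), mean_count(0.9))
})

test_that("spreadsheet mode perturbs counts but never below zero", {
  design <- build_design(cultivars = "solo", n_replicates = 1, n_timepoints = 5)
  truth <- simulate_growth(design,
                           growth_params(n0 = 0, rate = c(solo = 0.1),
                                         plant_effect_sd = 0),
                           seed = 3)
  profile <- observer_profile("s", "NExP", p_miss_young = c(high = 0, low = 0),
                              p_miss_old = 0, sd_extra_noise = 3)
  counts <- unlist(lapply(1:50, function(i) {
    simulate_observer_counts(truth, design, profile, mode = "spreadsheet",
                             seed = i, dot_times = FALSE)$count
  }))
  expect_true(all(counts >= 0))
  expect_gt(stats::var(counts), 0)
})

test_that("dot timestamps are generated with one dot per counted leaf", {
  cohort <- make_small_cohort()
  ann <- simulate_observer_counts(cohort$truth, cohort$design, noiseless(),
                                  seed = 4, dot_times = TRUE)
  lens <- vapply(ann$dot_times_s, length, integer(1))
  expect_equal(lens, ann$count)
  nondecreasing <- vapply(ann$dot_times_s,
                          function(d) is.null(d) || all(diff(d) >= 0),
                          logical(1))
  expect_true(all(nondecreasing))
})

test_that("citizen studies keep 3-8 distinct users per image", {
  cohort <- make_small_cohort()
  study <- simulate_citizen_study(cohort$truth, cohort$design, pool_size = 20,
                                  seed = 11)
  per_image <- table(study$image_id)
  expect_true(all(per_image >= 3 & per_image <= 8))
  expect_equal(anyDuplicated(study[, c("user_id", "image_id")]), 0L)
})

test_that("a noiseless citizen pool reports the truth with high confidence", {
  cohort <- make_small_cohort()
  study <- simulate_citizen_study(cohort$truth, cohort$design, pool_size = 12,
                                  base_profile = noiseless("citizen"),
                                  seed = 13)
  truth_by_image <- cohort$truth$counts$true_count[
    match(study$image_id, cohort$truth$counts$image_id)]
  expect_equal(study$count, truth_by_image)
  expect_equal(as.integer(names(which.max(table(study$confidence)))), 3L)
})

test_that("activity skew concentrates annotations on few users", {
  cohort <- make_small_cohort()
  pool_size <- 30
  shares <- vapply(1:20, function(i) {
    study <- simulate_citizen_study(cohort$truth, cohort$design,
                                    pool_size = pool_size, activity_skew = 1.5,
                                    seed = 500 + i)
    top4 <- sort(table(study$user_id), decreasing = TRUE)[1:4]
    sum(top4) / nrow(study)
  }, numeric(1))
  expect_gt(mean(shares), 4 / pool_size)
})

test_that("too small a citizen pool is an infeasible assignment", {
  cohort <- make_small_cohort()
  expect_error(
    simulate_citizen_study(cohort$truth, cohort$design, pool_size = 7, seed = 1),
    class = "leafagree_infeasible_assignment"
  )
})
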