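test_that("count tables have one row per plant and time point", {
  design <- build_design()
  truth <- simulate_growth(design, growth_params(), seed = 1)
  single <- simulate_observer_counts(truth, design,
                                     default_observer_profile("ExP", "o1"),
                                     seed = 2, dot_times = FALSE)
  tab <- build_count_table(single, design, "single")
  expect_equal(nrow(tab), 130)
  expect_equal(length(unique(tab$plant_id)), 10)
})

test_that("mean aggregation averages observers per image", {
  cohort <- make_small_cohort(plant_effect_sd = 0)
  ids <- cohort$design$image_id
  a <- tibble::tibble(observer_id = "a", image_id = ids, count = 4)
  b <- tibble::tibble(observer_id = "b", image_id = ids, count = 6)
  tab <- build_count_table(bind_annotations(a, b), cohort$design,
                           "mean_over_observers")
  expect_true(all(tab$count == 5))

  expect_error(build_count_table(bind_annotations(a, b), cohort$design, "single"),
               class = "leafagree_configuration")
  expect_error(build_count_table(a[-1, ], cohort$design, "single"),
               class = "leafagree_missing_data")
})

test_that("identical cultivar trajectories give a null interaction estimate", {
  design <- build_design(n_replicates = 3, n_timepoints = 6)
  truth <- simulate_growth(
    design,
    growth_params(rate = c(wild_type = 0.4, mutant = 0.4), plant_effect_sd = 0),
    seed = 1
  )
  tab <- build_count_table(truth, design, "single")
  res <- fit_interaction_anova(tab)
  expect_lt(abs(attr(res, "interaction")$estimate), 1e-8)
})

test_that("a degenerate mixed fit reproduces the OLS ANCOVA F test", {
  # Noise shared across plants within a cultivar: between-plant variance is
  # exactly zero, so the mixed model collapses onto ordinary least squares.
  set.seed(41)
  times <- seq(0, 24, by = 2)
  grid <- expand.grid(rep = 1:4, time_days = times,
                      cultivar = c("wild_type", "mutant"),
                      stringsAsFactors = FALSE)
  shared_noise <- stats::setNames(
    rnorm(length(times) * 2, 0, 0.8),
    paste(rep(c("wild_type", "mutant"), each = length(times)), times)
  )
  grid$count <- 2 + ifelse(grid$cultivar == "wild_type", 0.5, 0.35) * grid$time_days +
    shared_noise[paste(grid$cultivar, grid$time_days)]
  grid$plant_id <- paste(grid$cultivar, grid$rep)
  tab <- leafagree:::new_count_table(grid[, c("plant_id", "cultivar",
                                              "time_days", "count")])
  mixed <- fit_interaction_anova(tab, engine = "lmer")
  ols <- fit_interaction_anova(tab, engine = "ols")
  expect_equal(mixed$f_value[mixed$interaction], ols$f_value[ols$interaction],
               tolerance = 1e-6)
  # auto cascade also lands on the same F for these data
  auto <- fit_interaction_anova(tab)
  expect_equal(auto$f_value[auto$interaction], ols$f_value[ols$interaction],
               tolerance = 1e-6)
})

test_that("the OLS engine agrees with a nested-model F comparison", {
  cohort <- make_small_cohort(seed = 9)
  tab <- build_count_table(cohort$truth, cohort$design, "single")
  res <- fit_interaction_anova(tab, engine = "ols")
  full <- lm(count ~ time_days * cultivar, data = tab)
  reduced <- lm(count ~ time_days + cultivar, data = tab)
  oracle <- anova(reduced, full)
  expect_equal(res$f_value[res$interaction], oracle$F[2], tolerance = 1e-10)
  expect_equal(res$p_value[res$interaction], oracle$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("the default effect size is detected in almost all cohorts", {
  design <- build_design()
  p_vals <- vapply(1:200, function(i) {
    truth <- simulate_growth(design, growth_params(), seed = 3000 + i)
    tab <- build_count_table(truth, design, "single")
    res <- fit_interaction_anova(tab)
    res$p_value[res$interaction][1]
  }, numeric(1))
  expect_gte(mean(p_vals < 0.05), 0.95)
})

test_that("model output is invariant to count-table row order", {
  cohort <- make_small_cohort(seed = 4)
  tab <- build_count_table(cohort$truth, cohort$design, "single")
  res <- fit_interaction_anova(tab)
  shuffled <- tab[sample(nrow(tab)), ]
  res_shuffled <- fit_interaction_anova(leafagree:::new_count_table(shuffled))
  expect_identical(res$p_value, res_shuffled$p_value)
})

test_that("underpowered tables are rejected up front", {
  cohort <- make_small_cohort()
  tab <- build_count_table(cohort$truth, cohort$design, "single")
  one_cultivar <- tab[tab$cultivar == "mutant", ]
  expect_error(fit_interaction_anova(leafagree:::new_count_table(one_cultivar)),
               class = "leafagree_insufficient_data")
  mislabelled <- tab
  mislabelled$cultivar <- rep(c("wild_type", "mutant"),
                              length.out = nrow(mislabelled))
  expect_error(fit_interaction_anova(leafagree:::new_count_table(mislabelled)),
               class = "leafagree_invalid_design")
})

test_that("growth curves average plants with sample SDs", {
  toy <- leafagree:::new_count_table(tibble::tibble(
    plant_id = c("p1", "p1", "p2", "p2"),
    cultivar = "wild_type",
    time_days = c(0, 2, 0, 2),
    count = c(2, 4, 4, 6)
  ))
  gc <- growth_curves(toy)
  expect_equal(gc$mean_count, c(3, 5))
  expect_equal(gc$sd_count, c(sd(c(2, 4)), sd(c(4, 6))))
  expect_equal(gc$n, c(2L, 2L))

  singleton <- leafagree:::new_count_table(tibble::tibble(
    plant_id = c("p1", "p2"), cultivar = c("a", "b"),
    time_days = 0, count = c(3, 5)
  ))
  gc1 <- growth_curves(singleton)
  expect_equal(gc1$sd_count, c(0, 0))
  expect_equal(gc1$n, c(1L, 1L))

  cohort <- make_small_cohort(plant_effect_sd = 0)
  det <- growth_curves(build_count_table(cohort$truth, cohort$design, "single"))
  expect_true(all(det$sd_count == 0))
  expect_s3_class(plot_growth_curves(det), "ggplot")
})
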