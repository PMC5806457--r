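# Shared fixtures and independent oracles, all generated in code.

# Small deterministic cohort: 2 cultivars x 2 replicates x 5 occasions.
make_small_cohort <- function(seed = 1, plant_effect_sd = 0.05,
                              rate = c(wild_type = 0.50, mutant = 0.35)) {
  design <- build_design(n_replicates = 2, n_timepoints = 5)
  truth <- simulate_growth(
    design,
    growth_params(rate = rate, plant_effect_sd = plant_effect_sd),
    seed = seed
  )
  list(design = design, truth = truth)
}

# Stack several observers' annotation sets, keeping the class.
bind_annotations <- function(...) {
  out <- dplyr::bind_rows(...)
  structure(out, class = c("annotation_set", class(tibble::tibble())))
}

# The default 9-observer panel (5 experienced + 4 non-experienced) over a
# design, one seed per observer.
make_panel <- function(truth, design, seed = 100) {
  profiles <- c(
    lapply(1:5, function(i) default_observer_profile("ExP", sprintf("exp_%02d", i))),
    lapply(1:4, function(i) default_observer_profile("NExP", sprintf("nexp_%02d", i)))
  )
  bind_annotations(lapply(seq_along(profiles), function(i) {
    simulate_observer_counts(truth, design, profiles[[i]],
                             seed = seed + i, dot_times = FALSE)
  }))
}

# Minimal paired_counts from two raw vectors.
make_paired <- function(x_ref, x_other) {
  ids <- sprintf("img_%03d", seq_along(x_ref))
  pair_counts(tibble::tibble(image_id = ids, count = x_ref),
              tibble::tibble(image_id = ids, count = x_other))
}

# Independent brute-force oracle for Krippendorff's alpha (ratio scale):
# enumerates every ordered within-unit pair for the observed disagreement
# and every ordered cross-position pair of pairable values for the expected
# disagreement.  Deliberately takes a different route from the package's
# coincidence-matrix implementation.
alpha_bruteforce <- function(ratings) {
  m <- as.matrix(ratings)
  keep <- rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  delta2 <- function(c, k) {
    if (c == k) return(0)
    ((c - k) / (c + k))^2
  }
  d_obs_num <- 0
  n <- 0
  pooled <- numeric(0)
  for (u in seq_len(nrow(m))) {
    vals <- m[u, !is.na(m[u, ])]
    mu <- length(vals)
    n <- n + mu
    pooled <- c(pooled, vals)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) d_obs_num <- d_obs_num + delta2(vals[i], vals[j]) / (mu - 1)
    }
  }
  d_obs <- d_obs_num / n
  d_exp_num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d_exp_num <- d_exp_num + delta2(pooled[i], pooled[j])
  }
  d_exp <- d_exp_num / (n * (n - 1))
  if (d_exp == 0) return(1)
  1 - d_obs / d_exp
}

# Random small ratings matrix (counts 0..5, missingness allowed) that is
# guaranteed to be pairable.
random_ratings <- function(max_units = 6, max_raters = 3, p_missing = 0.2) {
  repeat {
    nu <- sample(2:max_units, 1)
    nr <- sample(2:max_raters, 1)
    m <- matrix(sample(0:5, nu * nr, replace = TRUE), nu, nr)
    m[matrix(runif(nu * nr) < p_missing, nu, nr)] <- NA
    pairable <- rowSums(!is.na(m)) >= 2
    if (sum(pairable) >= 2) return(m)
  }
}

# Hand-built annotation_set with dot timestamps for the timing tests.
make_dot_annotations <- function(dot_lists) {
  leafagree:::new_annotation_set(tibble::tibble(
    observer_id = "obs_1",
    experience = "ExP",
    image_id = sprintf("img_%03d", seq_along(dot_lists)),
    dataset_label = "A",
    mode = "tool",
    reading_index = 1L,
    count = vapply(dot_lists, length, integer(1)),
    dot_times_s = dot_lists
  ))
}

# Hand-built citizen_study from per-image counts and confidences.
make_citizen_study <- function(counts_by_image, conf_by_image) {
  rows <- lapply(seq_along(counts_by_image), function(i) {
    k <- length(counts_by_image[[i]])
    tibble::tibble(
      user_id = sprintf("citizen_%03d", seq_len(k)),
      logged_in = FALSE,
      image_id = sprintf("img_%03d", i),
      count = as.integer(counts_by_image[[i]]),
      confidence = as.integer(conf_by_image[[i]])
    )
  })
  leafagree:::new_citizen_study(dplyr::bind_rows(rows))
}
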