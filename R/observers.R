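#' Define an observer error profile
#'
#' An observer detects each true leaf independently, missing young leaves
#' (age below the cohort's `young_age_days`) with a resolution-dependent
#' probability and mature leaves with a smaller one, and occasionally adds
#' one spurious count.  Counting without the dot-annotation tool
#' ("spreadsheet" mode) adds a further discretised zero-mean perturbation,
#' emulating restarts of manual counting.
#'
#' @param observer_id Identifier string.
#' @param experience One of `"ExP"` (experienced in image-based phenotyping),
#'   `"NExP"` (experienced with images only) or `"citizen"`.
#' @param p_miss_young Named probabilities of missing a young leaf, one per
#'   resolution variant, e.g. `c(high = 0.10, low = 0.30)`.
#' @param p_miss_old Probability of missing a mature leaf.
#' @param p_spurious Probability of adding one extra count.
#' @param sd_extra_noise SD of the additional integer perturbation applied in
#'   spreadsheet mode (counts are clipped at 0).
#' @return An `observer_profile` object.
#' @export
observer_profile <- function(observer_id,
                             experience = c("ExP", "NExP", "citizen"),
                             p_miss_young = c(high = 0, low = 0),
                             p_miss_old = 0,
                             p_spurious = 0,
                             sd_extra_noise = 0.8) {
  experience <- match.arg(experience)
  probs <- c(p_miss_young, p_miss_old, p_spurious)
  if (!is.numeric(probs) || any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_class("configuration", "all miss/spurious probabilities must lie in [0, 1]")
  }
  if (is.null(names(p_miss_young)) ||
      !all(c("low", "high") %in% names(p_miss_young))) {
    stop_class("configuration", "`p_miss_young` needs named entries for \"low\" and \"high\"")
  }
  assert_scalar_number(sd_extra_noise, "sd_extra_noise", min = 0)
  structure(list(observer_id = as.character(observer_id),
                 experience = experience,
                 p_miss_young = p_miss_young,
                 p_miss_old = p_miss_old,
                 p_spurious = p_spurious,
                 sd_extra_noise = sd_extra_noise),
            class = "observer_profile")
}

#' Default observer profiles
#'
#' Experienced observers miss young leaves mainly at low resolution; the
#' non-experienced miss them regardless of resolution; citizen volunteers
#' behave like non-experienced observers with a slightly higher mature-leaf
#' miss rate (a net tendency to undercount).  All defaults are miss-only
#' (`p_spurious = 0`).
#'
#' @param experience `"ExP"`, `"NExP"` or `"citizen"`.
#' @param observer_id Identifier; defaults to the experience label.
#' @return An `observer_profile`.
#' @export
default_observer_profile <- function(experience = c("ExP", "NExP", "citizen"),
                                     observer_id = experience) {
  experience <- match.arg(experience)
  switch(experience,
    ExP = observer_profile(observer_id, "ExP",
                           p_miss_young = c(high = 0.10, low = 0.30),
                           p_miss_old = 0.01),
    NExP = observer_profile(observer_id, "NExP",
                            p_miss_young = c(high = 0.35, low = 0.35),
                            p_miss_old = 0.02),
    citizen = observer_profile(observer_id, "citizen",
                               p_miss_young = c(high = 0.35, low = 0.35),
                               p_miss_old = 0.04)
  )
}

# Leaf ages for one plant at one occasion, from the emergence times.
leaf_ages_at <- function(truth, plant_id, time_days) {
  e <- truth$emergence[[plant_id]]
  e <- e[e <= time_days + 1e-9]
  time_days - e
}

# One noisy reading of one image; returns the count and how many true
# leaves were missed (used by the citizen confidence model).
observe_one <- function(ages, profile, resolution, young_age_days) {
  p_miss <- ifelse(ages < young_age_days,
                   unname(profile$p_miss_young[[resolution]]),
                   profile$p_miss_old)
  detected <- if (length(ages) == 0) 0L else sum(runif(length(ages)) >= p_miss)
  spurious <- if (profile$p_spurious > 0) rbinom(1, 1, profile$p_spurious) else 0L
  list(count = as.integer(detected + spurious),
       missed = as.integer(length(ages) - detected))
}

#' Simulate one observer's counts over a study design
#'
#' Applies the profile's detection model to every image in the design.  In
#' `"tool"` mode, per-leaf dot-annotation timestamps can be generated as
#' cumulative exponential gaps; in `"spreadsheet"` mode a discretised
#' zero-mean perturbation (SD `sd_extra_noise`) is added and the count is
#' clipped at zero.
#'
#' @param truth A `ground_truth` from [simulate_growth()].
#' @param design The `study_design` the truth was simulated for (or a subset
#'   of it).
#' @param profile An `observer_profile`.
#' @param mode `"tool"` or `"spreadsheet"`.
#' @param reading_index 1-based index distinguishing repeated readings by the
#'   same observer.
#' @param seed Integer seed; identical seeds give identical annotations.
#' @param dot_times Generate per-leaf timestamps? Defaults to `TRUE` in tool
#'   mode.
#' @param gap_mean_s Mean gap (seconds) between successive dots.
#' @return An `annotation_set` tibble with columns `observer_id`,
#'   `experience`, `image_id`, `dataset_label`, `mode`, `reading_index`,
#'   `count` and a `dot_times_s` list-column (NULL entries when disabled).
#' @export
simulate_observer_counts <- function(truth, design, profile,
                                     mode = "tool",
                                     reading_index = 1L,
                                     seed = NULL,
                                     dot_times = identical(mode, "tool"),
                                     gap_mean_s = 1.1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"),
            inherits(profile, "observer_profile"))
  if (length(mode) != 1 || !mode %in% c("tool", "spreadsheet")) {
    stop_class("invalid_mode", "`mode` must be \"tool\" or \"spreadsheet\"")
  }
  missing_imgs <- setdiff(design$image_id, truth$counts$image_id)
  if (length(missing_imgs) > 0) {
    stop_class("missing_data", "truth does not cover %d design image(s), e.g. %s",
               length(missing_imgs), missing_imgs[1])
  }
  young <- truth$params$young_age_days

  counts <- with_seed_if(seed, {
    purrr::map(seq_len(nrow(design)), function(i) {
      ages <- leaf_ages_at(truth, design$plant_id[i], design$time_days[i])
      obs <- observe_one(ages, profile, design$resolution_variant[i], young)
      n <- obs$count
      if (mode == "spreadsheet") {
        n <- max(0L, n + as.integer(round_half_up(rnorm(1, 0, profile$sd_extra_noise))))
      }
      dots <- if (dot_times && n > 0) cumsum(rexp(n, rate = 1 / gap_mean_s)) else NULL
      list(count = n, dots = dots)
    })
  })

  new_annotation_set(tibble::tibble(
    observer_id = profile$observer_id,
    experience = profile$experience,
    image_id = design$image_id,
    dataset_label = design$dataset_label,
    mode = mode,
    reading_index = as.integer(reading_index),
    count = purrr::map_int(counts, "count"),
    dot_times_s = purrr::map(counts, "dots")
  ))
}

new_annotation_set <- function(x) {
  structure(tibble::as_tibble(x),
            class = c("annotation_set", class(tibble::tibble())))
}

default_confidence_table <- function() {
  # P(confidence 3/2/1 | leaves missed on that image).
  rbind(`0`  = c(`3` = 0.80, `2` = 0.15, `1` = 0.05),
        `1`  = c(`3` = 0.50, `2` = 0.30, `1` = 0.20),
        `2+` = c(`3` = 0.20, `2` = 0.40, `1` = 0.40))
}

#' Simulate a citizen-science annotation campaign
#'
#' Each image receives between 3 and 8 annotations from distinct users drawn
#' from a pool whose activity is Zipf-skewed (a few prolific users contribute
#' a large share, as crowd platforms typically show).  Counts come from the
#' base profile's detection model; each user's self-reported confidence
#' ("did you annotate all leaves": yes = 3, not sure = 2, missed leaves = 1)
#' is drawn conditionally on how many leaves that user actually missed.
#'
#' @param truth,design As in [simulate_observer_counts()].
#' @param pool_size Number of available users (>= 8, so that up to 8 distinct
#'   users per image exist).
#' @param activity_skew Zipf exponent of the user-activity weights
#'   (0 = uniform activity; larger = heavier tail).
#' @param base_profile `observer_profile` shared by all users.
#' @param confidence_table 3 x 3 row-stochastic matrix: rows = leaves missed
#'   (`"0"`, `"1"`, `"2+"`), columns = confidence (`"3"`, `"2"`, `"1"`).
#' @param p_logged_in Probability that a user is a logged-in platform member
#'   (fixed per user).
#' @param seed Integer seed.
#' @return A `citizen_study` tibble with columns `user_id`, `logged_in`,
#'   `image_id`, `count`, `confidence`.
#' @export
simulate_citizen_study <- function(truth, design,
                                   pool_size = 40,
                                   activity_skew = 1.0,
                                   base_profile = default_observer_profile("citizen"),
                                   confidence_table = default_confidence_table(),
                                   p_logged_in = 0.4,
                                   seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"),
            inherits(base_profile, "observer_profile"))
  if (!is_count(pool_size) || pool_size < 8) {
    stop_class("infeasible_assignment",
               "`pool_size` must be >= 8 so that 8 distinct users per image exist")
  }
  assert_scalar_number(activity_skew, "activity_skew", min = 0)
  stopifnot(is.matrix(confidence_table), dim(confidence_table) == c(3, 3))
  young <- truth$params$young_age_days
  conf_levels <- c(3L, 2L, 1L)

  with_seed_if(seed, {
    weights <- seq_len(pool_size)^(-activity_skew)
    logged_in <- runif(pool_size) < p_logged_in
    rows <- purrr::map(seq_len(nrow(design)), function(i) {
      n_u <- sample(3:8, 1)
      users <- sample.int(pool_size, n_u, prob = weights)
      ages <- leaf_ages_at(truth, design$plant_id[i], design$time_days[i])
      ann <- purrr::map(users, function(u) {
        obs <- observe_one(ages, base_profile, design$resolution_variant[i], young)
        miss_row <- min(obs$missed, 2L) + 1L
        conf <- sample(conf_levels, 1, prob = confidence_table[miss_row, ])
        list(user = u, count = obs$count, confidence = conf)
      })
      tibble::tibble(
        user_id = sprintf("citizen_%03d", purrr::map_int(ann, "user")),
        logged_in = logged_in[purrr::map_int(ann, "user")],
        image_id = design$image_id[i],
        count = purrr::map_int(ann, "count"),
        confidence = purrr::map_int(ann, "confidence")
      )
    })
    new_citizen_study(dplyr::bind_rows(rows))
  })
}

new_citizen_study <- function(x) {
  x <- tibble::as_tibble(x)
  dup <- duplicated(x[, c("user_id", "image_id")])
  if (any(dup)) {
    stop_class("invalid_design", "the same user rated the same image twice")
  }
  if (!all(x$confidence %in% 1:3)) {
    stop_class("parse", "confidence values must be 1, 2 or 3")
  }
  structure(x, class = c("citizen_study", class(tibble::tibble())))
}
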