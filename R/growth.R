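#' Growth parameters for the synthetic cohort
#'
#' The latent leaf count of plant *p* at time *t* (days) is
#' `n0 + max(0, rate[cultivar] + u_p) * t`, where `u_p` is a per-plant
#' normal deviation of the emergence rate with standard deviation
#' `plant_effect_sd`.  Observed true counts are the latent value rounded
#' half-up and forced non-decreasing.  Leaves younger than `young_age_days`
#' at an imaging occasion count as "young" for the observer error model.
#'
#' Defaults give end-of-study counts near 14 (wild type) vs 10 (mutant)
#' over a 24-day window, a clearly diverging pair of growth curves.
#'
#' @param n0 Initial leaf count (integer >= 0).
#' @param rate Named vector of leaf emergence rates (leaves/day, >= 0), one
#'   entry per cultivar.
#' @param plant_effect_sd Between-plant SD of the emergence rate
#'   (leaves/day, >= 0).
#' @param young_age_days Age threshold (days, > 0) below which a leaf is
#'   considered young (small and easy to miss).
#' @return A `growth_params` object.
#' @export
growth_params <- function(n0 = 2,
                          rate = c(wild_type = 0.50, mutant = 0.35),
                          plant_effect_sd = 0.05,
                          young_age_days = 2) {
  if (!is_count(n0)) stop_class("configuration", "`n0` must be an integer >= 0")
  if (!is.numeric(rate) || is.null(names(rate)) || any(!nzchar(names(rate))) ||
      any(!is.finite(rate)) || any(rate < 0)) {
    stop_class("configuration", "`rate` must be a named numeric vector of non-negative rates")
  }
  assert_scalar_number(plant_effect_sd, "plant_effect_sd", min = 0)
  assert_scalar_number(young_age_days, "young_age_days", min = 0, strict_min = TRUE)
  structure(list(n0 = n0, rate = rate, plant_effect_sd = plant_effect_sd,
                 young_age_days = young_age_days),
            class = "growth_params")
}

#' Simulate ground-truth leaf counts for a study design
#'
#' Draws one rate deviation per plant, evaluates the latent growth line at
#' every imaging occasion, and records both the rounded true count per image
#' and the per-plant leaf emergence times (the times at which the latent
#' count crosses successive integers; leaves present at the start emerge at
#' time 0).  Transformed image copies automatically share the truth of their
#' originals because truth depends only on plant and time.
#'
#' @param design A `study_design` from [build_design()].
#' @param params A `growth_params` object.
#' @param seed Integer seed; identical seeds give identical truths.
#' @return A `ground_truth` object: list with `counts` (tibble `image_id`,
#'   `plant_id`, `time_days`, `true_count`), `emergence` (named list of
#'   non-decreasing emergence-time vectors per plant) and `params`.
#' @examples
#' gt <- simulate_growth(build_design(), growth_params(), seed = 1)
#' head(gt$counts)
#' @export
simulate_growth <- function(design, params = growth_params(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (nrow(design) == 0) stop_class("invalid_design", "`design` is empty")
  if (!inherits(params, "growth_params")) {
    stop_class("configuration", "`params` must be a `growth_params` object")
  }
  plants <- dplyr::distinct(design, .data$plant_id, .data$cultivar)
  plants <- plants[order(plants$plant_id), ]
  unknown <- setdiff(plants$cultivar, names(params$rate))
  if (length(unknown) > 0) {
    stop_class("configuration", "no emergence rate configured for cultivar(s): %s",
               paste(unknown, collapse = ", "))
  }

  u <- with_seed_if(seed, rnorm(nrow(plants), 0, params$plant_effect_sd))
  plants$slope <- pmax(0, unname(params$rate[plants$cultivar]) + u)

  counts <- dplyr::left_join(
    design[, c("image_id", "plant_id", "time_days")],
    plants[, c("plant_id", "slope")], by = "plant_id"
  )
  counts$true_count <- round_half_up(params$n0 + counts$slope * counts$time_days)
  # Enforce monotone trajectories (no-op while slopes are non-negative).
  counts <- counts |>
    dplyr::arrange(.data$plant_id, .data$time_days) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::mutate(true_count = cummax(.data$true_count)) |>
    dplyr::ungroup()

  t_max <- max(design$time_days)
  emergence <- lapply(seq_len(nrow(plants)), function(i) {
    s <- plants$slope[i]
    final <- round_half_up(params$n0 + s * t_max)
    if (final == 0) return(numeric(0))
    j <- seq_len(final)
    if (s == 0) return(rep(0, final))
    pmax(0, (j - 0.5 - params$n0) / s)
  })
  names(emergence) <- plants$plant_id

  structure(
    list(counts = tibble::as_tibble(
           counts[, c("image_id", "plant_id", "time_days", "true_count")]),
         emergence = emergence,
         params = params),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d images, %d plants, final counts %d-%d\n",
              nrow(x$counts), length(x$emergence),
              min(x$counts$true_count), max(x$counts$true_count)))
  invisible(x)
}
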