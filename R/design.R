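#' Build a longitudinal imaging study design
#'
#' Enumerates one image record per cultivar, replicate, time point and
#' resolution variant, optionally adding a geometrically transformed copy of
#' every image.  The default arguments reproduce a two-cultivar design
#' (wild-type vs a slower-growing starch mutant) with 5 replicates each,
#' imaged every 48 h for 13 time points: 130 images per resolution variant.
#'
#' Dataset labels follow the usual blinding convention: `A` = low-resolution
#' originals, `B` = high-resolution originals, `C`/`D` = their transformed
#' copies.  Transformed copies depict the same plants, so they share the
#' ground truth of their originals; the transform is metadata only.
#'
#' @param cultivars Character vector of cultivar names. The first is treated
#'   as the wild type in downstream defaults.
#' @param n_replicates Plants per cultivar (>= 1).
#' @param n_timepoints Imaging occasions per plant (>= 2).
#' @param interval_h Hours between consecutive occasions (> 0).
#' @param resolution_variants Subset of `c("low", "high")` (nominal pixel
#'   sizes 300 and 470).
#' @param include_transformed If `TRUE`, add a transformed copy of every
#'   image, with the transform drawn at random from 90/180/270 degree
#'   rotations and horizontal/vertical flips.
#' @param seed Integer seed for the transform assignment (the only random
#'   element); ignored when `include_transformed = FALSE`.
#'
#' @return A `study_design` tibble with columns `image_id`, `plant_id`,
#'   `cultivar`, `replicate_index`, `timepoint_index`, `time_days`,
#'   `resolution_variant`, `transform_variant`, `dataset_label`.
#' @examples
#' design <- build_design()
#' nrow(design) # 130
#' @export
build_design <- function(cultivars = c("wild_type", "mutant"),
                         n_replicates = 5,
                         n_timepoints = 13,
                         interval_h = 48,
                         resolution_variants = "low",
                         include_transformed = FALSE,
                         seed = NULL) {
  if (length(cultivars) < 1 || anyDuplicated(cultivars)) {
    stop_class("invalid_design", "`cultivars` must be a non-empty set of distinct names")
  }
  if (!is_count(n_replicates) || n_replicates < 1) {
    stop_class("invalid_design", "`n_replicates` must be an integer >= 1")
  }
  if (!is_count(n_timepoints) || n_timepoints < 2) {
    stop_class("invalid_design", "`n_timepoints` must be an integer >= 2")
  }
  assert_scalar_number(interval_h, "interval_h", min = 0, strict_min = TRUE)
  if (length(resolution_variants) < 1 ||
      !all(resolution_variants %in% c("low", "high")) ||
      anyDuplicated(resolution_variants)) {
    stop_class("invalid_design",
               "`resolution_variants` must be a distinct subset of c(\"low\", \"high\")")
  }

  grid <- tidyr::expand_grid(
    cultivar = cultivars,
    replicate_index = seq_len(n_replicates),
    timepoint_index = seq_len(n_timepoints),
    resolution_variant = resolution_variants
  )
  grid$time_days <- (grid$timepoint_index - 1) * interval_h / 24
  grid$transform_variant <- "identity"

  if (include_transformed) {
    transforms <- c("rot90", "rot180", "rot270", "hflip", "vflip")
    copies <- grid
    copies$transform_variant <- with_seed_if(
      seed,
      sample(transforms, nrow(copies), replace = TRUE)
    )
    grid <- dplyr::bind_rows(grid, copies)
  }

  grid$dataset_label <- dataset_label_for(grid$resolution_variant,
                                          grid$transform_variant)
  grid$plant_id <- paste(grid$cultivar,
                         sprintf("r%02d", grid$replicate_index), sep = "_")
  grid$image_id <- paste(grid$plant_id,
                         sprintf("t%02d", grid$timepoint_index),
                         grid$resolution_variant,
                         grid$transform_variant, sep = "_")
  out <- grid[, c("image_id", "plant_id", "cultivar", "replicate_index",
                  "timepoint_index", "time_days", "resolution_variant",
                  "transform_variant", "dataset_label")]
  stopifnot(!anyDuplicated(out$image_id))
  new_study_design(out)
}

dataset_label_for <- function(resolution, transform) {
  transformed <- transform != "identity"
  dplyr::case_when(
    resolution == "low" & !transformed ~ "A",
    resolution == "high" & !transformed ~ "B",
    resolution == "low" & transformed ~ "C",
    TRUE ~ "D"
  )
}

new_study_design <- function(x) {
  structure(tibble::as_tibble(x),
            class = c("study_design", class(tibble::tibble())))
}
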