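# CSV/JSON readers and writers.  All CSVs are RFC 4180 with a header row,
# UTF-8, written/read through readr.

quiet_read <- function(path, col_types) {
  if (!file.exists(path)) stop_class("parse", "file not found: %s", path)
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_class("parse", "%s: missing column(s) %s", path,
               paste(miss, collapse = ", "))
  }
}

parse_count_column <- function(x, column, path) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | n < 0 | n != trunc(n))
  if (length(bad) > 0) {
    stop_class("parse", "%s: row %d, column `%s`: \"%s\" is not a non-negative integer",
               path, bad[1], column, x[bad[1]])
  }
  as.integer(n)
}

#' Write / read a study design as CSV
#'
#' Columns: `image_id`, `cultivar`, `replicate`, `timepoint`, `time_days`,
#' `resolution`, `transform`, `dataset_label`.
#'
#' @param design A `study_design`.
#' @param path File path.
#' @return `write_design_csv()` returns `path` invisibly;
#'   `read_design_csv()` returns a `study_design`.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  out <- tibble::tibble(
    image_id = design$image_id,
    cultivar = design$cultivar,
    replicate = design$replicate_index,
    timepoint = design$timepoint_index,
    time_days = design$time_days,
    resolution = design$resolution_variant,
    transform = design$transform_variant,
    dataset_label = design$dataset_label
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- quiet_read(path, readr::cols(.default = readr::col_character(),
                                     replicate = readr::col_integer(),
                                     timepoint = readr::col_integer(),
                                     time_days = readr::col_double()))
  require_columns(df, c("image_id", "cultivar", "replicate", "timepoint",
                        "time_days", "resolution", "transform",
                        "dataset_label"), path)
  new_study_design(tibble::tibble(
    image_id = df$image_id,
    plant_id = paste(df$cultivar, sprintf("r%02d", df$replicate), sep = "_"),
    cultivar = df$cultivar,
    replicate_index = df$replicate,
    timepoint_index = df$timepoint,
    time_days = df$time_days,
    resolution_variant = df$resolution,
    transform_variant = df$transform,
    dataset_label = df$dataset_label
  ))
}

#' Write / read ground-truth counts as CSV
#'
#' Columns: `image_id`, `true_count`.  Only the per-image counts are
#' serialised; emergence times are a simulation-internal construct and are
#' regenerated, not stored.
#'
#' @param truth A `ground_truth`.
#' @param path File path.
#' @return `write_truth_csv()` returns `path` invisibly;
#'   `read_truth_csv()` returns a tibble (`image_id`, `true_count`).
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  readr::write_csv(truth$counts[, c("image_id", "true_count")], path)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- quiet_read(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("image_id", "true_count"), path)
  tibble::tibble(image_id = df$image_id,
                 true_count = parse_count_column(df$true_count, "true_count", path))
}

#' Write / read an annotation set as CSV
#'
#' Columns: `observer_id`, `experience`, `image_id`, `dataset_label`,
#' `mode`, `reading_index`, `count`.  Dot timestamps are an in-memory
#' payload and are not serialised.  An empty (header-only) file reads as an
#' empty set with a warning.
#'
#' @param set An `annotation_set`.
#' @param path File path.
#' @return `write_annotation_csv()` returns `path` invisibly;
#'   `read_annotation_csv()` returns an `annotation_set`.
#' @export
write_annotation_csv <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  readr::write_csv(set[, c("observer_id", "experience", "image_id",
                           "dataset_label", "mode", "reading_index", "count")],
                   path)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- quiet_read(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("observer_id", "experience", "image_id",
                        "dataset_label", "mode", "reading_index", "count"),
                  path)
  if (nrow(df) == 0) {
    warn(sprintf("%s: header only, returning an empty annotation set", path))
    return(new_annotation_set(tibble::tibble(
      observer_id = character(), experience = character(),
      image_id = character(), dataset_label = character(),
      mode = character(), reading_index = integer(), count = integer(),
      dot_times_s = list()
    )))
  }
  new_annotation_set(tibble::tibble(
    observer_id = df$observer_id,
    experience = df$experience,
    image_id = df$image_id,
    dataset_label = df$dataset_label,
    mode = df$mode,
    reading_index = parse_count_column(df$reading_index, "reading_index", path),
    count = parse_count_column(df$count, "count", path),
    dot_times_s = vector("list", nrow(df))
  ))
}

#' Write / read a citizen-platform classification export
#'
#' The export dialect mirrors crowd-annotation platforms: one row per
#' classification with columns `classification_id`, `user_id`, `logged_in`,
#' `image_id`, `annotation_json` (a JSON array of `{x, y}` dot positions
#' whose length is the leaf count) and `confidence`.  On reading, the count
#' is the length of the dot array and the confidence answer is accepted as
#' literal 1/2/3 or as the words yes / not sure / missed leaves.
#'
#' @param study A `citizen_study`.
#' @param path File path.
#' @param image_px Nominal image size used to fabricate dot coordinates.
#' @param seed Integer seed for the fabricated coordinates.
#' @return `write_citizen_export()` returns `path` invisibly;
#'   `read_citizen_export()` returns a `citizen_study`.
#' @export
write_citizen_export <- function(study, path, image_px = 300, seed = NULL) {
  stopifnot(inherits(study, "citizen_study"))
  payload <- with_seed_if(seed, {
    purrr::map_chr(study$count, function(n) {
      if (n == 0) return("[]")
      dots <- data.frame(x = round(runif(n, 0, image_px), 1),
                         y = round(runif(n, 0, image_px), 1))
      as.character(jsonlite::toJSON(dots, dataframe = "rows"))
    })
  })
  out <- tibble::tibble(
    classification_id = seq_len(nrow(study)),
    user_id = study$user_id,
    logged_in = study$logged_in,
    image_id = study$image_id,
    annotation_json = payload,
    confidence = study$confidence
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_citizen_export
#' @export
read_citizen_export <- function(path) {
  df <- quiet_read(path, readr::cols(.default = readr::col_character()))
  require_columns(df, c("classification_id", "user_id", "logged_in",
                        "image_id", "annotation_json", "confidence"), path)
  counts <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    dots <- tryCatch(jsonlite::fromJSON(df$annotation_json[i],
                                        simplifyVector = FALSE),
                     error = function(e) NULL)
    if (is.null(dots) || !is.list(dots)) {
      stop_class("parse", "%s: row %d, column `annotation_json`: malformed JSON",
                 path, i)
    }
    counts[i] <- length(dots)
  }
  conf_map <- c(yes = 3L, `not sure` = 2L, `missed leaves` = 1L,
                `1` = 1L, `2` = 2L, `3` = 3L)
  key <- tolower(trimws(df$confidence))
  conf <- unname(conf_map[key])
  if (anyNA(conf)) {
    bad <- which(is.na(conf))[1]
    stop_class("parse", "%s: row %d, column `confidence`: \"%s\" is not a valid answer",
               path, bad, df$confidence[bad])
  }
  new_citizen_study(tibble::tibble(
    user_id = df$user_id,
    logged_in = tolower(df$logged_in) %in% c("true", "1", "yes"),
    image_id = df$image_id,
    count = counts,
    confidence = conf
  ))
}

#' Serialise an agreement report
#'
#' CSV keeps exactly the report's field names; JSON adds nothing else.
#'
#' @param report An `agreement_report`.
#' @param path File path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(tibble::as_tibble(report)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::as_tibble(report), path)
  }
  invisible(path)
}

#' Read a wide ratings table into a units-by-raters matrix
#'
#' Expects an `image_id` column plus one column per rater; empty cells are
#' missing ratings.
#'
#' @param path File path.
#' @return Numeric matrix with image ids as row names.
#' @export
read_ratings_csv <- function(path) {
  df <- quiet_read(path, readr::cols(.default = readr::col_double(),
                                     image_id = readr::col_character()))
  require_columns(df, "image_id", path)
  m <- as.matrix(df[, setdiff(names(df), "image_id"), drop = FALSE])
  rownames(m) <- df$image_id
  m
}

#' Serialise a Bland-Altman grid
#'
#' Writes the cells as CSV (`mean_value`, `diff_value`, `multiplicity`) and,
#' optionally, a JSON sidecar with the bias and limits of agreement.
#'
#' @param grid A `ba_grid`.
#' @param path CSV file path.
#' @param sidecar Optional JSON file path.
#' @return `path`, invisibly.
#' @export
write_ba_grid <- function(grid, path, sidecar = NULL) {
  stopifnot(inherits(grid, "ba_grid"))
  readr::write_csv(grid$cells, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(list(bias = grid$bias, loa_low = grid$loa_low,
                              loa_high = grid$loa_high, n = grid$n),
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Serialise consensus counts
#'
#' Columns: `image_id`, `method`, `value`, `n_annotations`.
#'
#' @param consensus A `consensus_counts` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_counts"))
  readr::write_csv(tibble::as_tibble(consensus), path)
  invisible(path)
}

#' Serialise one or more p-value summaries
#'
#' One row per summary: `pool`, `K`, `min`, `max`, `mean`, `sd`,
#' `kurtosis`, `n_failed`.
#'
#' @param summaries A `pvalue_summary` or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pvalue_summaries <- function(summaries, path) {
  if (inherits(summaries, "pvalue_summary")) summaries <- list(summaries)
  rows <- purrr::map(summaries, function(s) {
    tibble::tibble(pool = s$pool, K = s$K, min = s$minimum, max = s$maximum,
                   mean = s$mean, sd = s$sd, kurtosis = s$kurtosis,
                   n_failed = s$n_failed)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
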