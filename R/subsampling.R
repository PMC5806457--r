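#' Draw a random observer-sampling matrix
#'
#' A sampling matrix selects, for every plant-time observation (row),
#' exactly `K` observers (columns) whose annotations are averaged into that
#' row's consensus.  Columns are chosen uniformly at random without
#' replacement, independently across rows.
#'
#' @param n_rows Number of plant-time observations.
#' @param pool_size Number of available observers.
#' @param K Annotations per row (`1 <= K <= pool_size`).
#' @param seed Integer seed.
#' @return A `sampling_matrix`: binary `n_rows x pool_size` matrix whose
#'   rows each sum to `K` (stored as attribute `K`).
#' @export
draw_sampling_matrix <- function(n_rows, pool_size, K, seed = NULL) {
  if (!is_count(n_rows) || n_rows < 1 || !is_count(pool_size) || pool_size < 1) {
    stop_class("invalid_design", "`n_rows` and `pool_size` must be positive integers")
  }
  if (!is_count(K) || K < 1 || K > pool_size) {
    stop_class("infeasible", "`K` must satisfy 1 <= K <= pool_size (got K = %s)",
               format(K))
  }
  m <- matrix(0L, n_rows, pool_size)
  with_seed_if(seed, {
    for (i in seq_len(n_rows)) m[i, sample.int(pool_size, K)] <- 1L
  })
  structure(m, K = as.integer(K), class = c("sampling_matrix", "matrix", "array"))
}

#' Consensus counts selected by a sampling matrix
#'
#' @param matrix A `sampling_matrix` (or any binary matrix with constant row
#'   sums).
#' @param counts_by_observer Numeric matrix of counts, rows aligned with the
#'   sampling matrix's rows and one column per observer (a list of
#'   equal-length vectors is accepted).
#' @return Numeric vector: per row, the mean count of the selected
#'   observers.
#' @export
matrix_consensus <- function(matrix, counts_by_observer) {
  if (is.list(counts_by_observer) && !is.data.frame(counts_by_observer)) {
    counts_by_observer <- do.call(cbind, counts_by_observer)
  }
  counts_by_observer <- as.matrix(counts_by_observer)
  if (!all(dim(matrix) == dim(counts_by_observer))) {
    stop_class("shape", "sampling matrix is %d x %d but counts are %d x %d",
               nrow(matrix), ncol(matrix),
               nrow(counts_by_observer), ncol(counts_by_observer))
  }
  rs <- rowSums(matrix)
  rowSums(matrix * counts_by_observer) / rs
}

#' Select an observer pool by experience
#'
#' Named pools mirror the three conditions of the subsampling experiment:
#' all observers, experienced only, or non-experienced only.
#'
#' @param annotations An `annotation_set` containing the candidate
#'   observers.
#' @param pool `"any"`, `"ExP"` or `"NExP"`.
#' @return Character vector of observer ids.
#' @export
observer_pool <- function(annotations, pool = c("any", "ExP", "NExP")) {
  pool <- match.arg(pool)
  stopifnot(inherits(annotations, "annotation_set"))
  tab <- dplyr::distinct(annotations, .data$observer_id, .data$experience)
  ids <- switch(pool,
                any = tab$observer_id,
                ExP = tab$observer_id[tab$experience == "ExP"],
                NExP = tab$observer_id[tab$experience == "NExP"])
  if (length(ids) == 0) stop_class("insufficient_data", "pool \"%s\" is empty", pool)
  sort(ids)
}

#' Monte-Carlo observer-subsampling study
#'
#' Repeatedly asks: if each plant-time observation were annotated by only
#' `K` of the available observers (chosen at random), would the
#' genotype-by-time interaction still be detected?  Per trial it draws a
#' sampling matrix, averages the selected observers' counts into a
#' consensus, fits the interaction ANOVA and records the interaction
#' p-value; the p-value distribution over trials is then summarised.
#'
#' @param annotations An `annotation_set` stacking the pool observers'
#'   counts over all design images.
#' @param design The `study_design` (one resolution variant).
#' @param pool Character vector of observer ids to sample from.
#' @param K Annotations per plant-time observation.
#' @param n_trials Number of Monte-Carlo trials (default 500).
#' @param seed Master seed; each trial derives its own sub-seed, so single
#'   trials can be reproduced.
#' @param pool_label Label stored in the summary (e.g. `"Any"`,
#'   `"ExP only"`).
#' @return A `pvalue_summary` (see [summarize_pvalues()]) with the trial
#'   p-values attached as `p_values` and failed-trial count `n_failed`.
#' @export
run_subsampling_study <- function(annotations, design, pool, K,
                                  n_trials = 500, seed = NULL,
                                  pool_label = "Any") {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(design, "study_design"))
  if (!is_count(n_trials) || n_trials < 1) {
    stop_class("invalid_design", "`n_trials` must be a positive integer")
  }
  if (!is_count(K) || K < 1 || K > length(pool)) {
    stop_class("infeasible", "`K` must satisfy 1 <= K <= |pool|")
  }
  if (is.null(seed)) seed <- as.integer(runif(1, 1, 2^30))

  # Per-observer count vectors aligned with the design rows.
  counts <- matrix(NA_real_, nrow(design), length(pool),
                   dimnames = list(NULL, pool))
  for (j in seq_along(pool)) {
    obs <- annotations[annotations$observer_id == pool[j], ]
    idx <- match(design$image_id, obs$image_id)
    if (anyNA(idx)) {
      stop_class("missing_data", "observer %s lacks counts for %d design image(s)",
                 pool[j], sum(is.na(idx)))
    }
    counts[, j] <- obs$count[idx]
  }

  base <- design[, c("plant_id", "cultivar", "time_days")]
  p_values <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    m <- draw_sampling_matrix(nrow(design), length(pool), K,
                              seed = derive_seed(seed, i))
    base$count <- matrix_consensus(m, counts)
    tab <- base |>
      dplyr::group_by(.data$plant_id, .data$cultivar, .data$time_days) |>
      dplyr::summarise(count = mean(.data$count), .groups = "drop") |>
      new_count_table()
    p_values[i] <- tryCatch({
      res <- fit_interaction_anova(tab)
      res$p_value[res$interaction][1]
    }, error = function(e) NA_real_)
  }

  ok <- !is.na(p_values)
  out <- summarize_pvalues(p_values[ok])
  out$n_trials <- n_trials
  out$n_failed <- sum(!ok)
  out$K <- as.integer(K)
  out$pool <- pool_label
  out$p_values <- p_values[ok]
  out
}

#' Summary statistics of a p-value distribution
#'
#' @param p_list Numeric vector of p-values in `[0, 1]`.
#' @return A `pvalue_summary` list: `minimum`, `maximum`, `mean`, `sd`
#'   (sample SD; 0 for a single value), `kurtosis` (raw, non-excess moment
#'   ratio, `NA` when the values are constant), `n_trials`, `n_failed`,
#'   `pool`, `K`.
#' @export
summarize_pvalues <- function(p_list) {
  if (length(p_list) == 0) stop_class("insufficient_data", "empty p-value list")
  if (any(!is.finite(p_list)) || any(p_list < 0 | p_list > 1)) {
    stop_class("parse", "p-values must lie in [0, 1]")
  }
  structure(list(
    minimum = min(p_list),
    maximum = max(p_list),
    mean = mean(p_list),
    sd = if (length(p_list) > 1) sd(p_list) else 0,
    kurtosis = sample_kurtosis_raw(p_list),
    n_trials = length(p_list),
    n_failed = 0L,
    pool = NA_character_,
    K = NA_integer_
  ), class = "pvalue_summary")
}

#' @export
print.pvalue_summary <- function(x, ...) {
  cat(sprintf(
    "<pvalue_summary> pool %s, K %s: min %.2e, max %.2e, mean %.2e, sd %.2e, kurtosis %s (%d trials, %d failed)\n",
    x$pool, format(x$K), x$minimum, x$maximum, x$mean, x$sd,
    ifelse(is.na(x$kurtosis), "NA", sprintf("%.2f", x$kurtosis)),
    x$n_trials, x$n_failed))
  invisible(x)
}
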