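#' Align two count sources into paired vectors
#'
#' Extracts one count per image from each source, keeps the images present in
#' both, and returns the pairs ordered by `image_id`.  Sources can be
#' `annotation_set`s (optionally filtered down to a single observer, mode,
#' dataset or reading), `consensus_counts`, a `ground_truth`, or any tibble
#' with an `image_id` and a single count-like column.
#'
#' @param set_a Reference source (the `X_R` side).
#' @param set_b Comparison source (the `X_o` side).
#' @param select_a,select_b Optional named lists of column filters applied
#'   before pairing, e.g. `list(observer_id = "exp_1", mode = "tool")`.
#' @return A `paired_counts` tibble with columns `image_id`, `x_ref`,
#'   `x_other`; the number of images dropped from either side is attached as
#'   attribute `n_dropped`.
#' @export
pair_counts <- function(set_a, set_b, select_a = NULL, select_b = NULL) {
  a <- as_count_source(set_a, select_a, "set_a")
  b <- as_count_source(set_b, select_b, "set_b")
  shared <- sort(intersect(a$image_id, b$image_id))
  if (length(shared) == 0) {
    stop_class("no_overlap", "the two sources share no image after filtering")
  }
  n_dropped <- (nrow(a) - length(shared)) + (nrow(b) - length(shared))
  out <- tibble::tibble(
    image_id = shared,
    x_ref = a$count[match(shared, a$image_id)],
    x_other = b$count[match(shared, b$image_id)]
  )
  structure(out, class = c("paired_counts", class(tibble::tibble())),
            n_dropped = n_dropped)
}

as_count_source <- function(x, select, what) {
  if (inherits(x, "ground_truth")) {
    x <- dplyr::rename(x$counts, count = "true_count")
  } else if (inherits(x, "consensus_counts")) {
    x <- dplyr::rename(tibble::as_tibble(x), count = "value")
  }
  if (!is.data.frame(x) || !all(c("image_id", "count") %in% names(x))) {
    stop_class("parse", "`%s` must provide `image_id` and a count column", what)
  }
  for (nm in names(select)) {
    if (!nm %in% names(x)) {
      stop_class("parse", "`%s` has no column `%s` to filter on", what, nm)
    }
    x <- x[x[[nm]] %in% select[[nm]], ]
  }
  if (anyDuplicated(x$image_id)) {
    stop_class("parse",
               "`%s` still has multiple counts per image after filtering; refine the selector",
               what)
  }
  x[, c("image_id", "count")]
}

#' The agreement-metric suite for a pair of count sources
#'
#' Computes, for differences `d = x_ref - x_other` (positive values mean the
#' comparison source undercounts relative to the reference):
#' * **DiC** — mean and sample SD of `d`;
#' * **|DiC|** — mean and sample SD of `|d|`;
#' * **MSE** — `mean(d^2)`;
#' * **R^2** — squared Pearson correlation of the two vectors (flagged `NA`
#'   when either vector has zero variance);
#' * **alpha** — Krippendorff's alpha on a ratio scale over the two columns.
#'
#' @param paired A `paired_counts` object with at least 2 pairs.
#' @return An `agreement_report`: one-row tibble with fields `dic_mean`,
#'   `dic_sd`, `adic_mean`, `adic_sd`, `mse`, `r2`, `alpha`.  When R^2 is
#'   undefined the attribute `r2_undefined` is `TRUE`.
#' @examples
#' p <- pair_counts(tibble::tibble(image_id = letters[1:3], count = c(5, 6, 7)),
#'                  tibble::tibble(image_id = letters[1:3], count = c(4, 6, 9)))
#' agreement_report(p)
#' @export
agreement_report <- function(paired) {
  stopifnot(inherits(paired, "paired_counts"))
  n <- nrow(paired)
  if (n < 2) stop_class("insufficient_data", "need at least 2 pairs, got %d", n)
  d <- paired$x_ref - paired$x_other
  r2_undef <- sd(paired$x_ref) == 0 || sd(paired$x_other) == 0
  r2 <- if (r2_undef) NA_real_ else cor(paired$x_ref, paired$x_other)^2
  out <- tibble::tibble(
    dic_mean = mean(d),
    dic_sd = sd(d),
    adic_mean = mean(abs(d)),
    adic_sd = sd(abs(d)),
    mse = mean(d^2),
    r2 = r2,
    alpha = krippendorff_alpha(cbind(paired$x_ref, paired$x_other))
  )
  structure(out, class = c("agreement_report", class(tibble::tibble())),
            r2_undefined = r2_undef, n = n)
}

#' Krippendorff's alpha for count data on a ratio scale
#'
#' Chance-adjusted inter-rater agreement `1 - D_o / D_e`, with observed and
#' expected disagreement computed from the coincidence matrix over all
#' pairable values and the ratio difference function
#' `delta^2(c, k) = ((c - k) / (c + k))^2` (defined as 0 for `c = k`,
#' including two zero counts).  Units with fewer than two non-missing
#' ratings contribute nothing.
#'
#' @param ratings Numeric matrix or data frame, units (images) in rows and
#'   raters in columns; `NA` marks a missing rating.
#' @param metric Difference function; only `"ratio"` is supported.
#' @return Alpha (`<= 1`); exactly 1 when every unit's pairable values agree.
#' @export
krippendorff_alpha <- function(ratings, metric = "ratio") {
  if (!identical(metric, "ratio")) {
    stop_class("configuration", "only the ratio difference function is supported")
  }
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    stop_class("parse", "ratio-scale ratings must be non-negative")
  }
  pairable <- rowSums(!is.na(m)) >= 2
  if (sum(pairable) < 2) {
    stop_class("insufficient_data",
               "need at least 2 units with at least 2 non-missing ratings")
  }
  m <- m[pairable, , drop = FALSE]
  values <- sort(unique(as.vector(m[!is.na(m)])))
  v <- length(values)

  # Coincidence matrix: each ordered within-unit pair (c, k) adds
  # 1 / (m_u - 1) to cell (c, k).
  co <- matrix(0, v, v, dimnames = list(values, values))
  for (u in seq_len(nrow(m))) {
    vals <- m[u, !is.na(m[u, ])]
    mu <- length(vals)
    idx <- match(vals, values)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) co[idx[i], idx[j]] <- co[idx[i], idx[j]] + 1 / (mu - 1)
    }
  }
  n_c <- rowSums(co)
  n_tot <- sum(n_c)

  delta <- outer(values, values, function(c, k) {
    s <- c + k
    ifelse(c == k, 0, ((c - k) / ifelse(s == 0, 1, s))^2)
  })
  d_obs <- sum(co * delta) / n_tot
  d_exp <- sum(outer(n_c, n_c) * delta) / (n_tot * (n_tot - 1))
  if (d_exp == 0) return(1)
  1 - d_obs / d_exp
}

#' Fraction of pairs agreeing within one leaf
#'
#' @param paired A `paired_counts` object.
#' @return Fraction of pairs with `|x_ref - x_other| <= 1`.
#' @export
within_one_fraction <- function(paired) {
  stopifnot(inherits(paired, "paired_counts"))
  if (nrow(paired) < 1) stop_class("insufficient_data", "no pairs")
  mean(abs(paired$x_ref - paired$x_other) <= 1)
}

#' Summarise per-plant annotation timing from dot timestamps
#'
#' The duration of one plant annotation is the time between its first and
#' last dot.  Durations above `outlier_s` (annotators taking a break
#' mid-plant) are excluded from the summaries and counted.  Per-leaf gaps
#' are the successive dot-time differences pooled over included records;
#' records with fewer than two dots contribute no duration.
#'
#' @param annotations An `annotation_set` whose `dot_times_s` column is
#'   populated (tool mode).
#' @param outlier_s Exclusion threshold in seconds (default 200).
#' @return A `timing_summary`: list with a per-record tibble (`observer_id`,
#'   `image_id`, `n_dots`, `duration_s`, `excluded`), summary fields
#'   `duration_mean`, `duration_sd`, `gap_mean`, `gap_sd`, and `n_excluded`.
#' @export
timing_summary <- function(annotations, outlier_s = 200) {
  stopifnot(inherits(annotations, "annotation_set"))
  assert_scalar_number(outlier_s, "outlier_s", min = 0, strict_min = TRUE)
  has_dots <- purrr::map_int(annotations$dot_times_s, length) >= 2
  recs <- annotations[has_dots, ]
  bad <- purrr::map_lgl(recs$dot_times_s, function(d) any(diff(d) < 0))
  if (any(bad)) stop_class("parse", "dot_times_s must be non-decreasing")
  durations <- purrr::map_dbl(recs$dot_times_s, function(d) max(d) - min(d))
  excluded <- durations > outlier_s
  gaps <- unlist(purrr::map(recs$dot_times_s[!excluded], diff), use.names = FALSE)
  structure(list(
    records = tibble::tibble(
      observer_id = recs$observer_id,
      image_id = recs$image_id,
      n_dots = purrr::map_int(recs$dot_times_s, length),
      duration_s = durations,
      excluded = excluded
    ),
    duration_mean = if (any(!excluded)) mean(durations[!excluded]) else NA_real_,
    duration_sd = if (sum(!excluded) > 1) sd(durations[!excluded]) else NA_real_,
    gap_mean = if (length(gaps)) mean(gaps) else NA_real_,
    gap_sd = if (length(gaps) > 1) sd(gaps) else NA_real_,
    n_excluded = sum(excluded),
    outlier_s = outlier_s
  ), class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf(
    "<timing_summary> %d annotations (%d excluded > %g s); duration %.1f +/- %.1f s; per-leaf gap %.2f +/- %.2f s\n",
    nrow(x$records), x$n_excluded, x$outlier_s,
    x$duration_mean, x$duration_sd, x$gap_mean, x$gap_sd))
  invisible(x)
}
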