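#' Aggregate citizen annotations into per-image consensus counts
#'
#' Three aggregation rules: the arithmetic mean of the annotated counts, the
#' maximum (useful when annotators can only miss leaves, so the largest
#' count is the least biased), or a single annotation chosen uniformly at
#' random per image.
#'
#' @param study A `citizen_study`.
#' @param method `"average"`, `"max"` or `"single_random"`.
#' @param seed Integer seed (used by `"single_random"` only).
#' @return A `consensus_counts` tibble: `image_id`, `method`, `value`,
#'   `n_annotations`.
#' @export
consensus_counts <- function(study, method = c("average", "max", "single_random"),
                             seed = NULL) {
  stopifnot(inherits(study, "citizen_study"))
  if (length(method) == 1 && !method %in% c("average", "max", "single_random")) {
    stop_class("invalid_method", "unknown consensus method \"%s\"", method)
  }
  method <- match.arg(method)
  out <- with_seed_if(seed, {
    study |>
      dplyr::group_by(.data$image_id) |>
      dplyr::summarise(
        value = switch(method,
                       average = mean(.data$count),
                       max = as.numeric(max(.data$count)),
                       single_random = as.numeric(
                         .data$count[sample.int(dplyr::n(), 1)])),
        n_annotations = dplyr::n(),
        .groups = "drop"
      )
  })
  out$method <- method
  out <- out[, c("image_id", "method", "value", "n_annotations")]
  structure(out, class = c("consensus_counts", class(tibble::tibble())))
}

#' Self-reported confidence versus count spread
#'
#' For every image with at least two annotations, computes the sample SD of
#' the reported counts (0 meaning full agreement, labelled "none") and the
#' mean confidence, bins both into a normalised two-dimensional histogram,
#' and reports the probability mass in the low-spread / high-confidence
#' quadrant (`count_sd < sd_threshold` and `mean_confidence >
#' conf_threshold`, computed from the raw per-image values).
#'
#' @param study A `citizen_study`.
#' @param sd_threshold,conf_threshold Quadrant boundaries (defaults 1.0 and
#'   2.0, the midpoints of the natural axes).
#' @param sd_bins Numeric break points for the count-SD axis; 0 is always
#'   its own "none" bin.
#' @param conf_bins Numeric break points for the mean-confidence axis over
#'   `[1, 3]`.
#' @return A `confidence_spread`: list with `per_image` (tibble `image_id`,
#'   `count_sd`, `mean_confidence`, `n_annotations`), `histogram` (matrix of
#'   probabilities summing to 1, SD bins in rows), `quadrant_fraction`, and
#'   `n_excluded` (images with a single annotation).
#' @export
confidence_spread <- function(study, sd_threshold = 1.0, conf_threshold = 2.0,
                              sd_bins = c(0.5, 1, 1.5, 2, Inf),
                              conf_bins = c(1, 1.5, 2, 2.5, 3)) {
  stopifnot(inherits(study, "citizen_study"))
  per_image <- study |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      count_sd = if (dplyr::n() > 1) sd(.data$count) else NA_real_,
      mean_confidence = mean(.data$confidence),
      n_annotations = dplyr::n(),
      .groups = "drop"
    )
  n_excluded <- sum(is.na(per_image$count_sd))
  per_image <- per_image[!is.na(per_image$count_sd), ]
  if (nrow(per_image) == 0) {
    stop_class("insufficient_data", "no image has >= 2 annotations")
  }

  sd_breaks <- sort(unique(c(0, sd_bins)))
  sd_labels <- c("none", paste0("(", utils::head(sd_breaks, -1), ",",
                                utils::tail(sd_breaks, -1), "]"))
  sd_bin <- ifelse(per_image$count_sd == 0, "none",
                   as.character(cut(per_image$count_sd, sd_breaks,
                                    labels = utils::tail(sd_labels, -1))))
  conf_breaks <- sort(unique(conf_bins))
  conf_bin <- as.character(cut(per_image$mean_confidence, conf_breaks,
                               include.lowest = TRUE))

  histogram <- table(factor(sd_bin, levels = sd_labels), conf_bin)
  histogram <- histogram / sum(histogram)
  quadrant_fraction <- mean(per_image$count_sd < sd_threshold &
                              per_image$mean_confidence > conf_threshold)

  structure(list(per_image = per_image,
                 histogram = unclass(histogram),
                 quadrant_fraction = quadrant_fraction,
                 n_excluded = n_excluded,
                 sd_threshold = sd_threshold,
                 conf_threshold = conf_threshold),
            class = "confidence_spread")
}

#' @export
print.confidence_spread <- function(x, ...) {
  cat(sprintf(
    "<confidence_spread> %d images (%d excluded); %.0f%% in the low-spread/high-confidence quadrant (sd < %g, confidence > %g)\n",
    nrow(x$per_image), x$n_excluded, 100 * x$quadrant_fraction,
    x$sd_threshold, x$conf_threshold))
  invisible(x)
}
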