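#' Bland-Altman grid for discrete counts
#'
#' A Bland-Altman plot of integer counts stacks many pairs on identical
#' coordinates; the grid representation merges coincident points into cells
#' carrying a multiplicity, so the full distribution stays visible.  Bias is
#' the mean difference and the limits of agreement are `bias +/- 1.96 * SD`
#' of the differences.
#'
#' @param paired A `paired_counts` object with at least 2 pairs.
#' @return A `ba_grid`: list with `cells` (tibble `mean_value`, `diff_value`,
#'   `multiplicity`), `bias`, `loa_low`, `loa_high`, `n`.
#' @examples
#' p <- pair_counts(tibble::tibble(image_id = letters[1:3], count = c(5, 6, 7)),
#'                  tibble::tibble(image_id = letters[1:3], count = c(4, 6, 9)))
#' ba_grid(p)
#' @export
ba_grid <- function(paired) {
  stopifnot(inherits(paired, "paired_counts"))
  n <- nrow(paired)
  if (n < 2) stop_class("insufficient_data", "need at least 2 pairs, got %d", n)
  d <- paired$x_ref - paired$x_other
  m <- (paired$x_ref + paired$x_other) / 2
  cells <- tibble::tibble(mean_value = m, diff_value = as.integer(d)) |>
    dplyr::count(.data$mean_value, .data$diff_value, name = "multiplicity") |>
    dplyr::arrange(.data$mean_value, .data$diff_value)
  bias <- mean(d)
  half_width <- 1.96 * sd(d)
  structure(list(cells = cells, bias = bias,
                 loa_low = bias - half_width, loa_high = bias + half_width,
                 n = n),
            class = "ba_grid")
}

#' @export
print.ba_grid <- function(x, ...) {
  cat(sprintf("<ba_grid> %d pairs in %d cells; bias %.3f, LoA [%.3f, %.3f]\n",
              x$n, nrow(x$cells), x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Histogram of count differences
#'
#' @param paired A `paired_counts` object.
#' @return Tibble with one row per observed integer difference
#'   (`diff_value`, `count`); counts sum to the number of pairs.
#' @export
diff_histogram <- function(paired) {
  stopifnot(inherits(paired, "paired_counts"))
  if (nrow(paired) < 1) stop_class("insufficient_data", "no pairs")
  tibble::tibble(diff_value = as.integer(paired$x_ref - paired$x_other)) |>
    dplyr::count(.data$diff_value, name = "count") |>
    dplyr::arrange(.data$diff_value)
}

#' Plot a Bland-Altman grid
#'
#' Renders the multiplicity-coloured cells with the bias and limits of
#' agreement as horizontal lines.  All statistics live in the `ba_grid`
#' object; this is presentation only.
#'
#' @param grid A `ba_grid`.
#' @return A ggplot object.
#' @export
plot_ba_grid <- function(grid) {
  stopifnot(inherits(grid, "ba_grid"))
  ggplot2::ggplot(grid$cells,
                  ggplot2::aes(.data$mean_value, .data$diff_value,
                               fill = .data$multiplicity)) +
    ggplot2::geom_tile(width = 0.5, height = 0.9) +
    ggplot2::geom_hline(yintercept = grid$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(grid$loa_low, grid$loa_high),
                        linetype = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Mean of pair", y = "Difference (reference - other)",
                  fill = "Pairs") +
    ggplot2::theme_minimal()
}
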