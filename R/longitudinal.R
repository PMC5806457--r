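#' Build a plant-by-time count table for longitudinal modelling
#'
#' Reduces per-image annotations to one (possibly fractional) count per
#' plant and time point: either a single observer's reading or the mean over
#' all supplied observers (consensus counts enter unchanged).  Multiple
#' images of the same plant-time (e.g. a transformed copy) are averaged.
#'
#' @param counts An `annotation_set` (one or several observers stacked),
#'   `consensus_counts`, or a `ground_truth` (its true counts enter as a
#'   single noiseless source).
#' @param design The `study_design` the counts refer to, restricted to one
#'   resolution variant.
#' @param aggregation `"single"` (exactly one observer must be present) or
#'   `"mean_over_observers"`.
#' @return A `count_table` tibble: `plant_id`, `cultivar`, `time_days`,
#'   `count`, one row per plant and time point.
#' @export
build_count_table <- function(counts, design,
                              aggregation = c("single", "mean_over_observers")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(design, "study_design"))
  if (length(unique(design$resolution_variant)) > 1) {
    stop_class("invalid_design",
               "restrict `design` to a single resolution variant before modelling")
  }
  if (inherits(counts, "ground_truth")) {
    src <- tibble::tibble(image_id = counts$counts$image_id,
                          count = counts$counts$true_count)
  } else if (inherits(counts, "consensus_counts")) {
    src <- tibble::tibble(image_id = counts$image_id, count = counts$value)
  } else if (inherits(counts, "annotation_set") || is.data.frame(counts)) {
    src <- tibble::as_tibble(counts)
    if (aggregation == "single" && "observer_id" %in% names(src) &&
        length(unique(src$observer_id)) > 1) {
      stop_class("configuration",
                 "aggregation = \"single\" but %d observers supplied",
                 length(unique(src$observer_id)))
    }
    src <- src[, c("image_id", "count")]
  } else {
    stop_class("parse", "`counts` must be an annotation_set or consensus_counts")
  }

  per_image <- src |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop")
  missing <- setdiff(design$image_id, per_image$image_id)
  if (length(missing) > 0) {
    stop_class("missing_data", "no count for %d design image(s): %s%s",
               length(missing), paste(head(missing, 5), collapse = ", "),
               if (length(missing) > 5) ", ..." else "")
  }

  design |>
    dplyr::inner_join(per_image, by = "image_id") |>
    dplyr::group_by(.data$plant_id, .data$cultivar, .data$time_days) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$plant_id, .data$time_days) |>
    new_count_table()
}

new_count_table <- function(x) {
  structure(tibble::as_tibble(x),
            class = c("count_table", class(tibble::tibble())))
}

#' Mixed-effect repeated-measures ANOVA of counts over time
#'
#' Fits `count ~ time_days * cultivar` with time as a continuous predictor
#' and plant as the random-effect grouping unit, and reports an F test per
#' fixed term with Satterthwaite denominator degrees of freedom.  The term
#' of scientific interest is the time-by-cultivar interaction: it tests
#' whether the cultivars' longitudinal count trends differ.
#'
#' The default random-effect structure is a correlated random intercept and
#' random time slope per plant, matching a cohort in which plants of the
#' same cultivar differ in their individual emergence rates.  When the
#' mixed fit is degenerate (all random-effect variances estimated at zero,
#' or the fit fails), the model falls back first to a random intercept only
#' and finally to the ordinary least-squares ANCOVA, whose F tests coincide
#' with the mixed-model ones in that limit.
#'
#' @param table A `count_table` with >= 2 cultivars, >= 2 plants per
#'   cultivar and >= 3 time points.
#' @param engine `"auto"` (cascade described above), `"lmer"` (fail rather
#'   than fall back to OLS) or `"ols"`.
#' @return An `anova_result` tibble with columns `term`, `sum_sq`, `df_num`,
#'   `df_den`, `f_value`, `p_value`, `interaction` (logical flag).
#'   Attributes: `engine` (the fit actually used) and `interaction`, a list
#'   with the interaction slope-difference `estimate` (second cultivar level
#'   minus first), `se`, `df`, `ci_low`, `ci_high`.
#' @export
fit_interaction_anova <- function(table, engine = c("auto", "lmer", "ols")) {
  engine <- match.arg(engine)
  d <- as.data.frame(table)
  stopifnot(all(c("plant_id", "cultivar", "time_days", "count") %in% names(d)))
  d <- d[order(d$plant_id, d$time_days), ]
  d$cultivar <- factor(d$cultivar, levels = unique(d$cultivar))

  plants_per_cv <- tapply(d$plant_id, d$cultivar, function(p) length(unique(p)))
  if (nlevels(d$cultivar) < 2 || any(plants_per_cv < 2) ||
      length(unique(d$time_days)) < 3) {
    stop_class("insufficient_data",
               "need >= 2 cultivars, >= 2 plants per cultivar and >= 3 time points")
  }
  one_cv <- tapply(d$cultivar, d$plant_id, function(x) length(unique(x)))
  if (any(one_cv > 1)) {
    stop_class("invalid_design", "a plant_id maps to more than one cultivar")
  }

  # Random-effect SDs below 0.1% of the residual SD (theta is scaled by the
  # residual SD) are treated as zero: the fit is then the OLS ANCOVA in
  # mixed-model clothing.
  degenerate <- function(f) all(abs(lme4::getME(f, "theta")) < 1e-3)
  used <- engine
  fit <- NULL
  if (engine != "ols") {
    fit <- fit_lmer_quietly(count ~ time_days * cultivar + (1 + time_days | plant_id), d)
    if (is.null(fit) || degenerate(fit)) {
      # prefer the simpler structure once the slope variance vanishes
      fit2 <- fit_lmer_quietly(count ~ time_days * cultivar + (1 | plant_id), d)
      if (!is.null(fit2)) fit <- fit2
    }
    if (is.null(fit) || degenerate(fit)) {
      if (engine == "lmer" && is.null(fit)) {
        stop_class("model_error", "mixed-model fit failed")
      }
      if (engine == "auto") {
        used <- "ols"
        fit <- NULL
      }
    } else {
      used <- "lmer"
    }
  }

  if (is.null(fit)) {
    lmfit <- lm(count ~ time_days * cultivar, data = d)
    if (any(is.na(coef(lmfit)))) {
      bad <- names(coef(lmfit))[is.na(coef(lmfit))]
      stop_class("model_error", "rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", "))
    }
    a <- as.data.frame(anova(lmfit))
    keep <- rownames(a) != "Residuals"
    res <- tibble::tibble(
      term = rownames(a)[keep],
      sum_sq = a$`Sum Sq`[keep],
      df_num = a$Df[keep],
      df_den = df.residual(lmfit),
      f_value = a$`F value`[keep],
      p_value = a$`Pr(>F)`[keep]
    )
    ct <- coef(summary(lmfit))
    int_row <- grep(":", rownames(ct), value = TRUE)
    inter <- interaction_ci(ct[int_row, "Estimate"], ct[int_row, "Std. Error"],
                            df.residual(lmfit), int_row)
  } else {
    a <- as.data.frame(anova(fit))   # lmerTest: Satterthwaite type III
    res <- tibble::tibble(
      term = rownames(a),
      sum_sq = a$`Sum Sq`,
      df_num = a$NumDF,
      df_den = a$DenDF,
      f_value = a$`F value`,
      p_value = a$`Pr(>F)`
    )
    ct <- coef(summary(fit))
    int_row <- grep(":", rownames(ct), value = TRUE)
    inter <- interaction_ci(ct[int_row, "Estimate"], ct[int_row, "Std. Error"],
                            ct[int_row, "df"], int_row)
  }
  res$interaction <- grepl(":", res$term)
  structure(res, class = c("anova_result", class(tibble::tibble())),
            engine = used, interaction = inter)
}

# REML fit that treats non-convergence as failure and leaves singular fits
# to the caller.  calc.derivs = FALSE skips the finite-difference gradient
# check, which dominates runtime in Monte-Carlo loops.
fit_lmer_quietly <- function(formula, data) {
  tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
}

interaction_ci <- function(estimate, se, df, term, level = 0.95) {
  if (length(estimate) != 1) {
    return(list(term = term, estimate = NA_real_, se = NA_real_, df = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  q <- qt(1 - (1 - level) / 2, df)
  list(term = term, estimate = unname(estimate), se = unname(se),
       df = unname(df),
       ci_low = unname(estimate - q * se), ci_high = unname(estimate + q * se))
}

#' Average growth curves per cultivar
#'
#' @param table A non-empty `count_table`.
#' @return A `growth_curves` tibble: per cultivar and time point the mean
#'   count over plants, the sample SD (0 when a single plant contributes;
#'   inspect `n`), and the number of plants `n`.
#' @export
growth_curves <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table) == 0) stop_class("insufficient_data", "empty count table")
  out <- table |>
    dplyr::group_by(.data$cultivar, .data$time_days) |>
    dplyr::summarise(
      mean_count = mean(.data$count),
      sd_count = if (dplyr::n() > 1) sd(.data$count) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cultivar, .data$time_days)
  structure(out, class = c("growth_curves", class(tibble::tibble())))
}

#' Plot average growth curves with a 1-SD band
#'
#' @param curves A `growth_curves` tibble.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  stopifnot(inherits(curves, "growth_curves"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time_days, .data$mean_count,
                               colour = .data$cultivar, fill = .data$cultivar)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_count - .data$sd_count,
                                      ymax = .data$mean_count + .data$sd_count),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (days)", y = "Leaf count") +
    ggplot2::theme_minimal()
}
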