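#' Default pipeline configuration
#'
#' Returns the full set of simulation and analysis parameters as a nested
#' list: the study design (2 cultivars x 5 replicates x 13 occasions at
#' 48 h), growth defaults, the observer panel (5 experienced + 4
#' non-experienced, matching a 9-observer pool), citizen-pool settings,
#' and analysis thresholds.  A master `seed` is mandatory: every random
#' stage derives a named sub-stream from it.
#'
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed) {
  if (missing(seed) || !is_count(seed)) {
    stop_class("configuration", "a master `seed` is required (no silent nondeterminism)")
  }
  structure(list(
    seed = as.integer(seed),
    design = list(cultivars = c("wild_type", "mutant"), n_replicates = 5,
                  n_timepoints = 13, interval_h = 48,
                  resolution_variants = "low"),
    growth = list(n0 = 2, rate = c(wild_type = 0.50, mutant = 0.35),
                  plant_effect_sd = 0.05, young_age_days = 2),
    observers = list(n_exp = 5, n_nexp = 4),
    citizens = list(pool_size = 40, activity_skew = 1.0),
    analysis = list(outlier_s = 200, sd_threshold = 1.0, conf_threshold = 2.0,
                    n_trials = 500, K = c(1, 2, 3))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its default; the `seed` field is
#' mandatory.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_class("parse", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) {
    stop_class("configuration", "%s: config must set `seed`", path)
  }
  cfg <- default_pipeline_config(raw$seed)
  for (section in c("design", "growth", "observers", "citizens", "analysis")) {
    for (nm in names(raw[[section]])) {
      value <- raw[[section]][[nm]]
      if (nm == "rate") value <- unlist(value)
      cfg[[section]][[nm]] <- value
    }
  }
  cfg
}

#' Run the full simulation-and-analysis pipeline
#'
#' One-shot driver: simulates the cohort, a panel of observers and a
#' citizen campaign, then computes the agreement table against the
#' reference observer, the Bland-Altman grid, the growth curves and
#' interaction ANOVA, the observer-subsampling study and the citizen
#' consensus/confidence analyses, writing every table plus a
#' reproducibility manifest (`manifest.json`: package version, R version,
#' seed, configuration hash) to `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  pth <- function(f) file.path(out_dir, f)

  design <- do.call(build_design, config$design)
  params <- do.call(growth_params, config$growth)
  truth <- simulate_growth(design, params, seed = derive_seed(seed, 1))
  write_design_csv(design, pth("design.csv"))
  write_truth_csv(truth, pth("truth.csv"))

  profiles <- c(
    lapply(seq_len(config$observers$n_exp), function(i)
      default_observer_profile("ExP", sprintf("exp_%02d", i))),
    lapply(seq_len(config$observers$n_nexp), function(i)
      default_observer_profile("NExP", sprintf("nexp_%02d", i)))
  )
  annotations <- dplyr::bind_rows(purrr::imap(profiles, function(p, i) {
    simulate_observer_counts(truth, design, p, seed = derive_seed(seed, 100 + i))
  }))
  annotations <- new_annotation_set(annotations)
  write_annotation_csv(annotations, pth("annotations.csv"))

  ref_id <- profiles[[1]]$observer_id
  others <- setdiff(unique(annotations$observer_id), ref_id)
  agree <- dplyr::bind_rows(lapply(others, function(o) {
    p <- pair_counts(annotations, annotations,
                     select_a = list(observer_id = ref_id),
                     select_b = list(observer_id = o))
    rep <- agreement_report(p)
    dplyr::bind_cols(tibble::tibble(observer_id = o), tibble::as_tibble(rep))
  }))
  readr::write_csv(agree, pth("agreement.csv"))

  pair_first <- pair_counts(annotations, annotations,
                            select_a = list(observer_id = ref_id),
                            select_b = list(observer_id = others[1]))
  write_ba_grid(ba_grid(pair_first), pth("ba_grid.csv"), pth("ba_grid.json"))

  tab <- build_count_table(annotations, design, "mean_over_observers")
  anova_res <- fit_interaction_anova(tab)
  readr::write_csv(
    tibble::tibble(term = anova_res$term, sum_sq = anova_res$sum_sq,
                   F = anova_res$f_value, p = anova_res$p_value),
    pth("anova.csv"))
  readr::write_csv(growth_curves(tab), pth("growth_curves.csv"))

  pool <- observer_pool(annotations, "any")
  subsample <- lapply(config$analysis$K, function(k) {
    run_subsampling_study(annotations, design, pool, K = k,
                          n_trials = config$analysis$n_trials,
                          seed = derive_seed(seed, 200 + k),
                          pool_label = "Any")
  })
  write_pvalue_summaries(subsample, pth("subsampling.csv"))

  citizens <- simulate_citizen_study(
    truth, design, pool_size = config$citizens$pool_size,
    activity_skew = config$citizens$activity_skew,
    seed = derive_seed(seed, 300))
  write_citizen_export(citizens, pth("citizen_export.csv"),
                       seed = derive_seed(seed, 301))
  cons_avg <- consensus_counts(citizens, "average")
  write_consensus_csv(cons_avg, pth("consensus_average.csv"))
  spread <- confidence_spread(citizens,
                              sd_threshold = config$analysis$sd_threshold,
                              conf_threshold = config$analysis$conf_threshold)
  readr::write_csv(spread$per_image, pth("confidence_spread.csv"))
  jsonlite::write_json(
    list(histogram = spread$histogram,
         quadrant_fraction = spread$quadrant_fraction,
         n_excluded = spread$n_excluded),
    pth("confidence_spread.json"), digits = NA)

  manifest <- list(
    package = "leafagree",
    package_version = as.character(utils::packageVersion("leafagree")),
    r_version = R.version.string,
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)

  invisible(list(design = design, truth = truth, annotations = annotations,
                 agreement = agree, anova = anova_res, subsampling = subsample,
                 citizens = citizens, consensus = cons_avg, spread = spread))
}
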