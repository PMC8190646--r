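#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' study constants: fever threshold 38.0, AUC analysis
#' thresholds 38 and 39, horizons 6/8/10/12 h, 72 h case windows, 1 h
#' baseline tolerance, no maximum imputation gap, equal-weight Cohen's d.
#'
#' @param children_path,temps_path,meds_path Input CSVs (see
#'   [read_cohort()]); leave `NULL` to simulate instead.
#' @param sim A [sim_config()] used when no input paths are given.
#' @param fever_threshold_c Episode threshold in Celsius.
#' @param auc_thresholds_c Analysis-population thresholds.
#' @param horizons_h AUC horizons in hours.
#' @param window_h Case window length in hours.
#' @param baseline_tolerance_h Nearest-reading fallback for baselines.
#' @param max_gap_h Maximum imputation gap (`Inf` = off).
#' @param cohen_d_variant `"equal_weight"` or `"n_weighted"`.
#' @param out_dir Output directory for run artifacts (`NULL` = don't write).
#' @param seed Seed used when simulating.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(children_path = NULL, temps_path = NULL,
                            meds_path = NULL, sim = NULL,
                            fever_threshold_c = 38,
                            auc_thresholds_c = c(38, 39),
                            horizons_h = c(6, 8, 10, 12),
                            window_h = 72,
                            baseline_tolerance_h = 1,
                            max_gap_h = Inf,
                            cohen_d_variant = "equal_weight",
                            out_dir = NULL,
                            seed = 1) {
  paths <- c(children_path, temps_path, meds_path)
  if (is.null(sim) && length(paths) != 3) {
    stop("provide the three input CSV paths, or a sim_config", call. = FALSE)
  }
  structure(as.list(environment())[setdiff(ls(), "paths")],
            class = "pipeline_config")
}

#' Run the full fever-analytics pipeline
#'
#' Executes read (or simulate) -> child filters -> episode detection ->
#' case construction -> AUC -> descriptive and AUC comparison tables ->
#' delta curves, and (optionally) writes all artifacts plus a manifest of
#' per-stage record counts to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List: `cohort`, `episodes`, `cases`, `auc`, `table1`, `table2`,
#'   `delta_curves`, `manifest`, and `ground_truth` when simulating.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ground_truth <- NULL
  if (!is.null(config$children_path)) {
    cohort_raw <- read_cohort(config$children_path, config$temps_path,
                              config$meds_path)
  } else {
    sim <- generate_cohort(config$sim, seed = config$seed)
    cohort_raw <- sim$cohort
    ground_truth <- sim$ground_truth
  }

  cohort <- filter_children(cohort_raw,
                            fever_threshold_c = config$fever_threshold_c)
  excl <- attr(cohort, "exclusions")

  if (nrow(cohort$children) == 0) {
    warning("no children retained after eligibility filters", call. = FALSE)
    episodes <- .empty_episodes(); cases <- .empty_cases()
    auc <- tibble::tibble(case_id = character(), horizon_h = numeric(),
                          auc_c_h = numeric(), truncated = logical())
    table1 <- NULL; table2 <- tibble::tibble(); curves <- tibble::tibble()
  } else {
    episodes <- detect_episodes_cohort(cohort,
                                       threshold_c = config$fever_threshold_c,
                                       max_gap_h = config$max_gap_h)
    cases <- build_cases(cohort, window_h = config$window_h,
                         baseline_tolerance_h = config$baseline_tolerance_h)
    cases <- link_episodes(cases, episodes, cohort)
    auc <- compute_auc(cases, cohort, horizons = config$horizons_h)
    table1 <- table1_report(cohort, cases,
                            cohen_d_variant = config$cohen_d_variant)
    table2 <- table2_report(cases, auc, thresholds = config$auc_thresholds_c,
                            cohen_d_variant = config$cohen_d_variant)
    eligible <- cases[eligible_for_auc(cases$baseline_temp_c,
                                       min(config$auc_thresholds_c)), ]
    curves <- delta_curve(eligible, cohort, stratify_by = "group")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("feverpghd")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    settings = list(fever_threshold_c = config$fever_threshold_c,
                    auc_thresholds_c = config$auc_thresholds_c,
                    horizons_h = config$horizons_h,
                    window_h = config$window_h,
                    baseline_tolerance_h = config$baseline_tolerance_h,
                    cohen_d_variant = config$cohen_d_variant),
    counts = list(
      input_children = excl$input_children,
      retained_children = excl$retained,
      excluded_children = excl$excluded_total,
      excluded_by_criterion = as.list(excl$by_criterion),
      excluded_first_reason = as.list(unclass(excl$first_reason)),
      temperature_records = nrow(cohort$temperatures),
      antipyretic_records = nrow(cohort$antipyretics),
      episodes = nrow(episodes),
      cases = nrow(cases),
      single_cases = sum(cases$group == "single"),
      combination_cases = sum(cases$group == "combination"),
      auc_rows = nrow(auc)
    )
  )

  result <- list(cohort = cohort, episodes = episodes, cases = cases,
                 auc = auc, table1 = table1, table2 = table2,
                 delta_curves = curves, manifest = manifest,
                 ground_truth = ground_truth)
  if (!is.null(config$out_dir)) .write_run_artifacts(result, config)
  result
}

.write_run_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(config$out_dir, x)

  ep <- result$episodes
  readr::write_csv(tibble::tibble(
    child_id = ep$child_id,
    onset_time = .time_chr(ep$onset_time),
    offset_time = ifelse(ep$resolved, .time_chr(ep$offset_time), NA),
    duration_h = ep$duration_h,
    max_temp_c = ep$max_temp_c
  ), fp("episodes.csv"), na = "")

  cs <- result$cases
  readr::write_csv(tibble::tibble(
    case_id = cs$case_id, child_id = cs$child_id,
    window_start = .time_chr(cs$window_start),
    group = cs$group, pattern = cs$pattern,
    baseline_temp_c = cs$baseline_temp_c,
    onset_bin = as.character(cs$onset_bin),
    n_doses = cs$n_doses,
    baseline_missing_flag = cs$baseline_missing
  ), fp("cases.csv"), na = "")

  readr::write_csv(result$auc, fp("auc.csv"), na = "")
  readr::write_csv(result$delta_curves, fp("delta_curves.csv"), na = "")
  if (!is.null(result$table1)) {
    jsonlite::write_json(result$table1, fp("table1.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (nrow(result$table2)) {
    readr::write_csv(result$table2, fp("table2.csv"), na = "")
    jsonlite::write_json(result$table2, fp("table2.json"), digits = NA,
                         na = "null")
  }
  cfg_json <- jsonlite::toJSON(result$manifest$settings, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  result$manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(config$out_dir)
}

#' Plot mean temperature-change curves
#'
#' Line plot of the output of [delta_curve()], one line per stratum.
#'
#' @param curves Tibble from [delta_curve()].
#' @return A ggplot object.
#' @export
plot_delta_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$offset_h,
                                       y = .data$mean_delta_c,
                                       colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Hours since first antipyretic administration",
                  y = "Mean temperature change from baseline (℃)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
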