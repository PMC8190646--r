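#' Published reference summary tables
#'
#' Group-level summary statistics from a large observational cohort of
#' caregiver-managed febrile children (206,859 treatment cases), shipped as
#' plain CSVs under `inst/extdata`. These printed summaries — group means,
#' SDs and counts; onset-temperature-bin counts; regimen-pattern counts;
#' per-horizon AUC group summaries — are the inputs of the package's worked
#' examples: the summary-statistics operations ([cohens_d()],
#' [mixture_total()], [student_t()], [chi_square()]) reproduce the
#' published effect sizes, totals and percentages from them at run time.
#'
#' @param table One of `"group_summary"`, `"auc_groups"`, `"onset_bins"`,
#'   `"pattern_counts"`, `"sex_counts"`.
#' @return A tibble.
#' @export
#' @examples
#' ref <- reference_table("group_summary")
#' with(ref[ref$variable == "baseline_temp_c", ],
#'      cohens_d(single_mean, single_sd, combination_mean, combination_sd))
reference_table <- function(table = c("group_summary", "auc_groups",
                                      "onset_bins", "pattern_counts",
                                      "sex_counts")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_", table, ".csv"),
                      package = "feverpghd")
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}
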