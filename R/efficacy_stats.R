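#' Baseline-anchored AUC of the temperature-change curve
#'
#' The fever-exposure statistic for one case: the temperature change from
#' baseline, `dT(t) = T(window_start + t) - baseline`, is evaluated on the
#' hourly grid and integrated by the trapezoidal rule over `[0, horizon_h]`
#' hours. Negative values indicate net defervescence. When the series ends
#' before the horizon the partial integral is returned with
#' `truncated = TRUE`; such cases are excluded from group comparisons by
#' default.
#'
#' @param series A [temperature_series()].
#' @param window_start Case anchor (first administration), POSIXct or hours.
#' @param baseline_temp_c Baseline temperature (see
#'   [baseline_temperature()]); must be present.
#' @param horizon_h Integration horizon in hours; 6, 8, 10 and 12 are the
#'   standard choices (others are allowed with a warning).
#' @return List: `auc_c_h` (Celsius-hours), `truncated`, `n_grid`.
#' @export
auc_from_baseline <- function(series, window_start, baseline_temp_c,
                              horizon_h) {
  if (is.na(baseline_temp_c)) {
    stop("baseline temperature missing; case not eligible for AUC",
         call. = FALSE)
  }
  if (!horizon_h %in% c(6, 8, 10, 12)) {
    warning("non-standard AUC horizon ", horizon_h, " h", call. = FALSE)
  }
  grid <- hourly_grid(series, window_start, horizon_h)
  delta <- grid$temp_c - baseline_temp_c
  list(auc_c_h = .trapz(grid$offset_h, delta),
       truncated = attr(grid, "truncated"),
       n_grid = nrow(grid))
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Compute case AUCs at several horizons
#'
#' Batch evaluation of [auc_from_baseline()] for every case with a present
#' baseline whose anchor lies inside its child's series domain.
#'
#' @param cases Output of [build_cases()].
#' @param cohort The cohort the cases were built from.
#' @param horizons Integer vector of horizons in hours.
#' @return Tibble: `case_id`, `horizon_h`, `auc_c_h`, `truncated`.
#' @export
compute_auc <- function(cases, cohort, horizons = c(6, 8, 10, 12)) {
  stopifnot(inherits(cohort, "fever_cohort"))
  series_list <- split_series(cohort)
  H <- max(horizons)
  res <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    if (cases$baseline_missing[i]) next
    ser <- series_list[[cases$child_id[i]]]
    if (is.null(ser)) next
    t0 <- .as_hours(cases$window_start[i])
    dom <- .series_domain(ser)
    if (t0 < dom[1] || t0 > dom[2]) next
    grid <- hourly_grid(ser, t0, H)
    delta <- grid$temp_c - cases$baseline_temp_c[i]
    res[[i]] <- data.frame(
      case_id = cases$case_id[i],
      horizon_h = horizons,
      auc_c_h = vapply(horizons, function(h) {
        keep <- grid$offset_h <= h
        .trapz(grid$offset_h[keep], delta[keep])
      }, numeric(1)),
      truncated = vapply(horizons, function(h) {
        max(grid$offset_h) < h
      }, logical(1))
    )
  }
  tibble::as_tibble(do.call(rbind, res[!vapply(res, is.null, logical(1))]))
}

#' Mean temperature-change curves by stratum
#'
#' For each stratum (regimen group or pattern), the mean temperature change
#' from baseline at each hourly offset, over the cases whose series still
#' covers that offset. By construction the curve is exactly zero at offset
#' zero; the number of contributing cases is non-increasing in the offset.
#'
#' @param cases Output of [build_cases()]; restricted upstream to the
#'   analysis population (e.g. baseline >= 38).
#' @param cohort The cohort.
#' @param stratify_by `"group"` or `"pattern"`.
#' @param horizon_h Curve length in hours.
#' @return Tibble: `stratum`, `offset_h`, `mean_delta_c`, `n`.
#' @export
delta_curve <- function(cases, cohort, stratify_by = c("group", "pattern"),
                        horizon_h = 24) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(inherits(cohort, "fever_cohort"))
  series_list <- split_series(cohort)
  cases <- cases[!cases$baseline_missing, , drop = FALSE]

  sums <- list(); ns <- list()
  for (i in seq_len(nrow(cases))) {
    ser <- series_list[[cases$child_id[i]]]
    if (is.null(ser)) next
    t0 <- .as_hours(cases$window_start[i])
    dom <- .series_domain(ser)
    if (t0 < dom[1] || t0 > dom[2]) next
    grid <- hourly_grid(ser, t0, horizon_h)
    delta <- grid$temp_c - cases$baseline_temp_c[i]
    s <- cases[[stratify_by]][i]
    if (is.null(sums[[s]])) {
      sums[[s]] <- numeric(horizon_h + 1); ns[[s]] <- integer(horizon_h + 1)
    }
    k <- grid$offset_h + 1
    sums[[s]][k] <- sums[[s]][k] + delta
    ns[[s]][k] <- ns[[s]][k] + 1L
  }
  if (!length(sums)) {
    warning("no cases contributed to any stratum", call. = FALSE)
    return(tibble::tibble(stratum = character(), offset_h = integer(),
                          mean_delta_c = numeric(), n = integer()))
  }
  dplyr::bind_rows(lapply(names(sums), function(s) {
    keep <- ns[[s]] > 0
    tibble::tibble(stratum = s, offset_h = (0:horizon_h)[keep],
                   mean_delta_c = sums[[s]][keep] / ns[[s]][keep],
                   n = ns[[s]][keep])
  }))
}

#' Two-sample Student t test from summary statistics
#'
#' Pooled-variance Student t with `n1 + n2 - 2` degrees of freedom and a
#' two-sided p value, computed from group means, standard deviations and
#' sizes (the form used when only summary statistics are available). With
#' zero pooled variance the statistic is 0 for equal means and signed
#' infinite otherwise.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n >= 2`, `sd >= 0`).
#' @return List: `t`, `df`, `p`.
#' @export
student_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = if (is.infinite(t)) 0 else 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (wraps
#' [stats::chisq.test()]), `(r-1)(k-1)` degrees of freedom. A zero row or
#' column marginal is an error.
#'
#' @param counts Matrix of counts, typically 2 x k.
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Cohen's d standardized mean difference
#'
#' Reported as a magnitude. The default pooling is the equal-weight form
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`; the sample-size-weighted pooled SD
#' is available via `variant = "n_weighted"` (then `n1`, `n2` are required).
#' Interpretation bands: 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param mean1,sd1,mean2,sd2 Group summaries; the SDs must not both be 0.
#' @param variant `"equal_weight"` (default) or `"n_weighted"`.
#' @param n1,n2 Group sizes, only for the n-weighted variant.
#' @return Nonnegative effect size.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2,
                     variant = c("equal_weight", "n_weighted"),
                     n1 = NULL, n2 = NULL) {
  variant <- match.arg(variant)
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero", call. = FALSE)
  pooled <- switch(variant,
    equal_weight = sqrt((sd1^2 + sd2^2) / 2),
    n_weighted = {
      stopifnot(!is.null(n1), !is.null(n2))
      sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
    })
  abs(mean1 - mean2) / pooled
}

#' Cohen's h effect size for two proportions
#'
#' `h = |2 asin(sqrt(p1)) - 2 asin(sqrt(p2))|`, the arcsine-difference
#' effect size used for the proportion rows of descriptive tables.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @return Nonnegative effect size.
#' @export
cohens_h <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
}

#' Mixture mean and SD of two groups
#'
#' The overall ("Total") mean and SD implied by two group summaries:
#' `total_mean` is the size-weighted mean and the total variance follows the
#' mixture identity `var = sum_i w_i (sd_i^2 + mean_i^2) - total_mean^2`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n1 + n2 >= 1`).
#' @return List: `mean`, `sd`, `n`.
#' @export
mixture_total <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 + n2 >= 1, n1 >= 0, n2 >= 0)
  if (n2 == 0) return(list(mean = mean1, sd = sd1, n = n1))
  if (n1 == 0) return(list(mean = mean2, sd = sd2, n = n2))
  w1 <- n1 / (n1 + n2); w2 <- n2 / (n1 + n2)
  m <- w1 * mean1 + w2 * mean2
  v <- w1 * (sd1^2 + mean1^2) + w2 * (sd2^2 + mean2^2) - m^2
  list(mean = m, sd = sqrt(max(v, 0)), n = n1 + n2)
}

.group_stats <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

.row_compare <- function(variable, s, c, d_variant = "equal_weight") {
  comparable <- s$n >= 2 && c$n >= 2 && isTRUE(!(s$sd == 0 && c$sd == 0))
  if (comparable) {
    tt <- student_t(s$mean, s$sd, s$n, c$mean, c$sd, c$n)
    d <- cohens_d(s$mean, s$sd, c$mean, c$sd, variant = d_variant,
                  n1 = s$n, n2 = c$n)
  } else {
    tt <- list(t = NA_real_, p = NA_real_)
    d <- NA_real_
  }
  tot <- mixture_total(if (s$n) s$mean else 0, if (s$n) s$sd else 0, s$n,
                       if (c$n) c$mean else 0, if (c$n) c$sd else 0, c$n)
  tibble::tibble(
    variable = variable,
    single_mean = s$mean, single_sd = s$sd, single_n = s$n,
    combination_mean = c$mean, combination_sd = c$sd, combination_n = c$n,
    t = tt$t, p = tt$p, effect_size = d,
    total_mean = tot$mean, total_sd = tot$sd, total_n = tot$n
  )
}

#' Descriptive comparison of single and combination cases
#'
#' Builds the descriptive-statistics report comparing the two regimen
#' groups: male share (chi-square, Cohen's h), age, baseline temperature,
#' maximum window temperature and resolved fever duration (Student t,
#' Cohen's d, mixture totals), plus the onset-temperature-bin breakdown
#' with per-bin group shares. Values are unrounded; round at rendering.
#'
#' @param cohort The filtered cohort.
#' @param cases Output of [link_episodes()] (cases with linked episode
#'   summaries); age is computed at each case child's first record.
#' @param cohen_d_variant Pooling variant for [cohens_d()].
#' @return List of tibbles: `continuous`, `sex`, `onset_bins`.
#' @export
table1_report <- function(cohort, cases,
                          cohen_d_variant = c("equal_weight", "n_weighted")) {
  cohen_d_variant <- match.arg(cohen_d_variant)
  stopifnot(inherits(cohort, "fever_cohort"))
  chd <- cohort$children

  # age at the child's first record of any kind, as in filter_children()
  rec <- data.frame(
    child_id = c(cohort$temperatures$child_id, cohort$antipyretics$child_id),
    h = c(.as_hours(cohort$temperatures$time),
          .as_hours(cohort$antipyretics$time)))
  first_h <- tapply(rec$h, rec$child_id, min)
  age_days <- as.numeric(as.Date(.as_time(unname(first_h[chd$child_id]))) -
                           chd$birth_date)
  names(age_days) <- chd$child_id
  case_age <- age_days[cases$child_id]
  sex <- setNames(chd$sex, chd$child_id)[cases$child_id]

  sgl <- cases$group == "single"
  cmb <- cases$group == "combination"

  continuous <- dplyr::bind_rows(
    .row_compare("age_days", .group_stats(case_age[sgl]),
                 .group_stats(case_age[cmb]), cohen_d_variant),
    .row_compare("baseline_temp_c", .group_stats(cases$baseline_temp_c[sgl]),
                 .group_stats(cases$baseline_temp_c[cmb]), cohen_d_variant),
    .row_compare("max_temp_c", .group_stats(cases$max_temp_c[sgl]),
                 .group_stats(cases$max_temp_c[cmb]), cohen_d_variant),
    .row_compare("fever_duration_h", .group_stats(cases$fever_duration_h[sgl]),
                 .group_stats(cases$fever_duration_h[cmb]), cohen_d_variant)
  )

  male <- c(single = sum(sex[sgl] == "male", na.rm = TRUE),
            combination = sum(sex[cmb] == "male", na.rm = TRUE))
  tot <- c(single = sum(sgl), combination = sum(cmb))
  sex_tbl <- tibble::tibble(
    group = names(male), male_n = as.integer(male), n = as.integer(tot),
    male_pct = 100 * male / tot
  )
  if (all(tot > 0)) {
    ct <- rbind(male, female = tot - male)
    cs <- chi_square(ct)
    attr(sex_tbl, "chi_square") <- cs
    attr(sex_tbl, "effect_size") <- cohens_h(male[1] / tot[1], male[2] / tot[2])
  }

  bins <- table(bin = cases$onset_bin, group = factor(cases$group,
                levels = c("single", "combination")))
  onset_bins <- tibble::as_tibble(as.data.frame.matrix(bins), rownames = "onset_bin")
  onset_bins$total <- onset_bins$single + onset_bins$combination
  nz <- onset_bins$total > 0
  onset_bins$single_pct <- ifelse(nz, 100 * onset_bins$single / onset_bins$total,
                                  NA_real_)
  onset_bins$combination_pct <- ifelse(nz, 100 * onset_bins$combination /
                                         onset_bins$total, NA_real_)
  onset_bins$effect_size <- NA_real_
  if (all(tot > 0)) {
    onset_bins$effect_size[nz] <- mapply(function(s, c) {
      cohens_h(s / tot["single"], c / tot["combination"])
    }, onset_bins$single[nz], onset_bins$combination[nz])
  }
  if (sum(nz) >= 2 && all(tot > 0)) {
    attr(onset_bins, "chi_square") <- chi_square(t(bins[nz, , drop = FALSE]))
  }

  list(continuous = continuous, sex = sex_tbl, onset_bins = onset_bins)
}

#' AUC comparison between regimen groups
#'
#' For each analysis threshold and horizon: per-group mean (SD) AUC over the
#' non-truncated eligible cases, the Student t test, Cohen's d and the
#' mixture total. The threshold populations are nested: every case analysed
#' at 39 is also analysed at 38.
#'
#' @param cases Output of [build_cases()].
#' @param auc Output of [compute_auc()].
#' @param thresholds Analysis thresholds in Celsius.
#' @param include_truncated Include horizon-truncated cases (off by default).
#' @param cohen_d_variant Pooling variant for [cohens_d()].
#' @return Tibble with one row per threshold x horizon.
#' @export
table2_report <- function(cases, auc, thresholds = c(38, 39),
                          include_truncated = FALSE,
                          cohen_d_variant = c("equal_weight", "n_weighted")) {
  cohen_d_variant <- match.arg(cohen_d_variant)
  auc <- dplyr::left_join(auc,
                          cases[, c("case_id", "group", "baseline_temp_c")],
                          by = "case_id")
  if (!include_truncated) auc <- auc[!auc$truncated, , drop = FALSE]

  rows <- list()
  for (thr in thresholds) {
    sub <- auc[eligible_for_auc(auc$baseline_temp_c, thr), , drop = FALSE]
    for (h in sort(unique(sub$horizon_h))) {
      x <- sub[sub$horizon_h == h, ]
      s <- .group_stats(x$auc_c_h[x$group == "single"])
      c <- .group_stats(x$auc_c_h[x$group == "combination"])
      if (s$n < 2 || c$n < 2) next
      row <- .row_compare(paste0("auc_", h, "h"), s, c, cohen_d_variant)
      row$threshold_c <- thr
      row$horizon_h <- h
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::relocate(out, "threshold_c", "horizon_h")
  }
  out
}
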