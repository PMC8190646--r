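#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of large caregiver-entered fever
#' diaries: child age approximately log-normal (mean ~835, SD ~530 days,
#' truncated to 7000 days), a slight male excess, afebrile baseline near
#' 36.8 (SD 0.2), gamma-distributed febrile peaks, caregiver dosing
#' thresholds near 38.3 (SD 0.3, with a reaction delay during which the
#' fever keeps rising), a small early-dosing caregiver fraction so that
#' about 5.5% of first doses fall below 38, a combination probability that
#' increases with the onset-temperature band
#' (13% / 19% / 23.8% / 34.5% / 41.4%), and alternating combination dosing
#' at 4-6 hour intervals. See the methods vignette for the calibration
#' rationale of every default.
#'
#' @param n_children Number of children to simulate.
#' @param seed Optional RNG seed used by [generate_cohort()].
#' @param courses_per_child_lambda Courses per child are
#'   `1 + Poisson(lambda)`.
#' @param sex_male_prob Probability of male sex.
#' @param age_meanlog,age_sdlog Log-normal age parameters (days).
#' @param age_range_days Truncation interval for age.
#' @param weight_noise_sd_kg SD of weight noise around the monotone
#'   age-to-weight map.
#' @param baseline_temp_c `c(mean, sd)` of the afebrile baseline.
#' @param fever_peak_delta_c `c(shape, rate)` of the gamma peak rise.
#' @param fever_rise_h,fever_fall_h Rise duration and decay constant.
#' @param peak_time_range_h Uniform range of the peak time within a course.
#' @param drug_effect Per-ingredient kernel parameters
#'   `c(lag_h, nadir_h, nadir_drop_c, effect_duration_h)`.
#' @param dosing_threshold_c `c(mean, sd)` of the caregiver threshold,
#'   truncated to at least 38 for regular dosers.
#' @param reaction_delay_mean_h,reaction_delay_max_h Mean (exponential) and
#'   cap of the delay between the threshold crossing and the first
#'   administration; during the delay the fever keeps rising, which spreads
#'   onset temperatures above the threshold.
#' @param underthreshold_dosing_prob Fraction of early-dosing caregivers
#'   (threshold below 38); together with measurement noise around the 38.0
#'   boundary this targets a measured under-38 first-dose share of ~5.5%.
#' @param under_threshold_c `c(mean, sd)` of early-doser thresholds,
#'   truncated below 38.
#' @param combination_prob_by_band Named probabilities of a combination
#'   regimen per onset-temperature band (monotone increasing).
#' @param single_pattern_probs,combination_pattern_probs Ingredient /
#'   pattern choice probabilities per caregiver.
#' @param alternation_interval_h Uniform range of combination alternation
#'   intervals.
#' @param single_redose_gap_h Minimum re-dose gap for single-agent
#'   caregivers.
#' @param schedule_second_dose Combination caregivers give the second
#'   (alternate-agent) dose on schedule regardless of temperature.
#' @param measurement_rate_base_per_h,measurement_rate_slope,measurement_rate_pivot_c
#'   Inhomogeneous sampling intensity
#'   `base + slope * max(0, latent - pivot)` per hour.
#' @param post_dose_check_h Uniform range of the re-measurement delay after
#'   each dose.
#' @param measurement_noise_sd_c Gaussian measurement noise SD.
#' @param round_to_0_1 Quantise observed temperatures to 0.1 (part of the
#'   measurement model; disable for noise-free checks).
#' @param course_window_h,dosing_window_h Course length and the span within
#'   it during which doses may be given.
#' @param course_spacing_h,course_spacing_jitter_h Spacing between
#'   consecutive course starts of one child (keeps inter-course dose gaps
#'   above 72 h so cases never straddle courses).
#' @param sim_grid_h Simulation grid step (0.05 h = 3 min).
#' @param max_doses_per_course Safety cap.
#' @param enrollment_spread_days Children enrol uniformly over this span.
#' @param origin Calendar origin of the simulation.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_children = 1000,
                       seed = NULL,
                       courses_per_child_lambda = 1,
                       sex_male_prob = 0.504,
                       age_meanlog = 6.558,
                       age_sdlog = 0.582,
                       age_range_days = c(1, 7000),
                       weight_noise_sd_kg = 1.2,
                       baseline_temp_c = c(mean = 36.8, sd = 0.2),
                       fever_peak_delta_c = c(shape = 11, rate = 5),
                       fever_rise_h = 4,
                       fever_fall_h = 30,
                       peak_time_range_h = c(6, 16),
                       drug_effect = list(
                         ACE = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 1.0,
                                 effect_duration_h = 6),
                         IBU = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 1.2,
                                 effect_duration_h = 6),
                         DEX = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 1.1,
                                 effect_duration_h = 6)),
                       dosing_threshold_c = c(mean = 38.3, sd = 0.3),
                       reaction_delay_mean_h = 2,
                       reaction_delay_max_h = 8,
                       underthreshold_dosing_prob = 0.115,
                       under_threshold_c = c(mean = 37.6, sd = 0.35),
                       combination_prob_by_band = c("<37" = 0.13,
                                                    "[37,38)" = 0.19,
                                                    "[38,39)" = 0.238,
                                                    "[39,40)" = 0.345,
                                                    ">=40" = 0.414),
                       single_pattern_probs = c(ACE = 0.401, IBU = 0.232,
                                                DEX = 0.367),
                       combination_pattern_probs = c("ACE-DEX" = 0.512,
                                                     "ACE-IBU" = 0.406,
                                                     "IBU-DEX" = 0.060,
                                                     "ACE-IBU-DEX" = 0.022),
                       alternation_interval_h = c(4, 6),
                       single_redose_gap_h = 4,
                       schedule_second_dose = TRUE,
                       measurement_rate_base_per_h = 0.25,
                       measurement_rate_slope = 0.8,
                       measurement_rate_pivot_c = 37.5,
                       post_dose_check_h = c(1, 2.5),
                       measurement_noise_sd_c = 0.1,
                       round_to_0_1 = TRUE,
                       course_window_h = 96,
                       dosing_window_h = 72,
                       course_spacing_h = 168,
                       course_spacing_jitter_h = c(0, 48),
                       sim_grid_h = 0.05,
                       max_doses_per_course = 30,
                       enrollment_spread_days = 300,
                       origin = "2016-01-01") {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config` list.
#' @return The config, invisibly usable; errors on the first invalid field.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(config$n_children >= 1, "n_children must be >= 1")
  probs <- c(config$sex_male_prob, config$underthreshold_dosing_prob,
             config$combination_prob_by_band, config$single_pattern_probs,
             config$combination_pattern_probs)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  chk(all(names(config$combination_prob_by_band) ==
            c("<37", "[37,38)", "[38,39)", "[39,40)", ">=40")),
      "combination_prob_by_band must cover the five onset bands")
  chk(!is.unsorted(config$combination_prob_by_band),
      "combination_prob_by_band must be monotone non-decreasing")
  durs <- c(config$fever_rise_h, config$fever_fall_h, config$sim_grid_h,
            config$course_window_h, config$dosing_window_h,
            config$single_redose_gap_h, config$course_spacing_h)
  chk(all(durs > 0), "durations must be positive")
  for (ing in .INGREDIENTS) {
    p <- config$drug_effect[[ing]]
    chk(!is.null(p), paste("drug_effect missing", ing))
    chk(p[["nadir_drop_c"]] >= 0 && p[["lag_h"]] >= 0 &&
          p[["nadir_h"]] > p[["lag_h"]] &&
          p[["effect_duration_h"]] > p[["nadir_h"]],
        paste("malformed kernel for", ing))
  }
  chk(config$dosing_window_h <= config$course_window_h,
      "dosing window exceeds course window")
  chk(config$course_spacing_h >= config$course_window_h + 72,
      "course spacing must keep inter-course dose gaps above 72 h")
  config
}

# inverse-CDF truncated normal
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd); p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

# monotone paediatric age-to-weight map (kg), standard ward approximations
.weight_from_age <- function(age_days) {
  yr <- age_days / 365.25
  mo <- age_days / 30.44
  ifelse(yr < 1, 3.4 + 0.55 * mo,
         ifelse(yr < 5, 10 + 2.25 * (yr - 1), 19 + 3 * (yr - 5)))
}

#' Simulate child profiles
#'
#' Draws `n_children` profiles under the configured marginals. Uses the
#' current RNG state; call [set.seed()] (or use [generate_cohort()], which
#' seeds) for reproducibility. The returned tibble carries two extra
#' simulation columns beyond the canonical profile (`age_days`,
#' `enroll_h`); [generate_cohort()] strips them from the emitted cohort.
#'
#' @param config A [sim_config()].
#' @return Tibble: `child_id`, `sex`, `birth_date`, `weight_kg`,
#'   `age_days`, `enroll_h`.
#' @export
simulate_children <- function(config) {
  validate_sim_config(config)
  n <- config$n_children
  p_lo <- stats::plnorm(config$age_range_days[1], config$age_meanlog, config$age_sdlog)
  p_hi <- stats::plnorm(config$age_range_days[2], config$age_meanlog, config$age_sdlog)
  age <- stats::qlnorm(p_lo + runif(n) * (p_hi - p_lo),
                       config$age_meanlog, config$age_sdlog)
  weight <- pmax(1, .weight_from_age(age) + rnorm(n, 0, config$weight_noise_sd_kg))
  enroll_h <- round(runif(n, 0, config$enrollment_spread_days * 24) * 60) / 60
  origin_d <- as.Date(config$origin)
  tibble::tibble(
    child_id = sprintf("C%06d", seq_len(n)),
    sex = ifelse(runif(n) < config$sex_male_prob, "male", "female"),
    birth_date = origin_d + floor(enroll_h / 24) - round(age),
    weight_kg = round(weight, 1),
    age_days = age,
    enroll_h = enroll_h
  )
}

# caregiver-level latent attributes (threshold, combination propensity,
# ingredient preferences) — per child, not per dose
.simulate_caregiver <- function(config) {
  early <- runif(1) < config$underthreshold_dosing_prob
  th <- if (early) {
    .rtnorm(1, config$under_threshold_c[["mean"]],
            config$under_threshold_c[["sd"]], hi = 37.999)
  } else {
    .rtnorm(1, config$dosing_threshold_c[["mean"]],
            config$dosing_threshold_c[["sd"]], lo = 38)
  }
  single <- sample(names(config$single_pattern_probs), 1,
                   prob = config$single_pattern_probs)
  comb_pattern <- sample(names(config$combination_pattern_probs), 1,
                         prob = config$combination_pattern_probs)
  list(threshold_c = th,
       comb_u = runif(1),
       single_ingredient = single,
       comb_ingredients = strsplit(comb_pattern, "-", fixed = TRUE)[[1]])
}

#' Simulate one fever course with its dosing trace
#'
#' Draws the latent course (baseline, peak, rise, decay), then plays the
#' caregiver's dosing policy against it: the first dose follows the first
#' crossing of the caregiver threshold after a uniform reaction delay; the
#' regimen (single vs combination) is decided by comparing the caregiver's
#' propensity with the configured probability for the onset-temperature
#' band; combination caregivers alternate ingredients at the configured
#' 4-6 h interval (the second dose on schedule), single caregivers re-dose
#' at threshold re-crossings at least `single_redose_gap_h` apart. Each
#' dose adds its ingredient's response kernel to the latent course.
#'
#' @param config A [sim_config()].
#' @param caregiver Internal caregiver attributes; defaults to a fresh draw.
#' @return A [fever_course()]; attribute `policy` records the regimen
#'   (`group`, `pattern`, `baseline_true_c`, `onset_band`), or
#'   `group = "none"` for an untreated course.
#' @export
simulate_fever_course <- function(config, caregiver = .simulate_caregiver(config)) {
  dt <- config$sim_grid_h
  grid <- seq(0, config$course_window_h, by = dt)
  n <- length(grid)

  course0 <- fever_course(
    baseline_c = rnorm(1, config$baseline_temp_c[["mean"]],
                       config$baseline_temp_c[["sd"]]),
    peak_delta_c = rgamma(1, config$fever_peak_delta_c[["shape"]],
                          config$fever_peak_delta_c[["rate"]]),
    peak_time_h = runif(1, config$peak_time_range_h[1],
                        config$peak_time_range_h[2]),
    rise_h = config$fever_rise_h, fall_h = config$fever_fall_h,
    window_h = config$course_window_h, drug_effect = config$drug_effect
  )
  lat <- .backbone_value(course0, grid)
  th <- caregiver$threshold_c

  kern <- lapply(config$drug_effect, function(p) {
    kn <- .kernel_knots(p)
    .pwl_value(kn, seq(0, p[["effect_duration_h"]], by = dt))
  })
  add_dose <- function(i, ing) {
    k <- kern[[ing]]
    hi <- min(n, i + length(k) - 1)
    lat[i:hi] <<- lat[i:hi] + k[seq_len(hi - i + 1)]
  }

  doses_t <- numeric(0); doses_ing <- character(0)
  policy <- list(group = "none", pattern = NA_character_,
                 baseline_true_c = NA_real_, onset_band = NA_character_)

  i1 <- which(lat >= th)[1]
  if (!is.na(i1)) {
    delay <- min(stats::rexp(1, 1 / config$reaction_delay_mean_h),
                 config$reaction_delay_max_h)
    i1 <- min(n, i1 + round(delay / dt))
    if (grid[i1] <= config$dosing_window_h) {
      baseline_true <- lat[i1]
      band <- as.character(onset_bin(baseline_true))
      comb <- caregiver$comb_u < config$combination_prob_by_band[[band]]
      ings <- if (comb) caregiver$comb_ingredients else caregiver$single_ingredient
      policy <- list(
        group = if (comb) "combination" else "single",
        pattern = paste(.INGREDIENTS[.INGREDIENTS %in% ings], collapse = "-"),
        baseline_true_c = baseline_true, onset_band = band
      )
      k <- 1L
      add_dose(i1, ings[1])
      doses_t <- grid[i1]; doses_ing <- ings[1]
      i_last <- i1
      while (k < config$max_doses_per_course) {
        if (comb && k == 1L && config$schedule_second_dose) {
          gap <- runif(1, config$alternation_interval_h[1],
                       config$alternation_interval_h[2])
          j <- i_last + round(gap / dt)
          if (j > n || grid[j] > config$dosing_window_h) break
        } else {
          gap <- if (comb) {
            runif(1, config$alternation_interval_h[1],
                  config$alternation_interval_h[2])
          } else {
            config$single_redose_gap_h
          }
          j0 <- i_last + max(1L, round(gap / dt))
          if (j0 > n) break
          rel <- which(lat[j0:n] >= th)[1]
          if (is.na(rel)) break
          j <- j0 + rel - 1L
          if (grid[j] > config$dosing_window_h) break
        }
        k <- k + 1L
        ing <- ings[(k - 1L) %% length(ings) + 1L]
        add_dose(j, ing)
        doses_t <- c(doses_t, grid[j]); doses_ing <- c(doses_ing, ing)
        i_last <- j
      }
    }
  }

  course <- fever_course(course0$B, course0$P, course0$t_pk,
                         config$fever_rise_h, config$fever_fall_h,
                         config$course_window_h,
                         doses = data.frame(time_h = doses_t,
                                            ingredient = doses_ing),
                         drug_effect = config$drug_effect)
  attr(course, "policy") <- policy
  attr(course, "latent_grid") <- list(grid = grid, temp = lat)
  course
}

#' Simulate temperature measurements of a course
#'
#' Observation times follow an inhomogeneous sampling process whose
#' intensity increases with the latent temperature, plus a measurement at
#' every dose time and a re-check 1-2.5 h after each dose. Observed values
#' are latent plus Gaussian noise, quantised to 0.1 (configurable);
#' observation times are rounded to the minute.
#'
#' @param course A [fever_course()] from [simulate_fever_course()].
#' @param config A [sim_config()].
#' @return Data frame `time_h`, `temp_c` (times relative to course start).
#' @export
simulate_measurements <- function(course, config) {
  lg <- attr(course, "latent_grid")
  if (is.null(lg)) {
    grid <- seq(0, course$window_h, by = config$sim_grid_h)
    lg <- list(grid = grid, temp = course_temp(course, grid))
  }
  rate <- config$measurement_rate_base_per_h +
    config$measurement_rate_slope *
    pmax(0, lg$temp - config$measurement_rate_pivot_c)
  p <- pmin(1, rate * config$sim_grid_h)
  t_obs <- lg$grid[runif(length(p)) < p]
  if (nrow(course$doses)) {
    checks <- course$doses$time_h +
      runif(nrow(course$doses), config$post_dose_check_h[1],
            config$post_dose_check_h[2])
    t_obs <- c(t_obs, course$doses$time_h, checks)
  }
  t_obs <- sort(round(t_obs[t_obs <= course$window_h] * 60) / 60)
  t_obs <- t_obs[!duplicated(t_obs, fromLast = TRUE)]
  if (!length(t_obs)) {
    return(data.frame(time_h = numeric(0), temp_c = numeric(0)))
  }
  temp <- course_temp(course, t_obs) +
    rnorm(length(t_obs), 0, config$measurement_noise_sd_c)
  if (config$round_to_0_1) temp <- round(temp, 1)
  data.frame(time_h = t_obs, temp_c = pmin(43, pmax(30, temp)))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Runs the child, caregiver, course and measurement simulators and
#' assembles (a) a [fever_cohort()] in exactly the form the analysis
#' pipeline ingests and (b) a ground-truth table with one row per
#' dosing-anchored 72 h case: the true regimen label, the true (noise-free)
#' baseline, its onset band, and the exact closed-form baseline-anchored
#' AUC at 6, 8, 10 and 12 hours. Case identifiers match those produced by
#' [build_cases()] on the emitted cohort. Identical `(config, seed)` pairs
#' produce identical output, byte-for-byte through [write_cohort()].
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `fever_sim`: `cohort`, `ground_truth` (tibble),
#'   `children` (profiles with simulation columns); attribute `courses`
#'   holds the per-child latent [fever_course()] objects.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  children <- simulate_children(config)

  temps <- vector("list", config$n_children)
  meds <- vector("list", config$n_children)
  truth <- vector("list", config$n_children)
  courses_all <- vector("list", config$n_children)
  window_h <- 72

  for (ci in seq_len(config$n_children)) {
    cid <- children$child_id[ci]
    caregiver <- .simulate_caregiver(config)
    n_courses <- 1L + rpois(1, config$courses_per_child_lambda)
    start_h <- children$enroll_h[ci]
    child_courses <- vector("list", n_courses)
    dose_t <- numeric(0); dose_ing <- character(0); dose_course <- integer(0)
    tmp_rows <- vector("list", n_courses)

    for (k in seq_len(n_courses)) {
      course <- simulate_fever_course(config, caregiver)
      child_courses[[k]] <- course
      m <- simulate_measurements(course, config)
      if (nrow(m)) {
        tmp_rows[[k]] <- data.frame(time_h = start_h + m$time_h,
                                    temp_c = m$temp_c)
      }
      if (nrow(course$doses)) {
        dose_t <- c(dose_t, start_h + course$doses$time_h)
        dose_ing <- c(dose_ing, course$doses$ingredient)
        dose_course <- c(dose_course, rep(k, nrow(course$doses)))
      }
      attr(child_courses[[k]], "start_h") <- start_h
      start_h <- start_h + config$course_spacing_h +
        runif(1, config$course_spacing_jitter_h[1],
              config$course_spacing_jitter_h[2])
    }
    courses_all[[ci]] <- child_courses

    tmp <- do.call(rbind, tmp_rows[!vapply(tmp_rows, is.null, logical(1))])
    if (!is.null(tmp) && nrow(tmp)) {
      temps[[ci]] <- data.frame(child_id = cid, time_h = tmp$time_h,
                                temp_c = tmp$temp_c)
    }
    if (length(dose_t)) {
      dose_mg <- round(children$weight_kg[ci] *
                         c(ACE = 12.5, IBU = 10, DEX = 5)[dose_ing])
      meds[[ci]] <- data.frame(child_id = cid, time_h = dose_t,
                               ingredient = dose_ing, dose_mg = dose_mg)
      case <- .assign_case_windows(dose_t, window_h)
      truth[[ci]] <- do.call(rbind, lapply(unique(case), function(kc) {
        sel <- case == kc
        crs_id <- dose_course[sel][1]
        course <- child_courses[[crs_id]]
        pol <- attr(course, "policy")
        t0 <- dose_t[sel][1] - attr(course, "start_h")
        data.frame(
          case_id = paste0(cid, "-", kc), child_id = cid,
          course_id = crs_id,
          group = pol$group, pattern = pol$pattern,
          baseline_true_c = course_temp(course, t0),
          onset_band = as.character(onset_bin(course_temp(course, t0))),
          auc6_true = course_auc_true(course, t0, 6),
          auc8_true = course_auc_true(course, t0, 8),
          auc10_true = course_auc_true(course, t0, 10),
          auc12_true = course_auc_true(course, t0, 12),
          n_doses = sum(sel)
        )
      }))
    }
  }

  # simulation clocks are hours since the calendar origin
  origin_h <- .as_hours(as.POSIXct(paste(config$origin, "00:00:00"),
                                   tz = "UTC"))
  null_drop <- function(x) x[!vapply(x, is.null, logical(1))]
  tmp_all <- do.call(rbind, null_drop(temps))
  med_all <- do.call(rbind, null_drop(meds))
  cohort <- fever_cohort(
    children[, c("child_id", "sex", "birth_date", "weight_kg")],
    if (is.null(tmp_all)) .empty_temps() else
      tibble::tibble(child_id = tmp_all$child_id,
                     time = .as_time(origin_h + tmp_all$time_h),
                     temp_c = tmp_all$temp_c),
    if (is.null(med_all)) .empty_meds() else
      tibble::tibble(child_id = med_all$child_id,
                     time = .as_time(origin_h + med_all$time_h),
                     ingredient = med_all$ingredient,
                     dose_mg = med_all$dose_mg)
  )
  gt <- do.call(rbind, null_drop(truth))
  structure(
    list(cohort = cohort,
         ground_truth = if (is.null(gt)) tibble::tibble() else tibble::as_tibble(gt),
         children = children),
    courses = setNames(courses_all, children$child_id),
    class = "fever_sim"
  )
}

#' @export
print.fever_sim <- function(x, ...) {
  cat("<fever_sim>", nrow(x$children), "children,",
      nrow(x$ground_truth), "ground-truth cases\n")
  print(x$cohort)
  invisible(x)
}
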