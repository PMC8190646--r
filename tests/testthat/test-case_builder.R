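.mk_case_cohort <- function(dose_h, temps_h = NULL, temps_c = NULL,
                            ingredients = NULL) {
  d <- "2016-03-01 00:00:00"
  if (is.null(ingredients)) ingredients <- rep("ACE", length(dose_h))
  if (is.null(temps_h)) { temps_h <- c(0, 100); temps_c <- c(38.5, 38.5) }
  fever_cohort(
    tibble::tibble(child_id = "A", sex = "male",
                   birth_date = as.Date("2015-01-01"), weight_kg = 10),
    tibble::tibble(child_id = "A", time = .h(d, temps_h), temp_c = temps_c),
    tibble::tibble(child_id = "A", time = .h(d, dose_h),
                   ingredient = ingredients, dose_mg = NA_real_)
  )
}

test_that("greedy 72-hour windows partition doses with a half-open boundary", {
  expect_equal(nrow(build_cases(.mk_case_cohort(c(0, 6, 71)))), 1)

  cs <- build_cases(.mk_case_cohort(c(0, 72)))
  expect_equal(nrow(cs), 2)          # dose at exactly +72 h opens a new case

  cs2 <- build_cases(.mk_case_cohort(c(0, 70, 80)))
  expect_equal(cs2$n_doses, c(2, 1))
  expect_equal(.as_hours_test(cs2$window_start) - .as_hours_test(cs2$window_start[1]),
               c(0, 80))
  # every case window is exactly 72 h; every dose is in exactly one case
  expect_true(all(difftime(cs2$window_end, cs2$window_start, units = "hours") == 72))
  expect_equal(sum(cs2$n_doses), 3)
})

test_that("regimen classification counts distinct ingredients, canonical order", {
  expect_equal(classify_case(c("ACE", "ACE", "ACE")),
               list(group = "single", pattern = "ACE"))
  expect_equal(classify_case(c("ACE", "DEX", "ACE", "DEX")),
               list(group = "combination", pattern = "ACE-DEX"))
  expect_equal(classify_case(c("DEX", "IBU", "ACE")),
               list(group = "combination", pattern = "ACE-IBU-DEX"))
})

test_that("baseline is the imputed value at first administration, with fallback", {
  s <- temperature_series(c(-1, 1), temp_c = c(38, 39))
  expect_equal(baseline_temperature(s, 0), 38.5)
  s2 <- temperature_series(c(0, 2), temp_c = c(38.6, 39))
  expect_equal(baseline_temperature(s2, 0), 38.6)
  # outside the domain: nearest reading within 1 h, else missing
  expect_equal(baseline_temperature(s2, -0.5), 38.6)
  expect_true(is.na(baseline_temperature(s2, -3)))
  expect_equal(baseline_temperature(s2, -3, tolerance_h = 5), 38.6)
})

test_that("onset bins are half-open with <37 and >=40 tails", {
  expect_equal(as.character(onset_bin(c(36.9, 37.0, 38.0, 38.99, 39.0, 40.0))),
               c("<37", "[37,38)", "[38,39)", "[38,39)", "[39,40)", ">=40"))
})

test_that("AUC threshold populations are nested (39 implies 38)", {
  b <- c(37.9, 38.0, 38.5, 39.0, 40.1, NA)
  e38 <- eligible_for_auc(b, 38)
  e39 <- eligible_for_auc(b, 39)
  expect_equal(e38, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(!e39 | e38))
  expect_true(eligible_for_auc(40.1, 38) && eligible_for_auc(40.1, 39))
})

test_that("build_cases attaches baseline, bin and flags from the series", {
  co <- .mk_case_cohort(c(1.5, 10), temps_h = c(0, 2, 6),
                        temps_c = c(37, 39, 37),
                        ingredients = c("ACE", "DEX"))
  cs <- build_cases(co)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$group, "combination")
  expect_equal(cs$pattern, "ACE-DEX")
  expect_equal(cs$baseline_temp_c, 38.5)    # 37 + 1.5/2 * 2
  expect_equal(as.character(cs$onset_bin), "[38,39)")
  expect_false(cs$baseline_missing)

  # anchor far outside the series domain: flagged, not dropped
  co2 <- .mk_case_cohort(20, temps_h = c(0, 2), temps_c = c(38.5, 38.5))
  cs2 <- build_cases(co2)
  expect_true(cs2$baseline_missing)
  expect_true(is.na(cs2$baseline_temp_c))
})

test_that("case ids and windows agree between generator truth and pipeline", {
  sim <- generate_cohort(sim_config(n_children = 40), seed = 31)
  cases <- build_cases(filter_children(sim$cohort))
  gt <- sim$ground_truth
  common <- intersect(cases$case_id, gt$case_id)
  expect_gt(length(common), 0.9 * nrow(gt))
  m <- merge(cases, gt, by = "case_id")
  expect_true(all(m$group.x == m$group.y))
  expect_true(all(m$n_doses.x == m$n_doses.y))
})
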