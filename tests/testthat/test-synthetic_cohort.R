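test_that("config validation rejects malformed settings", {
  expect_error(sim_config(n_children = 0), "n_children")
  expect_error(sim_config(sex_male_prob = 1.2), "probabilities")
  expect_error(sim_config(fever_fall_h = -1), "durations")
  expect_error(sim_config(combination_prob_by_band = c(
    "<37" = 0.5, "[37,38)" = 0.2, "[38,39)" = 0.2, "[39,40)" = 0.3,
    ">=40" = 0.4)), "monotone")
})

test_that("identical (config, seed) reproduces the cohort byte-for-byte", {
  cfg <- sim_config(n_children = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg, seed = 7)$cohort, d1)
  write_cohort(generate_cohort(cfg, seed = 7)$cohort, d2)
  for (f in c("children.csv", "temperatures.csv", "antipyretics.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes it
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg, seed = 8)$cohort, d3)
  expect_false(identical(readLines(file.path(d1, "temperatures.csv")),
                         readLines(file.path(d3, "temperatures.csv"))))
})

test_that("profile marginals hit their configured targets", {
  set.seed(701)
  cfg <- sim_config(n_children = 10000)
  kids <- simulate_children(cfg)
  expect_equal(nrow(kids), 10000)

  male <- mean(kids$sex == "male")
  expect_gt(male, 0.49); expect_lt(male, 0.52)

  # truncated log-normal target mean in closed form
  mu <- cfg$age_meanlog; s <- cfg$age_sdlog
  lo <- cfg$age_range_days[1]; hi <- cfg$age_range_days[2]
  trunc_mean <- exp(mu + s^2 / 2) *
    (pnorm((log(hi) - mu - s^2) / s) - pnorm((log(lo) - mu - s^2) / s)) /
    (plnorm(hi, mu, s) - plnorm(lo, mu, s))
  expect_lt(abs(mean(kids$age_days) - trunc_mean),
            3 * sd(kids$age_days) / sqrt(nrow(kids)))
  expect_true(all(kids$age_days >= lo & kids$age_days <= hi))
  # weight grows monotonically with age on average
  expect_gt(cor(kids$age_days, kids$weight_kg), 0.8)

  set.seed(702)
  one <- simulate_children(sim_config(n_children = 1))
  expect_equal(nrow(one), 1)
})

test_that("zero-depth drug kernels leave the latent course untreated", {
  set.seed(703)
  cfg <- sim_config(n_children = 1, drug_effect = list(
    ACE = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 0, effect_duration_h = 6),
    IBU = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 0, effect_duration_h = 6),
    DEX = c(lag_h = 0.5, nadir_h = 2, nadir_drop_c = 0, effect_duration_h = 6)))
  crs <- simulate_fever_course(cfg)
  untreated <- fever_course(crs$B, crs$P, crs$t_pk, cfg$fever_rise_h,
                            cfg$fever_fall_h, cfg$course_window_h,
                            drug_effect = cfg$drug_effect)
  tg <- seq(0, 96, by = 0.25)
  expect_equal(course_temp(crs, tg), course_temp(untreated, tg))
})

test_that("single courses use one ingredient; combinations alternate >= 4 h apart", {
  set.seed(704)
  cfg0 <- sim_config(n_children = 1, combination_prob_by_band = c(
    "<37" = 0, "[37,38)" = 0, "[38,39)" = 0, "[39,40)" = 0, ">=40" = 0))
  cfg1 <- sim_config(n_children = 1, combination_prob_by_band = c(
    "<37" = 1, "[37,38)" = 1, "[38,39)" = 1, "[39,40)" = 1, ">=40" = 1))
  seen_multi <- 0
  for (i in 1:40) {
    c0 <- simulate_fever_course(cfg0)
    if (nrow(c0$doses)) {
      expect_equal(length(unique(c0$doses$ingredient)), 1)
    }
    c1 <- simulate_fever_course(cfg1)
    if (nrow(c1$doses) >= 2) {
      seen_multi <- seen_multi + 1
      ing <- c1$doses$ingredient
      expect_true(all(ing[-1] != ing[-length(ing)]))   # consecutive differ
      expect_true(all(diff(c1$doses$time_h) >= 4 - cfg1$sim_grid_h - 1e-9))
    }
  }
  expect_gt(seen_multi, 5)
})

test_that("a zero combination probability yields an all-single cohort", {
  cfg <- sim_config(n_children = 40, combination_prob_by_band = c(
    "<37" = 0, "[37,38)" = 0, "[38,39)" = 0, "[39,40)" = 0, ">=40" = 0))
  sim <- generate_cohort(cfg, seed = 11)
  cases <- build_cases(filter_children(sim$cohort))
  expect_gt(nrow(cases), 0)
  expect_true(all(cases$group == "single"))
  expect_true(all(sim$ground_truth$group == "single"))
})

test_that("noise-free unquantised measurements lie exactly on the latent curve", {
  set.seed(705)
  cfg <- sim_config(n_children = 1, measurement_noise_sd_c = 0,
                    round_to_0_1 = FALSE)
  crs <- simulate_fever_course(cfg)
  m <- simulate_measurements(crs, cfg)
  expect_gt(nrow(m), 0)
  expect_equal(m$temp_c, course_temp(crs, m$time_h), tolerance = 1e-12)

  # quantisation contract: observed values are multiples of 0.1
  cfg2 <- sim_config(n_children = 1)
  m2 <- simulate_measurements(crs, cfg2)
  expect_true(all(abs(m2$temp_c * 10 - round(m2$temp_c * 10)) < 1e-9))
})

test_that("sampling intensity rises with the latent temperature", {
  set.seed(706)
  # flat afebrile vs flat febrile course, same length: febrile window must
  # be sampled more densely on average
  cold <- fever_course(36.8, 0, 10, 4, 30, window_h = 96)
  hot <- fever_course(36.8, 2.6, 10, 4, 3000, window_h = 96)  # ~persistent
  cfg <- sim_config(n_children = 1)
  n_cold <- sum(replicate(30, nrow(simulate_measurements(cold, cfg))))
  n_hot <- sum(replicate(30, nrow(simulate_measurements(hot, cfg))))
  expect_gt(n_hot, n_cold * 1.5)
})

test_that("closed-form course integrals match numeric quadrature", {
  set.seed(707)
  cfg <- sim_config(n_children = 1)
  for (i in 1:5) {
    crs <- simulate_fever_course(cfg)
    a <- runif(1, 0, 40); b <- a + runif(1, 1, 30)
    num <- integrate(function(t) course_temp(crs, t), a, b,
                     subdivisions = 2000, rel.tol = 1e-10)$value
    expect_equal(course_integral(crs, a, b), num, tolerance = 1e-6)
  }
  # and the baseline-anchored truth built from it
  crs <- simulate_fever_course(cfg)
  if (nrow(crs$doses)) {
    t0 <- crs$doses$time_h[1]
    num <- integrate(function(t) course_temp(crs, t) - course_temp(crs, t0),
                     t0, t0 + 6, subdivisions = 2000, rel.tol = 1e-10)$value
    expect_equal(course_auc_true(crs, t0, 6), num, tolerance = 1e-6)
  }
})
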