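test_that("summary-statistic Student t matches t.test on raw data", {
  set.seed(501)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    got <- student_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter))
  }
})

test_that("Student t degenerate inputs follow the documented conventions", {
  eq <- student_t(1, 1, 10, 1, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  big <- student_t(1, 1, 10000, 0, 1, 10000)
  expect_lt(big$p, 0.001)
  z <- student_t(2, 0, 5, 1, 0, 5)
  expect_true(is.infinite(z$t) && z$t > 0)
  expect_equal(z$p, 0)
  expect_equal(student_t(3, 0, 5, 3, 0, 5)$t, 0)
})

test_that("chi-square is Pearson without continuity correction", {
  expect_equal(chi_square(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square(rbind(c(10, 10), c(10, 10)))$p, 1)
  # hand evaluation of sum (O-E)^2/E: all E = 20, four cells of (10)^2/20
  expect_equal(chi_square(rbind(c(30, 10), c(10, 30)))$statistic, 20)
  expect_equal(chi_square(rbind(c(30, 10), c(10, 30)))$df, 1)
  expect_error(chi_square(rbind(c(0, 0), c(10, 30))), "zero marginal")
})

test_that("Cohen's d is a shift/scale-invariant magnitude", {
  d0 <- cohens_d(1, 1, 1, 2)
  expect_equal(d0, 0)
  d <- cohens_d(38.6, 0.5, 38.9, 0.6)
  expect_equal(cohens_d(38.6 + 5, 0.5, 38.9 + 5, 0.6), d)
  expect_equal(cohens_d(2 * 38.6, 2 * 0.5, 2 * 38.9, 2 * 0.6), d)
  expect_equal(cohens_d(38.9, 0.6, 38.6, 0.5), d)   # symmetric magnitude
  expect_error(cohens_d(1, 0, 2, 0), "both SDs")
  # n-weighted variant uses the pooled-sample SD
  expect_equal(cohens_d(1, 1, 0, 2, variant = "n_weighted", n1 = 10, n2 = 30),
               1 / sqrt((9 * 1 + 29 * 4) / 38))
})

test_that("Cohen's h matches the arcsine formula and is symmetric", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(0.2, 0.5), abs(2 * asin(sqrt(0.2)) - 2 * asin(sqrt(0.5))))
  expect_equal(cohens_h(0.5, 0.2), cohens_h(0.2, 0.5))
})

test_that("mixture totals reproduce pooled moments exactly", {
  set.seed(502)
  x <- rnorm(37, 5, 2); y <- rnorm(53, 7, 3)
  psd <- function(v) sqrt(mean((v - mean(v))^2))   # population SD
  got <- mixture_total(mean(x), psd(x), length(x), mean(y), psd(y), length(y))
  expect_equal(got$mean, mean(c(x, y)), tolerance = 1e-12)
  expect_equal(got$sd, psd(c(x, y)), tolerance = 1e-12)
  expect_equal(got$n, 90)
  # single-component degenerate case
  expect_equal(mixture_total(3, 1, 10, 99, 99, 0), list(mean = 3, sd = 1, n = 10))
})

test_that("baseline-anchored AUC integrates the hourly delta curve", {
  # constant at baseline: zero exposure
  s <- temperature_series(0:6, temp_c = rep(38.5, 7))
  expect_equal(auc_from_baseline(s, 0, 38.5, 6)$auc_c_h, 0)

  # delta falls linearly to -2 over 2 h then holds: triangle + rectangle
  s2 <- temperature_series(c(0, 2, 6), temp_c = c(39, 37, 37))
  r <- auc_from_baseline(s2, 0, 39, 6)
  expect_equal(r$auc_c_h, -(0.5 * 2 * 2 + 4 * 2))
  expect_false(r$truncated)

  # truncated series: partial integral, flagged
  s3 <- temperature_series(c(0, 3.5), temp_c = c(39, 39))
  r3 <- auc_from_baseline(s3, 0, 39, 6)
  expect_true(r3$truncated)
  expect_error(auc_from_baseline(s3, 0, NA, 6), "baseline")
  expect_warning(auc_from_baseline(s2, 0, 39, 5), "non-standard")
})

test_that("AUC horizons are additive on the shared hourly grid", {
  set.seed(503)
  for (i in 1:25) {
    s <- random_series(n_pts = 20, span_h = 30)
    if (diff(range(s$time_h)) < 13) next
    t0 <- min(s$time_h)
    b <- interpolate_temperature(s, t0)
    a6 <- auc_from_baseline(s, t0, b, 6)$auc_c_h
    a12 <- auc_from_baseline(s, t0, b, 12)$auc_c_h
    g <- hourly_grid(s, t0, 12)
    mid <- sum((g$temp_c[7:12] + g$temp_c[8:13]) / 2 - b)  # AUC over [6,12]
    expect_equal(a6 + mid, a12, tolerance = 1e-9)
  }
})

test_that("delta curves are baseline-anchored with non-increasing support", {
  sim <- generate_cohort(sim_config(n_children = 50), seed = 61)
  co <- filter_children(sim$cohort)
  cases <- build_cases(co)
  cases <- cases[eligible_for_auc(cases$baseline_temp_c, 38), ]
  cur <- delta_curve(cases, co, stratify_by = "group")
  expect_true(all(abs(cur$mean_delta_c[cur$offset_h == 0]) < 1e-12))
  for (s in unique(cur$stratum)) {
    expect_true(all(diff(cur$n[cur$stratum == s]) <= 0))
  }
})

test_that("group tables are internally consistent with their inputs", {
  sim <- generate_cohort(sim_config(n_children = 120), seed = 62)
  co <- filter_children(sim$cohort)
  episodes <- detect_episodes_cohort(co)
  cases <- link_episodes(build_cases(co), episodes, co)
  auc <- compute_auc(cases, co)

  t1 <- table1_report(co, cases)
  expect_equal(t1$continuous$single_n + t1$continuous$combination_n,
               t1$continuous$total_n)
  expect_equal(sum(t1$onset_bins$total), nrow(cases))
  nz <- t1$onset_bins$total > 0
  expect_true(all(abs(t1$onset_bins$single_pct[nz] +
                        t1$onset_bins$combination_pct[nz] - 100) < 1e-9))

  t2 <- table2_report(cases, auc)
  # the printed total is the mixture of the two group columns
  for (i in seq_len(nrow(t2))) {
    mt <- mixture_total(t2$single_mean[i], t2$single_sd[i], t2$single_n[i],
                        t2$combination_mean[i], t2$combination_sd[i],
                        t2$combination_n[i])
    expect_equal(t2$total_mean[i], mt$mean, tolerance = 1e-9)
    expect_equal(t2$total_sd[i], mt$sd, tolerance = 1e-9)
  }
  # nesting: every case analysed at 39 is analysed at 38
  n38 <- t2$total_n[t2$threshold_c == 38]
  n39 <- t2$total_n[t2$threshold_c == 39]
  if (length(n38) && length(n39)) expect_true(all(n39 <= n38))
})
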