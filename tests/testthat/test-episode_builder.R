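test_that("linear imputation reproduces readings and segment midpoints", {
  s <- temperature_series(c(0, 2), temp_c = c(38, 39))
  expect_equal(interpolate_temperature(s, 1), 38.5)
  expect_equal(interpolate_temperature(s, 2), 39)
  s2 <- temperature_series(c(0, 4), temp_c = c(38, 38))
  expect_equal(interpolate_temperature(s2, c(0, 1.3, 4)), rep(38, 3))
  expect_error(interpolate_temperature(s, 2.5), "extrapolation")
  expect_error(interpolate_temperature(s, -0.1), "extrapolation")
})

test_that("imputed values are bounded by their neighbouring readings", {
  set.seed(401)
  for (i in 1:50) {
    s <- random_series()
    if (length(s$time_h) < 2) next
    t <- runif(20, min(s$time_h), max(s$time_h))
    v <- interpolate_temperature(s, t)
    k <- findInterval(t, s$time_h, rightmost.closed = TRUE)
    lo <- pmin(s$temp_c[k], s$temp_c[k + 1])
    hi <- pmax(s$temp_c[k], s$temp_c[k + 1])
    expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
  }
})

test_that("hourly grid has horizon+1 points, truncating at series end", {
  s <- temperature_series(0:12, temp_c = rep(38.5, 13))
  g <- hourly_grid(s, 0, 12)
  expect_equal(nrow(g), 13)
  expect_false(attr(g, "truncated"))
  expect_equal(g$temp_c, rep(38.5, 13))

  s2 <- temperature_series(c(0, 5.5), temp_c = c(38, 38))
  g2 <- hourly_grid(s2, 0, 6)
  expect_equal(g2$offset_h, 0:5)
  expect_true(attr(g2, "truncated"))
  expect_error(hourly_grid(s2, 6, 6), "anchor outside")
})

test_that("episode endpoints sit at interpolated threshold crossings", {
  expect_equal(nrow(detect_episodes(
    temperature_series(c(0, 3, 7), temp_c = c(37, 37.5, 37)))), 0)

  # 37 @0h rises to 39 @2h (crosses 38 at 1h), falls to 37 @6h
  # (slope -0.5/h, crosses 38 at 4h)
  ep <- detect_episodes(temperature_series(c(0, 2, 6), temp_c = c(37, 39, 37)))
  expect_equal(nrow(ep), 1)
  expect_equal(.as_hours_test(ep$onset_time), 1)
  expect_equal(.as_hours_test(ep$offset_time), 4)
  expect_equal(ep$duration_h, 3)
  expect_equal(ep$max_temp_c, 39)
  expect_true(ep$resolved)

  # single suprathreshold reading: open episode at that instant
  ep1 <- detect_episodes(temperature_series(5, temp_c = 40))
  expect_equal(nrow(ep1), 1)
  expect_false(ep1$resolved)
  expect_true(is.na(ep1$duration_h))
  expect_equal(ep1$max_temp_c, 40)

  # still febrile at the last reading: unresolved
  ep2 <- detect_episodes(temperature_series(c(0, 2), temp_c = c(37, 39)))
  expect_false(ep2$resolved)
  expect_equal(.as_hours_test(ep2$onset_time), 1)
})

test_that("episodes are disjoint, ordered, and shift-equivariant", {
  set.seed(402)
  for (i in 1:60) {
    s <- random_series()
    ep <- detect_episodes(s)
    if (nrow(ep) > 1) {
      on <- .as_hours_test(ep$onset_time)
      off <- ifelse(ep$resolved, .as_hours_test(ep$offset_time), Inf)
      expect_true(all(diff(on) > 0))
      expect_true(all(off[-nrow(ep)] <= on[-1] + 1e-9))
    }
    # shifting temperatures and threshold together preserves endpoints
    s_shift <- temperature_series(s$time_h, child_id = "X",
                                  temp_c = s$temp_c + 0.7)
    ep_shift <- detect_episodes(s_shift, threshold_c = 38.7)
    expect_equal(ep_shift$onset_time, ep$onset_time)
    expect_equal(ep_shift$offset_time, ep$offset_time)
  }
})

test_that("a configurable maximum imputation gap splits the series", {
  # febrile before and after a 30 h reporting gap
  s <- temperature_series(c(0, 1, 31, 32), temp_c = c(38.5, 38.4, 38.6, 37))
  expect_equal(nrow(detect_episodes(s)), 1)          # default: bridged
  ep <- detect_episodes(s, max_gap_h = 12)
  expect_equal(nrow(ep), 2)
  expect_false(ep$resolved[1])                       # cut at the gap
  expect_true(ep$resolved[2])
})

test_that("analytic endpoints match a 1-minute brute-force scan", {
  set.seed(403)
  checked <- 0
  for (i in 1:100) {
    s <- random_series()
    if (length(s$time_h) < 2) next
    expect_true(episodes_match_scan(detect_episodes(s), s),
                label = paste("series", i))
    checked <- checked + 1
  }
  expect_gt(checked, 90)
})
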