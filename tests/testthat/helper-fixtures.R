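# shared fixtures: random irregular series for oracle tests and a small
# hand-enumerated cohort

random_series <- function(n_pts = NULL, span_h = 48) {
  n <- if (is.null(n_pts)) sample(5:30, 1) else n_pts
  t <- sort(runif(n, 0, span_h))
  t <- t[c(TRUE, diff(t) > 1 / 60)]        # keep readings >= 1 min apart
  temp <- 37.5 + cumsum(rnorm(length(t), 0, 0.6))
  temp <- pmin(pmax(temp, 35), 41.5)
  temperature_series(t, child_id = "X", temp_c = temp)
}

# brute-force 1-minute-grid oracle: classify every grid minute as febrile
# directly from the interpolant, reconstruct the same classification from
# the analytic episode intervals, and require agreement everywhere except
# within `tol` of an analytic boundary. A misplaced onset/offset, a missed
# episode or an invented one wider than the grid step all produce
# unexcused mismatches; features narrower than the grid step (sub-minute
# episodes or dips) are below the scan's resolution by construction.
episodes_match_scan <- function(ep, series, threshold_c = 38,
                                tol = 1.01 / 60, step_min = 1) {
  dom <- range(series$time_h)
  tg <- unique(c(seq(dom[1], dom[2], by = step_min / 60), dom[2]))
  f_scan <- interpolate_temperature(series, tg) >= threshold_c
  on <- .as_hours_test(ep$onset_time)
  off <- ifelse(ep$resolved, .as_hours_test(ep$offset_time), dom[2])
  f_an <- rep(FALSE, length(tg))
  near_bnd <- rep(FALSE, length(tg))
  for (k in seq_along(on)) {
    f_an <- f_an | (tg >= on[k] & tg <= off[k])
    near_bnd <- near_bnd | abs(tg - on[k]) <= tol | abs(tg - off[k]) <= tol
  }
  all(f_an[!near_bnd] == f_scan[!near_bnd])
}

.h <- function(date, h) as.POSIXct(date, tz = "UTC") + h * 3600

.as_hours_test <- function(t) as.numeric(t) / 3600

# five hand-written children; expected downstream counts are enumerated in
# the pipeline tests: A, B, C retained; D fails weight; E has no doses
tiny_cohort <- function() {
  d <- "2016-03-01 00:00:00"
  children <- tibble::tibble(
    child_id = c("A", "B", "C", "D", "E"),
    sex = c("male", "female", "male", "female", "male"),
    birth_date = as.Date(c("2015-01-20", "2014-06-01", "2013-03-10",
                           "2016-02-20", "2015-08-01")),
    weight_kg = c(10, 13, 16, 1.5, 11)
  )
  temps <- tibble::tibble(
    child_id = c(rep("A", 3), rep("B", 4), rep("C", 5), rep("D", 2), "E"),
    time = c(.h(d, c(0, 2, 6)),                 # A: crossing episode
             .h(d, c(0, 4, 8, 12)),             # B: long febrile window
             .h(d, c(0, 1, 2, 80, 81)),         # C: two separate fevers
             .h(d, c(0, 1)), .h(d, 0)),
    temp_c = c(37.0, 39.0, 37.0,
               38.5, 38.6, 38.2, 37.2,
               38.9, 38.0, 37.5, 38.6, 37.9,
               39.0, 37.0, 39.0)
  )
  meds <- tibble::tibble(
    child_id = c("A", "B", "B", "C", "C", "D"),
    time = c(.h(d, 1.5), .h(d, 0), .h(d, 5), .h(d, 0), .h(d, 80), .h(d, 0.5)),
    ingredient = c("ACE", "ACE", "DEX", "ACE", "ACE", "IBU"),
    dose_mg = NA_real_
  )
  fever_cohort(children, temps, meds)
}
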