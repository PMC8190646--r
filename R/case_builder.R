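#' Classify a set of doses into regimen group and pattern
#'
#' A case is `single` when exactly one distinct ingredient appears in its
#' window and `combination` otherwise. The pattern is the canonical label
#' joining the distinct ingredients in `ACE < IBU < DEX` order
#' (e.g. `"ACE-DEX"`, `"ACE-IBU-DEX"`).
#'
#' @param ingredients Character vector of ingredient codes for the case's
#'   doses (repeats allowed).
#' @return List with elements `group` and `pattern`.
#' @export
#' @examples
#' classify_case(c("ACE", "DEX", "ACE", "DEX"))
classify_case <- function(ingredients) {
  stopifnot(length(ingredients) >= 1)
  distinct <- .INGREDIENTS[.INGREDIENTS %in% ingredients]
  if (!length(distinct)) stop("no recognised ingredient among doses", call. = FALSE)
  list(group = if (length(distinct) == 1) "single" else "combination",
       pattern = paste(distinct, collapse = "-"))
}

#' Baseline temperature at the first administration of a case
#'
#' The interpolated temperature at `window_start` when it lies inside the
#' series domain; otherwise the nearest reading within `tolerance_h` hours.
#' Beyond the tolerance the baseline is missing (`NA`), and such cases are
#' excluded from AUC analyses downstream.
#'
#' @param series A [temperature_series()].
#' @param window_start POSIXct or numeric hours.
#' @param tolerance_h Nearest-reading fallback tolerance in hours.
#' @return Baseline temperature in Celsius, or `NA_real_`.
#' @export
baseline_temperature <- function(series, window_start, tolerance_h = 1) {
  stopifnot(inherits(series, "temperature_series"))
  t0 <- .to_hours(window_start)
  if (!length(series$time_h)) return(NA_real_)
  dom <- .series_domain(series)
  if (t0 >= dom[1] && t0 <= dom[2]) {
    return(interpolate_temperature(series, t0))
  }
  d <- abs(series$time_h - t0)
  i <- which.min(d)
  if (d[i] <= tolerance_h) series$temp_c[i] else NA_real_
}

#' Onset-temperature bin
#'
#' Half-open bins used for stratified reporting:
#' `<37`, `[37,38)`, `[38,39)`, `[39,40)`, `>=40`.
#'
#' @param temp_c Numeric vector of baseline temperatures.
#' @return Factor with the five bin levels (`NA` stays `NA`).
#' @export
#' @examples
#' onset_bin(c(36.9, 38.0, 40.0))
onset_bin <- function(temp_c) {
  cut(temp_c, breaks = c(-Inf, 37, 38, 39, 40, Inf), right = FALSE,
      labels = c("<37", "[37,38)", "[38,39)", "[39,40)", ">=40"))
}

#' AUC eligibility at an analysis threshold
#'
#' A case enters the AUC comparison for a given analysis threshold when its
#' baseline temperature is at or above the threshold (non-strict; the
#' populations at 39 are nested within those at 38).
#'
#' @param baseline_temp_c Numeric vector of baselines.
#' @param threshold_c Analysis threshold, typically 38 or 39.
#' @param strict Use a strict inequality instead (off by default).
#' @return Logical vector; `NA` baselines give `FALSE`.
#' @export
eligible_for_auc <- function(baseline_temp_c, threshold_c, strict = FALSE) {
  ok <- if (strict) baseline_temp_c > threshold_c else baseline_temp_c >= threshold_c
  !is.na(ok) & ok
}

# greedy left-to-right 72h windowing of sorted dose times (numeric hours)
.assign_case_windows <- function(dose_h, window_h) {
  n <- length(dose_h)
  case <- integer(n)
  k <- 0L
  win_start <- -Inf
  for (i in seq_len(n)) {
    if (dose_h[i] >= win_start + window_h) {   # half-open [start, start+72)
      k <- k + 1L
      win_start <- dose_h[i]
    }
    case[i] <- k
  }
  case
}

#' Construct 72-hour antipyretic cases
#'
#' Greedy left-to-right windowing per child: the earliest unassigned dose
#' opens a case; every dose in the half-open window
#' `[window_start, window_start + window_h)` joins it; the next unassigned
#' dose opens the next case. Every dose belongs to exactly one case. Each
#' case carries its regimen classification, the baseline temperature at the
#' first administration and the onset-temperature bin.
#'
#' @param cohort A [fever_cohort()] (already filtered).
#' @param window_h Case window length in hours.
#' @param baseline_tolerance_h Tolerance for [baseline_temperature()].
#' @return Tibble: `case_id`, `child_id`, `window_start`, `window_end`,
#'   `n_doses`, `group`, `pattern`, `baseline_temp_c`, `baseline_missing`,
#'   `onset_bin`.
#' @export
build_cases <- function(cohort, window_h = 72, baseline_tolerance_h = 1) {
  stopifnot(inherits(cohort, "fever_cohort"))
  meds <- cohort$antipyretics
  if (nrow(meds) == 0) return(.empty_cases())
  series_list <- split_series(cohort)

  med_idx <- split(seq_len(nrow(meds)), meds$child_id)
  rows <- lapply(names(med_idx), function(cid) {
    i <- med_idx[[cid]]
    dose_h <- .as_hours(meds$time[i])
    ing <- meds$ingredient[i]
    case <- .assign_case_windows(dose_h, window_h)
    ser <- series_list[[cid]]
    per_case <- lapply(unique(case), function(k) {
      sel <- case == k
      t0 <- dose_h[sel][1]
      cls <- classify_case(ing[sel])
      base <- if (is.null(ser)) NA_real_ else
        baseline_temperature(ser, t0, tolerance_h = baseline_tolerance_h)
      data.frame(child_id = cid, case_num = k, start_h = t0,
                 n_doses = sum(sel), group = cls$group, pattern = cls$pattern,
                 baseline_temp_c = base)
    })
    do.call(rbind, per_case)
  })
  out <- do.call(rbind, rows)
  tibble::tibble(
    case_id = paste0(out$child_id, "-", out$case_num),
    child_id = out$child_id,
    window_start = .as_time(out$start_h),
    window_end = .as_time(out$start_h + window_h),
    n_doses = out$n_doses,
    group = out$group,
    pattern = out$pattern,
    baseline_temp_c = out$baseline_temp_c,
    baseline_missing = is.na(out$baseline_temp_c),
    onset_bin = onset_bin(out$baseline_temp_c)
  )
}

.empty_cases <- function() {
  tibble::tibble(case_id = character(), child_id = character(),
                 window_start = as.POSIXct(character(), tz = "UTC"),
                 window_end = as.POSIXct(character(), tz = "UTC"),
                 n_doses = integer(), group = character(),
                 pattern = character(), baseline_temp_c = numeric(),
                 baseline_missing = logical(),
                 onset_bin = onset_bin(numeric()))
}

#' Link fever episodes to cases
#'
#' Attaches, per case, the episodes overlapping the case window, and
#' summarises the fever duration of the first overlapping resolved episode
#' (unresolved episodes are counted but contribute no duration) and the
#' maximum observed reading inside the window.
#'
#' @param cases Output of [build_cases()].
#' @param episodes Output of [detect_episodes_cohort()].
#' @param cohort The cohort the cases were built from.
#' @return `cases` with added columns `n_episodes`, `fever_duration_h`
#'   (NA when no resolved episode overlaps) and `max_temp_c`.
#' @export
link_episodes <- function(cases, episodes, cohort) {
  stopifnot(inherits(cohort, "fever_cohort"))
  tmp <- cohort$temperatures
  tmp_h <- .as_hours(tmp$time)
  ep_on <- .as_hours(episodes$onset_time)
  ep_off <- ifelse(episodes$resolved, .as_hours(episodes$offset_time), Inf)

  ep_by_child <- split(seq_len(nrow(episodes)), episodes$child_id)
  tmp_by_child <- split(seq_len(nrow(tmp)), tmp$child_id)

  n_ep <- integer(nrow(cases)); dur <- rep(NA_real_, nrow(cases))
  maxt <- rep(NA_real_, nrow(cases))
  ws <- .as_hours(cases$window_start); we <- .as_hours(cases$window_end)
  for (i in seq_len(nrow(cases))) {
    ei <- ep_by_child[[cases$child_id[i]]]
    if (!is.null(ei)) {
      sel <- ei[ep_on[ei] < we[i] & ep_off[ei] > ws[i]]
      n_ep[i] <- length(sel)
      res <- sel[episodes$resolved[sel]]
      if (length(res)) dur[i] <- episodes$duration_h[res[1]]
    }
    ti <- tmp_by_child[[cases$child_id[i]]]
    if (!is.null(ti)) {
      in_win <- ti[tmp_h[ti] >= ws[i] & tmp_h[ti] < we[i]]
      if (length(in_win)) maxt[i] <- max(tmp$temp_c[in_win])
    }
  }
  cases$n_episodes <- n_ep
  cases$fever_duration_h <- dur
  cases$max_temp_c <- maxt
  cases
}
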