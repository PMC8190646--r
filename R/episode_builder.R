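#' Build a per-child temperature series
#'
#' A `temperature_series` is the piecewise-linear interpolation substrate for
#' one child: strictly increasing reading times (duplicate minutes keep the
#' last entry) with temperatures in Celsius. The interpolation domain is
#' `[first reading, last reading]`; the series is never extrapolated.
#'
#' @param x A [fever_cohort()] (then `child_id` selects the child) or a
#'   POSIXct/numeric vector of reading times.
#' @param child_id Child identifier when `x` is a cohort.
#' @param temp_c Temperatures when `x` is a time vector.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(x, child_id = NULL, temp_c = NULL) {
  if (inherits(x, "fever_cohort")) {
    stopifnot(!is.null(child_id))
    rows <- x$temperatures[x$temperatures$child_id == child_id, ]
    time <- rows$time
    temp_c <- rows$temp_c
  } else {
    time <- x
    if (is.null(child_id)) child_id <- "series"
  }
  stopifnot(length(time) == length(temp_c))
  time_h <- if (inherits(time, "POSIXct")) .as_hours(time) else as.numeric(time)
  ord <- order(time_h)
  time_h <- time_h[ord]
  temp_c <- temp_c[ord]
  dup <- duplicated(time_h, fromLast = TRUE)
  structure(
    list(child_id = child_id, time_h = time_h[!dup], temp_c = temp_c[!dup]),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("<temperature_series> child", x$child_id, "-", length(x$time_h),
      "readings")
  if (length(x$time_h)) {
    cat(sprintf(" spanning %.1f h, %.1f-%.1f ℃",
                diff(range(x$time_h)), min(x$temp_c), max(x$temp_c)))
  }
  cat("\n")
  invisible(x)
}

.series_domain <- function(series) range(series$time_h)

.to_hours <- function(t) {
  if (inherits(t, "POSIXct")) .as_hours(t) else as.numeric(t)
}

#' Linearly imputed temperature at arbitrary times
#'
#' Returns the exact reading when `t` coincides with a reading time,
#' otherwise the linear interpolation between the two neighbouring readings
#' (so the result is always bounded by them). Times outside the series
#' domain are an error: the series is never extrapolated.
#'
#' @param series A [temperature_series()].
#' @param t POSIXct vector, or numeric hours on the same scale as the series.
#' @return Numeric vector of temperatures, same length as `t`.
#' @export
interpolate_temperature <- function(series, t) {
  stopifnot(inherits(series, "temperature_series"))
  t <- .to_hours(t)
  if (length(series$time_h) == 0) stop("empty series", call. = FALSE)
  dom <- .series_domain(series)
  if (any(t < dom[1] | t > dom[2])) {
    stop("time outside interpolation domain [",
         format(dom[1]), ", ", format(dom[2]), "] h; no extrapolation",
         call. = FALSE)
  }
  if (length(series$time_h) == 1) return(rep(series$temp_c, length(t)))
  approx(series$time_h, series$temp_c, xout = t, method = "linear",
         ties = "ordered")$y
}

#' Hourly temperature grid from an anchor
#'
#' Temperatures at `anchor + 0, 1, ..., horizon_h` hours via
#' [interpolate_temperature()]. Where the series ends before
#' `anchor + horizon_h` the grid is truncated and flagged.
#'
#' @param series A [temperature_series()].
#' @param anchor POSIXct or numeric hours; must lie inside the domain.
#' @param horizon_h Number of hours; the grid has up to `horizon_h + 1` rows.
#' @return Tibble `offset_h`, `temp_c`; attribute `truncated` (logical).
#' @export
hourly_grid <- function(series, anchor, horizon_h) {
  stopifnot(inherits(series, "temperature_series"), horizon_h >= 0)
  anchor <- .to_hours(anchor)
  dom <- .series_domain(series)
  if (anchor < dom[1] || anchor > dom[2]) {
    stop("anchor outside interpolation domain", call. = FALSE)
  }
  offs <- 0:horizon_h
  keep <- anchor + offs <= dom[2]
  offs <- offs[keep]
  out <- tibble::tibble(
    offset_h = offs,
    temp_c = interpolate_temperature(series, anchor + offs)
  )
  attr(out, "truncated") <- length(offs) < horizon_h + 1
  out
}

#' Detect fever episodes by threshold crossing
#'
#' Fever episodes are the maximal intervals on which the piecewise-linear
#' interpolant is at or above `threshold_c`. Onsets and offsets falling
#' between readings are placed at the interpolated crossing time. An episode
#' still at or above threshold at the last reading (or at a gap break, see
#' `max_gap_h`) has no offset and is reported unresolved. A touch of exactly
#' `threshold_c` at a single instant is not an episode. `max_temp_c` is the
#' maximum observed reading within the episode.
#'
#' @param series A [temperature_series()].
#' @param threshold_c Fever threshold; at-threshold values count as febrile.
#' @param max_gap_h Optional maximum imputation gap in hours; consecutive
#'   readings further apart than this are not interpolated across (the
#'   series is split there). Default `Inf` (off).
#' @return Tibble: `child_id`, `onset_time`, `offset_time` (NA when
#'   unresolved), `duration_h`, `max_temp_c`, `resolved`.
#' @export
detect_episodes <- function(series, threshold_c = 38, max_gap_h = Inf) {
  stopifnot(inherits(series, "temperature_series"))
  n <- length(series$time_h)
  if (n == 0) return(.empty_episodes())

  gaps <- diff(series$time_h)
  seg_id <- cumsum(c(1, as.integer(gaps > max_gap_h)))
  pieces <- lapply(split(seq_len(n), seg_id), function(idx) {
    .detect_episodes_segment(series$time_h[idx], series$temp_c[idx],
                             threshold_c)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) return(.empty_episodes())
  tibble::tibble(
    child_id = series$child_id,
    onset_time = .as_time(out$onset_h),
    offset_time = .as_time(out$offset_h),  # NA propagates
    duration_h = out$offset_h - out$onset_h,
    max_temp_c = out$max_temp_c,
    resolved = !is.na(out$offset_h)
  )
}

.empty_episodes <- function() {
  tibble::tibble(child_id = character(),
                 onset_time = as.POSIXct(character(), tz = "UTC"),
                 offset_time = as.POSIXct(character(), tz = "UTC"),
                 duration_h = numeric(), max_temp_c = numeric(),
                 resolved = logical())
}

# one contiguous (gap-free) run of readings
.detect_episodes_segment <- function(time_h, temp_c, threshold_c) {
  f <- temp_c - threshold_c
  n <- length(f)
  onsets <- numeric(0); offsets <- numeric(0)
  in_ep <- FALSE; onset <- NA_real_

  if (f[1] >= 0) { in_ep <- TRUE; onset <- time_h[1] }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- f[i]; b <- f[i + 1]; dt <- time_h[i + 1] - time_h[i]
      if (a >= 0 && b < 0) {            # downward crossing: close episode
        tc <- time_h[i] + a / (a - b) * dt
        onsets <- c(onsets, onset); offsets <- c(offsets, tc)
        in_ep <- FALSE; onset <- NA_real_
      } else if (a < 0 && b >= 0) {     # upward crossing: open episode
        onset <- time_h[i] + (-a) / (b - a) * dt
        in_ep <- TRUE
      }
    }
  }
  if (in_ep) { onsets <- c(onsets, onset); offsets <- c(offsets, NA_real_) }
  if (!length(onsets)) {
    return(data.frame(onset_h = numeric(0), offset_h = numeric(0),
                      max_temp_c = numeric(0)))
  }
  keep <- is.na(offsets) | offsets > onsets   # drop zero-length touches
  onsets <- onsets[keep]; offsets <- offsets[keep]
  max_temp <- vapply(seq_along(onsets), function(k) {
    hi <- if (is.na(offsets[k])) time_h[n] else offsets[k]
    max(temp_c[time_h >= onsets[k] & time_h <= hi])
  }, numeric(1))
  data.frame(onset_h = onsets, offset_h = offsets, max_temp_c = max_temp)
}

#' Detect fever episodes for every child in a cohort
#'
#' @param cohort A [fever_cohort()].
#' @inheritParams detect_episodes
#' @return Tibble of episodes across children (see [detect_episodes()]).
#' @export
detect_episodes_cohort <- function(cohort, threshold_c = 38, max_gap_h = Inf) {
  stopifnot(inherits(cohort, "fever_cohort"))
  series_list <- split_series(cohort)
  dplyr::bind_rows(lapply(series_list, detect_episodes,
                          threshold_c = threshold_c, max_gap_h = max_gap_h))
}

#' Split a cohort into per-child temperature series
#'
#' @param cohort A [fever_cohort()].
#' @return Named list of [temperature_series()], one per child with
#'   at least one temperature record.
#' @export
split_series <- function(cohort) {
  stopifnot(inherits(cohort, "fever_cohort"))
  tmp <- cohort$temperatures
  idx <- split(seq_len(nrow(tmp)), tmp$child_id)
  lapply(idx, function(i) {
    temperature_series(tmp$time[i], child_id = tmp$child_id[i][1],
                       temp_c = tmp$temp_c[i])
  })
}
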