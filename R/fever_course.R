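#' @title Latent fever course
#' @description
#' The generator's noise-free temperature model for one fever course:
#' a baseline `B` plus a febrile excursion `P * g(t)` where `g` rises
#' logistically to 1 at the peak time and decays exponentially afterwards,
#' superposed with one additive drug-response kernel per administered dose.
#' Each kernel is piecewise linear: zero until `lag_h` after the dose, a
#' descent to `-nadir_drop_c` at `nadir_h`, and a linear recovery to zero at
#' `effect_duration_h`. Every piece is analytically integrable, so exact
#' per-case AUC ground truth is available in closed form.
#'
#' @param baseline_c Afebrile baseline temperature `B` (Celsius).
#' @param peak_delta_c Peak febrile rise `P` above baseline (Celsius).
#' @param peak_time_h Time of the fever peak within the course (hours).
#' @param rise_h Duration of the logistic rise (hours); the logistic scale
#'   is `rise_h / 3`.
#' @param fall_h Exponential decay time constant after the peak (hours).
#' @param window_h Course window length (hours).
#' @param doses Data frame `time_h`, `ingredient` of administrations.
#' @param drug_effect Named list of per-ingredient kernel parameter vectors
#'   `c(lag_h, nadir_h, nadir_drop_c, effect_duration_h)`.
#' @return An object of class `fever_course`.
#' @export
fever_course <- function(baseline_c, peak_delta_c, peak_time_h, rise_h,
                         fall_h, window_h = 96,
                         doses = data.frame(time_h = numeric(),
                                            ingredient = character()),
                         drug_effect = list()) {
  stopifnot(peak_delta_c >= 0, rise_h > 0, fall_h > 0, window_h > 0)
  s <- rise_h / 3
  m <- peak_time_h - rise_h            # logistic midpoint; g(peak) scale c0
  c0 <- stats::plogis((peak_time_h - m) / s)
  structure(
    list(B = baseline_c, P = peak_delta_c, t_pk = peak_time_h,
         s = s, m = m, c0 = c0, tau = fall_h, window_h = window_h,
         doses = doses, drug_effect = drug_effect),
    class = "fever_course"
  )
}

#' @export
print.fever_course <- function(x, ...) {
  cat(sprintf("<fever_course> B=%.2f P=%.2f peak@%.1fh tau=%.0fh, %d dose(s)\n",
              x$B, x$P, x$t_pk, x$tau, nrow(x$doses)))
  invisible(x)
}

.kernel_knots <- function(par) {
  # piecewise-linear response: (0,0) (lag,0) (nadir,-drop) (duration,0)
  lag <- par[["lag_h"]]; nad <- par[["nadir_h"]]
  drop <- par[["nadir_drop_c"]]; dur <- par[["effect_duration_h"]]
  stopifnot(lag >= 0, nad > lag, dur > nad)
  list(x = c(0, lag, nad, dur), y = c(0, 0, -drop, 0))
}

.pwl_value <- function(knots, u) {
  v <- numeric(length(u))
  inside <- u >= knots$x[1] & u <= knots$x[length(knots$x)]
  if (any(inside)) {
    v[inside] <- approx(knots$x, knots$y, xout = u[inside],
                        ties = "ordered")$y
  }
  v
}

.pwl_integral <- function(knots, a, b) {
  lo <- max(a, knots$x[1]); hi <- min(b, knots$x[length(knots$x)])
  if (hi <= lo) return(0)
  xs <- sort(unique(c(lo, hi, knots$x[knots$x > lo & knots$x < hi])))
  ys <- approx(knots$x, knots$y, xout = xs, ties = "ordered")$y
  .trapz(xs, ys)
}

# numerically safe log(1 + exp(x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.backbone_value <- function(course, t) {
  g <- ifelse(
    t <= course$t_pk,
    stats::plogis((t - course$m) / course$s) / course$c0,
    exp(-(t - course$t_pk) / course$tau)
  )
  course$B + course$P * g
}

.backbone_integral <- function(course, a, b) {
  stopifnot(b >= a)
  total <- course$B * (b - a)
  # logistic rise piece
  lo <- a; hi <- min(b, course$t_pk)
  if (hi > lo) {
    total <- total + (course$P / course$c0) * course$s *
      (.softplus((hi - course$m) / course$s) -
         .softplus((lo - course$m) / course$s))
  }
  # exponential decay piece
  lo <- max(a, course$t_pk)
  if (b > lo) {
    total <- total + course$P * course$tau *
      (exp(-(lo - course$t_pk) / course$tau) -
         exp(-(b - course$t_pk) / course$tau))
  }
  total
}

#' Evaluate the latent temperature of a fever course
#'
#' @param course A [fever_course()].
#' @param t Numeric vector of times in hours within the course window.
#' @return Latent (noise-free) temperature in Celsius.
#' @export
course_temp <- function(course, t) {
  stopifnot(inherits(course, "fever_course"))
  v <- .backbone_value(course, t)
  if (nrow(course$doses)) {
    for (i in seq_len(nrow(course$doses))) {
      kn <- .kernel_knots(course$drug_effect[[course$doses$ingredient[i]]])
      v <- v + .pwl_value(kn, t - course$doses$time_h[i])
    }
  }
  v
}

#' Exact integral of the latent temperature
#'
#' Closed-form integral of [course_temp()] over `[a, b]` (softplus terms for
#' the logistic rise, exponentials for the decay, trapezoids for the
#' piecewise-linear drug kernels). Used as the analytic ground truth that
#' the pipeline's trapezoidal AUC estimates are validated against.
#'
#' @param course A [fever_course()].
#' @param a,b Integration limits in hours, `b >= a`.
#' @return Integral in Celsius-hours.
#' @export
course_integral <- function(course, a, b) {
  stopifnot(inherits(course, "fever_course"), b >= a)
  total <- .backbone_integral(course, a, b)
  if (nrow(course$doses)) {
    for (i in seq_len(nrow(course$doses))) {
      kn <- .kernel_knots(course$drug_effect[[course$doses$ingredient[i]]])
      d <- course$doses$time_h[i]
      total <- total + .pwl_integral(kn, a - d, b - d)
    }
  }
  total
}

#' Exact baseline-anchored AUC of the latent course
#'
#' Ground-truth counterpart of [auc_from_baseline()]:
#' `integral of (latent(t0 + u) - latent(t0)) du` over `[0, horizon_h]`, in
#' closed form.
#'
#' @param course A [fever_course()].
#' @param t0 Anchor time in hours (first administration of the case).
#' @param horizon_h Horizon in hours.
#' @return AUC in Celsius-hours.
#' @export
course_auc_true <- function(course, t0, horizon_h) {
  course_integral(course, t0, t0 + horizon_h) -
    horizon_h * course_temp(course, t0)
}
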