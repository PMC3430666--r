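#' Virtual-to-real time scale from MSD slopes
#'
#' The simulation distance unit is 10 microns, so squared displacements are
#' a factor of 100 larger on the real (micron) scale. With observed and
#' simulated MSD slopes `S_R` and `S_V`, the scale factor is
#' `F = S_R / S_V` and real seconds per virtual step is `100 / F`. The
#' factor 100 is `distance_scale^2` and is not independently configurable.
#'
#' @param observed_slope real-cell MSD slope (square microns per second).
#' @param simulated_slope simulated MSD slope (square units per step), at
#'   the matching cell density.
#' @param distance_scale microns per simulation unit (default 10).
#' @return A `time_scale` with `F`, `ratio_TR_per_TV` (seconds of real time
#'   per virtual step) and `distance_scale`.
#' @export
time_scale <- function(observed_slope, simulated_slope,
                       distance_scale = 10) {
  stopifnot(is.numeric(observed_slope), is.numeric(simulated_slope))
  if (observed_slope <= 0 || simulated_slope <= 0)
    stop("MSD slopes must be positive")
  F <- observed_slope / simulated_slope
  structure(list(F = F, ratio_TR_per_TV = distance_scale^2 / F,
                 distance_scale = distance_scale),
            class = "time_scale")
}

#' @export
print.time_scale <- function(x, ...) {
  cat(sprintf(
    "<time_scale> F = %.4g; %.4g s of real time per virtual step (~%d)\n",
    x$F, x$ratio_TR_per_TV, round(x$ratio_TR_per_TV)))
  invisible(x)
}

#' Convert virtual steps to real seconds
#'
#' @param virtual_steps number of simulation steps (non-negative).
#' @param scale a [time_scale()].
#' @return Real time in seconds (`steps * ratio_TR_per_TV`). Divide by 3600
#'   for hours.
#' @export
to_real_time <- function(virtual_steps, scale) {
  stopifnot(inherits(scale, "time_scale"), all(virtual_steps >= 0))
  virtual_steps * scale$ratio_TR_per_TV
}

#' Fit the square-root segregation law
#'
#' Segregation scores grow with run length at an ever-diminishing rate;
#' fitting `S = a * n^b + c` (n in thousands of steps) typically recovers
#' an exponent near 1/2, so the data are also re-fitted as the linear law
#' `S = m * sqrt(n) + k`.
#'
#' @param points data frame with columns `n_ksteps` (thousands of steps,
#'   positive) and `S`; at least 4 points.
#' @return A `sqrt_law_fit` with `a`, `b`, `c` (power fit), `m`, `k`
#'   (linear fit on `sqrt(n)`), and the fitted models.
#' @export
fit_sqrt_law <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("n_ksteps", "S") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("n_ksteps", "S")]), ]
  if (nrow(points) < 4) stop("need at least 4 (n, S) points")
  if (any(points$n_ksteps <= 0)) stop("n_ksteps must be positive")
  if (stats::sd(points$S) == 0)
    stop("degenerate input: S is constant, no power law can be fitted")
  lin <- stats::lm(S ~ sqrt(n_ksteps), data = points)
  m <- unname(stats::coef(lin)[2])
  k <- unname(stats::coef(lin)[1])
  # multi-start Levenberg-Marquardt, keeping the lowest-RSS converged
  # fit: a*n^b + c has near-flat directions (small b trades off against
  # large a and negative c) and a single start can settle in them.
  # Starts sit slightly away from exact solutions: a perfectly fitting
  # start makes the initial gradient QR degenerate.
  fit_try <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(S ~ a * n_ksteps^b + c, data = points,
                        start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) NULL)
  }
  pow <- NULL
  for (b0 in c(0.45, 0.3, 0.6, 0.8)) {
    a0 <- unname(stats::coef(
      stats::lm(I(S - k) ~ 0 + I(n_ksteps^b0), data = points)))
    if (!is.finite(a0) || abs(a0) < 1e-12) a0 <- 1
    cand <- fit_try(list(a = a0, b = b0 + 0.03, c = k + 0.1))
    if (!is.null(cand) &&
        (is.null(pow) || stats::deviance(cand) < stats::deviance(pow)))
      pow <- cand
  }
  if (is.null(pow)) stop("power-law fit failed for all starting values")
  cf <- stats::coef(pow)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), m = m, k = k,
                 power_fit = pow, linear_fit = lin,
                 points = points),
            class = "sqrt_law_fit")
}

#' @export
print.sqrt_law_fit <- function(x, ...) {
  cat(sprintf(
    "<sqrt_law_fit> S = %.4g n^%.3f %+.3g;  sqrt refit S = %.4g sqrt(n) %+.3g\n",
    x$a, x$b, x$c, x$m, x$k))
  invisible(x)
}

#' Extrapolate to full segregation
#'
#' Inverts the linear square-root law `S = m * sqrt(n) + k` at a target
#' score (e.g. the mean score of artificially split populations) to
#' estimate the run length at which full segregation would be attained.
#'
#' @param fit a [fit_sqrt_law()] result (or a list with `m` and `k`).
#' @param S_target target segregation score; must be at least `k`.
#' @return Run length in *steps* (not thousands):
#'   `1000 * ((S_target - k) / m)^2`.
#' @export
extrapolate_full_segregation <- function(fit, S_target) {
  m <- fit$m; k <- fit$k
  stopifnot(is.numeric(m), is.numeric(k))
  if (m <= 0) stop("linear sqrt-law slope must be positive")
  if (S_target < k)
    stop("S_target is below the fit intercept; no crossing exists")
  1000 * ((S_target - k) / m)^2
}

#' Virtual time at which the mean score crosses an observed value
#'
#' Averages replicate scores at each run length and linearly interpolates
#' the mean curve to the observed segregation score, giving the virtual
#' time needed to attain the observed degree of segregation.
#'
#' @param score_series data frame with columns `n_steps` and `S`
#'   (replicates at the same `n_steps` are averaged first).
#' @param S_observed observed segregation score; must lie within the range
#'   of the mean curve.
#' @return Virtual time in steps (linear interpolation between the
#'   bracketing run lengths).
#' @export
crossing_time <- function(score_series, S_observed) {
  score_series <- as.data.frame(score_series)
  stopifnot(all(c("n_steps", "S") %in% names(score_series)))
  mean_s <- stats::aggregate(S ~ n_steps, data = score_series, FUN = mean)
  mean_s <- mean_s[order(mean_s$n_steps), ]
  if (nrow(mean_s) < 2) stop("need mean scores at >= 2 run lengths")
  s <- mean_s$S; n <- mean_s$n_steps
  for (i in seq_len(length(s) - 1)) {
    if ((s[i] - S_observed) * (s[i + 1] - S_observed) <= 0) {
      if (s[i + 1] == s[i]) return(n[i])
      return(n[i] + (S_observed - s[i]) / (s[i + 1] - s[i]) *
               (n[i + 1] - n[i]))
    }
  }
  stop("S_observed = ", S_observed, " is outside the mean score range [",
       min(s), ", ", max(s),
       "]; extend the simulated run-length range to bracket it")
}
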