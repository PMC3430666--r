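#' Peak window for segregation scoring
#'
#' The score sums RDF values over the bins covering
#' `[start, start + width)`. The default window is 20--30 microns as three
#' bins of 10/3 microns: a 10-micron peak width placed just below the
#' 30-micron cell diameter, where adhered cell pairs accumulate. The wider
#' 20--40 micron contact region can be requested with `width = 20`.
#'
#' @param start window start in microns.
#' @param width window width in microns.
#' @param n_bins nominal number of bins in the window (informational; the
#'   binning itself comes from the RDF's `bin_width`).
#' @return A `peak_window` object.
#' @export
peak_window <- function(start = 20, width = 10, n_bins = 3L) {
  stopifnot(start >= 0, width > 0, n_bins >= 1)
  structure(list(start = start, width = width, n_bins = as.integer(n_bins)),
            class = "peak_window")
}

# pairwise distances within one class
pair_dists_within <- function(xy) {
  as.vector(stats::dist(xy))
}

# distances between two classes
pair_dists_between <- function(xy1, xy2) {
  dx <- outer(xy1[, 1], xy2[, 1], "-")
  dy <- outer(xy1[, 2], xy2[, 2], "-")
  as.vector(sqrt(dx * dx + dy * dy))
}

# probability that the distance between two independent uniform points in a
# disc of radius R falls in each bin (disc line-picking density)
csr_bin_probs <- function(bin_edges, field_radius,
                          norm = c("mc", "analytic"), mc_draws = 1e6) {
  norm <- match.arg(norm)
  R <- field_radius
  nb <- length(bin_edges) - 1L
  if (norm == "analytic") {
    pdf <- function(d) {
      x <- pmin(d / (2 * R), 1)
      (4 * d / (pi * R^2)) * (acos(x) - x * sqrt(pmax(0, 1 - x^2)))
    }
    p <- numeric(nb)
    for (i in seq_len(nb)) {
      # fine trapezoid; pdf is smooth on each bin
      g <- seq(bin_edges[i], bin_edges[i + 1], length.out = 65)
      p[i] <- sum(diff(g) * (pdf(g[-1]) + pdf(g[-65])) / 2)
    }
    return(p)
  }
  counts <- numeric(nb)
  left <- mc_draws
  chunk <- 1e6
  while (left > 0) {
    m <- min(chunk, left)
    r1 <- R * sqrt(stats::runif(m)); a1 <- 2 * pi * stats::runif(m)
    r2 <- R * sqrt(stats::runif(m)); a2 <- 2 * pi * stats::runif(m)
    d <- sqrt((r1 * cos(a1) - r2 * cos(a2))^2 +
              (r1 * sin(a1) - r2 * sin(a2))^2)
    idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= nb]
    counts <- counts + tabulate(idx, nbins = nb)
    left <- left - m
  }
  counts / mc_draws
}

#' Pair-class radial distribution functions
#'
#' Histograms of pairwise cell-centre distances for the red-red, green-green
#' and red-green pair classes, each normalised by the complete-spatial-
#' randomness (CSR) expectation for the same pair count in the same circular
#' field, so that an unstructured pattern gives g = 1 in every bin.
#' Multi-frame input averages the normalised curves (used with samples from
#' the trailing frames of a simulation).
#'
#' @param frames a [frame_stack()], a single typed point data frame
#'   (columns `type`, `x_um`, `y_um`), or a `sim_result`.
#' @param field_radius radius of the circular field in microns.
#' @param bin_width histogram bin width in microns (default 10/3, three
#'   bins per 10-micron peak window).
#' @param r_max largest distance binned, microns.
#' @param norm `"mc"` (Monte-Carlo CSR expectation, `mc_factor` times the
#'   largest observed pair count) or `"analytic"` (disc line-picking
#'   density); the two agree within Monte-Carlo error.
#' @param mc_factor Monte-Carlo oversampling factor.
#' @param times for a multi-frame stack, the subset of frame times to
#'   average (default all).
#' @return An `rdf_result` with `bin_edges`, `g_rr`, `g_gg`, `g_rg`,
#'   `n_frames_averaged`, and the CSR bin probabilities used.
#' @export
compute_rdf <- function(frames, field_radius = 500, bin_width = 10 / 3,
                        r_max = 100, norm = c("mc", "analytic"),
                        mc_factor = 200, times = NULL) {
  norm <- match.arg(norm)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (inherits(frames, "sim_result")) frames <- frames$frames
  if (inherits(frames, "frame_stack")) {
    if (is.null(times)) times <- frames$times
    frame_list <- lapply(times, function(t) get_frame(frames, t))
  } else {
    frame_list <- list(as.data.frame(frames))
  }
  bin_edges <- seq(0, r_max, by = bin_width)
  if (bin_edges[length(bin_edges)] < r_max)
    bin_edges <- c(bin_edges, bin_edges[length(bin_edges)] + bin_width)
  nb <- length(bin_edges) - 1L

  n_pairs_of <- function(fr) {
    ty <- canonical_type(fr$type)
    nr <- sum(ty == 1L); ng <- sum(ty == 2L)
    c(rr = nr * (nr - 1) / 2, gg = ng * (ng - 1) / 2, rg = nr * ng)
  }
  npairs_max <- max(vapply(frame_list, function(fr) max(n_pairs_of(fr)),
                           numeric(1)))
  p_bin <- csr_bin_probs(bin_edges, field_radius, norm,
                         mc_draws = max(1e5, mc_factor * npairs_max))

  g_sum <- list(rr = numeric(nb), gg = numeric(nb), rg = numeric(nb))
  for (fr in frame_list) {
    ty <- canonical_type(fr$type)
    xy <- cbind(fr$x_um, fr$y_um)
    xr <- xy[ty == 1L, , drop = FALSE]
    xg <- xy[ty == 2L, , drop = FALSE]
    if (nrow(xr) < 2 || nrow(xg) < 2)
      stop("each cell type needs at least 2 points per frame")
    d <- list(rr = pair_dists_within(xr),
              gg = pair_dists_within(xg),
              rg = pair_dists_between(xr, xg))
    for (cl in names(d)) {
      idx <- findInterval(d[[cl]], bin_edges, rightmost.closed = FALSE)
      idx <- idx[idx >= 1 & idx <= nb]
      cnt <- tabulate(idx, nbins = nb)
      expect <- length(d[[cl]]) * p_bin
      g_sum[[cl]] <- g_sum[[cl]] + ifelse(expect > 0, cnt / expect, 0)
    }
  }
  K <- length(frame_list)
  structure(list(bin_edges = bin_edges,
                 g_rr = g_sum$rr / K, g_gg = g_sum$gg / K,
                 g_rg = g_sum$rg / K,
                 n_frames_averaged = K, field_radius = field_radius,
                 norm = norm, p_bin = p_bin),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf(
    "<rdf_result> %d bins of %.3g um, %d frame(s) averaged, norm = %s\n",
    length(x$bin_edges) - 1L, diff(x$bin_edges[1:2]),
    x$n_frames_averaged, x$norm))
  invisible(x)
}

bins_in_window <- function(rdf, window) {
  centers <- (rdf$bin_edges[-1] + rdf$bin_edges[-length(rdf$bin_edges)]) / 2
  lo <- window$start
  hi <- window$start + window$width
  if (lo < rdf$bin_edges[1] - 1e-9 ||
      hi > rdf$bin_edges[length(rdf$bin_edges)] + 1e-9)
    stop("peak window [", lo, ", ", hi, ") outside the binned range")
  sel <- which(centers >= lo & centers < hi)
  if (length(sel) == 0) stop("peak window covers no bins")
  sel
}

#' Peak area of one pair class
#'
#' Sum of the normalised RDF values over the bins covering the peak window
#' (default: three bins over 20--30 microns). A flat g = 1 curve gives an
#' area equal to the number of covered bins.
#'
#' @param rdf an [compute_rdf()] result.
#' @param window a [peak_window()].
#' @param pair_class `"rr"`, `"gg"` or `"rg"`.
#' @return Numeric peak area.
#' @export
peak_area <- function(rdf, window = peak_window(),
                      pair_class = c("rr", "gg", "rg")) {
  pair_class <- match.arg(pair_class)
  sel <- bins_in_window(rdf, window)
  g <- switch(pair_class, rr = rdf$g_rr, gg = rdf$g_gg, rg = rdf$g_rg)
  sum(g[sel])
}

#' Peak-ratio segregation score
#'
#' `S = (R + G) / B` where `R`, `G` and `B` are the peak areas of the
#' red-red, green-green and red-green RDFs over the peak window. A random
#' mixture scores about 2 (each class near its CSR expectation); segregated
#' patterns score much higher as like-type contacts accumulate and mixed
#' contacts vanish. `B = 0` yields an `UNDEFINED` score (`S = NA`), never
#' infinity.
#'
#' @inheritParams peak_area
#' @return A `score_result` with `S`, the three areas, the window, and an
#'   `undefined` flag.
#' @export
segregation_score <- function(rdf, window = peak_window()) {
  R <- peak_area(rdf, window, "rr")
  G <- peak_area(rdf, window, "gg")
  B <- peak_area(rdf, window, "rg")
  undefined <- B == 0
  structure(list(S = if (undefined) NA_real_ else (R + G) / B,
                 R_area = R, G_area = G, B_area = B,
                 window = window, undefined = undefined),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  if (x$undefined) {
    cat("<score_result> S = UNDEFINED (mixed-pair peak area is 0)\n")
  } else {
    cat(sprintf("<score_result> S = %.3f (R = %.3f, G = %.3f, B = %.3f)\n",
                x$S, x$R_area, x$G_area, x$B_area))
  }
  invisible(x)
}

#' Score a simulation from its trailing frames
#'
#' Averages the normalised RDF curves over `n_samples` equidistant
#' snapshots spanning the final `trailing_steps` steps (defaults: 20
#' samples across the final 1000 steps) before scoring, so that the score
#' is not based on a single time point.
#'
#' @param x a `sim_result` or [frame_stack()].
#' @param window a [peak_window()].
#' @param trailing_steps span of trailing virtual time to sample.
#' @param n_samples number of equidistant frames in that span.
#' @param ... passed to [compute_rdf()] (e.g. `norm`, `bin_width`).
#' @return A `score_result`.
#' @export
score_frames <- function(x, window = peak_window(), trailing_steps = 1000,
                         n_samples = 20, ...) {
  fs <- if (inherits(x, "sim_result")) x$frames else x
  stopifnot(inherits(fs, "frame_stack"))
  t_max <- max(fs$times)
  avail <- fs$times[fs$times >= t_max - trailing_steps]
  if (length(avail) == 0) avail <- t_max
  pick <- unique(avail[round(seq(1, length(avail),
                                 length.out = min(n_samples,
                                                  length(avail))))])
  rdf <- compute_rdf(fs, times = pick, ...)
  segregation_score(rdf, window)
}

#' Mean square displacement and linear fit
#'
#' MSD over all time lags up to `max_lag` frames, averaged over cells and
#' overlapping time origins, with a least-squares linear fit whose slope
#' estimates the diffusion rate (4D for a 2D random walk). Frames must be
#' equally spaced in time. A strongly curved MSD (e.g. ballistic motion,
#' MSD proportional to t^2) sets `nonlinear = TRUE`: the linear fit is then
#' a poor summary.
#'
#' @param fs a [frame_stack()] with cells identified across frames.
#' @param max_lag largest lag, in frames (default: a quarter of the
#'   series).
#' @param fit_range optional `c(min, max)` lag *times* over which to fit.
#' @return An `msd_fit` with `lags` (time units), `msd`, `slope`,
#'   `intercept`, `r_squared` and `nonlinear`.
#' @export
compute_msd <- function(fs, max_lag = NULL, fit_range = NULL) {
  stopifnot(inherits(fs, "frame_stack"))
  K <- length(fs$times)
  if (K < 2) stop("MSD needs at least 2 frames")
  dts <- diff(fs$times)
  if (length(unique(dts)) != 1)
    stop("MSD requires equally spaced frames")
  dt <- dts[1]
  if (is.null(max_lag)) max_lag <- max(1L, floor((K - 1) / 4))
  max_lag <- min(max_lag, K - 1L)
  ids <- sort(unique(fs$data$cell_id))
  n <- length(ids)
  X <- matrix(fs$data$x_um[order(fs$data$t, fs$data$cell_id)], n, K)
  Y <- matrix(fs$data$y_um[order(fs$data$t, fs$data$cell_id)], n, K)
  msd <- numeric(max_lag)
  for (l in seq_len(max_lag)) {
    dx <- X[, (1 + l):K, drop = FALSE] - X[, 1:(K - l), drop = FALSE]
    dy <- Y[, (1 + l):K, drop = FALSE] - Y[, 1:(K - l), drop = FALSE]
    msd[l] <- mean(dx * dx + dy * dy)
  }
  lags <- dt * seq_len(max_lag)
  sel <- if (is.null(fit_range)) seq_along(lags) else
    which(lags >= fit_range[1] & lags <= fit_range[2])
  if (length(sel) < 2) stop("fit_range leaves fewer than 2 lags")
  fit <- stats::lm(msd[sel] ~ lags[sel])
  rss_lin <- sum(stats::residuals(fit)^2)
  nonlinear <- FALSE
  if (length(sel) >= 3) {
    fit2 <- stats::lm(msd[sel] ~ lags[sel] + I(lags[sel]^2))
    rss_q <- sum(stats::residuals(fit2)^2)
    # flagged only when curvature both explains the linear misfit and is a
    # substantial part of the signal (sampling noise in a diffusive MSD
    # can be soaked up by a quadratic without either holding)
    quad <- unname(stats::coef(fit2)[3])
    span <- max(lags[sel]) - min(lags[sel])
    substantial <- is.finite(quad) &&
      abs(quad) * span^2 > 0.5 * abs(stats::coef(fit)[2]) * span
    nonlinear <- rss_lin > 0 && (rss_q < 0.1 * rss_lin) && substantial
  }
  structure(list(lags = lags, msd = msd,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 nonlinear = nonlinear, fit_range = range(lags[sel])),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> slope = %.4g per time unit over %d lags%s\n",
              x$slope, length(x$lags),
              if (x$nonlinear) " [nonlinear: linear fit is poor]" else ""))
  invisible(x)
}

#' Symmetry-split variability of the segregation score
#'
#' Splits the field into left/right and top/bottom halves, maintains cell
#' numbers by reflecting each half across the dividing diameter, and
#' re-scores each mirrored pattern. The spread of the four scores is an
#' empirical error estimate for the score of a single frame. Halves with
#' fewer than two cells of either type are skipped with a warning.
#'
#' @param frame a single typed point data frame (or [frame_stack()]; its
#'   last frame is used).
#' @param window a [peak_window()].
#' @param field_radius field radius in microns.
#' @param ... passed to [compute_rdf()].
#' @return List of `score_result`s named `left`, `right`, `top`, `bottom`
#'   (missing entries skipped), with the score range as attribute
#'   `"range"`.
#' @export
symmetry_split_scores <- function(frame, window = peak_window(),
                                  field_radius = 500, ...) {
  if (inherits(frame, "sim_result")) frame <- frame$frames
  if (inherits(frame, "frame_stack")) frame <- get_frame(frame)
  frame <- as.data.frame(frame)
  halves <- list(
    left = function(df) df[df$x_um <= 0, ],
    right = function(df) df[df$x_um >= 0, ],
    top = function(df) df[df$y_um >= 0, ],
    bottom = function(df) df[df$y_um <= 0, ])
  mirror <- list(
    left = function(df) transform(df, x_um = -x_um),
    right = function(df) transform(df, x_um = -x_um),
    top = function(df) transform(df, y_um = -y_um),
    bottom = function(df) transform(df, y_um = -y_um))
  out <- list()
  for (h in names(halves)) {
    kept <- halves[[h]](frame)
    ty <- canonical_type(kept$type)
    if (sum(ty == 1L) < 2 || sum(ty == 2L) < 2) {
      warning("half '", h, "' has too few cells of one type; skipped")
      next
    }
    full <- rbind(kept, mirror[[h]](kept))
    rdf <- compute_rdf(full, field_radius = field_radius, ...)
    out[[h]] <- segregation_score(rdf, window)
  }
  if (length(out) > 0) {
    s <- vapply(out, function(x) x$S, numeric(1))
    attr(out, "range") <- range(s, na.rm = TRUE)
  }
  out
}

#' Score sensitivity to the peak window
#'
#' Evaluates the segregation score for every combination of window width
#' and start displacement, reporting the grid and its maximum; used to
#' check how sensitive a score is to the exact summation region.
#'
#' @param rdf an [compute_rdf()] result.
#' @param widths vector of window widths (microns).
#' @param displacements vector of start displacements (microns) applied to
#'   `base_start`.
#' @param base_start reference window start (microns).
#' @return Data frame `width`, `displacement`, `S` with attribute `"max"`.
#' @export
window_sensitivity_scan <- function(rdf, widths = 10,
                                    displacements = 0, base_start = 20) {
  stopifnot(length(widths) > 0, length(displacements) > 0)
  grid <- expand.grid(width = widths, displacement = displacements,
                      KEEP.OUT.ATTRS = FALSE)
  grid$S <- vapply(seq_len(nrow(grid)), function(i) {
    w <- peak_window(start = base_start + grid$displacement[i],
                     width = grid$width[i])
    segregation_score(rdf, w)$S
  }, numeric(1))
  attr(grid, "max") <- if (all(is.na(grid$S))) NA_real_ else
    max(grid$S, na.rm = TRUE)
  grid
}
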