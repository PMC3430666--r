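#' Specification of a synthetic labelled point pattern
#'
#' Fixtures emulate digitized two-colour cell-centre fields with controlled
#' segregation structure, so the metrics and calibration layers can be
#' tested without running the simulator: `"csr"` is complete spatial
#' randomness with randomly assigned labels (the unsegregated baseline,
#' score about 2), `"clustered"` places like-labelled Gaussian clusters,
#' and `"split_halves"` is the fully segregated reference (all RED left,
#' all GREEN right).
#'
#' `min_separation` is a hard-core distance; the default for clustered and
#' split patterns is 24 microns, a confluent contact spacing slightly below
#' the 30-micron cell diameter (adhered cells tolerate slight overlap), so
#' that contact pairs fall inside the default 20--30 micron scoring window.
#' Pure CSR uses 0 so that the CSR normalisation tests see ideal CSR.
#'
#' @param n_points number of points (>= 2).
#' @param red_fraction fraction labelled RED (exact counts).
#' @param field_radius field radius in microns.
#' @param pattern `"csr"`, `"clustered"` or `"split_halves"`.
#' @param k_clusters number of clusters for `"clustered"`.
#' @param cluster_sd Gaussian spread of cluster members (microns).
#' @param min_separation hard-core distance in microns (`NULL` = pattern
#'   default: 0 for CSR, 24 otherwise).
#' @param seed RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_points = 500L, red_fraction = 0.5,
                         field_radius = 500,
                         pattern = c("csr", "clustered", "split_halves"),
                         k_clusters = 8L, cluster_sd = 60,
                         min_separation = NULL, seed = 1L) {
  pattern <- match.arg(pattern)
  if (is.null(min_separation))
    min_separation <- if (pattern == "csr") 0 else 24
  stopifnot(n_points >= 2, red_fraction >= 0, red_fraction <= 1,
            field_radius > 0, k_clusters >= 1, cluster_sd > 0,
            min_separation >= 0)
  structure(list(n_points = as.integer(n_points),
                 red_fraction = red_fraction,
                 field_radius = field_radius, pattern = pattern,
                 k_clusters = as.integer(k_clusters),
                 cluster_sd = cluster_sd,
                 min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

runif_disc <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  a <- 2 * pi * stats::runif(n)
  cbind(r * cos(a), r * sin(a))
}

# sequential hard-core sampling with bounded retries
sample_hardcore <- function(n, R, min_sep, propose, max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  total_tries <- max_tries * n
  while (got < n) {
    if (tries >= total_tries)
      stop("hard-core packing infeasible: placed ", got, " of ", n,
           " points with min_separation = ", min_sep)
    p <- propose()
    tries <- tries + 1L
    if (sum(p^2) > R^2) next
    if (min_sep > 0 && got > 0) {
      d2 <- (pts[seq_len(got), 1] - p[1])^2 +
        (pts[seq_len(got), 2] - p[2])^2
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  pts
}

#' Generate a synthetic labelled point pattern
#'
#' Deterministic under the spec's seed. See [fixture_spec()] for the
#' patterns.
#'
#' @param spec a [fixture_spec()].
#' @return Data frame with columns `cell_id`, `type`, `x_um`, `y_um`
#'   (directly consumable by [compute_rdf()] and friends).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_points
  R <- spec$field_radius
  ms <- spec$min_separation
  n_red <- round(spec$red_fraction * n)

  if (spec$pattern == "csr") {
    if (ms == 0) {
      pts <- runif_disc(n, R)
    } else {
      pts <- sample_hardcore(n, R, ms, function() runif_disc(1, R)[1, ])
    }
    type <- rep(2L, n)
    type[sample.int(n, n_red)] <- 1L
  } else if (spec$pattern == "split_halves") {
    prop_left <- function() {
      p <- runif_disc(1, R)[1, ]
      p[1] <- -abs(p[1])
      p
    }
    prop_right <- function() {
      p <- runif_disc(1, R)[1, ]
      p[1] <- abs(p[1])
      p
    }
    red <- sample_hardcore(n_red, R, ms, prop_left)
    # greens also keep distance ms from the reds near the midline
    green <- matrix(NA_real_, n - n_red, 2)
    got <- 0L; tries <- 0L
    while (got < n - n_red) {
      if (tries >= 200L * n)
        stop("hard-core packing infeasible in right half-disc")
      p <- prop_right()
      tries <- tries + 1L
      ok <- TRUE
      if (ms > 0) {
        d2r <- min((red[, 1] - p[1])^2 + (red[, 2] - p[2])^2)
        d2g <- if (got > 0)
          min((green[seq_len(got), 1] - p[1])^2 +
              (green[seq_len(got), 2] - p[2])^2) else Inf
        ok <- min(d2r, d2g) >= ms^2
      }
      if (ok) {
        got <- got + 1L
        green[got, ] <- p
      }
    }
    pts <- rbind(red, green)
    type <- c(rep(1L, n_red), rep(2L, n - n_red))
  } else {  # clustered
    k <- spec$k_clusters
    centres <- sample_hardcore(k, R * 0.8, 2 * spec$cluster_sd,
                               function() runif_disc(1, R * 0.8)[1, ])
    sizes <- rep(n %/% k, k)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    # cluster-level labels, balanced greedily toward the exact red count
    ord <- order(sizes, decreasing = TRUE)
    lab <- integer(k)
    red_left <- n_red; green_left <- n - n_red
    for (ci in ord) {
      if (red_left >= green_left && red_left >= sizes[ci]) {
        lab[ci] <- 1L; red_left <- red_left - sizes[ci]
      } else {
        lab[ci] <- 2L; green_left <- green_left - sizes[ci]
      }
    }
    pts <- matrix(NA_real_, n, 2)
    type <- integer(n)
    row <- 0L
    for (ci in seq_len(k)) {
      got <- 0L; tries <- 0L
      while (got < sizes[ci]) {
        if (tries >= 500L * sizes[ci])
          stop("hard-core packing infeasible in cluster ", ci)
        p <- centres[ci, ] + stats::rnorm(2, 0, spec$cluster_sd)
        tries <- tries + 1L
        if (sum(p^2) > R^2) next
        if (ms > 0 && row + got > 0) {
          prev <- pts[seq_len(row + got), , drop = FALSE]
          if (min((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2) < ms^2)
            next
        }
        got <- got + 1L
        pts[row + got, ] <- p
      }
      type[row + seq_len(sizes[ci])] <- lab[ci]
      row <- row + sizes[ci]
    }
  }
  data.frame(cell_id = seq_len(n), type = type_labels(type),
             x_um = pts[, 1], y_um = pts[, 2])
}

#' Generate independent 2D Gaussian random-walk tracks
#'
#' Ground truth for MSD estimation: each cell takes per-frame steps with
#' independent N(0, `step_sigma`^2) increments on each axis, so the true
#' MSD slope is `2 * step_sigma^2 / dt` (two axes, variance `step_sigma^2`
#' each).
#'
#' @param n_cells number of walkers.
#' @param n_frames number of frames (>= 2).
#' @param step_sigma per-axis, per-frame displacement standard deviation
#'   (microns).
#' @param seed RNG seed.
#' @param dt frame spacing in time units.
#' @return A [frame_stack()]; half the walkers are labelled RED, half
#'   GREEN.
#' @export
generate_walk <- function(n_cells, n_frames, step_sigma, seed = 1L,
                          dt = 1L) {
  stopifnot(n_cells >= 1, n_frames >= 2, step_sigma >= 0)
  set.seed(seed)
  X <- apply(matrix(stats::rnorm(n_cells * (n_frames - 1), 0, step_sigma),
                    n_cells), 1, cumsum)
  Y <- apply(matrix(stats::rnorm(n_cells * (n_frames - 1), 0, step_sigma),
                    n_cells), 1, cumsum)
  # prepend the origin frame; columns are cells after apply()'s transpose
  X <- rbind(0, X)
  Y <- rbind(0, Y)
  type <- rep(c("RED", "GREEN"), length.out = n_cells)
  df <- data.frame(
    t = rep(as.integer(dt) * (seq_len(n_frames) - 1L), each = n_cells),
    cell_id = rep(seq_len(n_cells), n_frames),
    type = rep(type, n_frames),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y)))
  frame_stack(df)
}
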