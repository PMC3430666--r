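# shared fixtures and independent oracles for the test suite

# a small, well-separated population (no initial contacts)
make_state <- function(n = 3, spacing = 10, r_cell = 1.5) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cell_state(cbind(spacing * cos(ang), spacing * sin(ang)),
             rep(c("RED", "GREEN"), length.out = n), r_cell = r_cell)
}

zero_motion <- function() {
  motion_params(sigma_body = 0, sigma_centre = 0, v_edge = 0,
                p_new_edge = 0)
}

# angular order of a cell's ring bodies (cyclic rank vector)
ring_order <- function(state, i) {
  idx <- (i - 1) * 10 + 1:10
  a <- atan2(state$ring[idx, 2] - state$cent[i, 2],
             state$ring[idx, 1] - state$cent[i, 1])
  order(a)
}

cyclic_equal <- function(a, b) {
  n <- length(a)
  any(vapply(seq_len(n) - 1, function(s) {
    all(a == b[(seq_len(n) + s - 1) %% n + 1]) ||
      all(a == rev(b)[(seq_len(n) + s - 1) %% n + 1])
  }, logical(1)))
}

# brute-force 2D random-walk MSD slope oracle: direct cumulative-sum walks
# with per-axis step sd sigma, slope from the same least-squares recipe
oracle_walk_slope <- function(n_walkers, n_steps, sigma, max_lag = 20) {
  msd <- numeric(max_lag)
  X <- apply(matrix(rnorm(n_walkers * n_steps, 0, sigma), n_steps), 2,
             cumsum)
  Y <- apply(matrix(rnorm(n_walkers * n_steps, 0, sigma), n_steps), 2,
             cumsum)
  for (l in seq_len(max_lag)) {
    dx <- X[(1 + l):n_steps, , drop = FALSE] -
      X[1:(n_steps - l), , drop = FALSE]
    dy <- Y[(1 + l):n_steps, , drop = FALSE] -
      Y[1:(n_steps - l), , drop = FALSE]
    msd[l] <- mean(dx^2 + dy^2)
  }
  unname(coef(lm(msd ~ seq_len(max_lag)))[2])
}

# brute-force peak area: direct pair counting, no histogram machinery
oracle_peak_area <- function(frame, pair_class, window, field_radius,
                             bin_width) {
  ty <- ifelse(toupper(frame$type) %in% c("RED", "R"), 1L, 2L)
  xy <- cbind(frame$x_um, frame$y_um)
  dists <- function(A, B = NULL) {
    if (is.null(B)) {
      out <- c()
      for (i in seq_len(nrow(A) - 1))
        for (j in (i + 1):nrow(A))
          out <- c(out, sqrt(sum((A[i, ] - A[j, ])^2)))
      out
    } else {
      out <- c()
      for (i in seq_len(nrow(A)))
        for (j in seq_len(nrow(B)))
          out <- c(out, sqrt(sum((A[i, ] - B[j, ])^2)))
      out
    }
  }
  d <- switch(pair_class,
              rr = dists(xy[ty == 1L, , drop = FALSE]),
              gg = dists(xy[ty == 2L, , drop = FALSE]),
              rg = dists(xy[ty == 1L, , drop = FALSE],
                         xy[ty == 2L, , drop = FALSE]))
  # CSR expectation per bin from the disc line-picking density
  pdf <- function(x) {
    z <- pmin(x / (2 * field_radius), 1)
    (4 * x / (pi * field_radius^2)) *
      (acos(z) - z * sqrt(pmax(0, 1 - z^2)))
  }
  edges <- seq(window$start, window$start + window$width, by = bin_width)
  area <- 0
  for (i in seq_len(length(edges) - 1)) {
    cnt <- sum(d >= edges[i] & d < edges[i + 1])
    p <- integrate(pdf, edges[i], edges[i + 1])$value
    area <- area + cnt / (length(d) * p)
  }
  area
}

# craft an rdf_result with prescribed flat g values (for algebra tests)
flat_rdf <- function(g_rr = 1, g_gg = 1, g_rg = 1, bin_width = 10 / 3,
                     r_max = 100) {
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  structure(list(bin_edges = edges,
                 g_rr = rep(g_rr, nb), g_gg = rep(g_gg, nb),
                 g_rg = rep(g_rg, nb),
                 n_frames_averaged = 1, field_radius = 500,
                 norm = "analytic", p_bin = rep(NA_real_, nb)),
            class = "rdf_result")
}

# artificial hook population for lifetime statistics: n_pairs cells in a
# row, body 1 of cell 2k-1 linked to body 1 of cell 2k
make_linked_state <- function(n_pairs, age = 1L) {
  st <- make_state(2 * n_pairs, spacing = 4 * n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- (2 * k - 2) * 10 + 1
    b <- (2 * k - 1) * 10 + 1
    st$partner[a] <- b
    st$partner[b] <- a
    st$hook_age[a] <- age
    st$hook_age[b] <- age
  }
  st
}

# observed hook lifetimes: repeatedly age/break a linked population until
# all hooks are gone, recording the age at which each disappears
simulate_lifetimes <- function(n_pairs, unhook, seize = Inf,
                               max_steps = 10000) {
  adh <- adhesion_params(unhook = unhook, seize = seize)
  st <- make_linked_state(n_pairs)
  first <- seq(1, by = 20, length.out = n_pairs)  # body 1 of odd cells
  lifetimes <- rep(NA_real_, n_pairs)
  prev_age <- st$hook_age[first]
  for (s in seq_len(max_steps)) {
    st <- break_hooks(st, adh)
    died <- which(is.na(lifetimes) & st$partner[first] == 0)
    lifetimes[died] <- prev_age[died]
    prev_age <- st$hook_age[first]
    if (!anyNA(lifetimes)) break
  }
  lifetimes
}
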