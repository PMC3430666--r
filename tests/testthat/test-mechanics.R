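test_that("zero-noise, zero-drift dynamics are the identity on positions", {
  st <- make_state(3)
  p <- zero_motion()
  set.seed(1)
  st2 <- random_move(st, p)
  st2 <- update_leading_edge(st2, p)
  expect_identical(st2$cent, st$cent)
  expect_identical(st2$ring, st$ring)
  # whole step with every stochastic rate zero
  cfg <- sim_config(n_cells = 3, motion = p,
                    exclusion = exclusion_params(p_repel = 0),
                    adhesion = adhesion_params(p_hook = 0),
                    n_steps = 1)
  st3 <- sim_step(st, cfg)
  expect_equal(st3$cent, st$cent)
  expect_equal(st3$ring, st$ring)
  expect_identical(st3$partner, st$partner)
})

test_that("the shared centre displacement translates all 11 bodies rigidly", {
  st <- make_state(4)
  p <- motion_params(sigma_body = 0, sigma_centre = 0.5)
  set.seed(42)
  st2 <- random_move(st, p)
  for (i in 1:4) {
    d <- st2$cent[i, ] - st$cent[i, ]
    idx <- (i - 1) * 10 + 1:10
    expect_equal(st2$ring[idx, ] - st$ring[idx, ],
                 matrix(d, 10, 2, byrow = TRUE), tolerance = 1e-12)
  }
  # different cells get different displacements
  expect_false(isTRUE(all.equal(st2$cent[1, ] - st$cent[1, ],
                                st2$cent[2, ] - st$cent[2, ])))
})

test_that("centroid MSD of pure Brownian moves matches the closed form and a brute-force oracle", {
  sigma <- 0.1
  n <- 100
  n_steps <- 400
  p <- motion_params(sigma_body = 0, sigma_centre = sigma)
  st <- make_state(n, spacing = 300)
  set.seed(7)
  pos <- array(NA_real_, c(n, 2, n_steps + 1))
  pos[, , 1] <- st$cent
  for (s in seq_len(n_steps)) {
    st <- random_move(st, p)
    pos[, , s + 1] <- st$cent
  }
  df <- data.frame(t = rep(0:n_steps, each = n),
                   cell_id = rep(1:n, n_steps + 1),
                   type = "RED",
                   x_um = as.vector(pos[, 1, ]),
                   y_um = as.vector(pos[, 2, ]))
  fit <- compute_msd(frame_stack(df), max_lag = 20)
  analytic <- 2 * sigma^2  # two axes, variance sigma^2 each, per step
  expect_equal(fit$slope, analytic, tolerance = 0.05)
  oracle <- oracle_walk_slope(n, n_steps, sigma)
  expect_equal(fit$slope, oracle, tolerance = 0.07)
  expect_false(fit$nonlinear)
})

test_that("leading edge is ballistic when persistent and off when v_edge = 0", {
  st <- make_state(1)
  p <- motion_params(sigma_body = 0, sigma_centre = 0, v_edge = 0.2,
                     p_new_edge = 0)
  st$edge[1, ] <- c(0, 1)
  set.seed(3)
  st2 <- st
  for (s in 1:50) st2 <- update_leading_edge(st2, p)
  expect_equal(st2$cent[1, ], st$cent[1, ] + c(0, 50 * 0.2),
               tolerance = 1e-12)
  expect_equal(st2$edge[1, ], c(0, 1))  # direction never resampled
  # v_edge = 0: resampling happens but positions never move
  p0 <- motion_params(sigma_body = 0, sigma_centre = 0, v_edge = 0,
                      p_new_edge = 1)
  st3 <- update_leading_edge(st, p0)
  expect_identical(st3$cent, st$cent)
  expect_false(isTRUE(all.equal(st3$edge, st$edge)))  # resampled
})

test_that("memoryless edge renewal gives diffusive long-time motion", {
  # p_new_edge = 1: displacement each step is v in a fresh uniform
  # direction; MSD slope must match a brute-force simulation of that rule
  v <- 0.3
  n <- 80
  n_steps <- 300
  p <- motion_params(sigma_body = 0, sigma_centre = 0, v_edge = v,
                     p_new_edge = 1)
  st <- make_state(n, spacing = 300)
  set.seed(11)
  pos <- array(NA_real_, c(n, 2, n_steps + 1))
  pos[, , 1] <- st$cent
  for (s in seq_len(n_steps)) {
    st <- update_leading_edge(st, p)
    pos[, , s + 1] <- st$cent
  }
  df <- data.frame(t = rep(0:n_steps, each = n),
                   cell_id = rep(1:n, n_steps + 1), type = "GREEN",
                   x_um = as.vector(pos[, 1, ]),
                   y_um = as.vector(pos[, 2, ]))
  fit <- compute_msd(frame_stack(df), max_lag = 15)
  # brute-force oracle for the same rule
  set.seed(12)
  th <- matrix(runif(n * n_steps, 0, 2 * pi), n_steps)
  X <- apply(v * cos(th), 2, cumsum)
  Y <- apply(v * sin(th), 2, cumsum)
  msd <- sapply(1:15, function(l) {
    mean((X[(1 + l):n_steps, ] - X[1:(n_steps - l), ])^2 +
         (Y[(1 + l):n_steps, ] - Y[1:(n_steps - l), ])^2)
  })
  oracle <- unname(coef(lm(msd ~ seq_len(15)))[2])
  expect_equal(fit$slope, oracle, tolerance = 0.1)
  expect_equal(fit$slope, v^2, tolerance = 0.1)  # closed form
})

test_that("constraint relaxation restores perturbed rings and fixes regular ones", {
  p <- motion_params()
  st <- make_state(1)
  # a regular decagon of radius r_cell is an exact fixed point
  st2 <- enforce_constraints(st, p)
  expect_identical(st2$ring, st$ring)
  expect_identical(st2$cent, st$cent)
  # one body displaced outward by 0.5 units
  st3 <- st
  dir <- (st3$ring[1, ] - st3$cent[1, ]) / p$r_cell
  st3$ring[1, ] <- st3$ring[1, ] + 0.5 * dir
  st3 <- enforce_constraints(st3, p)
  d <- sqrt(rowSums((st3$ring[1:10, ] -
                       matrix(st3$cent[1, ], 10, 2, byrow = TRUE))^2))
  expect_true(all(abs(d - p$r_cell) <= p$tol * p$r_cell))
  # whole ring scaled by 2 contracts back
  st4 <- st
  st4$ring <- 2 * (st4$ring -
                     st4$cent[rep(1, 10), , drop = FALSE]) +
    st4$cent[rep(1, 10), , drop = FALSE]
  st4 <- enforce_constraints(st4, p)
  d4 <- sqrt(rowSums((st4$ring[1:10, ] -
                        matrix(st4$cent[1, ], 10, 2, byrow = TRUE))^2))
  expect_true(all(abs(d4 - p$r_cell) <= p$tol * p$r_cell))
  expect_true(cyclic_equal(ring_order(st4, 1), ring_order(st, 1)))
})

test_that("volume exclusion displaces overlapping pairs by the closed form", {
  p <- motion_params()
  depth <- 0.8
  mk <- function() {
    cell_state(rbind(c(0, 0), c(2 * p$r_cell - depth, 0)),
               c("RED", "GREEN"))
  }
  # p_repel = 1: separation grows by exactly 2 * k_repel * depth
  st <- mk()
  st2 <- apply_exclusion(st, exclusion_params(p_repel = 1, k_repel = 0.5),
                         p)
  sep0 <- 2 * p$r_cell - depth
  sep2 <- st2$cent[2, 1] - st2$cent[1, 1]
  expect_equal(sep2, sep0 + 2 * 0.5 * depth, tolerance = 1e-12)
  expect_equal(st2$cent[1, 2], 0)
  # p_repel = 0: untouched regardless of overlap
  st3 <- apply_exclusion(mk(), exclusion_params(p_repel = 0), p)
  expect_identical(st3$cent, mk()$cent)
  # non-overlapping pair never displaced even with p_repel = 1
  far <- cell_state(rbind(c(0, 0), c(10, 0)), c("RED", "GREEN"))
  st4 <- apply_exclusion(far, exclusion_params(p_repel = 1), p)
  expect_identical(st4$cent, far$cent)
})

test_that("field confinement projects outside centroids and is idempotent", {
  p <- motion_params()
  inside <- make_state(2, spacing = 10)
  expect_identical(confine_to_field(inside, p)$cent, inside$cent)
  out <- cell_state(rbind(c(p$R_field + 1, 0), c(0, -p$R_field - 7)),
                    c("RED", "GREEN"))
  out2 <- confine_to_field(out, p)
  expect_true(all(sqrt(rowSums(out2$cent^2)) <= p$R_field + 1e-9))
  # ring follows rigidly
  expect_equal(out2$ring[1:10, ] - matrix(out2$cent[1, ], 10, 2,
                                          byrow = TRUE),
               out$ring[1:10, ] - matrix(out$cent[1, ], 10, 2,
                                         byrow = TRUE),
               tolerance = 1e-12)
  out3 <- confine_to_field(out2, p)
  expect_equal(out3$cent, out2$cent, tolerance = 1e-12)
})

test_that("stepping commutes with a rigid translation of the whole field", {
  # p_repel = 1 so the exclusion stage consumes no RNG; small shift keeps
  # every cell well inside the field in both frames
  # well-separated cells: no pair sits near a contact threshold whose
  # floating-point comparison could flip between the two frames
  cfg <- sim_config(n_cells = 6, n_steps = 5,
                    exclusion = exclusion_params(p_repel = 1),
                    seed = 5)
  st <- make_state(6, spacing = 8)
  shift <- c(4, -2)
  shifted <- st
  shifted$cent <- sweep(shifted$cent, 2, shift, "+")
  shifted$ring <- sweep(shifted$ring, 2, shift, "+")
  set.seed(123)
  a <- st
  for (s in 1:5) a <- sim_step(a, cfg)
  set.seed(123)
  b <- shifted
  for (s in 1:5) b <- sim_step(b, cfg)
  expect_equal(sweep(a$cent, 2, shift, "+"), b$cent, tolerance = 1e-8)
  expect_equal(sweep(a$ring, 2, shift, "+"), b$ring, tolerance = 1e-8)
  expect_identical(a$partner, b$partner)
})

test_that("ring topology and the field bound survive a long default run", {
  cfg <- sim_config(n_cells = 40, n_steps = 2000, snapshot_every = 2000,
                    seed = 8)
  res <- sim_run(cfg)
  st <- res$state
  p <- cfg$motion
  ref <- ring_order(make_state(1), 1)
  for (i in seq_len(40)) {
    expect_true(cyclic_equal(ring_order(st, i), ref))
  }
  r_body <- sqrt(rowSums(st$ring^2))
  expect_true(all(r_body <= p$R_field + p$r_cell * (1 + p$tol) + 1e-6))
  expect_true(all(sqrt(rowSums(st$cent^2)) <= p$R_field + 1e-9))
})
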