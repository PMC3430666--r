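test_that("CSR input is normalised to g ~ 1 in every pair class", {
  # weight bins by their CSR expectation: the bin-mean of g is then the
  # total observed / total expected pair count (unweighted means are
  # dominated by near-empty short-r bins). A single field fluctuates a
  # few percent; averaging fields beats the fluctuation down.
  fx <- generate_fixture(fixture_spec(500, seed = 5))
  rdf <- compute_rdf(fx, norm = "analytic")
  for (g in list(rdf$g_rr, rdf$g_gg, rdf$g_rg)) {
    expect_equal(weighted.mean(g, rdf$p_bin), 1, tolerance = 0.08)
    expect_true(all(g >= 0))
  }
  stack <- frame_stack(do.call(rbind, lapply(1:6, function(k) {
    cbind(t = k, generate_fixture(fixture_spec(500, seed = 100 + k)))
  })))
  rdf6 <- compute_rdf(stack, norm = "analytic")
  expect_identical(rdf6$n_frames_averaged, 6L)
  for (g in list(rdf6$g_rr, rdf6$g_gg, rdf6$g_rg)) {
    expect_equal(weighted.mean(g, rdf6$p_bin), 1, tolerance = 0.03)
  }
  # Monte-Carlo and analytic CSR expectations agree
  set.seed(6)
  rdf_mc <- compute_rdf(fx, norm = "mc", mc_factor = 50)
  expect_equal(rdf_mc$p_bin, rdf$p_bin, tolerance = 0.05)
  expect_equal(mean(rdf_mc$g_rg), 1, tolerance = 0.05)
})

test_that("two tight well-separated like-type clusters show the expected RDF signature", {
  set.seed(8)
  red <- cbind(rnorm(40, -200, 8), rnorm(40, 0, 8))
  green <- cbind(rnorm(40, 200, 8), rnorm(40, 0, 8))
  fx <- data.frame(type = rep(c("RED", "GREEN"), each = 40),
                   x_um = c(red[, 1], green[, 1]),
                   y_um = c(red[, 2], green[, 2]))
  rdf <- compute_rdf(fx, norm = "analytic")
  short <- rdf$bin_edges[-1] <= 30
  expect_gt(max(rdf$g_rr[short]), 10)
  expect_gt(max(rdf$g_gg[short]), 10)
  expect_equal(max(rdf$g_rg[short]), 0)
})

test_that("peak areas agree exactly with a brute-force pairwise count", {
  set.seed(12)
  fx <- generate_fixture(fixture_spec(40, pattern = "clustered",
                                      k_clusters = 4, seed = 12))
  rdf <- compute_rdf(fx, norm = "analytic")
  w <- peak_window()
  for (cl in c("rr", "gg", "rg")) {
    expect_equal(peak_area(rdf, w, cl),
                 oracle_peak_area(fx, cl, w, 500, 10 / 3),
                 tolerance = 1e-6)
  }
  # window geometry
  flat <- flat_rdf()
  expect_equal(peak_area(flat, peak_window(20, 10), "rr"), 3)
  expect_equal(peak_area(flat, peak_window(20, 20), "rr"), 6)
  expect_equal(peak_area(flat_rdf(g_rr = 0), peak_window(), "rr"), 0)
  expect_error(peak_area(flat, peak_window(95, 20), "rr"), "outside")
})

test_that("score algebra: equal areas give 2, empty mixed peak is UNDEFINED", {
  sc <- segregation_score(flat_rdf(3, 3, 3))
  expect_equal(sc$S, 2)
  sc2 <- segregation_score(flat_rdf(5, 3, 2))
  expect_equal(sc2$S, (sc2$R_area + sc2$G_area) / sc2$B_area)
  sc3 <- segregation_score(flat_rdf(3, 3, 0))
  expect_true(sc3$undefined)
  expect_true(is.na(sc3$S))
})

test_that("the score is invariant under rigid motions and label swap", {
  fx <- generate_fixture(fixture_spec(300, pattern = "clustered",
                                      seed = 33))
  w <- peak_window()
  s0 <- segregation_score(compute_rdf(fx, norm = "analytic"), w)$S
  # rotation about the field centre
  th <- 0.83
  rot <- fx
  rot$x_um <- cos(th) * fx$x_um - sin(th) * fx$y_um
  rot$y_um <- sin(th) * fx$x_um + cos(th) * fx$y_um
  expect_equal(segregation_score(compute_rdf(rot, norm = "analytic"),
                                 w)$S, s0, tolerance = 1e-9)
  # reflection
  refl <- fx
  refl$x_um <- -fx$x_um
  expect_equal(segregation_score(compute_rdf(refl, norm = "analytic"),
                                 w)$S, s0, tolerance = 1e-9)
  # RED <-> GREEN swap
  sw <- fx
  sw$type <- ifelse(fx$type == "RED", "GREEN", "RED")
  expect_equal(segregation_score(compute_rdf(sw, norm = "analytic"),
                                 w)$S, s0, tolerance = 1e-9)
})

test_that("MSD estimation: stationary, diffusive and ballistic regimes", {
  # stationary cells
  still <- generate_walk(20, 50, step_sigma = 0, seed = 2)
  fit0 <- compute_msd(still)
  expect_equal(fit0$slope, 0)
  # 2D random walk: slope 2 sigma^2 / dt
  walk <- generate_walk(300, 300, step_sigma = 0.5, seed = 3)
  fit <- compute_msd(walk, max_lag = 20)
  expect_equal(fit$slope, 2 * 0.5^2, tolerance = 0.05)
  expect_false(fit$nonlinear)
  # ballistic motion: quadratic MSD flagged as a poor linear fit
  v <- 2
  df <- data.frame(t = rep(0:60, each = 10),
                   cell_id = rep(1:10, 61), type = "RED",
                   x_um = rep(0:60, each = 10) * v,
                   y_um = rep(seq_len(10), 61))
  fitb <- compute_msd(frame_stack(df), max_lag = 30)
  expect_true(fitb$nonlinear)
  expect_equal(fitb$msd[10], (v * 10)^2, tolerance = 1e-9)
  expect_error(compute_msd(frame_stack(df[df$t == 0, ])), "2 frames")
})

test_that("symmetry splits reproduce the full-field score for mirror-symmetric input", {
  set.seed(44)
  quad <- data.frame(x = runif(60, 5, 480), y = runif(60, 5, 480))
  keep <- quad$x^2 + quad$y^2 < 490^2
  quad <- quad[keep, ]
  ty <- rep(c("RED", "GREEN"), length.out = nrow(quad))
  fx <- data.frame(
    type = rep(ty, 4),
    x_um = c(quad$x, -quad$x, quad$x, -quad$x),
    y_um = c(quad$y, quad$y, -quad$y, -quad$y))
  s_full <- segregation_score(compute_rdf(fx, norm = "analytic"))$S
  sp <- symmetry_split_scores(fx, norm = "analytic")
  expect_identical(sort(names(sp)), sort(c("left", "right", "top",
                                           "bottom")))
  for (h in names(sp)) expect_equal(sp[[h]]$S, s_full, tolerance = 1e-9)
})

test_that("symmetry splits of a CSR field all score near 2", {
  fx <- generate_fixture(fixture_spec(600, seed = 55))
  sp <- symmetry_split_scores(fx, norm = "analytic")
  for (h in names(sp)) {
    expect_gt(sp[[h]]$S, 1.2)
    expect_lt(sp[[h]]$S, 3.2)
  }
})

test_that("window sensitivity scan: defaults, flat curves, max property", {
  fx <- generate_fixture(fixture_spec(300, pattern = "clustered",
                                      seed = 66))
  rdf <- compute_rdf(fx, norm = "analytic")
  s_def <- segregation_score(rdf)$S
  one <- window_sensitivity_scan(rdf, widths = 10, displacements = 0)
  expect_equal(one$S, s_def)
  grid <- window_sensitivity_scan(rdf, widths = c(10, 20),
                                  displacements = c(-10, 0, 10))
  expect_identical(nrow(grid), 6L)
  expect_gte(attr(grid, "max"), s_def)
  flat <- flat_rdf()
  g2 <- window_sensitivity_scan(flat, widths = c(10, 20),
                                displacements = c(0, 10))
  expect_true(all(abs(g2$S - 2) < 1e-12))
})

test_that("like-type peak height falls with cell density at fixed adhesion", {
  # long enough that the sparse field has had time to aggregate
  heights <- sapply(c(100, 400, 800), function(n) {
    cfg <- sim_config(n_cells = n, n_steps = 8000, snapshot_every = 100,
                      seed = 90 + n)
    res <- sim_run(cfg)
    rdf <- compute_rdf(res$frames, norm = "analytic",
                       times = res$frames$times[
                         res$frames$times >= 7000])
    w <- which(rdf$bin_edges[-1] > 20 & rdf$bin_edges[-1] <= 32)
    max((rdf$g_rr[w] + rdf$g_gg[w]) / 2)
  })
  expect_gt(heights[1], heights[2])
  expect_gt(heights[2], heights[3])
})

test_that("trailing-frame averaging uses at most the requested samples", {
  cfg <- sim_config(n_cells = 80, n_steps = 1000, snapshot_every = 50,
                    seed = 10)
  res <- sim_run(cfg)
  sc <- score_frames(res, n_samples = 5, norm = "analytic")
  expect_s3_class(sc, "score_result")
  expect_true(is.finite(sc$S) || sc$undefined)
})
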