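#' Maximum number of hexagonally close-packed cells in the field
#'
#' For cells of radius `r` hexagonally (cubic) close packed, each cell
#' occupies a hexagon of area `2 * r^2 * sqrt(3)`, so a circular field of
#' radius `R` holds at most `floor(pi * R^2 / (2 * r^2 * sqrt(3)))` cells.
#' With the default geometry (`R` = 500 microns, `r` = 15 microns) this is
#' 1007 cells.
#'
#' @param R_field field radius.
#' @param r_cell cell radius (same length unit as `R_field`).
#' @return Integer maximum cell count.
#' @export
max_packed_cells <- function(R_field, r_cell) {
  stopifnot(is.numeric(R_field), is.numeric(r_cell),
            R_field > 0, r_cell > 0, r_cell < R_field)
  as.integer(floor(pi * R_field^2 / (2 * r_cell^2 * sqrt(3))))
}

# hexagonal lattice sites (spacing 2 r_cell) whose centres fall in the field
hex_sites <- function(R_field, r_cell) {
  dy <- sqrt(3) * r_cell
  kmax <- ceiling(R_field / dy)
  xs <- NULL; ys <- NULL
  for (k in -kmax:kmax) {
    y <- k * dy
    off <- if (k %% 2 == 0) 0 else r_cell
    x <- seq(-R_field - 2 * r_cell, R_field + 2 * r_cell, by = 2 * r_cell) +
      off
    keep <- x^2 + y^2 <= R_field^2
    xs <- c(xs, x[keep]); ys <- c(ys, rep(y, sum(keep)))
  }
  cbind(xs, ys)
}

#' Simulation configuration
#'
#' Bundles the population setup, motion/exclusion/adhesion parameters and
#' run control for [sim_run()].
#'
#' @param n_cells total number of cells; must not exceed
#'   [max_packed_cells()] for the field geometry.
#' @param red_fraction fraction of RED cells (exact count
#'   `round(red_fraction * n_cells)`).
#' @param motion a [motion_params()].
#' @param exclusion an [exclusion_params()].
#' @param adhesion an [adhesion_params()].
#' @param n_steps number of simulation steps.
#' @param snapshot_every snapshot interval in steps.
#' @param seed RNG seed for the run.
#' @param init_mode `"random_mix"` (random placement, random labels) or
#'   `"split_halves"` (RED left half-disc, GREEN right half-disc).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 500L, red_fraction = 0.5,
                       motion = motion_params(),
                       exclusion = exclusion_params(),
                       adhesion = adhesion_params(),
                       n_steps = 10000L, snapshot_every = 100L,
                       seed = 1L,
                       init_mode = c("random_mix", "split_halves")) {
  init_mode <- match.arg(init_mode)
  n_max <- max_packed_cells(motion$R_field, motion$r_cell)
  if (n_cells > n_max)
    stop("n_cells = ", n_cells, " exceeds the packing maximum of ", n_max,
         " cells for this field")
  stopifnot(n_cells >= 1, red_fraction >= 0, red_fraction <= 1,
            n_steps >= 1, snapshot_every >= 1)
  structure(list(n_cells = as.integer(n_cells),
                 red_fraction = red_fraction,
                 motion = motion, exclusion = exclusion,
                 adhesion = adhesion,
                 n_steps = as.integer(n_steps),
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed), init_mode = init_mode),
            class = "sim_config")
}

place_cells <- function(config, sites_pick) {
  jitter_amp <- 0.1 * config$motion$r_cell
  n <- nrow(sites_pick)
  sites_pick[, 1] <- sites_pick[, 1] + runif(n, -jitter_amp, jitter_amp)
  sites_pick[, 2] <- sites_pick[, 2] + runif(n, -jitter_amp, jitter_amp)
  # jitter must not push a centroid outside the field
  r <- sqrt(rowSums(sites_pick^2))
  over <- r > config$motion$R_field
  if (any(over)) {
    f <- config$motion$R_field / r[over]
    sites_pick[over, ] <- sites_pick[over, , drop = FALSE] * f
  }
  sites_pick
}

#' Initialise a random mixture of the two cell types
#'
#' Cells are placed without overlap (jittered random subset of a hexagonal
#' packing of the field) and exactly `round(red_fraction * n_cells)` of them
#' are labelled RED at random.
#'
#' @param config a [sim_config()].
#' @return A [cell_state()].
#' @export
init_random_mix <- function(config) {
  sites <- hex_sites(config$motion$R_field, config$motion$r_cell)
  n <- config$n_cells
  if (n > nrow(sites))
    stop("cannot place ", n, " non-overlapping cells in the field")
  pick <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  cent <- place_cells(config, pick)
  n_red <- round(config$red_fraction * n)
  type <- rep(2L, n)
  type[sample.int(n, n_red)] <- 1L
  cell_state(cent, type, config$motion$r_cell)
}

#' Initialise artificially segregated halves
#'
#' All RED cells are placed in the left half-disc (x <= 0) and all GREEN
#' cells in the right half-disc (x >= 0), each uniformly within its half.
#' This is the full-segregation reference configuration; equilibrating it
#' for ~10,000 steps gives the score level that a complete sort would reach.
#'
#' @param config a [sim_config()].
#' @return A [cell_state()].
#' @export
init_split_halves <- function(config) {
  sites <- hex_sites(config$motion$R_field, config$motion$r_cell)
  n <- config$n_cells
  n_red <- round(config$red_fraction * n)
  n_green <- n - n_red
  left <- which(sites[, 1] <= 0)
  right <- which(sites[, 1] >= 0)
  if (n_red > length(left) || n_green > length(right))
    stop("cannot place ", n_red, " RED / ", n_green,
         " GREEN non-overlapping cells in opposite half-discs")
  pick_r <- left[sample.int(length(left), n_red)]
  pick_g <- setdiff(right, pick_r)
  pick_g <- pick_g[sample.int(length(pick_g), n_green)]
  cent <- rbind(sites[pick_r, , drop = FALSE], sites[pick_g, , drop = FALSE])
  # jitter must not push RED across the midline (and vice versa)
  cent <- place_cells(config, cent)
  cent[seq_len(n_red), 1] <- pmin(cent[seq_len(n_red), 1], 0)
  cent[n_red + seq_len(n_green), 1] <- pmax(cent[n_red + seq_len(n_green), 1], 0)
  cell_state(cent, c(rep(1L, n_red), rep(2L, n_green)),
             config$motion$r_cell)
}

#' Advance the simulation by one step
#'
#' Applies, in order: leading-edge update, random moves, hook pull, ring
#' constraint relaxation, volume exclusion, field confinement, hook
#' breakage, hook formation. Exactly one step of virtual time elapses.
#' Randomness is drawn from R's RNG stream.
#'
#' @param state a [cell_state()].
#' @param config a [sim_config()].
#' @return The updated `cell_state`.
#' @export
sim_step <- function(state, config) {
  res <- cpp_run(state, config$motion, config$exclusion, config$adhesion,
                 1L, 1L, 0L)
  state$cent <- res$cent; state$ring <- res$ring; state$edge <- res$edge
  state$partner <- res$partner; state$hook_age <- res$age
  state
}

#' Run a simulation
#'
#' Seeds the RNG from `config$seed`, builds the initial configuration, runs
#' `n_steps` steps and collects centroid snapshots every `snapshot_every`
#' steps (including the initial state). Fixed seed implies a bitwise
#' reproducible trajectory.
#'
#' @param config a [sim_config()].
#' @param state optional pre-built [cell_state()]; when supplied the RNG is
#'   still seeded from `config$seed` but initialisation is skipped.
#' @param quiet suppress the progress message.
#' @return A `sim_result`: list with `frames` (a [frame_stack()] in
#'   microns), the final `state`, the `config`, and `n_nonconverged`, the
#'   total count of cell-steps that did not reach constraint tolerance.
#' @export
sim_run <- function(config, state = NULL, quiet = TRUE) {
  set.seed(config$seed)
  if (is.null(state)) {
    state <- switch(config$init_mode,
                    random_mix = init_random_mix(config),
                    split_halves = init_split_halves(config))
  }
  t_start <- Sys.time()
  res <- cpp_run(state, config$motion, config$exclusion, config$adhesion,
                 config$n_steps, config$snapshot_every, 0L)
  state$cent <- res$cent; state$ring <- res$ring; state$edge <- res$edge
  state$partner <- res$partner; state$hook_age <- res$age
  frames <- snaps_to_frame_stack(res$snaps, res$snap_times, state$type,
                                 units_per_um = 0.1)
  if (!quiet)
    message(sprintf("adhesim: %d cells x %d steps in %.1fs (%d hooks at end)",
                    nrow(state$cent), config$n_steps,
                    as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                    n_hooks(state)))
  structure(list(frames = frames, state = state, config = config,
                 n_nonconverged = res$n_nonconverged),
            class = "sim_result")
}

# snaps: n x 2 x K array in simulation units -> frame_stack in microns
snaps_to_frame_stack <- function(snaps, snap_times, type,
                                 units_per_um = 0.1) {
  n <- dim(snaps)[1]; K <- dim(snaps)[3]
  df <- data.frame(
    t = rep(as.integer(snap_times), each = n),
    cell_id = rep(seq_len(n), K),
    type = rep(type_labels(type), K),
    x_um = as.vector(snaps[, 1, ]) / units_per_um,
    y_um = as.vector(snaps[, 2, ]) / units_per_um)
  frame_stack(df)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d cells, %d steps, %d frames\n",
              nrow(x$state$cent), x$config$n_steps, length(x$frames$times)))
  invisible(x)
}
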