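#' Brownian body and centre moves
#'
#' Displaces every ring body by an independent isotropic Gaussian vector of
#' scale `sigma_body` plus one shared centre displacement of scale
#' `sigma_centre`; the centroid receives the shared displacement. With both
#' scales zero this is the identity. Uses R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param state a [cell_state()].
#' @param params a [motion_params()].
#' @return The displaced `cell_state`.
#' @export
random_move <- function(state, params = motion_params()) {
  res <- cpp_random_move(state$ring, state$cent,
                         params$sigma_body, params$sigma_centre)
  state$ring <- res$ring
  state$cent <- res$cent
  state
}

#' Persistent leading-edge drift
#'
#' With probability `p_new_edge` a cell's edge direction is resampled
#' uniformly on the circle; the cell (centroid and ring rigidly) then drifts
#' by `v_edge` along the current direction. This models an actin-based
#' leading edge that persists until a new edge emerges in a random
#' direction; persistence times are geometric with mean `1/p_new_edge`.
#'
#' @inheritParams random_move
#' @return The updated `cell_state`.
#' @export
update_leading_edge <- function(state, params = motion_params()) {
  res <- cpp_update_edge(state$ring, state$cent, state$edge,
                         params$v_edge, params$p_new_edge)
  state$ring <- res$ring
  state$cent <- res$cent
  state$edge <- res$edge
  state
}

#' Restore ring geometry by iterative relaxation
#'
#' Position-based relaxation drives every centroid-to-body distance toward
#' `r_cell` and every neighbouring body pair toward the regular-decagon
#' chord, preserving angular order. Corrections are split equally between
#' body and centroid, so forces applied to bodies (e.g. hook pulls) drag the
#' whole cell. Convergence is declared when all radial errors are within
#' `tol * r_cell`; cells still unconverged after `max_iter` sweeps are left
#' as-is with a warning.
#'
#' @inheritParams random_move
#' @return The relaxed `cell_state`.
#' @export
enforce_constraints <- function(state, params = motion_params()) {
  res <- cpp_enforce_constraints(state$ring, state$cent,
                                 params$r_cell, params$tol, params$max_iter)
  if (res$n_nonconverged > 0)
    warning(res$n_nonconverged,
            " cell(s) did not reach constraint tolerance; positions kept")
  state$ring <- res$ring
  state$cent <- res$cent
  state
}

#' Stochastic volume exclusion
#'
#' Each cell pair with centroid separation below one cell diameter
#' (`2 * r_cell`) is, with probability `p_repel`, pushed apart along the
#' centroid axis: each cell moves `k_repel` times the overlap depth, so the
#' separation grows by `2 * k_repel * depth`. With probability
#' `1 - p_repel` the overlap is tolerated this step.
#'
#' @inheritParams random_move
#' @param excl an [exclusion_params()].
#' @return The updated `cell_state`.
#' @export
apply_exclusion <- function(state, excl = exclusion_params(),
                            params = motion_params()) {
  res <- cpp_apply_exclusion(state$ring, state$cent, params$r_cell,
                             excl$p_repel, excl$k_repel, params$R_field)
  state$ring <- res$ring
  state$cent <- res$cent
  state
}

#' Confine cells to the circular field
#'
#' Any centroid outside radius `R_field` is radially projected back onto the
#' boundary; the ring follows rigidly. Idempotent.
#'
#' @inheritParams random_move
#' @return The confined `cell_state`.
#' @export
confine_to_field <- function(state, params = motion_params()) {
  res <- cpp_confine(state$ring, state$cent, params$R_field)
  state$ring <- res$ring
  state$cent <- res$cent
  state
}
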