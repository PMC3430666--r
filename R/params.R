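#' Motion parameters for the ring-of-bodies cell model
#'
#' Distances are in simulation units (1 unit = 10 microns). Each step, every
#' ring body receives an independent isotropic Gaussian displacement of scale
#' `sigma_body` plus one shared centre displacement of scale `sigma_centre`
#' (also applied to the centroid); a persistent leading edge drifts the whole
#' cell by `v_edge` along its current direction, resampled each step with
#' probability `p_new_edge` (geometric persistence time `1/p_new_edge`).
#'
#' The default magnitudes were calibrated once, jointly with the adhesion
#' kinetics, so that the stickiness transition of the two-population model
#' sits near `unhook = 0.002` with an optimum around `1e-4`--`1e-5`, and so
#' that score growth at optimal stickiness follows the square-root law over
#' 1e4--2e5 steps at 500 cells/field; see the package vignette. Motion is
#' dominated by the Brownian centre moves: a strong persistent edge makes
#' cluster coarsening ballistic (score linear in time) rather than
#' diffusive.
#'
#' @param sigma_body per-step random displacement scale of ring bodies
#'   (units).
#' @param sigma_centre per-step scale of the shared centre displacement
#'   (units).
#' @param v_edge leading-edge drift per step (units).
#' @param p_new_edge per-step probability that a new random edge direction
#'   replaces the current one.
#' @param r_cell cell radius (units); 1.5 units = 15 microns.
#' @param R_field field radius (units); 50 units = 500 microns.
#' @param tol ring-constraint tolerance as a fraction of `r_cell`.
#' @param max_iter maximum relaxation iterations per cell per step.
#' @return A `motion_params` list.
#' @export
motion_params <- function(sigma_body = 0.015, sigma_centre = 0.055,
                          v_edge = 0.003, p_new_edge = 0.02,
                          r_cell = 1.5, R_field = 50,
                          tol = 0.05, max_iter = 10L) {
  stopifnot(sigma_body >= 0, sigma_centre >= 0, v_edge >= 0,
            p_new_edge >= 0, p_new_edge <= 1,
            r_cell > 0, R_field > 0, r_cell < R_field,
            tol > 0, max_iter >= 1)
  structure(list(sigma_body = sigma_body, sigma_centre = sigma_centre,
                 v_edge = v_edge, p_new_edge = p_new_edge,
                 r_cell = r_cell, R_field = R_field,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "motion_params")
}

#' Stochastic volume-exclusion parameters
#'
#' Overlap is tested on centroid separation against one cell diameter
#' (`2 * r_cell`). Each overlapping pair is pushed apart with probability
#' `p_repel` per step, each cell moving `k_repel` times the overlap depth
#' along the centroid axis; otherwise the overlap is tolerated this step,
#' mimicking real cells that often remain in close contact without either
#' adhering or repelling. `mode = "enhanced"` is the increased-repulsion
#' variant (`p_repel = 1`).
#'
#' @param p_repel per-step repulsion probability for an overlapping pair.
#' @param k_repel displacement fraction of the overlap depth per cell.
#' @param mode `"basic"` or `"enhanced"`; presets `p_repel` when it is not
#'   supplied.
#' @return An `exclusion_params` list.
#' @export
exclusion_params <- function(p_repel = NULL, k_repel = 0.5,
                             mode = c("basic", "enhanced")) {
  mode <- match.arg(mode)
  if (is.null(p_repel)) p_repel <- if (mode == "enhanced") 1.0 else 0.25
  stopifnot(p_repel >= 0, p_repel <= 1, k_repel >= 0)
  structure(list(p_repel = p_repel, k_repel = k_repel, mode = mode),
            class = "exclusion_params")
}

#' Adhesion (hook) parameters
#'
#' Boundary bodies of different cells within `hook_range` can cross-link
#' ("hook"); a hook then breaks each step with probability
#' [effective_unhook()]`(unhook, age, seize)`. `seize = Inf` disables
#' time-dependent strengthening, recovering a geometric hook lifetime with
#' mean `1/unhook`. With `like_type_only = TRUE` (the two-population
#' differential-adhesion experiment) only cells of equal type can link.
#'
#' @param unhook per-step breakage probability in `[0, 1]`; 0 means permanent
#'   links, 1 immediate breakage.
#' @param seize Gaussian width, in steps, of the strengthening decay of
#'   `unhook` with link age; `Inf` disables strengthening. The string
#'   `"inf"` is accepted in YAML configs.
#' @param hook_range capture distance between bodies (units).
#' @param p_hook per-step formation probability for an eligible pair. The
#'   default is deliberately small: it is the rebinding friction that makes
#'   `unhook` effective (with instant rebinding a broken link re-forms
#'   before the pair can diffuse apart, and stickiness would not matter).
#'   It was calibrated together with the motion scales; see the vignette.
#' @param like_type_only logical; restrict links to like-type cells.
#' @param k_hook pull fraction applied to a linked pair's excess separation.
#' @param hook_rest separation below which a link exerts no pull (units).
#' @return An `adhesion_params` list.
#' @export
adhesion_params <- function(unhook = 5e-5, seize = Inf, hook_range = 0.3,
                            p_hook = 0.005, like_type_only = TRUE,
                            k_hook = 0.1, hook_rest = 0.1) {
  if (identical(seize, "inf") || identical(seize, "Inf")) seize <- Inf
  stopifnot(is.numeric(unhook), unhook >= 0, unhook <= 1,
            is.numeric(seize), seize > 0,
            hook_range > 0, p_hook >= 0, p_hook <= 1,
            is.logical(like_type_only),
            k_hook >= 0, k_hook <= 1, hook_rest >= 0)
  structure(list(unhook = unhook, seize = seize, hook_range = hook_range,
                 p_hook = p_hook, like_type_only = like_type_only,
                 k_hook = k_hook, hook_rest = hook_rest),
            class = "adhesion_params")
}
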