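#' Age-dependent effective breakage probability
#'
#' Adhesion strengthening with contact time: the per-step breakage
#' probability of a link of age `t` steps is the Gaussian decay
#' `P' = P * exp(-t^2 / (2 s^2))`, which starts at the nominal `unhook`
#' value `P` when the link forms and falls towards zero (a permanent link);
#' after about 4--5 `s` steps the link is effectively permanent
#' (`P'(4s) = P * exp(-8)`, about `3.35e-4 * P`). `s = Inf` disables
#' strengthening so that `P' = P` at every age.
#'
#' @param P nominal per-step breakage probability (`unhook`).
#' @param t link age in steps (non-negative; vectorised).
#' @param s Gaussian width in steps (`seize`); `Inf` disables.
#' @return `P * exp(-t^2 / (2 s^2))`, same length as `t`.
#' @export
effective_unhook <- function(P, t, s) {
  stopifnot(is.numeric(P), P >= 0, P <= 1,
            is.numeric(t), all(t >= 0),
            is.numeric(s), length(s) == 1)
  if (s <= 0) stop("'s' (seize) must be positive (Inf disables)")
  vapply(as.numeric(t), function(ti) cpp_effective_unhook(P, ti, s),
         numeric(1))
}

#' Form hooks between nearby bodies of different cells
#'
#' Every unlinked ring body scans for unlinked bodies of *other* cells
#' within `hook_range` (same-type cells only when `like_type_only`); the
#' nearest eligible body is chosen (ties by lowest owning cell id, then
#' lowest body index) and linked with probability `p_hook`. New hooks have
#' age 1. A body carries at most one hook.
#'
#' @param state a [cell_state()].
#' @param adh an [adhesion_params()].
#' @param params a [motion_params()] (field geometry for the search grid).
#' @return The `cell_state` with updated `partner`/`hook_age`.
#' @export
form_hooks <- function(state, adh = adhesion_params(),
                       params = motion_params()) {
  res <- cpp_form_hooks(state$ring, cell_of_body(state), state$type,
                        state$partner, state$hook_age,
                        adh$hook_range, adh$p_hook, adh$like_type_only,
                        params$R_field + 4 * params$r_cell)
  state$partner <- res$partner
  state$hook_age <- res$age
  state
}

#' Break hooks stochastically and age the survivors
#'
#' Each hook breaks independently with probability
#' [effective_unhook()]`(unhook, age, seize)`; broken hooks reset both
#' bodies' `hook_age` to 0, survivors have their age incremented. With
#' `seize = Inf` hook lifetimes are geometric with mean `1/unhook`.
#'
#' @inheritParams form_hooks
#' @return The `cell_state` with updated `partner`/`hook_age`.
#' @export
break_hooks <- function(state, adh = adhesion_params()) {
  res <- cpp_break_hooks(state$partner, state$hook_age,
                         adh$unhook, adh$seize)
  state$partner <- res$partner
  state$hook_age <- res$age
  state
}

#' Mechanical pull of formed hooks
#'
#' Each linked body pair is pulled toward its midpoint: when separated by
#' more than the rest distance `hook_rest`, each body moves
#' `k_hook / 2` times the excess separation inward. Bodies already in
#' contact are untouched; the centroid is unaffected here and follows via
#' [enforce_constraints()].
#'
#' @inheritParams form_hooks
#' @return The `cell_state` with displaced ring bodies.
#' @export
apply_hook_constraint <- function(state, adh = adhesion_params()) {
  state$ring <- cpp_hook_constraint(state$ring, state$partner,
                                    adh$k_hook, adh$hook_rest)
  state
}
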