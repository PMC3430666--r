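#' Segregation score versus run length
#'
#' Runs replicate simulations and scores the configuration at each
#' requested run length, using the trailing-frame averaging of
#' [score_frames()]. Each replicate is one continuous simulation scored at
#' nested times (replicate `k` is seeded `config$seed + k - 1`);
#' replicates provide the independent repeats.
#'
#' @param run_lengths vector of run lengths in steps (each a multiple of
#'   `snapshot_every`).
#' @param config a [sim_config()]; its `n_steps` is ignored.
#' @param replicates number of independent replicate runs.
#' @param window a [peak_window()].
#' @param ... passed to [compute_rdf()] via [score_frames()].
#' @return Data frame `n_steps`, `n_ksteps`, `replicate`, `S`, `R_area`,
#'   `G_area`, `B_area`.
#' @export
score_vs_runlength <- function(run_lengths, config = sim_config(),
                               replicates = 3, window = peak_window(),
                               ...) {
  run_lengths <- sort(as.integer(run_lengths))
  stopifnot(all(run_lengths >= 1))
  out <- list()
  for (k in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    cfg$n_steps <- max(run_lengths)
    res <- sim_run(cfg)
    fs <- res$frames
    for (L in run_lengths) {
      sub <- frame_stack(fs$data[fs$data$t <= L, ])
      sc <- score_frames(sub, window = window, ...)
      out[[length(out) + 1L]] <- data.frame(
        n_steps = L, n_ksteps = L / 1000, replicate = k,
        S = sc$S, R_area = sc$R_area, G_area = sc$G_area,
        B_area = sc$B_area)
    }
  }
  do.call(rbind, out)
}

#' Stickiness sweep: segregation versus unhook
#'
#' Reproduces the stickiness-transition experiment: for each `unhook`
#' value and run length, replicate simulations are scored, exposing the
#' sharp transition from unsegregated (S about 2) above
#' `unhook ~ 0.002` into segregating behaviour below it, with an optimum
#' near `1e-4`--`1e-5`.
#'
#' @param unhook_values vector of unhook probabilities.
#' @param run_lengths vector of run lengths in steps.
#' @param config base [sim_config()].
#' @param replicates replicate runs per combination.
#' @param ... passed to [score_frames()]/[compute_rdf()].
#' @return Data frame `unhook`, `n_steps`, `replicate`, `S`, ...
#' @export
sweep_unhook <- function(unhook_values, run_lengths,
                         config = sim_config(), replicates = 1, ...) {
  out <- list()
  for (u in unhook_values) {
    cfg <- config
    cfg$adhesion$unhook <- u
    df <- score_vs_runlength(run_lengths, cfg, replicates = replicates,
                             ...)
    df$unhook <- u
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}

#' Density-by-time sweep
#'
#' Scores simulations across cell densities and run lengths (the
#' density/run-time grid experiment): denser fields take longer to attain
#' the same degree of segregation.
#'
#' @param densities vector of cell counts per field.
#' @param run_lengths vector of run lengths in steps.
#' @param config base [sim_config()].
#' @param replicates replicate runs per density.
#' @param ... passed to [score_frames()]/[compute_rdf()].
#' @return Data frame `n_cells`, `n_steps`, `replicate`, `S`, ...
#' @export
sweep_density_time <- function(densities, run_lengths,
                               config = sim_config(), replicates = 1,
                               ...) {
  out <- list()
  for (d in densities) {
    cfg <- config
    cfg$n_cells <- as.integer(d)
    df <- score_vs_runlength(run_lengths, cfg, replicates = replicates,
                             ...)
    df$n_cells <- as.integer(d)
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}
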