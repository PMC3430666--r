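#' Time-ordered stack of typed cell-centre frames
#'
#' The standard container consumed by the metrics layer: a long table with
#' columns `t` (step index), `cell_id`, `type` (`RED`/`GREEN`), `x_um`,
#' `y_um` (microns, origin at the field centre). Single frames (digitized
#' microscopy tables) are stacks with one time.
#'
#' @param data data frame with columns `t`, `cell_id`, `type`, `x_um`,
#'   `y_um`; `t` and `cell_id` are optional for a single frame.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(data) {
  data <- as.data.frame(data)
  if (!"t" %in% names(data)) data$t <- 0L
  if (!"cell_id" %in% names(data)) {
    nt <- table(data$t)
    if (length(unique(nt)) != 1)
      stop("cannot infer cell_id: frames have unequal point counts")
    data$cell_id <- stats::ave(seq_len(nrow(data)), data$t,
                               FUN = seq_along)
  }
  need <- c("t", "cell_id", "type", "x_um", "y_um")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("frame table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data$x_um) || anyNA(data$y_um))
    stop("frame table contains NA coordinates")
  data$type <- type_labels(canonical_type(data$type))
  data <- data[order(data$t, data$cell_id), need]
  rownames(data) <- NULL
  times <- sort(unique(data$t))
  counts <- tapply(data$cell_id, data$t, length)
  if (length(unique(counts)) != 1)
    stop("frames have unequal cell counts")
  structure(list(times = as.integer(times), data = data, units = "um"),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  n <- nrow(x$data) / length(x$times)
  cat(sprintf("<frame_stack> %d frame(s) x %d cells (t = %s..%s)\n",
              length(x$times), n, min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one frame as a typed point table
#'
#' @param fs a [frame_stack()].
#' @param t step index of the frame (default: last frame).
#' @return Data frame with `cell_id`, `type`, `x_um`, `y_um`.
#' @export
get_frame <- function(fs, t = NULL) {
  if (is.null(t)) t <- max(fs$times)
  if (!t %in% fs$times) stop("no frame at t = ", t)
  out <- fs$data[fs$data$t == t, c("cell_id", "type", "x_um", "y_um")]
  rownames(out) <- NULL
  out
}

#' Read a frame table
#'
#' Reads the delimited frame-table dialect (header
#' `t,cell_id,type,x_um,y_um`); files without a `t` column are accepted as
#' single-frame stacks. Type labels `red`/`green`/`R`/`G` in any case are
#' canonicalised to `RED`/`GREEN`. Malformed rows (missing or non-numeric
#' coordinates) raise an error naming the line.
#'
#' @param path file path.
#' @param origin `"centre"` (default) or `"topleft"`; with `"topleft"`,
#'   pixel coordinates are recentred on their bounding-box midpoint after
#'   scaling.
#' @param pixel_um microns per pixel when `origin = "topleft"`.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, origin = c("centre", "topleft"),
                        pixel_um = 1) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  for (col in c("x_um", "y_um")) {
    if (!col %in% names(raw)) stop("missing column '", col, "' in ", path)
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !nzchar(trimws(raw[[col]])))
    if (length(bad) > 0)
      stop("malformed ", col, " at line ", bad[1] + 1L, " of ", path)
    raw[[col]] <- v
  }
  if ("t" %in% names(raw)) raw$t <- as.integer(raw$t)
  if ("cell_id" %in% names(raw)) raw$cell_id <- as.integer(raw$cell_id)
  if (origin == "topleft") {
    raw$x_um <- raw$x_um * pixel_um
    raw$y_um <- raw$y_um * pixel_um
    raw$x_um <- raw$x_um - (min(raw$x_um) + max(raw$x_um)) / 2
    raw$y_um <- -(raw$y_um - (min(raw$y_um) + max(raw$y_um)) / 2)
  }
  frame_stack(raw)
}

#' Write a frame table
#'
#' Full-precision CSV in the `t,cell_id,type,x_um,y_um` dialect;
#' write-then-read round trips are lossless.
#'
#' @param fs a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "frame_stack"))
  df <- fs$data
  df$x_um <- formatC(df$x_um, digits = 17, format = "g")
  df$y_um <- formatC(df$y_um, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_blocks <- c("motion", "exclusion", "adhesion", "engine",
                   "metrics", "calibration")

#' Read a simulation configuration from YAML
#'
#' A single YAML document with optional blocks `motion`, `exclusion`,
#' `adhesion`, `engine`, `metrics`, `calibration`; unknown blocks or keys
#' are rejected. `adhesion$seize` accepts the literal `"inf"`. Values not
#' given fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A [sim_config()]; `metrics`/`calibration` blocks are attached as
#'   attributes of the same names.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), config_blocks)
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  take <- function(block, fn) {
    args <- y[[block]]
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  motion <- take("motion", motion_params)
  excl <- take("exclusion", exclusion_params)
  adh <- take("adhesion", adhesion_params)
  eng <- y[["engine"]]
  if (is.null(eng)) eng <- list()
  eng_ok <- c("n_cells", "red_fraction", "n_steps", "snapshot_every",
              "seed", "init_mode")
  bad <- setdiff(names(eng), eng_ok)
  if (length(bad) > 0)
    stop("unknown key(s) in 'engine': ", paste(bad, collapse = ", "))
  cfg <- do.call(sim_config,
                 c(eng, list(motion = motion, exclusion = excl,
                             adhesion = adh)))
  attr(cfg, "metrics") <- y[["metrics"]]
  attr(cfg, "calibration") <- y[["calibration"]]
  cfg
}

#' Write the fully resolved configuration back to YAML
#'
#' Emitted alongside simulation output for provenance.
#'
#' @param config a [sim_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (identical(v, Inf)) "inf" else v)
  }
  out <- list(
    motion = strip(config$motion),
    exclusion = strip(config$exclusion),
    adhesion = strip(config$adhesion),
    engine = list(n_cells = config$n_cells,
                  red_fraction = config$red_fraction,
                  n_steps = config$n_steps,
                  snapshot_every = config$snapshot_every,
                  seed = config$seed, init_mode = config$init_mode))
  yaml::write_yaml(out, path)
  invisible(path)
}
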