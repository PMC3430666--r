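RING_N <- 10L

#' Build a cell population state
#'
#' A `cell_state` holds the full mechanical state of a population of model
#' cells: centroids, the ten ring bodies per cell (regular decagons at
#' construction), a per-cell leading-edge direction, the cell type labels,
#' and the hook state of every ring body (`partner`, a 1-based global body
#' index or 0 when unlinked, and `hook_age`).
#'
#' Ring bodies are stored cell-major: body `j` of cell `i` is row
#' `(i - 1) * 10 + j` of `$ring`.
#'
#' @param cent numeric n x 2 matrix of centroid positions (simulation
#'   units).
#' @param type character or integer vector of cell types (`"RED"`/`"GREEN"`
#'   or 1/2).
#' @param r_cell cell radius in units.
#' @return A `cell_state` object.
#' @export
cell_state <- function(cent, type, r_cell = 1.5) {
  cent <- as.matrix(cent)
  stopifnot(ncol(cent) == 2, nrow(cent) >= 1, !anyNA(cent))
  n <- nrow(cent)
  type <- canonical_type(type)
  stopifnot(length(type) == n)
  ang <- 2 * pi * (seq_len(RING_N) - 1) / RING_N
  ring <- matrix(0, n * RING_N, 2)
  ring[, 1] <- rep(cent[, 1], each = RING_N) + r_cell * cos(ang)
  ring[, 2] <- rep(cent[, 2], each = RING_N) + r_cell * sin(ang)
  structure(list(cent = unname(cent), ring = ring,
                 edge = matrix(c(rep(1, n), rep(0, n)), n, 2),
                 type = type,
                 partner = integer(n * RING_N),
                 hook_age = integer(n * RING_N)),
            class = "cell_state")
}

# map RED/GREEN (and aliases) to the internal 1/2 coding
canonical_type <- function(type) {
  if (is.numeric(type)) {
    stopifnot(all(type %in% c(1, 2)))
    return(as.integer(type))
  }
  key <- toupper(trimws(as.character(type)))
  map <- c(RED = 1L, R = 1L, GREEN = 2L, G = 2L)
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unknown cell type label(s): ", paste(bad, collapse = ", "))
  }
  out
}

type_labels <- function(type_int) c("RED", "GREEN")[type_int]

#' @export
print.cell_state <- function(x, ...) {
  n <- nrow(x$cent)
  nh <- sum(x$partner > 0) / 2
  cat(sprintf("<cell_state> %d cells (%d RED, %d GREEN), %d hooks\n",
              n, sum(x$type == 1L), sum(x$type == 2L), nh))
  invisible(x)
}

#' Number of hooks currently formed
#'
#' @param state a `cell_state`.
#' @return Integer count of hooks (each link counted once).
#' @export
n_hooks <- function(state) {
  as.integer(sum(state$partner > 0) / 2)
}

#' Table of current hooks
#'
#' @param state a `cell_state`.
#' @return Data frame with global body indices `body_a < body_b`, the owning
#'   cells, and the link `age` in steps.
#' @export
hook_table <- function(state) {
  a <- which(state$partner > 0)
  b <- state$partner[a]
  keep <- a < b
  a <- a[keep]; b <- b[keep]
  data.frame(body_a = a, body_b = b,
             cell_a = (a - 1L) %/% RING_N + 1L,
             cell_b = (b - 1L) %/% RING_N + 1L,
             age = state$hook_age[a])
}

cell_of_body <- function(state) {
  rep(seq_len(nrow(state$cent)), each = RING_N)
}
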