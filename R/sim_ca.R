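# Conway-style cellular automaton on a bounded (non-periodic) grid.
#
# Each cell is an agent with state {x, y, c}: fixed integer grid coordinates
# and a binary alive/dead flag.  A live cell survives iff it has two or three
# live Moore neighbors; a dead cell is born iff it has exactly three.  Edge
# cells simply have fewer than eight neighbors (no wrap-around).

#' Create a cellular-automaton grid
#'
#' @param width,height Grid dimensions in cells.
#' @param p_alive Probability that each cell starts alive.
#' @param state Optional explicit binary matrix (`height x width`, entries 0/1);
#'   overrides `p_alive`.
#' @param seed Optional RNG seed for the random initial state.
#' @return An object of class `ca_grid`: a list with the binary `state` matrix
#'   and the cell coordinate table (`x`, `y` are 0-based, row-major by `y`).
#' @export
#' @examples
#' g <- ca_grid(seed = 1)
#' sum(ca_state(g))
ca_grid <- function(width = 14L, height = 14L, p_alive = 0.5,
                    state = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) {
    state <- matrix(as.integer(runif(width * height) < p_alive), height, width)
  } else {
    state <- as.matrix(state)
    if (!all(state %in% c(0, 1))) stop("cell states must be binary (0/1)")
    storage.mode(state) <- "integer"
  }
  if (nrow(state) != height || ncol(state) != width) {
    stop("`state` must be a height x width matrix")
  }
  coords <- expand.grid(x = seq_len(width) - 1L, y = seq_len(height) - 1L)
  structure(list(state = state, width = width, height = height,
                 coords = coords),
            class = "ca_grid")
}

#' @export
print.ca_grid <- function(x, ...) {
  cat(sprintf("<ca_grid %dx%d, %d alive>\n", x$width, x$height, sum(x$state)))
  invisible(x)
}

#' Cell states of a grid
#'
#' @param grid A [ca_grid()].
#' @return Integer vector of cell states in cell-index order (row-major by
#'   `y`, matching `grid$coords`).
#' @export
ca_state <- function(grid) {
  stopifnot(inherits(grid, "ca_grid"))
  # coords enumerate x fastest; state matrix is (y, x) -> transpose flatten
  as.integer(t(grid$state))
}

# Moore-neighborhood live counts via shifted copies (zero padding at edges).
ca_neighbor_counts <- function(state) {
  h <- nrow(state); w <- ncol(state)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- state
  counts <- matrix(0L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    counts <- counts + padded[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  counts
}

#' Advance a cellular-automaton grid one step
#'
#' Applies the two birth/survival rules to every cell simultaneously.  Cell
#' positions never change; only the binary state evolves.
#'
#' @param grid A [ca_grid()].
#' @return The next-step `ca_grid`.
#' @export
#' @examples
#' blinker <- matrix(0L, 5, 5); blinker[2:4, 3] <- 1L
#' g <- ca_grid(5, 5, state = blinker)
#' ca_step(g)$state
ca_step <- function(grid) {
  stopifnot(inherits(grid, "ca_grid"))
  s <- grid$state
  if (!all(s %in% c(0L, 1L))) stop("cell states must be binary (0/1)")
  h <- ca_neighbor_counts(s)
  nxt <- ifelse(s == 1L, as.integer(h == 2L | h == 3L), as.integer(h == 3L))
  grid$state <- matrix(as.integer(nxt), grid$height, grid$width)
  grid
}

#' Ground-truth interaction strength between two cells
#'
#' The cell-state interaction weight is the Moore-neighborhood indicator:
#' 1 when cell `j` lies within Euclidean distance `sqrt(2)` of cell `i`
#' (its at-most-eight adjacent cells), else 0.
#'
#' @param grid A [ca_grid()].
#' @param i,j Cell indices (1-based, row-major by `y`); must differ.
#' @return 0 or 1.
#' @export
ca_interaction <- function(grid, i, j) {
  stopifnot(inherits(grid, "ca_grid"))
  if (i == j) stop("self-interaction is undefined (i must differ from j)")
  dx <- grid$coords$x[i] - grid$coords$x[j]
  dy <- grid$coords$y[i] - grid$coords$y[j]
  as.numeric(dx * dx + dy * dy <= 2)
}

# Full n x n Moore adjacency (zero diagonal), in cell-index order.
ca_interaction_matrix <- function(grid) {
  dx <- outer(grid$coords$x, grid$coords$x, "-")
  dy <- outer(grid$coords$y, grid$coords$y, "-")
  w <- (dx * dx + dy * dy <= 2) * 1
  diag(w) <- 0
  w
}
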