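#' @useDynLib dsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn hash .data %||%
#' @importFrom stats cor quantile sd runif setNames
#' @importFrom utils head tail
NULL

# Cardinal actions and their (row, col) displacements. N decreases row
# (raster layout: row 1 is the top of the map).
ACTIONS <- c("N", "S", "E", "W")
ACTION_DROW <- c(N = -1L, S = 1L, E = 0L, W = 0L)
ACTION_DCOL <- c(N = 0L, S = 0L, E = 1L, W = -1L)

#' Build a discrete 2-D grid-world environment
#'
#' States are the free cells of a `height` x `width` room, indexed in
#' column-major raster order (1-based `(row, col)` coordinates; row 1 is the
#' top). Movements are the four cardinal actions; the default policy used by
#' [random_walk()] is uniform over the actions available at each state.
#' Barriers come in two forms: `blocked` removes cells from the state space,
#' while `walls` are thin barriers between adjacent cells that block the
#' connecting edge but keep both cells as states. Edge walls are what the
#' barrier-context experiments use, so that every context shares an identical
#' state space and positions align across contexts.
#'
#' @param width,height Room dimensions in cells (both >= 2).
#' @param blocked Optional two-column matrix or data frame of `(row, col)`
#'   cells to remove from the state space.
#' @param walls Optional list of edge walls. Each wall is a list with
#'   elements `orientation` (`"v"` blocks movement between columns `at` and
#'   `at + 1`; `"h"` between rows `at` and `at + 1`), `at`, `from`, `to`
#'   (inclusive span along the wall).
#' @return An object of class `grid_env`: free-cell states, adjacency under
#'   the four cardinal actions, and degree (available-action count) per
#'   state. Errors if the free-cell graph is disconnected, naming the
#'   unreachable component.
#' @examples
#' env <- grid_env(5, 5)
#' env$n_states
#' @export
grid_env <- function(width, height, blocked = NULL, walls = NULL) {
  if (width < 2 || height < 2) {
    abort("`width` and `height` must both be at least 2.")
  }
  width <- as.integer(width)
  height <- as.integer(height)

  blocked_mat <- matrix(integer(0), ncol = 2)
  if (!is.null(blocked)) {
    blocked_mat <- as.matrix(as.data.frame(blocked))
    storage.mode(blocked_mat) <- "integer"
    if (ncol(blocked_mat) != 2) abort("`blocked` must have two columns (row, col).")
    out_of_bounds <- blocked_mat[, 1] < 1 | blocked_mat[, 1] > height |
      blocked_mat[, 2] < 1 | blocked_mat[, 2] > width
    if (any(out_of_bounds)) {
      abort(sprintf("blocked cell outside the %dx%d room: (%d, %d)",
                    height, width,
                    blocked_mat[which(out_of_bounds)[1], 1],
                    blocked_mat[which(out_of_bounds)[1], 2]))
    }
  }

  free <- matrix(TRUE, height, width)
  free[blocked_mat] <- FALSE
  n_states <- sum(free)
  if (n_states < 2) abort("fewer than 2 free cells remain.")

  index <- matrix(NA_integer_, height, width)
  index[free] <- seq_len(n_states)
  rc <- which(free, arr.ind = TRUE)
  ord <- order(index[free])
  rows <- rc[ord, 1]
  cols <- rc[ord, 2]

  blocked_edges <- .wall_edges(walls, width, height)

  neighbors <- vector("list", n_states)
  neighbor_actions <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    r <- rows[s]; c <- cols[s]
    nb <- integer(0); ac <- integer(0)
    for (a in seq_along(ACTIONS)) {
      r2 <- r + ACTION_DROW[a]; c2 <- c + ACTION_DCOL[a]
      if (r2 < 1 || r2 > height || c2 < 1 || c2 > width) next
      if (!free[r2, c2]) next
      if (.edge_blocked(blocked_edges, r, c, r2, c2)) next
      nb <- c(nb, index[r2, c2])
      ac <- c(ac, a)
    }
    neighbors[[s]] <- nb
    neighbor_actions[[s]] <- ac
  }

  env <- structure(
    list(width = width, height = height,
         blocked = blocked_mat, walls = walls,
         n_states = n_states,
         rows = rows, cols = cols, index = index,
         neighbors = neighbors, neighbor_actions = neighbor_actions,
         degree = lengths(neighbors)),
    class = "grid_env")
  env$hash <- hash(list(width, height, blocked_mat, blocked_edges))

  comp <- .reachable(env, 1L)
  if (!all(comp)) {
    bad <- which(!comp)
    cells <- paste(sprintf("(%d,%d)", rows[head(bad, 5)], cols[head(bad, 5)]),
                   collapse = ", ")
    abort(sprintf(
      "free-cell graph is disconnected: %d states unreachable from (%d,%d), e.g. %s",
      length(bad), rows[1], cols[1], cells))
  }
  env
}

# Expand wall specs into a set of blocked edges, stored as a character key
# "r1,c1|r2,c2" with both orientations present.
.wall_edges <- function(walls, width, height) {
  if (is.null(walls) || length(walls) == 0) return(character(0))
  keys <- character(0)
  for (wl in walls) {
    orientation <- wl$orientation %||% wl[[1]]
    at <- wl$at; from <- wl$from; to <- wl$to
    if (!orientation %in% c("v", "h")) abort("wall orientation must be \"v\" or \"h\".")
    if (orientation == "v") {
      if (at < 1 || at >= width) abort("vertical wall `at` outside room.")
      if (from < 1 || to > height) abort("wall span outside room.")
      for (r in from:to) {
        keys <- c(keys, sprintf("%d,%d|%d,%d", r, at, r, at + 1L),
                  sprintf("%d,%d|%d,%d", r, at + 1L, r, at))
      }
    } else {
      if (at < 1 || at >= height) abort("horizontal wall `at` outside room.")
      if (from < 1 || to > width) abort("wall span outside room.")
      for (c in from:to) {
        keys <- c(keys, sprintf("%d,%d|%d,%d", at, c, at + 1L, c),
                  sprintf("%d,%d|%d,%d", at + 1L, c, at, c))
      }
    }
  }
  keys
}

.edge_blocked <- function(blocked_edges, r, c, r2, c2) {
  if (length(blocked_edges) == 0) return(FALSE)
  sprintf("%d,%d|%d,%d", r, c, r2, c2) %in% blocked_edges
}

.reachable <- function(env, from) {
  seen <- logical(env$n_states)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(unlist(env$neighbors[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' @export
print.grid_env <- function(x, ...) {
  cat(sprintf("<grid_env> %dx%d room, %d states, %d blocked cells, %d walls\n",
              x$height, x$width, x$n_states, nrow(x$blocked),
              length(x$walls %||% list())))
  invisible(x)
}

#' States of an environment as a tibble
#'
#' @param env A [grid_env()].
#' @return A tibble with columns `state`, `row`, `col`, `degree`.
#' @export
env_states <- function(env) {
  tibble::tibble(state = seq_len(env$n_states), row = env$rows,
                 col = env$cols, degree = env$degree)
}

#' Look up the state index at a cell
#'
#' @param env A [grid_env()].
#' @param row,col Cell coordinates (1-based).
#' @return Integer state index (errors on a blocked or out-of-bounds cell).
#' @export
state_at <- function(env, row, col) {
  if (row < 1 || row > env$height || col < 1 || col > env$width) {
    abort("cell outside the room.")
  }
  s <- env$index[row, col]
  if (is.na(s)) abort(sprintf("cell (%d,%d) is blocked.", row, col))
  s
}

#' Generate a random walk under the default policy
#'
#' At each step one of the actions available at the current state is chosen
#' uniformly at random (blocked moves are never attempted), so the stationary
#' state distribution is proportional to the number of available actions.
#'
#' @param env A [grid_env()].
#' @param length Number of states in the trajectory (>= 1).
#' @param start Starting state index, or `"uniform"` to draw one uniformly.
#' @param seed Optional integer seed; when given, the walk is reproducible.
#' @return A `dsi_trajectory`: integer state sequence with the action labels
#'   taken between consecutive states.
#' @export
random_walk <- function(env, length, start = "uniform", seed = NULL) {
  stopifnot(length >= 1)
  run <- function() {
    s0 <- if (identical(start, "uniform")) {
      sample.int(env$n_states, 1)
    } else {
      stopifnot(start >= 1, start <= env$n_states)
      as.integer(start)
    }
    cpp_random_walk(env$neighbors, env$neighbor_actions, as.integer(length), s0)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_trajectory(res$states, actions = ACTIONS[res$actions],
                 n_states = env$n_states, env_hash = env$hash)
}

#' Construct a trajectory object
#'
#' @param states Integer vector of 1-based state indices.
#' @param actions Optional character vector of action labels
#'   (`length(states) - 1`); absent for corpus-derived trajectories.
#' @param breaks 1-based positions where a new segment (document) begins;
#'   discounted counting in [sr_empirical()] never crosses a break.
#' @param n_states Number of states in the generating space.
#' @param env_hash Optional hash of the generating environment.
#' @return A `dsi_trajectory` object.
#' @export
new_trajectory <- function(states, actions = NULL, breaks = 1L,
                           n_states, env_hash = NULL) {
  states <- as.integer(states)
  if (any(states < 1) || any(states > n_states)) {
    abort("state index out of range.")
  }
  if (!is.null(actions) && length(actions) != length(states) - 1) {
    abort("`actions` must have length(states) - 1 entries.")
  }
  structure(list(states = states, actions = actions,
                 breaks = as.integer(breaks), n_states = as.integer(n_states),
                 env_hash = env_hash),
            class = "dsi_trajectory")
}

#' @export
print.dsi_trajectory <- function(x, ...) {
  cat(sprintf("<dsi_trajectory> %d steps over %d states (%d segment%s)\n",
              length(x$states), x$n_states, length(x$breaks),
              if (length(x$breaks) == 1) "" else "s"))
  invisible(x)
}

#' Breadth-first-search distances from one state
#'
#' @param env A [grid_env()].
#' @param s Source state index.
#' @return Integer vector of move counts to every state (`Inf`-free: the
#'   graph is connected by construction).
#' @export
bfs_distances <- function(env, s) {
  d <- rep(NA_integer_, env$n_states)
  d[s] <- 0L
  frontier <- s
  lvl <- 0L
  while (length(frontier) > 0) {
    lvl <- lvl + 1L
    nxt <- unique(unlist(env$neighbors[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- lvl
    frontier <- nxt
  }
  d
}

#' Shortest-path length between two states
#'
#' Breadth-first-search distance in moves; 0 iff `s == g`.
#'
#' @param env A [grid_env()].
#' @param s,g State indices.
#' @return Nonnegative integer.
#' @export
shortest_path_length <- function(env, s, g) {
  stopifnot(s >= 1, s <= env$n_states, g >= 1, g <= env$n_states)
  d <- bfs_distances(env, s)[g]
  if (is.na(d)) abort("states are not connected.")
  d
}

#' Default-policy transition matrix
#'
#' @param env A [grid_env()].
#' @return Row-stochastic `n_states` x `n_states` matrix: uniform over the
#'   actions available at each state.
#' @export
transition_matrix <- function(env) {
  n <- env$n_states
  TM <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nb <- env$neighbors[[s]]
    TM[s, nb] <- 1 / length(nb)
  }
  TM
}

#' Classic four-room environment
#'
#' A square room split into four interconnected rooms by one horizontal and
#' one vertical edge wall, each pierced by two doorways.
#'
#' @param size Side length in cells (default 30).
#' @return A [grid_env()].
#' @export
four_room_env <- function(size = 30) {
  mid <- size %/% 2
  q1 <- max(2, size %/% 4)
  q3 <- min(size - 1, size - size %/% 4)
  walls <- list(
    list(orientation = "v", at = mid, from = 1, to = q1 - 1),
    list(orientation = "v", at = mid, from = q1 + 1, to = q3 - 1),
    list(orientation = "v", at = mid, from = q3 + 1, to = size),
    list(orientation = "h", at = mid, from = 1, to = q1 - 1),
    list(orientation = "h", at = mid, from = q1 + 1, to = q3 - 1),
    list(orientation = "h", at = mid, from = q3 + 1, to = size)
  )
  grid_env(size, size, walls = walls)
}

#' Barrier-context environments for analogical composition
#'
#' Four environments on an identical `size` x `size` footprint: context
#' `phi` (no barriers), `A` (one straight vertical wall segment), `B` (a
#' second, disjoint horizontal wall segment), and `AB` (both). Walls are
#' blocked edges, so all four contexts share the same state space and state
#' indices align position-wise across contexts.
#'
#' @param size Side length in cells (default 30; must be >= 12).
#' @return Named list of [grid_env()] objects `phi`, `A`, `B`, `AB`.
#' @export
barrier_context_envs <- function(size = 30) {
  stopifnot(size >= 12)
  wall_a <- list(orientation = "v", at = size %/% 3,
                 from = size %/% 5 + 1, to = size - size %/% 6)
  wall_b <- list(orientation = "h", at = size - size %/% 3,
                 from = size %/% 2 + 1, to = size)
  list(
    phi = grid_env(size, size),
    A   = grid_env(size, size, walls = list(wall_a)),
    B   = grid_env(size, size, walls = list(wall_b)),
    AB  = grid_env(size, size, walls = list(wall_a, wall_b))
  )
}

#' Start/goal sampling regions for the barrier contexts
#'
#' Start cells lie in the left strip of the room and goal cells in the
#' bottom-right block, so that trajectories between them must negotiate both
#' wall segments of [barrier_context_envs()].
#'
#' @param env A context environment from [barrier_context_envs()].
#' @return List with integer state vectors `start` and `goal`.
#' @export
context_regions <- function(env) {
  size <- env$width
  st <- env_states(env)
  list(
    start = st$state[st$col <= size %/% 4],
    goal  = st$state[st$col >= size - size %/% 4 + 1 &
                     st$row >= size - size %/% 4 + 1]
  )
}
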