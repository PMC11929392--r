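#' Analytic successor representation
#'
#' Closed form of the discounted-occupancy geometric series for a
#' row-stochastic transition matrix T: `(I - gamma * T)^-1`. Row sums equal
#' `1 / (1 - gamma)` exactly. Serves as the oracle for [sr_empirical()].
#'
#' @param transition Row-stochastic square matrix.
#' @param gamma Discount factor in `[0, 1)`.
#' @return An `n x n` SR matrix with attributes `gamma` and
#'   `source = "analytic"`.
#' @export
sr_analytic <- function(transition, gamma) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition))
  if (gamma < 0 || gamma >= 1) abort("`gamma` must be in [0, 1).")
  if (any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("`transition` must be row-stochastic (nonnegative rows summing to 1).")
  }
  n <- nrow(transition)
  M <- solve(diag(n) - gamma * transition)
  structure(M, gamma = gamma, source = "analytic")
}

#' Empirical successor representation from a trajectory
#'
#' Row `s` is the average, over visits of `s`, of the discounted future
#' indicator sum `sum_t gamma^t 1[s_t = s']`, truncated at the end of the
#' trajectory (or of the containing segment for multi-document
#' trajectories). Rows of never-visited states are zero and flagged.
#'
#' @param trajectory A `dsi_trajectory` (see [new_trajectory()]).
#' @param gamma Discount factor in `[0, 1)`.
#' @param n_states Number of states (defaults to the trajectory's).
#' @return SR matrix with attributes `gamma`, `source = "empirical"`,
#'   `visits` (visit counts) and `unvisited` (indices of zero-visit states).
#' @export
sr_empirical <- function(trajectory, gamma, n_states = trajectory$n_states) {
  stopifnot(inherits(trajectory, "dsi_trajectory"), length(trajectory$states) >= 2)
  if (gamma < 0 || gamma >= 1) abort("`gamma` must be in [0, 1).")
  acc <- cpp_sr_accumulate(trajectory$states, trajectory$breaks,
                           as.integer(n_states), gamma)
  visits <- acc$visits
  M <- t(acc$sum_t)
  pos <- visits > 0
  M[pos, ] <- M[pos, , drop = FALSE] / visits[pos]
  structure(M, gamma = gamma, source = "empirical",
            visits = visits, unvisited = which(!pos))
}

#' Empirical one-step transition matrix of a trajectory
#'
#' Row-normalized transition counts (transitions crossing a segment break
#' are not counted). Feeding the result to [sr_analytic()] gives the
#' plug-in (model-based) SR estimator: far more sample-efficient than
#' discounted pair counting when the discount horizon is long relative to
#' the walk, because its error is set by per-state transition counts (see
#' the methods vignette).
#'
#' @param trajectory A `dsi_trajectory`.
#' @param n_states Number of states (defaults to the trajectory's).
#' @return Row-stochastic matrix; rows of never-left states fall back to a
#'   self-loop and are flagged in the `unvisited` attribute.
#' @export
transition_matrix_empirical <- function(trajectory,
                                        n_states = trajectory$n_states) {
  s <- trajectory$states
  from <- s[-length(s)]
  to <- s[-1]
  # drop transitions that span a segment boundary
  if (length(trajectory$breaks) > 1) {
    cut <- trajectory$breaks[-1] - 1L
    keep <- !(seq_along(from) %in% cut)
    from <- from[keep]
    to <- to[keep]
  }
  counts <- tabulate((from - 1L) * n_states + to, nbins = n_states^2)
  TM <- matrix(counts, n_states, n_states, byrow = TRUE)
  rs <- rowSums(TM)
  unvisited <- which(rs == 0)
  TM[unvisited, ] <- 0
  TM[cbind(unvisited, unvisited)] <- 1
  TM[rs > 0, ] <- TM[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(TM, unvisited = unvisited)
}

#' State-occupancy distribution
#'
#' For a trajectory, the empirical visit frequency of each state; for a
#' row-stochastic transition matrix, the stationary distribution (leading
#' left eigenvector, normalized). Zero-visit states are flagged: their
#' self-information is undefined and [compute_psi()] zeroes the affected
#' entries.
#'
#' @param x A `dsi_trajectory` or a row-stochastic matrix.
#' @param n_states Number of states (trajectory input only).
#' @return Probability vector with attribute `zero_states`.
#' @export
occupancy <- function(x, n_states = NULL) {
  if (inherits(x, "dsi_trajectory")) {
    n <- n_states %||% x$n_states
    counts <- tabulate(x$states, nbins = n)
    p <- counts / sum(counts)
  } else if (is.matrix(x)) {
    if (any(abs(rowSums(x) - 1) > 1e-8)) {
      abort("`x` must be row-stochastic when given as a matrix.")
    }
    e <- eigen(t(x))
    i <- which.max(Re(e$values))
    v <- abs(Re(e$vectors[, i]))
    p <- v / sum(v)
  } else {
    abort("`x` must be a dsi_trajectory or a transition matrix.")
  }
  structure(p, zero_states = which(p == 0))
}

#' Positive successor information (PSI)
#'
#' Successor information is `log SR(s, s') - log P(s')` (natural log): the
#' log discounted reachability of `s'` from `s`, normalized by the
#' self-information of `s'`. PSI rectifies it at zero, the analogue of
#' positive pointwise mutual information for word co-occurrence. Entries
#' where `SR = 0` or `P(s') = 0` are set to 0 and counted in the
#' diagnostics attribute.
#'
#' @param sr SR matrix from [sr_analytic()] or [sr_empirical()].
#' @param occupancy Probability vector from [occupancy()].
#' @param epsilon_floor Guard inside the logs; entries at the floor are
#'   rectified to zero by construction. Default `1e-12`.
#' @return Nonnegative `n x n` PSI matrix with attributes `gamma` and
#'   `diagnostics` (counts of zeroed degenerate entries).
#' @export
compute_psi <- function(sr, occupancy, epsilon_floor = 1e-12) {
  stopifnot(is.matrix(sr), length(occupancy) == ncol(sr))
  if (anyNA(sr) || anyNA(occupancy)) abort("NA in inputs.")
  degenerate <- (sr <= 0) | rep(occupancy <= 0, each = nrow(sr))
  si <- log(pmax(sr, epsilon_floor)) -
    rep(log(pmax(occupancy, epsilon_floor)), each = nrow(sr))
  si[degenerate] <- 0
  psi <- pmax(si, 0)
  structure(psi, gamma = attr(sr, "gamma"),
            diagnostics = list(n_degenerate = sum(degenerate)))
}
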