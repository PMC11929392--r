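#' Fit movement-conditional linear maps over embedding vectors
#'
#' For each cardinal action `a`, a `D x D` matrix `M_a` is fitted by
#' ridge-regularized least squares over every legal transition `(s, a, s')`
#' of the environment, minimizing `sum ||x(s') - M_a x(s)||^2`. Applying
#' `M_a` to the current representation predicts the representation after
#' the movement, which is the substrate for path integration.
#'
#' @param embedding A `dsi_embedding`.
#' @param env The generating [grid_env()].
#' @param ridge Ridge penalty for conditioning (default 1e-6).
#' @return A `movement_model`: per-action matrices, per-action RMS fit
#'   residuals, and the reference `X` matrix used for decoding.
#' @export
fit_movement_models <- function(embedding, env, ridge = 1e-6) {
  X <- embedding$X
  stopifnot(nrow(X) == env$n_states)
  D <- ncol(X)
  models <- list()
  residuals <- setNames(numeric(length(ACTIONS)), ACTIONS)
  for (a in seq_along(ACTIONS)) {
    from <- integer(0); to <- integer(0)
    for (s in seq_len(env$n_states)) {
      hit <- which(env$neighbor_actions[[s]] == a)
      if (length(hit) == 1) {
        from <- c(from, s)
        to <- c(to, env$neighbors[[s]][hit])
      }
    }
    if (length(from) == 0) {
      warn(sprintf("action %s has no legal transition; using identity model.",
                   ACTIONS[a]))
      models[[ACTIONS[a]]] <- diag(D)
      residuals[a] <- NA_real_
      next
    }
    Xs <- t(X[from, , drop = FALSE])   # D x n
    Ys <- t(X[to, , drop = FALSE])
    G <- Xs %*% t(Xs) + ridge * diag(D)
    M <- Ys %*% t(Xs) %*% solve(G)
    models[[ACTIONS[a]]] <- M
    residuals[a] <- sqrt(mean((M %*% Xs - Ys)^2))
  }
  structure(list(M = models, residuals = residuals, X_ref = X,
                 env_hash = env$hash),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model> %d actions, D = %d; RMS residuals: %s\n",
              length(x$M), ncol(x$X_ref),
              paste(sprintf("%s %.3g", names(x$residuals), x$residuals),
                    collapse = ", ")))
  invisible(x)
}

# Nearest-state decoder. Ties (within 1e-12 of the maximum) are broken
# uniformly at random through the R RNG.
.decode_state <- function(v, Xn, metric) {
  sims <- if (metric == "cosine") {
    nv <- sqrt(sum(v^2))
    if (nv == 0) rep(0, nrow(Xn)) else (Xn %*% v) / nv
  } else {
    Xn %*% v
  }
  mx <- max(sims)
  cand <- which(sims >= mx - 1e-12)
  if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
}

#' Path integration: decode a trajectory from movements alone
#'
#' Starting from `x(start)`, each action's fitted matrix is applied to the
#' running representation and the nearest state vector (cosine by default)
#' is decoded; with `snap_each_step` the running vector is reset to the
#' decoded state's vector (attractor-style denoising).
#'
#' @param model A [fit_movement_models()] result.
#' @param start Starting state index.
#' @param actions Character vector of action labels to integrate.
#' @param snap_each_step Snap the running vector to the decoded state each
#'   step (default TRUE).
#' @param metric `"cosine"` (default) or `"dot"` decoder similarity.
#' @return Integer vector of decoded states, starting with `start`
#'   (`length(actions) + 1` entries).
#' @export
path_integrate <- function(model, start, actions, snap_each_step = TRUE,
                           metric = c("cosine", "dot")) {
  metric <- match.arg(metric)
  X <- model$X_ref
  stopifnot(start >= 1, start <= nrow(X), all(actions %in% names(model$M)))
  Xn <- if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X / nrm
  } else X
  decoded <- integer(length(actions) + 1)
  decoded[1] <- start
  v <- X[start, ]
  for (i in seq_along(actions)) {
    v <- as.vector(model$M[[actions[i]]] %*% v)
    s_hat <- .decode_state(v, Xn, metric)
    decoded[i + 1] <- s_hat
    if (snap_each_step) v <- X[s_hat, ]
  }
  decoded
}

#' Path-integration success rate over random movement sequences
#'
#' Each trial draws a random start and a random sequence of legal moves;
#' the trial succeeds only if the decoded trajectory matches the true one
#' at every step.
#'
#' @param embedding A `dsi_embedding`.
#' @param env The generating [grid_env()].
#' @param n_trials Number of trials (>= 1).
#' @param n_steps Moves per trial (default 10).
#' @param seed Integer seed.
#' @param model Optional prefitted [fit_movement_models()] result.
#' @param snap_each_step,metric Passed to [path_integrate()].
#' @return One-row tibble: `successes`, `n_trials`, `rate`.
#' @export
path_integration_success_rate <- function(embedding, env, n_trials = 1000,
                                          n_steps = 10, seed = 1,
                                          model = NULL,
                                          snap_each_step = TRUE,
                                          metric = "cosine") {
  stopifnot(n_trials >= 1)
  model <- model %||% fit_movement_models(embedding, env)
  successes <- withr::with_seed(seed, {
    ok <- 0L
    for (trial in seq_len(n_trials)) {
      walk <- random_walk(env, n_steps + 1, start = "uniform")
      decoded <- path_integrate(model, walk$states[1], walk$actions,
                                snap_each_step = snap_each_step,
                                metric = metric)
      if (all(decoded == walk$states)) ok <- ok + 1L
    }
    ok
  })
  tibble::tibble(successes = successes, n_trials = n_trials,
                 rate = successes / n_trials)
}

#' Goal-directed navigation by the embedding value proxy
#'
#' From the current state the agent evaluates `x(s') . w(goal)` for every
#' neighboring state `s'` and moves greedily to the argmax (ties broken
#' uniformly at random), stopping at the goal or after `max_steps` moves.
#' `x . w` approximates the PSI value of `s'` with the goal as target, so
#' greedy ascent approximates value-based decision making.
#'
#' @param embedding A `dsi_embedding`.
#' @param env The [grid_env()] to navigate in (its adjacency is used; it may
#'   differ from the training environment, as in context composition).
#' @param start,goal State indices.
#' @param max_steps Step cap; defaults to 8 x the shortest-path length
#'   (minimum 8).
#' @param seed Optional seed for tie-breaks.
#' @param epsilon Probability of a uniform random move per step (default
#'   0: pure greedy). A small positive value lets the agent escape the
#'   local value-field maxima that an imperfect reconstruction produces
#'   (noise pockets trap a deterministic greedy agent in two-state
#'   cycles).
#' @param values Optional precomputed value matrix `X %*% t(W)` (state x
#'   goal), to amortize over many trials.
#' @return A one-row tibble: `start`, `goal`, `moves`, `shortest`,
#'   `normalized` (moves / shortest; 1 when `start == goal`; computed with
#'   `moves = max_steps` when the goal was not reached), `reached`, and the
#'   visited `path` (list column).
#' @export
navigate <- function(embedding, env, start, goal, max_steps = NULL,
                     seed = NULL, epsilon = 0, values = NULL) {
  stopifnot(start >= 1, start <= env$n_states, goal >= 1, goal <= env$n_states)
  shortest <- shortest_path_length(env, start, goal)
  max_steps <- max_steps %||% max(8L, 8L * shortest)
  vals <- if (is.null(values)) {
    as.vector(embedding$X %*% embedding$W[goal, ])
  } else {
    values[, goal]
  }
  run <- function() {
    path <- integer(max_steps + 1)
    path[1] <- start
    cur <- start
    moves <- 0L
    while (cur != goal && moves < max_steps) {
      nb <- env$neighbors[[cur]]
      if (epsilon > 0 && runif(1) < epsilon) {
        pick <- sample.int(length(nb), 1)
      } else {
        v <- vals[nb]
        mx <- max(v)
        cand <- which(v >= mx - 1e-12)
        pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      }
      cur <- nb[pick]
      moves <- moves + 1L
      path[moves + 1] <- cur
    }
    list(path = path[seq_len(moves + 1)], moves = moves, reached = cur == goal)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  normalized <- if (start == goal) 1 else if (res$reached) {
    res$moves / shortest
  } else {
    max_steps / shortest
  }
  tibble::tibble(start = start, goal = goal, moves = res$moves,
                 shortest = shortest, normalized = normalized,
                 reached = res$reached, path = list(res$path))
}

#' Batch navigation trials with random starts and goals
#'
#' @param embedding A `dsi_embedding`.
#' @param env The [grid_env()] to navigate in.
#' @param n_trials Number of trials.
#' @param seed Integer seed (start/goal sampling and tie-breaks).
#' @param start_cells,goal_cells Optional state index pools to sample from
#'   (defaults: all states; start and goal are forced distinct).
#' @param max_steps_factor Step cap as a multiple of the trial's
#'   shortest-path length (default 8).
#' @param epsilon Random-move probability per step (see [navigate()]).
#' @return A tibble with one row per trial (see [navigate()]), without the
#'   `path` column.
#' @export
navigation_trials <- function(embedding, env, n_trials = 1000, seed = 1,
                              start_cells = NULL, goal_cells = NULL,
                              max_steps_factor = 8, epsilon = 0) {
  start_cells <- start_cells %||% seq_len(env$n_states)
  goal_cells <- goal_cells %||% seq_len(env$n_states)
  values <- embedding$X %*% t(embedding$W)
  withr::with_seed(seed, {
    out <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      repeat {
        s <- start_cells[sample.int(length(start_cells), 1)]
        g <- goal_cells[sample.int(length(goal_cells), 1)]
        if (s != g) break
      }
      shortest <- shortest_path_length(env, s, g)
      tr <- navigate(embedding, env, s, g,
                     max_steps = max(8L, max_steps_factor * shortest),
                     epsilon = epsilon, values = values)
      out[[i]] <- tr[, setdiff(names(tr), "path")]
    }
    dplyr::bind_rows(out)
  })
}
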