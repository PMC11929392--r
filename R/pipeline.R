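#' Train a spatial embedding from a random walk
#'
#' The standard spatial pipeline: generate a random walk under the default
#' policy, estimate the successor representation, compute PSI, and
#' factorize. The SR estimator is the plug-in form by default — the
#' empirical one-step transition matrix pushed through the geometric-series
#' closed form — which at spatial discount rates is far less noisy than
#' direct discounted counting for the same walk (see the methods
#' vignette); `estimator = "count"` selects the direct
#' [sr_empirical()] estimator instead.
#'
#' @param env A [grid_env()].
#' @param config A [dsi_config()].
#' @param gamma Spatial discount rate (default 0.99).
#' @param walk_length Steps in the random walk (default 3e5).
#' @param seed Seed for the walk (defaults to `config$seed`).
#' @param estimator `"transition"` (plug-in, default) or `"count"`.
#' @return A `dsi_embedding`.
#' @export
train_spatial_embedding <- function(env, config = dsi_config(),
                                    gamma = 0.99, walk_length = 3e5,
                                    seed = config$seed,
                                    estimator = c("transition", "count")) {
  estimator <- match.arg(estimator)
  walk <- random_walk(env, walk_length, seed = seed)
  sr <- if (estimator == "transition") {
    sr_analytic(transition_matrix_empirical(walk), gamma)
  } else {
    sr_empirical(walk, gamma)
  }
  psi <- compute_psi(sr, occupancy(walk))
  dsi_factorize(psi, config, init = config$init)
}

#' Train aligned embeddings for the barrier contexts
#'
#' Trains the empty context phi from the seeded random start, then
#' fine-tunes contexts A and B from phi's factors (warm start, fewer
#' iterations). The warm start is what gives unit identities meaning
#' across contexts: unit k of A is the adapted unit k of phi, so
#' per-unit representational distances and the composition
#' `A + B - phi` operate on corresponding units. Training each context
#' from an independent random start would scramble unit correspondence
#' and make composition meaningless.
#'
#' @param envs Named list from [barrier_context_envs()] (`phi`, `A`, `B`).
#' @param config A [dsi_config()] for the phi training.
#' @param gamma,walk_length,seed As in [train_spatial_embedding()].
#' @param finetune_iter Iterations for the A/B fine-tuning (default
#'   `config$n_iter / 3`).
#' @return A [context_set()] with embeddings `A`, `B`, `phi`.
#' @export
train_context_embeddings <- function(envs, config = dsi_config(),
                                     gamma = 0.99, walk_length = 3e5,
                                     seed = config$seed,
                                     finetune_iter = NULL) {
  stopifnot(all(c("phi", "A", "B") %in% names(envs)))
  phi <- train_spatial_embedding(envs$phi, config, gamma = gamma,
                                 walk_length = walk_length, seed = seed)
  ft_cfg <- config
  ft_cfg$n_iter <- as.integer(finetune_iter %||% max(1L, config$n_iter %/% 3L))
  tune <- function(env, seed_off) {
    walk <- random_walk(env, walk_length, seed = seed + seed_off)
    sr <- sr_analytic(transition_matrix_empirical(walk), gamma)
    psi <- compute_psi(sr, occupancy(walk))
    dsi_factorize(psi, ft_cfg, init = phi)
  }
  context_set(A = tune(envs$A, 1L), B = tune(envs$B, 2L), phi = phi)
}
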