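#' Configuration for PSI factorization
#'
#' Settings for the constrained factorization `PSI ~ X W^T`. Two named
#' variants: `"decorr"` (nonnegativity + decorrelation of the columns of X +
#' L2 shrinkage) and `"sparse"` (nonnegativity + L1 sparsity, no
#' decorrelation). `"decorr-nonneg-off"` is the ablation that keeps the
#' decorr objective but drops the nonnegativity projection.
#'
#' The reconstruction term is normalized per state row, the decorrelation
#' term per unit, and the L2/L1 terms are plain norms, so the default
#' weights `beta = 1`, `rho = 0.01` keep the three forces of the decorr
#' objective within one order of magnitude of each other at the random
#' initialization on a 30x30 open-room PSI.
#'
#' @param D Embedding dimensionality (`D < N_s`).
#' @param variant `"decorr"`, `"sparse"` or `"decorr-nonneg-off"`.
#' @param beta Weight of the squared-correlation (decorrelation) term.
#' @param rho Weight of the L2 term (decorr variants).
#' @param rho_l1 Weight of the L1 term (sparse variant).
#' @param learning_rate Step size of the optimizer.
#' @param n_iter Number of gradient iterations.
#' @param optimizer `"gd"` (plain fixed-step projected gradient descent,
#'   default) or `"adam"` (adaptive per-parameter scaling).
#' @param decorr_w Also apply the decorrelation force to the goal matrix
#'   `W` (default FALSE: the constraint acts on the state vectors, and the
#'   goal vectors are shaped by reconstruction and shrinkage alone).
#' @param nonneg Enforce nonnegativity by clipping at 0 after each step.
#'   Defaults to `FALSE` only for the `"decorr-nonneg-off"` variant.
#' @param seed Integer seed for the random initialization.
#' @return A `dsi_config` list.
#' @export
dsi_config <- function(D = 100,
                       variant = c("decorr", "sparse", "decorr-nonneg-off"),
                       beta = 1, rho = 0.01, rho_l1 = 0.005,
                       learning_rate = 0.05, n_iter = 3000,
                       optimizer = c("gd", "adam"),
                       nonneg = NULL, decorr_w = FALSE, seed = 1) {
  variant <- match.arg(variant)
  optimizer <- match.arg(optimizer)
  if (is.null(nonneg)) nonneg <- variant != "decorr-nonneg-off"
  stopifnot(D >= 1, beta >= 0, rho >= 0, rho_l1 >= 0,
            learning_rate > 0, n_iter >= 1)
  structure(list(D = as.integer(D), variant = variant, beta = beta,
                 rho = rho, rho_l1 = rho_l1,
                 learning_rate = learning_rate, n_iter = as.integer(n_iter),
                 optimizer = optimizer, nonneg = nonneg,
                 decorr_w = decorr_w,
                 seed = as.integer(seed)),
            class = "dsi_config")
}

# Decorrelation penalty: raw value sum_{k != l} corr(X_k, X_l)^2 and its
# exact gradient wrt X (chain rule through the column normalization and
# centering). Constant columns carry zero correlation and zero gradient.
# Also returns the off-diagonal correlation matrix for the
# activity-proportional force used during training.
.decorr_term <- function(X, with_grad = TRUE) {
  D <- ncol(X)
  if (D < 2) {
    return(list(value = 0, grad = if (with_grad) X * 0, R = NULL))
  }
  U <- sweep(X, 2, colMeans(X))
  s <- sqrt(colSums(U^2))
  ok <- s > 1e-12
  V <- U
  V[, ok] <- sweep(U[, ok, drop = FALSE], 2, s[ok], "/")
  V[, !ok] <- 0
  R <- crossprod(V)
  diag(R) <- 0
  value <- sum(R^2)
  grad <- NULL
  if (with_grad) {
    GV <- 4 * (V %*% R)
    proj <- colSums(V * GV)
    GU <- GV - sweep(V, 2, proj, "*")
    GU[, ok] <- sweep(GU[, ok, drop = FALSE], 2, s[ok], "/")
    GU[, !ok] <- 0
    grad <- sweep(GU, 2, colMeans(GU))
  }
  list(value = value, grad = grad, R = R)
}

#' Factorization objective with per-term breakdown
#'
#' For the decorr variants:
#' `sum((PSI - X W^T)^2) / (2 N_s) +
#'  beta / (2 D) * sum_{k != l} corr(X_k, X_l)^2 +
#'  rho / 2 * (||X||_F^2 + ||W||_F^2)`;
#' the sparse variant drops the decorrelation term and replaces the L2 term
#' by `rho_l1 * (sum(|X|) + sum(|W|))`. Gradients are the exact analytic
#' derivatives of these terms (verified against finite differences in the
#' test suite).
#'
#' @param X,W Factor matrices (`N_s x D`).
#' @param psi Nonnegative target matrix (`N_s x N_s`).
#' @param config A [dsi_config()].
#' @param gradients Also return analytic gradients wrt `X` and `W`.
#' @return List with `total`, `terms` (named numeric: `recon` plus
#'   `decorr`/`l2` or `l1`), and when requested `grad_X`, `grad_W`.
#' @export
dsi_objective <- function(X, W, psi, config, gradients = FALSE) {
  if (anyNA(X) || anyNA(W) || anyNA(psi)) abort("NA in inputs.")
  stopifnot(nrow(X) == nrow(psi), nrow(W) == ncol(psi), ncol(X) == ncol(W))
  n <- nrow(psi)
  D <- ncol(X)
  E <- X %*% t(W) - psi
  recon <- sum(E^2) / (2 * n)
  terms <- c(recon = recon)
  gX <- gW <- NULL
  if (gradients) {
    gX <- (E %*% W) / n
    gW <- (t(E) %*% X) / n
  }
  if (config$variant %in% c("decorr", "decorr-nonneg-off")) {
    dec <- .decorr_term(X, with_grad = gradients)
    terms <- c(terms,
               decorr = config$beta / (2 * D) * dec$value,
               l2 = config$rho / 2 * (sum(X^2) + sum(W^2)))
    if (gradients) {
      gX <- gX + config$beta / (2 * D) * dec$grad + config$rho * X
      gW <- gW + config$rho * W
    }
  } else {
    terms <- c(terms, l1 = config$rho_l1 * (sum(abs(X)) + sum(abs(W))))
    if (gradients) {
      gX <- gX + config$rho_l1 * sign(X)
      gW <- gW + config$rho_l1 * sign(W)
    }
  }
  out <- list(total = sum(terms), terms = terms)
  if (gradients) {
    out$grad_X <- gX
    out$grad_W <- gW
  }
  out
}

#' Factorize a PSI matrix into nonnegative state and goal vectors
#'
#' Plain projected gradient descent (clipping at zero after each step when
#' the nonnegativity flag is set) from a seeded random nonnegative
#' initialization. Columns of `X` are state-vector units `x(s)`; columns of
#' `W` are goal-vector units `w(s)`, with `x(s) . w(s') ~ PSI(s, s')`.
#'
#' The decorrelation constraint is applied as its activity-proportional
#' (lateral-inhibition) force `(beta / D) X R`, where `R` is the
#' off-diagonal inter-unit correlation matrix: the exact penalty gradient
#' with the per-unit normalization factors dropped. This is the form in
#' which decorrelation is implemented in neural-network models of grid
#' formation; it drives correlations to zero without vanishing for
#' strongly active units, which matters for the emergence of periodic
#' tuning (see the methods vignette). [dsi_objective()] carries the exact
#' analytic gradient of the written penalty for verification purposes.
#'
#' A column that collapses to all zeros during training is reinitialized
#' once (dead-unit rescue); training errors out if the loss exceeds ten
#' times its initial value (advice: lower the learning rate).
#'
#' @param psi Nonnegative square matrix (typically from [compute_psi()]).
#' @param config A [dsi_config()]; `config$D < nrow(psi)` is required.
#' @param labels Optional state labels (character) for the rows of `X`/`W`.
#' @param init Optional warm start: a `dsi_embedding` (or list with `X`,
#'   `W`) whose factors seed the optimization instead of the random init.
#'   Used for fine-tuning across barrier contexts, where unit identities
#'   must correspond position-wise between contexts.
#' @return A `dsi_embedding`: matrices `X` and `W`, the variant, the config
#'   snapshot, the training-loss trace, and the dead-unit reinit count.
#' @export
dsi_factorize <- function(psi, config = dsi_config(), labels = NULL,
                          init = NULL) {
  stopifnot(is.matrix(psi), nrow(psi) == ncol(psi))
  if (any(psi < 0)) abort("`psi` must be nonnegative.")
  if (anyNA(psi)) abort("NA in `psi`.")
  n <- nrow(psi)
  D <- config$D
  if (D >= n) abort("`config$D` must be smaller than the number of states.")
  decorr <- config$variant %in% c("decorr", "decorr-nonneg-off")

  sigma <- sqrt(max(mean(psi), 1e-8) / D)
  if (!is.null(init)) {
    stopifnot(all(dim(init$X) == c(n, D)), all(dim(init$W) == c(n, D)))
    X <- unname(init$X)
    W <- unname(init$W)
  } else if (config$nonneg) {
    start <- withr::with_seed(config$seed, list(
      X = matrix(abs(rnorm(n * D, sd = sigma)), n, D),
      W = matrix(abs(rnorm(n * D, sd = sigma)), n, D)
    ))
    X <- start$X
    W <- start$W
  } else {
    # unconstrained ablation: start from signed noise
    start <- withr::with_seed(config$seed + 1L, list(
      X = matrix(rnorm(n * D, sd = sigma), n, D),
      W = matrix(rnorm(n * D, sd = sigma), n, D)
    ))
    X <- start$X
    W <- start$W
  }

  lr <- config$learning_rate
  adam <- config$optimizer == "adam"
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (adam) {
    mX <- vX <- X * 0
    mW <- vW <- W * 0
  }

  loss_trace <- numeric(config$n_iter)
  initial_loss <- NULL
  check_every <- max(10L, config$n_iter %/% 10L)
  reinit_done <- logical(D)
  n_reinit <- 0L
  psi_sq <- sum(psi^2)

  for (it in seq_len(config$n_iter)) {
    # residual gradients without forming the N_s x N_s residual:
    # E W = psi W - X (W'W), E'X = psi'X - W (X'X)
    PW <- psi %*% W
    PtX <- crossprod(psi, X)
    WtW <- crossprod(W)
    XtX <- crossprod(X)
    loss <- (psi_sq - 2 * sum(X * PW) + sum(XtX * WtW)) / (2 * n)
    gX <- (PW - X %*% WtW) / n
    gW <- (PtX - W %*% XtX) / n
    if (decorr) {
      dec <- .decorr_term(X, with_grad = FALSE)
      loss <- loss + config$beta / (2 * D) * dec$value +
        config$rho / 2 * (sum(X^2) + sum(W^2))
      gX <- gX - config$beta / D * (X %*% dec$R) - config$rho * X
      gW <- gW - config$rho * W
      if (config$decorr_w) {
        decw <- .decorr_term(W, with_grad = FALSE)
        gW <- gW - config$beta / D * (W %*% decw$R)
      }
    } else {
      loss <- loss + config$rho_l1 * (sum(abs(X)) + sum(abs(W)))
      gX <- gX - config$rho_l1 * sign(X)
      gW <- gW - config$rho_l1 * sign(W)
    }
    loss_trace[it] <- loss
    if (is.null(initial_loss)) initial_loss <- loss
    if (!is.finite(loss) || loss > 10 * initial_loss) {
      abort("factorization diverged (loss > 10x initial); try a smaller learning rate.")
    }
    if (adam) {
      mX <- b1 * mX + (1 - b1) * gX
      vX <- b2 * vX + (1 - b2) * gX^2
      mW <- b1 * mW + (1 - b1) * gW
      vW <- b2 * vW + (1 - b2) * gW^2
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      X <- X + lr * (mX / corr1) / (sqrt(vX / corr2) + eps)
      W <- W + lr * (mW / corr1) / (sqrt(vW / corr2) + eps)
    } else {
      # per-entry step cap at half the init scale: a trust region that
      # keeps small problems stable without affecting converged regimes
      cap <- 0.5 * sigma
      X <- X + pmin(pmax(lr * gX, -cap), cap)
      W <- W + pmin(pmax(lr * gW, -cap), cap)
    }
    if (config$nonneg) {
      X[X < 0] <- 0
      W[W < 0] <- 0
    }
    if (it %% check_every == 0 && it < config$n_iter) {
      dead <- which(colSums(X) == 0 | colSums(W) == 0)
      dead <- dead[!reinit_done[dead]]
      if (length(dead) > 0) {
        fresh <- withr::with_seed(config$seed + it, {
          list(x = matrix(abs(rnorm(n * length(dead), sd = sigma)), n),
               w = matrix(abs(rnorm(n * length(dead), sd = sigma)), n))
        })
        X[, dead] <- fresh$x
        W[, dead] <- fresh$w
        reinit_done[dead] <- TRUE
        n_reinit <- n_reinit + length(dead)
      }
    }
  }

  labels <- labels %||% as.character(seq_len(n))
  rownames(X) <- rownames(W) <- labels
  structure(list(X = X, W = W, variant = config$variant, config = config,
                 loss_trace = loss_trace, dead_reinits = n_reinit,
                 labels = labels),
            class = "dsi_embedding")
}

#' Construct an embedding from explicit matrices
#'
#' Mostly useful for oracles and analyses: e.g. the identity embedding
#' (`X = W = I`) turns the decoder and movement models into exact one-hot
#' machinery, and `X = PSI`, `W = I` makes the navigation value proxy the
#' exact PSI value.
#'
#' @param X,W Equal-sized numeric matrices (states x units).
#' @param variant Label stored on the object (default `"custom"`).
#' @param labels Optional row labels.
#' @return A `dsi_embedding`.
#' @export
as_dsi_embedding <- function(X, W = X, variant = "custom", labels = NULL) {
  stopifnot(is.matrix(X), is.matrix(W), all(dim(X) == dim(W)))
  labels <- labels %||% rownames(X) %||% as.character(seq_len(nrow(X)))
  rownames(X) <- rownames(W) <- labels
  structure(list(X = X, W = W, variant = variant, config = NULL,
                 loss_trace = numeric(0), dead_reinits = 0L, labels = labels),
            class = "dsi_embedding")
}

#' Reconstruct the PSI approximation from an embedding
#'
#' @param embedding A `dsi_embedding`.
#' @return `X %*% t(W)`.
#' @export
reconstruct <- function(embedding) {
  stopifnot(inherits(embedding, "dsi_embedding"))
  embedding$X %*% t(embedding$W)
}

#' @export
print.dsi_embedding <- function(x, ...) {
  cat(sprintf(
    "<dsi_embedding> %s: %d states x %d units (final loss %.4g, %d dead-unit reinits)\n",
    x$variant, nrow(x$X), ncol(x$X),
    x$loss_trace[length(x$loss_trace)], x$dead_reinits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-unit summary of a fitted embedding
#'
#' @param x A `dsi_embedding`.
#' @param ... Unused.
#' @return A tibble with one row per unit: column norms and maxima of `X`
#'   and `W` and whether the unit is dead (all-zero in either matrix).
#' @export
tidy.dsi_embedding <- function(x, ...) {
  tibble::tibble(
    unit = seq_len(ncol(x$X)),
    x_norm = sqrt(colSums(x$X^2)),
    w_norm = sqrt(colSums(x$W^2)),
    x_max = apply(x$X, 2, max),
    dead = colSums(x$X) == 0 | colSums(x$W) == 0
  )
}

#' One-row summary of a fitted embedding
#'
#' @param x A `dsi_embedding`.
#' @param ... Unused.
#' @return A tibble with the variant, sizes, final loss and reconstruction
#'   error statistics.
#' @export
glance.dsi_embedding <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_states = nrow(x$X),
    D = ncol(x$X),
    iterations = length(x$loss_trace),
    final_loss = x$loss_trace[length(x$loss_trace)],
    dead_reinits = x$dead_reinits
  )
}

#' Training-loss trace plot
#'
#' @param embedding A `dsi_embedding`.
#' @return A ggplot object.
#' @export
plot_loss <- function(embedding) {
  df <- tibble::tibble(iteration = seq_along(embedding$loss_trace),
                       loss = embedding$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "objective") +
    ggplot2::theme_minimal()
}
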