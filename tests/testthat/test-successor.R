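swap_chain <- matrix(c(0, 1, 1, 0), 2, 2)

test_that("analytic SR matches the brute-force geometric series", {
  # partial sums of gamma^t T^t as the independent oracle
  brute <- function(T, gamma, tmax = 60) {
    acc <- diag(nrow(T)); Tp <- diag(nrow(T))
    for (t in seq_len(tmax)) {
      Tp <- Tp %*% T
      acc <- acc + gamma^t * Tp
    }
    acc
  }
  sa <- sr_analytic(swap_chain, 0.5)
  expect_equal(unclass(sa), brute(swap_chain, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sa[1, 1], 4 / 3, tolerance = 1e-12)
  expect_equal(sa[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(rowSums(sa), c(2, 2), tolerance = 1e-12)  # 1 / (1 - gamma)

  # gamma -> 0 limit is the identity
  expect_equal(unclass(sr_analytic(swap_chain, 0)), diag(2),
               ignore_attr = TRUE)

  expect_error(sr_analytic(matrix(c(0.5, 0.2, 0.5, 0.2), 2, 2), 0.5),
               "stochastic")
})

test_that("empirical SR converges to the analytic SR", {
  tr <- new_trajectory(rep(c(1L, 2L), 5000), n_states = 2)
  se <- sr_empirical(tr, 0.5)
  sa <- sr_analytic(swap_chain, 0.5)
  expect_lt(max(abs(se - sa)), 1e-2)

  # gamma = 0 degenerate case: identity rows
  s0 <- sr_empirical(tr, 0)
  expect_equal(unclass(s0), diag(2), ignore_attr = TRUE)

  # error shrinks with trajectory length (open room, analytic oracle)
  env <- grid_env(8, 8)
  sa2 <- sr_analytic(transition_matrix(env), 0.95)
  errs <- vapply(c(2e3, 2e4, 2e5), function(len) {
    walk <- random_walk(env, len, seed = 5)
    norm(sr_empirical(walk, 0.95) - sa2, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  expect_error(sr_empirical(new_trajectory(c(1L, 3L), n_states = 2), 0.5))
})

test_that("occupancy matches symmetry, degree weighting and sums to one", {
  tr <- new_trajectory(rep(c(1L, 2L), 500), n_states = 2)
  expect_equal(as.numeric(occupancy(tr)), c(0.5, 0.5))

  env <- grid_env(6, 6)
  p <- occupancy(transition_matrix(env))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # detailed balance: stationary law proportional to available-action count
  expect_equal(as.numeric(p), env$degree / sum(env$degree), tolerance = 1e-9)

  walk <- random_walk(env, 1e4, seed = 3)
  expect_equal(sum(occupancy(walk)), 1, tolerance = 1e-12)
})

test_that("PSI applies the log-ratio and rectification rules", {
  sr <- structure(matrix(c(4 / 3, 0.3, 2 / 3, 0.5), 2, 2), gamma = 0.5)
  p <- c(0.5, 0.5)
  psi <- compute_psi(sr, p)
  expect_equal(psi[1, 1], log(8 / 3), tolerance = 1e-12)
  expect_equal(psi[2, 1], 0)  # log(0.6) < 0 rectified
  expect_true(all(psi >= 0))

  # uniform occupancy and constant-row SR: all SI equal, rectified alike
  srk <- structure(matrix(2, 3, 3), gamma = 0.5)
  psik <- compute_psi(srk, rep(1 / 3, 3))
  expect_true(all(abs(psik - psik[1, 1]) < 1e-12))

  # degenerate entries are zeroed and counted
  sr0 <- structure(matrix(c(1, 0, 1, 2), 2, 2), gamma = 0.5)
  psi0 <- compute_psi(sr0, c(0.5, 0.5))
  expect_equal(psi0[2, 1], 0)
  expect_equal(attr(psi0, "diagnostics")$n_degenerate, 1)
})

test_that("SI matches the joint-probability (PMI-style) series on a reversible chain", {
  # brute-force series: sum_t gamma^t P(s_t = s', s_0 = s) for an unfair
  # 2-state chain, stationary start
  T2 <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  p <- occupancy(T2)
  gamma <- 0.8
  sa <- sr_analytic(T2, gamma)
  si <- log(unclass(sa)) - rep(log(as.numeric(p)), each = 2)

  joint <- matrix(0, 2, 2)
  Tp <- diag(2)
  for (t in 0:200) {
    if (t > 0) Tp <- Tp %*% T2
    joint <- joint + gamma^t * (as.numeric(p) * Tp)
  }
  # log[sum_{t>=1}] - log P(s) - log P(s') differs from SI exactly by the
  # t = 0 term of the series: SR = delta + sum_{t>=1} gamma^t P(.|.)
  joint1 <- joint - diag(as.numeric(p))   # remove the t = 0 term
  rhs <- log(joint1) - rep(log(as.numeric(p)), 2) -
    rep(log(as.numeric(p)), each = 2)
  # off-diagonal entries have no t = 0 term, so the two forms agree exactly
  expect_equal(si[1, 2], rhs[1, 2], tolerance = 1e-10)
  expect_equal(si[2, 1], rhs[2, 1], tolerance = 1e-10)
  # and on the diagonal the two differ by exactly the t = 0 contribution
  expect_equal(exp(si[1, 1]) - exp(rhs[1, 1]), 1 / p[1], tolerance = 1e-8)
})
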