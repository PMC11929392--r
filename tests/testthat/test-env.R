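test_that("open-room adjacency has the expected structure", {
  env <- grid_env(30, 30)
  expect_equal(env$n_states, 900)
  expect_equal(sum(env$degree == 2), 4)           # corners
  expect_equal(sum(env$degree == 3), 4 * 28)      # edges
  expect_equal(sum(env$degree == 4), 28 * 28)     # interior

  env2 <- grid_env(2, 2)
  expect_equal(env2$n_states, 4)
  expect_true(all(env2$degree == 2))
})

test_that("adjacency is symmetric and never crosses barriers", {
  env <- grid_env(8, 8,
                  blocked = cbind(c(3, 4, 5), c(4, 4, 4)),
                  walls = list(list(orientation = "h", at = 6, from = 1, to = 3)))
  for (s in seq_len(env$n_states)) {
    for (t in env$neighbors[[s]]) {
      expect_true(s %in% env$neighbors[[t]])
      # edges connect cells at Manhattan distance 1
      expect_equal(abs(env$rows[s] - env$rows[t]) +
                     abs(env$cols[s] - env$cols[t]), 1)
    }
  }
  # no neighbor is a blocked cell (blocked cells are not states at all)
  expect_false(any(is.na(unlist(env$neighbors))))
  # the horizontal wall blocks the vertical edge at (6,2)-(7,2)
  s <- state_at(env, 6, 2)
  expect_false(state_at(env, 7, 2) %in% env$neighbors[[s]])
})

test_that("disconnected rooms and out-of-bounds barriers are rejected", {
  expect_error(grid_env(5, 5, blocked = cbind(1:5, rep(2, 5))),
               "disconnected")
  expect_error(grid_env(5, 5, blocked = cbind(6, 2)), "outside")
  expect_error(grid_env(5, 5, walls = list(list(orientation = "v", at = 5,
                                                from = 1, to = 5))),
               "outside")
})

test_that("shortest paths match the Manhattan/BFS oracles", {
  env <- grid_env(10, 10)
  s <- state_at(env, 1, 1)
  g <- state_at(env, 4, 5)
  expect_equal(shortest_path_length(env, s, g), 7)
  expect_equal(shortest_path_length(env, s, s), 0)

  # wall with a gap: detour length agrees with an independent flood fill
  env2 <- grid_env(9, 9, blocked = cbind(c(1:7), rep(5, 7)))
  free <- matrix(TRUE, 9, 9); free[cbind(1:7, 5)] <- FALSE
  s2 <- state_at(env2, 2, 2); g2 <- state_at(env2, 2, 8)
  oracle <- flood_fill_distance(free, c(2, 2), c(2, 8))
  expect_equal(shortest_path_length(env2, s2, g2), oracle)
  expect_gt(oracle, 6)   # exceeds Manhattan distance by the detour
})

test_that("shortest-path length is a metric on small rooms", {
  env <- grid_env(5, 4, blocked = cbind(c(2, 3), c(2, 2)))
  n <- env$n_states
  D <- t(vapply(seq_len(n), function(s) bfs_distances(env, s), integer(n)))
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))
  for (k in seq_len(n)) {
    expect_true(all(D <= outer(D[, k], D[k, ], "+")))
  }
})

test_that("random walks are reproducible, legal and follow the default policy", {
  env <- grid_env(2, 2, blocked = cbind(2, 1:2))  # 2-cell corridor
  w <- random_walk(env, 10, start = 1, seed = 1)
  expect_equal(w$states, rep(c(1L, 2L), 5))       # single available action

  env2 <- grid_env(12, 12)
  w1 <- random_walk(env2, 5000, seed = 99)
  w2 <- random_walk(env2, 5000, seed = 99)
  expect_identical(w1$states, w2$states)

  # every step is an edge
  ok <- vapply(seq_len(length(w1$states) - 1), function(t) {
    w1$states[t + 1] %in% env2$neighbors[[w1$states[t]]]
  }, logical(1))
  expect_true(all(ok))

  # action choice at a fixed state is uniform over available actions
  long <- random_walk(env2, 2e5, seed = 7)
  s0 <- state_at(env2, 6, 6)
  at <- which(long$states[-length(long$states)] == s0)
  counts <- table(factor(long$actions[at], levels = c("N", "S", "E", "W")))
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # state-visit frequencies approach the degree-proportional stationary law
  freq <- tabulate(long$states, env2$n_states) / length(long$states)
  statd <- env2$degree / sum(env2$degree)
  expect_lt(0.5 * sum(abs(freq - statd)), 0.03)
})

test_that("context fixtures share a footprint and their regions straddle the walls", {
  envs <- barrier_context_envs(30)
  expect_true(all(vapply(envs, function(e) e$n_states, integer(1)) == 900))
  # same state indexing everywhere
  expect_equal(envs$phi$index, envs$AB$index)
  # walls change connectivity: strictly fewer edges with more walls
  n_edges <- vapply(envs, function(e) sum(e$degree), integer(1))
  expect_true(n_edges[["AB"]] < n_edges[["A"]])
  expect_true(n_edges[["A"]] < n_edges[["phi"]])
  # start/goal regions force barrier interaction: shortest path in AB longer
  # than in phi for a representative pair
  reg <- context_regions(envs$AB)
  s <- reg$start[1]; g <- reg$goal[length(reg$goal)]
  expect_gte(shortest_path_length(envs$AB, s, g),
             shortest_path_length(envs$phi, s, g))
})
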