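# Synthetic rate maps with known lattice structure (gridness oracles) and
# small shared fixtures. Heavy trained fixtures are memoized in .fix_cache
# so several test files can share one training run.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

# Gaussian-bump map on an h x w grid with fields at the given lattice.
bump_map <- function(h, w, centers, sigma = 2.5) {
  m <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    d2 <- (centers[, 1] - r)^2 + (centers[, 2] - c)^2
    m[r, c] <- sum(exp(-d2 / (2 * sigma^2)))
  }
  m
}

# Hexagonal lattice centered on the map: basis (s, 0) and (s/2, s*sqrt(3)/2).
hex_centers <- function(h, w, spacing = 9) {
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  pts <- expand.grid(i = -6:6, j = -6:6)
  rr <- ctr[1] + pts$i * spacing * sqrt(3) / 2
  cc <- ctr[2] + pts$j * spacing + (pts$i %% 2) * spacing / 2
  keep <- rr > -spacing & rr < h + spacing & cc > -spacing & cc < w + spacing
  cbind(rr[keep], cc[keep])
}

square_centers <- function(h, w, spacing = 9) {
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  pts <- expand.grid(i = -6:6, j = -6:6)
  rr <- ctr[1] + pts$i * spacing
  cc <- ctr[2] + pts$j * spacing
  keep <- rr > -spacing & rr < h + spacing & cc > -spacing & cc < w + spacing
  cbind(rr[keep], cc[keep])
}

# Independent BFS oracle (plain R flood fill over 4-neighborhoods on a
# free-cell logical matrix), used to cross-check shortest paths.
flood_fill_distance <- function(free, from, to) {
  h <- nrow(free); w <- ncol(free)
  dist <- matrix(Inf, h, w)
  dist[from[1], from[2]] <- 0
  frontier <- list(from)
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- list()
    for (cell in frontier) {
      for (dd in list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1))) {
        r <- cell[1] + dd[1]; c <- cell[2] + dd[2]
        if (r < 1 || r > h || c < 1 || c > w) next
        if (!free[r, c] || dist[r, c] <= d) next
        dist[r, c] <- d
        nxt[[length(nxt) + 1]] <- c(r, c)
      }
    }
    frontier <- nxt
  }
  dist[to[1], to[2]]
}

# Hand-built disentangled word embedding over factor units
# (capital, country, French, German): France = country + French, etc.
toy_word_embedding <- function() {
  X <- rbind(
    France  = c(0, 1, 1, 0),
    Paris   = c(1, 0, 1, 0),
    Germany = c(0, 1, 0, 1),
    Berlin  = c(1, 0, 0, 1)
  )
  as_dsi_embedding(X, X, labels = rownames(X))
}

# A small trained spatial fixture shared by several test files:
# 15x15 open room, D = 40, decorr.
small_space_fixture <- function() {
  memo("small_space", {
    env <- grid_env(15, 15)
    walk <- random_walk(env, 6e4, seed = 11)
    sr <- sr_empirical(walk, 0.99)
    psi <- compute_psi(sr, occupancy(walk))
    cfg <- dsi_config(D = 40, variant = "decorr", n_iter = 400, seed = 11)
    list(env = env, psi = psi, embedding = dsi_factorize(psi, cfg))
  })
}
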