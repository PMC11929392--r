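test_that("objective terms behave as specified on constructed cases", {
  set.seed(4)
  X <- matrix(abs(rnorm(30)), 10, 3)
  W <- matrix(abs(rnorm(30)), 10, 3)
  psi <- X %*% t(W)
  cfg0 <- dsi_config(D = 3, beta = 0, rho = 0)
  expect_equal(dsi_objective(X, W, psi, cfg0)$total, 0)

  # two identical columns contribute corr^2 = 1 per ordered pair,
  # weighted beta / (2 D)
  X2 <- cbind(X[, 1], X[, 1], X[, 3])
  cfgb <- dsi_config(D = 3, beta = 1, rho = 0)
  dec <- dsi_objective(X2, W, psi, cfgb)$terms[["decorr"]]
  expect_gte(dec, 2 / 6 - 1e-9)

  # permutation of unit order leaves the objective invariant
  cfg <- dsi_config(D = 3, beta = 2, rho = 0.5)
  p <- c(3, 1, 2)
  expect_equal(dsi_objective(X[, p], W[, p], psi, cfg)$total,
               dsi_objective(X, W, psi, cfg)$total)

  expect_error(dsi_objective(X * NA, W, psi, cfg), "NA")
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  psi <- matrix(abs(rnorm(100)), 10, 10)
  h <- 1e-5
  for (variant in c("decorr", "sparse")) {
    cfg <- dsi_config(D = 4, variant = variant, beta = 2, rho = 1,
                      rho_l1 = 0.5, seed = 3)
    X <- matrix(abs(rnorm(40)) + 0.1, 10, 4)  # keep away from |x| = 0 kink
    W <- matrix(abs(rnorm(40)) + 0.1, 10, 4)
    obj <- dsi_objective(X, W, psi, cfg, gradients = TRUE)
    for (M in c("X", "W")) {
      num <- matrix(0, 10, 4)
      for (i in seq_along(num)) {
        up <- list(X = X, W = W); up[[M]][i] <- up[[M]][i] + h
        dn <- list(X = X, W = W); dn[[M]][i] <- dn[[M]][i] - h
        num[i] <- (dsi_objective(up$X, up$W, psi, cfg)$total -
                     dsi_objective(dn$X, dn$W, psi, cfg)$total) / (2 * h)
      }
      grad <- obj[[paste0("grad_", M)]]
      expect_lt(max(abs(num - grad)) / max(abs(num)), 1e-4)
    }
  }
})

test_that("factorization recovers a planted nonnegative low-rank product", {
  set.seed(1)
  A <- matrix(abs(rnorm(40)), 20, 2)
  B <- matrix(abs(rnorm(40)), 20, 2)
  psi <- A %*% t(B)
  cfg <- dsi_config(D = 2, beta = 0, rho = 0, n_iter = 3000,
                    learning_rate = 0.02, seed = 5)
  emb <- dsi_factorize(psi, cfg)
  expect_lt(norm(reconstruct(emb) - psi, "F") / norm(psi, "F"), 0.05)
  # nonnegativity enforced exactly
  expect_gte(min(emb$X), 0)
  expect_gte(min(emb$W), 0)
  expect_true(all(reconstruct(emb) >= 0))
})

test_that("training loss trends downward (windowed medians decrease)", {
  fix <- small_space_fixture()
  lt <- fix$embedding$loss_trace
  wins <- split(lt, cut(seq_along(lt), 4))
  meds <- vapply(wins, median, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("decorrelation penalty lowers inter-unit correlation from the same init", {
  fix <- small_space_fixture()
  psi <- fix$psi
  cfg_on <- dsi_config(D = 20, beta = 5, rho = 0.01, n_iter = 300, seed = 2)
  cfg_off <- dsi_config(D = 20, beta = 0, rho = 0.01, n_iter = 300, seed = 2)
  e_on <- dsi_factorize(psi, cfg_on)
  e_off <- dsi_factorize(psi, cfg_off)
  mean_abs_corr <- function(M) {
    cc <- suppressWarnings(cor(M))
    mean(abs(cc[upper.tri(cc)]), na.rm = TRUE)
  }
  expect_lt(mean_abs_corr(e_on$X), mean_abs_corr(e_off$X))
})

test_that("divergent learning rates raise the advisory error", {
  set.seed(2)
  psi <- matrix(abs(rnorm(64)), 8, 8)
  cfg <- dsi_config(D = 2, optimizer = "adam", learning_rate = 20, n_iter = 200,
                    seed = 1)
  expect_error(dsi_factorize(psi, cfg), "learning rate")
})

test_that("nonnegativity-off ablation produces signed factors", {
  set.seed(3)
  psi <- matrix(abs(rnorm(100)), 10, 10)
  cfg <- dsi_config(D = 3, variant = "decorr-nonneg-off", n_iter = 100,
                    seed = 1)
  emb <- dsi_factorize(psi, cfg)
  expect_lt(min(emb$X), 0)
  expect_identical(emb$variant, "decorr-nonneg-off")
})

test_that("tidy and glance summarize a fitted embedding", {
  fix <- small_space_fixture()
  td <- tidy(fix$embedding)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_false(any(td$dead))
  gl <- glance(fix$embedding)
  expect_equal(gl$D, 40)
  expect_equal(gl$variant, "decorr")
})
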