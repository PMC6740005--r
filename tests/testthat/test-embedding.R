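test_that("penalty matrix marks observed edges with beta", {
  G <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(build_penalty_matrix(G, 5), matrix(c(1, 5, 5, 1), 2, 2))
  expect_true(all(build_penalty_matrix(matrix(0, 3, 3), 2) == 1))
  set.seed(1)
  Gr <- matrix(rbinom(36, 1, 0.3), 6, 6); Gr <- pmax(Gr, t(Gr)); diag(Gr) <- 0
  expect_equal(sum(build_penalty_matrix(Gr, 7) == 7), sum(Gr != 0))
  expect_error(build_penalty_matrix(G, 1), "beta")
})

test_that("loss components match hand computations", {
  # single edge, codes (0,0) and (1,1): both ordered pairs contribute 2
  G <- matrix(c(0, 1, 1, 0), 2, 2)
  Y <- rbind(c(0, 0), c(1, 1))
  expect_equal(first_order_loss(G, Y), 4)
  expect_equal(first_order_loss(G, rbind(c(1, 1), c(1, 1))), 0)
  expect_equal(first_order_loss(matrix(0, 2, 2), Y), 0)
  expect_error(first_order_loss(G, matrix(0, 3, 2)), "row per node")

  X <- matrix(c(1, 0), 1, 2)
  X_hat <- matrix(c(0, 0), 1, 2)
  B <- matrix(c(3, 1), 1, 2)
  expect_equal(second_order_loss(X, X_hat, B), 9)
  expect_equal(second_order_loss(X, X, B), 0)
  expect_equal(second_order_loss(X, X_hat, 2 * B),
               4 * second_order_loss(X, X_hat, B))
  expect_error(second_order_loss(X, matrix(0, 2, 2), B), "shape")

  expect_equal(reg_loss(list(matrix(2, 1, 1)), list(matrix(2, 1, 1))), 4)
  expect_equal(reg_loss(list(matrix(0, 3, 2))), 0)
  W <- list(matrix(rnorm(6), 2, 3))
  expect_equal(reg_loss(lapply(W, `*`, 3)), 9 * reg_loss(W))
})

test_that("total loss is the weighted sum of its components", {
  set.seed(5)
  for (rep in 1:5) {
    N <- sample(3:6, 1); d <- 2
    G <- matrix(rbinom(N * N, 1, 0.4), N, N); G <- pmax(G, t(G)); diag(G) <- 0
    X <- G * 1.0
    X_hat <- matrix(runif(N * N), N, N)
    Y <- matrix(rnorm(N * d), N, d)
    We <- list(matrix(rnorm(8), 4, 2)); Wd <- list(matrix(rnorm(8), 2, 4))
    cfg <- sdne_config(d = d, hidden_layers = c(4L, d), alpha = 2,
                       beta = 3, nu = 0.5)
    expect_equal(total_loss(G, X, X_hat, Y, We, Wd, cfg),
                 second_order_loss(X, X_hat, build_penalty_matrix(G, 3)) +
                   2 * first_order_loss(G, Y) + 0.5 * reg_loss(We, Wd),
                 tolerance = 1e-9)
    # alpha = nu = 0 reduces to the reconstruction loss alone
    cfg0 <- sdne_config(d = d, hidden_layers = c(4L, d), alpha = 0,
                        beta = 3, nu = 0)
    expect_equal(total_loss(G, X, X_hat, Y, We, Wd, cfg0),
                 second_order_loss(X, X_hat, build_penalty_matrix(G, 3)))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(9)
  N <- 6
  G <- matrix(rbinom(N * N, 1, 0.5), N, N); G <- pmax(G, t(G)); diag(G) <- 0
  X <- G * 1.0
  B <- build_penalty_matrix(G, 4)
  Lap <- diag(rowSums(G)) - G
  cfg <- sdne_config(d = 2L, hidden_layers = c(4L, 2L), alpha = 0.7,
                     beta = 4, nu = 0.2)
  par <- list(We = list(mirdnet:::glorot_init(N, 4), mirdnet:::glorot_init(4, 2)),
              be = list(rnorm(4), rnorm(2)),
              Wd = list(mirdnet:::glorot_init(2, 4), mirdnet:::glorot_init(4, N)),
              bd = list(rnorm(4), rnorm(N)))
  loss_at <- function(p) {
    fwd <- mirdnet:::sdne_forward(X, p)
    second_order_loss(X, fwd$X_hat, B) +
      cfg$alpha * first_order_loss(G, fwd$Y) +
      cfg$nu * reg_loss(p$We, p$Wd)
  }
  fwd <- mirdnet:::sdne_forward(X, par)
  grad <- mirdnet:::sdne_backward(X, G, B, Lap, par, fwd, cfg)
  eps <- 1e-6
  for (grp in c("We", "be", "Wd", "bd")) {
    for (k in seq_along(par[[grp]])) {
      idx <- sample(length(par[[grp]][[k]]), min(3, length(par[[grp]][[k]])))
      for (q in idx) {
        up <- par; up[[grp]][[k]][q] <- up[[grp]][[k]][q] + eps
        dn <- par; dn[[grp]][[k]][q] <- dn[[grp]][[k]][q] - eps
        fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grad[[grp]][[k]][q], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic, reduces the loss and respects second-order proximity", {
  # connected ring of 20 nodes
  N <- 20
  G <- matrix(0L, N, N)
  for (i in seq_len(N)) {
    j <- i %% N + 1L
    G[i, j] <- G[j, i] <- 1L
  }
  cfg <- sdne_config(d = 4L, hidden_layers = c(8L, 4L), epochs = 300L,
                     seed = 5L)
  fit1 <- train_sdne(G, cfg)
  fit2 <- train_sdne(G, cfg)
  expect_identical(fit1$embedding, fit2$embedding)
  expect_lt(fit1$report$final["Lmix"], fit1$report$per_epoch$Lmix[1])
  expect_true(all(is.finite(fit1$embedding)))

  # two nodes with identical neighborhoods embed closer than the median pair
  G2 <- matrix(0L, 10, 10)
  G2[1, 5:8] <- G2[2, 5:8] <- 1L     # duplicate rows
  G2[3, 9] <- G2[4, 10] <- 1L
  G2 <- pmax(G2, t(G2))
  fit3 <- train_sdne(G2, sdne_config(d = 3L, hidden_layers = c(6L, 3L),
                                     epochs = 500L, seed = 2L))
  D <- as.matrix(dist(fit3$embedding))
  expect_lt(D[1, 2], stats::median(D[upper.tri(D)]))

  expect_warning(train_sdne(G2, sdne_config(d = 12L,
                                            hidden_layers = c(12L, 12L),
                                            epochs = 2L)),
                 "dimension")
})

test_that("Laplacian eigenmaps satisfy the generalized-eigen contracts", {
  # path graph P4: the first nontrivial eigenvector orders the path
  G <- matrix(0L, 4, 4)
  G[cbind(1:3, 2:4)] <- 1L
  G <- pmax(G, t(G))
  Y <- embed_laplacian(G, 1)
  expect_true(all(diff(Y[, 1]) > 0) || all(diff(Y[, 1]) < 0))
  # generalized orthonormality t(Y) D Y = I
  Y2 <- embed_laplacian(G, 2)
  Dm <- diag(rowSums(G))
  expect_equal(unname(t(Y2) %*% Dm %*% Y2), diag(2), tolerance = 1e-8)
  # disconnected graph warns
  G3 <- matrix(0L, 6, 6)
  G3[1, 2] <- G3[2, 1] <- 1L
  G3[3, 4] <- G3[4, 3] <- 1L
  G3[5, 6] <- G3[6, 5] <- 1L
  expect_warning(embed_laplacian(G3, 2), "disconnected")
})

test_that("HOPE matches the Katz power series and improves with rank", {
  G <- matrix(0L, 3, 3)
  G[1, 2] <- G[2, 1] <- G[2, 3] <- G[3, 2] <- 1L
  bk <- 0.1
  S_inv <- solve(diag(3) - bk * G, bk * G)
  S_series <- matrix(0, 3, 3)
  term <- diag(3)
  for (k in 1:50) {
    term <- term %*% (bk * G)
    S_series <- S_series + term
  }
  expect_equal(S_inv, S_series, tolerance = 1e-10)
  Y <- embed_hope(G, 2, beta_katz = bk)
  expect_equal(dim(Y), c(3L, 2L))

  set.seed(3)
  G2 <- matrix(rbinom(64, 1, 0.4), 8, 8); G2 <- pmax(G2, t(G2)); diag(G2) <- 0
  rho <- max(abs(eigen(G2, symmetric = TRUE, only.values = TRUE)$values))
  bk2 <- 0.5 / rho
  S <- solve(diag(8) - bk2 * G2, bk2 * G2)
  errs <- vapply(c(2, 4, 8), function(dd) {
    Y <- embed_hope(G2, dd, beta_katz = bk2)
    r <- dd / 2
    norm(S - Y[, 1:r, drop = FALSE] %*% t(Y[, r + 1:r, drop = FALSE]), "F")
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(embed_hope(G2, 2, beta_katz = 1 / rho), "spectral radius")
  expect_error(embed_hope(G2, 3), "even")
})

test_that("dimension sweeps reuse one seed base and return full-height embeddings", {
  set.seed(4)
  G <- matrix(rbinom(144, 1, 0.3), 12, 12); G <- pmax(G, t(G)); diag(G) <- 0
  cfg <- sdne_config(d = 2L, hidden_layers = c(6L, 2L), epochs = 30L, seed = 9L)
  sw <- dimension_sweep(G, "sdne", dims = c(2L, 4L), cfg = cfg)
  expect_named(sw, c("2", "4"))
  expect_equal(vapply(sw, nrow, 0L), c(`2` = 12L, `4` = 12L))
  expect_equal(ncol(sw[["4"]]), 4L)
  # same seed base: repeating the sweep reproduces it
  sw2 <- dimension_sweep(G, "sdne", dims = c(2L, 4L), cfg = cfg)
  expect_identical(sw, sw2)
})
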