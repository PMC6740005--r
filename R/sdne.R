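#' @title Structural deep network embedding (SDNE)
#' @description A deep autoencoder over adjacency rows. The encoder maps
#'   each node's adjacency row x_i = G\[i, \] through K sigmoid layers to a
#'   d-dimensional code y_i; a mirrored decoder reconstructs the row. The
#'   objective couples three terms: a reconstruction loss in which observed
#'   edges are up-weighted by a penalty beta > 1 (second-order proximity:
#'   nodes with similar neighborhoods get similar codes), an edge-wise code
#'   distance penalty (first-order proximity: linked nodes get similar
#'   codes), and an L2 weight penalty. Training is full-batch gradient
#'   descent with Adam updates, deterministic under the configured seed.
#' @name sdne
NULL

#' SDNE hyperparameter configuration
#'
#' @param d embedding dimension (width of the innermost code layer).
#' @param hidden_layers encoder layer widths, last entry must equal `d`;
#'   default `c(256, d)`. Widths must be non-increasing toward the code.
#' @param alpha weight of the first-order (edge distance) loss.
#' @param beta reconstruction penalty on observed edges; must exceed 1.
#' @param nu L2 regularization weight on the layer weight matrices.
#' @param epochs number of full-batch training iterations.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for weight initialization (training itself is
#'   deterministic).
#' @return an `sdne_config` list.
#' @export
sdne_config <- function(d = 128L, hidden_layers = NULL, alpha = 0.05,
                        beta = 5, nu = 1e-4, epochs = 200L,
                        learning_rate = 0.01, seed = 1L) {
  d <- as.integer(d)
  stopifnot(d >= 1L, beta > 1, alpha >= 0, nu >= 0, epochs >= 1L,
            learning_rate > 0)
  if (is.null(hidden_layers)) hidden_layers <- c(256L, d)
  hidden_layers <- as.integer(hidden_layers)
  if (hidden_layers[length(hidden_layers)] != d) {
    stop("last hidden layer width must equal d", call. = FALSE)
  }
  if (is.unsorted(rev(hidden_layers))) {
    stop("hidden layer widths must be non-increasing toward d", call. = FALSE)
  }
  structure(list(d = d, hidden_layers = hidden_layers, alpha = alpha,
                 beta = beta, nu = nu, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "sdne_config")
}

as_adjacency_matrix <- function(G) {
  if (inherits(G, "bipartite_adjacency")) G <- G$G
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  G
}

#' Reconstruction penalty matrix
#'
#' `B[i, j] = beta` wherever `G[i, j] != 0`, and 1 elsewhere, so that the
#' reconstruction loss punishes missed edges more than missed non-edges.
#'
#' @param G adjacency matrix (or `bipartite_adjacency`).
#' @param beta penalty for observed edges; must exceed 1.
#' @return a matrix the shape of `G`.
#' @export
build_penalty_matrix <- function(G, beta) {
  G <- as_adjacency_matrix(G)
  if (beta <= 1) stop("beta must be > 1", call. = FALSE)
  B <- matrix(1, nrow(G), ncol(G))
  B[G != 0] <- beta
  B
}

#' First-order proximity loss
#'
#' `sum_{i,j} G[i, j] * ||y_i - y_j||^2` over ordered index pairs, so each
#' undirected edge of a symmetric adjacency contributes twice.
#'
#' @param G adjacency matrix (or `bipartite_adjacency`).
#' @param Y node code matrix, one row per node.
#' @return a non-negative scalar.
#' @export
first_order_loss <- function(G, Y) {
  G <- as_adjacency_matrix(G)
  if (nrow(Y) != nrow(G)) stop("Y must have one row per node", call. = FALSE)
  rn <- rowSums(Y^2)
  cross <- tcrossprod(Y)
  sum(G * (outer(rn, rep(1, length(rn))) +
             outer(rep(1, length(rn)), rn) - 2 * cross))
}

#' Second-order (penalized reconstruction) loss
#'
#' Squared Frobenius norm of the elementwise product of the reconstruction
#' error with the penalty matrix: `||(X_hat - X) * B||_F^2`.
#'
#' @param X input matrix (adjacency rows).
#' @param X_hat reconstruction, same shape.
#' @param B penalty matrix, same shape.
#' @return a non-negative scalar.
#' @export
second_order_loss <- function(X, X_hat, B) {
  if (!all(dim(X) == dim(X_hat)) || !all(dim(X) == dim(B))) {
    stop("X, X_hat and B must share a shape", call. = FALSE)
  }
  sum(((X_hat - X) * B)^2)
}

#' L2 weight regularization loss
#'
#' Half the summed squared Frobenius norms of the encoder and decoder
#' weight matrices (biases excluded).
#'
#' @param encoder_weights,decoder_weights lists of weight matrices.
#' @return a non-negative scalar.
#' @export
reg_loss <- function(encoder_weights, decoder_weights = list()) {
  0.5 * (sum(vapply(encoder_weights, function(w) sum(w^2), 0)) +
           sum(vapply(decoder_weights, function(w) sum(w^2), 0)))
}

#' Combined SDNE objective
#'
#' `L_2nd + alpha * L_1st + nu * L_reg`, with the penalty matrix derived
#' from `G` and `cfg$beta`.
#'
#' @param G adjacency matrix (or `bipartite_adjacency`).
#' @param X,X_hat autoencoder input and reconstruction.
#' @param Y code matrix.
#' @param encoder_weights,decoder_weights weight matrix lists.
#' @param cfg an `sdne_config` supplying `alpha`, `beta`, `nu`.
#' @return a scalar.
#' @export
total_loss <- function(G, X, X_hat, Y, encoder_weights, decoder_weights,
                       cfg) {
  B <- build_penalty_matrix(G, cfg$beta)
  second_order_loss(X, X_hat, B) +
    cfg$alpha * first_order_loss(G, Y) +
    cfg$nu * reg_loss(encoder_weights, decoder_weights)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

sdne_forward <- function(X, par) {
  K <- length(par$We)
  H <- vector("list", K + 1L)
  H[[1L]] <- X
  for (k in seq_len(K)) {
    H[[k + 1L]] <- sigmoid(sweep(H[[k]] %*% par$We[[k]], 2, par$be[[k]], "+"))
  }
  Hd <- vector("list", K + 1L)
  Hd[[1L]] <- H[[K + 1L]]
  for (k in seq_len(K)) {
    Hd[[k + 1L]] <- sigmoid(sweep(Hd[[k]] %*% par$Wd[[k]], 2, par$bd[[k]], "+"))
  }
  list(H = H, Hd = Hd, Y = H[[K + 1L]], X_hat = Hd[[K + 1L]])
}

# full-batch gradient of the combined objective; Lap = diag(rowSums(G)) - G
sdne_backward <- function(X, G, B, Lap, par, fwd, cfg) {
  K <- length(par$We)
  gWe <- vector("list", K); gbe <- vector("list", K)
  gWd <- vector("list", K); gbd <- vector("list", K)
  # decoder
  delta <- 2 * (fwd$X_hat - X) * B^2 * fwd$X_hat * (1 - fwd$X_hat)
  for (k in rev(seq_len(K))) {
    gWd[[k]] <- crossprod(fwd$Hd[[k]], delta) + cfg$nu * par$Wd[[k]]
    gbd[[k]] <- colSums(delta)
    delta <- delta %*% t(par$Wd[[k]])
    if (k > 1L) delta <- delta * fwd$Hd[[k]] * (1 - fwd$Hd[[k]])
  }
  # at the code layer the decoder gradient meets the first-order term
  dY <- delta + cfg$alpha * 4 * (Lap %*% fwd$Y)
  delta <- dY * fwd$Y * (1 - fwd$Y)
  for (k in rev(seq_len(K))) {
    gWe[[k]] <- crossprod(fwd$H[[k]], delta) + cfg$nu * par$We[[k]]
    gbe[[k]] <- colSums(delta)
    if (k > 1L) {
      delta <- (delta %*% t(par$We[[k]])) * fwd$H[[k]] * (1 - fwd$H[[k]])
    }
  }
  list(We = gWe, be = gbe, Wd = gWd, bd = gbd)
}

adam_step <- function(state, par, grad, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (grp in c("We", "be", "Wd", "bd")) {
    for (k in seq_along(par[[grp]])) {
      g <- grad[[grp]][[k]]
      state$m[[grp]][[k]] <- b1 * state$m[[grp]][[k]] + (1 - b1) * g
      state$v[[grp]][[k]] <- b2 * state$v[[grp]][[k]] + (1 - b2) * g^2
      mhat <- state$m[[grp]][[k]] / (1 - b1^t)
      vhat <- state$v[[grp]][[k]] / (1 - b2^t)
      par[[grp]][[k]] <- par[[grp]][[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, par = par)
}

#' Train an SDNE embedding of a network
#'
#' Runs full-batch Adam on the combined objective and returns the code
#' matrix (one row per node, in adjacency order) plus a per-epoch training
#' report. Degree-zero nodes simply carry an all-zero input row; they need
#' no special casing. Reproducible to the bit under a fixed seed.
#'
#' @param G a `bipartite_adjacency` or symmetric adjacency matrix.
#' @param cfg an `sdne_config`.
#' @return list with `embedding` (the (m+n) x d matrix `NE`, rownames =
#'   node order) and `report` (per-epoch loss components and final losses).
#' @export
train_sdne <- function(G, cfg = sdne_config()) {
  node_order <- if (inherits(G, "bipartite_adjacency")) G$node_order else
    rownames(as_adjacency_matrix(G))
  A <- as_adjacency_matrix(G)
  N <- nrow(A)
  if (N == 0L) stop("empty network", call. = FALSE)
  if (cfg$d >= N) {
    warning("embedding dimension >= number of nodes", call. = FALSE)
  }
  X <- A * 1.0
  B <- build_penalty_matrix(A, cfg$beta)
  Lap <- diag(rowSums(A)) - A
  widths <- c(N, cfg$hidden_layers)
  K <- length(cfg$hidden_layers)
  dec_widths <- c(cfg$d, rev(cfg$hidden_layers)[-1L], N)

  set.seed(cfg$seed)
  par <- list(
    We = lapply(seq_len(K), function(k) glorot_init(widths[k], widths[k + 1L])),
    be = lapply(seq_len(K), function(k) numeric(widths[k + 1L])),
    Wd = lapply(seq_len(K), function(k) glorot_init(dec_widths[k], dec_widths[k + 1L])),
    bd = lapply(seq_len(K), function(k) numeric(dec_widths[k + 1L]))
  )
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  state <- list(m = lapply(par, zeros_like), v = lapply(par, zeros_like))

  losses <- function(fwd) {
    l2 <- second_order_loss(X, fwd$X_hat, B)
    l1 <- 2 * sum(fwd$Y * (Lap %*% fwd$Y))
    lr_ <- reg_loss(par$We, par$Wd)
    c(L1st = l1, L2nd = l2, Lreg = lr_,
      Lmix = l2 + cfg$alpha * l1 + cfg$nu * lr_)
  }

  report <- matrix(NA_real_, cfg$epochs, 4,
                   dimnames = list(NULL, c("L1st", "L2nd", "Lreg", "Lmix")))
  for (ep in seq_len(cfg$epochs)) {
    fwd <- sdne_forward(X, par)
    report[ep, ] <- losses(fwd)
    if (!is.finite(report[ep, "Lmix"])) {
      stop(sprintf("non-finite loss at epoch %d (L2nd=%.3g, L1st=%.3g)",
                   ep, report[ep, "L2nd"], report[ep, "L1st"]), call. = FALSE)
    }
    grad <- sdne_backward(X, A, B, Lap, par, fwd, cfg)
    upd <- adam_step(state, par, grad, cfg$learning_rate, ep)
    state <- upd$state
    par <- upd$par
  }
  fwd <- sdne_forward(X, par)
  final <- losses(fwd)
  NE <- fwd$Y
  rownames(NE) <- node_order
  colnames(NE) <- paste0("e", seq_len(ncol(NE)))
  list(embedding = NE,
       report = list(per_epoch = as.data.frame(report), final = final,
                     seed = cfg$seed))
}
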