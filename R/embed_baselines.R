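#' @title Baseline network embedders
#' @description Deterministic spectral baselines against which the
#'   autoencoder embedding is compared: Laplacian eigenmaps (smallest
#'   nontrivial generalized Laplacian eigenvectors) and HOPE (truncated SVD
#'   of the Katz proximity matrix).
#' @name embed_baselines
NULL

#' Laplacian-eigenmap embedding
#'
#' Solves the generalized eigenproblem `L v = lambda D v` (with
#' `L = D - G`) via the symmetric normalization `D^{-1/2} L D^{-1/2}` and
#' returns the eigenvectors of the `d` smallest nonzero eigenvalues,
#' back-transformed so that `t(Y) %*% D %*% Y = I`. One null eigenvector
#' is discarded per connected component; a disconnected graph triggers a
#' warning (its spectra are those of the components). Degree-zero nodes
#' receive all-zero rows.
#'
#' @param G a `bipartite_adjacency` or symmetric adjacency matrix.
#' @param d number of embedding dimensions; needs `d + 1` or fewer nodes
#'   than the connected part of the graph provides eigenvectors for.
#' @return an (N x d) embedding matrix, rownames = node order.
#' @export
embed_laplacian <- function(G, d) {
  node_order <- if (inherits(G, "bipartite_adjacency")) G$node_order else
    rownames(as_adjacency_matrix(G))
  A <- as_adjacency_matrix(G) * 1.0
  N <- nrow(A)
  deg <- rowSums(A)
  live <- deg > 0
  if (sum(live) < d + 1L) {
    stop("graph too small for the requested dimension", call. = FALSE)
  }
  Al <- A[live, live, drop = FALSE]
  dl <- deg[live]
  inv_sqrt <- 1 / sqrt(dl)
  Lsym <- diag(sum(live)) - (inv_sqrt * t(inv_sqrt * Al))
  eig <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  null_dim <- sum(vals < 1e-9)
  if (null_dim > 1L || any(!live)) {
    warning("graph is disconnected; embedding uses component spectra",
            call. = FALSE)
  }
  take <- seq(null_dim + 1L, length.out = d)
  if (max(take) > length(vals)) {
    stop("not enough nonzero eigenvalues for the requested dimension",
         call. = FALSE)
  }
  U <- vecs[, take, drop = FALSE]
  Y <- matrix(0, N, d, dimnames = list(node_order, paste0("e", seq_len(d))))
  Y[live, ] <- inv_sqrt * U
  Y
}

#' HOPE embedding (Katz proximity + truncated SVD)
#'
#' Computes the Katz similarity `S = (I - b G)^{-1} (b G)` with decay `b`
#' below the inverse spectral radius, factorizes it by truncated SVD, and
#' concatenates the scaled source and target factors (`U sqrt(sigma)` and
#' `V sqrt(sigma)`) per node into a width-`d` embedding.
#'
#' @param G a `bipartite_adjacency` or symmetric adjacency matrix.
#' @param d total embedding width; must be even (d/2 source + d/2 target
#'   dimensions).
#' @param beta_katz Katz decay; default half the inverse spectral radius.
#' @return an (N x d) embedding matrix, rownames = node order.
#' @export
embed_hope <- function(G, d, beta_katz = NULL) {
  node_order <- if (inherits(G, "bipartite_adjacency")) G$node_order else
    rownames(as_adjacency_matrix(G))
  A <- as_adjacency_matrix(G) * 1.0
  if (d %% 2L != 0L) stop("d must be even for HOPE", call. = FALSE)
  rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (rho == 0) stop("empty graph has no Katz proximity", call. = FALSE)
  if (is.null(beta_katz)) beta_katz <- 0.5 / rho
  if (beta_katz >= 1 / rho) {
    stop("beta_katz must be below the inverse spectral radius 1/",
         format(rho), call. = FALSE)
  }
  N <- nrow(A)
  S <- solve(diag(N) - beta_katz * A, beta_katz * A)
  sv <- svd(S, nu = d / 2L, nv = d / 2L)
  scale <- sqrt(sv$d[seq_len(d / 2L)])
  Y <- cbind(sweep(sv$u, 2, scale, "*"), sweep(sv$v, 2, scale, "*"))
  dimnames(Y) <- list(node_order, paste0("e", seq_len(d)))
  Y
}

#' Embed a network with a chosen method
#'
#' Dispatcher used by the pipeline: `"sdne"` trains the autoencoder under
#' `cfg`, `"le"` and `"hope"` run the deterministic spectral baselines at
#' dimension `cfg$d`.
#'
#' @param G a `bipartite_adjacency` or adjacency matrix.
#' @param method one of `"sdne"`, `"le"`, `"hope"`.
#' @param cfg an `sdne_config` (supplies `d` for every method and the
#'   training hyperparameters for `"sdne"`).
#' @return an (N x d) embedding matrix.
#' @export
embed_network <- function(G, method = c("sdne", "le", "hope"),
                          cfg = sdne_config()) {
  method <- match.arg(method)
  switch(method,
         sdne = train_sdne(G, cfg)$embedding,
         le = embed_laplacian(G, cfg$d),
         hope = embed_hope(G, cfg$d))
}

#' Embeddings across a sweep of dimensions
#'
#' Recomputes the embedding at each requested dimension, reusing one seed
#' base so sweeps are reproducible.
#'
#' @param G a `bipartite_adjacency` or adjacency matrix.
#' @param method embedding method, as in [embed_network()].
#' @param dims integer vector of embedding dimensions.
#' @param cfg an `sdne_config` template; its `d` and final layer width are
#'   overridden per sweep point.
#' @return named list of embedding matrices, one per dimension.
#' @export
dimension_sweep <- function(G, method = c("sdne", "le", "hope"),
                            dims = c(32L, 64L, 128L, 256L, 512L),
                            cfg = sdne_config()) {
  method <- match.arg(method)
  stopifnot(length(dims) >= 1L, all(dims >= 1L))
  out <- lapply(dims, function(dd) {
    hl <- cfg$hidden_layers
    hl[length(hl)] <- as.integer(dd)
    hl <- pmax(hl, as.integer(dd))
    cfg_d <- sdne_config(d = dd, hidden_layers = hl, alpha = cfg$alpha,
                         beta = cfg$beta, nu = cfg$nu, epochs = cfg$epochs,
                         learning_rate = cfg$learning_rate, seed = cfg$seed)
    embed_network(G, method, cfg_d)
  })
  names(out) <- as.character(dims)
  out
}
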