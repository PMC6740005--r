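#' @title Pair feature assembly
#' @description A miRNA-disease pair (i, j) is described by concatenating,
#'   in fixed order, the miRNA's binary family-membership row `Z[i, ]`, the
#'   disease's semantic-similarity row `SS[j, ]`, and the two network
#'   embedding rows `NE[i, ]` (miRNA node) and `NE[m + j, ]` (disease
#'   node). Five canonical combinations toggle the three sources.
#' @name features
NULL

#' Feature combination configuration
#'
#' The five canonical combinations:
#' 1. embedding only; 2. family + disease similarity (no embedding);
#' 3. embedding + family; 4. embedding + disease similarity;
#' 5. all three sources.
#' Alternatively pass the three flags explicitly (at least one must be
#' set).
#'
#' @param combo integer 1-5 selecting a canonical combination, or `NULL`
#'   to use the flags.
#' @param use_family,use_disease_sim,use_embedding logical flags.
#' @return a `feature_config`.
#' @export
feature_config <- function(combo = NULL, use_family = TRUE,
                           use_disease_sim = TRUE, use_embedding = TRUE) {
  if (!is.null(combo)) {
    stopifnot(combo %in% 1:5)
    flags <- switch(combo,
                    `1` = c(FALSE, FALSE, TRUE),
                    `2` = c(TRUE, TRUE, FALSE),
                    `3` = c(TRUE, FALSE, TRUE),
                    `4` = c(FALSE, TRUE, TRUE),
                    `5` = c(TRUE, TRUE, TRUE))
    use_family <- flags[1]; use_disease_sim <- flags[2]
    use_embedding <- flags[3]
  }
  if (!any(use_family, use_disease_sim, use_embedding)) {
    stop("at least one feature source must be enabled", call. = FALSE)
  }
  structure(list(use_family = use_family,
                 use_disease_sim = use_disease_sim,
                 use_embedding = use_embedding,
                 combo = combo),
            class = "feature_config")
}

feature_width <- function(cfg, t, n, d) {
  cfg$use_family * t + cfg$use_disease_sim * n + cfg$use_embedding * 2L * d
}

#' Feature vector of one miRNA-disease pair
#'
#' Concatenation `[Z[i, ] | SS[j, ] | NE[i, ] | NE[m + j, ]]` restricted to
#' the enabled blocks.
#'
#' @param i miRNA index (row of `Z` / `NE`).
#' @param j disease index (row of `SS`; `NE` row `m + j`).
#' @param Z m x t family matrix (may be `NULL` when disabled).
#' @param SS n x n similarity matrix (may be `NULL` when disabled).
#' @param NE (m+n) x d embedding matrix (may be `NULL` when disabled).
#' @param cfg a `feature_config`.
#' @param m number of miRNAs (to offset disease embedding rows).
#' @return a numeric vector.
#' @export
pair_vector <- function(i, j, Z, SS, NE, cfg, m) {
  if (i < 1L || i > m) stop("miRNA index out of range", call. = FALSE)
  v <- numeric(0)
  if (cfg$use_family) {
    if (j < 1L) stop("disease index out of range", call. = FALSE)
    v <- c(v, Z[i, ])
  }
  if (cfg$use_disease_sim) {
    if (j > nrow(SS)) stop("disease index out of range", call. = FALSE)
    v <- c(v, SS[j, ])
  }
  if (cfg$use_embedding) {
    if (m + j > nrow(NE)) stop("disease index out of range", call. = FALSE)
    v <- c(v, NE[i, ], NE[m + j, ])
  }
  unname(v)
}

#' Feature matrix over all miRNA-disease pairs
#'
#' Builds one row per pair in row-major order (miRNA outer, disease
#' inner). Positives are the 1-cells of the training association matrix;
#' every 0-cell is kept as an (unlabeled-as-negative) negative — the full
#' complement, with no subsampling, matching the semi-supervised protocol.
#'
#' @param A_train m x n binary training association matrix.
#' @param Z,SS,NE feature source matrices (see [pair_vector()]).
#' @param cfg a `feature_config`.
#' @return a `pair_features` list: `X` (features), `labels` (0/1 integer),
#'   `pairs` (two-column index matrix), `offsets` (block start offsets),
#'   `cfg`.
#' @export
build_training_set <- function(A_train, Z, SS, NE, cfg) {
  m <- nrow(A_train); n <- ncol(A_train)
  if (sum(A_train) == 0) stop("no positive pairs in training matrix",
                              call. = FALSE)
  ii <- rep(seq_len(m), each = n)
  jj <- rep(seq_len(n), times = m)
  blocks <- list()
  offsets <- integer(0)
  w <- 0L
  if (cfg$use_family) {
    offsets <- c(offsets, family = w); w <- w + ncol(Z)
    blocks <- c(blocks, list(Z[ii, , drop = FALSE]))
  }
  if (cfg$use_disease_sim) {
    offsets <- c(offsets, disease_sim = w); w <- w + ncol(SS)
    blocks <- c(blocks, list(SS[jj, , drop = FALSE]))
  }
  if (cfg$use_embedding) {
    offsets <- c(offsets, embedding = w); w <- w + 2L * ncol(NE)
    blocks <- c(blocks, list(NE[ii, , drop = FALSE],
                             NE[m + jj, , drop = FALSE]))
  }
  X <- do.call(cbind, blocks)
  dimnames(X) <- list(NULL, paste0("f", seq_len(ncol(X))))
  labels <- as.integer(t(A_train))
  structure(list(X = X, labels = labels, pairs = cbind(i = ii, j = jj),
                 offsets = offsets, cfg = cfg),
            class = "pair_features")
}
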