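#' @title Semi-supervised cross-validation protocol and metrics
#' @description Known associations are positives; every other pair is
#'   unlabeled and treated as negative during training. In each of five
#'   folds one fifth of the positives is removed, the network embedding is
#'   retrained on the reduced bipartite graph, a forest is trained on the
#'   reduced positive set against the full complement, and every pair that
#'   is 0 in the training matrix is scored — held-out positives labeled 1,
#'   the rest 0. Fold scores are pooled per run; runs are averaged.
#' @name evaluation
NULL

#' Pipeline configuration bundle
#'
#' Collects the stage configurations used by the cross-validation driver
#' and the experiment wrappers.
#'
#' @param feature a `feature_config`.
#' @param embed an `sdne_config` (also supplies `d` for the baselines).
#' @param rf an `rf_config`.
#' @param method embedding method: `"sdne"`, `"le"` or `"hope"`.
#' @param threshold score cut-off for the thresholded metrics.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(feature = feature_config(5), embed = sdne_config(),
                            rf = rf_config(),
                            method = c("sdne", "le", "hope"),
                            threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold < 1)
  structure(list(feature = feature, embed = embed, rf = rf, method = method,
                 threshold = threshold),
            class = "pipeline_config")
}

#' Evaluation metrics for scored pairs
#'
#' AUC is computed from the rank statistic (ties share averaged ranks),
#' AUPR by the step-wise average-precision estimator (no interpolation),
#' and the five thresholded metrics from the confusion matrix at
#' `score >= threshold`. When no pair is called positive, precision and F1
#' are defined as 0 with a warning.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold cut-off for the thresholded metrics (default 0.5).
#' @return a named numeric `metric_set`: AUPR, AUC, F1, ACC, REC, SPEC,
#'   PRE, with the threshold as an attribute.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  NN <- sum(labels == 0)
  if (P == 0 || NN == 0) stop("labels contain a single class", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * NN)
  # average precision over distinct score thresholds (descending)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  cut <- c(which(diff(s) != 0), length(s))
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / P
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  acc <- (TP + TN) / length(labels)
  recall <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  if (TP + FP == 0) {
    warning("no pair scored above threshold; PRE and F1 set to 0",
            call. = FALSE)
    pre <- 0; f1 <- 0
  } else {
    pre <- TP / (TP + FP)
    f1 <- if (pre + recall == 0) 0 else 2 * pre * recall / (pre + recall)
  }
  structure(c(AUPR = aupr, AUC = auc, F1 = f1, ACC = acc, REC = recall,
              SPEC = spec, PRE = pre),
            threshold = threshold, class = "metric_set")
}

#' Split positives into five folds
#'
#' Randomly permutes the positive pairs under `seed` and chunks them into
#' five near-equal held-out subsets (sizes differ by at most one). Each
#' fold carries the training matrix with its held-out cells zeroed.
#'
#' @param A m x n binary association matrix.
#' @param seed RNG seed for the permutation.
#' @param k number of folds (default 5).
#' @return list of folds, each with `held_out` (two-column index matrix)
#'   and `A_train`.
#' @export
five_fold_split <- function(A, seed, k = 5L) {
  pos <- which(A == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (npos < k) stop("need at least one positive per fold", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(npos)
  q <- npos %/% k; r <- npos %% k
  sizes <- c(rep(q + 1L, r), rep(q, k - r))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(f) {
    held <- pos[perm[seq(starts[f], ends[f])], , drop = FALSE]
    A_train <- A
    A_train[held] <- 0L
    list(fold = f, held_out = held, A_train = A_train)
  })
}

embed_for_fold <- function(A_train, cfgs) {
  if (!cfgs$feature$use_embedding) return(NULL)
  m <- nrow(A_train); n <- ncol(A_train)
  G <- matrix(0L, m + n, m + n)
  G[seq_len(m), m + seq_len(n)] <- A_train
  G[m + seq_len(n), seq_len(m)] <- t(A_train)
  embed_network(G, cfgs$method, cfgs$embed)
}

#' Evaluate one cross-validation fold
#'
#' Retrains the embedding on the fold's training graph, rebuilds pair
#' features, trains the forest (positives = remaining associations,
#' negatives = full complement), and scores every pair that is 0 in the
#' training matrix — the held-out positives among them labeled 1.
#'
#' @param fold a fold from [five_fold_split()].
#' @param Z,SS feature source matrices.
#' @param cfgs a `pipeline_config`.
#' @return data frame with columns `i`, `j`, `score`, `label`.
#' @export
evaluate_fold <- function(fold, Z, SS, cfgs) {
  NE <- embed_for_fold(fold$A_train, cfgs)
  feats <- build_training_set(fold$A_train, Z, SS, NE, cfgs$feature)
  model <- train_rf(feats, cfgs$rf)
  eval_rows <- which(feats$labels == 0L)
  scores <- predict_scores(model, feats$X[eval_rows, , drop = FALSE])
  pairs <- feats$pairs[eval_rows, , drop = FALSE]
  n <- ncol(fold$A_train)
  held_key <- (fold$held_out[, 1] - 1L) * n + fold$held_out[, 2]
  key <- (pairs[, 1] - 1L) * n + pairs[, 2]
  data.frame(i = pairs[, 1], j = pairs[, 2], score = scores,
             label = as.integer(key %in% held_key))
}

#' Run repeated five-fold cross-validation
#'
#' For each run the positives are re-split, each fold is evaluated with
#' the embedding retrained on its training graph, fold scores are pooled
#' into one score/label set per run, and the seven metrics are computed on
#' the pooled set. Per-run seeds are `seed + run`; the embedding and
#' forest inherit the run seed so the whole experiment is reproducible
#' from the master seed alone.
#'
#' @param data list with `A` (association matrix), `Z`, `SS`.
#' @param cfgs a `pipeline_config`.
#' @param runs number of cross-validation repetitions (default 10).
#' @param seed master seed.
#' @param keep_pooled keep the pooled per-run score frames (needed for
#'   per-disease metrics).
#' @return an `experiment_result`: `per_run` metric data frame, `summary`
#'   (mean and sd per metric), and optionally `pooled` frames.
#' @export
run_cv <- function(data, cfgs = pipeline_config(), runs = 10L, seed = 1L,
                   keep_pooled = FALSE) {
  per_run <- vector("list", runs)
  pooled_frames <- if (keep_pooled) vector("list", runs) else NULL
  for (run in seq_len(runs)) {
    run_seed <- seed + run
    cfgs_run <- cfgs
    cfgs_run$embed$seed <- run_seed
    cfgs_run$rf$seed <- run_seed
    folds <- five_fold_split(data$A, run_seed)
    pooled <- do.call(rbind, lapply(folds, evaluate_fold, Z = data$Z,
                                    SS = data$SS, cfgs = cfgs_run))
    per_run[[run]] <- compute_metrics(pooled$score, pooled$label,
                                      cfgs$threshold)
    if (keep_pooled) pooled_frames[[run]] <- pooled
  }
  metrics <- do.call(rbind, lapply(per_run, unclass))
  per_run_df <- data.frame(run = seq_len(runs), metrics)
  summary <- data.frame(metric = colnames(metrics),
                        mean = colMeans(metrics),
                        sd = apply(metrics, 2, stats::sd),
                        row.names = NULL)
  structure(list(per_run = per_run_df, summary = summary,
                 pooled = pooled_frames, runs = runs, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d run(s) of 5-fold CV (seed %d)\n",
              x$runs, x$seed))
  s <- x$summary
  cat(paste(sprintf("  %-5s %.4f +/- %.4f", s$metric, s$mean, s$sd),
            collapse = "\n"), "\n")
  invisible(x)
}

remove_positives <- function(A, fraction, seed) {
  pos <- which(A == 1, arr.ind = TRUE)
  n_remove <- round(fraction * nrow(pos))
  if (n_remove >= nrow(pos)) stop("removal would empty the positives",
                                  call. = FALSE)
  if (n_remove == 0L) return(list(A = A, removed = pos[0, , drop = FALSE]))
  set.seed(seed)
  idx <- sample.int(nrow(pos), n_remove)
  removed <- pos[idx, , drop = FALSE]
  A2 <- A
  A2[removed] <- 0L
  list(A = A2, removed = removed)
}

#' Sparsification experiment
#'
#' Removes a fraction of the known associations (seeded), then reruns the
#' full cross-validation on the reduced dataset, for each fraction.
#' Fraction 0 reduces to plain [run_cv()].
#'
#' @param data list with `A`, `Z`, `SS`.
#' @param fractions fractions of positives to remove, each in \[0, 1).
#' @param cfgs a `pipeline_config`.
#' @param runs,seed as in [run_cv()].
#' @return named list of `experiment_result`, one per fraction.
#' @export
sparsification_experiment <- function(data, fractions = c(0.1, 0.2, 0.3),
                                      cfgs = pipeline_config(), runs = 10L,
                                      seed = 1L) {
  stopifnot(all(fractions >= 0), all(fractions < 1))
  out <- lapply(seq_along(fractions), function(k) {
    red <- remove_positives(data$A, fractions[k], seed + 1000L * k)
    data_k <- data
    data_k$A <- red$A
    run_cv(data_k, cfgs, runs = runs, seed = seed)
  })
  names(out) <- paste0(round(100 * fractions), "%")
  out
}

#' Train a scorer on the full known-association set
#'
#' Fits the embedding + forest pipeline on the given association matrix
#' and returns a closure that scores arbitrary (miRNA, disease) index
#' pairs. Used by the recovery experiment, candidate ranking, and
#' permutation baselines.
#'
#' @param data list with `A`, `Z`, `SS`.
#' @param cfgs a `pipeline_config`.
#' @param seed seed for the embedding and forest.
#' @return `function(pairs)` mapping a two-column index matrix to scores.
#' @export
pair_scorer <- function(data, cfgs = pipeline_config(), seed = 1L) {
  cfgs$embed$seed <- seed
  cfgs$rf$seed <- seed
  fit_pair_scorer(data$A, data$Z, data$SS, cfgs)
}

fit_pair_scorer <- function(A, Z, SS, cfgs) {
  NE <- if (cfgs$feature$use_embedding) {
    embed_for_fold(A, cfgs)
  } else NULL
  feats <- build_training_set(A, Z, SS, NE, cfgs$feature)
  model <- train_rf(feats, cfgs$rf)
  n <- ncol(A)
  function(pairs) {
    rows <- (pairs[, 1] - 1L) * n + pairs[, 2]
    predict_scores(model, feats$X[rows, , drop = FALSE])
  }
}

#' Association recovery experiment
#'
#' Removes a fraction of the known associations, trains one model on the
#' remaining positives (negatives = full complement), scores the removed
#' pairs, and reports the fraction recovered (scored at or above the
#' threshold) — a recall on deliberately hidden links.
#'
#' @param data list with `A`, `Z`, `SS`.
#' @param fractions fractions of positives to remove, each in (0, 1).
#' @param cfgs a `pipeline_config`.
#' @param threshold recovery score cut-off (default 0.5).
#' @param seed RNG seed for the removals and model.
#' @param scorer optional replacement scoring function
#'   `function(pairs) -> scores` (used by oracle tests); default is the
#'   full pipeline.
#' @return data frame with `fraction`, `n_removed`, `REC`, and the removed
#'   pairs with their scores as an attribute `details`.
#' @export
recovery_experiment <- function(data, fractions = c(0.1, 0.2, 0.3),
                                cfgs = pipeline_config(), threshold = 0.5,
                                seed = 1L, scorer = NULL) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  details <- vector("list", length(fractions))
  rec <- numeric(length(fractions))
  n_removed <- integer(length(fractions))
  for (k in seq_along(fractions)) {
    red <- remove_positives(data$A, fractions[k], seed + 1000L * k)
    sc <- if (is.null(scorer)) {
      cfgs_k <- cfgs
      cfgs_k$embed$seed <- seed + k
      cfgs_k$rf$seed <- seed + k
      fit_pair_scorer(red$A, data$Z, data$SS, cfgs_k)
    } else scorer
    scores <- sc(red$removed)
    rec[k] <- mean(scores >= threshold)
    n_removed[k] <- nrow(red$removed)
    details[[k]] <- data.frame(i = red$removed[, 1], j = red$removed[, 2],
                               score = scores)
  }
  out <- data.frame(fraction = fractions, n_removed = n_removed, REC = rec)
  attr(out, "details") <- details
  out
}

#' Per-disease metrics from pooled cross-validation output
#'
#' Restricts a pooled score/label frame to the pairs of one disease
#' (column index) and recomputes the metric set there. Diseases without a
#' held-out positive in the pooled set have undefined metrics and return
#' `NULL` with a message.
#'
#' @param pooled data frame from [evaluate_fold()] / `run_cv(...,
#'   keep_pooled = TRUE)`.
#' @param disease disease column index.
#' @param threshold cut-off for the thresholded metrics.
#' @return a `metric_set`, or `NULL` when undefined.
#' @export
per_disease_metrics <- function(pooled, disease, threshold = 0.5) {
  sub <- pooled[pooled$j == disease, , drop = FALSE]
  if (nrow(sub) == 0L || sum(sub$label) == 0L) {
    message("no held-out positives for disease ", disease,
            "; metrics undefined")
    return(NULL)
  }
  compute_metrics(sub$score, sub$label, threshold)
}

#' Rank candidate associations
#'
#' Trains on the complete known-association set and scores every unknown
#' pair (0-cell), optionally restricted to one disease. Candidates are
#' sorted by descending score with ties broken lexicographically by
#' (miRNA id, disease id); the top `k` are returned.
#'
#' @param data list with `A`, `Z`, `SS`, `mirna_ids`, `disease_ids`.
#' @param cfgs a `pipeline_config`.
#' @param k number of candidates to return (0 gives an empty frame; more
#'   than available returns all).
#' @param disease optional disease id restricting candidates to one
#'   column.
#' @param seed seed for the embedding and forest.
#' @return data frame with `mirna`, `disease`, `score`, `rank`.
#' @export
rank_candidates <- function(data, cfgs = pipeline_config(), k = 10L,
                            disease = NULL, seed = 1L) {
  cfgs$embed$seed <- seed
  cfgs$rf$seed <- seed
  scorer <- fit_pair_scorer(data$A, data$Z, data$SS, cfgs)
  cand <- which(data$A == 0, arr.ind = TRUE)
  if (!is.null(disease)) {
    jd <- match(disease, data$disease_ids)
    if (is.na(jd)) stop("unknown disease: ", disease, call. = FALSE)
    cand <- cand[cand[, 2] == jd, , drop = FALSE]
  }
  scores <- scorer(cand)
  mid <- data$mirna_ids[cand[, 1]]
  did <- data$disease_ids[cand[, 2]]
  ord <- order(-scores, mid, did, method = "radix")
  k <- min(k, length(ord))
  take <- ord[seq_len(k)]
  data.frame(mirna = mid[take], disease = did[take], score = scores[take],
             rank = seq_len(k), stringsAsFactors = FALSE)
}
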