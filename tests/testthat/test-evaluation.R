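test_that("metrics match hand computations and null behaviour", {
  m <- compute_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(unname(m["AUC"]), 0.75)
  perfect <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(perfect["AUC"]), 1)
  expect_equal(unname(perfect["AUPR"]), 1)
  set.seed(31)
  null <- compute_metrics(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(unname(null["AUC"]), 0.5, tolerance = 0.05)
  expect_error(compute_metrics(runif(5), rep(1, 5)), "single class")
  expect_warning(z <- compute_metrics(c(0.1, 0.2), c(0, 1), threshold = 0.9),
                 "PRE and F1")
  expect_equal(unname(z[c("PRE", "F1")]), c(0, 0))
})

test_that("rank-based AUC and thresholded metrics equal brute-force oracles", {
  set.seed(32)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    m <- suppressWarnings(compute_metrics(scores, labels))
    expect_equal(unname(m["AUC"]), brute_auc(scores, labels),
                 tolerance = 1e-10)
    bc <- brute_confusion(scores, labels)
    expect_equal(unname(m[names(bc)]), unname(bc), tolerance = 1e-12)
  }
  # independent library cross-check on a few continuous-score sets
  for (rep in 1:5) {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.3)
    if (length(unique(labels)) < 2) next
    m <- suppressWarnings(compute_metrics(scores, labels))
    ref <- suppressMessages(pROC::auc(labels, scores,
                                      direction = "<", quiet = TRUE))
    expect_equal(unname(m["AUC"]), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("five-fold splits partition the positives into near-equal folds", {
  set.seed(33)
  A <- matrix(0L, 8, 6)
  A[sample(48, 17)] <- 1L
  folds <- five_fold_split(A, seed = 2)
  sizes <- vapply(folds, function(f) nrow(f$held_out), 0L)
  expect_equal(sum(sizes), 17L)
  expect_lte(diff(range(sizes)), 1L)
  keys <- unlist(lapply(folds, function(f)
    paste(f$held_out[, 1], f$held_out[, 2])))
  expect_equal(sort(keys), sort(paste(which(A == 1, arr.ind = TRUE)[, 1],
                                      which(A == 1, arr.ind = TRUE)[, 2])))
  expect_equal(anyDuplicated(keys), 0L)
  for (f in folds) {
    expect_equal(sum(f$A_train), sum(A) - nrow(f$held_out))
    expect_true(all(f$A_train[f$held_out] == 0L))
  }
  # ten positives give five folds of two
  A2 <- matrix(0L, 5, 4); A2[1:10] <- 1L
  expect_equal(vapply(five_fold_split(A2, 1), function(f) nrow(f$held_out), 0L),
               rep(2L, 5))
  expect_error(five_fold_split(matrix(c(1L, rep(0L, 8)), 3, 3), 1),
               "at least one positive")
})

test_that("fold evaluation scores exactly the complement of the training positives", {
  inp <- small_inputs()
  cfgs <- small_cfgs()
  fold <- five_fold_split(inp$A, seed = 3)[[1]]
  out <- evaluate_fold(fold, inp$Z, inp$SS, cfgs)
  expect_equal(nrow(out), length(inp$A) - sum(fold$A_train))
  expect_equal(sum(out$label), nrow(fold$held_out))
  held_keys <- paste(fold$held_out[, 1], fold$held_out[, 2])
  out_keys <- paste(out$i[out$label == 1], out$j[out$label == 1])
  expect_setequal(out_keys, held_keys)
  expect_true(all(out$score >= 0 & out$score <= 1))
})

test_that("repeated cross-validation is reproducible from the master seed", {
  inp <- small_inputs()
  cfgs <- small_cfgs()
  r1 <- run_cv(inp, cfgs, runs = 2, seed = 5)
  r2 <- run_cv(inp, cfgs, runs = 2, seed = 5)
  expect_identical(r1$per_run, r2$per_run)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$per_run), 2L)
  expect_true(all(c("AUPR", "AUC", "F1", "ACC", "REC", "SPEC", "PRE")
                  %in% names(r1$per_run)))
  r3 <- run_cv(inp, cfgs, runs = 2, seed = 6)
  expect_false(identical(r1$per_run$AUC, r3$per_run$AUC))
})

test_that("sparsification removes the requested share and reduces to plain CV at zero", {
  inp <- small_inputs()
  cfgs <- small_cfgs()
  red <- mirdnet:::remove_positives(inp$A, 0.2, seed = 9)
  expect_equal(nrow(red$removed), round(0.2 * sum(inp$A)))
  expect_equal(sum(red$A), sum(inp$A) - nrow(red$removed))
  res0 <- sparsification_experiment(inp, fractions = 0, cfgs = cfgs,
                                    runs = 1, seed = 4)
  plain <- run_cv(inp, cfgs, runs = 1, seed = 4)
  expect_identical(res0[[1]]$per_run, plain$per_run)
  expect_error(mirdnet:::remove_positives(inp$A, 0.999999, 1), "empty")
})

test_that("recovery recall responds to the plugged-in scorer", {
  inp <- small_inputs()
  all_one <- function(pairs) rep(1, nrow(pairs))
  all_zero <- function(pairs) rep(0, nrow(pairs))
  r1 <- recovery_experiment(inp, fractions = 0.2, scorer = all_one, seed = 2)
  expect_equal(r1$REC, 1)
  expect_equal(r1$n_removed, round(0.2 * sum(inp$A)))
  r0 <- recovery_experiment(inp, fractions = 0.2, scorer = all_zero, seed = 2)
  expect_equal(r0$REC, 0)
})

test_that("per-disease metrics restrict the pooled evaluation set", {
  inp <- small_inputs()
  cfgs <- small_cfgs()
  res <- run_cv(inp, cfgs, runs = 1, seed = 8, keep_pooled = TRUE)
  pooled <- res$pooled[[1]]
  j <- pooled$j[pooled$label == 1][1]
  sub <- pooled[pooled$j == j, ]
  m <- suppressWarnings(per_disease_metrics(pooled, j))
  expect_s3_class(m, "metric_set")
  expect_equal(unname(m["AUC"]),
               suppressWarnings(unname(compute_metrics(sub$score,
                                                       sub$label)["AUC"])))
  # a disease with no held-out positives yields NULL
  empty_j <- setdiff(seq_len(ncol(inp$A)), unique(pooled$j[pooled$label == 1]))
  if (length(empty_j) > 0) {
    expect_message(out <- per_disease_metrics(pooled, empty_j[1]),
                   "undefined")
    expect_null(out)
  }
})

test_that("candidate ranking excludes known pairs and recovers a planted link", {
  inp <- small_inputs(seed = 3, p_in = 0.9, p_out = 0.02)
  # withhold one planted in-block association
  pos <- which(inp$A == 1, arr.ind = TRUE)
  inblock <- pos[inp$blocks$mirna[pos[, 1]] == inp$blocks$disease[pos[, 2]], ,
                 drop = FALSE]
  hide <- inblock[1, ]
  inp$A[hide[1], hide[2]] <- 0L
  cfgs <- small_cfgs()
  expect_equal(nrow(rank_candidates(inp, cfgs, k = 0, seed = 2)), 0L)
  all_ranked <- rank_candidates(inp, cfgs, k = 1e6, seed = 2)
  expect_equal(nrow(all_ranked), sum(inp$A == 0))
  known <- paste(inp$mirna_ids[pos[, 1]], inp$disease_ids[pos[, 2]])
  known <- setdiff(known, paste(inp$mirna_ids[hide[1]],
                                inp$disease_ids[hide[2]]))
  expect_false(any(paste(all_ranked$mirna, all_ranked$disease) %in% known))
  # descending scores with lexical tie-break
  ord <- order(-all_ranked$score, all_ranked$mirna, all_ranked$disease,
               method = "radix")
  expect_equal(ord, seq_len(nrow(all_ranked)))
  hidden_rank <- which(all_ranked$mirna == inp$mirna_ids[hide[1]] &
                         all_ranked$disease == inp$disease_ids[hide[2]])
  expect_lte(hidden_rank, ceiling(0.05 * nrow(all_ranked)))
})
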