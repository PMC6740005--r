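#' @title Random-forest pair classifier
#' @description Pairs are classified by a probability random forest
#'   (implemented by the `ranger` package, single-threaded for
#'   reproducibility). The weighted variant assigns each class label the
#'   weight `n_samples / (2 * n_i)`, halving the total weight between the
#'   two classes regardless of their imbalance.
#' @name classifier
NULL

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 350).
#' @param seed RNG seed for bootstrap and split sampling.
#' @param class_weighting `"uniform"` (conventional forest) or
#'   `"balanced_half"` (class weights `n_samples / (2 * n_i)`).
#' @param mtry features tried per split; default `sqrt(width)`.
#' @return an `rf_config`.
#' @export
rf_config <- function(n_trees = 350L, seed = 1L,
                      class_weighting = c("uniform", "balanced_half"),
                      mtry = NULL) {
  class_weighting <- match.arg(class_weighting)
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = n_trees, seed = as.integer(seed),
                 class_weighting = class_weighting, mtry = mtry),
            class = "rf_config")
}

#' Class weights halving total weight between classes
#'
#' `w_i = n_samples / (2 * n_i)` for labels i in \{0, 1\}; balanced labels
#' give unit weights.
#'
#' @param labels 0/1 vector with both classes present.
#' @return named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
compute_class_weights <- function(labels) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present", call. = FALSE)
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Train the pair classifier
#'
#' Fits a probability forest of `cfg$n_trees` trees on the pair feature
#' matrix, with bootstrap samples per tree and random feature subsets per
#' node. Under `"balanced_half"` weighting the class weights enter the
#' split impurity and reweight the predicted label probabilities at
#' scoring time; with uniform weights both effects vanish, so the
#' weighted path with equal weights is exactly the conventional forest.
#'
#' @param features a `pair_features` (or list with `X` and `labels`).
#' @param cfg an `rf_config`.
#' @return an `rf_model` wrapping the fitted forest.
#' @export
train_rf <- function(features, cfg = rf_config()) {
  X <- features$X
  y <- features$labels
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  weights <- if (cfg$class_weighting == "balanced_half") {
    compute_class_weights(y)
  } else {
    c("0" = 1, "1" = 1)
  }
  fit <- ranger::ranger(
    x = as.data.frame(X),
    y = factor(y, levels = c("0", "1")),
    num.trees = cfg$n_trees,
    mtry = cfg$mtry,
    probability = TRUE,
    class.weights = weights,
    seed = cfg$seed,
    num.threads = 1L,
    verbose = FALSE
  )
  structure(list(fit = fit, width = ncol(X), cfg = cfg, weights = weights),
            class = "rf_model")
}

#' Score pairs with a trained classifier
#'
#' Returns the mean over trees of the per-tree class-1 probability; under
#' `"balanced_half"` weighting the label probabilities are reweighted by
#' the class weights (`w1 p / (w1 p + w0 (1 - p))`) so that the output
#' label votes, not just the split impurity, carry the weights. Scores
#' lie in \[0, 1\] and read as predicted association confidence.
#'
#' @param model an `rf_model`.
#' @param features a `pair_features` or feature matrix of matching width.
#' @return numeric score vector.
#' @export
predict_scores <- function(model, features) {
  X <- if (is.matrix(features)) features else features$X
  if (ncol(X) != model$width) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(X), model$width), call. = FALSE)
  }
  pred <- stats::predict(model$fit, data = as.data.frame(X),
                         num.threads = 1L, verbose = FALSE)
  p <- unname(pred$predictions[, "1"])
  w <- model$weights
  if (w["0"] != w["1"]) {
    p <- w["1"] * p / (w["1"] * p + w["0"] * (1 - p))
  }
  unname(p)
}
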