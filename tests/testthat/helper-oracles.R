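# Independent oracles and tiny fixtures shared across the suite.

# AUC by exhaustive concordant-pair counting (ties count one half)
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# thresholded metrics straight from the confusion matrix definitions
brute_confusion <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred & labels); FP <- sum(pred & !labels)
  TN <- sum(!pred & !labels); FN <- sum(!pred & labels)
  pre <- if (TP + FP == 0) 0 else TP / (TP + FP)
  rec <- TP / (TP + FN)
  c(ACC = (TP + TN) / length(labels), REC = rec,
    SPEC = TN / (TN + FP), PRE = pre,
    F1 = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec))
}

# random ancestor DAG in edge-list form: node 1 is the target, every later
# node keeps at least one child with a smaller index, so all nodes reach
# the target and the graph is acyclic
random_dag <- function(n_nodes, delta = 0.5) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  parent <- character(); child <- character()
  for (i in seq(2, n_nodes)) {
    kids <- sample.int(i - 1L, size = min(i - 1L, sample(1:2, 1)))
    parent <- c(parent, rep(ids[i], length(kids)))
    child <- c(child, ids[kids])
  }
  structure(list(target = ids[1],
                 nodes = sort(ids, method = "radix"),
                 edges = data.frame(parent = parent, child = child,
                                    stringsAsFactors = FALSE),
                 delta = delta),
            class = "disease_dag")
}

# shortest downward path length (in edges) from d to the DAG target
bfs_depth <- function(dag, d) {
  if (d == dag$target) return(0L)
  children_of <- split(dag$edges$child, dag$edges$parent)
  depth <- 0L
  frontier <- d
  seen <- character()
  while (length(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    if (dag$target %in% nxt) return(depth)
    seen <- c(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  NA_integer_
}

# contribution by exhaustive enumeration of downward paths: max delta^len
path_enum_contribution <- function(dag, d) {
  if (d == dag$target) return(1)
  children_of <- split(dag$edges$child, dag$edges$parent)
  best <- -Inf
  walk <- function(node, len) {
    if (node == dag$target) {
      best <<- max(best, dag$delta^len)
      return(invisible())
    }
    for (ch in children_of[[node]]) walk(ch, len + 1L)
  }
  walk(d, 0L)
  best
}

# random tree-number ontology over `n` diseases with shared random prefixes
random_tree_ontology <- function(n, max_depth = 4L) {
  roots <- c("A01", "B02", "C03")
  tn <- lapply(seq_len(n), function(j) {
    k <- sample(1:2, 1)
    vapply(seq_len(k), function(q) {
      depth <- sample.int(max_depth, 1)
      segs <- c(sample(roots, 1),
                if (depth > 1) sprintf("s%d", sample.int(3, depth - 1L,
                                                         replace = TRUE)))
      paste(c(segs, sprintf("d%02d", j)), collapse = ".")
    }, "")
  })
  names(tn) <- sprintf("dis%02d", seq_len(n))
  disease_ontology(tree_numbers = tn)
}

# small, strongly structured dataset + fast pipeline config for protocol
# tests (not the acceptance study conditions)
small_inputs <- function(seed = 1L, p_in = 0.8, p_out = 0.05) {
  synthetic_inputs(synthetic_config(m = 12L, n = 8L, t = 2L, n_blocks = 2L,
                                    p_in = p_in, p_out = p_out,
                                    family_purity = 1, dag_depth = 3L,
                                    seed = seed))
}

small_cfgs <- function(combo = 5L, n_trees = 60L, epochs = 150L) {
  pipeline_config(feature = feature_config(combo),
                  embed = sdne_config(d = 4L, hidden_layers = c(8L, 4L),
                                      epochs = epochs, alpha = 1),
                  rf = rf_config(n_trees = n_trees))
}

# the frozen desk-scale study configuration used by the acceptance checks
study_inputs <- function(seed = 1L) {
  synthetic_inputs(synthetic_config(seed = seed))
}

study_cfgs <- function(combo = 5L, class_weighting = "uniform") {
  pipeline_config(feature = feature_config(combo),
                  embed = sdne_config(d = 8L, hidden_layers = c(32L, 8L),
                                      alpha = 1, epochs = 2000L),
                  rf = rf_config(n_trees = 350L,
                                 class_weighting = class_weighting))
}
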