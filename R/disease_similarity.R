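#' @title MeSH-style DAG semantic similarity between diseases
#' @description Each disease is represented by the directed acyclic graph of
#'   its ontology ancestors. An ancestor's semantic contribution decays by a
#'   factor delta per hierarchy level below it, and two diseases are similar
#'   in proportion to the summed contributions of their shared ancestors.
#' @name disease_similarity
NULL

# proper dot-prefixes of a tree code: "C04.588.123" -> "C04", "C04.588"
code_prefixes <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(character())
  vapply(seq_len(length(parts) - 1L),
         function(k) paste(parts[seq_len(k)], collapse = "."), "")
}

# code -> owning disease id; codes claimed by several diseases resolve to the
# radix-first owner, codes owned by no dataset disease keep the code string
# itself as node identity (contributions still flow through them).
code_owner_map <- function(onto) {
  codes <- unlist(onto$tree_numbers, use.names = FALSE)
  owners <- rep(names(onto$tree_numbers),
                vapply(onto$tree_numbers, length, 1L))
  ord <- order(codes, owners, method = "radix")
  codes <- codes[ord]
  owners <- owners[ord]
  keep <- !duplicated(codes)
  stats::setNames(owners[keep], codes[keep])
}

#' Build the ancestor DAG of a disease
#'
#' In tree-number mode every proper dot-prefix of each of the disease's
#' codes becomes an ancestor node (identified by the disease owning that
#' code, or by the code string when no disease in the ontology owns it),
#' with parent-to-child edges between consecutive prefix levels; DAGs from
#' multiple codes are merged into one node set. In edge-list mode the DAG
#' is the ancestor closure of the disease under the parent-to-child edges.
#'
#' @param disease disease identifier.
#' @param onto a `disease_ontology`.
#' @param delta per-level contribution decay in (0, 1]; default 0.5.
#' @return a `disease_dag` with fields `target`, `nodes`, `edges`
#'   (two-column parent/child data frame) and `delta`.
#' @export
build_dag <- function(disease, onto, delta = 0.5) {
  stopifnot(delta > 0, delta <= 1)
  if (!ontology_has(onto, disease)) {
    stop("disease has no ontology record: ", disease, call. = FALSE)
  }
  if (onto$mode == "tree") {
    owner <- code_owner_map(onto)
    node_of <- function(code) {
      o <- owner[code]
      ifelse(is.na(o), code, o)
    }
    parents <- character()
    children <- character()
    for (code in onto$tree_numbers[[disease]]) {
      chain <- c(code_prefixes(code), code)
      ids <- unname(node_of(chain))
      ids[length(ids)] <- disease  # leaf is the target itself
      if (length(ids) > 1L) {
        parents <- c(parents, ids[-length(ids)])
        children <- c(children, ids[-1L])
      }
    }
    keep <- parents != children            # same owner at adjacent levels
    edges <- unique(data.frame(parent = parents[keep],
                               child = children[keep],
                               stringsAsFactors = FALSE))
    nodes <- sort_ids(c(disease, edges$parent, edges$child))
  } else {
    # reverse reachability: all nodes with a directed path down to `disease`
    parent_of <- split(onto$edges$parent, onto$edges$child)
    nodes <- disease
    frontier <- disease
    while (length(frontier) > 0L) {
      up <- unique(unlist(parent_of[frontier], use.names = FALSE))
      up <- setdiff(up, nodes)
      nodes <- c(nodes, up)
      frontier <- up
    }
    nodes <- sort_ids(nodes)
    keep <- onto$edges$parent %in% nodes & onto$edges$child %in% nodes
    edges <- onto$edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
    assert_acyclic(nodes, edges)
  }
  structure(list(target = disease, nodes = nodes, edges = edges,
                 delta = delta),
            class = "disease_dag")
}

assert_acyclic <- function(nodes, edges) {
  # Kahn's algorithm; leftover nodes imply a cycle
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out_of <- split(edges$child, edges$parent)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in out_of[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) stop("cycle detected in ontology edge list",
                                 call. = FALSE)
  invisible(TRUE)
}

# contributions of every DAG node to the target, by memoized recursion:
# S(target) = 1, S(d) = max over DAG children d' of delta * S(d')
dag_contributions <- function(dag) {
  children_of <- split(dag$edges$child, dag$edges$parent)
  memo <- new.env(parent = emptyenv())
  assign(dag$target, 1, envir = memo)
  rec <- function(d) {
    if (!is.null(got <- memo[[d]])) return(got)
    ch <- children_of[[d]]
    if (is.null(ch)) stop("node without a path to the target: ", d,
                          call. = FALSE)
    val <- dag$delta * max(vapply(ch, rec, 0))
    assign(d, val, envir = memo)
    val
  }
  stats::setNames(vapply(dag$nodes, rec, 0), dag$nodes)
}

#' Semantic contribution of a DAG node to the target disease
#'
#' The target contributes 1 to itself; any ancestor `d` contributes
#' `delta` times the largest contribution among its children inside the
#' DAG, i.e. `delta^k` where `k` is the length of the shortest directed
#' path from `d` down to the target.
#'
#' @param dag a `disease_dag`.
#' @param d a node of the DAG.
#' @return a score in (0, 1].
#' @export
semantic_contribution <- function(dag, d) {
  if (!d %in% dag$nodes) stop("node not in DAG: ", d, call. = FALSE)
  unname(dag_contributions(dag)[d])
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of all DAG nodes; at least 1 because
#' the target contributes 1 to itself.
#'
#' @param dag a `disease_dag`.
#' @return a scalar >= 1.
#' @export
semantic_value <- function(dag) {
  sum(dag_contributions(dag))
}

#' Semantic similarity between two diseases
#'
#' Shared-ancestor similarity: the contributions of every node present in
#' both DAGs are summed from each side and normalized by the two semantic
#' values, giving a value in \[0, 1\] that is 1 for identical diseases and
#' 0 when the ancestor sets are disjoint.
#'
#' @param dag_i,dag_j `disease_dag` objects built with the same `delta`.
#' @return similarity in \[0, 1\].
#' @export
semantic_similarity <- function(dag_i, dag_j) {
  stopifnot(dag_i$delta == dag_j$delta)
  si <- dag_contributions(dag_i)
  sj <- dag_contributions(dag_j)
  common <- intersect(dag_i$nodes, dag_j$nodes)
  (sum(si[common]) + sum(sj[common])) / (sum(si) + sum(sj))
}

#' Pairwise semantic similarity matrix
#'
#' Builds one DAG per disease and fills the symmetric n x n matrix `SS`
#' with unit diagonal.
#'
#' @param diseases character vector of disease identifiers (output order).
#' @param onto a `disease_ontology` covering every disease.
#' @param delta contribution decay, default 0.5.
#' @return a `similarity_matrix`: list with `disease_ids` and `SS`.
#' @export
similarity_matrix <- function(diseases, onto, delta = 0.5) {
  dags <- lapply(diseases, build_dag, onto = onto, delta = delta)
  contr <- lapply(dags, dag_contributions)
  sv <- vapply(contr, sum, 0)
  n <- length(diseases)
  SS <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        common <- intersect(dags[[i]]$nodes, dags[[j]]$nodes)
        SS[i, j] <- SS[j, i] <-
          (sum(contr[[i]][common]) + sum(contr[[j]][common])) /
          (sv[i] + sv[j])
      }
    }
  }
  dimnames(SS) <- list(diseases, diseases)
  structure(list(disease_ids = diseases, SS = SS),
            class = "similarity_matrix")
}
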