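#' @title Association dataset construction and filtering
#' @description Loaders for the three flat input tables (miRNA-disease
#'   associations, miRNA-family memberships, disease ontology records) and
#'   constructors for the binary association matrix and the bipartite
#'   adjacency used by the embedding stage.
#' @name data_model
NULL

# All identifier sorting uses radix order (C locale) so row/column orders are
# reproducible across platforms.
sort_ids <- function(x) sort(unique(x), method = "radix")

read_tsv_body <- function(path, min_fields, header_sentinel) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty input file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- trimws(fields[[1]][1])
  if (grepl(header_sentinel, first, ignore.case = TRUE)) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
    if (length(fields) == 0L) {
      stop("input file contains only a header line: ", path, call. = FALSE)
    }
  }
  bad <- which(vapply(fields, length, 1L) < min_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields",
                 line_no[bad[1]], path, min_fields), call. = FALSE)
  }
  lapply(fields, function(f) trimws(f))
}

new_association_dataset <- function(mirna_ids, disease_ids, A) {
  stopifnot(nrow(A) == length(mirna_ids), ncol(A) == length(disease_ids))
  if (anyDuplicated(mirna_ids) || anyDuplicated(disease_ids)) {
    stop("duplicate identifiers in dataset", call. = FALSE)
  }
  dimnames(A) <- list(mirna_ids, disease_ids)
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids,
                 A = A),
            class = "association_dataset")
}

#' Load a miRNA-disease association edge list
#'
#' Reads a two-column tab-separated edge list (miRNA id, disease id) into an
#' `association_dataset`: sorted unique identifier lists plus the m x n
#' binary association matrix `A` with `A[i, j] = 1` iff the pair appears in
#' the file. An optional single header line is auto-detected by the sentinel
#' "miRNA" in the first field. Duplicate edges are collapsed with a warning;
#' a line with fewer than two fields aborts with its line number.
#'
#' @param path path to a UTF-8 TSV edge list.
#' @return an `association_dataset` with fields `mirna_ids`, `disease_ids`
#'   and `A`.
#' @export
load_associations <- function(path) {
  fields <- read_tsv_body(path, 2L, "miRNA")
  mirna <- vapply(fields, `[`, "", 1L)
  disease <- vapply(fields, `[`, "", 2L)
  key <- paste(mirna, disease, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate association edge(s) removed",
                    sum(duplicated(key))), call. = FALSE)
    keep <- !duplicated(key)
    mirna <- mirna[keep]
    disease <- disease[keep]
  }
  mids <- sort_ids(mirna)
  dids <- sort_ids(disease)
  A <- matrix(0L, length(mids), length(dids))
  A[cbind(match(mirna, mids), match(disease, dids))] <- 1L
  new_association_dataset(mids, dids, A)
}

#' Write an association dataset back to a TSV edge list
#'
#' Emits one `miRNA<TAB>disease` line per 1-cell of `A`, in row-major
#' (miRNA-then-disease) identifier order, with a header line. Together with
#' [load_associations()] this round-trips the deduplicated edge set.
#'
#' @param ds an `association_dataset`.
#' @param path output path.
#' @export
write_associations <- function(ds, path) {
  idx <- which(t(ds$A) == 1L)
  j <- (idx - 1L) %% length(ds$disease_ids) + 1L
  i <- (idx - 1L) %/% length(ds$disease_ids) + 1L
  lines <- c("miRNA\tdisease",
             paste(ds$mirna_ids[i], ds$disease_ids[j], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load a miRNA-family membership table
#'
#' Reads a `miRNA<TAB>family` TSV (optional header with sentinel "miRNA")
#' into a family table: sorted family identifiers and a binary membership
#' matrix over the miRNAs present in the file. Membership may be
#' many-to-many.
#'
#' @param path path to a UTF-8 TSV membership list.
#' @return a `family_table` with fields `mirna_ids`, `family_ids`, `Z`.
#' @export
load_family <- function(path) {
  fields <- read_tsv_body(path, 2L, "miRNA")
  mirna <- vapply(fields, `[`, "", 1L)
  family <- vapply(fields, `[`, "", 2L)
  mids <- sort_ids(mirna)
  fids <- sort_ids(family)
  Z <- matrix(0L, length(mids), length(fids),
              dimnames = list(mids, fids))
  Z[cbind(match(mirna, mids), match(family, fids))] <- 1L
  structure(list(mirna_ids = mids, family_ids = fids, Z = Z),
            class = "family_table")
}

#' Load disease ontology records
#'
#' Two dialects are supported, selected by `mode`:
#' * `"tree"`: lines `disease<TAB>tree_number` where the tree number is a
#'   dot-separated hierarchy code (several lines per disease allowed);
#' * `"edges"`: lines `parent<TAB>child` giving explicit is-a edges.
#'
#' A single header line is auto-detected (sentinel "disease" or "parent").
#'
#' @param path path to a UTF-8 TSV.
#' @param mode `"tree"` or `"edges"`.
#' @return a `disease_ontology` object.
#' @export
load_ontology <- function(path, mode = c("tree", "edges")) {
  mode <- match.arg(mode)
  fields <- read_tsv_body(path, 2L, if (mode == "tree") "disease" else "parent")
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  if (mode == "tree") {
    tn <- split(b, a)
    tn <- lapply(tn, function(x) sort_ids(x))
    structure(list(mode = "tree", tree_numbers = tn),
              class = "disease_ontology")
  } else {
    keep <- !duplicated(paste(a, b, sep = "\r"))
    structure(list(mode = "edges",
                   edges = data.frame(parent = a[keep], child = b[keep],
                                      stringsAsFactors = FALSE)),
              class = "disease_ontology")
  }
}

#' Construct a disease ontology in code
#'
#' Convenience constructor used by the synthetic generator and tests:
#' either a named list of tree-number character vectors, or a two-column
#' parent/child data frame.
#'
#' @param tree_numbers named list of character vectors (one per disease).
#' @param edges data frame with columns `parent`, `child`.
#' @return a `disease_ontology`.
#' @export
disease_ontology <- function(tree_numbers = NULL, edges = NULL) {
  if (!is.null(tree_numbers)) {
    stopifnot(is.list(tree_numbers), !is.null(names(tree_numbers)))
    structure(list(mode = "tree", tree_numbers = tree_numbers),
              class = "disease_ontology")
  } else if (!is.null(edges)) {
    stopifnot(all(c("parent", "child") %in% names(edges)))
    structure(list(mode = "edges",
                   edges = data.frame(parent = as.character(edges$parent),
                                      child = as.character(edges$child),
                                      stringsAsFactors = FALSE)),
              class = "disease_ontology")
  } else {
    stop("supply tree_numbers or edges", call. = FALSE)
  }
}

ontology_has <- function(onto, disease) {
  if (onto$mode == "tree") {
    d <- onto$tree_numbers[[disease]]
    !is.null(d) && length(d) > 0L
  } else {
    disease %in% onto$edges$parent || disease %in% onto$edges$child
  }
}

#' Filter a dataset to annotated miRNAs and diseases
#'
#' Removes miRNAs without any family membership and diseases without an
#' ontology record, dropping their associations consistently from all three
#' structures, and reports the removal counts. The family matrix is aligned
#' to the filtered miRNA order (rows = dataset miRNAs); its column order is
#' preserved. Filtering is idempotent.
#'
#' @param ds an `association_dataset`.
#' @param fam a `family_table`.
#' @param onto a `disease_ontology`.
#' @return list with elements `dataset`, `family` (aligned `family_table`),
#'   `ontology`, and `removed` (named counts).
#' @export
filter_dataset <- function(ds, fam, onto) {
  fam_rows <- match(ds$mirna_ids, fam$mirna_ids)
  has_family <- !is.na(fam_rows) & rowSums(fam$Z)[fam_rows] > 0
  has_family[is.na(has_family)] <- FALSE
  has_onto <- vapply(ds$disease_ids, ontology_has, TRUE, onto = onto)
  removed <- c(mirnas = sum(!has_family), diseases = sum(!has_onto))
  if (!any(has_family) || !any(has_onto)) {
    stop("filtering removed every miRNA or every disease", call. = FALSE)
  }
  mids <- ds$mirna_ids[has_family]
  dids <- ds$disease_ids[has_onto]
  A <- ds$A[has_family, has_onto, drop = FALSE]
  out_ds <- new_association_dataset(mids, dids, A)
  Z <- fam$Z[match(mids, fam$mirna_ids), , drop = FALSE]
  rownames(Z) <- mids
  out_fam <- structure(list(mirna_ids = mids, family_ids = fam$family_ids,
                            Z = Z),
                       class = "family_table")
  if (removed["mirnas"] + removed["diseases"] > 0) {
    message(sprintf("removed %d unannotated miRNA(s) and %d disease(s)",
                    removed["mirnas"], removed["diseases"]))
  }
  list(dataset = out_ds, family = out_fam, ontology = onto,
       removed = removed)
}

#' Build the bipartite adjacency matrix
#'
#' Forms the symmetric (m+n) x (m+n) adjacency `G = [[0, A], [t(A), 0]]`
#' of the miRNA-disease bipartite network, with miRNAs occupying rows
#' 1..m (sorted id order) and diseases rows m+1..m+n.
#'
#' @param ds an `association_dataset`.
#' @return a `bipartite_adjacency` with fields `G`, `node_order`, `m`, `n`.
#' @export
build_adjacency <- function(ds) {
  m <- length(ds$mirna_ids)
  n <- length(ds$disease_ids)
  G <- matrix(0L, m + n, m + n)
  G[seq_len(m), m + seq_len(n)] <- ds$A
  G[m + seq_len(n), seq_len(m)] <- t(ds$A)
  node_order <- c(ds$mirna_ids, ds$disease_ids)
  dimnames(G) <- list(node_order, node_order)
  structure(list(G = G, node_order = node_order, m = m, n = n),
            class = "bipartite_adjacency")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("association_dataset: %d miRNAs x %d diseases, %d associations\n",
              length(x$mirna_ids), length(x$disease_ids), sum(x$A)))
  invisible(x)
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("family_table: %d miRNAs x %d families, %d memberships\n",
              length(x$mirna_ids), length(x$family_ids), sum(x$Z)))
  invisible(x)
}

#' Write a matrix as a headered TSV
#'
#' Dense export with row names in the first column, for inspection of
#' association, similarity and embedding matrices.
#'
#' @param x a matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
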