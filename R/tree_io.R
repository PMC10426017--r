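#' Read and write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so every tree
#' entering or leaving the pipeline goes through one place.
#'
#' @param path file path.
#' @param tree a `phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("could not parse a tree from '%s'", path))
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Build a tree from a parent-child taxonomy table
#'
#' Converts a taxonomy expressed as parent links — the natural form of
#' genealogical classifications such as language family assignments — into a
#' rooted `phylo` topology without branch lengths. The table must contain one
#' row per non-root node with columns `child_id`, `parent_id`, `is_leaf`, and
#' optionally `label` (defaulting to `child_id` for leaves). The root is the
#' single id appearing as a parent but never as a child.
#'
#' @param taxonomy a data frame with columns `child_id`, `parent_id`,
#'   `is_leaf`, and optionally `label`.
#' @return a rooted `phylo` object whose tip labels are the leaf labels.
#' @export
taxonomy_to_tree <- function(taxonomy) {
  req <- c("child_id", "parent_id", "is_leaf")
  if (!all(req %in% names(taxonomy))) {
    stop("taxonomy table needs columns child_id, parent_id, is_leaf")
  }
  child <- as.character(taxonomy$child_id)
  parent <- as.character(taxonomy$parent_id)
  if (anyDuplicated(child)) stop("duplicate child_id in taxonomy table")
  roots <- setdiff(unique(parent), child)
  if (length(roots) != 1L) {
    stop(sprintf("taxonomy must have exactly one root, found %d", length(roots)))
  }
  root <- roots
  is_leaf <- as.logical(taxonomy$is_leaf)
  labels <- if ("label" %in% names(taxonomy)) as.character(taxonomy$label) else child
  labels[is.na(labels) | labels == ""] <- child[is.na(labels) | labels == ""]

  tips <- child[is_leaf]
  internals <- c(root, child[!is_leaf])
  n <- length(tips)
  if (n < 2L) stop("taxonomy must contain at least two leaves")
  if (anyDuplicated(labels[is_leaf])) stop("leaf labels must be unique")

  ## preorder the internal nodes so the root gets number n + 1
  kids <- split(child, parent)
  ord <- character(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% internals) {
      ord <- c(ord, v)
      stack <- c(kids[[v]] %||% character(0), stack)
    }
  }
  if (!setequal(ord, internals)) stop("taxonomy table is not a connected tree")
  num <- c(seq_len(n), n + seq_along(ord))
  names(num) <- c(tips, ord)
  if (anyNA(num[parent])) stop("a parent_id refers to a leaf node")

  tr <- list(
    edge = cbind(unname(num[parent]), unname(num[child])),
    tip.label = labels[is_leaf][order(num[tips])],
    Nnode = length(ord)
  )
  ## order tip labels by assigned tip number
  tip_order <- order(num[tips])
  tr$tip.label <- labels[is_leaf][tip_order]
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' @rdname taxonomy_to_tree
#' @param path path to a CSV file with the taxonomy columns.
#' @export
read_taxonomy <- function(path) {
  taxonomy_to_tree(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read and write labelled square matrices as CSV
#'
#' Distance, proximity, and connection matrices are serialised as square CSV
#' tables with row labels in the first column and matching column headers.
#'
#' @param M a labelled square numeric matrix.
#' @param path file path.
#' @return `read_matrix_csv` returns the matrix; `write_matrix_csv` returns
#'   `path` invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  assert_square_labelled(M, "matrix")
  utils::write.csv(as.data.frame(M), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  assert_square_labelled(M, "matrix")
  M
}
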