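#' Assign Grafen branch lengths to a rooted tree
#'
#' Implements Grafen's method for turning a rooted topology (possibly with
#' polytomies) into an ultrametric tree: each internal node is given a height
#' equal to the number of leaves in its subtree minus one, heights are scaled
#' so the root sits at 1 and every leaf at 0, and the scaled heights are raised
#' to the power `rho`. The branch length of an edge is the difference between
#' the heights of its parent and child, so every root-to-leaf path sums to 1.
#'
#' @param tree a rooted `phylo` object with at least two leaves. Existing
#'   branch lengths, if any, are discarded.
#' @param rho positive exponent applied to the scaled node heights. `rho = 1`
#'   gives the conventional linear height profile; values below 1 stretch
#'   branches near the root, values above 1 stretch branches near the tips.
#' @return the same tree with `edge.length` set; ultrametric with total height 1.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tr <- grafen_branch_lengths(tr, rho = 1)
#' max(ape::node.depth.edgelength(tr)) # 1
#' @export
grafen_branch_lengths <- function(tree, rho = 1) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("'rho' must be a single positive number")
  }
  n <- length(tree$tip.label)
  if (n < 2L) stop("degenerate tree: fewer than 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")

  n_nodes <- n + tree$Nnode
  leaves_below <- numeric(n_nodes)
  leaves_below[seq_len(n)] <- 1
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    leaves_below[post[k, 1L]] <- leaves_below[post[k, 1L]] + leaves_below[post[k, 2L]]
  }
  height <- ((leaves_below - 1) / (n - 1))^rho
  height[seq_len(n)] <- 0
  tree$edge.length <- height[tree$edge[, 1L]] - height[tree$edge[, 2L]]
  tree
}

#' Cophenetic (patristic) distances between leaves
#'
#' Sums branch lengths along the tree path between every pair of leaves. Rows
#' and columns follow the tree's tip-label order.
#'
#' @param tree a `phylo` object with all branch lengths set.
#' @return a symmetric labelled matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths unset: assign branch lengths first")
  }
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Reverse a distance matrix into a proximity matrix
#'
#' Converts pairwise trait distances into similarities `s_ij` suitable for
#' weighting connection matrices. The default rescales so the most distant
#' pair has proximity 0 and identical traits have proximity 1:
#' `s = 1 - d / d_max`, with `d_max` the maximum off-diagonal distance. The
#' `"unnormalised"` variant uses `s = d_max - d` instead, preserving the
#' original scale.
#'
#' @param D symmetric non-negative labelled distance matrix with zero diagonal.
#' @param method `"normalised"` (default) or `"unnormalised"`.
#' @return a proximity matrix with attributes `proximity_method` set; under
#'   the default, entries lie in `[0, 1]` and the diagonal is 1.
#' @export
distances_to_proximities <- function(D, method = c("normalised", "unnormalised")) {
  method <- match.arg(method)
  assert_square_labelled(D, "distance matrix")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (!is_symmetric_matrix(D)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  off <- D[lower.tri(D)]
  if (length(off) == 0L) stop("distance matrix needs at least two traits")
  d_max <- max(off)
  if (d_max == 0) stop("degenerate distance matrix: all traits identical")
  S <- if (method == "normalised") 1 - D / d_max else d_max - D
  attr(S, "proximity_method") <- paste0("reversed-", method)
  S
}

#' Patristic similarity from tree topology alone
#'
#' Treats every branch as one edge and scores each leaf pair by how deep their
#' most recent common ancestor (MRCA) sits relative to the tree height:
#' `s_ij = (d_r - d_m) / d_r`, where `d_r` is the maximum edge-count path from
#' any leaf to the root (the tree height) and `d_m` is the maximum edge-count
#' path from a leaf descended from the MRCA up to the MRCA. Pairs whose MRCA is
#' the root score 0; a leaf paired with itself scores 1. Branch lengths on the
#' input, if present, are ignored.
#'
#' @param tree a rooted `phylo` object.
#' @return a symmetric labelled similarity matrix in `[0, 1]`, with attribute
#'   `proximity_method = "patristic-unit-branch"`.
#' @export
patristic_similarity <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("degenerate tree: fewer than 2 leaves")
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  depth <- ape::node.depth.edgelength(unit) # edges from root

  ## deepest descendant leaf per node, by postorder accumulation
  n_nodes <- n + tree$Nnode
  max_leaf_depth <- rep(-Inf, n_nodes)
  max_leaf_depth[seq_len(n)] <- depth[seq_len(n)]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1L]; ch <- post[k, 2L]
    if (max_leaf_depth[ch] > max_leaf_depth[p]) max_leaf_depth[p] <- max_leaf_depth[ch]
  }

  d_r <- max(depth[seq_len(n)])
  d_m <- max_leaf_depth - depth # per node: deepest leaf below, in edges from node
  M <- ape::mrca(tree)
  S <- (d_r - matrix(d_m[M], n, n)) / d_r
  dimnames(S) <- list(tree$tip.label, tree$tip.label)
  diag(S) <- 1
  attr(S, "proximity_method") <- "patristic-unit-branch"
  S
}

#' Average a set of distance matrices
#'
#' Entrywise arithmetic mean of distance matrices sharing identical labels and
#' ordering, as used to combine alternative resolutions of horizontal
#' transmission into a single working distance matrix. Cells on which all
#' inputs agree are unchanged.
#'
#' @param matrices a non-empty list of labelled square matrices with identical
#'   dimnames.
#' @return the entrywise mean matrix.
#' @export
average_distance_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("'matrices' must be a non-empty list")
  }
  ref <- matrices[[1L]]
  assert_square_labelled(ref, "distance matrix")
  for (M in matrices[-1L]) {
    assert_square_labelled(M, "distance matrix")
    if (!identical(dimnames(M), dimnames(ref))) {
      stop("label mismatch: all matrices must share identical labels and ordering")
    }
  }
  Reduce(`+`, matrices) / length(matrices)
}
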