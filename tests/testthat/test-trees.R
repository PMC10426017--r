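test_that("Grafen heights scale the root to 1 and leaves to 0, any rho", {
  for (seed in 1:5) {
    n <- sample(5:60, 1)
    tr <- random_test_tree(n, seed)
    for (rho in c(0.5, 1, 2)) {
      g <- grafen_branch_lengths(tr, rho)
      depth <- ape::node.depth.edgelength(g)
      expect_equal(max(depth[seq_len(n)]), 1, tolerance = 1e-12)
      # ultrametric: every root-to-leaf path sums to exactly the tree height
      expect_lt(diff(range(depth[seq_len(n)])), 1e-12)
    }
  }
})

test_that("Grafen branch lengths match the recursive oracle and ape's implementation", {
  for (seed in 1:8) {
    tr <- random_test_tree(sample(5:50, 1), seed + 100)
    rho <- sample(c(0.5, 1, 2), 1)
    g <- grafen_branch_lengths(tr, rho)
    h <- oracle_grafen_heights(tr, rho)
    expect_equal(g$edge.length, h[g$edge[, 1]] - h[g$edge[, 2]], tolerance = 1e-12)
    ref <- ape::compute.brlen(tr, method = "Grafen", power = rho)
    expect_equal(g$edge.length, ref$edge.length, tolerance = 1e-10)
  }
})

test_that("hand-worked Grafen values on small trees", {
  cherry <- grafen_branch_lengths(ape::read.tree(text = "(A,B);"), rho = 1)
  expect_equal(cherry$edge.length, c(1, 1))

  tr <- ape::read.tree(text = "((A,B),(C,D));")
  g <- grafen_branch_lengths(tr, rho = 1)
  depth <- ape::node.depth.edgelength(g)
  n <- 4L
  internal_heights <- 1 - depth[(n + 2):(n + 3)] # the two cherry nodes
  expect_equal(internal_heights, c(1 / 3, 1 / 3))
  expect_setequal(round(g$edge.length, 10), round(c(2 / 3, 1 / 3), 10))
})

test_that("degenerate trees and invalid rho are rejected", {
  tr <- ape::read.tree(text = "(A,B);")
  expect_error(grafen_branch_lengths(tr, rho = 0), "rho")
  expect_error(grafen_branch_lengths(tr, rho = -1), "rho")
  one <- ape::read.tree(text = "(A);")
  expect_error(grafen_branch_lengths(one), "degenerate")
})

test_that("cophenetic distances match the path-walk oracle", {
  for (seed in 1:8) {
    tr <- random_test_tree(sample(4:50, 1), seed + 200)
    D <- cophenetic_distances(tr)
    expect_equal(D, oracle_cophenetic(tr), tolerance = 1e-10)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
  }
})

test_that("cophenetic distances on the balanced Grafen tree give hand values", {
  g <- grafen_branch_lengths(ape::read.tree(text = "((A,B),(C,D));"), rho = 1)
  D <- cophenetic_distances(g)
  expect_equal(D["A", "B"], 2 / 3, tolerance = 1e-12)
  expect_equal(D["A", "C"], 2, tolerance = 1e-12)
  tr_nolen <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(cophenetic_distances(tr_nolen), "branch lengths")
})

test_that("distance reversal maps 0 to 1, d_max to 0, and reverses order", {
  g <- grafen_branch_lengths(random_test_tree(20, 7), rho = 1)
  D <- cophenetic_distances(g)
  S <- distances_to_proximities(D)
  expect_equal(unname(diag(S)), rep(1, 20))
  expect_equal(min(S), 0)
  expect_true(all(S >= 0 & S <= 1))
  # order anti-isomorphism on off-diagonal entries: exact affine reversal,
  # strictly decreasing wherever distances are separated beyond float noise
  off <- lower.tri(D)
  expect_equal(S[off], 1 - D[off] / max(D[off]), tolerance = 1e-12)
  ord <- order(D[off])
  gap <- diff(D[off][ord])
  expect_true(all(diff(S[off][ord])[gap > 1e-9] < 0))
  # unnormalised variant keeps the scale
  S2 <- distances_to_proximities(D, method = "unnormalised")
  d_max <- max(D[off])
  expect_equal(S2, d_max - D, ignore_attr = TRUE)
})

test_that("reversal rejects degenerate all-identical distance matrices", {
  D <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(distances_to_proximities(D), "degenerate")
})

test_that("patristic similarity matches the MRCA/edge-count oracle", {
  for (seed in 1:8) {
    tr <- random_test_tree(sample(4:50, 1), seed + 300)
    S <- patristic_similarity(tr)
    expect_equal(S, oracle_patristic_similarity(tr),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, length(tr$tip.label)))
  }
})

test_that("patristic similarity hand values: siblings 1/2, cross-root 0", {
  S <- patristic_similarity(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(S["A", "B"], 1 / 2)
  expect_equal(S["A", "C"], 0)
  # unbalanced: deeper cherries score higher
  S2 <- patristic_similarity(ape::read.tree(text = "(((A,B),C),D);"))
  expect_equal(S2["A", "B"], 2 / 3)
  expect_equal(S2["A", "C"], 1 / 3)
  expect_equal(S2["A", "D"], 0)
})

test_that("averaging distance matrices is the entrywise mean", {
  labs <- letters[1:4]
  mk <- function(x) {
    M <- matrix(x, 4, 4, dimnames = list(labs, labs))
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 0
    M
  }
  A <- mk(2); B <- mk(4)
  avg <- average_distance_matrices(list(A, B))
  expect_equal(avg["a", "b"], 3)
  expect_equal(avg, t(avg))
  expect_true(all(diag(avg) == 0))
  # idempotent and order-commutative
  expect_equal(average_distance_matrices(list(A, A, A)), A)
  expect_equal(average_distance_matrices(list(B, A)), avg)
  C <- mk(1); dimnames(C) <- list(LETTERS[1:4], LETTERS[1:4])
  expect_error(average_distance_matrices(list(A, C)), "label mismatch")
})

test_that("taxonomy tables round-trip into trees usable by the pipeline", {
  tax <- data.frame(
    child_id = c("f1", "f2", "A", "B", "C", "D", "E"),
    parent_id = c("root", "root", "f1", "f1", "f2", "f2", "f2"),
    is_leaf = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    label = c(NA, NA, "A", "B", "C", "D", "E")
  )
  tr <- taxonomy_to_tree(tax)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D", "E"))
  g <- grafen_branch_lengths(tr)
  D <- cophenetic_distances(g)
  # f1 holds 2 of 5 leaves: height (2-1)/(5-1), path A-B crosses it twice
  expect_equal(D["A", "B"], 2 * (1 / 4), tolerance = 1e-12)
  # two roots rejected
  bad <- tax; bad$parent_id[2] <- "other_root"
  expect_error(taxonomy_to_tree(bad), "exactly one root")
})

test_that("newick and matrix CSV writers round-trip", {
  tr <- grafen_branch_lengths(random_test_tree(12, 11))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  tr2 <- read_newick(p)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(cophenetic_distances(tr2)[tr$tip.label, tr$tip.label],
               cophenetic_distances(tr), tolerance = 1e-8)

  M <- cophenetic_distances(tr)
  q <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(M, q)
  expect_equal(read_matrix_csv(q), M, tolerance = 1e-12)
})
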