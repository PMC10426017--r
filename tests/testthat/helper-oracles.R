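# Brute-force oracles, independent of the package's implementation paths.
# All tree oracles work directly on the phylo edge table with plain recursion.

# children list and parent vector from an edge table
edge_maps <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    kids[[p]] <- c(kids[[p]], ch)
    parent[ch] <- p
  }
  list(kids = kids, parent = parent, root = length(tree$tip.label) + 1L)
}

# node heights under Grafen's rule, by direct recursion
oracle_grafen_heights <- function(tree, rho) {
  em <- edge_maps(tree)
  n <- length(tree$tip.label)
  count_leaves <- function(v) {
    if (v <= n) return(1L)
    sum(vapply(em$kids[[v]], count_leaves, integer(1)))
  }
  vapply(seq_len(n + tree$Nnode), function(v) {
    L <- count_leaves(v)
    if (L == 1L) 0 else ((L - 1) / (n - 1))^rho
  }, numeric(1))
}

# path from a node up to the root (inclusive)
path_to_root <- function(em, v) {
  out <- v
  while (!is.na(em$parent[v])) {
    v <- em$parent[v]
    out <- c(out, v)
  }
  out
}

# pairwise leaf distances by walking both paths to the root
oracle_cophenetic <- function(tree) {
  em <- edge_maps(tree)
  n <- length(tree$tip.label)
  edge_len <- rep(NA_real_, n + tree$Nnode)
  edge_len[tree$edge[, 2]] <- tree$edge.length
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi_ <- path_to_root(em, i)
    for (j in seq_len(n)) {
      if (i == j) next
      pj <- path_to_root(em, j)
      shared <- intersect(pi_, pj)
      on_path <- c(setdiff(pi_, shared), setdiff(pj, shared))
      D[i, j] <- sum(edge_len[on_path])
    }
  }
  D
}

# mrca by first shared ancestor; depths counted in edges
oracle_patristic_similarity <- function(tree) {
  em <- edge_maps(tree)
  n <- length(tree$tip.label)
  depth <- vapply(seq_len(n + tree$Nnode),
                  function(v) length(path_to_root(em, v)) - 1L, integer(1))
  leaves_below <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(em$kids[[v]], leaves_below))
  }
  d_r <- max(depth[seq_len(n)])
  S <- matrix(1, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m <- intersect(path_to_root(em, i), path_to_root(em, j))[1]
      d_m <- max(depth[leaves_below(m)]) - depth[m]
      S[i, j] <- (d_r - d_m) / d_r
    }
  }
  S
}

# Eq.-1 style double sum, looped
oracle_connection <- function(profiles, S) {
  cc <- names(profiles)
  C <- matrix(0, length(cc), length(cc), dimnames = list(cc, cc))
  for (r in cc) {
    for (k in cc) {
      acc <- 0
      for (i in names(profiles[[k]])) {
        for (j in names(profiles[[r]])) {
          acc <- acc + profiles[[k]][[i]] * profiles[[r]][[j]] * S[i, j]
        }
      }
      C[r, k] <- acc
    }
  }
  C
}

# all-pairs dyad table, looped
oracle_dyads <- function(slice, layers) {
  cc <- names(slice)
  rows <- list()
  for (b in 2:length(cc)) {
    for (a in seq_len(b - 1)) {
      row <- list(id_i = cc[a], id_j = cc[b],
                  dem.diff = abs(slice[[a]] - slice[[b]]))
      for (nm in names(layers)) row[[nm]] <- layers[[nm]][cc[b], cc[a]]
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# row sums of connection-weighted neighbour democracy, looped
oracle_neighbor_democracy <- function(W, slice) {
  cc <- names(slice)
  out <- numeric(length(cc))
  names(out) <- cc
  for (r in cc) {
    for (k in cc) if (k != r) out[r] <- out[r] + W[r, k] * slice[[k]]
  }
  out
}

# closed-form REML log-likelihood of the crossed-intercepts dyadic model
reml_loglik_mvn <- function(varcomp, y, X, Zi, Zj) {
  m <- length(y)
  V <- varcomp[1] * tcrossprod(Zi) + varcomp[2] * tcrossprod(Zj) +
    varcomp[3] * diag(m)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * as.numeric((m - ncol(X)) * log(2 * pi) +
                      determinant(V)$modulus +
                      determinant(XtVX)$modulus +
                      t(r) %*% Vi %*% r)
}

# a random tree with branch lengths, from machinery unrelated to the generator
random_test_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}

# small random country-trait worlds for connection-matrix checks
random_profiles <- function(n_countries, n_traits, seed) {
  set.seed(seed)
  traits <- sprintf("x%02d", seq_len(n_traits))
  profiles <- lapply(seq_len(n_countries), function(i) {
    k <- sample(2:n_traits, 1)
    sh <- stats::runif(k)
    stats::setNames(sh / sum(sh), sample(traits, k))
  })
  names(profiles) <- sprintf("N%02d", seq_len(n_countries))
  D <- matrix(stats::runif(n_traits^2), n_traits)
  S <- (D + t(D)) / 2
  diag(S) <- 1
  dimnames(S) <- list(traits, traits)
  list(profiles = profiles, S = S)
}

default_layer_list <- function(study) {
  list(ling.con = study$layers$ling, rel.con = study$layers$rel,
       geo.prox = study$layers$geo)
}
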