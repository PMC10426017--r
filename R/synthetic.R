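#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic world in one place. The defaults
#' define the study conditions used throughout the package's tests: 80
#' nations observed for 40 years under the polity2 convention, with a known
#' diffusion process in which linguistic relatives transmit democracy
#' (b_ling = 0.3), geographic neighbours transmit more weakly (b_geo = 0.15),
#' and religious relatives do not (b_rel = 0), on top of autoregressive
#' persistence 0.5 and unit-SD innovation noise.
#'
#' @param seed master seed; all randomness in [simulate_study()] derives from
#'   it.
#' @param n_countries number of nations.
#' @param n_languages,n_religions leaves of the two trait trees.
#' @param n_lang_families,n_rel_families top-level families of the two trees
#'   (children of the root); cultural structure in the generated world is
#'   organised around these families.
#' @param years,start_year length and first year of the democracy panel.
#' @param concentration Dirichlet concentration of each nation's home trait;
#'   larger values give more monolingual/monoreligious nations.
#' @param family_alpha,minority_alpha Dirichlet weights of the remaining
#'   home-family traits and of out-of-family traits (see
#'   [simulate_profiles()]).
#' @param clustering spatial clustering in `[0, 1)`: 0 scatters capitals
#'   uniformly over the globe, values near 1 pull nations of the same
#'   language family tightly around a shared regional centre.
#' @param n_regions continents grouping the language families (see
#'   [simulate_geography()]).
#' @param persistence autoregressive coefficient `a` of a nation's own score.
#' @param b_ling,b_rel,b_geo diffusion coefficients on the row-normalised
#'   connection layers; `persistence + b_ling + b_rel + b_geo` must not
#'   exceed 1 (stability).
#' @param noise_sd SD of the yearly innovation on the index scale.
#' @param convention democracy index convention for the generated panel.
#' @param threshold trait-share inclusion threshold (1 permille).
#' @param rho Grafen exponent for branch lengths.
#' @param polytomy_prob probability that a new lineage attaches as an extra
#'   child of an existing node instead of splitting a branch.
#' @param k_borders each nation borders its k nearest neighbours.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_countries = 80L,
                       n_languages = 45L,
                       n_religions = 15L,
                       n_lang_families = 30L,
                       n_rel_families = 5L,
                       years = 40L,
                       start_year = 1970L,
                       concentration = 25,
                       family_alpha = 0.3,
                       minority_alpha = 0.01,
                       clustering = 0.92,
                       n_regions = 8L,
                       persistence = 0.55,
                       b_ling = 0.3,
                       b_rel = 0,
                       b_geo = 0.15,
                       noise_sd = 1,
                       convention = "polity2",
                       threshold = 0.001,
                       rho = 1,
                       polytomy_prob = 0.7,
                       k_borders = 3L) {
  cfg <- as.list(environment())
  if (cfg$persistence < 0 || cfg$b_ling < 0 || cfg$b_rel < 0 || cfg$b_geo < 0) {
    stop("generative coefficients must be non-negative")
  }
  if (cfg$persistence + cfg$b_ling + cfg$b_rel + cfg$b_geo > 1) {
    stop("unstable coefficient set: persistence + diffusion coefficients exceed 1")
  }
  if (cfg$clustering < 0 || cfg$clustering >= 1) stop("'clustering' must be in [0, 1)")
  democracy_range(cfg$convention) # validates the convention
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a rooted trait taxonomy by sequential random attachment
#'
#' Grows a rooted topology one leaf at a time: each new lineage either splits
#' a randomly chosen branch (bifurcation) or, with probability
#' `polytomy_prob`, attaches as an additional child of the branch's parent
#' (multifurcation — the unresolved nodes typical of taxonomies). Leaves are
#' labelled deterministically; the same seed yields the identical tree.
#'
#' @param n_leaves number of leaves, at least 2.
#' @param seed RNG seed.
#' @param polytomy_prob probability of multifurcating attachment.
#' @param prefix leaf label prefix.
#' @param n_families number of children of the root (top-level families of
#'   the taxonomy). Later lineages attach inside existing families, so the
#'   family count is exact. Default `min(2, n_leaves)`.
#' @return a rooted `phylo` object without branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = 1L, polytomy_prob = 0.25, prefix = "T",
                          n_families = 2L) {
  if (n_leaves < 2L) stop("'n_leaves' must be at least 2")
  n_families <- min(n_families, n_leaves)
  if (n_families < 2L) stop("'n_families' must be at least 2")
  set.seed(seed)
  labels <- sprintf("%s%03d", prefix, seq_len(n_leaves))
  ## taxonomy as parent vectors over string ids; root = "R"
  parent <- stats::setNames(rep("R", n_families), labels[seq_len(n_families)])
  next_internal <- 1L
  if (n_leaves > n_families) {
    for (t in (n_families + 1L):n_leaves) {
      k <- sample.int(length(parent), 1L)
      child <- names(parent)[k]
      p <- parent[[k]]
      if (p != "R" && stats::runif(1) < polytomy_prob) {
        parent[labels[t]] <- p
      } else {
        m <- sprintf("I%04d", next_internal)
        next_internal <- next_internal + 1L
        parent[[k]] <- m
        parent[labels[t]] <- m
        parent[m] <- p
      }
    }
  }
  ids <- names(parent)
  taxonomy_to_tree(data.frame(
    child_id = ids,
    parent_id = unname(parent),
    is_leaf = ids %in% labels,
    label = ids,
    stringsAsFactors = FALSE
  ))
}

#' Top-level clade membership of each leaf
#'
#' Maps every leaf to the child-of-root subtree (the "family") it belongs to.
#'
#' @param tree a rooted `phylo`.
#' @return named integer vector: leaf label to clade index.
#' @export
root_clades <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  clade <- integer(n + tree$Nnode)
  top <- tree$edge[tree$edge[, 1L] == root, 2L]
  clade[top] <- seq_along(top)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    if (pre[k, 1L] != root) clade[pre[k, 2L]] <- clade[pre[k, 1L]]
  }
  stats::setNames(clade[seq_len(n)], tree$tip.label)
}

#' Simulate national trait profiles around home clades
#'
#' Each nation is assigned a home family (a child-of-root clade of the trait
#' tree) and a dominant home trait inside it; population shares are drawn
#' from a Dirichlet distribution whose concentration favours the home trait,
#' mildly favours the rest of the home family, and leaves a thin tail of
#' minority traits — some below the 1-permille inclusion threshold, so the
#' filter is genuinely exercised. Shares sum to 1 per nation.
#'
#' @param tree trait tree whose leaves are the trait codes.
#' @param n_countries number of nations.
#' @param concentration Dirichlet weight of the home trait.
#' @param seed RNG seed.
#' @param family_alpha Dirichlet weight of the other traits in the home
#'   family (regional minority languages/denominations).
#' @param minority_alpha Dirichlet weight of traits outside the home family;
#'   small values leave most foreign minorities below the 1-permille filter,
#'   as in real national repertoires.
#' @return named list of share vectors keyed by country code, with
#'   attributes `home_clade` and `home_trait` (named by country).
#' @export
simulate_profiles <- function(tree, n_countries, concentration = 25, seed = 1L,
                              family_alpha = 0.3, minority_alpha = 0.01) {
  set.seed(seed)
  clades <- root_clades(tree)
  traits <- names(clades)
  countries <- sprintf("C%03d", seq_len(n_countries))
  home_clade <- sample(rep_len(sort(unique(clades)), n_countries))
  home_trait <- vapply(home_clade, function(cl) {
    pool <- traits[clades == cl]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  profiles <- vector("list", n_countries)
  for (i in seq_len(n_countries)) {
    alpha <- ifelse(traits == home_trait[i], concentration,
                    ifelse(clades == home_clade[i], family_alpha, minority_alpha))
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    profiles[[i]] <- stats::setNames(g / sum(g), traits)
  }
  names(profiles) <- countries
  attr(profiles, "home_clade") <- stats::setNames(home_clade, countries)
  attr(profiles, "home_trait") <- stats::setNames(home_trait, countries)
  profiles
}

## uniform random points on the unit sphere, as 3-vectors
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

## n well-separated points on the sphere (Fibonacci lattice), randomly rotated
## so different seeds give different continents but always spread-out ones
spread_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  pts %*% Q
}

## spherical linear interpolation from u toward v by fraction t
slerp <- function(u, v, t) {
  d <- pmin(1, pmax(-1, rowSums(u * v)))
  w <- acos(d)
  out <- u
  nz <- w > 1e-9
  out[nz, ] <- (sin((1 - t) * w[nz]) * u[nz, , drop = FALSE] +
                  sin(t * w[nz]) * v[nz, , drop = FALSE]) / sin(w[nz])
  out
}

#' Simulate capital locations and borders
#'
#' Geography is hierarchical, as on the real globe: continents hold several
#' language families each. Continent centres are drawn uniformly on the
#' sphere; each clade (family) receives a centre pulled three quarters of the
#' way from a uniform point toward its continent's centre; each nation's
#' capital sits on the great circle between an independent uniform point and
#' its family centre, a fraction `clustering` of the way. `clustering = 0`
#' gives capitals uniform over the globe (geography independent of culture);
#' values near 1 co-locate cultural relatives tightly. Borders connect each
#' nation to its `k` nearest neighbours by geodesic distance.
#'
#' @param n_countries number of nations.
#' @param clustering spatial clustering in `[0, 1)`.
#' @param seed RNG seed.
#' @param clades named integer vector of clade membership per country (from
#'   [simulate_profiles()]); `NULL` assigns all countries one clade.
#' @param k_borders neighbours per nation in the border list.
#' @param n_regions number of continents grouping the clades.
#' @return list with `geos` (data frame `country`, `lat`, `lon`) and
#'   `borders` (data frame `a`, `b` of undirected bordering pairs).
#' @export
simulate_geography <- function(n_countries, clustering = 0.6, seed = 1L,
                               clades = NULL, k_borders = 3L, n_regions = 4L) {
  set.seed(seed)
  countries <- sprintf("C%03d", seq_len(n_countries))
  if (is.null(clades)) clades <- stats::setNames(rep(1L, n_countries), countries)
  clades <- clades[countries]
  clade_ids <- sort(unique(clades))
  region_centres <- spread_sphere(n_regions)
  region_of <- sample(rep_len(seq_len(n_regions), length(clade_ids)))
  centres <- slerp(runif_sphere(length(clade_ids)),
                   region_centres[region_of, , drop = FALSE], 0.75)
  rownames(centres) <- as.character(clade_ids)
  u <- runif_sphere(n_countries)
  xyz <- slerp(u, centres[as.character(clades), , drop = FALSE], clustering)
  geos <- data.frame(
    country = countries,
    lat = asin(pmin(1, pmax(-1, xyz[, 3]))) * 180 / pi,
    lon = atan2(xyz[, 2], xyz[, 1]) * 180 / pi,
    stringsAsFactors = FALSE
  )
  D <- geodesic_distances(geos)
  pairs <- list()
  for (i in seq_len(n_countries)) {
    nb <- order(D[i, ])[2:(k_borders + 1L)]
    for (j in nb) {
      a <- min(i, j); b <- max(i, j)
      pairs[[paste(a, b)]] <- c(a, b)
    }
  }
  mat <- do.call(rbind, pairs)
  borders <- data.frame(a = countries[mat[, 1]], b = countries[mat[, 2]],
                        stringsAsFactors = FALSE)
  borders <- borders[order(borders$a, borders$b), , drop = FALSE]
  rownames(borders) <- NULL
  list(geos = geos, borders = borders)
}

#' Simulate a democracy panel with a known diffusion process
#'
#' Generates the panel from an explicit contagion model: each year,
#' `dem[t+1] = a * dem[t] + b_ling * Wl dem[t] + b_rel * Wr dem[t] +
#' b_geo * Wg dem[t] + noise`, where the connection layers are row-normalised
#' to unit row sums (so the coefficients are interpretable as weights on the
#' neighbour average and stability requires `a + sum(b) <= 1`), and scores
#' are clipped to the index range — reproducing the boundary censoring of
#' real bounded indices. Initial scores are uniform over the range. Note the
#' estimation side deliberately uses raw (un-normalised) neighbour sums; the
#' generative model fixes a convenient, stable parameterisation, not the
#' estimator's.
#'
#' @param layers named list with `ling`, `rel`, `geo` connection matrices
#'   (diagonals are zeroed; row normalisation is applied internally).
#' @param config a [sim_config()].
#' @return a `democracy_panel` covering `config$years` consecutive years.
#' @export
simulate_panel <- function(layers, config) {
  req <- c("ling", "rel", "geo")
  if (!all(req %in% names(layers))) stop("'layers' needs elements ling, rel, geo")
  a <- config$persistence
  bs <- c(config$b_ling, config$b_rel, config$b_geo)
  if (a + sum(bs) > 1) {
    stop("unstable coefficient set: persistence + diffusion coefficients exceed 1")
  }
  W <- lapply(layers[req], function(M) {
    M <- zero_diagonal(M)
    rs <- rowSums(M)
    M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
    M
  })
  countries <- rownames(W$ling)
  n <- length(countries)
  rng <- democracy_range(config$convention)
  set.seed(derive_seed(config$seed, 4L))
  dem <- stats::runif(n, rng[1], rng[2])
  years <- config$start_year + seq_len(config$years) - 1L
  scores <- matrix(NA_real_, n, length(years), dimnames = list(countries, years))
  scores[, 1L] <- dem
  for (t in seq_along(years)[-1L]) {
    dem <- a * dem +
      config$b_ling * as.numeric(W$ling %*% dem) +
      config$b_rel * as.numeric(W$rel %*% dem) +
      config$b_geo * as.numeric(W$geo %*% dem) +
      stats::rnorm(n, 0, config$noise_sd)
    dem <- pmin(rng[2], pmax(rng[1], dem))
    scores[, t] <- dem
  }
  as_democracy_panel(data.frame(
    country = rep(countries, times = length(years)),
    year = rep(years, each = n),
    score = as.numeric(scores)
  ), config$convention)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with seeds derived from the master seed and wires the
#' results through the network-building stage, returning all the inputs and
#' intermediate layers the analysis consumes: language and religion trees,
#' national trait profiles, capitals and borders, the three connection layers
#' (Grafen-cophenetic proximities aggregated through the share-weighted
#' double sum; reversed log10 geodesic proximity), majority-trait
#' assignments, and a democracy panel generated by the known diffusion
#' process over those same layers.
#'
#' @param config a [sim_config()].
#' @return list with elements `config`, `lang_tree`, `rel_tree`,
#'   `lang_profiles`, `rel_profiles`, `geos`, `borders`, `layers` (named list
#'   `ling`, `rel`, `geo`, zero diagonals), `majority_language`,
#'   `majority_religion`, `panel`.
#' @export
simulate_study <- function(config = sim_config()) {
  lang_tree <- simulate_tree(config$n_languages, seed = derive_seed(config$seed, 1L),
                             polytomy_prob = config$polytomy_prob, prefix = "L",
                             n_families = config$n_lang_families)
  rel_tree <- simulate_tree(config$n_religions, seed = derive_seed(config$seed, 2L),
                            polytomy_prob = config$polytomy_prob, prefix = "R",
                            n_families = config$n_rel_families)
  lang_profiles <- simulate_profiles(lang_tree, config$n_countries,
                                     concentration = config$concentration,
                                     seed = derive_seed(config$seed, 3L),
                                     family_alpha = config$family_alpha,
                                     minority_alpha = config$minority_alpha)
  rel_profiles <- simulate_profiles(rel_tree, config$n_countries,
                                    concentration = config$concentration,
                                    seed = derive_seed(config$seed, 5L),
                                    family_alpha = config$family_alpha,
                                    minority_alpha = config$minority_alpha)
  geo <- simulate_geography(config$n_countries, clustering = config$clustering,
                            seed = derive_seed(config$seed, 6L),
                            clades = attr(lang_profiles, "home_clade"),
                            k_borders = config$k_borders,
                            n_regions = config$n_regions)

  trait_layer <- function(tree, profiles, layer) {
    S <- distances_to_proximities(
      cophenetic_distances(grafen_branch_lengths(tree, rho = config$rho))
    )
    filtered <- lapply(profiles, filter_profile, threshold = config$threshold)
    zero_diagonal(connection_matrix(filtered, S, layer = layer))
  }
  layers <- list(
    ling = trait_layer(lang_tree, lang_profiles, "linguistic"),
    rel = trait_layer(rel_tree, rel_profiles, "religious"),
    geo = zero_diagonal(geodesic_proximity(geo$geos))
  )
  majority <- function(profiles) {
    vapply(profiles, function(p) names(p)[which.max(p)], character(1))
  }
  list(
    config = config,
    lang_tree = lang_tree,
    rel_tree = rel_tree,
    lang_profiles = lang_profiles,
    rel_profiles = rel_profiles,
    geos = geo$geos,
    borders = geo$borders,
    layers = layers,
    majority_language = majority(lang_profiles),
    majority_religion = majority(rel_profiles),
    panel = simulate_panel(layers, config)
  )
}

#' Write every synthetic input in its standard on-disk format
#'
#' Newick trees, long-format trait share tables (percent), capitals, borders,
#' the democracy panel, and the three connection layers as labelled square
#' CSVs. Output is deterministic: the same study writes byte-identical files.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_newick(study$lang_tree, fp("language_tree.nwk"))
  write_newick(study$rel_tree, fp("religion_tree.nwk"))
  shares_table <- function(profiles) {
    do.call(rbind, lapply(names(profiles), function(cc) {
      data.frame(country = cc, trait = names(profiles[[cc]]),
                 percent = 100 * unname(profiles[[cc]]),
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(shares_table(study$lang_profiles), fp("language_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(shares_table(study$rel_profiles), fp("religion_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(study$geos, fp("capitals.csv"), row.names = FALSE)
  utils::write.csv(study$borders, fp("borders.csv"), row.names = FALSE)
  write_panel(study$panel, fp("panel.csv"))
  write_matrix_csv(study$layers$ling, fp("layer_linguistic.csv"))
  write_matrix_csv(study$layers$rel, fp("layer_religious.csv"))
  write_matrix_csv(study$layers$geo, fp("layer_geographic.csv"))
  invisible(dir)
}

#' Simulate dyadic data with known coefficients
#'
#' Direct generator for calibrating the dyadic mixed model: dyad-level
#' predictors are iid standard normal, each country contributes a random
#' intercept to every dyad it belongs to (drawn once per country for each
#' side-role variance), and the outcome adds iid residual noise. The true
#' fixed effects are exactly `beta`, so estimator bias, interval coverage,
#' and type-I error can be measured against the generative truth.
#'
#' @param n_countries number of countries (dyads = n(n-1)/2).
#' @param beta named numeric vector of true coefficients; names become
#'   predictor columns (default `ling.con`, `rel.con`, `geo.prox` as needed).
#' @param re_sd SD of the country random intercepts.
#' @param resid_sd residual SD.
#' @param seed RNG seed.
#' @param intercept true intercept, default 0.
#' @return data frame with `id_i`, `id_j`, predictor columns, and `dem.diff`.
#' @export
simulate_dyadic <- function(n_countries = 60L,
                            beta = c(ling.con = 0.5, rel.con = 0.3, geo.prox = -0.2),
                            re_sd = 0.4, resid_sd = 1, seed = 1L, intercept = 0) {
  set.seed(seed)
  if (is.null(names(beta))) {
    names(beta) <- c("ling.con", "rel.con", "geo.prox")[seq_along(beta)]
  }
  countries <- sprintf("C%03d", seq_len(n_countries))
  pairs <- lower_triangle_pairs(countries)
  m <- nrow(pairs)
  X <- matrix(stats::rnorm(m * length(beta)), m, length(beta),
              dimnames = list(NULL, names(beta)))
  u <- stats::setNames(stats::rnorm(n_countries, 0, re_sd), countries)
  v <- stats::setNames(stats::rnorm(n_countries, 0, re_sd), countries)
  y <- intercept + as.numeric(X %*% beta) + u[pairs$j] + v[pairs$i] +
    stats::rnorm(m, 0, resid_sd)
  out <- data.frame(
    id_i = factor(pairs$j, levels = countries),
    id_j = factor(pairs$i, levels = countries),
    X,
    dem.diff = unname(y),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  out
}
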