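#' Filter a country's trait profile at a population-share threshold
#'
#' Keeps only traits (languages or religions) spoken or practised by at least
#' a fixed share of the population — by default 1 permille — mirroring the
#' inclusion rule applied to national language repertoires. Shares are stored
#' as proportions in `[0, 1]`; they are not renormalised after filtering
#' unless requested, so a nation's retained shares keep their absolute
#' demographic meaning.
#'
#' @param shares named numeric vector mapping trait code to population share
#'   (proportion). Multilingual overlap may push totals slightly above 1;
#'   totals above 1 are warned about, totals above 1.2 rejected.
#' @param threshold inclusion threshold (inclusive), default `0.001`.
#' @param renormalise if `TRUE`, retained shares are rescaled to sum to the
#'   original total. Default `FALSE`.
#' @return the filtered named share vector.
#' @export
filter_profile <- function(shares, threshold = 0.001, renormalise = FALSE) {
  if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
    stop("'shares' must be a named vector of trait shares")
  }
  if (any(shares < 0)) stop("shares must be non-negative")
  tot <- sum(shares)
  if (tot > 1.2) stop("profile shares sum above 1.2; check units (proportions, not percent)")
  if (tot > 1 + 1e-9) warning("profile shares sum above 1 (multilingual overlap)")
  kept <- shares[shares >= threshold]
  if (length(kept) == 0L) stop("no qualifying traits after filtering")
  if (renormalise) kept <- kept * (tot / sum(kept))
  kept
}

#' Country-by-country cultural connection matrix
#'
#' Aggregates trait-level proximities into a national connection score. For
#' nations r and k with trait shares p, the connection is the share-weighted
#' double sum over all trait pairs:
#' `c_rk = sum_i sum_j p_ik * p_jr * s_ij`,
#' computed for every pair of nations at once as `t(P) S P` with `P` the
#' trait-by-country share matrix. The diagonal holds each nation's
#' self-connection (internal cultural homogeneity); it is reported but zeroed
#' before any dyadic or neighbour-sum use — see [zero_diagonal()].
#'
#' @param profiles named list of filtered share vectors, one per country
#'   (names are country codes).
#' @param S trait proximity matrix covering every trait present in the
#'   profiles (see [distances_to_proximities()] or [patristic_similarity()]).
#' @param layer label recorded on the result, e.g. `"linguistic"`.
#' @return symmetric labelled country matrix with attribute `layer`.
#' @export
connection_matrix <- function(profiles, S, layer = "cultural") {
  if (!is.list(profiles) || is.null(names(profiles)) || length(profiles) < 2L) {
    stop("'profiles' must be a named list of at least two country profiles")
  }
  assert_square_labelled(S, "proximity matrix")
  traits <- sort(unique(unlist(lapply(profiles, names))))
  missing <- setdiff(traits, rownames(S))
  if (length(missing) > 0L) {
    stop(sprintf("trait(s) missing from proximity matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  P <- matrix(0, nrow = length(traits), ncol = length(profiles),
              dimnames = list(traits, names(profiles)))
  for (cc in names(profiles)) P[names(profiles[[cc]]), cc] <- profiles[[cc]]
  C <- t(P) %*% S[traits, traits, drop = FALSE] %*% P
  C <- (C + t(C)) / 2 # remove floating-point asymmetry
  attr(C, "layer") <- layer
  C
}

#' Pairwise geodesic capital distances on the WGS84 ellipsoid
#'
#' Distances between national capitals in metres, computed with
#' [geosphere::distGeo()] (ellipsoidal geodesics). Coincident or near-
#' coincident capitals — which occur for successor states inheriting a
#' capital — are floored at `floor_m` metres so the subsequent log transform
#' is defined.
#'
#' @param geos data frame with columns `country`, `lat`, `lon` (decimal
#'   degrees, WGS84).
#' @param floor_m minimum distance in metres applied off the diagonal
#'   (default 1000).
#' @return symmetric labelled matrix of distances in metres, zero diagonal.
#' @export
geodesic_distances <- function(geos, floor_m = 1000) {
  req <- c("country", "lat", "lon")
  if (!all(req %in% names(geos))) stop("'geos' needs columns country, lat, lon")
  bad <- !is.finite(geos$lat) | !is.finite(geos$lon) |
    abs(geos$lat) > 90 | abs(geos$lon) > 180
  if (any(bad)) {
    stop(sprintf("missing or invalid coordinates for: %s",
                 paste(geos$country[bad], collapse = ", ")))
  }
  D <- geosphere::distm(cbind(geos$lon, geos$lat), fun = geosphere::distGeo)
  D[D < floor_m] <- floor_m
  diag(D) <- 0
  dimnames(D) <- list(geos$country, geos$country)
  D
}

#' Geographic proximity layer from capital coordinates
#'
#' Log10-transforms the pairwise geodesic distances and reverses them to
#' proximities relative to the current country sample:
#' `prox = max(log10 d) - log10 d`, so the farthest pair scores 0 and closer
#' pairs score higher. The reversal is sample-relative and should be
#' recomputed whenever the country set changes (e.g. per year slice). The
#' diagonal is set to 0.
#'
#' @inheritParams geodesic_distances
#' @param log10_transform set `FALSE` to reverse raw metre distances instead
#'   (robustness variant).
#' @return symmetric labelled proximity matrix with attribute
#'   `layer = "geographic"`.
#' @export
geodesic_proximity <- function(geos, floor_m = 1000, log10_transform = TRUE) {
  D <- geodesic_distances(geos, floor_m = floor_m)
  off <- row(D) != col(D)
  G <- D
  G[off] <- if (log10_transform) log10(D[off]) else D[off]
  m <- max(G[off])
  G[off] <- m - G[off]
  diag(G) <- 0
  attr(G, "layer") <- "geographic"
  G
}

#' Binary contiguity layers
#'
#' Marks pairs of nations as contiguous (1) when they share a land or river
#' border, the same majority language, or the same majority religion, and 0
#' otherwise. Diagonal is 0.
#'
#' @param kind one of `"border"`, `"majority-language"`, `"majority-religion"`.
#' @param countries character vector of country codes defining matrix order.
#' @param borders for `kind = "border"`: data frame with columns `a`, `b`
#'   listing bordering pairs (undirected).
#' @param majority for the majority kinds: named character vector mapping every
#'   country to its majority trait.
#' @return binary symmetric labelled matrix with attribute `layer`.
#' @export
contiguity_matrix <- function(kind = c("border", "majority-language", "majority-religion"),
                              countries, borders = NULL, majority = NULL) {
  kind <- match.arg(kind)
  n <- length(countries)
  M <- matrix(0, n, n, dimnames = list(countries, countries))
  if (kind == "border") {
    if (is.null(borders)) stop("'borders' required for kind = \"border\"")
    a <- as.character(borders$a); b <- as.character(borders$b)
    known <- a %in% countries & b %in% countries
    for (k in which(known)) {
      M[a[k], b[k]] <- 1
      M[b[k], a[k]] <- 1
    }
  } else {
    if (is.null(majority)) stop("'majority' required for majority contiguity")
    missing <- setdiff(countries, names(majority))
    if (length(missing) > 0L) {
      stop(sprintf("missing majority assignment for: %s",
                   paste(missing, collapse = ", ")))
    }
    same <- outer(majority[countries], majority[countries], `==`)
    M[same] <- 1
  }
  diag(M) <- 0
  attr(M, "layer") <- paste0("contiguity-", sub("majority-", "", kind))
  M
}

#' Zero the diagonal of a connection layer
#'
#' Dyadic analyses use only off-diagonal pairs and neighbour sums must exclude
#' the focal nation, so every layer's diagonal is zeroed before downstream use.
#'
#' @param M labelled square matrix.
#' @return `M` with a zero diagonal, other attributes preserved.
#' @export
zero_diagonal <- function(M) {
  assert_square_labelled(M, "connection matrix")
  diag(M) <- 0
  M
}

#' Subset a connection layer to a set of countries
#'
#' @param M labelled square matrix.
#' @param countries country codes to retain, in the returned order.
#' @return the submatrix; errors if any country is absent from the layer.
#' @export
subset_layer <- function(M, countries) {
  assert_square_labelled(M, "connection matrix")
  missing <- setdiff(countries, rownames(M))
  if (length(missing) > 0L) {
    stop(sprintf("countries missing from layer: %s", paste(missing, collapse = ", ")))
  }
  out <- M[countries, countries, drop = FALSE]
  attr(out, "layer") <- attr(M, "layer")
  out
}

#' Read a long-format trait share table into country profiles
#'
#' Accepts the conventional long CSV layout `country, trait, percent` (percent
#' of population, 0-100), converts percentages to proportions, and applies the
#' inclusion filter per country.
#'
#' @param path CSV path with columns `country`, `trait`, `percent`.
#' @param threshold share threshold passed to [filter_profile()].
#' @param renormalise passed to [filter_profile()].
#' @return named list of filtered share vectors keyed by country code.
#' @export
read_trait_profiles <- function(path, threshold = 0.001, renormalise = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("country", "trait", "percent")
  if (!all(req %in% names(df))) stop("trait table needs columns country, trait, percent")
  split_df <- split(df, df$country)
  lapply(split_df, function(d) {
    shares <- stats::setNames(d$percent / 100, d$trait)
    filter_profile(shares, threshold = threshold, renormalise = renormalise)
  })
}
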