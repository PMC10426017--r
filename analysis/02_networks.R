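#!/usr/bin/env Rscript
# Step 2: rebuild the three country-by-country connection layers from the
# on-disk inputs written by step 1, exactly as they would be built from real
# data: Grafen branch lengths on each trait tree, cophenetic distances
# reversed to proximities, the share-weighted double sum over national trait
# repertoires (1-permille inclusion filter), and reversed log10 geodesic
# distance between capitals. Also derives the three binary contiguity layers.

library(demodiff)

dir.create("results/layers", showWarnings = FALSE, recursive = TRUE)

build_trait_layer <- function(tree_file, shares_file, layer) {
  tree <- read_newick(file.path("results/inputs", tree_file))
  S <- distances_to_proximities(
    cophenetic_distances(grafen_branch_lengths(tree, rho = 1))
  )
  profiles <- read_trait_profiles(file.path("results/inputs", shares_file))
  zero_diagonal(connection_matrix(profiles, S, layer = layer))
}

ling <- build_trait_layer("language_tree.nwk", "language_shares.csv", "linguistic")
rel <- build_trait_layer("religion_tree.nwk", "religion_shares.csv", "religious")
capitals <- read.csv("results/inputs/capitals.csv")
geo <- zero_diagonal(geodesic_proximity(capitals))

write_matrix_csv(ling, "results/layers/linguistic.csv")
write_matrix_csv(rel, "results/layers/religious.csv")
write_matrix_csv(geo, "results/layers/geographic.csv")

# contiguity controls: shared border, shared majority language/religion
borders <- read.csv("results/inputs/borders.csv")
majority_of <- function(shares_file) {
  profiles <- read_trait_profiles(file.path("results/inputs", shares_file))
  vapply(profiles, function(p) names(p)[which.max(p)], character(1))
}
countries <- rownames(ling)
write_matrix_csv(contiguity_matrix("border", countries, borders = borders),
                 "results/layers/contiguity_border.csv")
write_matrix_csv(contiguity_matrix("majority-language", countries,
                                   majority = majority_of("language_shares.csv")),
                 "results/layers/contiguity_language.csv")
write_matrix_csv(contiguity_matrix("majority-religion", countries,
                                   majority = majority_of("religion_shares.csv")),
                 "results/layers/contiguity_religion.csv")

for (nm in c("linguistic", "religious", "geographic")) {
  M <- read_matrix_csv(file.path("results/layers", paste0(nm, ".csv")))
  off <- row(M) != col(M)
  cat(sprintf("%-11s layer: %d nations, connection range %.3f-%.3f\n",
              nm, nrow(M), min(M[off]), max(M[off])))
}
cat("layers written to results/layers/\n")
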