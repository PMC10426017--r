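Package: demodiff
Title: Cultural Ancestry, Geography, and the Diffusion of Democracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether shared linguistic or religious ancestry
    and geographic proximity predict cross-sectional similarity in national
    democracy scores and longitudinal diffusion of democracy between cultural
    relatives. Builds ultrametric trait trees with Grafen branch lengths,
    converts cophenetic and patristic distances into trait proximity matrices,
    aggregates them into country-by-country connection networks weighted by
    population trait shares, and fits per-year dyadic linear mixed models with
    crossed node-identity random intercepts as well as lagged contagion
    regressions of national democracy on the connection-weighted democracy of
    cultural relatives and geographic neighbours. Includes semi-partial
    coefficients of determination for mixed models, AICc model selection, and
    a fully seeded synthetic-data generator (trees, trait profiles, capitals,
    borders, democracy panels with a known diffusion process) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
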