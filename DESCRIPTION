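Package: elohist
Title: Elo Ratings for Animal Dominance Hierarchies with Prior History
    and Variable K
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential Elo-rating models of social dominance hierarchies
    from dated win/loss interaction records. Extends the standard
    equal-start, constant-K formulation in two ways: starting ratings can
    be initialized from prior dominance history (explicit ratings, ordinal
    ranks, or ordered rank categories, spread by a reciprocal-power index)
    to shorten or eliminate the burn-in period, and each interaction can
    carry its own K value so that the intensity of aggression weights its
    influence on rank trajectories. Includes daily rating and ordinal-rank
    extraction, burn-in detection, validation of modeled hierarchies
    against directional subordination signals (such as chimpanzee
    pant-grunts), and a seeded simulator of interaction sequences from a
    latent hierarchy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
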