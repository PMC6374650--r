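Package: rarityframe
Title: Rabinowitz Rarity Classification from Presence-Only Occurrence Records
Version: 0.1.0
Authors@R: person("rarityframe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes spatial rarity indices from presence-only species
    occurrence records: maximum pairwise distance (a range-size proxy), the
    mean nearest-neighbour distance and its ratio to the maximum distance (a
    local-abundance proxy), and the count of landcover classes occupied (a
    habitat-specificity proxy). Species are assigned to the eight classes of
    the Rabinowitz rarity typology using mean-based cutoffs, summarized
    against conservation species lists, and mapped as gridded species
    richness with top-quantile congruence overlays for conservation
    prioritization. Includes a seeded synthetic occurrence and landcover
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
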