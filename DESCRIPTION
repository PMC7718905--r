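Package: pbsi
Title: Person-Based Similarity Indices for Brain Morphometric Profiles
Version: 0.1.0
Authors@R: person("PBSI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computes person-based similarity indices (PBSI) from regional
    brain morphometry tables: each subject's profile of cortical-thickness or
    subcortical-volume measures is compared to every other member of the same
    diagnostic group within the same site by Spearman rank correlation, and
    the mean of those pairwise correlations is the subject's similarity score.
    Includes regional-contribution diagnostics (leave-one-out deltas and
    random-subset resampling), a synthetic multi-site cohort generator with a
    tunable within-group heterogeneity knob, and the accompanying
    non-parametric inferential toolkit (Mann-Whitney U with tie-corrected
    normal approximation, Cliff's delta, Feltz-Miller test for equality of
    coefficients of variation, Spearman associations, Benjamini-Hochberg
    false-discovery-rate adjustment), orchestrated by a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
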