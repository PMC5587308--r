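Package: assemblr
Title: Empirical Hierarchical Typologies of Tree Species Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives empirical, hierarchical typologies of tree species
    assemblages from forest-inventory plot records. Per-plot species
    importance values (the mean of relative basal area and relative stem
    abundance, scaled to 100) are clustered by k-means seeding followed by
    size-weighted average-linkage agglomeration on Bray-Curtis
    dissimilarities between seed centroids, so that hierarchies over 10^5
    plots fit in memory. Candidate cut levels are screened with indicator
    species analysis (Dufrene-Legendre indicator values with permutation
    p-values), silhouette widths, and coverage diagnostics; a species
    dominance index (mean relative importance, mean suppression, and
    tendency toward high cover) designates dominant species per assemblage
    by a pooled percentile cutoff; and projected per-species importance-value
    changes under climate scenarios are aggregated to dominance-weighted
    assemblage impact summaries. A synthetic inventory generator with
    planted assemblage structure provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
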