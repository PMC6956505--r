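Package: drupevol
Title: Comparative Phylogenetics of Fleshy-Fruit Syndromes and Color Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the evolution of fleshy-fruit (drupe)
    syndromes on a phylogeny. Processes fruit reflectance spectra and places
    them in a UV-sensitive avian tetrahedral color space with convex-hull
    overlap between color categories; derives nutritional and morphological
    fruit traits from raw measurements; runs phylogenetically corrected
    syndrome statistics (phylogenetic PCA under Brownian motion, independent
    contrasts with Bonferroni-corrected regressions, simulation-based
    phylogenetic ANOVA, Brown-Forsythe and Kruskal-Wallis tests); and models
    discrete fruit-color evolution with constrained Mk models (including a
    paedomorphy model of developmental truncation), AICc model comparison,
    marginal ancestral state reconstruction, step-matrix (Sankoff) parsimony,
    and stochastic character mapping with transition counts. A synthetic-data
    module simulates birth-death trees, Mk character histories, correlated
    Brownian traits with syndrome structure, and reflectance spectra so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
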