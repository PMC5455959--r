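Package: casteMK
Title: Molecular Evolution of Caste-Associated Genes by McDonald-Kreitman
    Maximum Likelihood and Phylostratigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study molecular evolution of genes associated with
    social-insect castes. Implements site filtering and synonymous versus
    nonsynonymous classification of coding variants, construction of per-gene
    McDonald-Kreitman tables, maximum-likelihood estimation of the proportion
    of adaptive amino-acid substitutions (alpha) and the selective constraint
    (f) under a Poisson model with per-gene nuisance intensities, gene
    resampling bootstrap confidence intervals and between-class comparisons,
    phylostratigraphic gene-age assignment from homology hit tables, and
    class-level statistics (Poisson or quasi-Poisson generalized linear models
    on mean phylostratum, contingency tables with standardized Pearson
    residuals, hypergeometric Gene Ontology over-representation). A synthetic
    data generator with planted ground truth supports end-to-end testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'sim-mk.R'
    'sim-expression.R'
    'sim-blast.R'
    'sim-cds.R'
    'variant-io.R'
    'variant-filter.R'
    'classify-effect.R'
    'tabulate-mk.R'
    'mk-alpha.R'
    'bootstrap.R'
    'phylostrat.R'
    'class-stats.R'
    'pipeline.R'
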