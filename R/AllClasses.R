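#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet GENETIC_CODE
#' @importClassesFrom Biostrings DNAString
#' @importFrom stats rpois rlnorm rnbinom runif rnorm
#' @importFrom utils head read.table write.table
NULL

#' Per-gene McDonald-Kreitman count tables
#'
#' Holds, for each gene, the four McDonald-Kreitman cells: nonsynonymous
#' (`Pn`) and synonymous (`Ps`) polymorphism counts within the ingroup, and
#' nonsynonymous (`Dn`) and synonymous (`Ds`) fixed differences to the
#' outgroup. An optional caste-class label (`reproductive`, `worker`, `NDE`)
#' can be attached per gene.
#'
#' @slot counts data.frame with columns `gene_id`, `Pn`, `Ps`, `Dn`, `Ds`;
#'   counts are nonnegative integers.
#' @slot classes character vector parallel to the rows of `counts`; one of
#'   `"reproductive"`, `"worker"`, `"NDE"` or `NA` when unlabelled.
#' @export
setClass("MKCountSet",
  representation(counts = "data.frame", classes = "character"),
  prototype(
    counts = data.frame(gene_id = character(), Pn = integer(),
                        Ps = integer(), Dn = integer(), Ds = integer()),
    classes = character()
  )
)

setValidity("MKCountSet", function(object) {
  cn <- c("gene_id", "Pn", "Ps", "Dn", "Ds")
  if (!all(cn %in% colnames(object@counts)))
    return(paste("counts must have columns", paste(cn, collapse = ", ")))
  cm <- as.matrix(object@counts[, c("Pn", "Ps", "Dn", "Ds")])
  if (nrow(cm) && (any(!is.finite(cm)) || any(cm < 0) || any(cm != round(cm))))
    return("Pn, Ps, Dn, Ds must be nonnegative integers")
  if (length(object@classes) != nrow(object@counts))
    return("classes must have one entry per gene")
  bad <- !is.na(object@classes) &
    !object@classes %in% c("reproductive", "worker", "NDE")
  if (any(bad))
    return("classes must be 'reproductive', 'worker', 'NDE' or NA")
  if (anyDuplicated(object@counts$gene_id))
    return("gene_id values must be unique")
  TRUE
})

#' Class-level estimate of the adaptive-substitution proportion
#'
#' Result container for [mlAlpha()] and [bootstrapAlpha()]: the maximum
#' likelihood estimates of alpha (proportion of amino-acid substitutions fixed
#' by positive selection) and of the selective constraint f (fraction of
#' nonsynonymous mutations behaving neutrally), the profile log-likelihood at
#' the optimum, and, when a bootstrap was run, the percentile 95% confidence
#' interval and the replicate draws.
#'
#' @slot classLabel label of the gene class estimated (may be `NA`).
#' @slot alphaHat estimated alpha; always `< 1`, may be negative.
#' @slot fHat estimated constraint in `(0, 1]`.
#' @slot logLik profile log-likelihood at the optimum (Poisson terms, gene
#'   factorials dropped).
#' @slot nGenes number of genes contributing likelihood information.
#' @slot nDropped genes removed because all four counts were zero.
#' @slot ciLow,ciHigh percentile bootstrap 95% CI bounds (`NA` if no bootstrap).
#' @slot nBootstrap number of bootstrap replicates requested (0 if none).
#' @slot nFailed bootstrap replicates dropped for non-convergence.
#' @slot seed integer seed used for the bootstrap (`NA` if none).
#' @slot draws numeric vector of bootstrap alpha draws (possibly empty).
#' @export
setClass("AlphaEstimate",
  representation(
    classLabel = "character", alphaHat = "numeric", fHat = "numeric",
    logLik = "numeric", nGenes = "integer", nDropped = "integer",
    ciLow = "numeric", ciHigh = "numeric", nBootstrap = "integer",
    nFailed = "integer", seed = "integer", draws = "numeric"
  ),
  prototype(classLabel = NA_character_, ciLow = NA_real_, ciHigh = NA_real_,
            nBootstrap = 0L, nFailed = 0L, nDropped = 0L, seed = NA_integer_,
            draws = numeric())
)

setValidity("AlphaEstimate", function(object) {
  if (length(object@alphaHat) != 1 || length(object@fHat) != 1)
    return("alphaHat and fHat must be scalars")
  if (is.finite(object@alphaHat) && object@alphaHat >= 1)
    return("alphaHat must be < 1")
  if (is.finite(object@fHat) && (object@fHat <= 0 || object@fHat > 1))
    return("fHat must lie in (0, 1]")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ciLow must not exceed ciHigh")
  TRUE
})

#' Ordered phylostratigraphic lineage
#'
#' The ordered series of clades on the focal species' taxonomic path, from the
#' root (rank 1, oldest, e.g. cellular organisms) to the focal species itself
#' (youngest rank). Each stratum owns a set of taxon ids; homology hits are
#' mapped to strata through these ids. A condensation map groups the ranks
#' into a smaller set of ordered analysis categories.
#'
#' @slot strata data.frame with columns `rank` (consecutive integers from 1)
#'   and `name` (unique clade labels).
#' @slot taxa data.frame with columns `taxon_id` (integer) and `rank`, mapping
#'   subject taxa to strata; each taxon id belongs to exactly one stratum.
#' @slot condensed character vector, one category label per rank, constant or
#'   order-preserving along the lineage.
#' @export
setClass("PhyloLineage",
  representation(strata = "data.frame", taxa = "data.frame",
                 condensed = "character")
)

setValidity("PhyloLineage", function(object) {
  st <- object@strata
  if (!all(c("rank", "name") %in% colnames(st)))
    return("strata must have columns rank, name")
  if (!identical(as.integer(st$rank), seq_len(nrow(st))))
    return("ranks must be consecutive integers starting at 1")
  if (anyDuplicated(st$name))
    return("stratum names must be unique")
  tx <- object@taxa
  if (!all(c("taxon_id", "rank") %in% colnames(tx)))
    return("taxa must have columns taxon_id, rank")
  if (anyDuplicated(tx$taxon_id))
    return("each taxon_id must map to exactly one stratum")
  if (nrow(tx) && !all(tx$rank %in% st$rank))
    return("taxa reference ranks outside the lineage")
  if (length(object@condensed) != nrow(st))
    return("condensed map must assign a category to every rank")
  # order-preserving: first occurrence order of categories must follow rank
  idx <- match(object@condensed, unique(object@condensed))
  if (is.unsorted(idx))
    return("condensation must be order-preserving along the lineage")
  TRUE
})

#' A filtered set of variant sites with genotypes
#'
#' Minimal container for biallelic-candidate variant sites: per-site
#' coordinates, alleles and quality, plus a character genotype matrix over the
#' ingroup samples and the single outgroup sample.
#'
#' @slot sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`.
#' @slot geno character matrix, one row per site, one column per sample;
#'   VCF-style genotype strings (`"0/0"`, `"0/1"`, `"./."`, ...).
#' @slot outgroup name of the outgroup column in `geno`.
#' @export
setClass("VariantSet",
  representation(sites = "data.frame", geno = "matrix", outgroup = "character")
)

setValidity("VariantSet", function(object) {
  cn <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(cn %in% colnames(object@sites)))
    return(paste("sites must have columns", paste(cn, collapse = ", ")))
  if (nrow(object@sites) != nrow(object@geno))
    return("geno must have one row per site")
  if (nrow(object@sites) && any(object@sites$pos < 1))
    return("positions are 1-based and must be >= 1")
  if (length(object@outgroup) != 1 ||
      !(object@outgroup %in% colnames(object@geno)))
    return("outgroup must name one genotype column")
  TRUE
})

#' Coding gene model
#'
#' One transcript's coding sequence with its genomic mapping. The CDS is
#' stored 5' to 3' in reading frame; `map` gives, for each CDS base in order,
#' its genomic coordinate on `contig` (for minus-strand models the map is
#' therefore decreasing).
#'
#' @slot geneId,txId gene and transcript identifiers.
#' @slot contig contig/chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot cds [Biostrings::DNAString] of the coding sequence, length divisible
#'   by 3, no internal stop codons.
#' @slot map integer vector of genomic positions, one per CDS base.
#' @export
setClass("CodingGeneModel",
  representation(geneId = "character", txId = "character", contig = "character",
                 strand = "character", cds = "DNAString", map = "integer")
)

setValidity("CodingGeneModel", function(object) {
  n <- length(object@cds)
  if (n %% 3 != 0)
    return("CDS length must be divisible by 3")
  if (length(object@map) != n)
    return("map must give one genomic position per CDS base")
  if (!object@strand %in% c("+", "-"))
    return("strand must be '+' or '-'")
  s <- as.character(object@cds)
  codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (n >= 6 && any(aa[-length(aa)] == "*", na.rm = TRUE))
    return("CDS contains an internal stop codon")
  TRUE
})
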