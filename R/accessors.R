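#' Construct an MKCountSet
#'
#' @param counts data.frame with columns `gene_id`, `Pn`, `Ps`, `Dn`, `Ds`.
#' @param classes optional character vector of caste-class labels
#'   (`"reproductive"`, `"worker"`, `"NDE"`), recycled NA if missing.
#' @return an [MKCountSet-class] object.
#' @examples
#' mk <- MKCountSet(data.frame(gene_id = "g1", Pn = 2, Ps = 3, Dn = 1, Ds = 4))
#' mkCounts(mk)
#' @export
MKCountSet <- function(counts, classes = NULL) {
  counts <- as.data.frame(counts)
  counts$gene_id <- as.character(counts$gene_id)
  for (cl in c("Pn", "Ps", "Dn", "Ds")) counts[[cl]] <- as.integer(counts[[cl]])
  if (is.null(classes)) classes <- rep(NA_character_, nrow(counts))
  new("MKCountSet", counts = counts[, c("gene_id", "Pn", "Ps", "Dn", "Ds")],
      classes = as.character(classes))
}

#' @rdname MKCountSet
#' @param x an `MKCountSet`.
#' @export
mkCounts <- function(x) x@counts

#' @rdname MKCountSet
#' @export
geneIds <- function(x) x@counts$gene_id

#' @rdname MKCountSet
#' @export
geneClasses <- function(x) x@classes

#' @rdname MKCountSet
#' @param value replacement class labels.
#' @export
`geneClasses<-` <- function(x, value) {
  x@classes <- as.character(value)
  validObject(x)
  x
}

#' Subset an MKCountSet by gene index or class label
#'
#' @param x an `MKCountSet`.
#' @param i integer/logical index, or a class label string.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "MKCountSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i) && length(i) == 1 &&
      i %in% c("reproductive", "worker", "NDE"))
    i <- which(!is.na(x@classes) & x@classes == i)
  new("MKCountSet", counts = x@counts[i, , drop = FALSE],
      classes = x@classes[i])
})

setMethod("length", "MKCountSet", function(x) nrow(x@counts))

setMethod("show", "MKCountSet", function(object) {
  cat("MKCountSet with", nrow(object@counts), "genes\n")
  tab <- table(factor(object@classes,
                      levels = c("reproductive", "worker", "NDE")),
               useNA = "ifany")
  if (any(!is.na(object@classes))) {
    cat("  classes:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  cat("  total counts: Pn=", sum(object@counts$Pn),
      " Ps=", sum(object@counts$Ps),
      " Dn=", sum(object@counts$Dn),
      " Ds=", sum(object@counts$Ds), "\n", sep = "")
})

#' @rdname AlphaEstimate-class
#' @param x an `AlphaEstimate`.
#' @export
alphaHat <- function(x) x@alphaHat

#' @rdname AlphaEstimate-class
#' @export
constraintHat <- function(x) x@fHat

#' @rdname AlphaEstimate-class
#' @export
alphaCI <- function(x) c(lower = x@ciLow, upper = x@ciHigh)

#' @rdname AlphaEstimate-class
#' @export
bootstrapDraws <- function(x) x@draws

setMethod("show", "AlphaEstimate", function(object) {
  lab <- if (is.na(object@classLabel)) "all genes" else object@classLabel
  cat("AlphaEstimate [", lab, "]\n", sep = "")
  cat(sprintf("  alpha = %.4f, f = %.4f (logLik %.2f, %d genes",
              object@alphaHat, object@fHat, object@logLik, object@nGenes))
  if (object@nDropped > 0) cat(",", object@nDropped, "all-zero dropped")
  cat(")\n")
  if (object@nBootstrap > 0) {
    cat(sprintf("  95%% CI [%.4f, %.4f] from %d bootstrap replicates",
                object@ciLow, object@ciHigh,
                object@nBootstrap - object@nFailed))
    if (object@nFailed > 0) cat(sprintf(" (%d failed)", object@nFailed))
    cat("\n")
  }
})

#' @rdname PhyloLineage-class
#' @param x a `PhyloLineage`.
#' @export
strataTable <- function(x) x@strata

#' @rdname PhyloLineage-class
#' @export
nStrata <- function(x) nrow(x@strata)

#' @rdname PhyloLineage-class
#' @export
condensedCategories <- function(x) unique(x@condensed)

setMethod("show", "PhyloLineage", function(object) {
  cat("PhyloLineage with", nrow(object@strata), "strata (rank 1 =",
      object@strata$name[1], "... youngest =",
      object@strata$name[nrow(object@strata)], ")\n")
  cat("  condensed into", length(unique(object@condensed)), "categories:",
      paste(unique(object@condensed), collapse = ", "), "\n")
  cat(" ", nrow(object@taxa), "taxon ids mapped\n")
})

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet:", nrow(object@sites), "sites,",
      ncol(object@geno) - 1L, "ingroup samples + outgroup '",
      object@outgroup, "'\n", sep = " ")
})

#' @rdname VariantSet-class
#' @param x a `VariantSet`.
#' @export
variantSites <- function(x) x@sites

#' @rdname VariantSet-class
#' @export
genotypes <- function(x) x@geno

#' @rdname VariantSet-class
#' @export
outgroupSample <- function(x) x@outgroup

setMethod("show", "CodingGeneModel", function(object) {
  cat("CodingGeneModel", object@txId, "(gene", object@geneId, ")",
      length(object@cds), "bp on", object@contig, object@strand, "\n")
})
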