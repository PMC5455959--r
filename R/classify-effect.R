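COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-nucleotide variant against a coding gene model
#'
#' Substitutes the alternate allele into the reference codon of the model's
#' CDS (reverse-complementing alleles for minus-strand models) and compares
#' the translated amino acids under the standard genetic code.
#'
#' @param model a [CodingGeneModel-class].
#' @param pos 1-based genomic position of the variant on the model's contig.
#' @param ref,alt single-base reference and alternate alleles (genomic
#'   strand).
#' @param chrom optional contig name; checked against the model when given.
#' @param code named character vector mapping codons to amino acids
#'   (default standard genetic code).
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"stop_affected"`
#'   (stop gained or lost), or `"noncoding"` when the position does not fall
#'   in the model's CDS.
#' @examples
#' sim <- simCDSVariants(1, seed = 1)
#' m <- sim$models[[1]]
#' classifyEffect(m, sim$truth$pos[1], sim$truth$ref[1], sim$truth$alt[1])
#' @export
classifyEffect <- function(model, pos, ref, alt, chrom = NULL,
                           code = Biostrings::GENETIC_CODE) {
  if (!is.null(chrom) && chrom != model@contig) return("noncoding")
  i <- match(pos, model@map)
  if (is.na(i)) return("noncoding")
  cds <- as.character(model@cds)
  ref_cds <- if (model@strand == "+") ref else unname(COMPLEMENT[ref])
  alt_cds <- if (model@strand == "+") alt else unname(COMPLEMENT[alt])
  have <- substring(cds, i, i)
  if (have != ref_cds)
    stop(sprintf(
      "reference mismatch at %s:%d (CDS has %s, variant REF implies %s)",
      model@contig, pos, have, ref_cds), call. = FALSE)
  ci <- (i - 1) %/% 3
  ref_codon <- substring(cds, ci * 3 + 1, ci * 3 + 3)
  within <- i - ci * 3
  alt_codon <- ref_codon
  substring(alt_codon, within, within) <- alt_cds
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  if (aa_ref == "*" || aa_alt == "*") {
    if (aa_ref == aa_alt) return("synonymous")
    return("stop_affected")
  }
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Classify every site in a VariantSet against a set of gene models
#'
#' @param vs a [VariantSet-class] (expected already filtered to SNVs).
#' @param models list of [CodingGeneModel-class] objects.
#' @return data.frame with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `tx_id` and `effect`; sites outside every model get
#'   `effect = "noncoding"` and `NA` gene.
#' @export
classifyVariants <- function(vs, models) {
  s <- variantSites(vs)
  key <- unlist(lapply(models, function(m) paste(m@contig, m@map)))
  mod_idx <- rep(seq_along(models), vapply(models, function(m)
    length(m@map), integer(1)))
  lookup <- match(paste(s$chrom, s$pos), key)
  eff <- character(nrow(s))
  gid <- rep(NA_character_, nrow(s))
  tid <- rep(NA_character_, nrow(s))
  for (r in seq_len(nrow(s))) {
    if (is.na(lookup[r])) {
      eff[r] <- "noncoding"
      next
    }
    m <- models[[mod_idx[lookup[r]]]]
    eff[r] <- classifyEffect(m, s$pos[r], s$ref[r], s$alt[r],
                             chrom = s$chrom[r])
    if (eff[r] != "noncoding") {
      gid[r] <- m@geneId
      tid[r] <- m@txId
    }
  }
  cbind(s[, c("chrom", "pos", "ref", "alt")],
        data.frame(gene_id = gid, tx_id = tid, effect = eff))
}
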