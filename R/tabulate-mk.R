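#' Aggregate classified sites into per-gene McDonald-Kreitman tables
#'
#' For every coding site the ingroup genotype calls decide its row and the
#' effect class its column:
#' * a site segregating within the ingroup (both alleles observed among
#'   non-missing ingroup calls) increments `Pn` or `Ps`;
#' * a site monomorphic in the ingroup whose allele differs from a confident
#'   homozygous outgroup call increments `Dn` or `Ds`;
#' * a site both segregating and differing from the outgroup counts as
#'   polymorphism only;
#' * a site whose outgroup call is heterozygous or missing contributes no
#'   divergence information.
#'
#' Stop-gain/stop-loss variants are counted as nonsynonymous by default.
#' Genes in `models` with no qualifying site receive all-zero rows.
#'
#' @param vs a [VariantSet-class].
#' @param models list of [CodingGeneModel-class] objects (defines the gene
#'   universe), or `NULL` to take genes from `effects`.
#' @param effects optional data.frame from [classifyVariants()]; computed
#'   from `vs` and `models` when missing.
#' @param count_stop_affected count stop-affected variants as nonsynonymous
#'   (`TRUE`, default) or drop them.
#' @return an [MKCountSet-class], one row per gene.
#' @examples
#' sim <- simCDSVariants(3, seed = 2)
#' tabulateMK(sim$variants, sim$models)
#' @export
tabulateMK <- function(vs, models = NULL, effects = NULL,
                       count_stop_affected = TRUE) {
  if (is.null(effects)) {
    stopIfNot(!is.null(models), "provide models and/or a classified table")
    effects <- classifyVariants(vs, models)
  }
  gt <- genotypes(vs)
  og <- outgroupSample(vs)
  in_gt <- gt[, setdiff(colnames(gt), og), drop = FALSE]
  out_gt <- gt[, og]

  genes <- if (!is.null(models)) {
    unique(vapply(models, function(m) m@geneId, character(1)))
  } else unique(stats::na.omit(effects$gene_id))
  tab <- data.frame(gene_id = genes, Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L)
  rownames(tab) <- genes

  allele_set <- function(g) {
    a <- unlist(strsplit(g, "[/|]"))
    unique(a[a != "."])
  }
  for (r in seq_len(nrow(effects))) {
    eff <- effects$effect[r]
    if (eff == "noncoding") next
    gid <- effects$gene_id[r]
    if (!gid %in% genes)
      stop(sprintf("site %s:%d assigned to unknown gene '%s'",
                   effects$chrom[r], effects$pos[r], gid), call. = FALSE)
    if (eff == "stop_affected") {
      if (!count_stop_affected) next
      eff <- "nonsynonymous"
    }
    col <- if (eff == "nonsynonymous") "n" else "s"
    in_alleles <- allele_set(in_gt[r, ])
    if (length(in_alleles) >= 2) {
      cell <- paste0("P", col)
      tab[gid, cell] <- tab[gid, cell] + 1L
    } else if (length(in_alleles) == 1) {
      out_alleles <- allele_set(out_gt[r])
      if (length(out_alleles) == 1 && out_alleles != in_alleles) {
        cell <- paste0("D", col)
        tab[gid, cell] <- tab[gid, cell] + 1L
      }
    }
  }
  rownames(tab) <- NULL
  MKCountSet(tab)
}
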