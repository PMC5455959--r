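#' Simulate homology hit tables with planted gene ages
#'
#' For every gene with a planted stratum rank, emits at least one hit in that
#' stratum with an E-value passing the threshold, plus a random number of
#' passing hits in younger strata (homologs are necessarily detectable in
#' clades nested within the oldest one). Genes planted in the youngest,
#' species-specific stratum receive no hit at all by default (with
#' `self_hits = TRUE`, a focal-species self-hit that age assignment
#' ignores). Optionally, decoy hits in strata older than
#' the planted one are added with E-values between the strict and a liberal
#' threshold, to exercise threshold sensitivity.
#'
#' @param gene_ages integer vector of planted stratum ranks, named by gene id.
#' @param lineage a [PhyloLineage-class].
#' @param evalue_pass strict E-value threshold the planted hits must pass.
#' @param decoy_frac fraction of non-species-specific genes that also receive
#'   an older-stratum decoy hit with E-value in `(evalue_pass, 0.1)`.
#' @param self_hits emit a focal-species self-hit for species-specific genes.
#' @param seed integer seed.
#' @return data.frame with outfmt-6-like columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `evalue`, `bitscore`, `staxid`.
#' @export
simBlastHits <- function(gene_ages, lineage, evalue_pass = 1e-5,
                         decoy_frac = 0, self_hits = FALSE, seed = 1L) {
  stopIfNot(is(lineage, "PhyloLineage"), "lineage must be a PhyloLineage")
  L <- nStrata(lineage)
  stopIfNot(all(gene_ages >= 1 & gene_ages <= L),
            "planted ranks fall outside the lineage")
  genes <- names(gene_ages)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_along(gene_ages))
  # one representative taxon id per stratum, for hit placement
  taxon_of_rank <- vapply(seq_len(L), function(r) {
    ids <- lineage@taxa$taxon_id[lineage@taxa$rank == r]
    stopIfNot(length(ids) > 0, paste("no taxon id for rank", r))
    ids[1]
  }, numeric(1))

  withSeed(seed, {
    rows <- vector("list", length(gene_ages))
    for (i in seq_along(gene_ages)) {
      r <- gene_ages[[i]]
      q <- genes[i]
      if (r == L) {
        # species-specific: no age-informative hit
        if (self_hits)
          rows[[i]] <- data.frame(qseqid = q, sseqid = paste0(q, "_self"),
                                  pident = 100, length = 200,
                                  evalue = 1e-180, bitscore = 400,
                                  staxid = taxon_of_rank[L])
        next
      }
      younger <- if (r + 1 <= L - 1) {
        pool <- (r + 1):(L - 1)   # resample() idiom: pool may have length 1
        pool[sample.int(length(pool), size = sample(0:2, 1), replace = TRUE)]
      } else integer()
      ranks <- c(r, younger)
      ev <- 10^stats::runif(length(ranks), -60, log10(evalue_pass) - 0.5)
      hit <- data.frame(
        qseqid = q,
        sseqid = sprintf("subj_r%02d_%s", ranks, q),
        pident = round(stats::runif(length(ranks), 35, 95), 1),
        length = round(stats::runif(length(ranks), 80, 400)),
        evalue = ev,
        bitscore = round(-10 * log10(ev) / 2, 1),
        staxid = taxon_of_rank[ranks]
      )
      if (r > 1 && stats::runif(1) < decoy_frac) {
        older <- sample.int(r - 1, 1)
        hit <- rbind(hit, data.frame(
          qseqid = q, sseqid = sprintf("decoy_r%02d_%s", older, q),
          pident = 25, length = 60,
          evalue = 10^stats::runif(1, log10(evalue_pass) + 0.5, -1.2),
          bitscore = 30, staxid = taxon_of_rank[older]
        ))
      }
      rows[[i]] <- hit
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(qseqid = character(), sseqid = character(),
                        pident = numeric(), length = numeric(),
                        evalue = numeric(), bitscore = numeric(),
                        staxid = numeric())
    rownames(out) <- NULL
    out
  })
}
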