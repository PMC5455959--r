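#' Simulate coding sequences and variants with known effects
#'
#' Builds random coding gene models (ATG start, stop-free interior, terminal
#' stop codon; one gene per contig, plus strand, CDS starting at position 1)
#' and places single-nucleotide variants at known positions: `n_poly` sites
#' segregating within the ingroup and `n_div` sites fixed for the alternate
#' allele in the outgroup, per gene. The true synonymous/nonsynonymous status
#' of every variant is computed by translating the reference versus alternate
#' codon under the standard genetic code.
#'
#' @param n_genes number of genes.
#' @param codons_per_gene codons per CDS including start and stop (>= 5).
#' @param n_poly,n_div polymorphic and divergent variants per gene.
#' @param n_ingroup number of ingroup samples (default 22, plus one outgroup).
#' @param seed integer seed.
#' @return list with `models` (list of [CodingGeneModel-class]), `fasta`
#'   ([Biostrings::DNAStringSet] of the CDSs), `variants` (a
#'   [VariantSet-class]), and `truth` (data.frame: chrom, pos, ref, alt,
#'   gene_id, site_type poly/div, effect).
#' @export
simCDSVariants <- function(n_genes, codons_per_gene = 60, n_poly = 4,
                           n_div = 4, n_ingroup = 22, seed = 1L) {
  stopIfNot(n_genes >= 1 && codons_per_gene >= 5,
            "n_genes >= 1 and codons_per_gene >= 5 required")
  stopIfNot(n_poly + n_div <= 3 * (codons_per_gene - 2),
            "more variants requested than interior positions")
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                      collapse = "")
  interior <- setdiff(all_codons, stops)

  withSeed(seed, {
    samp_names <- c(sprintf("ingroup%02d", seq_len(n_ingroup)), "outgroup")
    models <- vector("list", n_genes)
    seqs <- character(n_genes)
    var_rows <- list()
    geno_rows <- list()
    truth_rows <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%04d", g)
      contig <- sprintf("ctg%04d", g)
      cds <- paste0("ATG",
                    paste(sample(interior, codons_per_gene - 2,
                                 replace = TRUE), collapse = ""),
                    sample(stops, 1))
      seqs[g] <- cds
      n_cds <- nchar(cds)
      models[[g]] <- new("CodingGeneModel", geneId = gid,
                         txId = paste0(gid, ".t1"), contig = contig,
                         strand = "+", cds = Biostrings::DNAString(cds),
                         map = seq_len(n_cds))
      # variant positions in the interior (outside start and stop codons)
      pos <- sample(4:(n_cds - 3), n_poly + n_div)
      refb <- substring(cds, pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1),
                     character(1))
      type <- c(rep("poly", n_poly), rep("div", n_div))
      ci <- (pos - 1) %/% 3
      ref_codon <- substring(cds, ci * 3 + 1, ci * 3 + 3)
      within <- pos - ci * 3
      alt_codon <- ref_codon
      substring(alt_codon, within, within) <- altb
      aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
      aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
      effect <- ifelse(aa_ref == "*" | aa_alt == "*", "stop_affected",
                       ifelse(aa_ref == aa_alt, "synonymous",
                              "nonsynonymous"))
      gt <- matrix("0/0", length(pos), length(samp_names),
                   dimnames = list(NULL, samp_names))
      for (k in seq_along(pos)) {
        if (type[k] == "poly") {
          carriers <- sample.int(n_ingroup, sample(1:(n_ingroup - 1), 1))
          gt[k, carriers] <- sample(c("0/1", "1/1"), length(carriers),
                                    replace = TRUE)
          # keep it segregating: at least one ref-carrying ingroup sample
          gt[k, "outgroup"] <- "0/0"
        } else {
          gt[k, "outgroup"] <- "1/1"
        }
      }
      ord <- order(pos)
      var_rows[[g]] <- data.frame(chrom = contig, pos = pos[ord],
                                  ref = refb[ord], alt = altb[ord],
                                  qual = round(stats::runif(length(pos),
                                                            60, 500), 1))
      geno_rows[[g]] <- gt[ord, , drop = FALSE]
      truth_rows[[g]] <- data.frame(chrom = contig, pos = pos[ord],
                                    ref = refb[ord], alt = altb[ord],
                                    gene_id = gid, site_type = type[ord],
                                    effect = effect[ord])
    }
    fasta <- Biostrings::DNAStringSet(seqs)
    names(fasta) <- vapply(models, function(m) m@txId, character(1))
    sites <- do.call(rbind, var_rows)
    rownames(sites) <- NULL
    variants <- new("VariantSet", sites = sites,
                    geno = do.call(rbind, geno_rows), outgroup = "outgroup")
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(models = models, fasta = fasta, variants = variants, truth = truth)
  })
}

#' Write a VariantSet as a minimal VCF v4.2 file
#'
#' @param vs a [VariantSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantsVCF <- function(vs, path) {
  s <- variantSites(vs)
  gt <- genotypes(vs)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i],
            format(s$qual[i], trim = TRUE), "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
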