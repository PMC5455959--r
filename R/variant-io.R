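#' Read variants from a VCF file into a VariantSet
#'
#' Parses a VCF v4.x file (gzipped accepted) with `vcfR` and extracts the
#' coordinates, alleles, site quality and per-sample GT strings. All samples
#' other than `outgroup` are treated as the ingroup.
#'
#' @param path VCF file path.
#' @param outgroup name of the outgroup sample column.
#' @return a [VariantSet-class].
#' @export
readVariantsVCF <- function(path, outgroup) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  stopIfNot(outgroup %in% colnames(gt),
            paste("outgroup sample", outgroup, "not found in VCF"))
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  new("VariantSet", sites = sites, geno = unname(gt) |>
        `dimnames<-`(list(NULL, colnames(gt))), outgroup = outgroup)
}

#' Build coding gene models from CDS sequences and a CDS-mapping table
#'
#' The mapping table is a GFF3-lite TSV with one row per CDS segment:
#' columns `gene_id`, `transcript_id`, `contig`, `start`, `end`, `strand`
#' (`phase` optional, ignored: CDS sequences are expected in frame). Segments
#' of a transcript are concatenated in genomic order (reverse order,
#' complement handled at classification time, for minus-strand models) to
#' produce the genomic position of every CDS base.
#'
#' @param cds a named [Biostrings::DNAStringSet] of in-frame CDS sequences
#'   (names = transcript ids), or a FASTA path.
#' @param map data.frame as above, or a TSV path.
#' @return named list of [CodingGeneModel-class], by transcript id.
#' @export
readCDSModels <- function(cds, map) {
  if (is.character(cds)) cds <- Biostrings::readDNAStringSet(cds)
  if (is.character(map)) map <- readTsv(map)
  need <- c("gene_id", "transcript_id", "contig", "start", "end", "strand")
  stopIfNot(all(need %in% colnames(map)),
            paste("mapping table needs columns",
                  paste(need, collapse = ", ")))
  models <- list()
  for (tx in unique(map$transcript_id)) {
    rows <- map[map$transcript_id == tx, , drop = FALSE]
    strand <- rows$strand[1]
    stopIfNot(tx %in% names(cds),
              paste("no CDS sequence for transcript", tx))
    if (strand == "+") {
      rows <- rows[order(rows$start), , drop = FALSE]
      gpos <- unlist(mapply(seq, rows$start, rows$end, SIMPLIFY = FALSE))
    } else {
      rows <- rows[order(rows$start, decreasing = TRUE), , drop = FALSE]
      gpos <- unlist(mapply(function(s, e) seq(e, s), rows$start, rows$end,
                            SIMPLIFY = FALSE))
    }
    models[[tx]] <- new("CodingGeneModel", geneId = rows$gene_id[1],
                        txId = tx, contig = rows$contig[1], strand = strand,
                        cds = cds[[tx]], map = as.integer(gpos))
  }
  models
}
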