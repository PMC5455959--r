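#' Filter variant sites to biallelic, well-genotyped, high-quality SNVs
#'
#' Applies the four site filters in order: (1) indels (any allele longer than
#' one base) removed; (2) sites with more than two alleles removed; (3) sites
#' with more than `max_missing` missing genotype calls removed; (4) sites with
#' quality strictly below `min_quality` removed (quality exactly at the
#' threshold is retained). Each removed site is tallied under the first rule
#' it violates.
#'
#' @param vs a [VariantSet-class].
#' @param max_missing maximum tolerated fraction of missing calls (over
#'   ingroup plus outgroup samples).
#' @param min_quality minimum phred site quality retained.
#' @return list with `variants` (filtered `VariantSet`) and `tally`, a named
#'   integer vector `c(indel, multiallelic, missingness, quality, retained)`;
#'   the tally sums to the number of input sites.
#' @examples
#' sim <- simCDSVariants(2, seed = 1)
#' filterSites(sim$variants)$tally
#' @export
filterSites <- function(vs, max_missing = 0.10, min_quality = 40) {
  s <- variantSites(vs)
  gt <- genotypes(vs)
  n <- nrow(s)
  bad_gt <- grepl("[^0-9/|.]", gt)
  if (any(bad_gt)) {
    i <- arrayInd(which(bad_gt)[1], dim(gt))[1, 1]
    stop(sprintf("malformed genotype string at %s:%d",
                 s$chrom[i], s$pos[i]), call. = FALSE)
  }
  alt_alleles <- strsplit(s$alt, ",", fixed = TRUE)
  is_indel <- nchar(s$ref) != 1L |
    vapply(alt_alleles, function(a) any(nchar(a) != 1L), logical(1))
  n_alt <- lengths(alt_alleles)
  is_multi <- !is_indel & n_alt > 1L
  miss_frac <- rowMeans(gt == "./." | gt == "." | gt == ".|.")
  is_miss <- !is_indel & !is_multi & miss_frac > max_missing
  low_q <- !is_indel & !is_multi & !is_miss &
    (is.na(s$qual) | s$qual < min_quality)
  keep <- !(is_indel | is_multi | is_miss | low_q)
  tally <- c(indel = sum(is_indel), multiallelic = sum(is_multi),
             missingness = sum(is_miss), quality = sum(low_q),
             retained = sum(keep))
  out <- new("VariantSet", sites = s[keep, , drop = FALSE] |>
               `rownames<-`(NULL),
             geno = gt[keep, , drop = FALSE], outgroup = outgroupSample(vs))
  list(variants = out, tally = tally)
}
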