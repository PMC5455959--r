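fourSiteSet <- function() {
  sites <- data.frame(
    chrom = "c1", pos = c(10L, 20L, 30L, 40L, 50L),
    ref = c("A", "A", "C", "G", "T"),
    alt = c("AT", "C,G", "T", "A", "C"),
    qual = c(100, 100, 100, 39.99, 40)
  )
  geno <- matrix("0/0", 5, 23,
                 dimnames = list(NULL, c(sprintf("s%02d", 1:22), "outgroup")))
  makeVariantSet(sites, geno)
}

test_that("site filters apply in order and the tally conserves sites", {
  fr <- filterSites(fourSiteSet())
  expect_equal(unname(fr$tally),
               c(1L, 1L, 0L, 1L, 2L), ignore_attr = TRUE)  # indel, multi, miss, qual, kept
  expect_equal(sum(fr$tally), 5)
  # quality exactly 40 retained ("lower than" is strict)
  expect_true(50 %in% variantSites(fr$variants)$pos)
  expect_false(40 %in% variantSites(fr$variants)$pos)

  # 3 of 23 missing (13%) exceeds the 10% cutoff
  vs <- fourSiteSet()
  g <- genotypes(vs)
  g[3, 1:3] <- "./."
  vs2 <- makeVariantSet(variantSites(vs), g)
  fr2 <- filterSites(vs2)
  expect_equal(unname(fr2$tally["missingness"]), 1L)
  expect_false(30 %in% variantSites(fr2$variants)$pos)
  # 2 of 23 missing (8.7%) passes
  g2 <- genotypes(vs)
  g2[3, 1:2] <- "./."
  expect_true(30 %in% variantSites(
    filterSites(makeVariantSet(variantSites(vs), g2))$variants)$pos)
})

test_that("a site violating several rules is tallied under the first", {
  vs <- fourSiteSet()
  s <- variantSites(vs)
  s$qual[1] <- 1  # indel AND low quality
  fr <- filterSites(makeVariantSet(s, genotypes(vs)))
  expect_equal(unname(fr$tally["indel"]), 1L)
  expect_equal(unname(fr$tally["quality"]), 1L)  # only site 4
})

test_that("malformed genotype strings raise a coordinate-bearing error", {
  vs <- fourSiteSet()
  g <- genotypes(vs)
  g[2, 5] <- "0/x"
  expect_error(filterSites(makeVariantSet(variantSites(vs), g)), "c1:20")
})

test_that("codon classification handles canonical and strand-aware cases", {
  # CDS: ATG GGT AAA TAA  (Met Gly Lys stop)
  m <- makeModel("ATGGGTAAATAA")
  expect_identical(classifyEffect(m, 6, "T", "C"), "synonymous")    # GGT->GGC
  expect_identical(classifyEffect(m, 7, "A", "G"), "nonsynonymous") # AAA->GAA
  expect_identical(classifyEffect(m, 8, "A", "G"), "nonsynonymous") # AAA->AGA
  expect_identical(classifyEffect(m, 10, "T", "C"), "stop_affected") # TAA->CAA
  expect_identical(classifyEffect(m, 100, "A", "G"), "noncoding")
  expect_error(classifyEffect(m, 6, "G", "C"), "mismatch")

  # minus strand: genomic positions 12..1 map to CDS 1..12
  mm <- makeModel("ATGGGTAAATAA", strand = "-", map = 12:1)
  # CDS base 6 (T of GGT) sits at genomic position 7; genomic ref is A
  expect_identical(classifyEffect(mm, 7, "A", "G"), "synonymous")   # GGT->GGC
  # CDS base 7 (A of AAA) at genomic position 6, genomic ref T
  expect_identical(classifyEffect(mm, 6, "T", "C"), "nonsynonymous")
})

test_that("swapping ref and alt never flips synonymous vs nonsynonymous", {
  sim <- simCDSVariants(3, codons_per_gene = 40, n_poly = 6, n_div = 6,
                        seed = 21)
  models <- sim$models
  names(models) <- vapply(models, function(m) m@geneId, character(1))
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    if (tr$effect == "stop_affected") next
    m <- models[[tr$gene_id]]
    fwd <- classifyEffect(m, tr$pos, tr$ref, tr$alt)
    # build the alternate-background model and classify the reverse change
    cds <- as.character(m@cds)
    substr(cds, tr$pos, tr$pos) <- tr$alt
    if (any(ORACLE_CODE[substring(cds, seq(1, nchar(cds) - 5, 3),
                                  seq(3, nchar(cds) - 3, 3))] == "*"))
      next  # alt background gained an internal stop; not a valid model
    m_alt <- makeModel(cds, contig = m@contig)
    rev <- classifyEffect(m_alt, tr$pos, tr$alt, tr$ref)
    expect_identical(fwd, rev)
  }
})

test_that("MK tabulation counts each qualifying site in exactly one cell", {
  # hand-built: gene with 2 nonsyn + 3 syn segregating, 1 nonsyn + 4 syn fixed
  eff <- data.frame(
    chrom = "c1", pos = 1:10, ref = "A", alt = "G",
    gene_id = "g1", tx_id = "g1.t1",
    effect = c(rep("nonsynonymous", 2), rep("synonymous", 3),
               "nonsynonymous", rep("synonymous", 4))
  )
  geno <- matrix("0/0", 10, 4,
                 dimnames = list(NULL, c("a", "b", "c", "outgroup")))
  geno[1:5, "a"] <- "0/1"            # segregating in ingroup
  geno[6:10, "outgroup"] <- "1/1"    # fixed difference
  vs <- makeVariantSet(data.frame(chrom = "c1", pos = 1:10, ref = "A",
                                  alt = "G", qual = 100), geno)
  mk <- mkCounts(tabulateMK(vs, models = NULL, effects = eff))
  expect_equal(mk[mk$gene_id == "g1", c("Pn", "Ps", "Dn", "Ds")],
               data.frame(Pn = 2L, Ps = 3L, Dn = 1L, Ds = 4L),
               ignore_attr = TRUE)
  expect_equal(sum(unlist(mk[, c("Pn", "Ps", "Dn", "Ds")])), 10)
})

test_that("polymorphic-and-divergent sites count as polymorphism only; bad outgroup drops divergence", {
  eff <- data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "G",
                    gene_id = "g1", tx_id = "g1.t1", effect = "synonymous")
  geno <- matrix("0/0", 3, 4,
                 dimnames = list(NULL, c("a", "b", "c", "outgroup")))
  geno[1, "a"] <- "0/1"; geno[1, "outgroup"] <- "1/1"  # poly AND divergent
  geno[2, c("a", "b", "c")] <- "1/1"; geno[2, "outgroup"] <- "0/1"  # het outgroup
  geno[3, c("a", "b", "c")] <- "1/1"; geno[3, "outgroup"] <- "./."  # missing outgroup
  vs <- makeVariantSet(data.frame(chrom = "c1", pos = 1:3, ref = "A",
                                  alt = "G", qual = 100), geno)
  mk <- mkCounts(tabulateMK(vs, models = NULL, effects = eff))
  expect_equal(unlist(mk[1, c("Pn", "Ps", "Dn", "Ds")]),
               c(Pn = 0L, Ps = 1L, Dn = 0L, Ds = 0L))
})

test_that("tabulation round-trips the planted truth and zero-site genes get zero rows", {
  sim <- simCDSVariants(6, codons_per_gene = 45, n_poly = 5, n_div = 5,
                        seed = 31)
  fr <- filterSites(sim$variants)
  mk <- mkCounts(tabulateMK(fr$variants, sim$models))
  tr <- sim$truth
  tr$cell <- paste0(ifelse(tr$site_type == "poly", "P", "D"),
                    ifelse(tr$effect == "synonymous", "s", "n"))
  for (g in unique(tr$gene_id)) {
    want <- table(factor(tr$cell[tr$gene_id == g],
                         c("Pn", "Ps", "Dn", "Ds")))
    expect_equal(unlist(mk[mk$gene_id == g, c("Pn", "Ps", "Dn", "Ds")]),
                 c(want), ignore_attr = TRUE)
  }
  # a model with no sites yields an all-zero row
  extra <- makeModel("ATGGGTAAATAA", gene = "gX", tx = "gX.t1",
                     contig = "ctgX")
  mk2 <- mkCounts(tabulateMK(fr$variants, c(sim$models, extra)))
  expect_equal(unlist(mk2[mk2$gene_id == "gX", c("Pn", "Ps", "Dn", "Ds")]),
               c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L))
})

test_that("VCF and gene-model files round-trip through the readers", {
  sim <- simCDSVariants(3, codons_per_gene = 30, n_poly = 3, n_div = 3,
                        seed = 41)
  vcf <- tempfile(fileext = ".vcf")
  writeVariantsVCF(sim$variants, vcf)
  vs <- readVariantsVCF(vcf, "outgroup")
  expect_equal(variantSites(vs)$pos, variantSites(sim$variants)$pos)
  expect_equal(unname(genotypes(vs)), unname(genotypes(sim$variants)))

  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(sim$fasta, fa)
  gff <- data.frame(
    gene_id = vapply(sim$models, function(m) m@geneId, character(1)),
    transcript_id = vapply(sim$models, function(m) m@txId, character(1)),
    contig = vapply(sim$models, function(m) m@contig, character(1)),
    start = 1L,
    end = vapply(sim$models, function(m) length(m@cds), integer(1)),
    strand = "+"
  )
  models <- readCDSModels(fa, gff)
  eff <- classifyVariants(vs, models)
  expect_identical(eff$effect, sim$truth$effect)
})
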