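lin <- defaultLineage()

test_that("the default lineage is a valid 19-stratum, 6-category configuration", {
  expect_true(validObject(lin))
  expect_equal(nStrata(lin), 19)
  expect_equal(length(condensedCategories(lin)), 6)
  expect_identical(condensedCategories(lin),
                   c("cellular organisms", "eukaryotes", "bilaterian animals",
                     "insects", "hymenopterans", "ants"))
})

test_that("transcripts are assigned to the oldest stratum with a passing hit", {
  tax <- function(r) lin@taxa$taxon_id[lin@taxa$rank == r]
  hits <- data.frame(evalue = c(1e-10, 1e-20),
                     staxid = c(tax(2), tax(12)))  # eukaryote + insect
  expect_equal(assignTranscript(hits, lin), 2)

  # no hit below threshold -> youngest species-specific rank
  weak <- data.frame(evalue = c(1e-3, 0.5), staxid = c(tax(2), tax(12)))
  expect_equal(assignTranscript(weak, lin), 19)
  expect_equal(assignTranscript(NULL, lin), 19)

  # boundary: E exactly at the threshold fails ("below" is strict)
  edge <- data.frame(evalue = 1e-5, staxid = tax(1))
  expect_equal(assignTranscript(edge, lin), 19)
  expect_equal(assignTranscript(edge, lin, threshold = 1.0000001e-5), 1)

  # self-hits to the focal species carry no age information
  self <- data.frame(evalue = 1e-100, staxid = tax(19))
  expect_equal(assignTranscript(self, lin), 19)

  expect_error(assignTranscript(data.frame(evalue = 1e-9, staxid = 99999),
                                lin), "99999")
})

test_that("genes take the rank of their longest isoform over 30 aa", {
  ranks <- c(t1 = 3L, t2 = 1L, t3 = 5L, t4 = 2L, t5 = 4L)
  iso <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC", "gC"),
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    protein_length = c(300, 200, 29, 300, 300)
  )
  ga <- assignGene(ranks, iso, lin)
  expect_equal(ga$stratum_rank[ga$gene_id == "gA"], 3)    # longest, not oldest
  expect_true(is.na(ga$stratum_rank[ga$gene_id == "gB"])) # under 30 aa
  expect_equal(ga$stratum_rank[ga$gene_id == "gC"], 2)    # tie -> oldest
  ga_first <- assignGene(ranks, iso, lin, tie = "first")
  expect_equal(ga_first$stratum_rank[ga_first$gene_id == "gC"], 2)
  ga_first2 <- assignGene(c(t4 = 5L, t5 = 2L),
                          iso[iso$gene_id == "gC", ], lin, tie = "first")
  expect_equal(ga_first2$stratum_rank, 5)                 # first-listed
  expect_identical(ga$condensed_category[ga$gene_id == "gA"],
                   "eukaryotes")
})

test_that("condensation partitions all ranks order-preservingly", {
  expect_identical(condense(1, lin), "cellular organisms")
  expect_identical(condense(match("Hymenoptera", strataTable(lin)$name), lin),
                   "hymenopterans")
  cats <- condense(1:19, lin)
  expect_equal(length(unique(cats)), 6)
  idx <- match(cats, condensedCategories(lin))
  expect_false(is.unsorted(idx))      # older ranks never map younger
  expect_equal(sum(table(cats)), 19)  # every rank mapped exactly once
  expect_error(condense(20, lin), "outside")
})

test_that("liberal thresholds only move assignments toward older strata", {
  set.seed(50)
  ages <- sample(1:19, 400, replace = TRUE)
  names(ages) <- sprintf("tx%04d", seq_along(ages))
  hits <- simBlastHits(ages, lin, decoy_frac = 0.4, seed = 51)
  st <- sensitivityThreshold(hits, lin, transcripts = names(ages))
  r_strict <- st$assignments[["rank_1e-05"]]
  r_liberal <- st$assignments[["rank_0.1"]]
  expect_true(all(r_liberal <= r_strict))
  expect_equal(st$agreement, mean(r_liberal == r_strict))

  # a gene whose only old hit is weak moves older under the liberal threshold
  tax1 <- lin@taxa$taxon_id[lin@taxa$rank == 1]
  tax12 <- lin@taxa$taxon_id[lin@taxa$rank == 12]
  one <- data.frame(qseqid = "tx", evalue = c(1e-3, 1e-20),
                    staxid = c(tax1, tax12))
  st1 <- sensitivityThreshold(one, lin)
  expect_equal(st1$assignments[["rank_1e-05"]], 12)
  expect_equal(st1$assignments[["rank_0.1"]], 1)

  # all strong hits: identical under both thresholds
  strong <- simBlastHits(ages, lin, decoy_frac = 0, seed = 52)
  expect_equal(sensitivityThreshold(strong, lin,
                                    transcripts = names(ages))$agreement, 1)
})

test_that("planted strata round-trip through assignment", {
  set.seed(53)
  ages <- sample(1:19, 500, replace = TRUE)
  names(ages) <- sprintf("tx%04d", seq_along(ages))
  hits <- simBlastHits(ages, lin, seed = 54)
  rk <- assignTranscripts(hits, lin, transcripts = names(ages))
  expect_equal(unname(rk[names(ages)]), unname(ages))
})

test_that("lineage configurations round-trip through TSV", {
  tsv <- tempfile(fileext = ".tsv")
  ids <- split(lin@taxa$taxon_id, lin@taxa$rank)
  writeTsv(data.frame(rank = strataTable(lin)$rank,
                      name = strataTable(lin)$name,
                      taxon_ids = vapply(ids, paste, "", collapse = ","),
                      condensed = lin@condensed), tsv)
  lin2 <- readLineage(tsv)
  expect_equal(strataTable(lin2), strataTable(lin))
  expect_equal(lin2@condensed, lin@condensed)
  expect_equal(sort(lin2@taxa$taxon_id), sort(lin@taxa$taxon_id))
})
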