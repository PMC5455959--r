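#' Construct a PhyloLineage
#'
#' @param strata data.frame with columns `rank` (1 = oldest, consecutive) and
#'   `name`; the final rank is the focal-species stratum.
#' @param taxa data.frame with columns `taxon_id` and `rank` mapping subject
#'   taxa to strata.
#' @param condensed character vector of category labels, one per rank,
#'   order-preserving along the lineage.
#' @return a [PhyloLineage-class].
#' @export
PhyloLineage <- function(strata, taxa, condensed) {
  strata <- data.frame(rank = as.integer(strata$rank),
                       name = as.character(strata$name))
  taxa <- data.frame(taxon_id = as.numeric(taxa$taxon_id),
                     rank = as.integer(taxa$rank))
  new("PhyloLineage", strata = strata, taxa = taxa,
      condensed = as.character(condensed))
}

#' Default 19-stratum lineage for the pharaoh ant
#'
#' The ordered clades on the NCBI taxonomic path from cellular organisms down
#' to *Monomorium pharaonis*, condensed into the six analysis categories
#' (cellular organisms, eukaryotes, bilaterian animals, insects,
#' hymenopterans, ants). The stratum names, taxon ids and condensation are a
#' configurable default: supply your own table through [PhyloLineage()] or
#' [readLineage()] to override.
#'
#' @return a [PhyloLineage-class] with 19 strata and 6 condensed categories.
#' @examples
#' defaultLineage()
#' @export
defaultLineage <- function() {
  strata <- data.frame(
    rank = 1:19,
    name = c("cellular organisms", "Eukaryota", "Opisthokonta", "Metazoa",
             "Eumetazoa", "Bilateria", "Protostomia", "Ecdysozoa",
             "Arthropoda", "Pancrustacea", "Hexapoda", "Insecta",
             "Holometabola", "Hymenoptera", "Apocrita", "Aculeata",
             "Formicidae", "Myrmicinae", "Monomorium pharaonis")
  )
  taxa <- data.frame(taxon_id = c(131567, 2759, 33154, 33208, 6072, 33213,
                                  33317, 1206794, 6656, 197562, 6960, 50557,
                                  33392, 7399, 7400, 7434, 36668, 144999,
                                  307658),
                     rank = 1:19)
  condensed <- c("cellular organisms",
                 rep("eukaryotes", 2),
                 rep("bilaterian animals", 8),
                 rep("insects", 2),
                 rep("hymenopterans", 3),
                 rep("ants", 3))
  PhyloLineage(strata, taxa, condensed)
}

#' Read a lineage configuration from TSV or JSON
#'
#' TSV columns: `rank`, `name`, `taxon_ids` (comma-separated) and
#' `condensed`. JSON: an object with `strata` (rank, name, condensed) and
#' `taxa` (taxon_id, rank) arrays.
#'
#' @param path file path ending in `.tsv`/`.txt` or `.json`.
#' @return a [PhyloLineage-class].
#' @export
readLineage <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(PhyloLineage(x$strata, x$taxa, x$strata$condensed))
  }
  tab <- readTsv(path)
  ids <- strsplit(as.character(tab$taxon_ids), ",")
  taxa <- data.frame(taxon_id = as.numeric(unlist(ids)),
                     rank = rep(tab$rank, lengths(ids)))
  PhyloLineage(tab[, c("rank", "name")], taxa, tab$condensed)
}

#' Assign one transcript to its oldest supported phylostratum
#'
#' Returns the minimum (oldest) rank among strata holding at least one hit
#' with E-value strictly below `threshold`. Hits to the focal species' own
#' stratum carry no age information and are ignored. When no hit passes, the
#' transcript is placed in the youngest, species-specific stratum.
#'
#' @param hits data.frame of hits for one transcript with columns `evalue`
#'   and `staxid` (may have zero rows).
#' @param lineage a [PhyloLineage-class].
#' @param threshold E-value threshold (strict `<`).
#' @return the assigned stratum rank (integer).
#' @export
assignTranscript <- function(hits, lineage, threshold = 1e-5) {
  L <- nStrata(lineage)
  if (is.null(hits) || nrow(hits) == 0) return(L)
  rk <- lineage@taxa$rank[match(hits$staxid, lineage@taxa$taxon_id)]
  if (anyNA(rk))
    stop(sprintf("hit taxon id(s) not in lineage: %s",
                 paste(unique(hits$staxid[is.na(rk)]), collapse = ", ")),
         call. = FALSE)
  pass <- hits$evalue < threshold & rk < L   # self-stratum hits ignored
  if (!any(pass)) return(L)
  min(rk[pass])
}

#' Assign every transcript in a hit table
#'
#' @param hits data.frame with columns `qseqid`, `evalue`, `staxid`.
#' @param lineage a [PhyloLineage-class].
#' @param transcripts optional character vector of transcript ids to assign;
#'   transcripts absent from `hits` get the youngest rank. Defaults to the
#'   transcripts present in `hits`.
#' @param threshold E-value threshold (strict `<`).
#' @return named integer vector of ranks, one per transcript.
#' @export
assignTranscripts <- function(hits, lineage, transcripts = NULL,
                              threshold = 1e-5) {
  if (is.null(transcripts)) transcripts <- unique(hits$qseqid)
  split_hits <- split(hits, factor(hits$qseqid, levels = transcripts))
  out <- vapply(transcripts, function(tx)
    as.integer(assignTranscript(split_hits[[tx]], lineage, threshold)),
    integer(1))
  names(out) <- transcripts
  out
}

#' Assign genes from transcript-level phylostrata
#'
#' Isoforms shorter than `min_aa` amino acids are excluded; each gene takes
#' the rank of its longest remaining isoform. Ties on length are broken
#' toward the oldest rank by default (`tie = "oldest"`), or toward the
#' first-listed isoform (`tie = "first"`). Genes with no isoform passing the
#' length filter are reported unassigned (`NA` rank).
#'
#' @param tx_ranks named integer vector of transcript ranks (from
#'   [assignTranscripts()]).
#' @param isoforms data.frame with columns `gene_id`, `transcript_id`,
#'   `protein_length` (amino acids).
#' @param lineage a [PhyloLineage-class] (for the condensed category).
#' @param min_aa minimum protein length retained (default 30).
#' @param tie `"oldest"` or `"first"`.
#' @return data.frame with `gene_id`, `stratum_rank`, `condensed_category`,
#'   `assigned_from` (transcript id; `NA` when unassigned).
#' @export
assignGene <- function(tx_ranks, isoforms, lineage, min_aa = 30,
                       tie = c("oldest", "first")) {
  tie <- match.arg(tie)
  need <- c("gene_id", "transcript_id", "protein_length")
  stopIfNot(all(need %in% colnames(isoforms)),
            paste("isoforms needs columns", paste(need, collapse = ", ")))
  genes <- unique(isoforms$gene_id)
  out <- data.frame(gene_id = genes, stratum_rank = NA_integer_,
                    condensed_category = NA_character_,
                    assigned_from = NA_character_)
  for (k in seq_along(genes)) {
    iso <- isoforms[isoforms$gene_id == genes[k], , drop = FALSE]
    stopIfNot(nrow(iso) >= 1, paste("gene", genes[k], "has no isoforms"))
    iso <- iso[iso$protein_length >= min_aa, , drop = FALSE]
    if (nrow(iso) == 0) next
    rk <- tx_ranks[iso$transcript_id]
    stopIfNot(!anyNA(rk),
              paste("missing transcript assignment for gene", genes[k]))
    longest <- which(iso$protein_length == max(iso$protein_length))
    pick <- if (tie == "oldest") longest[which.min(rk[longest])]
            else longest[1]
    out$stratum_rank[k] <- rk[pick]
    out$condensed_category[k] <- condense(rk[pick], lineage)
    out$assigned_from[k] <- iso$transcript_id[pick]
  }
  out
}

#' Condense a stratum rank into its analysis category
#'
#' @param rank integer rank (vectorized).
#' @param lineage a [PhyloLineage-class] carrying the condensation map.
#' @return category label(s).
#' @examples
#' condense(1, defaultLineage())   # "cellular organisms"
#' condense(14, defaultLineage())  # "hymenopterans"
#' @export
condense <- function(rank, lineage) {
  if (any(is.na(rank)) || any(rank < 1 | rank > nStrata(lineage)))
    stop("rank outside the lineage", call. = FALSE)
  lineage@condensed[rank]
}

#' Compare phylostratum assignments across E-value thresholds
#'
#' Runs [assignTranscripts()] at each threshold (default: the conservative
#' 1e-5 and a liberal 1e-1) and reports the per-transcript rank pairs and the
#' fraction unchanged. A more liberal threshold can only move an assignment
#' toward older (smaller) ranks.
#'
#' @param hits hit table as for [assignTranscripts()].
#' @param lineage a [PhyloLineage-class].
#' @param thresholds numeric vector of E-value thresholds.
#' @param transcripts optional transcript universe.
#' @return list with `assignments` (data.frame: transcript plus one rank
#'   column per threshold) and `agreement` (fraction of transcripts whose
#'   rank is identical across all thresholds).
#' @export
sensitivityThreshold <- function(hits, lineage, thresholds = c(1e-5, 1e-1),
                                 transcripts = NULL) {
  cols <- lapply(thresholds, function(th)
    assignTranscripts(hits, lineage, transcripts = transcripts,
                      threshold = th))
  tx <- names(cols[[1]])
  tab <- data.frame(transcript = tx)
  for (i in seq_along(thresholds))
    tab[[sprintf("rank_%g", thresholds[i])]] <- unname(cols[[i]][tx])
  ranks <- as.matrix(tab[, -1, drop = FALSE])
  agreement <- mean(apply(ranks, 1, function(r) length(unique(r)) == 1))
  list(assignments = tab, agreement = agreement)
}
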