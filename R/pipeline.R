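#' Expression filter on FPKM across three tissues
#'
#' A gene is removed when, in each of the three tissues separately, its FPKM
#' is below `min_fpkm` in at least half of that tissue's samples ("at least
#' half" inclusive). A gene adequately expressed in any one tissue is
#' retained. The alternative pooled reading (at least half of all samples,
#' tissues pooled) is available via `pooled = TRUE`.
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param tissue_of_sample named character vector mapping every sample
#'   (column) to one of exactly three tissues.
#' @param min_fpkm expression threshold (default 1).
#' @param pooled use the pooled-samples reading instead of the per-tissue
#'   conjunction.
#' @return list with `retained` (gene ids), `removed` (count) and `keep`
#'   (logical vector over rows of `fpkm`).
#' @export
filterExpressed <- function(fpkm, tissue_of_sample, min_fpkm = 1,
                            pooled = FALSE) {
  samples <- colnames(fpkm)
  stopIfNot(all(samples %in% names(tissue_of_sample)),
            "every sample must be mapped to a tissue")
  tis <- tissue_of_sample[samples]
  stopIfNot(length(unique(tis)) == 3, "expected exactly three tissues")
  low <- fpkm < min_fpkm
  if (pooled) {
    keep <- rowMeans(low) < 0.5
  } else {
    low_by_tissue <- vapply(unique(tis), function(t)
      rowMeans(low[, tis == t, drop = FALSE]) >= 0.5,
      logical(nrow(fpkm)))
    keep <- !apply(low_by_tissue, 1, all)
  }
  list(retained = rownames(fpkm)[keep], removed = sum(!keep), keep = keep)
}

#' Derive caste-class labels from differential-expression results
#'
#' Genes with FDR below the cutoff are labelled by the caste they are
#' upregulated in (positive effect = reproductive, negative = worker); all
#' others are NDE.
#'
#' @param de_results data.frame with columns `gene_id`, `log2fc` (signed
#'   effect, positive toward reproductives) and `fdr`.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return named character vector of labels (`reproductive`/`worker`/`NDE`)
#'   with an attribute `counts` giving the per-class tally.
#' @export
ingestDELabels <- function(de_results, fdr_cutoff = 0.05) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% colnames(de_results)))
    stop("de_results must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lab <- ifelse(de_results$fdr < fdr_cutoff,
                ifelse(de_results$log2fc > 0, "reproductive", "worker"),
                "NDE")
  names(lab) <- de_results$gene_id
  attr(lab, "counts") <- table(factor(lab, c("reproductive", "worker",
                                             "NDE")))
  lab
}

#' Run the full caste molecular-evolution analysis
#'
#' Orchestrates the stages on already-tabulated inputs: per-class maximum
#' likelihood alpha estimates (with bootstrap CIs when `B > 0`), pairwise
#' bootstrap class comparisons, the gene-age GLM contrasting reproductive and
#' worker classes, the class x condensed-stratum residual grid, and GO
#' over-representation per class. All sections use the same class table; the
#' run is deterministic given `seed`.
#'
#' @param config list with components:
#'   \describe{
#'     \item{counts}{an [MKCountSet-class] or path to an MK counts TSV
#'       (`gene_id`, `Pn`, `Ps`, `Dn`, `Ds`).}
#'     \item{classes}{named character vector gene -> label, or a
#'       DE-results data.frame for [ingestDELabels()]; omitted if `counts`
#'       already carries labels.}
#'     \item{ages}{data.frame `gene_id`, `stratum_rank`,
#'       `condensed_category` (e.g. from [assignGene()]); optional.}
#'     \item{annotations}{gene -> GO term table for [goEnrichment()];
#'       optional.}
#'     \item{contrasts}{list of 2-vectors of class labels to compare
#'       (default `list(c("reproductive", "worker"))`).}
#'     \item{B}{bootstrap replicates (0 disables CIs and comparisons'
#'       resampling; default 1000).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{fdr_cutoff}{for label ingestion (default 0.05).}
#'   }
#' @return a report list with elements `alpha` (per-class
#'   [AlphaEstimate-class]), `comparisons`, `age_glm`, `age_mosaic`, `go`,
#'   and `provenance` (seeds, thresholds, class tallies, package version).
#' @export
runPipeline <- function(config) {
  cfg <- config
  counts <- cfg$counts
  if (is.character(counts)) counts <- MKCountSet(readTsv(counts))
  stopIfNot(is(counts, "MKCountSet"), "config$counts must be an MKCountSet")
  if (!is.null(cfg$classes)) {
    lab <- cfg$classes
    if (is.data.frame(lab))
      lab <- ingestDELabels(lab, cfg$fdr_cutoff %||% 0.05)
    geneClasses(counts) <- unname(lab[geneIds(counts)])
  }
  stopIfNot(any(!is.na(geneClasses(counts))),
            "no class labels available on the MK counts")
  B <- cfg$B %||% 1000
  seed <- as.integer(cfg$seed %||% 1L)
  classes <- intersect(c("reproductive", "worker", "NDE"),
                       unique(stats::na.omit(geneClasses(counts))))

  alpha <- list()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    alpha[[cl]] <- if (B > 0) {
      bootstrapAlpha(counts[cl], B = B, seed = seed + k,
                     class_label = cl)
    } else mlAlpha(counts[cl], class_label = cl)
  }
  alpha$all <- if (B > 0) {
    bootstrapAlpha(counts, B = B, seed = seed, class_label = "all")
  } else mlAlpha(counts, class_label = "all")

  contrasts <- cfg$contrasts %||% list(c("reproductive", "worker"))
  comparisons <- list()
  if (B > 0) {
    for (ct in contrasts) {
      if (!all(ct %in% classes)) next
      nm <- paste(ct, collapse = "_vs_")
      comparisons[[nm]] <- compareClasses(counts[ct[1]], counts[ct[2]],
                                          B = B, seed = seed + 97L)
    }
  }

  age_glm <- NULL
  age_mosaic <- NULL
  if (!is.null(cfg$ages)) {
    ages <- cfg$ages
    m <- match(geneIds(counts), ages$gene_id)
    cls <- geneClasses(counts)
    ok <- !is.na(m) & !is.na(cls) & !is.na(ages$stratum_rank[m])
    cw <- ok & cls %in% c("reproductive", "worker")
    if (sum(cw) >= 4)
      age_glm <- glmMeanStratum(data.frame(
        class_label = cls[cw], stratum = ages$stratum_rank[m[cw]]),
        ref = "reproductive")
    cat_lv <- unique(ages$condensed_category[!is.na(ages$condensed_category)])
    tab <- table(class = cls[ok],
                 category = factor(ages$condensed_category[m[ok]], cat_lv))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2 && ncol(tab) >= 2)
      age_mosaic <- contingencyResiduals(unclass(tab))
  }

  go <- NULL
  if (!is.null(cfg$annotations)) {
    background <- geneIds(counts)
    go <- lapply(stats::setNames(classes, classes), function(cl)
      goEnrichment(geneIds(counts[cl]), background, cfg$annotations,
                   p_cutoff = cfg$go_cutoff %||% 0.05))
  }

  list(
    alpha = alpha,
    comparisons = comparisons,
    age_glm = age_glm,
    age_mosaic = age_mosaic,
    go = go,
    provenance = list(
      package_version = as.character(utils::packageVersion("casteMK")),
      seed = seed, B = B,
      fdr_cutoff = cfg$fdr_cutoff %||% 0.05,
      class_counts = as.list(table(geneClasses(counts), useNA = "no")),
      n_genes = length(counts)
    )
  )
}

#' Write a pipeline report to disk
#'
#' Serializes the report from [runPipeline()] as a JSON summary plus flat
#' TSVs (per-class alpha table; mosaic cell grid and GO tables when present).
#'
#' @param report list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atab <- do.call(rbind, lapply(report$alpha, function(e) data.frame(
    class = e@classLabel, alpha = e@alphaHat, f = e@fHat,
    log_likelihood = e@logLik, n_genes = e@nGenes,
    ci_low = e@ciLow, ci_high = e@ciHigh, n_bootstrap = e@nBootstrap,
    seed = e@seed)))
  writeTsv(atab, file.path(dir, "alpha_estimates.tsv"))
  if (!is.null(report$age_mosaic))
    writeTsv(report$age_mosaic$cells, file.path(dir, "age_mosaic.tsv"))
  if (!is.null(report$go))
    for (cl in names(report$go))
      writeTsv(report$go[[cl]], file.path(dir, sprintf("go_%s.tsv", cl)))
  summary <- list(
    alpha = lapply(report$alpha, function(e) list(
      alpha = e@alphaHat, f = e@fHat, ci = c(e@ciLow, e@ciHigh),
      n_genes = e@nGenes)),
    comparisons = lapply(report$comparisons, function(cc)
      cc[c("delta_hat", "bootstrap_p", "alpha_a", "alpha_b")]),
    age_glm = if (!is.null(report$age_glm))
      report$age_glm[c("coefficient", "std_error", "z", "df", "dispersion",
                       "family_used", "p")],
    age_chi_square = if (!is.null(report$age_mosaic))
      report$age_mosaic[c("chi_square", "df", "p")],
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
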