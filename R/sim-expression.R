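#' Simulate caste-labelled expression matrices
#'
#' Generates negative-binomial counts for two caste groups (reproductive and
#' worker samples) with a planted fraction of differentially expressed genes,
#' and derives an FPKM matrix from simulated gene lengths and library sizes.
#' Planted genes are split evenly between the two directions; the planted
#' label of a gene is the caste it is upregulated in, all other genes are NDE
#' (non-differentially expressed).
#'
#' Samples are also given a tissue assignment cycling over head, gaster and
#' larva within each group, so the expression filter on all three tissues can
#' be exercised downstream.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per caste group.
#' @param frac_de fraction of genes with a planted caste effect, in `[0, 1]`.
#' @param effect_log2fc planted log2 fold change of DE genes.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param base_mean mean count of an average gene at the reference library size.
#' @param seed integer seed.
#' @return list with `counts` and `fpkm` (gene x sample matrices), `samples`
#'   (data.frame: sample, caste, tissue), `labels` (planted per-gene class),
#'   and `truth` (gene lengths, library sizes, planted log2 fold changes).
#' @export
simExpression <- function(n_genes, n_samples_per_group, frac_de = 0.1,
                          effect_log2fc = 2, nb_dispersion = 0.2,
                          base_mean = 50, seed = 1L) {
  stopIfNot(frac_de >= 0 && frac_de <= 1, "frac_de must lie in [0, 1]")
  stopIfNot(nb_dispersion > 0, "nb_dispersion must be positive")
  stopIfNot(n_genes >= 1 && n_samples_per_group >= 1,
            "n_genes and n_samples_per_group must be positive")
  withSeed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    n_de <- round(frac_de * n_genes)
    labels <- rep("NDE", n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer()
    up_repro <- de_idx[seq_len(ceiling(n_de / 2))]
    up_worker <- setdiff(de_idx, up_repro)
    labels[up_repro] <- "reproductive"
    labels[up_worker] <- "worker"

    groups <- rep(c("reproductive", "worker"), each = n_samples_per_group)
    tissues <- rep(rep_len(c("head", "gaster", "larva"), n_samples_per_group), 2)
    samples <- data.frame(
      sample = sprintf("%s_%02d", substr(groups, 1, 4),
                       rep(seq_len(n_samples_per_group), 2)),
      caste = groups, tissue = tissues
    )

    gene_mu <- stats::rlnorm(n_genes, log(base_mean) - 0.5^2 / 2, 0.5)
    lfc <- numeric(n_genes)
    lfc[up_repro] <- effect_log2fc
    lfc[up_worker] <- -effect_log2fc
    lib_fac <- stats::rlnorm(nrow(samples), 0, 0.1)
    gene_len <- round(stats::rlnorm(n_genes, log(1500), 0.4))

    # mu_gs: caste effect applied symmetrically around the gene mean
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      sign <- if (samples$caste[j] == "reproductive") +0.5 else -0.5
      mu <- gene_mu * 2^(sign * lfc) * lib_fac[j]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    }
    lib_size <- colSums(counts)
    fpkm <- t(t(counts) / (lib_size / 1e6)) / (gene_len / 1e3)

    list(counts = counts, fpkm = fpkm, samples = samples, labels = labels,
         truth = list(gene_length = gene_len, lib_size = lib_size,
                      log2fc = lfc, labels = labels))
  })
}

#' Simulate differential-expression results for label ingestion
#'
#' Produces the per-gene effect/FDR table that [ingestDELabels()] consumes,
#' from a planted label vector: planted genes receive a signed effect and an
#' FDR below the cutoff except for a nominal miss rate; NDE genes receive
#' null effects with uniform FDR.
#'
#' @param labels planted per-gene labels (`reproductive` / `worker` / `NDE`).
#' @param fdr_below value used for significant genes (default 1e-4).
#' @param miss_rate fraction of planted genes reported non-significant.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `log2fc` (positive = up in
#'   reproductives) and `fdr`.
#' @export
simDEResults <- function(labels, fdr_below = 1e-4, miss_rate = 0.02,
                         seed = 1L) {
  withSeed(seed, {
    n <- length(labels)
    genes <- names(labels)
    if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(n))
    lfc <- stats::rnorm(n, 0, 0.1)
    fdr <- stats::runif(n, 0.05, 1)
    de <- labels != "NDE"
    sig <- de & (stats::runif(n) > miss_rate)
    lfc[labels == "reproductive"] <- abs(stats::rnorm(sum(labels ==
      "reproductive"), 2, 0.5))
    lfc[labels == "worker"] <- -abs(stats::rnorm(sum(labels == "worker"),
                                                 2, 0.5))
    fdr[sig] <- fdr_below
    data.frame(gene_id = genes, log2fc = lfc, fdr = fdr)
  })
}
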