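#' Poisson/quasi-Poisson GLM comparing mean phylostratum between classes
#'
#' Fits a log-link Poisson regression of the (integer) stratum value on the
#' class indicator. The Pearson dispersion `phi = X^2 / df` is computed from
#' the Poisson fit; when it exceeds `overdispersion_cutoff` the reported
#' standard errors are rescaled by `sqrt(phi)` (quasi-Poisson). Treating the
#' ordinal stratum as a count response follows the standard practice for
#' mean-phylostratum comparisons and is a documented approximation.
#'
#' @param table data.frame with columns `class_label` and `stratum` (positive
#'   integers: raw ranks or condensed category indices).
#' @param ref reference class level (coefficient is the log rate ratio of the
#'   other class relative to it); default: first level alphabetically.
#' @param overdispersion_cutoff Pearson dispersion above which quasi-Poisson
#'   standard errors are used (default 1.2).
#' @return list with `coefficient` (log rate ratio per non-reference class),
#'   `std_error`, `z`, `df` (residual degrees of freedom), `dispersion`,
#'   `family_used` (`"poisson"` or `"quasipoisson"`), `p`, and the fitted
#'   `model`. Both the Poisson and dispersion-scaled z statistics are kept in
#'   `z_poisson` / `z_quasi`.
#' @examples
#' tab <- data.frame(class_label = rep(c("worker", "reproductive"), each = 50),
#'                   stratum = rpois(100, 3) + 1)
#' glmMeanStratum(tab)$family_used
#' @export
glmMeanStratum <- function(table, ref = NULL,
                           overdispersion_cutoff = 1.2) {
  stopIfNot(all(c("class_label", "stratum") %in% colnames(table)),
            "table needs columns class_label and stratum")
  cls <- factor(table$class_label)
  stopIfNot(nlevels(cls) >= 2, "need at least two classes")
  stopIfNot(min(tabulate(cls)) >= 2, "need at least two genes per class")
  stopIfNot(stats::var(table$stratum) > 0, "stratum response has no variance")
  if (!is.null(ref)) cls <- stats::relevel(cls, ref)
  fit <- stats::glm(table$stratum ~ cls, family = stats::poisson())
  df <- fit$df.residual
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / df
  sm <- summary(fit)$coefficients
  coefs <- sm[-1, 1]
  se_pois <- sm[-1, 2]
  quasi <- phi > overdispersion_cutoff
  se <- if (quasi) se_pois * sqrt(phi) else se_pois
  z <- coefs / se
  names(z) <- names(se) <- names(coefs) <- sub("^cls", "", rownames(sm)[-1])
  list(coefficient = coefs, std_error = se, z = z, df = df,
       dispersion = phi,
       family_used = if (quasi) "quasipoisson" else "poisson",
       p = 2 * stats::pnorm(-abs(z)),
       z_poisson = coefs / se_pois,
       z_quasi = coefs / (se_pois * sqrt(phi)),
       model = fit)
}

#' Omnibus chi-square with standardized Pearson residuals
#'
#' For a class x category contingency table, computes the omnibus Pearson
#' chi-square (no continuity correction) and, per cell, the standardized
#' Pearson residual
#' \deqn{r_{ij} = \frac{O_{ij} - E_{ij}}
#'   {\sqrt{E_{ij}(1 - n_{i\cdot}/n)(1 - n_{\cdot j}/n)}},}
#' flagged at the conventional thresholds: `|r| > 2` approximately p < 0.05,
#' `|r| > 4` approximately p < 0.001. The cell grid (observed, expected,
#' residual, flag, direction, and relative cell area) is mosaic-plot ready.
#'
#' @param counts integer matrix of observed counts with row (class) and
#'   column (category) names; all margins must be positive.
#' @return list with `chi_square`, `df`, `p`, and `cells`, a data.frame with
#'   one row per cell: `row`, `col`, `observed`, `expected`,
#'   `std_pearson_residual`, `significance` (`none` / `p<0.05` / `p<0.001`),
#'   `direction` (`over`/`under`), `area` (observed / total).
#' @examples
#' contingencyResiduals(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
#' @export
contingencyResiduals <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("row", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("col", seq_len(ncol(counts)))
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0))
    stop("zero row margin: ", rownames(counts)[which(rs == 0)[1]],
         call. = FALSE)
  if (any(cs == 0))
    stop("zero column margin: ", colnames(counts)[which(cs == 0)[1]],
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  r <- ct$stdres
  flag <- ifelse(abs(r) > 4, "p<0.001", ifelse(abs(r) > 2, "p<0.05", "none"))
  cells <- data.frame(
    row = rownames(counts)[row(counts)][seq_along(counts)],
    col = colnames(counts)[col(counts)][seq_along(counts)],
    observed = as.vector(counts),
    expected = as.vector(ct$expected),
    std_pearson_residual = as.vector(r),
    significance = as.vector(flag),
    direction = ifelse(as.vector(counts) >= as.vector(ct$expected),
                       "over", "under"),
    area = as.vector(counts) / sum(counts)
  )
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), cells = cells)
}

#' Hypergeometric GO over-representation test
#'
#' For each term annotating at least one background gene, computes the
#' upper-tail hypergeometric probability of observing at least `k` annotated
#' genes in a set of size `n` drawn from a background of size `N` with `K`
#' annotated genes. P-values are reported raw (no multiple-testing
#' correction, matching common over-representation practice); an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param gene_set character vector of gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param annotations data.frame with columns `gene_id`, `term_id` (and
#'   optionally `term_name`).
#' @param p_cutoff enrichment flag threshold (default 0.05).
#' @param bh add a BH-adjusted column (`FALSE` by default).
#' @return data.frame per term: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p`, `enriched` (and `p_bh` when requested), ordered by `p`.
#' @export
goEnrichment <- function(gene_set, background, annotations, p_cutoff = 0.05,
                         bh = FALSE) {
  missing <- setdiff(gene_set, background)
  if (length(missing))
    stop("gene_set members absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(gene_set))
  terms <- unique(ann$term_id)
  res <- data.frame(term_id = terms, term_name = NA_character_,
                    k = 0L, K = 0L, n = n, N = N, p = NA_real_)
  if ("term_name" %in% colnames(ann))
    res$term_name <- ann$term_name[match(terms, ann$term_id)]
  for (i in seq_along(terms)) {
    g <- unique(ann$gene_id[ann$term_id == terms[i]])
    K <- length(g)
    k <- length(intersect(g, gene_set))
    res$k[i] <- k
    res$K[i] <- K
    res$p[i] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  res$enriched <- res$p < p_cutoff
  if (bh) res$p_bh <- stats::p.adjust(res$p, "BH")
  res[order(res$p), , drop = FALSE]
}
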