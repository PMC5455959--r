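#' Configuration for simulating McDonald-Kreitman count tables
#'
#' The generator runs the estimation model forward: each gene i carries
#' nuisance intensities theta_i (synonymous polymorphism rate) and lambda_i
#' (synonymous divergence rate) drawn log-normally around the stated means,
#' and the four counts are Poisson,
#' \deqn{Ps_i \sim Pois(\theta_i),\quad Pn_i \sim Pois(f\,\theta_i),\quad
#'       Ds_i \sim Pois(\lambda_i),\quad
#'       Dn_i \sim Pois\!\left(\frac{f\,\lambda_i}{1-\alpha}\right),}
#' where `f` is the shared selective constraint (fraction of nonsynonymous
#' mutations behaving neutrally) and `alpha` the proportion of nonsynonymous
#' substitutions fixed by positive selection. `alpha` may be negative, the
#' regime produced by segregating mildly deleterious mutations.
#'
#' @param n_genes number of genes to simulate (>= 1).
#' @param alpha_true true adaptive proportion, any real `< 1`.
#' @param f_true true constraint in `(0, 1]`.
#' @param theta_mean,lambda_mean mean per-gene synonymous polymorphism and
#'   divergence intensities (counts per gene; positive).
#' @param intensity_dispersion standard deviation of `log(theta_i)` and
#'   `log(lambda_i)` around their means (0 = all genes identical).
#' @param seed integer seed.
#' @return a validated list of class `MKSimConfig`.
#' @examples
#' cfg <- mkSimConfig(n_genes = 100, alpha_true = 0.3, f_true = 0.7, seed = 1)
#' sim <- simMKCounts(cfg)
#' sim$counts
#' @export
mkSimConfig <- function(n_genes, alpha_true, f_true,
                        theta_mean = 8, lambda_mean = 12,
                        intensity_dispersion = 0.6, seed = 1L) {
  stopIfNot(length(n_genes) == 1 && n_genes >= 1 && n_genes == round(n_genes),
            "n_genes must be a positive integer")
  stopIfNot(is.numeric(alpha_true) && alpha_true < 1,
            "alpha_true must be < 1 (negative values allowed)")
  stopIfNot(is.numeric(f_true) && f_true > 0 && f_true <= 1,
            "f_true must lie in (0, 1]")
  stopIfNot(theta_mean > 0 && lambda_mean > 0,
            "theta_mean and lambda_mean must be positive")
  stopIfNot(intensity_dispersion >= 0,
            "intensity_dispersion must be nonnegative")
  structure(list(n_genes = as.integer(n_genes), alpha_true = alpha_true,
                 f_true = f_true, theta_mean = theta_mean,
                 lambda_mean = lambda_mean,
                 intensity_dispersion = intensity_dispersion,
                 seed = as.integer(seed)),
            class = "MKSimConfig")
}

#' Simulate per-gene McDonald-Kreitman counts with planted truth
#'
#' Draws a table of `(Pn, Ps, Dn, Ds)` per gene from the forward model
#' described in [mkSimConfig()]. The log-normal intensity draws are
#' mean-corrected so that `E[theta_i] = theta_mean` exactly.
#'
#' @param cfg an `MKSimConfig` from [mkSimConfig()].
#' @param class_label optional label recorded on every simulated gene.
#' @return list with `counts` (an [MKCountSet-class]) and `truth`, a list
#'   carrying `alpha_true`, `f_true` and the per-gene `theta`, `lambda`.
#' @export
simMKCounts <- function(cfg, class_label = NA_character_) {
  stopIfNot(inherits(cfg, "MKSimConfig"), "cfg must come from mkSimConfig()")
  withSeed(cfg$seed, {
    n <- cfg$n_genes
    s <- cfg$intensity_dispersion
    mu_t <- log(cfg$theta_mean) - s^2 / 2
    mu_l <- log(cfg$lambda_mean) - s^2 / 2
    theta <- stats::rlnorm(n, mu_t, s)
    lambda <- stats::rlnorm(n, mu_l, s)
    f <- cfg$f_true
    a <- cfg$alpha_true
    counts <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      Pn = stats::rpois(n, f * theta),
      Ps = stats::rpois(n, theta),
      Dn = stats::rpois(n, f * lambda / (1 - a)),
      Ds = stats::rpois(n, lambda)
    )
    truth <- list(alpha_true = a, f_true = f, theta = theta, lambda = lambda,
                  class_label = rep(class_label, n))
    list(counts = MKCountSet(counts, classes = rep(class_label, n)),
         truth = truth)
  })
}

#' Simulate a labelled multi-class MK data set
#'
#' Convenience wrapper: one [simMKCounts()] draw per caste class, each with
#' its own true alpha (and optionally constraint), concatenated into a single
#' labelled [MKCountSet-class]. Gene ids are made unique across classes.
#'
#' @param class_alphas named numeric vector of true alphas, e.g.
#'   `c(reproductive = 0.31, worker = 0.15, NDE = 0.21)`.
#' @param n_per_class genes per class (recycled).
#' @param f_true shared constraint (recycled per class).
#' @param seed integer seed; per-class seeds are derived from it.
#' @param ... further arguments passed to [mkSimConfig()].
#' @return list with `counts` (labelled `MKCountSet`) and `truth` (per-class
#'   parameter list).
#' @export
simClassedMKCounts <- function(class_alphas, n_per_class = 1000,
                               f_true = 0.7, seed = 1L, ...) {
  labs <- names(class_alphas)
  stopIfNot(!is.null(labs) && all(nzchar(labs)),
            "class_alphas must be a named vector")
  n_per_class <- rep_len(n_per_class, length(labs))
  f_true <- rep_len(f_true, length(labs))
  parts <- vector("list", length(labs))
  truth <- list()
  for (k in seq_along(labs)) {
    cfg <- mkSimConfig(n_genes = n_per_class[k], alpha_true = class_alphas[[k]],
                       f_true = f_true[k], seed = seed + 1000L * k, ...)
    sim <- simMKCounts(cfg, class_label = labs[k])
    tab <- mkCounts(sim$counts)
    tab$gene_id <- paste0(labs[k], "_", tab$gene_id)
    parts[[k]] <- MKCountSet(tab, classes = geneClasses(sim$counts))
    truth[[labs[k]]] <- sim$truth[c("alpha_true", "f_true")]
  }
  all_tab <- do.call(rbind, lapply(parts, mkCounts))
  all_cls <- unlist(lapply(parts, geneClasses), use.names = FALSE)
  list(counts = MKCountSet(all_tab, classes = all_cls), truth = truth)
}
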