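# Resample gene indices with replacement B times and return the B x 4 matrix
# of resampled count sums. Multinomial weights avoid materializing indices.
.bootSums <- function(tab, B) {
  cm <- as.matrix(tab[, c("Pn", "Ps", "Dn", "Ds")])
  n <- nrow(cm)
  W <- stats::rmultinom(B, n, rep.int(1 / n, n))  # n x B
  crossprod(W, cm)                                # B x 4
}

# Fit alpha on each row of a sums matrix; NA where the fit is undefined.
.bootAlphas <- function(S) {
  apply(S, 1, function(s) {
    tryCatch(.fitAlphaF(s[1], s[2], s[3], s[4])$alpha,
             error = function(e) NA_real_)
  })
}

#' Gene-resampling bootstrap confidence interval for alpha
#'
#' Resamples genes with replacement `B` times, re-estimates alpha by maximum
#' likelihood on each replicate, and reports the percentile 95% confidence
#' interval. Replicates on which the estimate is undefined (a required count
#' sum resampled to zero) are dropped and counted; a warning is attached when
#' more than 5% fail.
#'
#' @param x an [MKCountSet-class] or data.frame with `Pn`, `Ps`, `Dn`, `Ds`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed; fixed seed gives identical CIs.
#' @param class_label optional label stored on the result.
#' @return an [AlphaEstimate-class] with `ciLow`, `ciHigh` and the replicate
#'   draws filled in.
#' @examples
#' sim <- simMKCounts(mkSimConfig(500, alpha_true = 0.3, f_true = 0.7,
#'                                seed = 3))
#' bootstrapAlpha(sim$counts, B = 100, seed = 1)
#' @export
bootstrapAlpha <- function(x, B = 1000, seed = 1L,
                           class_label = NA_character_) {
  stopIfNot(B >= 100, "B must be at least 100")
  est <- mlAlpha(x, class_label = class_label)
  tab <- if (is(x, "MKCountSet")) mkCounts(x) else as.data.frame(x)
  tab <- tab[(tab$Pn + tab$Ps + tab$Dn + tab$Ds) > 0, , drop = FALSE]
  draws <- withSeed(seed, .bootAlphas(.bootSums(tab, B)))
  ok <- draws[!is.na(draws)]
  n_fail <- sum(is.na(draws))
  if (n_fail > 0.05 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", n_fail, B))
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  initialize(est, ciLow = ci[1], ciHigh = ci[2], nBootstrap = as.integer(B),
             nFailed = as.integer(n_fail), seed = as.integer(seed),
             draws = ok)
}

#' Bootstrap comparison of alpha between two gene classes
#'
#' Estimates the difference `delta = alpha_a - alpha_b` and its two-tailed
#' bootstrap p-value by independent gene resampling of each class within each
#' replicate: `p = 2 * min(frac(delta_r <= 0), frac(delta_r >= 0))`, capped
#' at 1. Passing an empty second class tests `alpha_a` against zero
#' (`delta_r = alpha_{a,r}`).
#'
#' @param a,b [MKCountSet-class] or count data.frames for the two classes;
#'   `b` may be `NULL` or empty to test against zero.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return list with `delta_hat` (point estimate of the difference),
#'   `bootstrap_p`, the per-class point estimates, the replicate `draws`, and
#'   `n_failed` replicates dropped.
#' @examples
#' sim <- simClassedMKCounts(c(reproductive = 0.3, worker = 0.1),
#'                           n_per_class = 800, seed = 5)
#' compareClasses(sim$counts["reproductive"], sim$counts["worker"],
#'                B = 200, seed = 1)
#' @export
compareClasses <- function(a, b = NULL, B = 1000, seed = 1L) {
  stopIfNot(B >= 100, "B must be at least 100")
  tab_a <- if (is(a, "MKCountSet")) mkCounts(a) else as.data.frame(a)
  tab_a <- tab_a[(tab_a$Pn + tab_a$Ps + tab_a$Dn + tab_a$Ds) > 0, ,
                 drop = FALSE]
  est_a <- mlAlpha(tab_a)
  vs_zero <- is.null(b) ||
    (if (is(b, "MKCountSet")) length(b) else nrow(as.data.frame(b))) == 0
  if (!vs_zero) {
    tab_b <- if (is(b, "MKCountSet")) mkCounts(b) else as.data.frame(b)
    tab_b <- tab_b[(tab_b$Pn + tab_b$Ps + tab_b$Dn + tab_b$Ds) > 0, ,
                   drop = FALSE]
    est_b <- mlAlpha(tab_b)
  }
  draws <- withSeed(seed, {
    da <- .bootAlphas(.bootSums(tab_a, B))
    if (vs_zero) da else da - .bootAlphas(.bootSums(tab_b, B))
  })
  ok <- draws[!is.na(draws)]
  n_fail <- sum(is.na(draws))
  if (n_fail > 0.05 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", n_fail, B))
  p <- min(1, 2 * min(mean(ok <= 0), mean(ok >= 0)))
  list(
    delta_hat = if (vs_zero) alphaHat(est_a)
                else alphaHat(est_a) - alphaHat(est_b),
    bootstrap_p = p,
    alpha_a = alphaHat(est_a),
    alpha_b = if (vs_zero) 0 else alphaHat(est_b),
    draws = ok, n_failed = n_fail
  )
}
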