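#' Per-gene McDonald-Kreitman test statistics
#'
#' Computes, per gene, the neutrality index `NI = (Pn/Ps)/(Dn/Ds)` (reported
#' `NA` when `Ps`, `Dn` or `Ds` is zero), the two-sided Fisher exact
#' probability of the 2x2 table `[[Pn, Ps], [Dn, Ds]]`, and the direction of
#' departure: `excess_divergence` when `Pn*Ds < Ps*Dn` (adaptive-divergence
#' pattern, NI < 1), `excess_polymorphism` for the converse, `balanced` when
#' the cross-products are equal.
#'
#' The two-sided p-value is the standard enumeration: the sum of
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.
#'
#' @param x an [MKCountSet-class], or a data.frame with columns `Pn`, `Ps`,
#'   `Dn`, `Ds`.
#' @return data.frame with columns `gene_id`, `NI`, `fisher_p`, `direction`.
#' @examples
#' mkTest(data.frame(gene_id = "g", Pn = 10, Ps = 10, Dn = 30, Ds = 10))
#' @export
mkTest <- function(x) {
  tab <- if (is(x, "MKCountSet")) mkCounts(x) else as.data.frame(x)
  if (is.null(tab$gene_id)) tab$gene_id <- sprintf("gene%d", seq_len(nrow(tab)))
  res <- data.frame(gene_id = tab$gene_id, NI = NA_real_,
                    fisher_p = NA_real_, direction = NA_character_)
  for (i in seq_len(nrow(tab))) {
    Pn <- tab$Pn[i]; Ps <- tab$Ps[i]; Dn <- tab$Dn[i]; Ds <- tab$Ds[i]
    if (Ps > 0 && Dn > 0 && Ds > 0)
      res$NI[i] <- (Pn / Ps) / (Dn / Ds)
    m <- matrix(c(Pn, Dn, Ps, Ds), 2)
    res$fisher_p[i] <- stats::fisher.test(m)$p.value
    cross <- Pn * Ds - Ps * Dn
    res$direction[i] <- if (cross < 0) "excess_divergence"
      else if (cross > 0) "excess_polymorphism" else "balanced"
  }
  res
}

#' Pooled (counting) estimator of the adaptive proportion alpha
#'
#' Sums the four McDonald-Kreitman cells over genes and returns
#' \deqn{\hat\alpha = 1 - \frac{\sum D_s \sum P_n}{\sum D_n \sum P_s}.}
#'
#' @param x an [MKCountSet-class] or data.frame with `Pn`, `Ps`, `Dn`, `Ds`.
#' @return the pooled alpha estimate (scalar).
#' @examples
#' pooledAlpha(data.frame(Pn = 10, Ps = 10, Dn = 20, Ds = 10))  # 0.5
#' @export
pooledAlpha <- function(x) {
  tab <- if (is(x, "MKCountSet")) mkCounts(x) else as.data.frame(x)
  S <- colSums(tab[, c("Pn", "Ps", "Dn", "Ds")])
  if (S["Dn"] == 0) stop("pooled alpha undefined: sum(Dn) is zero",
                         call. = FALSE)
  if (S["Ps"] == 0) stop("pooled alpha undefined: sum(Ps) is zero",
                         call. = FALSE)
  unname(1 - (S["Ds"] * S["Pn"]) / (S["Dn"] * S["Ps"]))
}

# Profile log-likelihood of (alpha, f) given the four count sums.
# Per-gene Poisson nuisances are profiled out analytically; the resulting
# (alpha, f)-dependent part depends on the data only through the sums:
#   ll = SPn*log f - ST*log(1+f) + SDn*log g - SU*log(1+g),  g = f/(1-alpha)
# (gene-specific constants are handled by the caller).
.llSums <- function(alpha, f, SPn, ST, SDn, SU) {
  g <- f / (1 - alpha)
  t1 <- if (SPn > 0) SPn * log(f) else 0
  t2 <- if (SDn > 0) SDn * log(g) else 0
  t1 - ST * log1p(f) + t2 - SU * log1p(g)
}

# Maximize the profile likelihood over (alpha, f) from count sums.
# Coarse grid over alpha in [-5, 0.99] x f in (0.01, 1], ties broken toward
# smaller |alpha|, then Nelder-Mead refinement on transformed coordinates
# (alpha = 1 - exp(a), f = plogis(b)); the returned point never has lower
# likelihood than the best grid point.
.fitAlphaF <- function(SPn, SPs, SDn, SDs, f_fixed = NULL) {
  ST <- SPn + SPs
  SU <- SDn + SDs
  if (ST == 0 || SU == 0 || SDn == 0 || SDs == 0)
    stop("alpha MLE undefined: a required count sum is zero", call. = FALSE)
  if (!is.null(f_fixed)) {
    obj <- function(a) .llSums(a, f_fixed, SPn, ST, SDn, SU)
    grid_a <- seq(-5, 0.99, by = 0.01)
    ll <- vapply(grid_a, obj, numeric(1))
    best <- grid_a[which.max(ll)]
    opt <- stats::optimize(obj, lower = max(-50, best - 0.5),
                           upper = min(0.9999, best + 0.5), maximum = TRUE,
                           tol = 1e-10)
    if (opt$objective < max(ll)) {
      opt$maximum <- best
      opt$objective <- max(ll)
    }
    return(list(alpha = opt$maximum, f = f_fixed, ll = opt$objective,
                converged = TRUE))
  }
  grid_a <- seq(-5, 0.99, by = 0.1)
  grid_f <- seq(0.02, 1, by = 0.02)
  ll <- outer(grid_a, grid_f, function(a, f)
    .llSums(a, f, SPn, ST, SDn, SU))
  mx <- max(ll)
  cand <- which(ll >= mx - 1e-12, arr.ind = TRUE)
  pick <- cand[which.min(abs(grid_a[cand[, 1]])), , drop = FALSE]
  a0 <- grid_a[pick[1, 1]]
  f0 <- grid_f[pick[1, 2]]
  # the profile likelihood has a closed-form stationary point
  # (f = SPn/SPs, f/(1-alpha) = SDn/SDs, truncated at the f <= 1 boundary);
  # use it as the refinement start when it beats the grid
  f_c <- min(SPn / SPs, 1)
  if (f_c > 0) {
    a_c <- 1 - f_c * SDs / SDn
    ll_c <- .llSums(a_c, f_c, SPn, ST, SDn, SU)
    if (is.finite(ll_c) && ll_c >= mx && a_c < 1) {
      a0 <- a_c
      f0 <- f_c
      mx <- ll_c
    }
  }
  # transformed coordinates keep alpha < 1 and f in (0, 1)
  neg <- function(p) {
    a <- 1 - exp(p[1])
    f <- stats::plogis(p[2])
    -.llSums(a, f, SPn, ST, SDn, SU)
  }
  p0 <- c(log(1 - a0), stats::qlogis(min(f0, 0.999)))
  opt <- stats::optim(p0, neg, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  # gradient-based polish from the simplex optimum tightens the last digits
  opt <- tryCatch(stats::optim(opt$par, neg, method = "BFGS",
                               control = list(reltol = 1e-14)),
                  error = function(e) opt)
  alpha <- 1 - exp(opt$par[1])
  f <- min(stats::plogis(opt$par[2]), 1)
  ll_opt <- .llSums(alpha, f, SPn, ST, SDn, SU)
  if (ll_opt < mx) {  # refinement must never regress below the grid
    alpha <- a0
    f <- f0
    ll_opt <- mx
  }
  list(alpha = alpha, f = f, ll = ll_opt,
       converged = opt$convergence == 0 || ll_opt >= mx)
}

# Gene-specific constant part of the profile log-likelihood (independent of
# alpha and f): sum_i T_i log T_i - T_i + U_i log U_i - U_i.
.llGeneConst <- function(tab) {
  Ti <- tab$Pn + tab$Ps
  Ui <- tab$Dn + tab$Ds
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  sum(xlogx(Ti) - Ti + xlogx(Ui) - Ui)
}

#' Maximum-likelihood estimation of alpha and the selective constraint
#'
#' Fits, to a set of per-gene McDonald-Kreitman tables, the Poisson model
#' with shared adaptive proportion `alpha` and selective constraint `f` and
#' per-gene nuisance intensities:
#' \deqn{Ps_i \sim Pois(\theta_i),\; Pn_i \sim Pois(f\theta_i),\;
#'       Ds_i \sim Pois(\lambda_i),\; Dn_i \sim Pois(f\lambda_i/(1-\alpha)).}
#' The nuisance MLEs are closed-form given `(alpha, f)` —
#' `theta_i = (Ps_i + Pn_i)/(1 + f)`, `lambda_i = (Ds_i + Dn_i)/(1 + f/(1-alpha))`
#' — and the profile likelihood is maximized numerically over a coarse grid
#' (`alpha` in `[-5, 0.99]`, `f` in `(0.01, 1]`) followed by Nelder-Mead
#' refinement. `alpha` is unconstrained below 1 (negative estimates arise
#' from segregating mildly deleterious variants), `f` is constrained to
#' `(0, 1]`. Genes whose four counts are all zero carry no likelihood
#' information and are dropped (their number is recorded).
#'
#' @param x an [MKCountSet-class] or data.frame with `Pn`, `Ps`, `Dn`, `Ds`.
#' @param class_label optional label stored on the result.
#' @param f_fixed optionally fix the constraint (e.g. `1` for the neutral
#'   model) and profile alpha only.
#' @return an [AlphaEstimate-class] (CI fields empty).
#' @examples
#' sim <- simMKCounts(mkSimConfig(2000, alpha_true = 0.3, f_true = 0.7,
#'                                seed = 42))
#' mlAlpha(sim$counts)
#' @export
mlAlpha <- function(x, class_label = NA_character_, f_fixed = NULL) {
  tab <- if (is(x, "MKCountSet")) mkCounts(x) else as.data.frame(x)
  nz <- (tab$Pn + tab$Ps + tab$Dn + tab$Ds) > 0
  dropped <- sum(!nz)
  tab <- tab[nz, , drop = FALSE]
  stopIfNot(nrow(tab) >= 1, "no genes with nonzero counts")
  fit <- .fitAlphaF(sum(tab$Pn), sum(tab$Ps), sum(tab$Dn), sum(tab$Ds),
                    f_fixed = f_fixed)
  new("AlphaEstimate", classLabel = class_label, alphaHat = fit$alpha,
      fHat = fit$f, logLik = fit$ll + .llGeneConst(tab),
      nGenes = nrow(tab), nDropped = as.integer(dropped))
}
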