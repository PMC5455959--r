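---
title: "Estimating adaptive evolution and gene age for caste-associated genes"
author: "casteMK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adaptive evolution and gene age for caste-associated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteMK)
```

## The scientific problem

In social insects with obligately sterile workers, worker-expressed genes can
only be shaped by kin selection — selection acting through the reproduction of
relatives — while genes expressed in queens and males are exposed to direct
selection. Population-genetic theory predicts that, all else equal,
worker-associated genes should therefore evolve more nearly neutrally:
both adaptive substitution and purifying selection should be weakened
relative to reproductive-associated genes, with the effect strongest in
species of low nestmate relatedness (many queens, multiple mating).

casteMK implements the analysis chain used to test this prediction on
resequencing and expression data: per-gene McDonald–Kreitman (MK) tables
from coding variants, maximum-likelihood estimation of the proportion of
adaptive amino-acid substitutions per caste class, phylostratigraphic gene
ages, and class-level statistics tying the two together. A synthetic-data
generator with planted ground truth makes every stage testable without any
sequencing data.

## The MK model and the likelihood

For gene $i$ we count nonsynonymous and synonymous polymorphisms within the
ingroup ($P_{N,i}$, $P_{S,i}$) and nonsynonymous and synonymous fixed
differences to a single outgroup ($D_{N,i}$, $D_{S,i}$). Under neutrality
the two ratios $P_N/P_S$ and $D_N/D_S$ should agree; an excess of
nonsynonymous divergence indicates adaptive fixation. The model behind
`mlAlpha()` assigns each gene its own synonymous polymorphism and divergence
intensities $\theta_i$, $\lambda_i$ (nuisance parameters), and shares across
genes the selective constraint $f$ — the fraction of nonsynonymous mutations
that behave neutrally, $1-f$ being strongly deleterious — and $\alpha$, the
proportion of nonsynonymous substitutions fixed by positive selection:

$$P_{S,i}\sim\mathrm{Pois}(\theta_i),\quad
  P_{N,i}\sim\mathrm{Pois}(f\theta_i),\quad
  D_{S,i}\sim\mathrm{Pois}(\lambda_i),\quad
  D_{N,i}\sim\mathrm{Pois}\!\left(\frac{f\lambda_i}{1-\alpha}\right).$$

Given $(\alpha, f)$ the nuisance MLEs are closed-form,
$\hat\theta_i = (P_{S,i}+P_{N,i})/(1+f)$ and
$\hat\lambda_i = (D_{S,i}+D_{N,i})/(1+f/(1-\alpha))$, and profiling them out
collapses the $(\alpha,f)$-dependent part of the log-likelihood to a
function of the four count totals — equivalently, a pair of binomial
(conditional) likelihoods for the nonsynonymous shares of polymorphism and
divergence. Two consequences are worth knowing:

* whenever the unconstrained optimum satisfies $\hat f \le 1$, the MLE
  coincides with the pooled counting estimator
  $\hat\alpha = 1 - (\sum D_S \sum P_N)/(\sum D_N \sum P_S)$ — the package
  exposes that estimator separately as `pooledAlpha()` and the test suite
  checks the agreement;
* because the profiled likelihood is conditional, the estimator does not
  suffer the incidental-parameter inconsistency one might fear from one
  nuisance pair per gene, and parameter recovery improves with gene count.

$\alpha$ is unconstrained below 1: negative estimates are expected when
mildly deleterious variants segregate (inflating $P_N$) without fixing.
$f$ is constrained to $(0,1]$.

### Optimization

`mlAlpha()` evaluates a coarse grid ($\alpha \in [-5, 0.99]$ step 0.1,
$f \in (0.01, 1]$ step 0.02; ties broken toward smaller $|\alpha|$), then
refines by Nelder–Mead followed by a BFGS polish on transformed coordinates
($\alpha = 1-e^{a}$, $f = \mathrm{logit}^{-1}(b)$), with the closed-form
stationary point (truncated at the $f \le 1$ boundary) offered as an
alternative start when it beats the grid. The returned optimum is guaranteed
not to fall below any evaluated grid point. Degenerate inputs — a zero total
for $D_N$, $D_S$ or the polymorphism pair — make the estimate undefined and
raise an error; inside the bootstrap such replicates are dropped and counted
instead. Genes whose four counts are all zero carry no information and are
removed up front (reported in the result object).

## Bootstrap inference

Genes, not sites, are the unit of replication in per-locus MK tables, so
`bootstrapAlpha()` resamples genes with replacement (`B = 1000` by default,
multinomial weights for speed), re-fits each replicate, and reports the
percentile 95% interval. `compareClasses()` resamples each class
independently within a replicate and returns the two-tailed bootstrap
p-value $2\min(\Pr(\delta_r \le 0), \Pr(\delta_r \ge 0))$ for
$\delta = \alpha_a - \alpha_b$, capped at 1; passing an empty second class
tests a single $\alpha$ against zero. With `B = 200` the smallest
attainable two-sided p is 0.01, which is why power claims in the tests are
phrased at that resolution. Calibration (type-I error at the 5% level) and
power for a contrast of the size seen between reproductive- and
worker-associated genes (0.30 vs 0.15) are checked by simulation in the
acceptance tests.

## Variant effects and MK table construction

`filterSites()` applies the site filters in a fixed order — indels, more
than two alleles, more than 10% missing genotypes, site quality below phred
40 (strictly: quality exactly 40 is kept) — and reports a per-rule tally
that sums to the input count. `classifyEffect()` substitutes the alternate
allele into the reference codon (reverse-complementing for minus-strand
models), translates both codons under the standard genetic code, and returns
synonymous / nonsynonymous / stop_affected / noncoding; a reference-allele
mismatch against the CDS is an error, not a silent skip. `tabulateMK()`
counts each qualifying site in exactly one cell: segregating in the ingroup
→ polymorphism; ingroup-monomorphic and different from a confident
homozygous outgroup call → divergence; both polymorphic and divergent →
polymorphism only (the conservative standard treatment); heterozygous or
missing outgroup → no divergence information. Counts are unpolarized — with
a single outgroup there is no ancestral-state inference — and stop-affected
variants count as nonsynonymous by default (`count_stop_affected = FALSE`
to drop them). Multiple variants in one codon are classified independently
against the reference codon.

## Phylostratigraphy

`assignTranscript()` places a transcript in the oldest stratum of the focal
species' lineage containing at least one hit with E-value strictly below
the threshold (default $10^{-5}$); with no passing hit the transcript falls
to the youngest, species-specific stratum. Hits to the focal species itself
are ignored — self-hits carry no age information. `assignGene()` filters
isoforms shorter than 30 amino acids, then takes the rank of the longest
remaining isoform, breaking length ties toward the older rank (conservative
toward ancient assignment; `tie = "first"` switches to first-listed).
`sensitivityThreshold()` re-runs assignment at a liberal threshold
($10^{-1}$) — which can only move assignments toward older strata — and
reports the agreement fraction.

The default lineage (`defaultLineage()`) is the 19-step NCBI taxonomic path
for the pharaoh ant, condensed order-preservingly into six analysis
categories (cellular organisms, eukaryotes, bilaterian animals, insects,
hymenopterans, ants). Both the strata and the condensation are configuration,
not code: any lineage can be supplied as a table via `PhyloLineage()` or
`readLineage()`.

## Class-level statistics

`glmMeanStratum()` compares mean phylostratum between classes with a
log-link Poisson GLM on the integer stratum value — treating an ordinal
stratum as a count is a deliberate, documented approximation that matches
standard practice for mean-phylostratum comparisons. The Pearson dispersion
$\phi$ is computed from the Poisson fit; above 1.2 (a configurable default:
mild overdispersion is tolerated, anything beyond that rescales inference)
the reported standard errors switch to quasi-Poisson ($\mathrm{SE}\times
\sqrt{\phi}$). Both the Poisson and the dispersion-scaled z statistics are
returned, since either convention may be wanted downstream.

`contingencyResiduals()` runs the omnibus Pearson chi-square (no continuity
correction) on a class × category table and returns per-cell standardized
Pearson residuals
$r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-n_{i\cdot}/n)(1-n_{\cdot j}/n)}$,
flagged at $|r|>2$ (≈ p < 0.05) and $|r|>4$ (≈ p < 0.001), plus the
relative cell areas a mosaic plot needs. `goEnrichment()` is the upper-tail
hypergeometric over-representation test with a raw-p cutoff of 0.05 —
no multiple-testing correction by default, matching common
over-representation practice, with an optional BH column.

## What the synthetic data emulate — and what they do not

`simMKCounts()` runs the estimation model forward: log-normal per-gene
intensities (mean-corrected so `theta_mean` is the exact expectation,
dispersion 0.6 on the log scale by default — enough spread to make the
per-gene nuisances matter, as real per-locus tables show strong
heterogeneity) and Poisson counts at the model rates. Defaults of
`theta_mean = 8`, `lambda_mean = 12` give count magnitudes typical of
per-gene tables from a ~20-genome resequencing panel against a congeneric
outgroup; they are a realistic choice, not a calibration to any particular
data set. `simExpression()` draws negative-binomial counts with a planted
caste effect split between directions and derives FPKM from simulated gene
lengths and library sizes. `simBlastHits()` plants a recoverable oldest
stratum per gene; `simCDSVariants()` builds random stop-free coding models
and variants whose synonymous/nonsynonymous truth comes from translation.

What passing these tests shows: the estimator, the assignment rules and the
statistics recover exactly the structure they assume, at the scale of the
study design (thousands of genes, 22 ingroup samples + 1 outgroup). What it
does not show: robustness to model violations in real data — linked
selection, segregating deleterious variants beyond the constraint model
(these bias $\alpha$ downward, the known reason for negative estimates),
misannotation, reference bias, or BLAST homology-detection failure for fast
genes ("phylostratigraphic age" is detectability, not origin). Those caveats
belong to any MK-based or phylostratigraphic analysis and are not resolved
by simulation.

## Design choices where the design was open

* **Model variant.** Among ML extensions of the MK framework we implement
  the minimal shared-$(\alpha, f)$, per-gene-nuisance Poisson model that
  yields both the constraint and the adaptive proportion; per-locus
  selection-coefficient distributions are out of scope.
* **Bootstrap unit.** Genes, with replacement; site-level resampling would
  understate between-locus variance given per-locus tables.
* **Fisher two-sidedness.** The enumeration definition (sum of table
  probabilities not exceeding the observed), stated explicitly because
  two-sided conventions differ.
* **Expression filter reading.** "Low in at least half the samples of all
  three tissues" is implemented as the per-tissue conjunction (a gene is
  dropped only when inadequate in head *and* gaster *and* larva separately),
  with `pooled = TRUE` for the pooled-samples reading. "At least half" is
  inclusive.
* **DE significance.** Labels are ingested from an external
  differential-expression result (or the simulator) at FDR < 0.05 by
  default; the DE model fit itself is deliberately not reimplemented —
  it is a solved problem owned by established count-model packages, and the
  contribution here is downstream of it.
* **Stop-affected variants** count as nonsynonymous by default (they alter
  the protein), with a flag to exclude.

## Problem sizes used in the checks

The packaged tests run the estimator recovery at 5,000 genes, bootstrap
calibration over 500 null simulations of 1,000 genes per class at `B = 200`,
power at 5,000 genes per class, and the phylostratum round-trip at 1,000
genes — sizes chosen to match the study scale where that matters (gene
counts) while keeping simulation Monte-Carlo error well inside the asserted
bands. `scripts/acceptance.R` re-runs the same computations from scratch and
writes the resulting numbers as JSON.

## A worked example

```{r example}
sim <- simClassedMKCounts(c(reproductive = 0.31, worker = 0.15, NDE = 0.21),
                          n_per_class = 2000, f_true = 0.7, seed = 7)
report <- runPipeline(list(counts = sim$counts, B = 200, seed = 1))
for (cl in c("reproductive", "worker", "NDE"))
  show(report$alpha[[cl]])
report$comparisons$reproductive_vs_worker$bootstrap_p
```

The reproductive class recovers the highest adaptive proportion, the worker
class the lowest, and the bootstrap comparison rejects equality — the planted
ordering, which is also the ordering the kin-selection prediction expects
from real caste-associated gene sets.
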