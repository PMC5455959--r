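# Independent oracles, written against textbook definitions only — no calls
# into the package code paths they are used to check.

# Hand-written standard genetic code (codon -> one-letter amino acid).
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Classify one codon change by brute-force translation with ORACLE_CODE.
oracleCodonEffect <- function(ref_codon, alt_codon) {
  a <- ORACLE_CODE[[ref_codon]]
  b <- ORACLE_CODE[[alt_codon]]
  if (a == b) return("synonymous")
  if (a == "*" || b == "*") return("stop_affected")
  "nonsynonymous"
}

# Enumerate all 576 single-nucleotide codon changes with their oracle class.
oracleAllCodonChanges <- function() {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (cod in names(ORACLE_CODE)) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        rows[[length(rows) + 1]] <- data.frame(
          ref_codon = cod, alt_codon = alt, pos = p, alt_base = b,
          effect = oracleCodonEffect(cod, alt))
      }
    }
  }
  do.call(rbind, rows)
}

# Two-sided Fisher exact p for [[Pn, Ps], [Dn, Ds]] by hypergeometric
# enumeration over all tables with the observed margins.
oracleFisherP <- function(Pn, Ps, Dn, Ds) {
  r1 <- Pn + Ps
  r2 <- Dn + Ds
  c1 <- Pn + Dn
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(Pn, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square and standardized residuals from the textbook formulas.
oracleChisq <- function(O) {
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  X2 <- sum((O - E)^2 / E)
  r <- (O - E) / sqrt(E * outer(1 - rowSums(O) / n, 1 - colSums(O) / n))
  list(X2 = X2, E = E, stdres = r,
       df = (nrow(O) - 1) * (ncol(O) - 1))
}

# Upper-tail hypergeometric p by explicit summation over k.
oracleHyperP <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Build a tiny plus-strand coding model from a CDS string.
makeModel <- function(cds, gene = "g1", tx = "g1.t1", contig = "ctg1",
                      strand = "+", map = NULL) {
  if (is.null(map)) map <- seq_len(nchar(cds))
  new("CodingGeneModel", geneId = gene, txId = tx, contig = contig,
      strand = strand, cds = Biostrings::DNAString(cds),
      map = as.integer(map))
}

# Minimal VariantSet builder for filter tests: one row per site.
makeVariantSet <- function(sites, geno, outgroup = "outgroup") {
  new("VariantSet", sites = sites, geno = geno, outgroup = outgroup)
}
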