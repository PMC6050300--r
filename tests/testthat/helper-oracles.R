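# Shared fixtures and independent oracles for the test suite.

# Build a small genotype matrix from a sites x samples integer matrix.
make_gm <- function(geno, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                    mean_depth = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  genotype_matrix(chrom %||% rep("chr1", n),
                  pos %||% (seq_len(n) * 100L),
                  ref %||% rep("A", n),
                  alt %||% rep("G", n),
                  geno,
                  colnames(geno) %||% paste0("s", seq_len(ncol(geno))),
                  mean_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_popmap <- function(...) {
  groups <- list(...)
  unlist(lapply(names(groups), function(p)
    stats::setNames(rep(p, length(groups[[p]])), groups[[p]])))
}

# Independent literal transcription of the Weir & Cockerham (1984)
# two-population estimator, scalar, straight from the printed formulas.
wc84_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  if (n1 < 2 || n2 < 2) return(c(a = NA, b = NA, c = NA, fst = NA))
  r <- 2
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  c(a = a, b = b, c = cc, fst = if (denom == 0) NA else a / denom)
}

# Brute-force nucleotide diversity: mean pairwise difference count per bp
# over all haplotype pairs. haps: haplotypes x sites 0/1 matrix.
pi_pairwise_oracle <- function(haps, window_bp) {
  n <- nrow(haps)
  diffs <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      diffs <- diffs + sum(haps[i, ] != haps[j, ])
  diffs / choose(n, 2) / window_bp
}

# Convert a haplotype matrix (2k x S) into a diploid genotype matrix by
# pairing consecutive rows.
haps_to_geno <- function(haps) {
  idx <- seq(1, nrow(haps), by = 2)
  t(haps[idx, , drop = FALSE] + haps[idx + 1, , drop = FALSE])
}

# Default chromosome lengths for the simulator's standard output.
sim_chrom_lengths <- function(cfg) {
  stats::setNames(rep(cfg$L, cfg$n_chrom), paste0("chr", seq_len(cfg$n_chrom)))
}

# Scan configuration scaled to the simulator's desk-scale genomes.
test_scan_config <- function(...) {
  scan_config(window = 20000, step = 5000, min_snps = 20,
              merge_gap = 50000, ...)
}
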