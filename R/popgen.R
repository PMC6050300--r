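#' Per-site allele frequencies for one population
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map (named character vector).
#' @param pop population label.
#' @return data frame with per-site `n` (non-missing allele count,
#'   2 x non-missing samples), `p_alt` (alternate allele frequency, `NA` when
#'   `n` is 0), and `het` (observed heterozygote fraction among non-missing
#'   samples).
#' @export
allele_frequencies <- function(gm, pm, pop) {
  s <- pop_samples(pm, pop)
  missing_s <- setdiff(s, gm$sample_ids)
  if (length(missing_s))
    stop("samples not in genotype matrix: ", paste(missing_s, collapse = ", "))
  g <- gm$geno[, s, drop = FALSE]
  nn <- rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  n <- 2L * nn
  data.frame(n = n,
             p_alt = ifelse(n > 0, ac / n, NA_real_),
             het = ifelse(nn > 0, rowSums(g == 1L, na.rm = TRUE) / nn,
                          NA_real_))
}

#' Per-site Weir-Cockerham F_ST for two populations
#'
#' The two-population Weir & Cockerham (1984) estimator with observed
#' heterozygote counts. Variance components `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals) are
#' returned so windowed estimates can be formed as ratios of sums. Per-site
#' values are not clamped and may be negative. A site is undefined (`NA`)
#' when either population has fewer than two non-missing samples; sites
#' monomorphic across the pair have `a + b + c = 0` and an undefined ratio.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param popA,popB population labels.
#' @return data frame with per-site columns `a`, `b`, `c`, `fst` and
#'   `defined` (logical: both populations had >= 2 non-missing samples).
#' @export
site_fst <- function(gm, pm, popA, popB) {
  fa <- allele_frequencies(gm, pm, popA)
  fb <- allele_frequencies(gm, pm, popB)
  comp <- wc84_components(fa$n / 2, fa$p_alt, fa$het,
                          fb$n / 2, fb$p_alt, fb$het)
  comp
}

# Weir & Cockerham (1984) variance components for r = 2 populations,
# vectorized over sites. n1, n2 are diploid sample counts; p the alt allele
# frequencies; h the observed heterozygote fractions.
wc84_components <- function(n1, p1, h1, n2, p2, h2) {
  defined <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!defined] <- b[!defined] <- cc[!defined] <- NA_real_
  denom <- a + b + cc
  fst <- ifelse(defined & denom != 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, fst = fst, defined = defined)
}

#' Genome-scan configuration
#'
#' Window/step sizes and CDR-calling thresholds for the two-stage sweep scan.
#' Defaults are the full-scale study design values; scale `window`, `step` and
#' `min_snps` down together for small simulated genomes.
#'
#' @param window window size (bp).
#' @param step step size (bp); windows slide, so `step <= window`.
#' @param min_snps minimum SNP count for a window to enter standardization.
#' @param alpha one-sided upper-tail significance level for the Z test.
#' @param merge_gap CDRs closer than this (bp) are merged.
#' @param fixed_daf derived-allele frequency above which a site counts as
#'   nearly fixed in the derived population (strict `>`).
#' @param standing_max_af derived-allele frequency below which a site counts
#'   as standing variation in the wild population (strict `<`).
#' @param min_fixed_sites_per_cdr minimum nearly-fixed standing-variant count
#'   for a CDR to qualify in the standing-variation screen.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window = 40000, step = 10000, min_snps = 40,
                        alpha = 0.005, merge_gap = 200000, fixed_daf = 0.95,
                        standing_max_af = 0.5, min_fixed_sites_per_cdr = 5) {
  stopifnot(window >= step, step > 0, alpha > 0, alpha < 1, merge_gap >= 0,
            fixed_daf >= 0.5, fixed_daf <= 1, standing_max_af >= 0,
            standing_max_af <= 1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_snps = as.integer(min_snps), alpha = alpha,
                 merge_gap = as.integer(merge_gap), fixed_daf = fixed_daf,
                 standing_max_af = standing_max_af,
                 min_fixed_sites_per_cdr = as.integer(min_fixed_sites_per_cdr)),
            class = "scan_config")
}

#' Windowed F_ST, nucleotide diversity and pi ln-ratio
#'
#' Sliding windows tile each chromosome from position 1 at `cfg$step`
#' intervals. Within a window (SNP sites only; indels are excluded from
#' scans):
#' \itemize{
#'   \item windowed F_ST is the ratio of sums `sum(a) / sum(a + b + c)` of the
#'     WC84 components over SNPs in the window;
#'   \item per-population pi is `sum(n/(n-1) * 2 * p * (1-p)) / window size`
#'     (per bp; monomorphic sites contribute 0; the denominator is the full
#'     configured window size);
#'   \item `pi_ln_ratio = log(pi_a / pi_b)` with the ancestral-stage
#'     population `pop_a` in the numerator, so a sweep in the derived
#'     population gives a large positive value. When `pi_b` is 0 the ratio is
#'     `+Inf` and the window is flagged.
#' }
#' Windows shorter than the window size (chromosome end) are flagged
#' `partial`.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param pop_a ancestral-stage population label (e.g. wild).
#' @param pop_b derived-stage population label (e.g. domestic).
#' @param cfg a [scan_config()].
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the maximum observed position per chromosome.
#' @return data frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `n_snps`, `fst`, `pi_a`, `pi_b`, `pi_ln_ratio`, `partial`, `flagged`
#'   (low SNP count or non-finite ratio).
#' @export
window_stats <- function(gm, pm, pop_a, pop_b, cfg = scan_config(),
                         chrom_lengths = NULL) {
  snp <- is_snp(gm)
  fa <- allele_frequencies(gm, pm, pop_a)
  fb <- allele_frequencies(gm, pm, pop_b)
  comp <- wc84_components(fa$n / 2, fa$p_alt, fa$het, fb$n / 2, fb$p_alt,
                          fb$het)
  # unbiased per-site heterozygosity terms for pi
  pi_term <- function(n, p) ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), 0)
  ta <- pi_term(fa$n, fa$p_alt)
  tb <- pi_term(fb$n, fb$p_alt)
  ta[is.na(ta)] <- 0; tb[is.na(tb)] <- 0
  chroms <- unique(gm$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch) max(gm$pos[gm$chrom == ch]),
                            numeric(1))
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- chrom_lengths[[ch]]
    starts <- seq(1L, max(1L, len), by = cfg$step)
    ends <- pmin(starts + cfg$window - 1L, len)
    partial <- (ends - starts + 1L) < cfg$window
    idx <- which(gm$chrom == ch & snp)
    pos <- gm$pos[idx]
    nw <- length(starts)
    n_snps <- integer(nw); fst <- pi_a <- pi_b <- numeric(nw)
    sa <- sabc <- numeric(nw)
    for (w in seq_len(nw)) {
      inw <- idx[pos >= starts[w] & pos <= ends[w]]
      n_snps[w] <- length(inw)
      ok <- inw[comp$defined[inw]]
      sa[w] <- sum(comp$a[ok])
      sabc[w] <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
      pi_a[w] <- sum(ta[inw]) / cfg$window
      pi_b[w] <- sum(tb[inw]) / cfg$window
    }
    fst <- ifelse(sabc != 0, sa / sabc, NA_real_)
    ratio <- ifelse(pi_b > 0, log(pi_a / pi_b),
                    ifelse(pi_a > 0, Inf, NA_real_))
    out[[ci]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_snps = n_snps, fst = fst, pi_a = pi_a,
                            pi_b = pi_b, pi_ln_ratio = ratio,
                            partial = partial, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$flagged <- res$n_snps < cfg$min_snps | !is.finite(res$pi_ln_ratio) |
    is.na(res$fst)
  class(res) <- c("window_stats", "data.frame")
  res
}
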