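#' Per-site ABBA / BABA pattern counts
#'
#' For the quartet (outgroup, ((P1, P2), P3)) the outgroup defines the
#' ancestral (A) state; sites where the outgroup is polymorphic, heterozygous
#' or missing are skipped. With derived allele frequencies `p1`, `p2`, `p3`,
#' frequency mode scores
#' `C_ABBA(i) = (1 - p1) * p2 * p3` and `C_BABA(i) = p1 * (1 - p2) * p3`;
#' sampled mode draws one allele per population per site and scores 1/0
#' patterns (seed the RNG for reproducibility).
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param p1,p2,p3,outgroup population labels (disjoint).
#' @param anc optional [assign_ancestral()] result; computed from the
#'   outgroup (with `min_og_samples = 1`) when absent.
#' @param mode `"frequency"` (default, uses all samples) or `"sampled"`.
#' @return data frame of informative sites: `chrom`, `pos`, `c_abba`,
#'   `c_baba`.
#' @export
count_patterns <- function(gm, pm, p1, p2, p3, outgroup, anc = NULL,
                           mode = c("frequency", "sampled")) {
  mode <- match.arg(mode)
  pops <- list(p1, p2, p3, outgroup)
  if (anyDuplicated(unlist(pops)))
    stop("the four populations must be disjoint")
  if (is.null(anc)) anc <- assign_ancestral(gm, pm, outgroup,
                                            min_og_samples = 1)
  d1 <- derived_allele_frequency(gm, pm, p1, anc)
  d2 <- derived_allele_frequency(gm, pm, p2, anc)
  d3 <- derived_allele_frequency(gm, pm, p3, anc)
  use <- anc$status == "polarized" & !is.na(d1) & !is.na(d2) & !is.na(d3)
  d1 <- d1[use]; d2 <- d2[use]; d3 <- d3[use]
  if (mode == "sampled") {
    d1 <- as.numeric(stats::runif(length(d1)) < d1)
    d2 <- as.numeric(stats::runif(length(d2)) < d2)
    d3 <- as.numeric(stats::runif(length(d3)) < d3)
  }
  data.frame(chrom = gm$chrom[use], pos = gm$pos[use],
             c_abba = (1 - d1) * d2 * d3,
             c_baba = d1 * (1 - d2) * d3,
             stringsAsFactors = FALSE)
}

#' ABBA-BABA D-statistic with weighted block jackknife
#'
#' The statistic is the ratio of sums
#' `D = sum(C_BABA - C_ABBA) / sum(C_BABA + C_ABBA)`; a positive value
#' indicates gene flow between P1 and P3, a negative value gene flow between
#' P2 and P3. (Note the numerator orientation: many tools use ABBA - BABA;
#' `convention = "abba-baba"` negates D for cross-tool comparison.)
#' The standard error is a weighted delete-one-block jackknife (Busing,
#' Meijer & van der Leeden 1999) over contiguous genomic blocks, weighting
#' each block by its informative-site count; `Z = D / SE`.
#'
#' @param counts per-site pattern counts from [count_patterns()].
#' @param block_size block span in bp (default 5 Mb).
#' @param convention `"printed"` (BABA - ABBA numerator) or `"abba-baba"`.
#' @return an object of class `dstat`: `D`, `se`, `Z`, `n_sites`, `n_blocks`,
#'   `c_abba`, `c_baba`, `convention`.
#' @export
d_statistic <- function(counts, block_size = 5e6,
                        convention = c("printed", "abba-baba")) {
  convention <- match.arg(convention)
  sgn <- if (convention == "printed") 1 else -1
  num <- counts$c_baba - counts$c_abba
  den <- counts$c_baba + counts$c_abba
  informative <- den > 0
  if (!any(informative)) {
    warning("no informative sites; D undefined")
    return(structure(list(D = NA_real_, se = NA_real_, Z = NA_real_,
                          n_sites = 0L, n_blocks = 0L, c_abba = 0,
                          c_baba = 0, convention = convention),
                     class = "dstat"))
  }
  D <- sgn * sum(num) / sum(den)
  block <- paste0(counts$chrom, ":", (counts$pos - 1L) %/% block_size)
  blocks <- unique(block[informative])
  g <- length(blocks)
  se <- NA_real_
  if (g >= 10) {
    bnum <- vapply(blocks, function(b) sum(num[block == b]), numeric(1))
    bden <- vapply(blocks, function(b) sum(den[block == b]), numeric(1))
    m_j <- vapply(blocks, function(b) sum(informative & block == b),
                  numeric(1))
    n_tot <- sum(m_j)
    D_del <- sgn * (sum(num) - bnum) / (sum(den) - bden)
    h_j <- n_tot / m_j
    theta_jack <- g * D - sum((1 - m_j / n_tot) * D_del)
    tau <- h_j * D - (h_j - 1) * D_del   # pseudovalues
    se <- sqrt(sum((tau - theta_jack)^2 / (h_j - 1)) / g)
  } else {
    warning("fewer than 10 non-empty blocks; jackknife SE omitted")
  }
  structure(list(D = D, se = se, Z = if (is.na(se) || se == 0) NA_real_ else
                   D / se,
                 n_sites = sum(informative), n_blocks = g,
                 c_abba = sum(counts$c_abba), c_baba = sum(counts$c_baba),
                 convention = convention),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat("ABBA-BABA D-statistic (", x$convention, " convention)\n", sep = "")
  cat(sprintf("  C_ABBA = %.4f  C_BABA = %.4f over %d informative sites\n",
              x$c_abba, x$c_baba, x$n_sites))
  cat(sprintf("  D = %.4f  SE = %.4f  Z = %.3f  (%d jackknife blocks)\n",
              x$D, x$se, x$Z, x$n_blocks))
  if (is.finite(x$Z) && abs(x$Z) >= 3)
    cat("  |Z| >= 3:", if (x$D > 0) "gene flow between P1 and P3"
        else "gene flow between P2 and P3", "\n")
  invisible(x)
}

#' One-call D-statistic for a population quartet
#'
#' @inheritParams count_patterns
#' @inheritParams d_statistic
#' @return a `dstat` object (see [d_statistic()]).
#' @export
dstat <- function(gm, pm, p1, p2, p3, outgroup, anc = NULL,
                  mode = "frequency", block_size = 5e6,
                  convention = "printed") {
  d_statistic(count_patterns(gm, pm, p1, p2, p3, outgroup, anc, mode),
              block_size = block_size, convention = convention)
}
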