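#' Variant filter configuration
#'
#' Thresholds mirroring a standard resequencing pipeline: sites are retained
#' when mean sequencing depth lies strictly inside `(min_mean_depth,
#' max_mean_depth)` (skipped when depth is unavailable), minor allele frequency
#' exceeds `min_maf`, the major allele frequency is below `max_af`, the missing
#' fraction is below `max_missing`, the site is biallelic, and (for indels)
#' both alleles are at most `max_indel_len` bp of inserted/deleted sequence.
#'
#' @param min_mean_depth,max_mean_depth mean-depth bounds (x coverage),
#'   exclusive.
#' @param min_maf minimum minor allele frequency (strict `>`).
#' @param max_af maximum allele frequency (strict `<`).
#' @param max_missing maximum fraction of missing genotypes (strict `<`).
#' @param biallelic_only drop sites that are not biallelic (always true for
#'   this container; kept as a switch for interface completeness).
#' @param max_indel_len maximum indel length (bp) retained.
#' @return a `variant_filter_config` list.
#' @export
variant_filter_config <- function(min_mean_depth = 3, max_mean_depth = 30,
                                  min_maf = 0.05, max_af = 0.99,
                                  max_missing = 0.1, biallelic_only = TRUE,
                                  max_indel_len = 6) {
  stopifnot(min_mean_depth < max_mean_depth,
            min_maf >= 0, min_maf <= 1, max_af >= 0, max_af <= 1,
            max_missing >= 0, max_missing <= 1, max_indel_len >= 0)
  structure(list(min_mean_depth = min_mean_depth,
                 max_mean_depth = max_mean_depth, min_maf = min_maf,
                 max_af = max_af, max_missing = max_missing,
                 biallelic_only = isTRUE(biallelic_only),
                 max_indel_len = max_indel_len),
            class = "variant_filter_config")
}

#' Filter variants
#'
#' Applies [variant_filter_config()] thresholds. Allele frequencies are
#' computed over non-missing alleles only. A per-criterion removal tally is
#' attached as attribute `"removed"` (a site failing several criteria is
#' counted once per criterion).
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [variant_filter_config()].
#' @return the filtered `genotype_matrix`, site order preserved, with
#'   attribute `removed` (named integer vector).
#' @export
filter_variants <- function(gm, cfg = variant_filter_config()) {
  n <- n_sites(gm)
  nn <- rowSums(!is.na(gm$geno))          # non-missing samples per site
  ac <- rowSums(gm$geno, na.rm = TRUE)    # alt allele count
  an <- 2 * nn
  p_alt <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  max_freq <- pmax(p_alt, 1 - p_alt)
  miss <- 1 - nn / ncol(gm$geno)

  # thresholds at their 0/1 extremes disable the corresponding criterion
  fail_maf <- if (cfg$min_maf > 0) is.na(maf) | !(maf > cfg$min_maf) else
    rep(FALSE, n)
  fail_maxaf <- if (cfg$max_af < 1) is.na(max_freq) | !(max_freq < cfg$max_af)
    else rep(FALSE, n)
  fail_miss <- if (cfg$max_missing < 1) !(miss < cfg$max_missing) else
    rep(FALSE, n)
  fail_depth <- if (is.null(gm$mean_depth)) rep(FALSE, n) else
    !is.na(gm$mean_depth) &
      !(gm$mean_depth > cfg$min_mean_depth &
        gm$mean_depth < cfg$max_mean_depth)
  # indels: retained only when both alleles are short
  indel <- !is_snp(gm)
  fail_indel <- indel & (nchar(gm$ref) > cfg$max_indel_len + 1L |
                         nchar(gm$alt) > cfg$max_indel_len + 1L)

  removed <- c(depth = sum(fail_depth), maf = sum(fail_maf),
               max_af = sum(fail_maxaf), missing = sum(fail_miss),
               indel_len = sum(fail_indel))
  keep <- !(fail_maf | fail_maxaf | fail_miss | fail_depth | fail_indel)
  if (!any(keep)) warning("all sites removed by variant filters")
  out <- subset_gm(gm, sites = keep)
  attr(out, "removed") <- removed
  out
}
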