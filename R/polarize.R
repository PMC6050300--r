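#' Assign ancestral alleles from outgroup genotypes
#'
#' A site is polarized when at least `min_og_samples` outgroup samples are
#' non-missing, all of them are homozygous, and all carry the same allele;
#' that allele is the ancestral state. Heterozygous outgroup genotypes never
#' polarize a site (a heterozygote carries both states, so no single fixed
#' ancestral state exists). The derived allele at a polarized site is the
#' non-ancestral allele.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map (named character vector).
#' @param outgroup_pop outgroup population label in `pm`.
#' @param min_og_samples minimum number of concordant non-missing outgroup
#'   samples.
#' @return a data frame with one row per site of `gm`: `chrom`, `pos`,
#'   `status` (`"polarized"` / `"unpolarized"`), `ancestral_allele`
#'   (`"ref"`, `"alt"`, or `NA`).
#' @export
assign_ancestral <- function(gm, pm, outgroup_pop, min_og_samples = 2) {
  stopifnot(min_og_samples >= 1)
  og <- pop_samples(pm, outgroup_pop)
  og <- intersect(og, gm$sample_ids)
  if (!length(og)) stop("no outgroup samples present in the genotype matrix")
  g <- gm$geno[, og, drop = FALSE]
  nn <- rowSums(!is.na(g))
  n_homref <- rowSums(g == 0L, na.rm = TRUE)
  n_homalt <- rowSums(g == 2L, na.rm = TRUE)
  all_homref <- nn >= min_og_samples & n_homref == nn
  all_homalt <- nn >= min_og_samples & n_homalt == nn
  status <- ifelse(all_homref | all_homalt, "polarized", "unpolarized")
  ancestral <- rep(NA_character_, n_sites(gm))
  ancestral[all_homref] <- "ref"
  ancestral[all_homalt] <- "alt"
  data.frame(chrom = gm$chrom, pos = gm$pos, status = status,
             ancestral_allele = ancestral, stringsAsFactors = FALSE)
}

#' Derived allele frequency per site for one population
#'
#' Frequency of the non-ancestral allele among non-missing alleles;
#' `NA` at unpolarized sites or sites with no data in the population.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param pop population label.
#' @param anc ancestral assignment from [assign_ancestral()].
#' @return numeric vector of derived allele frequencies per site.
#' @export
derived_allele_frequency <- function(gm, pm, pop, anc) {
  af <- allele_frequencies(gm, pm, pop)
  daf <- ifelse(anc$ancestral_allele == "ref", af$p_alt, 1 - af$p_alt)
  daf[anc$status != "polarized" | af$n == 0L] <- NA_real_
  daf
}
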