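#' Construct a genotype matrix
#'
#' The central container of the package: biallelic sites x diploid samples,
#' genotypes coded as the count of the alternate allele (0, 1, 2) with `NA`
#' for missing calls. Sites must be sorted by chromosome with strictly
#' increasing positions within each chromosome.
#'
#' @param chrom character vector of chromosome identifiers, one per site.
#' @param pos integer vector of 1-based positions (bp).
#' @param ref,alt character vectors of reference / alternate alleles.
#' @param geno integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of sample identifiers (columns of `geno`).
#' @param mean_depth optional numeric vector of per-site mean sequencing depth.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, sample_ids,
                            mean_depth = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- length(pos)
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites, nrow(geno) == n_sites,
            ncol(geno) == length(sample_ids))
  if (!is.null(mean_depth)) stopifnot(length(mean_depth) == n_sites)
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  if (n_sites > 1L) {
    same <- chrom[-1L] == chrom[-n_sites]
    if (any(same & diff(pos) <= 0L))
      stop("positions must be strictly increasing within each chromosome")
  }
  colnames(geno) <- sample_ids
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, sample_ids = as.character(sample_ids),
                 mean_depth = mean_depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_sites(x), "sites x", length(x$sample_ids),
      "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  SNP sites:", sum(is_snp(x)), "| indel sites:", sum(!is_snp(x)), "\n")
  cat("  missing genotype fraction:",
      signif(mean(is.na(x$geno)), 3), "\n")
  if (!is.null(x$mean_depth)) cat("  mean depth available\n")
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer site count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Logical index of SNP sites (both alleles single nucleotides)
#' @param gm a `genotype_matrix`.
#' @return logical vector over sites.
#' @export
is_snp <- function(gm) nchar(gm$ref) == 1L & nchar(gm$alt) == 1L

#' Subset a genotype matrix by site and/or sample
#'
#' @param gm a `genotype_matrix`.
#' @param sites logical or integer index over sites.
#' @param samples logical/integer/character index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(samples)) samples <- seq_along(gm$sample_ids)
  if (is.character(samples)) samples <- match(samples, gm$sample_ids)
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites],
                  gm$geno[sites, samples, drop = FALSE],
                  gm$sample_ids[samples],
                  if (!is.null(gm$mean_depth)) gm$mean_depth[sites])
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample<TAB>population`), `#` lines are comments.
#'
#' @param path file path.
#' @return named character vector: names are sample ids, values populations.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(df$sample))
    stop("duplicated sample id in population map: ",
         df$sample[duplicated(df$sample)][1L])
  stats::setNames(df$population, df$sample)
}

#' Write a sample-to-population map
#' @param popmap named character vector (names = samples, values = populations).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap),
                                population = unname(popmap)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Samples belonging to a population
#' @param pm population map (named character vector).
#' @param pop population label.
#' @return character vector of sample ids.
#' @export
pop_samples <- function(pm, pop) {
  s <- names(pm)[pm %in% pop]
  if (!length(s)) stop("no samples in population '", paste(pop, collapse = ","),
                       "'")
  s
}

#' Load genotypes from a VCF and an optional population map
#'
#' Parses a (possibly gzipped) VCF 4.x with `vcfR`, keeping biallelic records
#' only; multiallelic records are skipped and counted. Per-site mean depth is
#' taken from the INFO `DP` field divided by the sample count, or from the mean
#' of FORMAT `DP` values, when either is present.
#'
#' @param vcf_path VCF file path (plain or gzip).
#' @param popmap_path optional population map TSV; every mapped sample must be
#'   present in the VCF.
#' @return a list with elements `gm` (a [genotype_matrix()]), `popmap` (named
#'   character vector or `NULL`) and `n_excluded_multiallelic`.
#' @export
load_genotypes <- function(vcf_path, popmap_path = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  n_multi <- sum(multi)
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # alt-allele dosage; phase is ignored
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  rownames(dos) <- NULL
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  o <- order(chrom, pos)
  if (any(diff(o) != 1L)) stop("VCF is not coordinate-sorted")
  md <- NULL
  info_dp <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "DP")))[keep]
  fmt_ids <- tryCatch(vcfR::vcf_field_names(v, tag = "FORMAT")$ID,
                      error = function(e) character(0))
  if (any(!is.na(info_dp))) {
    md <- info_dp / ncol(gt)
  } else if ("DP" %in% fmt_ids) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[keep, ,
                                                              drop = FALSE]
    if (any(!is.na(dp))) md <- rowMeans(dp, na.rm = TRUE)
  }
  gm <- genotype_matrix(chrom, pos, fix[keep, "REF"], alt[keep], dos,
                        colnames(gt), mean_depth = md)
  popmap <- NULL
  if (!is.null(popmap_path)) {
    popmap <- read_popmap(popmap_path)
    absent <- setdiff(names(popmap), gm$sample_ids)
    if (length(absent))
      stop("population-map sample absent from VCF: ",
           paste(absent, collapse = ", "))
  }
  list(gm = gm, popmap = popmap, n_excluded_multiallelic = n_multi)
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal diploid VCF 4.2 (GT field only) via `vcfR`. Genotype codes
#' round-trip exactly through [load_genotypes()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output path; `vcfR` writes gzip when the name ends in `.gz`,
#'   plain text otherwise.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- n_sites(gm)
  fix <- cbind(CHROM = gm$chrom, POS = as.character(gm$pos),
               ID = rep(".", n), REF = gm$ref, ALT = gm$alt,
               QUAL = rep(".", n), FILTER = rep("PASS", n),
               INFO = if (is.null(gm$mean_depth)) rep(".", n) else
                 paste0("DP=", round(gm$mean_depth * length(gm$sample_ids))))
  gtc <- c("0/0", "0/1", "1/1")
  gt <- matrix(".", n, length(gm$sample_ids))
  ok <- !is.na(gm$geno)
  gt[ok] <- gtc[gm$geno[ok] + 1L]
  gt[!ok] <- "./."
  gt <- cbind(FORMAT = rep("GT", n), gt)
  colnames(gt) <- c("FORMAT", gm$sample_ids)
  requireNamespace("vcfR", quietly = TRUE)
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
           meta = c("##fileformat=VCFv4.2",
                    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write candidate divergent regions as BED5
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention. The name column carries the stage label and the score
#' column is mean window F_ST x 1000 truncated to `[0, 1000]`.
#'
#' @param cdrs a data frame of CDRs as returned by [call_cdrs()] (columns
#'   `chrom`, `start`, `end`, and optionally `stage`, `mean_fst`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(cdrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED5: chrom start end stage score(mean FST x 1000)", con)
  if (is.null(cdrs) || nrow(cdrs) == 0L) return(invisible(path))
  o <- order(cdrs$chrom, cdrs$start)
  cdrs <- cdrs[o, , drop = FALSE]
  ends <- c(-Inf, cdrs$end[-nrow(cdrs)])
  if (any(cdrs$start[-1L] <= cdrs$end[-nrow(cdrs)] &
          cdrs$chrom[-1L] == cdrs$chrom[-nrow(cdrs)]))
    warning("overlapping intervals written as-is")
  stage <- if ("stage" %in% names(cdrs)) cdrs$stage else "."
  score <- if ("mean_fst" %in% names(cdrs))
    pmin(1000L, pmax(0L, as.integer(trunc(cdrs$mean_fst * 1000)))) else 0L
  writeLines(paste(cdrs$chrom, cdrs$start - 1L, cdrs$end, stage, score,
                   sep = "\t"), con)
  invisible(path)
}
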