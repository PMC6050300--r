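#' Call candidate divergent regions (CDRs) from window statistics
#'
#' Windows with at least `cfg$min_snps` SNPs and finite statistics define the
#' empirical null: `z = (x - mean) / sd` per statistic, with one-sided
#' upper-tail normal P values. A window is significant when `P < cfg$alpha`
#' for BOTH F_ST and the pi ln-ratio. Windows whose ln-ratio is `+Inf`
#' (zero diversity in the derived population — the strongest sweep signal)
#' are excluded from the mean/sd estimation but pass the ratio criterion
#' outright. Overlapping or step-adjacent significant windows are merged into
#' CDRs, and CDRs separated by less than `cfg$merge_gap` bp are merged again.
#'
#' @param windows a `window_stats` data frame from [window_stats()].
#' @param cfg a [scan_config()].
#' @param stage stage label recorded on each CDR (e.g. `"domestication"`,
#'   `"improvement"`).
#' @return a data frame of CDRs (`chrom`, `start`, `end`, `stage`,
#'   `n_windows`, `mean_fst`, `max_fst`, `mean_pi_ln_ratio`) with attributes
#'   `thresholds` (the F_ST and ln-ratio values at `P = alpha`) and `windows`
#'   (the input windows with `z_fst`, `z_ratio`, `p_fst`, `p_ratio`,
#'   `significant` columns added).
#' @export
call_cdrs <- function(windows, cfg = scan_config(), stage = "custom") {
  eligible <- windows$n_snps >= cfg$min_snps & !is.na(windows$fst)
  std_set <- eligible & is.finite(windows$pi_ln_ratio)
  if (sum(std_set) < 30)
    warning("fewer than 30 windows enter standardization; ",
            "Z-test calibration is unreliable")
  m_f <- mean(windows$fst[std_set]); s_f <- stats::sd(windows$fst[std_set])
  m_r <- mean(windows$pi_ln_ratio[std_set])
  s_r <- stats::sd(windows$pi_ln_ratio[std_set])
  if (is.na(s_f) || is.na(s_r) || s_f == 0 || s_r == 0)
    stop("degenerate window statistics: zero variance in the null set")
  windows$z_fst <- (windows$fst - m_f) / s_f
  windows$z_ratio <- (windows$pi_ln_ratio - m_r) / s_r
  windows$p_fst <- stats::pnorm(windows$z_fst, lower.tail = FALSE)
  windows$p_ratio <- stats::pnorm(windows$z_ratio, lower.tail = FALSE)
  zc <- stats::qnorm(1 - cfg$alpha)
  thresholds <- c(fst = m_f + zc * s_f, pi_ln_ratio = m_r + zc * s_r)
  sig_f <- !is.na(windows$p_fst) & windows$p_fst < cfg$alpha
  sig_r <- (eligible & windows$pi_ln_ratio == Inf) |
    (!is.na(windows$p_ratio) & windows$p_ratio < cfg$alpha)
  windows$significant <- eligible & sig_f & sig_r
  sig <- windows[windows$significant, , drop = FALSE]
  cdrs <- merge_windows(sig, cfg$merge_gap, stage)
  attr(cdrs, "thresholds") <- thresholds
  attr(cdrs, "windows") <- windows
  cdrs
}

# Merge significant windows into CDRs: overlapping/adjacent windows first,
# then intervals separated by < merge_gap bp. Idempotent and order-invariant.
merge_windows <- function(sig, merge_gap, stage) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stage = character(),
                      n_windows = integer(), mean_fst = numeric(),
                      max_fst = numeric(), mean_pi_ln_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               stage = stage, n_windows = length(cur$fst),
               mean_fst = mean(cur$fst, na.rm = TRUE),
               max_fst = max(cur$fst, na.rm = TRUE),
               mean_pi_ln_ratio = mean(cur$ratio[is.finite(cur$ratio)]),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sig))) {
    w <- sig[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom &&
        (w$start <= cur$end + 1L || (w$start - cur$end - 1L) < merge_gap)) {
      cur$end <- max(cur$end, w$end)
      cur$fst <- c(cur$fst, w$fst)
      cur$ratio <- c(cur$ratio, w$pi_ln_ratio)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, fst = w$fst,
                  ratio = w$pi_ln_ratio)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-population selective-sweep scan
#'
#' Convenience wrapper running [window_stats()] and [call_cdrs()] for one
#' stage comparison (ancestral-stage vs derived-stage population).
#'
#' @inheritParams window_stats
#' @inheritParams call_cdrs
#' @return an object of class `sweep_scan` with elements `windows`, `cdrs`,
#'   `thresholds`, `pair` and `cfg`.
#' @export
sweep_scan <- function(gm, pm, pop_a, pop_b, cfg = scan_config(),
                       stage = "custom", chrom_lengths = NULL) {
  w <- window_stats(gm, pm, pop_a, pop_b, cfg, chrom_lengths)
  cdrs <- call_cdrs(w, cfg, stage)
  structure(list(windows = attr(cdrs, "windows"),
                 cdrs = structure(cdrs, thresholds = NULL, windows = NULL),
                 thresholds = attr(cdrs, "thresholds"),
                 pair = c(ancestral = pop_a, derived = pop_b), cfg = cfg),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("Selective-sweep scan:", x$pair["ancestral"], "(ancestral) vs",
      x$pair["derived"], "(derived)\n")
  cat(sprintf("  %d windows (%d bp / %d bp step), %d pass min_snps = %d\n",
              nrow(x$windows), x$cfg$window, x$cfg$step,
              sum(x$windows$n_snps >= x$cfg$min_snps), x$cfg$min_snps))
  cat(sprintf("  empirical thresholds at P = %.3g: FST > %.4f, ln-ratio > %.4f\n",
              x$cfg$alpha, x$thresholds["fst"],
              x$thresholds["pi_ln_ratio"]))
  cat(sprintf("  %d significant windows -> %d CDRs\n",
              sum(x$windows$significant, na.rm = TRUE), nrow(x$cdrs)))
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  w <- object$windows
  ok <- !w$flagged
  cat("Window statistics over", sum(ok), "unflagged windows:\n")
  print(summary(w[ok, c("n_snps", "fst", "pi_a", "pi_b", "pi_ln_ratio")]))
  cat("\nCDRs:\n")
  print(object$cdrs)
  invisible(object)
}

#' Plot a sweep scan
#'
#' Windowed F_ST and pi ln-ratio along one chromosome, with the empirical
#' significance thresholds and called CDRs shaded.
#'
#' @param x a `sweep_scan`.
#' @param chrom chromosome to plot (default: first).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sweep_scan <- function(x, chrom = NULL, ...) {
  w <- x$windows
  if (is.null(chrom)) chrom <- w$chrom[1L]
  w <- w[w$chrom == chrom, ]
  mid <- (w$start + w$end) / 2 / 1e6
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    cd <- x$cdrs[x$cdrs$chrom == chrom, ]
    if (nrow(cd)) {
      usr <- graphics::par("usr")
      graphics::rect(cd$start / 1e6, usr[3], cd$end / 1e6, usr[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  plot(mid, w$fst, type = "l", xlab = "", ylab = expression(F[ST]),
       main = chrom)
  shade()
  graphics::abline(h = x$thresholds["fst"], lty = 2, col = "grey40")
  fin <- is.finite(w$pi_ln_ratio)
  plot(mid[fin], w$pi_ln_ratio[fin], type = "l", xlab = "position (Mb)",
       ylab = expression(ln(pi[a] / pi[b])))
  shade()
  graphics::abline(h = x$thresholds["pi_ln_ratio"], lty = 2, col = "grey40")
  invisible(x)
}

#' Find fixed differences between two populations
#'
#' Sites with per-site F_ST exactly 1: opposite fixation of the two
#' populations over their non-missing calls. When an ancestral assignment is
#' provided, per-population derived allele frequencies are reported.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param popA,popB population labels.
#' @param anc optional [assign_ancestral()] result.
#' @return data frame of fixed sites: `chrom`, `pos`, `p_alt_A`, `p_alt_B`
#'   and, with `anc`, `daf_A`, `daf_B`.
#' @export
find_fixed_sites <- function(gm, pm, popA, popB, anc = NULL) {
  fa <- allele_frequencies(gm, pm, popA)
  fb <- allele_frequencies(gm, pm, popB)
  fixed <- fa$n > 0 & fb$n > 0 &
    ((fa$p_alt == 0 & fb$p_alt == 1) | (fa$p_alt == 1 & fb$p_alt == 0))
  fixed[is.na(fixed)] <- FALSE
  out <- data.frame(chrom = gm$chrom[fixed], pos = gm$pos[fixed],
                    p_alt_A = fa$p_alt[fixed], p_alt_B = fb$p_alt[fixed],
                    stringsAsFactors = FALSE)
  if (!is.null(anc)) {
    dafA <- derived_allele_frequency(gm, pm, popA, anc)
    dafB <- derived_allele_frequency(gm, pm, popB, anc)
    out$daf_A <- dafA[fixed]
    out$daf_B <- dafB[fixed]
  }
  out
}

#' Screen for selection on standing variation
#'
#' Polarized sites whose derived allele segregates at moderate frequency in
#' the wild population (`daf < cfg$standing_max_af`, strict) but is nearly
#' fixed in the derived population (`daf > cfg$fixed_daf`, strict).
#' Unpolarized sites are skipped and counted. When CDRs are supplied, the
#' per-CDR count of qualifying sites and the subset of CDRs with at least
#' `cfg$min_fixed_sites_per_cdr` such sites are returned.
#'
#' @param gm a [genotype_matrix()].
#' @param pm population map.
#' @param wild_pop,derived_pop population labels.
#' @param anc [assign_ancestral()] result.
#' @param cfg a [scan_config()].
#' @param cdrs optional CDR data frame from [call_cdrs()].
#' @return list with `sites` (data frame `chrom`, `pos`, `daf_wild`,
#'   `daf_derived`), `n_unpolarized`, and with `cdrs`: `cdr_counts` (input
#'   CDRs plus `n_standing_fixed_sites`) and `qualifying_cdrs`.
#' @export
find_standing_fixed_sites <- function(gm, pm, wild_pop, derived_pop, anc,
                                      cfg = scan_config(), cdrs = NULL) {
  polarized <- anc$status == "polarized"
  if (!any(polarized)) {
    warning("no polarized sites")
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   daf_wild = numeric(),
                                   daf_derived = numeric()),
                n_unpolarized = n_sites(gm)))
  }
  dw <- derived_allele_frequency(gm, pm, wild_pop, anc)
  dd <- derived_allele_frequency(gm, pm, derived_pop, anc)
  pass <- polarized & !is.na(dw) & !is.na(dd) &
    dw < cfg$standing_max_af & dd > cfg$fixed_daf
  sites <- data.frame(chrom = gm$chrom[pass], pos = gm$pos[pass],
                      daf_wild = dw[pass], daf_derived = dd[pass],
                      stringsAsFactors = FALSE)
  res <- list(sites = sites, n_unpolarized = sum(!polarized))
  if (!is.null(cdrs) && nrow(cdrs)) {
    counts <- integer(nrow(cdrs))
    for (i in seq_len(nrow(cdrs)))
      counts[i] <- sum(sites$chrom == cdrs$chrom[i] &
                       sites$pos >= cdrs$start[i] & sites$pos <= cdrs$end[i])
    cdrs$n_standing_fixed_sites <- counts
    res$cdr_counts <- cdrs
    res$qualifying_cdrs <-
      cdrs[counts >= cfg$min_fixed_sites_per_cdr, , drop = FALSE]
  }
  res
}

#' Read gene intervals from GFF3 or BED
#'
#' Thin wrapper over `rtracklayer::import()`. For GFF3, rows of type `gene`
#' are kept (all rows when no `type` column matches).
#'
#' @param path annotation file path (`.gff3`, `.gff`, `.bed`).
#' @return a `GRanges` with a `gene_id` metadata column.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID)
        else if ("Name" %in% names(md)) as.character(md$Name)
        else if ("name" %in% names(md)) as.character(md$name)
        else paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr)$gene_id <- id
  gr
}

#' Annotate CDRs with overlapping genes
#'
#' A gene is assigned to a CDR when their spans overlap by at least 1 bp.
#' Genes on chromosomes absent from the CDR set are skipped with a warning.
#'
#' @param cdrs CDR data frame from [call_cdrs()].
#' @param genes a `GRanges` from [read_genes()], or a data frame with
#'   `chrom`, `start`, `end`, `gene_id` (1-based inclusive).
#' @return `cdrs` with list-column `gene_ids` and integer column `n_genes`;
#'   attribute `n_genes_total` gives the number of distinct genes over all
#'   CDRs.
#' @export
annotate_cdrs <- function(cdrs, genes) {
  if (is.data.frame(genes))
    genes <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    gene_id = genes$gene_id)
  if (nrow(cdrs) == 0L) {
    cdrs$gene_ids <- list(); cdrs$n_genes <- integer(0)
    attr(cdrs, "n_genes_total") <- 0L
    return(cdrs)
  }
  unknown <- !(as.character(GenomicRanges::seqnames(genes)) %in% cdrs$chrom)
  if (any(unknown))
    warning(sum(unknown), " gene(s) on chromosomes absent from the CDR set ",
            "were skipped")
  cdr_gr <- GenomicRanges::GRanges(cdrs$chrom,
                                   IRanges::IRanges(cdrs$start, cdrs$end))
  hits <- GenomicRanges::findOverlaps(cdr_gr, genes)
  ids <- S4Vectors::mcols(genes)$gene_id
  gene_ids <- split(ids[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_len(nrow(cdrs))))
  cdrs$gene_ids <- lapply(gene_ids, unique)
  cdrs$n_genes <- vapply(cdrs$gene_ids, length, integer(1))
  attr(cdrs, "n_genes_total") <-
    length(unique(unlist(cdrs$gene_ids)))
  cdrs
}
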