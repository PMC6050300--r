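#' Select diagnostic markers from founder populations
#'
#' Markers with absolute founder allele-frequency difference
#' `|p_elite - p_wild| > min_delta` (strict). The allele more frequent in the
#' elite founders is recorded so F2 genotypes can be recoded as elite-allele
#' dosage.
#'
#' @param gm founder [genotype_matrix()].
#' @param pm population map.
#' @param wild_pop,elite_pop founder population labels.
#' @param min_delta minimum |delta AF| (default 0.6).
#' @return data frame of markers sorted by position: `chrom`, `pos`,
#'   `delta_af`, `elite_allele` (`"ref"` or `"alt"`).
#' @export
select_diagnostic_markers <- function(gm, pm, wild_pop, elite_pop,
                                      min_delta = 0.6) {
  fw <- allele_frequencies(gm, pm, wild_pop)
  fe <- allele_frequencies(gm, pm, elite_pop)
  delta <- abs(fe$p_alt - fw$p_alt)
  pass <- !is.na(delta) & delta > min_delta
  if (!any(pass)) warning("no markers exceed the delta-AF threshold")
  out <- data.frame(chrom = gm$chrom[pass], pos = gm$pos[pass],
                    delta_af = delta[pass],
                    elite_allele = ifelse(fe$p_alt[pass] >= fw$p_alt[pass],
                                          "alt", "ref"),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Classify F2 individuals into recombination haplotypes
#'
#' Each F2 individual's genotypes at the diagnostic markers are recoded as
#' elite-allele dosage (M = 0 wild homozygote, H = 1 heterozygote, P = 2
#' elite homozygote), smoothed by a sliding majority vote over `smooth_k`
#' markers (missing values ignored), and runs shorter than `min_segment`
#' markers are absorbed into the flanking majority. Breakpoints are the
#' marker intervals where the smoothed code changes; individuals with
#' identical segment-code sequences share a haplotype class (e.g. `"P|M"`).
#'
#' @param f2_gm [genotype_matrix()] of the F2 individuals at the target
#'   region.
#' @param markers diagnostic markers from [select_diagnostic_markers()];
#'   matched to `f2_gm` sites by chromosome and position.
#' @param smooth_k odd sliding-window width (markers).
#' @param min_segment minimum run length (markers) kept as a segment.
#' @return an object of class `haplotype_calls`: a list with `calls` (data
#'   frame: `id`, `haplotype_class`, `n_breakpoints`, `classified`),
#'   `segments` (per individual: list of data frames `code`, `start_marker`,
#'   `end_marker`), `breakpoints` (per individual: integer vector of marker
#'   indices after which the code changes), `raw` and `smoothed` code
#'   matrices (individuals x markers), and `markers`.
#' @export
classify_haplotypes <- function(f2_gm, markers, smooth_k = 7,
                                min_segment = 3) {
  stopifnot(smooth_k %% 2 == 1, min_segment >= 1)
  key_gm <- paste(f2_gm$chrom, f2_gm$pos)
  key_mk <- paste(markers$chrom, markers$pos)
  idx <- match(key_mk, key_gm)
  if (anyNA(idx))
    stop("marker(s) absent from the F2 genotype matrix: ",
         paste(head(key_mk[is.na(idx)], 3), collapse = ", "))
  dos <- t(f2_gm$geno[idx, , drop = FALSE])   # individuals x markers
  flip <- markers$elite_allele == "ref"
  dos[, flip] <- 2L - dos[, flip]
  n_ind <- nrow(dos); n_mark <- ncol(dos)
  half <- (smooth_k - 1L) / 2L
  smooth_one <- function(x) {
    sm <- integer(n_mark)
    for (j in seq_len(n_mark)) {
      w <- x[max(1L, j - half):min(n_mark, j + half)]
      w <- w[!is.na(w)]
      if (!length(w)) { sm[j] <- NA_integer_; next }
      tab <- tabulate(w + 1L, nbins = 3L)
      best <- which(tab == max(tab)) - 1L
      if (length(best) > 1L && !is.na(x[j]) && x[j] %in% best)
        sm[j] <- x[j]                     # tie: keep the raw centre code
      else sm[j] <- best[1L]              # tie without centre: lowest code
    }
    # fill any all-missing stretches from the nearest called marker
    if (anyNA(sm)) {
      ok <- which(!is.na(sm))
      if (!length(ok)) return(sm)
      for (j in which(is.na(sm)))
        sm[j] <- sm[ok[which.min(abs(ok - j))]]
    }
    sm
  }
  segments_of <- function(sm) {
    r <- rle(sm)
    data.frame(code = r$values,
               start_marker = cumsum(c(1L, r$lengths[-length(r$lengths)])),
               end_marker = cumsum(r$lengths))
  }
  absorb_short <- function(seg) {
    repeat {
      if (nrow(seg) <= 1L) return(seg)
      len <- seg$end_marker - seg$start_marker + 1L
      short <- which(len < min_segment)
      if (!length(short)) return(seg)
      i <- short[which.min(len[short])]
      # merge into the longer flank (ties: left)
      left_len <- if (i > 1L) len[i - 1L] else -1L
      right_len <- if (i < nrow(seg)) len[i + 1L] else -1L
      into <- if (left_len >= right_len) i - 1L else i + 1L
      seg$code[i] <- seg$code[into]
      # re-run-length-encode
      seg <- segments_of(rep(seg$code, len))
    }
  }
  codes <- c("M", "H", "P")
  calls <- data.frame(id = rownames(dos) %||% paste0("F2_", seq_len(n_ind)),
                      haplotype_class = NA_character_,
                      n_breakpoints = NA_integer_,
                      classified = TRUE, stringsAsFactors = FALSE)
  smoothed <- matrix(NA_integer_, n_ind, n_mark)
  seg_list <- vector("list", n_ind)
  bp_list <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    x <- dos[i, ]
    if (mean(is.na(x)) > 0.5) {
      calls$classified[i] <- FALSE
      next
    }
    sm <- smooth_one(x)
    seg <- absorb_short(segments_of(sm))
    smoothed[i, ] <- rep(seg$code, seg$end_marker - seg$start_marker + 1L)
    seg_list[[i]] <- seg
    bp_list[[i]] <- seg$end_marker[-nrow(seg)]
    calls$n_breakpoints[i] <- nrow(seg) - 1L
    calls$haplotype_class[i] <- paste(codes[seg$code + 1L], collapse = "|")
  }
  structure(list(calls = calls, segments = seg_list,
                 breakpoints = bp_list, raw = dos, smoothed = smoothed,
                 markers = markers),
            class = "haplotype_calls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.haplotype_calls <- function(x, ...) {
  ok <- x$calls$classified
  cat("F2 haplotype classification:", nrow(x$calls), "individuals,",
      ncol(x$raw), "markers\n")
  if (any(!ok)) cat("  unclassified (>50% missing):", sum(!ok), "\n")
  tab <- sort(table(x$calls$haplotype_class[ok]), decreasing = TRUE)
  cat("  ", length(tab), "haplotype classes:\n")
  print(head(tab, 15))
  invisible(x)
}

#' Adjust phenotypes for fixed covariates
#'
#' Least-squares adjustment: each trait is regressed on the additive factor
#' effects and replaced by `grand mean + residual`, so downstream genotype
#' contrasts are free of site/sex/cross-direction structure. Factors with
#' fewer than two observed levels are dropped with a warning; missing trait
#' values stay missing.
#'
#' @param pt phenotype data frame (one row per individual).
#' @param traits character vector of trait column names.
#' @param factors character vector of covariate column names.
#' @return `pt` with the trait columns replaced by adjusted values.
#' @export
adjust_phenotypes <- function(pt, traits, factors) {
  usable <- character(0)
  for (f in factors) {
    lv <- unique(pt[[f]][!is.na(pt[[f]])])
    if (length(lv) >= 2) usable <- c(usable, f) else
      warning("factor '", f, "' has fewer than 2 levels; dropped")
  }
  for (tr in traits) {
    y <- pt[[tr]]
    if (all(is.na(y))) { warning("trait '", tr, "' all missing; skipped")
                         next }
    if (!length(usable)) next   # identity transform
    df <- data.frame(y = y, pt[usable], stringsAsFactors = TRUE)
    fit <- stats::lm(stats::as.formula(
      paste("y ~", paste(usable, collapse = " + "))), data = df,
      na.action = stats::na.exclude)
    pt[[tr]] <- mean(y, na.rm = TRUE) + stats::residuals(fit)
  }
  pt
}

#' Genotype-class association for one trait
#'
#' One-way ANOVA of an (adjusted) trait across genotype classes, typically
#' M / H / P elite-allele dosage groups. Variance explained is
#' `SS_between / SS_total`; the effect percentage contrasts the two
#' homozygote means, `(mean_P - mean_M) / mean_M * 100`.
#'
#' @param genotype vector of class labels per individual (e.g. `"M"`, `"H"`,
#'   `"P"`, or 0/1/2 dosages, coerced to factor).
#' @param phenotype numeric trait values, same length.
#' @param m_level,p_level labels of the wild and elite homozygote classes
#'   used for the effect percentage (defaults `"M"` and `"P"`, falling back
#'   to the extreme dosage labels present).
#' @return an object of class `assoc_result`: group means and sizes,
#'   `effect_pct`, `variance_explained`, `anova_p`.
#' @export
genotype_association <- function(genotype, phenotype, m_level = NULL,
                                 p_level = NULL) {
  ok <- !is.na(genotype) & !is.na(phenotype)
  g <- factor(as.character(genotype[ok]))
  y <- phenotype[ok]
  means <- tapply(y, g, mean)
  sizes <- as.integer(table(g))
  names(sizes) <- levels(g)
  lv <- levels(g)
  if (is.null(m_level)) m_level <- if ("M" %in% lv) "M" else lv[1L]
  if (is.null(p_level)) p_level <- if ("P" %in% lv) "P" else lv[length(lv)]
  effect_pct <- if (m_level %in% lv && p_level %in% lv)
    (means[[p_level]] - means[[m_level]]) / means[[m_level]] * 100 else
    NA_real_
  # groups with < 2 individuals are excluded from the ANOVA
  keep_lv <- names(sizes)[sizes >= 2L]
  anova_p <- NA_real_
  variance_explained <- NA_real_
  if (length(keep_lv) >= 2L) {
    sub <- g %in% keep_lv
    gg <- droplevels(g[sub]); yy <- y[sub]
    fit <- stats::lm(yy ~ gg)
    av <- stats::anova(fit)
    ss_between <- av$`Sum Sq`[1L]
    ss_total <- sum(av$`Sum Sq`)
    variance_explained <- if (isTRUE(all.equal(ss_total, 0))) 0 else
      ss_between / ss_total
    anova_p <- av$`Pr(>F)`[1L]
  }
  structure(list(group_means = means, group_sizes = sizes,
                 effect_pct = unname(effect_pct),
                 variance_explained = variance_explained,
                 anova_p = anova_p, m_level = m_level, p_level = p_level),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Genotype-class association (one-way ANOVA)\n")
  df <- data.frame(mean = round(unclass(x$group_means), 3),
                   n = x$group_sizes[names(x$group_means)])
  print(df)
  cat(sprintf("  effect (%s vs %s): %+.2f%%\n", x$p_level, x$m_level,
              x$effect_pct))
  cat(sprintf("  variance explained: %.4f  ANOVA P = %.3g\n",
              x$variance_explained, x$anova_p))
  invisible(x)
}

#' Mendelian segregation chi-square test
#'
#' Pearson goodness-of-fit of two observed phenotype counts against an
#' expected `a:b` ratio (df = 1), with the Yates continuity-corrected value
#' also reported.
#'
#' @param observed integer vector of length 2 (e.g. colored, colorless
#'   counts).
#' @param expected_ratio positive ratio, default `c(3, 1)`.
#' @return list: `chi2`, `chi2_yates`, `df`, `p`, `p_yates`, `expected`.
#' @export
segregation_chi2 <- function(observed, expected_ratio = c(3, 1)) {
  stopifnot(length(observed) == 2, all(observed >= 0),
            all(expected_ratio > 0))
  n <- sum(observed)
  if (n == 0) stop("zero total count")
  p <- expected_ratio / sum(expected_ratio)
  expected <- n * p
  ct <- suppressWarnings(stats::chisq.test(observed, p = p))
  chi2_yates <- sum((abs(observed - expected) - 0.5)^2 / expected)
  list(chi2 = unname(ct$statistic), chi2_yates = chi2_yates, df = 1L,
       p = unname(ct$p.value),
       p_yates = stats::pchisq(chi2_yates, 1, lower.tail = FALSE),
       expected = expected)
}

#' Genotype a structural variant from junction read support
#'
#' Read-count genotyping of a presence/absence structural variant:
#' `ref_support` reads span the uninserted junction, `ins_support` reads
#' support the insertion junction. Calls per individual:
#' homozygous uninserted `NN` when `ins_support < min_allele_reads` and
#' `ref_support >= min_depth`; homozygous inserted `II` symmetrically;
#' heterozygous `IN` when both supports reach `min_allele_reads`; otherwise
#' `NA` (missing).
#'
#' @param counts data frame with columns `ref_support`, `ins_support` (and
#'   optionally `id`).
#' @param min_depth minimum supporting reads for a homozygous call.
#' @param min_allele_reads minimum reads to accept an allele as present.
#' @return character vector of genotypes (`"NN"`, `"IN"`, `"II"`, `NA`).
#' @export
genotype_sv <- function(counts, min_depth = 4, min_allele_reads = 2) {
  r <- counts$ref_support; i <- counts$ins_support
  stopifnot(all(r >= 0), all(i >= 0))
  out <- rep(NA_character_, length(r))
  out[i < min_allele_reads & r >= min_depth] <- "NN"
  out[r < min_allele_reads & i >= min_depth] <- "II"
  out[r >= min_allele_reads & i >= min_allele_reads] <- "IN"
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,sample - Ct_ref,sample) - (Ct_target,calibrator -
#' Ct_ref,calibrator)]`, i.e. target-gene expression normalized to a
#' reference gene and expressed relative to a calibrator sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator.
#' @return fold change (numeric).
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
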