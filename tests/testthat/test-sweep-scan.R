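# CDR calling, merging, fixed-site and standing-variation screens,
# gene annotation.

# Construct a plausible null window set with planted outliers.
null_windows <- function(n = 1000, seed = 101, chrom = "chr1",
                         step = 10000, window = 40000) {
  set.seed(seed)
  starts <- seq(1L, by = step, length.out = n)
  data.frame(chrom = chrom, start = starts,
             end = starts + window - 1L,
             n_snps = rpois(n, 60) + 40L,
             fst = rnorm(n, 0.07, 0.02),
             pi_a = rep(2e-4, n), pi_b = rep(2e-4, n),
             pi_ln_ratio = rnorm(n, 0, 0.3),
             partial = FALSE, flagged = FALSE)
}

test_that("a single planted outlier window becomes exactly one CDR", {
  w <- null_windows()
  w$fst[500] <- 0.07 + 5 * 0.02
  w$pi_ln_ratio[500] <- 5 * 0.3
  cfg <- scan_config(min_snps = 40, alpha = 0.005, merge_gap = 200000)
  cdrs <- call_cdrs(w, cfg, stage = "domestication")
  expect_equal(nrow(cdrs), 1L)
  expect_equal(cdrs$stage, "domestication")
  expect_lte(cdrs$start, w$start[500])
  expect_gte(cdrs$end, w$end[500])
  expect_equal(cdrs$n_windows, 1L)
  # empirical thresholds sit near mean + 2.576 sd
  th <- attr(cdrs, "thresholds")
  expect_equal(unname(th["fst"]), 0.07 + qnorm(0.995) * 0.02,
               tolerance = 0.15)
})

test_that("significant windows under 200 kb apart merge into one CDR", {
  w <- null_windows()
  w$fst[c(300, 315)] <- 0.25          # 150 kb apart (< 200 kb)
  w$pi_ln_ratio[c(300, 315)] <- 2.5
  cfg <- scan_config(min_snps = 40, merge_gap = 200000)
  cdrs <- call_cdrs(w, cfg)
  expect_equal(nrow(cdrs), 1L)
  expect_equal(cdrs$n_windows, 2L)
  expect_equal(cdrs$start, w$start[300])
  expect_equal(cdrs$end, w$end[315])
  # beyond the merge gap they stay separate
  w2 <- null_windows()
  w2$fst[c(300, 325)] <- 0.25         # 250 kb apart
  w2$pi_ln_ratio[c(300, 325)] <- 2.5
  expect_equal(nrow(call_cdrs(w2, cfg)), 2L)
})

test_that("CDR merging reproduces a hand-merged interval list exactly", {
  w <- null_windows()
  sig <- c(100, 101, 102,       # overlapping run -> one CDR
           140,                 # 370 kb away -> separate under 200 kb rule
           150, 164)            # 100 kb gap -> merged
  w$fst[sig] <- 0.3; w$pi_ln_ratio[sig] <- 3
  cfg <- scan_config(min_snps = 40, merge_gap = 200000)
  cdrs <- call_cdrs(w, cfg)
  hand <- data.frame(start = w$start[c(100, 140)],
                     end = w$end[c(102, 164)])
  # windows 140 and 150 are 60 kb apart edge-to-edge: still < 200 kb, merged
  hand <- data.frame(start = w$start[100], end = w$end[102])
  expect_equal(cdrs$start[1], hand$start)
  expect_equal(cdrs$end[1], hand$end)
  # gap between window 102 (ends 1,050,000) and 140 (starts 1,390,001):
  # 340 kb > 200 kb -> new CDR; 140..164 all within 200 kb -> one CDR
  expect_equal(nrow(cdrs), 2L)
  expect_equal(cdrs$start[2], w$start[140])
  expect_equal(cdrs$end[2], w$end[164])
  # every CDR spans the union of its member windows
  expect_true(all(cdrs$end >= cdrs$start))
})

test_that("merging is idempotent and input-order invariant", {
  w <- null_windows()
  sig <- c(200, 203, 400, 401, 800)
  w$fst[sig] <- 0.3; w$pi_ln_ratio[sig] <- 3
  cfg <- scan_config(min_snps = 40, merge_gap = 200000)
  a <- call_cdrs(w, cfg)
  b <- call_cdrs(w[sample(nrow(w)), ], cfg)
  attr(a, "windows") <- attr(b, "windows") <- NULL
  attr(a, "thresholds") <- attr(b, "thresholds") <- NULL
  expect_equal(a, b)
})

test_that("no jointly significant window yields an empty CDR set", {
  w <- null_windows()
  w$fst[500] <- 0.25          # F_ST outlier only
  cfg <- scan_config(min_snps = 40)
  expect_equal(nrow(call_cdrs(w, cfg)), 0L)
  # degenerate input: zero variance
  w$fst <- 0.07; w$pi_ln_ratio <- 0
  expect_error(call_cdrs(w, cfg), "degenerate")
})

test_that("infinite-ratio windows are excluded from the null but can pass", {
  w <- null_windows()
  w$fst[600] <- 0.25
  w$pi_ln_ratio[600] <- Inf
  w$flagged[600] <- TRUE
  cfg <- scan_config(min_snps = 40)
  cdrs <- call_cdrs(w, cfg)
  expect_equal(nrow(cdrs), 1L)
  wz <- attr(cdrs, "windows")
  expect_true(wz$significant[600])
})

test_that("fixed-site screen lists exactly the opposite-fixation sites", {
  g <- rbind(c(rep(0L, 4), rep(2L, 4)),     # fixed difference
             c(rep(2L, 4), rep(0L, 4)),     # fixed difference (other way)
             c(0L, 0L, 0L, 1L, 2L, 2L, 2L, 2L),  # p_A = 0.125 -> not fixed
             c(rep(0L, 4), rep(2L, 3), NA),  # fixed over non-missing calls
             c(rep(0L, 8)),                  # monomorphic
             matrix(sample(0:2, 8 * 5, replace = TRUE), 5, 8))
  gm <- make_gm(g)
  pm <- make_popmap(A = paste0("s", 1:4), B = paste0("s", 5:8))
  set.seed(41)
  fx <- find_fixed_sites(gm, pm, "A", "B")
  expect_true(all(c(100L, 200L, 400L) %in% fx$pos))
  expect_false(300L %in% fx$pos)
  expect_false(500L %in% fx$pos)
  res <- site_fst(gm, pm, "A", "B")
  expect_true(all(res$fst[match(fx$pos, gm$pos)] == 1))
})

test_that("the standing-variation filter matches enumeration on a 20-site toy", {
  set.seed(51)
  n_w <- 10; n_d <- 10; n_o <- 3
  daf_w <- round(runif(20), 2)
  daf_d <- round(runif(20, 0.9, 1), 3)
  daf_d[1:5] <- c(0.96, 0.95, 0.99, 0.94, 1.0)
  daf_w[1:5] <- c(0.40, 0.40, 0.60, 0.10, 0.49)
  # build genotypes whose allele frequencies are exactly daf (alt = derived)
  freq_to_geno <- function(p, n) {
    k <- round(p * 2 * n)
    c(rep(2L, k %/% 2), rep(1L, k %% 2),
      rep(0L, n - k %/% 2 - k %% 2))
  }
  g <- t(vapply(seq_len(20), function(i)
    c(freq_to_geno(daf_w[i], n_w), freq_to_geno(daf_d[i], n_d),
      rep(0L, n_o)), integer(n_w + n_d + n_o)))
  gm <- make_gm(g)
  pm <- make_popmap(wild = paste0("s", 1:n_w),
                    indigenous = paste0("s", n_w + 1:n_d),
                    outgroup = paste0("s", n_w + n_d + 1:n_o))
  anc <- assign_ancestral(gm, pm, "outgroup")
  cfg <- scan_config()
  res <- find_standing_fixed_sites(gm, pm, "wild", "indigenous", anc, cfg)
  # recompute actual frequencies and enumerate by hand
  pw <- rowSums(g[, 1:n_w]) / (2 * n_w)
  pd <- rowSums(g[, n_w + 1:n_d]) / (2 * n_d)
  manual <- which(pw < 0.5 & pd > 0.95)
  expect_equal(res$sites$pos, gm$pos[manual])
  # boundary semantics: exactly 0.95 fails the strict >, exactly 0.5 fails <
  expect_false(gm$pos[2] %in% res$sites$pos)  # daf_d = 0.95
  expect_false(gm$pos[3] %in% res$sites$pos)  # daf_w = 0.60
})

test_that("per-CDR standing-site counts gate on the minimum-count rule", {
  # 6 qualifying sites in CDR1, 2 in CDR2
  pos <- c(seq(1000, 6000, by = 1000), c(50000, 51000))
  g <- cbind(matrix(0L, 8, 6), matrix(2L, 8, 6), matrix(0L, 8, 2))
  gm <- make_gm(g, pos = as.integer(pos))
  pm <- make_popmap(wild = paste0("s", 1:6), indigenous = paste0("s", 7:12),
                    outgroup = paste0("s", 13:14))
  anc <- assign_ancestral(gm, pm, "outgroup")
  cdrs <- data.frame(chrom = "chr1", start = c(500L, 45000L),
                     end = c(10000L, 60000L), stage = "domestication")
  res <- find_standing_fixed_sites(gm, pm, "wild", "indigenous", anc,
                                   scan_config(), cdrs = cdrs)
  expect_equal(res$cdr_counts$n_standing_fixed_sites, c(6L, 2L))
  expect_equal(nrow(res$qualifying_cdrs), 1L)
  expect_equal(res$qualifying_cdrs$start, 500L)
})

test_that("gene annotation counts overlaps exactly on a toy gene set", {
  cdrs <- data.frame(chrom = c("chr1", "chr1"),
                     start = c(15000L, 100000L), end = c(55000L, 120000L),
                     stage = "domestication")
  genes <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                      start = c(10000L, 60000L, 54000L, 110000L, 1000L),
                      end = c(20000L, 70000L, 56000L, 115000L, 2000L),
                      gene_id = c("g_in1", "g_out", "g_edge", "g_in2",
                                  "g_otherchrom"))
  expect_warning(out <- annotate_cdrs(cdrs, genes), "skipped")
  expect_setequal(out$gene_ids[[1]], c("g_in1", "g_edge"))
  expect_equal(out$gene_ids[[2]], "g_in2")
  expect_equal(out$n_genes, c(2L, 1L))
  expect_equal(attr(out, "n_genes_total"), 3L)
})

test_that("GFF3 gene annotation reads through rtracklayer", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "gene", "10000", "20000", ".", "+", ".",
                     "ID=gene1;Name=PLA2G4A", sep = "\t"),
               paste("chr1", "test", "exon", "10000", "12000", ".", "+", ".",
                     "ID=exon1;Parent=gene1", sep = "\t"),
               paste("chr1", "test", "gene", "90000", "95000", ".", "+", ".",
                     "ID=gene2", sep = "\t")), gff)
  genes <- read_genes(gff)
  expect_length(genes, 2L)
  cdrs <- data.frame(chrom = "chr1", start = 15000L, end = 50000L,
                     stage = "x")
  out <- suppressWarnings(annotate_cdrs(cdrs, genes))
  expect_equal(out$n_genes, 1L)
})
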