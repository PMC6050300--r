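# Diagnostic markers, haplotype classification, phenotype adjustment,
# association, segregation, SV genotyping and ddCt.

test_that("diagnostic marker selection applies the strict delta-AF rule", {
  # wild (4) + elite (4) founders with controlled frequencies
  g <- rbind(c(0L, 0L, 0L, 1L, 2L, 2L, 2L, 1L),   # 0.125 vs 0.875: 0.75 > 0.6
             c(1L, 1L, 0L, 0L, 2L, 2L, 2L, 1L),   # 0.25 vs 0.875: 0.625
             c(1L, 1L, 1L, 0L, 2L, 2L, 1L, 2L),   # 0.375 vs 0.875: 0.5 -> out
             c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L))   # 1 vs 0: elite allele = ref
  gm <- make_gm(g)
  pm <- make_popmap(wild = paste0("s", 1:4), elite = paste0("s", 5:8))
  mk <- select_diagnostic_markers(gm, pm, "wild", "elite", min_delta = 0.6)
  expect_equal(mk$pos, c(100L, 200L, 400L))
  expect_equal(mk$elite_allele, c("alt", "alt", "ref"))
  expect_equal(mk$delta_af, c(0.75, 0.625, 1))
  # brute-force agreement on a random panel
  set.seed(71)
  g2 <- matrix(sample(0:2, 20 * 8, replace = TRUE), 20, 8)
  gm2 <- make_gm(g2)
  mk2 <- select_diagnostic_markers(gm2, pm, "wild", "elite", 0.6)
  pw <- rowSums(g2[, 1:4]) / 8; pe <- rowSums(g2[, 5:8]) / 8
  expect_equal(mk2$pos, gm2$pos[abs(pe - pw) > 0.6])
})

simple_markers <- function(m) {
  data.frame(chrom = "chr1", pos = seq_len(m) * 100L, delta_af = 1,
             elite_allele = "alt", stringsAsFactors = FALSE)
}

test_that("a clean recombinant classifies as P|M with one breakpoint", {
  codes <- c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L)
  gm <- make_gm(matrix(codes, ncol = 1), pos = seq_len(8) * 100L)
  hc <- classify_haplotypes(gm, simple_markers(8), smooth_k = 3,
                            min_segment = 2)
  expect_equal(hc$calls$haplotype_class, "P|M")
  expect_equal(hc$breakpoints[[1]], 4L)
  expect_equal(hc$calls$n_breakpoints, 1L)
})

test_that("majority smoothing absorbs isolated genotyping errors", {
  codes <- c(2L, 2L, 0L, 2L, 2L, 2L, 0L, 0L, 0L)
  gm <- make_gm(matrix(codes, ncol = 1), pos = seq_len(9) * 100L)
  hc <- classify_haplotypes(gm, simple_markers(9), smooth_k = 3,
                            min_segment = 2)
  expect_equal(hc$calls$haplotype_class, "P|M")
  expect_equal(hc$breakpoints[[1]], 6L)
})

test_that("mostly-missing individuals are reported unclassified", {
  codes <- c(2L, NA, NA, NA, NA, NA, 0L, 0L)
  gm <- make_gm(matrix(codes, ncol = 1), pos = seq_len(8) * 100L)
  hc <- classify_haplotypes(gm, simple_markers(8), smooth_k = 3,
                            min_segment = 2)
  expect_false(hc$calls$classified)
  expect_true(is.na(hc$calls$haplotype_class))
})

test_that("breakpoint counts are non-increasing in the smoothing window", {
  f2 <- simulate_f2(f2_sim_config(n_f2 = 120), seed = 3)
  bks <- vapply(c(3, 7, 11), function(k) {
    hc <- classify_haplotypes(f2$gm, f2$markers, smooth_k = k,
                              min_segment = 3)
    sum(hc$calls$n_breakpoints, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(bks) <= 0))
})

test_that("phenotype adjustment removes balanced site effects exactly", {
  pt <- data.frame(y = c(100, 100, 200, 200),
                   site = factor(c("a", "a", "b", "b")),
                   sex = factor(c("F", "M", "F", "M")))
  out <- adjust_phenotypes(pt, "y", c("site", "sex"))
  expect_equal(out$y, rep(150, 4))
  # single-level factor -> identity with a warning
  pt2 <- data.frame(y = c(1, 2, 3), site = factor("a"))
  expect_warning(out2 <- adjust_phenotypes(pt2, "y", "site"), "fewer than 2")
  expect_equal(out2$y, pt2$y)
})

test_that("adjusted values are grand mean + least-squares residuals", {
  set.seed(72)
  n <- 60
  site <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  y <- 50 + c(a = 0, b = 10, c = -5)[site] + c(F = 0, M = 8)[sex] + rnorm(n)
  y[c(3, 10)] <- NA
  pt <- data.frame(y = y, site = site, sex = sex)
  out <- adjust_phenotypes(pt, "y", c("site", "sex"))
  # normal-equation oracle
  X <- model.matrix(~ site + sex)
  ok <- !is.na(y)
  beta <- solve(t(X[ok, ]) %*% X[ok, ], t(X[ok, ]) %*% y[ok])
  resid <- y[ok] - X[ok, ] %*% beta
  expect_equal(unname(out$y[ok]), unname(mean(y, na.rm = TRUE) + resid[, 1]),
               tolerance = 1e-10)
  expect_true(all(is.na(out$y[c(3, 10)])))
  # residuals sum to zero within each factor level
  for (lv in levels(site))
    expect_equal(sum(out$y[site == lv & ok] - mean(y, na.rm = TRUE)), 0,
                 tolerance = 1e-8)
})

test_that("genotype-class effects and variance explained are exact arithmetic", {
  geno <- rep(c("M", "H", "P"), each = 4)
  y <- c(rep(2000, 4), rep(2100, 4), rep(2300, 4))
  a <- suppressWarnings(genotype_association(geno, y))
  expect_equal(a$effect_pct, 15)
  expect_equal(a$variance_explained, 1)    # no within-group variance
  # identical means: zero effect, zero variance explained
  b <- suppressWarnings(genotype_association(rep(c("M", "P"), 5),
                                             rep(c(7, 7), 5)))
  expect_equal(b$effect_pct, 0)
  expect_equal(b$variance_explained, 0)
})

test_that("ANOVA output matches lm on included groups and drops singletons", {
  set.seed(73)
  geno <- c(rep("M", 10), rep("H", 12), rep("P", 9), "X")
  y <- rnorm(32, mean = c(M = 0, H = 1, P = 2, X = 50)[geno])
  a <- genotype_association(geno, y)
  keep <- geno != "X"
  fit <- stats::lm(y[keep] ~ factor(geno[keep]))
  av <- stats::anova(fit)
  expect_equal(a$anova_p, av$`Pr(>F)`[1])
  expect_equal(a$variance_explained,
               av$`Sum Sq`[1] / sum(av$`Sum Sq`))
})

test_that("a programmed QTL variance fraction is recovered at n = 1000", {
  set.seed(74)
  n <- 1000
  dos <- rbinom(n, 2, 0.5)
  f <- 0.15; sd_res <- 1
  a_eff <- sd_res * sqrt(2 * f / (1 - f))
  y <- 10 + a_eff * dos + rnorm(n, 0, sd_res)
  res <- genotype_association(c("M", "H", "P")[dos + 1], y)
  expect_lt(abs(res$variance_explained - f), 0.03)
})

test_that("segregation chi-square reproduces hand-computed values", {
  exact <- segregation_chi2(c(750, 250), c(3, 1))
  expect_equal(exact$chi2, 0)
  printed <- segregation_chi2(c(776, 250), c(3, 1))
  expect_equal(printed$chi2, 0.2196, tolerance = 1e-3)
  expect_equal(printed$chi2_yates, 0.1871, tolerance = 1e-3)
  expect_equal(printed$df, 1L)
  extreme <- segregation_chi2(c(0, 100), c(3, 1))
  expect_equal(extreme$chi2, 300)
  expect_error(segregation_chi2(c(0, 0)), "zero")
})

test_that("SV genotyping follows the read-support decision rule", {
  counts <- data.frame(ref_support = c(10, 0, 6, 1, 3, 0),
                       ins_support = c(0, 12, 5, 1, 0, 3))
  gt <- genotype_sv(counts, min_depth = 4, min_allele_reads = 2)
  expect_equal(gt, c("NN", "II", "IN", NA, NA, NA))
})

test_that("the ddCt worked examples hold exactly", {
  expect_equal(relative_expression_ddct(25, 20, 24, 20), 0.5)
  expect_equal(relative_expression_ddct(23, 20, 23, 20), 1.0)
  expect_equal(relative_expression_ddct(20, 20, 23, 20), 8.0)
})
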