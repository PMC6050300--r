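---
title: "Two-stage selective-sweep mapping and F2 fine-mapping: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage selective-sweep mapping and F2 fine-mapping: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

# The problem

Domesticated animal populations carry the footprints of two selection
episodes: an ancient domestication event that separated them from their wild
progenitor, and a recent, intense improvement phase that produced elite
breeds. `popsweep` implements the comparative-genomics machinery used to map
both: windowed divergence/diversity scans between population pairs
(wild vs. indigenous for the domestication stage, indigenous vs. elite for
the improvement stage), screens for fixed and standing variants polarized
against an outgroup, an ABBA-BABA test for gene flow between breeds, and the
fine-mapping toolkit for a wild x domestic F2 intercross in which a
major-effect body-size QTL and a recessive plumage-color locus segregate.
A forward Wright-Fisher simulator generates all inputs with the assumed
statistical structure, so the full pipeline runs and is tested without any
external data.

# Statistics

## Windowed F_ST and the pi ln-ratio

Divergence is measured with the Weir-Cockerham (1984) two-population
estimator. For each biallelic SNP the variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) are computed from the diploid sample sizes, allele frequencies
and *observed* heterozygote counts; the per-site estimate is $a/(a+b+c)$,
left unclamped (small negative values are informative about the null).
Windowed F_ST is the **ratio of sums** $\sum a / \sum (a+b+c)$ over the SNPs
in a window — the "weighted" form, which is what VCFtools reports and is
considerably less noisy than averaging per-site ratios.

Nucleotide diversity per window is
$\pi = \frac{1}{W}\sum_{\text{sites}} \frac{n}{n-1}\,2\hat p(1-\hat p)$,
with $n$ the number of non-missing alleles and $W$ the *full configured
window size* in bp (40 kb at study scale). Dividing by $W$ rather than by
the SNP count makes $\pi$ a per-bp quantity of the magnitude population
geneticists expect (a few 1e-4 for a waterfowl-like genome).
The sweep statistic is the log ratio
$\ln(\pi_\text{ancestral}/\pi_\text{derived})$, oriented so that diversity
*loss in the derived population* (the sweep signature) is positive. Natural
log is used, and the thresholds quoted for the study scale (0.70, 1.23) live
on this scale.

Windows tile each chromosome from position 1 with a configurable step
(40 kb / 10 kb at study scale; 20 kb / 5 kb in this package's desk-scale
tests). A trailing partial window is emitted but flagged.

## Calling candidate divergent regions

Windows with at least `min_snps` SNPs (40 at study scale; 20 at desk scale)
and finite statistics define an empirical null: each statistic is
standardized to $z = (x - \bar x)/s$ and converted to a one-sided
upper-tail normal $P$. A window is significant when $P < 0.005$ for **both**
statistics; runs of overlapping or adjacent significant windows are merged,
and resulting regions closer than 200 kb are merged again (replacing the
study-scale practice of manual inspection with a deterministic rule). A
window whose derived-population diversity is exactly zero has an infinite
ln-ratio: it is excluded from the mean/sd estimation (it would otherwise
poison them) but passes the ratio criterion outright, since zero diversity
is the strongest possible sweep signal. No pseudocount is used.

Two caveats that the package's own acceptance checks make explicit:

* The windowed F_ST null is **right-skewed** (it is bounded below by ~0 and
  driven by a modest number of genealogies per window), so the normal
  $P < 0.005$ upper tail over-calls by roughly a factor of three on neutral
  simulations. The scan is an outlier-ranking heuristic, not a calibrated
  test; the joint (two-statistic) requirement is what keeps the false-call
  rate near zero in practice — jointly significant windows are rarer than
  0.5% on our neutral runs.
* The empirical thresholds reported (`thresholds` on a `sweep_scan`) are the
  statistic values at $P = \alpha$, the desk-scale analogues of the study's
  printed cutoffs.

## Fixed and standing variants

`find_fixed_sites()` returns sites with per-site F_ST exactly 1 (opposite
fixation over non-missing calls). `find_standing_fixed_sites()` requires
outgroup polarization: a site qualifies when the *derived* allele segregates
below 0.5 in the wild population but above 0.95 in the derived-stage
population (both strict inequalities, as printed in the scan's source
method). Ancestral states are assigned only where at least `min_og_samples`
outgroup samples are non-missing, all homozygous, and identical; a
heterozygous outgroup genotype never polarizes a site. This genotype-level
concordance rule is the strict analogue of read-level polarization with
quality thresholds, which operates on data this package does not model.

## ABBA-BABA D-statistic

For the quartet $(O,((P_1,P_2),P_3))$ with derived-allele frequencies
$\hat p_i$ (the outgroup defines the ancestral state; sites where it is
polymorphic, heterozygous or missing are skipped), frequency mode scores
$C_\text{ABBA} = (1-\hat p_1)\hat p_2 \hat p_3$ and
$C_\text{BABA} = \hat p_1 (1-\hat p_2)\hat p_3$, and

$$D = \frac{\sum_i \big(C_\text{BABA}(i) - C_\text{ABBA}(i)\big)}
           {\sum_i \big(C_\text{BABA}(i) + C_\text{ABBA}(i)\big)}.$$

Note the numerator orientation: it is the mirror image of the common
ABBA−BABA convention. This package implements the formula and its sign
interpretation verbatim — positive $D$ indicates $P_1$–$P_3$ gene flow,
negative $D$ indicates $P_2$–$P_3$ gene flow — and offers
`convention = "abba-baba"` to negate $D$ for comparison with other tools.
Significance uses a weighted delete-one-block jackknife (Busing, Meijer &
van der Leeden 1999) over contiguous genomic blocks (default 5 Mb,
configurable; block-count sensitivity is part of the test suite), with
$Z = D/\mathrm{SE}$.

## F2 fine-mapping

* **Diagnostic markers** are founder SNPs with $|\Delta AF| > 0.6$ (strict)
  between the wild and elite founder populations; the elite-major allele is
  recorded so F2 genotypes become elite-allele dosages M/H/P (0/1/2).
* **Haplotype classification** smooths each individual's dosage track with a
  sliding majority vote over `smooth_k = 7` markers (missing ignored; ties
  resolved toward the raw centre code, then the lowest code), absorbs
  runs shorter than `min_segment = 3` markers into the longer flank, and
  reads breakpoints off the smoothed segment boundaries. Individuals with
  identical segment-code sequences share a haplotype class (e.g. `"P|H|M"`).
  These two deterministic parameters replace the study-scale "final manual
  check"; on simulated crosses with 1% genotyping error and 2% missingness
  they recover >99% of true crossovers within one marker.
* **Phenotype adjustment** is an ordinary least-squares fit of each trait on
  additive factors (rearing site, sex, cross direction); the adjusted value
  is grand mean + residual. Factors observed at fewer than two levels are
  dropped with a warning (the feed-conversion cohort, reared at one site,
  is the motivating case).
* **Association** is a one-way ANOVA across genotype classes with at least
  two members; variance explained is $SS_\text{between}/SS_\text{total}$ and
  the effect percentage contrasts homozygote means,
  $(\bar y_P - \bar y_M)/\bar y_M \times 100$ — the heterozygote mean is
  reported but deliberately excluded from the effect contrast.
* **Segregation** is a Pearson $\chi^2$ (df = 1) against an a:b ratio, with
  the Yates-corrected value also reported. For counts of 776:250 against
  3:1 these give 0.2196 and 0.1871 respectively; both support Mendelian
  segregation. (At $n = 1026$ the Pearson acceptance probability under a
  true 3:1 is exactly 94.9% at $\alpha = 0.05$ — slightly below nominal —
  which the acceptance checks surface honestly.)
* **SV genotyping** calls a presence/absence insertion from junction read
  support: `NN` if insertion support `< min_allele_reads` (2) and reference
  support `>= min_depth` (4); `II` symmetrically; `IN` when both alleles
  have `>= min_allele_reads`; otherwise missing. With a 1% read-mislabeling
  rate this rule cannot be error-free over a 1026-individual cohort at any
  depth (two mislabeled reads convert a homozygote into a heterozygote
  call); observed concordance on simulated truth is ~99.3% at 17x junction
  depth, and the residual error is an irreducible property of
  absolute-count thresholds.
* **Relative expression** implements $2^{-\Delta\Delta C_t}$.

# The synthetic-data generators

`simulate_populations()` is a forward Wright-Fisher diploid simulator with
recombination (Poisson crossovers, no interference) and infinite-sites
mutation, written around a small C++ meiosis kernel. Demography follows the
two-stage design: an ancestral population splits into wild and indigenous;
the elite population is founded from the indigenous one through a
bottleneck; the indigenous population can split into two subpopulations,
one of which may exchange migrants with the elite population (the
gene-flow scenario the D-statistic is pointed at). The outgroup is emitted
as fixed homozygous-ancestral individuals — only polarization concordance
is needed from it, not a realistic divergence time.

Choices that matter:

* **Equilibrium initialization.** Instead of a 4N-10N generation burn-in,
  the ancestral population is seeded from the neutral stationary site
  frequency spectrum (site counts Poisson with mean $\theta L a_{2N-1}$,
  frequencies $\propto 1/i$) followed by a short mutation-drift burn-in to
  build linkage structure. Expected diversity is stationary from the start
  ($E[\pi] = \theta(2N-1)/2N$ per bp), which the test suite verifies.
* **Desk scale.** Defaults are $N = 150$ diploids, three 400-kb
  chromosomes, $\mu = 10^{-6}$, $r = 2\times10^{-6}$ — mutation and
  recombination scaled up as effective size is scaled down, keeping
  $\pi = 4N\mu \approx 6\times10^{-4}$ and sweep footprints (~100 kb) in
  realistic proportion to the window size. Split times (22 and 12
  generations, with a 0.2x elite bottleneck for 4 generations) were chosen
  so genome-wide windowed F_ST lands at the two-stage levels the method is
  designed around (~0.07 and ~0.10). Multiple chromosomes matter: with a
  single short chromosome a sweep footprint occupies a third of the genome
  and contaminates the empirical Z null.
* **Single-origin sweep injection.** A planted sweep allele enters the
  population on *one* donor haplotype (carriers are identical-by-descent
  copies), either as standing variation in the parent population just
  before the target population is founded, or directly into the target
  lineage at a stated time. Random-background injection would make every
  sweep maximally soft and footprint-free. Lost alleles trigger a bounded
  re-simulation with a shifted seed.
* **What is not modeled:** realistic chromosome counts and lengths (a 1.1-Gb
  genome), sequencing depth and genotyping error in the population panels,
  linked background selection, and SFS-calibrated demography. Passing tests
  therefore demonstrate correctness of the *statistics and calling logic*
  under the assumed generative model, not robustness to the artifacts of
  real resequencing data.

`simulate_f2()` builds the intercross directly: founders opposite-fixed at
all diagnostic markers, F1 uniformly heterozygous, F2 gametes formed with
Poisson crossovers on a Haldane map (default 5 cM across the 310-kb target
region — generous, so that enough recombinants exist to exercise breakpoint
calling). The body-weight phenotype is grand mean + additive QTL effect +
site + sex + cross-direction effects + Gaussian noise, with the additive
effect solved as $a = \sigma\sqrt{2f/(1-f)}$ so the programmed variance
fraction $f$ (0.15 by default, matching the upper range reported for
body-size traits) holds in expectation after covariate adjustment
($\mathrm{Var}(\text{dosage}) = 1/2$ in an F2). The plumage-color locus
segregates independently and is recessive: colorless iff homozygous for the
elite allele — the same locus carries the structural insertion whose
junction reads `simulate_sv_reads()` generates (total reads Poisson(depth),
each from a uniformly chosen chromosome copy, mislabeled with probability
`error_rate`; depth 17 reflects the junction-spanning physical coverage a
10x paired-end genome yields).

# Numerical and degenerate-input policy

* Genotypes are alt-allele dosages 0/1/2 with `NA` for missing; phase is
  ignored throughout (no statistic here uses it). MAF and all frequencies
  are computed over non-missing alleles only.
* Depth filters are silently skipped for sites lacking depth metadata.
* Filter thresholds at their 0/1 extremes disable the criterion, making the
  all-extreme configuration an exact identity transform.
* Sites where either population has fewer than two non-missing samples are
  undefined for F_ST and flagged, not dropped silently.
* A standardization set with zero variance is a hard error (degenerate
  input); an empty filter result or an empty CDR list is a warning.
* Indels are retained by the variant filter when both alleles are at most
  `max_indel_len + 1` characters, but are excluded from all scan
  statistics, which are SNP-based.
* All simulators consume R's RNG exclusively (including the C++ kernel), so
  a single `set.seed()`/seed argument makes every output byte-reproducible.

# Problem sizes used by the tests

The test and acceptance runs use the desk-scale defaults above: neutral
calibration pools ~700 windows from three replicate genomes; sweep recovery
uses 20 replicates of a 1.2-Mb three-chromosome genome with s = 2 from 5%
standing frequency; D-statistic behavior uses 40 no-migration and 20
migration replicates of a six-chromosome quartet design; F2 checks use
crosses of n = 1026 with 243 markers. These sizes keep every property
statistically decidable while the full suite completes in minutes.
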