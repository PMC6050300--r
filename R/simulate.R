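#' Population-simulation configuration
#'
#' Parameters of the forward Wright-Fisher simulation emulating a
#' domestication sampling design: an ancestral (wild-like) population splits
#' into a wild and an indigenous population; the elite population is founded
#' from the indigenous one through a bottleneck; optionally the indigenous
#' population later splits into two subpopulations, one of which can exchange
#' migrants with the elite population. An outgroup is emitted as a fixed
#' ancestral haplotype for polarization.
#'
#' Defaults are desk-scale: a small effective size with mutation and
#' recombination rates scaled up so that per-bp diversity (`pi ~ 4*N*mu`)
#' and sweep widths land in the ranges the scan statistics expect.
#'
#' @param n_wild,n_indigenous,n_elite,n_outgroup diploid sample sizes emitted
#'   (0 for wild skips that deme entirely).
#' @param N diploid effective size per population.
#' @param split_gens generations before present of (wild/indigenous split,
#'   elite founding); the first must be >= the second.
#' @param bottleneck_factor elite founding size as a fraction of `N`.
#' @param bottleneck_gens generations the elite population stays at the
#'   bottleneck size before recovering to `N`.
#' @param mu per-site per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate.
#' @param L simulated sequence length per chromosome (bp).
#' @param n_chrom number of independent chromosomes (`chr1`, `chr2`, ...).
#' @param burn_gens mutation-drift burn-in generations after the equilibrium
#'   (neutral site-frequency-spectrum) initialization.
#' @param init_theta per-bp scaled diversity `4*N*mu` used for the
#'   equilibrium initialization; defaults to `4 * N * mu`. Setting it
#'   explicitly with `mu = 0` gives a mutation-free population seeded with
#'   standing variation (used to study pure drift).
#' @param sweep_loci data frame with columns `chrom`, `pos`, `s`,
#'   `target_pop` (`"indigenous"` or `"elite"`) and optionally `time_gens`,
#'   or `NULL`. By default the sweep allele is injected as standing
#'   variation in the parent population just before the target population
#'   is founded; with `time_gens` it is injected directly into the target
#'   lineage that many generations before present. Injected alleles are
#'   single-origin (carriers share one donor haplotype background).
#' @param sweep_init_freq injection frequency of each sweep allele.
#' @param indigenous_split_gens generations before present at which the
#'   indigenous population splits into `indigenous1` / `indigenous2`
#'   (0 = no split; must be <= `split_gens[2]` when the elite deme exists).
#' @param migration `NULL`, or `list(pops = c(a, b), rate = m)`: from the
#'   later of the two demes' founding, each gamete of deme a (b) is drawn
#'   from deme b (a) with probability `m`.
#' @param label_swap_prob probability that a site's ref/alt labels are
#'   swapped in the emitted VCF-style output (exercises polarization).
#' @param max_retries re-simulation attempts when a sweep allele is lost.
#' @return a `pop_sim_config` list.
#' @export
pop_sim_config <- function(n_wild = 30, n_indigenous = 30, n_elite = 20,
                           n_outgroup = 4, N = 150,
                           split_gens = c(22, 12),
                           bottleneck_factor = 0.2, bottleneck_gens = 4,
                           mu = 1e-6, rec = 2e-6, L = 4e5, n_chrom = 3,
                           burn_gens = 80, sweep_loci = NULL,
                           sweep_init_freq = 0.1,
                           indigenous_split_gens = 0, migration = NULL,
                           label_swap_prob = 0.2, max_retries = 5,
                           init_theta = NULL) {
  stopifnot(N >= 2, split_gens[1] >= split_gens[2], split_gens[2] >= 0,
            bottleneck_factor > 0, bottleneck_factor <= 1,
            mu >= 0, rec >= 0, L >= 1, n_chrom >= 1,
            sweep_init_freq > 0, sweep_init_freq < 1,
            label_swap_prob >= 0, label_swap_prob <= 1)
  if (!is.null(migration))
    stopifnot(is.list(migration), length(migration$pops) == 2,
              migration$rate >= 0, migration$rate <= 0.5)
  if (!is.null(sweep_loci))
    stopifnot(all(sweep_loci$s >= 0),
              all(sweep_loci$target_pop %in% c("indigenous", "elite")))
  if (indigenous_split_gens > 0 && n_elite > 0 && split_gens[2] > 0)
    stopifnot(indigenous_split_gens <= split_gens[2])
  structure(as.list(environment()), class = "pop_sim_config")
}

# ---- internal engine ----------------------------------------------------

# Equilibrium initialization: S ~ Poisson(theta*L*a_{2N-1}) sites with
# population frequencies i/2N drawn proportional to 1/i (the neutral SFS),
# alleles assigned to haplotypes at random.
sfs_init <- function(two_n, theta_L) {
  a <- sum(1 / seq_len(two_n - 1))
  S <- stats::rpois(1, theta_L * a)
  if (S == 0) return(list(haps = matrix(0L, two_n, 0), pos = numeric(0)))
  i <- sample(seq_len(two_n - 1), S, replace = TRUE,
              prob = 1 / seq_len(two_n - 1))
  haps <- matrix(0L, two_n, S)
  for (s in seq_len(S)) haps[sample(two_n, i[s]), s] <- 1L
  pos <- sort(stats::runif(S))
  list(haps = haps[, order(pos), drop = FALSE], pos = sort(pos))
}

# One generation for one deme, with optional selection and migration.
# demes: named list of 2N x S matrices; pos on [0,1]; returns new matrix.
step_deme <- function(demes, name, n_off, pos, rec_L, s_coef = 0,
                      sweep_col = NA, mig_from = NULL, mig_rate = 0) {
  haps <- demes[[name]]
  n_par <- nrow(haps) / 2L
  w <- rep(1, n_par)
  if (s_coef > 0 && !is.na(sweep_col)) {
    dos <- haps[seq(1, 2 * n_par, 2), sweep_col] +
      haps[seq(2, 2 * n_par, 2), sweep_col]
    w <- 1 + 0.5 * s_coef * dos
  }
  n_gam <- 2L * n_off
  parents <- sample.int(n_par, n_gam, replace = TRUE, prob = w)
  gam <- wf_gametes(haps, pos, parents, rec_L, 1.0)
  if (!is.null(mig_from) && mig_rate > 0) {
    mig <- which(stats::runif(n_gam) < mig_rate)
    if (length(mig)) {
      src <- demes[[mig_from]]
      n_src <- nrow(src) / 2L
      mpar <- sample.int(n_src, length(mig), replace = TRUE)
      gam[mig, ] <- wf_gametes(src, pos, mpar, rec_L, 1.0)
    }
  }
  gam
}

# Add new mutations across all demes for one generation; returns updated
# state. Positions are uniform on [0,1] (infinite sites; collisions with
# existing positions are re-drawn).
add_mutations <- function(state, mu_L) {
  new_per_deme <- vapply(state$demes, function(h)
    stats::rpois(1, nrow(h) * mu_L), numeric(1))
  total <- sum(new_per_deme)
  if (total == 0) return(state)
  repeat {
    newpos <- stats::runif(total)
    if (!any(newpos %in% state$pos) && !anyDuplicated(newpos)) break
  }
  for (d in names(state$demes)) {
    nh <- nrow(state$demes[[d]])
    block <- matrix(0L, nh, total)
    k <- which(names(state$demes) == d)
    off <- c(0, cumsum(new_per_deme))[k]
    n_d <- new_per_deme[k]
    if (n_d > 0)
      block[cbind(sample.int(nh, n_d, replace = TRUE),
                  off + seq_len(n_d))] <- 1L
    state$demes[[d]] <- cbind(state$demes[[d]], block)
  }
  state$pos <- c(state$pos, newpos)
  o <- order(state$pos)
  state$pos <- state$pos[o]
  for (d in names(state$demes))
    state$demes[[d]] <- state$demes[[d]][, o, drop = FALSE]
  state
}

# Drop sites lost from every deme (kept if fixed anywhere: the outgroup is
# all-ancestral, so globally fixed derived sites remain informative).
prune_lost <- function(state, keep_cols = integer(0)) {
  tot <- Reduce(`+`, lapply(state$demes, colSums))
  keep <- tot > 0L
  keep[keep_cols] <- TRUE
  if (all(keep)) return(state)
  state$pos <- state$pos[keep]
  for (d in names(state$demes))
    state$demes[[d]] <- state$demes[[d]][, keep, drop = FALSE]
  state
}

# Inject a derived allele as a single-origin variant: carriers are copies of
# one donor haplotype (identical-by-descent flanking background), so strong
# selection on the allele produces a hard-sweep diversity trough.
inject_allele <- function(state, deme, rel_pos, freq) {
  nh <- nrow(state$demes[[deme]])
  n_carrier <- max(1L, round(freq * nh))
  p <- rel_pos
  while (p %in% state$pos) p <- p + 1e-9
  donor <- sample.int(nh, 1)
  carriers <- c(donor, sample(setdiff(seq_len(nh), donor),
                              n_carrier - 1L))
  state$demes[[deme]][carriers, ] <-
    matrix(state$demes[[deme]][donor, ], n_carrier, ncol(state$demes[[deme]]),
           byrow = TRUE)
  for (d in names(state$demes)) {
    col <- matrix(0L, nrow(state$demes[[d]]), 1)
    if (d == deme) col[carriers, 1] <- 1L
    state$demes[[d]] <- cbind(state$demes[[d]], col)
  }
  state$pos <- c(state$pos, p)
  o <- order(state$pos)
  state$pos <- state$pos[o]
  for (d in names(state$demes))
    state$demes[[d]] <- state$demes[[d]][, o, drop = FALSE]
  state
}

# Simulate one chromosome; returns haplotypes of sampled individuals per
# population plus site positions and sweep outcome.
sim_one_chrom <- function(cfg, chrom_name) {
  mu_L <- cfg$mu * cfg$L
  rec_L <- cfg$rec * cfg$L          # expected crossovers per meiosis
  two_n <- 2L * cfg$N
  theta_L <- if (is.null(cfg$init_theta)) 2 * two_n * cfg$mu * cfg$L else
    cfg$init_theta * cfg$L
  init <- sfs_init(two_n, theta_L)
  state <- list(demes = list(ancestral = init$haps), pos = init$pos)
  sweeps <- if (is.null(cfg$sweep_loci)) NULL else
    cfg$sweep_loci[cfg$sweep_loci$chrom == chrom_name, , drop = FALSE]
  sweep_cols <- rep(NA_integer_, if (is.null(sweeps)) 0 else nrow(sweeps))

  n_bott <- max(2L, round(cfg$bottleneck_factor * cfg$N))
  has_wild <- cfg$n_wild > 0
  g1 <- cfg$split_gens[1]; g2 <- cfg$split_gens[2]
  g3 <- cfg$indigenous_split_gens
  has_elite <- cfg$n_elite > 0 && g2 > 0
  mig <- cfg$migration

  run_gen <- function(state, active, sizes) {
    # selection bookkeeping: locate sweep columns by position each call
    new <- list()
    for (d in active) {
      s_coef <- 0; sweep_col <- NA_integer_
      if (!is.null(sweeps) && nrow(sweeps)) {
        for (k in seq_len(nrow(sweeps))) {
          tgt <- sweeps$target_pop[k]
          tgt_demes <- if (tgt == "indigenous")
            c("indigenous", "indigenous1", "indigenous2") else tgt
          if (d %in% tgt_demes) {
            col <- match(sweeps$rel_pos[k], state$pos)
            if (!is.na(col)) { s_coef <- sweeps$s[k]; sweep_col <- col }
          }
        }
      }
      mf <- NULL; mr <- 0
      if (!is.null(mig) && d %in% mig$pops) {
        other <- setdiff(mig$pops, d)
        if (other %in% names(state$demes)) { mf <- other; mr <- mig$rate }
      }
      new[[d]] <- step_deme(state$demes, d, sizes[[d]], state$pos, rec_L,
                            s_coef, sweep_col, mf, mr)
    }
    state$demes[names(new)] <- new
    state <- add_mutations(state, mu_L)
    prune_lost(state)
  }

  # burn-in of the ancestral population
  for (g in seq_len(cfg$burn_gens))
    state <- run_gen(state, "ancestral", list(ancestral = cfg$N))

  # Injection schedule. Default (time_gens absent/NA): an allele targeted at
  # the indigenous lineage enters the ancestral pool just before the
  # wild/indigenous split, so the wild population carries it as standing
  # variation; an elite-targeted allele enters the indigenous population just
  # before the elite founding. An explicit time_gens injects directly into
  # the target lineage that many generations before present.
  if (!is.null(sweeps) && nrow(sweeps)) {
    sweeps$rel_pos <- sweeps$pos / cfg$L
    if (is.null(sweeps$time_gens)) sweeps$time_gens <- NA_real_
    for (k in which(sweeps$target_pop == "indigenous" &
                    is.na(sweeps$time_gens)))
      state <- inject_allele(state, "ancestral", sweeps$rel_pos[k],
                             cfg$sweep_init_freq)
  }

  # split: ancestral -> wild + indigenous (wild optional)
  if (has_wild) {
    par_w <- sample.int(cfg$N, 2L * cfg$N, replace = TRUE)
    wild0 <- wf_gametes(state$demes$ancestral, state$pos, par_w, rec_L, 1.0)
    par_i <- sample.int(cfg$N, 2L * cfg$N, replace = TRUE)
    ind0 <- wf_gametes(state$demes$ancestral, state$pos, par_i, rec_L, 1.0)
    state$demes <- list(wild = wild0, indigenous = ind0)
  } else {
    names(state$demes) <- "indigenous"
  }

  for (g in (if (g1 >= 1) g1:1 else integer(0))) {
    if (has_elite && g == g2) {
      # elite founded from indigenous through a bottleneck, with any
      # elite-targeted sweep allele injected into indigenous just before
      if (!is.null(sweeps) && nrow(sweeps))
        for (k in which(sweeps$target_pop == "elite" &
                        is.na(sweeps$time_gens)))
          state <- inject_allele(state, "indigenous", sweeps$rel_pos[k],
                                 cfg$sweep_init_freq)
      par_e <- sample.int(cfg$N, 2L * n_bott, replace = TRUE)
      state$demes$elite <- wf_gametes(state$demes$indigenous, state$pos,
                                      par_e, rec_L, 1.0)
    }
    if (g3 > 0 && g == g3 && "indigenous" %in% names(state$demes)) {
      ind <- state$demes$indigenous
      par1 <- sample.int(cfg$N, 2L * cfg$N, replace = TRUE)
      par2 <- sample.int(cfg$N, 2L * cfg$N, replace = TRUE)
      state$demes$indigenous1 <- wf_gametes(ind, state$pos, par1, rec_L, 1.0)
      state$demes$indigenous2 <- wf_gametes(ind, state$pos, par2, rec_L, 1.0)
      state$demes$indigenous <- NULL
    }
    if (!is.null(sweeps) && nrow(sweeps))
      for (k in which(!is.na(sweeps$time_gens) & sweeps$time_gens == g)) {
        tgt <- sweeps$target_pop[k]
        d <- if (tgt %in% names(state$demes)) tgt else
          intersect(c(paste0(tgt, 1:2), "indigenous"),
                    names(state$demes))[1]
        state <- inject_allele(state, d, sweeps$rel_pos[k],
                               cfg$sweep_init_freq)
      }
    active <- names(state$demes)
    sizes <- list(wild = cfg$N, indigenous = cfg$N, indigenous1 = cfg$N,
                  indigenous2 = cfg$N,
                  elite = if (has_elite && g > g2 - cfg$bottleneck_gens &&
                              g <= g2) n_bott else cfg$N)
    state <- run_gen(state, active, sizes)
  }

  # sweep outcome in target demes
  sweep_status <- NULL
  if (!is.null(sweeps) && nrow(sweeps)) {
    sweep_status <- sweeps
    sweep_status$final_freq <- NA_real_
    for (k in seq_len(nrow(sweeps))) {
      tgt <- sweeps$target_pop[k]
      d <- if (tgt %in% names(state$demes)) tgt else
        intersect(paste0(tgt, 1:2), names(state$demes))[1]
      col <- match(sweeps$rel_pos[k], state$pos)
      sweep_status$final_freq[k] <- if (is.na(col)) 0 else
        mean(state$demes[[d]][, col])
    }
  }
  list(state = state, sweep_status = sweep_status)
}

#' Simulate structured populations under a domestication design
#'
#' Forward Wright-Fisher diploid simulation with recombination, infinite-sites
#' mutation, selection at planted sweep loci, an elite founding bottleneck and
#' optional migration (see [pop_sim_config()]). Sampled genotypes are emitted
#' as a [genotype_matrix()] plus population map; the outgroup is emitted as
#' fixed homozygous-ancestral individuals. When a sweep allele is lost in its
#' target population the whole replicate is re-run (up to
#' `cfg$max_retries`).
#'
#' @param cfg a [pop_sim_config()].
#' @param seed integer RNG seed (also consumed by retries).
#' @return list: `gm`, `popmap`, `truth` (parameters, per-sweep final
#'   derived-allele frequencies, per-site `ancestral_is_ref` flags, seed and
#'   retry count).
#' @export
simulate_populations <- function(cfg = pop_sim_config(), seed = 1) {
  for (attempt in 0:cfg$max_retries) {
    set.seed(seed + 7919L * attempt)
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    runs <- lapply(chroms, function(ch) sim_one_chrom(cfg, ch))
    names(runs) <- chroms
    status <- do.call(rbind, lapply(runs, `[[`, "sweep_status"))
    if (is.null(status) || all(status$final_freq > 0)) break
    if (attempt == cfg$max_retries)
      warning("sweep allele lost after ", cfg$max_retries,
              " retries; replicate reported as failed")
  }

  sample_sizes <- c(wild = cfg$n_wild, indigenous = cfg$n_indigenous,
                    elite = cfg$n_elite)
  out_chrom <- character(0); out_pos <- integer(0)
  ref <- alt <- character(0); geno_list <- list()
  anc_is_ref <- logical(0)
  nucs <- c("A", "C", "G", "T")
  popmap <- character(0)

  for (ch in names(runs)) {
    state <- runs[[ch]]$state
    demes <- state$demes
    split_ind <- "indigenous1" %in% names(demes)
    # genotype columns per population sample
    geno_cols <- list(); ids <- character(0); pops <- character(0)
    take <- function(deme, n_samp, label) {
      h <- demes[[deme]]
      n_ind <- nrow(h) / 2L
      pick <- sample.int(n_ind, min(n_samp, n_ind))
      g <- h[2 * pick - 1, , drop = FALSE] + h[2 * pick, , drop = FALSE]
      list(g = t(g), ids = paste0(label, "_", seq_along(pick)),
           pop = rep(label, length(pick)))
    }
    parts <- list()
    if (cfg$n_wild > 0) parts$wild <- take("wild", cfg$n_wild, "wild")
    if (split_ind) {
      n1 <- ceiling(cfg$n_indigenous / 2); n2 <- cfg$n_indigenous - n1
      parts$ind1 <- take("indigenous1", n1, "indigenous1")
      parts$ind2 <- take("indigenous2", n2, "indigenous2")
    } else if (cfg$n_indigenous > 0) {
      parts$ind <- take("indigenous", cfg$n_indigenous, "indigenous")
    }
    if ("elite" %in% names(demes) && cfg$n_elite > 0)
      parts$elite <- take("elite", cfg$n_elite, "elite")
    g <- do.call(cbind, lapply(parts, `[[`, "g"))
    ids <- unlist(lapply(parts, `[[`, "ids"), use.names = FALSE)
    pops <- unlist(lapply(parts, `[[`, "pop"), use.names = FALSE)
    # outgroup: fixed ancestral homozygotes
    if (cfg$n_outgroup > 0) {
      g <- cbind(g, matrix(0L, nrow(g), cfg$n_outgroup))
      ids <- c(ids, paste0("outgroup_", seq_len(cfg$n_outgroup)))
      pops <- c(pops, rep("outgroup", cfg$n_outgroup))
    }
    popmap <- c(popmap, stats::setNames(pops, ids))
    # keep sites segregating among the emitted samples
    seg <- rowSums(g) > 0L
    g <- g[seg, , drop = FALSE]
    pos_bp <- pmax(1L, as.integer(round(state$pos[seg] * cfg$L)))
    # resolve coincident integer positions, preserving site order
    if (length(pos_bp) > 1L)
      for (k in 2:length(pos_bp))
        if (pos_bp[k] <= pos_bp[k - 1L]) pos_bp[k] <- pos_bp[k - 1L] + 1L
    n_s <- length(pos_bp)
    ref_ch <- sample(nucs, n_s, replace = TRUE)
    alt_ch <- vapply(ref_ch, function(r) sample(setdiff(nucs, r), 1),
                     character(1))
    swap <- stats::runif(n_s) < cfg$label_swap_prob
    g[swap, ] <- 2L - g[swap, ]
    tmp <- ref_ch[swap]; ref_ch[swap] <- alt_ch[swap]; alt_ch[swap] <- tmp
    out_chrom <- c(out_chrom, rep(ch, n_s))
    out_pos <- c(out_pos, pos_bp)
    ref <- c(ref, ref_ch); alt <- c(alt, alt_ch)
    anc_is_ref <- c(anc_is_ref, !swap)
    geno_list[[ch]] <- g
  }
  # identical sample ids across chromosomes; popmap recorded once
  ids <- names(popmap)[seq_len(ncol(geno_list[[1]]))]
  popmap <- popmap[seq_len(ncol(geno_list[[1]]))]
  gm <- genotype_matrix(out_chrom, out_pos, ref, alt,
                        do.call(rbind, geno_list), ids)
  truth <- list(config = cfg, seed = seed,
                retries = attempt,
                sweeps = if (is.null(status)) NULL else
                  status[, c("chrom", "pos", "s", "target_pop",
                             "final_freq")],
                ancestral_is_ref = anc_is_ref)
  list(gm = gm, popmap = popmap, truth = truth)
}

#' F2 intercross simulation configuration
#'
#' @param n_f2 number of F2 individuals.
#' @param n_markers diagnostic marker count across the target region.
#' @param region_length_bp physical length of the fine-mapped region.
#' @param map_length_cM genetic length of the region (Haldane map, no
#'   interference).
#' @param qtl list with `rel_pos` (0-1 within the region) and
#'   `variance_fraction` (fraction of adjusted phenotypic variance explained
#'   by the additive QTL, in expectation).
#' @param grand_mean,residual_sd body-weight grand mean and residual SD (g).
#' @param site_effects,sex_effects,cross_effects additive covariate effects
#'   (g); lengths give the level counts.
#' @param expression_base,expression_slope,expression_sd target-gene
#'   expression model: `base + slope * dosage + N(0, sd)`.
#' @param color_rel_pos relative position of the recessive plumage-color
#'   locus (on its own chromosome, segregating independently); individuals
#'   homozygous for the elite allele are colorless.
#' @param geno_error_rate per-marker genotyping error rate (a called
#'   genotype is replaced by one of the other two codes).
#' @param missing_rate per-marker missing-call rate.
#' @param sv_depth mean junction-spanning read depth for the structural
#'   variant read-count table.
#' @param sv_error_rate read mislabeling probability.
#' @return an `f2_sim_config` list.
#' @export
f2_sim_config <- function(n_f2 = 1026, n_markers = 243,
                          region_length_bp = 310000, map_length_cM = 5,
                          qtl = list(rel_pos = 0.35,
                                     variance_fraction = 0.15),
                          grand_mean = 2200, residual_sd = 250,
                          site_effects = c(-120, 0, 120),
                          sex_effects = c(-150, 150),
                          cross_effects = c(-30, 30),
                          expression_base = 1, expression_slope = 1.5,
                          expression_sd = 0.4,
                          color_rel_pos = 0.5,
                          geno_error_rate = 0.01, missing_rate = 0.02,
                          sv_depth = 17, sv_error_rate = 0.01) {
  stopifnot(n_f2 >= 10, n_markers >= 2,
            qtl$variance_fraction >= 0, qtl$variance_fraction < 1,
            map_length_cM >= 0, sv_depth > 0)
  structure(as.list(environment()), class = "f2_sim_config")
}

#' Simulate a wild x elite F2 intercross
#'
#' Founders are opposite-fixed at every diagnostic marker (wild allele coded
#' 0, elite allele coded 2). F1 individuals are uniformly heterozygous; F2
#' gametes are formed with Poisson crossovers on the cM map (Haldane, no
#' interference). The body-weight phenotype is
#' `grand mean + a * dosage + site + sex + cross + N(0, residual_sd)`, with
#' the additive effect `a` solved so the programmed QTL variance fraction
#' holds in expectation after covariate adjustment
#' (`a = residual_sd * sqrt(2 f / (1 - f))`, since `Var(dosage) = 1/2` in an
#' F2). Plumage color segregates at an independent recessive locus: colorless
#' iff homozygous for the elite allele, the locus that also carries the
#' structural insertion genotyped by [genotype_sv()].
#'
#' @param cfg an [f2_sim_config()].
#' @param seed integer RNG seed.
#' @return list: `gm` (F2 genotypes at the markers, elite allele = alt),
#'   `markers` (data frame usable by [classify_haplotypes()]), `phenotypes`
#'   (data frame: `id`, `body_weight_g`, `igf2bp1_expression`, `site`,
#'   `sex`, `cross_direction`, `color`), `sv_counts` (junction read-support
#'   table), `truth` (per-individual crossover positions in marker-interval
#'   units, true QTL dosages, true SV genotypes, the QTL effect size and
#'   marker index).
#' @export
simulate_f2 <- function(cfg = f2_sim_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_f2; m <- cfg$n_markers
  marker_rel <- sort(stats::runif(m))
  marker_bp <- as.integer(round(marker_rel * cfg$region_length_bp))
  marker_bp <- marker_bp + seq_len(m)     # keep strictly increasing
  marker_cm <- marker_rel * cfg$map_length_cM

  # each F2 gamete is a crossover mosaic of the two founder haplotypes
  # (0 = wild, 1 = elite); all F1 parents are identical heterozygotes
  founder <- rbind(rep(0L, m), rep(1L, m))
  gam <- wf_gametes(founder, marker_cm, rep(1L, 2L * n), 0.01,
                    cfg$map_length_cM)
  g1 <- gam[seq(1, 2 * n, 2), , drop = FALSE]
  g2 <- gam[seq(2, 2 * n, 2), , drop = FALSE]
  dos <- g1 + g2                           # true elite dosage per marker
  true_bp <- lapply(seq_len(n), function(i) {
    b1 <- which(diff(g1[i, ]) != 0L)
    b2 <- which(diff(g2[i, ]) != 0L)
    sort(c(b1, b2))                        # marker index after which a
  })                                       # crossover occurred
  # observed genotypes: genotyping error + missingness
  obs <- dos
  err <- matrix(stats::runif(n * m) < cfg$geno_error_rate, n, m)
  if (any(err)) {
    wrong <- (obs[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
    obs[err] <- wrong
  }
  obs[matrix(stats::runif(n * m) < cfg$missing_rate, n, m)] <- NA_integer_

  qtl_marker <- which.min(abs(marker_rel - cfg$qtl$rel_pos))
  qtl_dos <- dos[, qtl_marker]
  f <- cfg$qtl$variance_fraction
  a <- cfg$residual_sd * sqrt(2 * f / (1 - f))
  site <- sample(seq_along(cfg$site_effects), n, replace = TRUE)
  sex <- sample(seq_along(cfg$sex_effects), n, replace = TRUE)
  crx <- sample(seq_along(cfg$cross_effects), n, replace = TRUE)
  bw <- cfg$grand_mean + a * qtl_dos + cfg$site_effects[site] +
    cfg$sex_effects[sex] + cfg$cross_effects[crx] +
    stats::rnorm(n, 0, cfg$residual_sd)
  expr <- cfg$expression_base + cfg$expression_slope * qtl_dos +
    stats::rnorm(n, 0, cfg$expression_sd)

  # independent recessive color / insertion locus: one Mendelian locus
  color_dos <- stats::rbinom(n, 2, 0.5)
  color <- ifelse(color_dos == 2L, "colorless", "colored")
  sv_geno <- c("NN", "IN", "II")[color_dos + 1L]
  sv_counts <- simulate_sv_reads(sv_geno, cfg$sv_depth, cfg$sv_error_rate)

  ids <- sprintf("F2_%04d", seq_len(n))
  rownames(obs) <- ids
  gm <- genotype_matrix(rep("chr28", m), marker_bp,
                        rep("A", m), rep("G", m), t(obs), ids)
  markers <- data.frame(chrom = "chr28", pos = marker_bp,
                        delta_af = 1, elite_allele = "alt",
                        stringsAsFactors = FALSE)
  phenotypes <- data.frame(id = ids, body_weight_g = bw,
                           igf2bp1_expression = expr,
                           site = factor(paste0("site", site)),
                           sex = factor(c("F", "M")[sex]),
                           cross_direction =
                             factor(c("forward", "backward")[crx]),
                           color = color, stringsAsFactors = FALSE)
  truth <- list(crossovers = true_bp, qtl_dosage = qtl_dos,
                qtl_marker = qtl_marker, qtl_effect = a,
                sv_genotype = sv_geno, color_dosage = color_dos,
                config = cfg, seed = seed)
  list(gm = gm, markers = markers, phenotypes = phenotypes,
       sv_counts = sv_counts, truth = truth)
}

#' Simulate junction read-support counts for a structural variant
#'
#' Per individual, the total junction-spanning read count is Poisson(depth);
#' each read originates from a uniformly chosen chromosome copy and supports
#' that copy's junction, but is mislabeled (recorded as the other junction)
#' with probability `error_rate`.
#'
#' @param true_genotypes character vector of `"NN"`, `"IN"`, `"II"`.
#' @param depth mean read depth.
#' @param error_rate mislabeling probability per read.
#' @return data frame: `id`, `ref_support`, `ins_support`.
#' @export
simulate_sv_reads <- function(true_genotypes, depth = 17,
                              error_rate = 0.01) {
  stopifnot(depth > 0, all(true_genotypes %in% c("NN", "IN", "II")))
  n <- length(true_genotypes)
  total <- stats::rpois(n, depth)
  p_ins <- c(NN = 0, IN = 0.5, II = 1)[true_genotypes]
  from_ins <- stats::rbinom(n, total, p_ins)
  from_ref <- total - from_ins
  flip_ins <- stats::rbinom(n, from_ins, error_rate)
  flip_ref <- stats::rbinom(n, from_ref, error_rate)
  data.frame(id = if (!is.null(names(true_genotypes)))
               names(true_genotypes) else sprintf("ind_%04d", seq_len(n)),
             ref_support = from_ref - flip_ref + flip_ins,
             ins_support = from_ins - flip_ins + flip_ref,
             stringsAsFactors = FALSE)
}
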