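# shared fixture builders (all data generated in code)

# small panel from an explicit call matrix; loci laid out on one or more
# chromosomes at the given positions
toy_panel <- function(calls, positions = seq_len(ncol(calls)),
                      chromosome = rep("1A", ncol(calls)),
                      genome = substr(chromosome, 2, 2),
                      population = rep("P1", nrow(calls)),
                      growth_habit = rep("spring", nrow(calls))) {
  calls <- as.matrix(calls)
  genotype_panel(
    calls,
    lines = data.frame(line_id = sprintf("l%02d", seq_len(nrow(calls))),
                       population = population, growth_habit = growth_habit,
                       stringsAsFactors = FALSE),
    loci = data.frame(locus_id = sprintf("s%03d", seq_len(ncol(calls))),
                      genome = genome, chromosome = chromosome,
                      position_cM = positions, stringsAsFactors = FALSE))
}

# iid random panel (no structure) for counting/permutation oracles
random_panel <- function(seed, n_lines = 20, n_loci = 30, n_pops = 2,
                         miss = 0.05, het = 0.05) {
  set.seed(seed)
  p <- runif(n_loci, 0.1, 0.9)
  calls <- matrix(0L, n_lines, n_loci)
  for (j in seq_len(n_loci)) calls[, j] <- 2L * rbinom(n_lines, 1, p[j])
  u <- matrix(runif(n_lines * n_loci), n_lines)
  calls[u < het] <- 1L
  calls[u >= het & u < het + miss] <- NA_integer_
  pops <- rep_len(sprintf("P%d", seq_len(n_pops)), n_lines)
  toy_panel(calls,
            positions = sort(runif(n_loci, 0, 100)),
            chromosome = rep(c("1A", "2A"), length.out = n_loci),
            population = pops,
            growth_habit = ifelse(pops %in% sprintf("P%d",
                                                    seq_len(ceiling(n_pops / 2))),
                                  "spring", "winter"))
}

# compact simulation config used across tests
test_sim_config <- function(seed, n_pops_per_group = c(4, 4),
                            lines_per_pop = 30, n_chr = 6, loci_per_chr = 40,
                            fst_target = 0.10, n_founders = 10,
                            generations = 5, planted_regions = NULL, ...) {
  sim_config(
    populations_per_group = n_pops_per_group,
    lines_per_population = lapply(n_pops_per_group, function(k)
      rep(lines_per_pop, k)),
    chromosomes = default_chromosomes()[seq_len(n_chr), , drop = FALSE],
    loci_per_chromosome = loci_per_chr,
    fst_target = fst_target, n_founders = n_founders,
    generations = generations, planted_regions = planted_regions,
    seed = seed, ...)
}

# single-population panel with map-dependent LD, for decay properties
single_pop_panel <- function(seed, n_lines = 60, n_loci = 150,
                             length_cM = 100, n_founders = 10,
                             generations = 5) {
  cfg <- sim_config(
    n_groups = 2, group_labels = c("spring", "winter"),
    populations_per_group = c(1, 1),
    lines_per_population = list(n_lines, 5),
    chromosomes = data.frame(chromosome = c("1A", "2A"), genome = "A",
                             length_cM = length_cM),
    loci_per_chromosome = c(`1A` = n_loci, `2A` = 5),
    n_founders = n_founders, generations = generations,
    het_rate = 0, missing_rate = 0, ascertain_maf_min = 0.05, seed = seed)
  sim <- simulate_panel(cfg)
  subset_panel(sim$panel,
               lines = which(sim$panel$lines$growth_habit == "spring"),
               loci = which(sim$panel$loci$chromosome == "1A"))
}

# mean pairwise r^2 (het->missing, pairwise-complete) between loci whose
# map distance falls in [lo, hi); independent of the ld module
mean_r2_in_band <- function(panel, lo, hi) {
  m <- panel$calls
  m[!is.na(m) & m == 1L] <- NA_integer_
  x <- m / 2
  cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  d <- abs(outer(panel$loci$position_cM, panel$loci$position_cM, "-"))
  same <- outer(panel$loci$chromosome, panel$loci$chromosome, "==")
  sel <- upper.tri(d) & same & d >= lo & d < hi
  mean(cc[sel]^2, na.rm = TRUE)
}

# independent two-sided Fisher exact probability by direct enumeration of
# all tables with the observed margins (choose()-based, not dhyper)
enum_exact_p <- function(counts) {
  n11 <- counts[1]; n12 <- counts[2]; n21 <- counts[3]; n22 <- counts[4]
  m <- n11 + n12; n <- n21 + n22; k <- n11 + n21; N <- m + n
  if (k == 0 || k == N || m == 0 || n == 0) return(1)
  kk <- max(0, k - n):min(k, m)
  pr <- choose(m, kk) * choose(n, k - kk) / choose(N, k)
  p_obs <- choose(m, n11) * choose(n, k - n11) / choose(N, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# reference BH step-up: largest k with p_(k) <= k q / m rejects p_(1..k)
stepup_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# haploid Weir-Cockerham theta for one locus via stats::aov on the 0/1
# allele indicators (independent route: ANOVA sums of squares)
aov_theta <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  n_i <- tabulate(g)
  r <- nlevels(g)
  N <- length(x)
  fit <- suppressWarnings(stats::anova(stats::aov(x ~ g)))
  msp <- fit["g", "Mean Sq"]
  msg <- fit["Residuals", "Mean Sq"]
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  (msp - msg) / (msp + (n_c - 1) * msg)
}
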