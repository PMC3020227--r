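#' Simulation configuration for a structured inbred-line panel
#'
#' Defaults emulate a spring/winter wheat cultivar panel: 17 breeding
#' populations nested in 2 growth-habit groups, 478 lines, 21 chromosomes in
#' 3 genomes (A/B/D), ~849 MAF-ascertained biallelic SNPs, 0.5% residual
#' heterozygosity and 0.9% missing calls, among-population differentiation
#' at a target F_ST of 0.10, distance-dependent LD from a founder-mosaic
#' model on a cM map, and a few planted high-differentiation regions between
#' the two growth-habit groups.
#'
#' @param n_groups number of growth-habit groups
#' @param group_labels labels for the groups
#' @param populations_per_group integer vector, populations in each group
#' @param lines_per_population list (one vector per group) of population
#'   sizes; defaults reproduce the panel's 237 winter + 241 spring split
#' @param chromosomes data.frame `chromosome`, `genome`, `length_cM`
#' @param loci_per_chromosome named integer vector (names = chromosome) or a
#'   single count per chromosome
#' @param fst_target target F_ST among populations, in (0, 1)
#' @param n_founders founder haplotypes per population (controls LD level)
#' @param generations recombination generations compounding the mosaic
#' @param planted_regions data.frame `chromosome`, `start_cM`, `end_cM`,
#'   `delta` — allele-frequency shift `+delta` in group 1, `-delta` in
#'   group 2, clipped to `[0.02, 0.98]`
#' @param het_rate,missing_rate per-call rates of heterozygous / missing
#'   noise
#' @param ascertain_maf_min pooled-panel MAF ascertainment threshold
#'   (strict `>`), applied after noise
#' @param seed integer seed (mandatory); stage sub-streams are derived from
#'   it deterministically
#' @return a `sim_config` list
#' @export
sim_config <- function(n_groups = 2,
                       group_labels = c("spring", "winter"),
                       populations_per_group = c(8, 9),
                       lines_per_population = list(
                         c(30, 40, 30, 40, 30, 10, 30, 31),
                         c(21, 49, 40, 11, 30, 38, 34, 4, 10)),
                       chromosomes = default_chromosomes(),
                       loci_per_chromosome = default_loci_per_chromosome(),
                       fst_target = 0.10,
                       n_founders = 10,
                       generations = 5,
                       planted_regions = NULL,
                       het_rate = 0.005,
                       missing_rate = 0.009,
                       ascertain_maf_min = 0.05,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_groups >= 1, length(group_labels) == n_groups,
            length(populations_per_group) == n_groups,
            length(lines_per_population) == n_groups,
            fst_target > 0, fst_target < 1,
            het_rate >= 0, het_rate <= 1, missing_rate >= 0,
    missing_rate <= 1, het_rate + missing_rate <= 1,
            all(chromosomes$length_cM > 0), n_founders >= 1, generations >= 0)
  for (g in seq_len(n_groups))
    stopifnot(length(lines_per_population[[g]]) == populations_per_group[g])
  if (length(loci_per_chromosome) == 1)
    loci_per_chromosome <- stats::setNames(
      rep(loci_per_chromosome, nrow(chromosomes)), chromosomes$chromosome)
  stopifnot(all(chromosomes$chromosome %in% names(loci_per_chromosome)))
  if (!is.null(planted_regions)) {
    planted_regions <- as.data.frame(planted_regions, stringsAsFactors = FALSE)
    bad <- !(planted_regions$chromosome %in% chromosomes$chromosome)
    if (any(bad))
      stop("planted region on unknown chromosome: ",
           paste(planted_regions$chromosome[bad], collapse = ", "))
    len <- chromosomes$length_cM[match(planted_regions$chromosome,
                                       chromosomes$chromosome)]
    if (any(planted_regions$start_cM < 0 | planted_regions$end_cM > len))
      stop("planted region outside its chromosome")
    stopifnot(all(planted_regions$delta > 0), all(planted_regions$delta < 1))
  }
  structure(list(
    n_groups = n_groups, group_labels = group_labels,
    populations_per_group = populations_per_group,
    lines_per_population = lines_per_population,
    chromosomes = as.data.frame(chromosomes, stringsAsFactors = FALSE),
    loci_per_chromosome = loci_per_chromosome,
    fst_target = fst_target, n_founders = n_founders,
    generations = generations, planted_regions = planted_regions,
    het_rate = het_rate, missing_rate = missing_rate,
    ascertain_maf_min = ascertain_maf_min, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default 21-chromosome wheat-like map (7 chromosomes per genome, 150 cM)
#' @return data.frame `chromosome`, `genome`, `length_cM`
#' @export
default_chromosomes <- function() {
  data.frame(
    chromosome = paste0(rep(1:7, 3), rep(c("A", "B", "D"), each = 7)),
    genome = rep(c("A", "B", "D"), each = 7),
    length_cM = 150,
    stringsAsFactors = FALSE)
}

#' Default per-chromosome locus counts (~849 loci, D-genome sparser)
#' @return named integer vector
#' @export
default_loci_per_chromosome <- function() {
  chr <- default_chromosomes()$chromosome
  # 368 A / 374 B / 107 D polymorphic loci, spread over 7 chromosomes each
  n <- c(rep_len(c(53, 53, 52, 53, 52, 53, 52), 7),
         rep_len(c(54, 53, 54, 53, 53, 54, 53), 7),
         rep_len(c(16, 15, 15, 16, 15, 15, 15), 7))
  stats::setNames(n, chr)
}

# deterministic per-stage sub-seed, kept below 2^31
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483587)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one frequency per population from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, whose mean is the ancestral
#' frequency `p` and whose variance is `F p (1 - p)` — i.e. the
#' among-population variance matching a target F_ST of `F`.
#'
#' @param p ancestral allele frequency; vector allowed (one locus per entry)
#' @param fst_target F in (0, 1)
#' @param n_pops number of populations
#' @return matrix `n_pops` x `length(p)` of population frequencies;
#'   degenerate loci (`p` 0 or 1) are passed through unchanged.
#' @export
draw_population_frequencies <- function(p, fst_target, n_pops) {
  stopifnot(fst_target > 0, fst_target < 1, all(p >= 0), all(p <= 1))
  out <- matrix(rep(p, each = n_pops), nrow = n_pops)
  ok <- p > 0 & p < 1
  if (any(ok)) {
    a <- p[ok] * (1 - fst_target) / fst_target
    b <- (1 - p[ok]) * (1 - fst_target) / fst_target
    out[, ok] <- matrix(
      stats::rbeta(n_pops * sum(ok), rep(a, each = n_pops),
                   rep(b, each = n_pops)),
      nrow = n_pops)
  }
  out
}

haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate a structured inbred-line SNP panel with known truth
#'
#' Generating model, per locus: ancestral frequency `p ~ Uniform(0.05,
#' 0.95)`; population frequencies by the Balding-Nichols draw at the target
#' F_ST; in planted regions the frequency is shifted `+delta` for group-1
#' populations and `-delta` for group-2 populations (clipped to
#' `[0.02, 0.98]`). Per population, `n_founders` haplotypes are drawn by
#' Bernoulli sampling at the population frequencies; each inbred line is a
#' founder mosaic walked in cM order, switching to a random founder between
#' adjacent loci with probability `1 - (1 - r)^generations` where `r` is the
#' Haldane recombination fraction of the gap. A line's genotype is the
#' homozygote of its haplotype; calls are then flipped to heterozygous or
#' missing at the configured rates, and loci failing the pooled-panel MAF
#' ascertainment are dropped. Truth (frequencies, planted flags, realized
#' F_ST of the generating frequencies) is recorded before noise and
#' ascertainment.
#'
#' @param config a [sim_config()]
#' @return list with elements `panel` (a `genotype_panel`) and `truth` (a
#'   `sim_truth` data.frame plus the config); `truth$kept` flags loci
#'   surviving ascertainment.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$chromosomes

  # --- map (stage 1)
  set.seed(sub_seed(config$seed, 1L))
  loci <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
    nl <- config$loci_per_chromosome[[cc$chromosome[i]]]
    data.frame(
      locus_id = sprintf("%s_%03d", cc$chromosome[i], seq_len(nl)),
      genome = cc$genome[i], chromosome = cc$chromosome[i],
      position_cM = sort(stats::runif(nl, 0, cc$length_cM[i])),
      stringsAsFactors = FALSE)
  }))
  loci$allele1 <- "A"; loci$allele2 <- "B"
  L <- nrow(loci)

  # --- population layout
  pop_tab <- do.call(rbind, lapply(seq_len(config$n_groups), function(g) {
    data.frame(
      population = sprintf("%s%02d", substr(config$group_labels[g], 1, 1),
                           seq_len(config$populations_per_group[g])),
      growth_habit = config$group_labels[g],
      n = config$lines_per_population[[g]],
      group_index = g, stringsAsFactors = FALSE)
  }))
  n_pops <- nrow(pop_tab)

  # --- frequencies (stage 2)
  set.seed(sub_seed(config$seed, 2L))
  p_anc <- stats::runif(L, 0.05, 0.95)
  pop_freq <- draw_population_frequencies(p_anc, config$fst_target, n_pops)

  planted <- rep(FALSE, L)
  if (!is.null(config$planted_regions) && nrow(config$planted_regions)) {
    for (k in seq_len(nrow(config$planted_regions))) {
      reg <- config$planted_regions[k, ]
      in_reg <- loci$chromosome == reg$chromosome &
        loci$position_cM >= reg$start_cM & loci$position_cM <= reg$end_cM
      planted <- planted | in_reg
      if (any(in_reg)) {
        sgn <- ifelse(pop_tab$group_index == 1, 1, -1)
        pop_freq[, in_reg] <- pmin(0.98, pmax(0.02,
          pop_freq[, in_reg, drop = FALSE] + outer(sgn * reg$delta,
                                                   rep(1, sum(in_reg)))))
      }
    }
  }

  # realized F_ST of the generating frequencies (among-pop variance ratio)
  pbar <- colMeans(pop_freq)
  s2 <- apply(pop_freq, 2, stats::var)
  fst_realized <- ifelse(pbar > 0 & pbar < 1, s2 / (pbar * (1 - pbar)), NA)

  # --- haplotypes (stage 3): founders + mosaic per population
  set.seed(sub_seed(config$seed, 3L))
  chr_index <- match(loci$chromosome, cc$chromosome)
  gap <- c(NA, diff(loci$position_cM))
  gap[c(TRUE, diff(chr_index) != 0)] <- NA  # chromosome starts
  p_switch <- 1 - (1 - haldane_r(gap))^config$generations
  p_switch[is.na(p_switch)] <- 1  # independent founder choice per chromosome

  haps <- matrix(NA_integer_, nrow = sum(pop_tab$n), ncol = L)
  row0 <- 0
  for (k in seq_len(n_pops)) {
    founders <- matrix(
      stats::rbinom(config$n_founders * L, 1, rep(pop_freq[k, ],
                                                  each = config$n_founders)),
      nrow = config$n_founders)
    nl <- pop_tab$n[k]
    switch_draw <- matrix(stats::runif(nl * L), nrow = nl) <
      matrix(rep(p_switch, each = nl), nrow = nl)
    fid <- matrix(0L, nrow = nl, ncol = L)
    cur <- sample.int(config$n_founders, nl, replace = TRUE)
    for (l in seq_len(L)) {
      sw <- switch_draw[, l]
      if (l == 1 || any(sw)) {
        # at chromosome starts p_switch = 1, so all lines redraw
        n_sw <- sum(sw)
        if (n_sw) cur[sw] <- sample.int(config$n_founders, n_sw,
                                        replace = TRUE)
      }
      fid[, l] <- cur
    }
    for (l in seq_len(L)) haps[row0 + seq_len(nl), l] <- founders[fid[, l], l]
    row0 <- row0 + nl
  }

  lines <- data.frame(
    line_id = sprintf("L%04d", seq_len(sum(pop_tab$n))),
    population = rep(pop_tab$population, pop_tab$n),
    growth_habit = rep(pop_tab$growth_habit, pop_tab$n),
    stringsAsFactors = FALSE)

  calls <- haps * 2L  # homozygote of the line's haplotype allele

  # --- noise (stage 4): mutually exclusive het / missing flips per call
  set.seed(sub_seed(config$seed, 4L))
  u <- matrix(stats::runif(length(calls)), nrow = nrow(calls))
  calls[u < config$het_rate] <- 1L
  calls[u >= config$het_rate &
          u < config$het_rate + config$missing_rate] <- NA_integer_

  truth <- data.frame(locus_id = loci$locus_id,
                      chromosome = loci$chromosome,
                      position_cM = loci$position_cM,
                      p_ancestral = p_anc, planted = planted,
                      fst_realized = fst_realized,
                      stringsAsFactors = FALSE)
  pf <- as.data.frame(t(pop_freq))
  names(pf) <- paste0("p_", pop_tab$population)
  truth <- cbind(truth, pf)

  panel <- genotype_panel(calls, lines, loci)

  # --- ascertainment (stage 5): pooled-panel MAF, after noise
  mafs <- maf(panel)
  keep <- !is.na(mafs) & mafs > config$ascertain_maf_min
  if (!any(keep)) stop("ascertainment removed every locus")
  panel <- subset_panel(panel, loci = which(keep))
  truth$kept <- truth$locus_id %in% panel$loci$locus_id

  list(panel = panel,
       truth = structure(list(table = truth, config = config),
                         class = "sim_truth"))
}

#' Write / read simulation truth as TSV
#'
#' @param truth a `sim_truth` from [simulate_panel()]
#' @param path output path
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth table
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  write_tsv(truth$table, path,
            header = c("simulation truth (pre-noise, pre-ascertainment)",
                       paste0("seed=", truth$config$seed,
                              " fst_target=", truth$config$fst_target)))
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_tsv(path)
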