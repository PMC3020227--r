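#' Two-locus haplotype counts for inbred lines
#'
#' Inbred shortcut: homozygous genotypes stand in for haplotypes, so the
#' 2x2 gamete table is counted directly over lines that are non-missing and
#' non-heterozygous at both loci. Counts are ordered
#' (allele1/allele1, allele1/allele2, allele2/allele1, allele2/allele2).
#'
#' @param panel a `genotype_panel`
#' @param locus_i,locus_j locus ids or column indices
#' @return integer vector `c(n11, n12, n21, n22)`
#' @export
haplotype_counts <- function(panel, locus_i, locus_j) {
  if (is.character(locus_i)) locus_i <- match(locus_i, panel$loci$locus_id)
  if (is.character(locus_j)) locus_j <- match(locus_j, panel$loci$locus_id)
  gi <- panel$calls[, locus_i]
  gj <- panel$calls[, locus_j]
  ok <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
  gi <- gi[ok] / 2L  # 0 = allele1, 1 = allele2
  gj <- gj[ok] / 2L
  c(n11 = sum(gi == 0 & gj == 0), n12 = sum(gi == 0 & gj == 1),
    n21 = sum(gi == 1 & gj == 0), n22 = sum(gi == 1 & gj == 1))
}

count_margins <- function(counts) {
  n <- sum(counts)
  list(n = n,
       p_i = (counts[1] + counts[2]) / n,   # allele1 frequency, locus i
       p_j = (counts[1] + counts[3]) / n,   # allele1 frequency, locus j
       D = counts[1] / n - (counts[1] + counts[2]) * (counts[1] + counts[3]) / n^2)
}

#' Squared allele-frequency correlation r^2
#'
#' `r^2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))` with
#' `D = f11 - p_i p_j` from the 2x2 gamete counts; identical to the squared
#' Pearson correlation of the two 0/1 allele vectors.
#'
#' @param counts `c(n11, n12, n21, n22)` as from [haplotype_counts()]
#' @return r^2 in `[0, 1]`, or `NA` if a margin is monomorphic
#' @export
r_squared <- function(counts) {
  m <- count_margins(counts)
  den <- m$p_i * (1 - m$p_i) * m$p_j * (1 - m$p_j)
  if (is.na(den) || den <= 0) return(NA_real_)
  unname(min(1, m$D^2 / den))
}

d_prime_point <- function(counts) {
  m <- count_margins(counts)
  dmax <- if (m$D < 0) min(m$p_i * m$p_j, (1 - m$p_i) * (1 - m$p_j))
          else min(m$p_i * (1 - m$p_j), (1 - m$p_i) * m$p_j)
  if (is.na(dmax) || dmax <= 0) return(NA_real_)
  unname(min(1, abs(m$D) / dmax))
}

#' D-prime with a likelihood confidence interval
#'
#' `D' = |D| / D_max` where `D_max` bounds `D` given the allele
#' frequencies. The two-sided 90% CI is obtained by normalising the
#' multinomial likelihood of the observed counts over a grid of D' values
#' (allele frequencies fixed at their sample values, the sign of D fixed at
#' the observed sign) and reading the cumulative 5% and 95% points — the
#' block-detection convention of Gabriel-style methods.
#'
#' @param counts `c(n11, n12, n21, n22)`
#' @param grid_size number of D' grid points on `[0, 1]`
#' @return list `dprime`, `low`, `high`, or `NULL` if a margin is
#'   monomorphic
#' @export
d_prime_ci <- function(counts, grid_size = 1001) {
  m <- count_margins(counts)
  if (any(c(m$p_i, m$p_j) %in% c(0, 1)) || is.na(m$p_i)) return(NULL)
  s <- if (m$D < 0) -1 else 1
  dmax <- if (s < 0) min(m$p_i * m$p_j, (1 - m$p_i) * (1 - m$p_j))
          else min(m$p_i * (1 - m$p_j), (1 - m$p_i) * m$p_j)
  dp <- seq(0, 1, length.out = grid_size)
  D <- s * dp * dmax
  f11 <- m$p_i * m$p_j + D
  f12 <- m$p_i * (1 - m$p_j) - D
  f21 <- (1 - m$p_i) * m$p_j - D
  f22 <- (1 - m$p_i) * (1 - m$p_j) + D
  eps <- 1e-12
  ll <- counts[1] * log(pmax(f11, eps)) + counts[2] * log(pmax(f12, eps)) +
    counts[3] * log(pmax(f21, eps)) + counts[4] * log(pmax(f22, eps))
  ll[f11 < -eps | f12 < -eps | f21 < -eps | f22 < -eps] <- -Inf
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  list(dprime = unname(min(1, abs(m$D) / dmax)),
       low = dp[which(cum >= 0.05)[1]],
       high = dp[which(cum >= 0.95)[1]])
}

#' Exact test of two-locus association
#'
#' Two-sided Fisher exact probability on the 2x2 gamete table: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables no more probable than the observed one. For haploid data the
#' exact test of linkage disequilibrium reduces to this test.
#'
#' @param counts `c(n11, n12, n21, n22)`
#' @return p-value in `(0, 1]`
#' @export
exact_test <- function(counts) {
  exact_test_p(counts[1], counts[1] + counts[2], counts[3] + counts[4],
               counts[1] + counts[3])
}

# p for observed n11 = k_obs with row margins m (row1), n (row2), col1 = k
exact_test_p <- function(k_obs, m, n, k) {
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(k_obs, m, n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH at level `q`; q-values are the monotone-adjusted
#' `min_{k >= rank}(m p_(k) / k)`, capped at 1. Rejection at level `q` is
#' `q_value <= q`, equivalent to the step-up rule.
#'
#' @param p_values vector of p-values in `(0, 1]`
#' @param q FDR level
#' @return list `reject` (logical), `q_values`
#' @export
bh_fdr <- function(p_values, q = 0.01) {
  if (!length(p_values)) return(list(reject = logical(), q_values = numeric()))
  qv <- stats::p.adjust(p_values, method = "BH")
  list(reject = qv <= q, q_values = qv)
}

allele_matrix <- function(panel) {
  m <- panel$calls
  m[!is.na(m) & m == 1L] <- NA_integer_
  m / 2
}

#' All pairwise LD statistics for a mapped panel
#'
#' Computes, for every locus pair passing the MAF floor, the 2x2 gamete
#' counts over lines complete at both loci, r^2, D', the map distance
#' (`NA` for inter-chromosomal pairs), the exact-test p-value and the BH
#' q-value over the whole pair universe (intra- and inter-chromosomal pairs
#' under one FDR). Pairs with fewer than `min_complete` complete lines or a
#' monomorphic margin are skipped (counts recorded in the `"skipped"`
#' attribute).
#'
#' @param panel a `genotype_panel`
#' @param config an [analysis_config()] (uses `maf_min`, `min_complete`,
#'   `fdr_q`)
#' @param intra_only drop inter-chromosomal pairs before testing
#' @return data.frame of class `ld_pairs`; attribute `skipped` gives
#'   skip counts, attribute `config` the configuration used.
#' @export
ld_pairs <- function(panel, config = analysis_config(), intra_only = FALSE) {
  mafs <- maf(panel)
  keep <- !is.na(mafs) & mafs > config$maf_min
  if (sum(keep) < 2) stop("fewer than 2 loci pass the MAF floor")
  panel <- subset_panel(panel, loci = which(keep))
  x <- allele_matrix(panel)
  L <- ncol(x)

  A1 <- (x == 0); A1[is.na(A1)] <- FALSE
  A2 <- (x == 1); A2[is.na(A2)] <- FALSE
  storage.mode(A1) <- "numeric"; storage.mode(A2) <- "numeric"
  N11 <- crossprod(A1)
  N12 <- crossprod(A1, A2)
  N21 <- crossprod(A2, A1)
  N22 <- crossprod(A2)

  ut <- which(upper.tri(N11), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  chr_i <- panel$loci$chromosome[i]; chr_j <- panel$loci$chromosome[j]
  intra <- chr_i == chr_j
  if (intra_only) {
    sel <- intra
    i <- i[sel]; j <- j[sel]; chr_i <- chr_i[sel]; chr_j <- chr_j[sel]
    intra <- intra[sel]
  }
  n11 <- N11[cbind(i, j)]; n12 <- N12[cbind(i, j)]
  n21 <- N21[cbind(i, j)]; n22 <- N22[cbind(i, j)]
  n <- n11 + n12 + n21 + n22

  p_i <- (n11 + n12) / n
  p_j <- (n11 + n21) / n
  poly <- p_i > 0 & p_i < 1 & p_j > 0 & p_j < 1
  enough <- n >= config$min_complete
  skipped <- c(low_n = sum(!enough),
               monomorphic_margin = sum(enough & !poly))
  sel <- enough & poly
  i <- i[sel]; j <- j[sel]; chr_i <- chr_i[sel]; chr_j <- chr_j[sel]
  intra <- intra[sel]
  n11 <- n11[sel]; n12 <- n12[sel]; n21 <- n21[sel]; n22 <- n22[sel]
  n <- n[sel]; p_i <- p_i[sel]; p_j <- p_j[sel]
  if (!length(i)) stop("no testable locus pair")

  D <- n11 / n - p_i * p_j
  r2 <- pmin(1, D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j)))
  dmax <- ifelse(D < 0, pmin(p_i * p_j, (1 - p_i) * (1 - p_j)),
                 pmin(p_i * (1 - p_j), (1 - p_i) * p_j))
  dprime <- pmin(1, abs(D) / dmax)

  p_exact <- vapply(seq_along(i), function(k)
    exact_test_p(n11[k], n11[k] + n12[k], n21[k] + n22[k], n11[k] + n21[k]),
    0)
  fdr <- bh_fdr(p_exact, config$fdr_q)

  out <- data.frame(
    locus_i = panel$loci$locus_id[i], locus_j = panel$loci$locus_id[j],
    chromosome_i = chr_i, chromosome_j = chr_j,
    genome_i = panel$loci$genome[i], genome_j = panel$loci$genome[j],
    distance_cM = ifelse(intra,
                         abs(panel$loci$position_cM[i] -
                               panel$loci$position_cM[j]), NA),
    intra = intra, n_complete = as.integer(n),
    n11 = as.integer(n11), n12 = as.integer(n12),
    n21 = as.integer(n21), n22 = as.integer(n22),
    r2 = r2, dprime = dprime,
    p_exact = p_exact, q_bh = fdr$q_values, significant = fdr$reject,
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "config") <- config
  class(out) <- c("ld_pairs", "data.frame")
  out
}

#' Summaries of significant LD
#'
#' Over BH-significant intra-chromosomal pairs: the mean and median pair
#' distance (the "extent of significant LD"); the proportion of loci with at
#' least one significant linked pair; the proportion of inter-chromosomal
#' pairs significant; background LD (the 95th percentile of all
#' inter-chromosomal r^2); and the realized r^2 significance cutoff (the
#' smallest r^2 among significant pairs). Intra-chromosomal statistics are
#' also broken down per genome. `extent = "per_locus"` replaces the
#' per-pair extent by the mean/median over loci of each locus's maximum
#' significant pair distance.
#'
#' @param pairs an `ld_pairs` table
#' @param extent `"per_pair"` (default) or `"per_locus"`
#' @return list of class `ld_summary`
#' @export
ld_summary <- function(pairs, extent = c("per_pair", "per_locus")) {
  extent <- match.arg(extent)
  intra <- pairs[pairs$intra, , drop = FALSE]
  inter <- pairs[!pairs$intra, , drop = FALSE]
  sig_intra <- intra[intra$significant, , drop = FALSE]

  extent_stats <- function(sig) {
    if (!nrow(sig)) return(c(mean = NA, median = NA))
    if (extent == "per_pair")
      c(mean = mean(sig$distance_cM), median = stats::median(sig$distance_cM))
    else {
      dmax <- tapply(c(sig$distance_cM, sig$distance_cM),
                     c(sig$locus_i, sig$locus_j), max)
      c(mean = mean(dmax), median = stats::median(dmax))
    }
  }

  loci_in_intra <- unique(c(intra$locus_i, intra$locus_j))
  loci_sig <- unique(c(sig_intra$locus_i, sig_intra$locus_j))

  ext <- extent_stats(sig_intra)
  by_genome <- do.call(rbind, lapply(sort(unique(intra$genome_i)), function(g) {
    gi <- intra[intra$genome_i == g, , drop = FALSE]
    gs <- gi[gi$significant, , drop = FALSE]
    e <- extent_stats(gs)
    data.frame(genome = g, n_pairs = nrow(gi), n_significant = nrow(gs),
               mean_extent_cM = unname(e["mean"]),
               median_extent_cM = unname(e["median"]),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    n_intra_pairs = nrow(intra), n_intra_significant = nrow(sig_intra),
    mean_extent_cM = unname(ext["mean"]),
    median_extent_cM = unname(ext["median"]),
    prop_loci_with_sig_linked_pair =
      if (length(loci_in_intra)) length(loci_sig) / length(loci_in_intra)
      else NA,
    n_inter_pairs = nrow(inter),
    prop_inter_significant = if (nrow(inter)) mean(inter$significant) else NA,
    background_ld = if (nrow(inter))
      unname(stats::quantile(inter$r2, 0.95)) else NA,
    r2_cutoff_realized = if (any(pairs$significant))
      min(pairs$r2[pairs$significant]) else NA,
    extent = extent, by_genome = by_genome),
    class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("Significant-LD summary (", x$extent, " extent)\n", sep = "")
  cat(sprintf("  intra-chromosomal: %d/%d pairs significant; extent mean %.1f cM, median %.1f cM\n",
              x$n_intra_significant, x$n_intra_pairs,
              x$mean_extent_cM, x$median_extent_cM))
  cat(sprintf("  loci with >=1 significant linked pair: %.1f%%\n",
              100 * x$prop_loci_with_sig_linked_pair))
  cat(sprintf("  inter-chromosomal: %.1f%% of %d pairs significant; background LD (95th pct r2) = %.3f\n",
              100 * x$prop_inter_significant, x$n_inter_pairs,
              x$background_ld))
  cat(sprintf("  realized r2 significance cutoff: %.3f\n",
              x$r2_cutoff_realized))
  invisible(x)
}

#' Loess decay of r^2 with genetic distance
#'
#' Fits a locally-weighted linear regression (degree 1, tricube weights) of
#' r^2 on intra-chromosomal pair distance, evaluates it on a distance grid,
#' and reports the initial LD (fitted value at the smallest observed
#' distance) and the half-decay distance — the smallest grid distance at
#' which the fit falls to half the initial LD, linearly interpolated
#' between grid points (`NA` with `reached = FALSE` if never).
#'
#' @param pairs an `ld_pairs` table (intra-chromosomal rows are used)
#' @param span loess span (default 0.5)
#' @param grid_n number of grid points
#' @param min_pairs minimum number of intra-chromosomal pairs required
#' @return list of class `decay_curve`: `grid` (distance, r2_fit),
#'   `initial_ld`, `half_decay_cM`, `reached`, `span`, `n_pairs`
#' @export
decay_curve <- function(pairs, span = 0.5, grid_n = 200, min_pairs = 30) {
  d <- pairs$distance_cM[pairs$intra]
  r2 <- pairs$r2[pairs$intra]
  ok <- !is.na(d) & !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (length(d) < min_pairs)
    stop("need at least ", min_pairs, " intra-chromosomal pairs (have ",
         length(d), ")")
  fit <- tryCatch(
    stats::loess(r2 ~ d, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")),
    error = function(e)
      stop("loess fit failed (", conditionMessage(e),
           "); try a larger span", call. = FALSE))
  grid <- seq(min(d), max(d), length.out = grid_n)
  fitv <- stats::predict(fit, newdata = data.frame(d = grid))
  initial <- fitv[1]
  half <- initial / 2
  below <- which(fitv <= half)
  below <- below[below > 1]
  if (length(below) && !is.na(initial) && initial > 0) {
    k <- below[1]
    # linear interpolation between grid[k-1] and grid[k]
    f0 <- fitv[k - 1]; f1 <- fitv[k]
    hd <- grid[k - 1] + (f0 - half) / (f0 - f1) * (grid[k] - grid[k - 1])
    reached <- TRUE
  } else {
    hd <- NA_real_
    reached <- FALSE
  }
  structure(list(grid = data.frame(distance_cM = grid, r2_fit = fitv),
                 initial_ld = unname(initial), half_decay_cM = unname(hd),
                 reached = reached, span = span, n_pairs = length(d)),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("LD decay (loess span %.2f, %d pairs): initial r2 = %.3f; ",
              x$span, x$n_pairs, x$initial_ld))
  if (x$reached) cat(sprintf("half-decay at %.2f cM\n", x$half_decay_cM))
  else cat("half-decay not reached\n")
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, ...) {
  graphics::plot(x$grid$distance_cM, x$grid$r2_fit, type = "l",
                 xlab = "distance (cM)", ylab = expression(r^2), ...)
  if (x$reached) graphics::abline(v = x$half_decay_cM, lty = 2)
  invisible(x)
}

#' Parameters for Gabriel-style block detection
#'
#' Conventional thresholds of the confidence-bound block method: a pair is
#' "strong LD" if its D' CI lower bound is >= 0.70 and upper bound >= 0.98;
#' "strong recombination" if the upper bound is < 0.90; a candidate block
#' (a map-contiguous run whose outermost pair is strong LD) is accepted if
#' at least 95% of its informative pairs are strong LD.
#'
#' @param ci_low_strong,ci_high_strong,ci_high_recomb classification bounds
#' @param frac_strong minimum fraction of informative pairs in strong LD
#' @param max_span_cM D' CIs are computed only for pairs within this span
#' @param grid_size D' likelihood grid size
#' @return a list of parameters
#' @export
gabriel_params <- function(ci_low_strong = 0.70, ci_high_strong = 0.98,
                           ci_high_recomb = 0.90, frac_strong = 0.95,
                           max_span_cM = 30, grid_size = 1001) {
  list(ci_low_strong = ci_low_strong, ci_high_strong = ci_high_strong,
       ci_high_recomb = ci_high_recomb, frac_strong = frac_strong,
       max_span_cM = max_span_cM, grid_size = grid_size)
}

#' Haplotype blocks by the D' confidence-bound method
#'
#' Classifies intra-chromosomal pairs within `max_span_cM` by their D'
#' likelihood CIs, enumerates map-contiguous candidate runs whose outermost
#' pair is in strong LD, accepts runs where the strong-LD fraction of
#' informative pairs reaches `frac_strong`, and resolves overlaps
#' longest-span-first (ties: more loci, then leftmost).
#'
#' @param panel a `genotype_panel` (typically MAF-filtered)
#' @param config an [analysis_config()] (uses `maf_min`, `min_complete`)
#' @param params a [gabriel_params()] list
#' @return data.frame: `chromosome`, `start_cM`, `end_cM`, `n_loci`,
#'   `loci` (comma-joined ids)
#' @export
gabriel_blocks <- function(panel, config = analysis_config(),
                           params = gabriel_params()) {
  mafs <- maf(panel)
  keep <- !is.na(mafs) & mafs > config$maf_min
  panel <- subset_panel(panel, loci = which(keep))
  empty <- data.frame(chromosome = character(), start_cM = numeric(),
                      end_cM = numeric(), n_loci = integer(),
                      loci = character(), stringsAsFactors = FALSE)
  blocks <- list()
  for (chr in unique(panel$loci$chromosome)) {
    idx <- which(panel$loci$chromosome == chr)
    L <- length(idx)
    if (L < 2) next
    pos <- panel$loci$position_cM[idx]
    # classify pairs: 1 strong LD, -1 strong recombination, 0 uninformative
    cls <- matrix(0L, L, L)
    for (a in seq_len(L - 1)) for (b in (a + 1):L) {
      if (pos[b] - pos[a] > params$max_span_cM) next
      cnt <- haplotype_counts(panel, idx[a], idx[b])
      if (sum(cnt) < config$min_complete) next
      ci <- d_prime_ci(cnt, params$grid_size)
      if (is.null(ci)) next
      if (ci$low >= params$ci_low_strong && ci$high >= params$ci_high_strong)
        cls[a, b] <- 1L
      else if (ci$high < params$ci_high_recomb)
        cls[a, b] <- -1L
    }
    # candidate runs: outermost pair strong LD, >= frac_strong informative
    cand <- list()
    for (a in seq_len(L - 1)) for (b in (a + 1):L) {
      if (cls[a, b] != 1L) next
      sub <- cls[a:b, a:b]
      inf <- sum(sub != 0L)
      if (inf == 0 || sum(sub == 1L) / inf < params$frac_strong) next
      cand[[length(cand) + 1]] <- c(a = a, b = b)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    span <- pos[cand[, "b"]] - pos[cand[, "a"]]
    nlo <- cand[, "b"] - cand[, "a"] + 1
    ord <- order(-span, -nlo, cand[, "a"])
    used <- logical(L)
    for (k in ord) {
      rng <- cand[k, "a"]:cand[k, "b"]
      if (any(used[rng])) next
      used[rng] <- TRUE
      blocks[[length(blocks) + 1]] <- data.frame(
        chromosome = chr, start_cM = pos[cand[k, "a"]],
        end_cM = pos[cand[k, "b"]], n_loci = length(rng),
        loci = paste(panel$loci$locus_id[idx[rng]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  out <- out[order(out$chromosome, out$start_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end LD analysis of a panel
#'
#' MAF-filters the pair universe, computes the full pair table with
#' exact-test significance under one BH FDR, summarises significant LD,
#' fits the overall and per-genome decay curves, and detects haplotype
#' blocks.
#'
#' @param panel a `genotype_panel`
#' @param config an [analysis_config()]
#' @param span loess span for the decay curves
#' @param blocks compute Gabriel-style blocks (can be slow on dense maps)
#' @return object of class `ld_analysis`: `pairs`, `summary`, `decay`,
#'   `decay_by_genome`, `blocks`, `config`
#' @export
ld_analysis <- function(panel, config = analysis_config(), span = 0.5,
                        blocks = TRUE) {
  pairs <- ld_pairs(panel, config)
  smry <- ld_summary(pairs)
  dec <- tryCatch(decay_curve(pairs, span = span), error = function(e) NULL)
  dec_g <- lapply(split(as.data.frame(pairs)[pairs$intra, , drop = FALSE],
                        pairs$genome_i[pairs$intra]),
                  function(sub) {
    sub$intra <- TRUE
    tryCatch(decay_curve(sub, span = span), error = function(e) NULL)
  })
  blk <- if (blocks) gabriel_blocks(panel, config) else NULL
  structure(list(pairs = pairs, summary = smry, decay = dec,
                 decay_by_genome = dec_g, blocks = blk, config = config),
            class = "ld_analysis")
}

#' @export
print.ld_analysis <- function(x, ...) {
  cat("LD analysis:", nrow(x$pairs), "testable pairs\n")
  print(x$summary)
  if (!is.null(x$decay)) print(x$decay)
  if (!is.null(x$blocks))
    cat(sprintf("  %d haplotype block(s)\n", nrow(x$blocks)))
  invisible(x)
}

#' Per-chromosome square r^2 matrix (heatmap-ready)
#'
#' @param pairs an `ld_pairs` table
#' @param chromosome chromosome label
#' @return symmetric numeric matrix of r^2, loci in map order
#' @export
r2_matrix <- function(pairs, chromosome) {
  sub <- pairs[pairs$intra & pairs$chromosome_i == chromosome, , drop = FALSE]
  if (!nrow(sub)) stop("no intra-chromosomal pairs on ", chromosome)
  ids <- unique(c(sub$locus_i, sub$locus_j))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(sub$locus_i, sub$locus_j)] <- sub$r2
  m[cbind(sub$locus_j, sub$locus_i)] <- sub$r2
  diag(m) <- 1
  m
}
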