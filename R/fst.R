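#' Analysis configuration
#'
#' Houses the scan and LD constants: window size `W` (5 consecutive linked
#' SNPs), bootstrap replicates `B` (1000), the 95th percentile threshold,
#' FDR level 0.01, MAF floor 0.05, 4 cM thinning distance and the minimum
#' stratum size 5.
#'
#' @param W sliding-window size in loci (>= 2)
#' @param B bootstrap replicates (>= 1)
#' @param percentile percentile of the bootstrap null used as threshold
#' @param fdr_q Benjamini-Hochberg FDR level for LD significance
#' @param maf_min minor-allele-frequency floor (strict `>`)
#' @param thin_cM minimum distance for map thinning
#' @param min_lines minimum lines per stratum
#' @param min_complete minimum lines complete at both loci for an LD pair
#' @param seed integer seed for the bootstrap
#' @return an `analysis_config` list
#' @export
analysis_config <- function(W = 5, B = 1000, percentile = 95, fdr_q = 0.01,
                            maf_min = 0.05, thin_cM = 4, min_lines = 5,
                            min_complete = 10, seed = 1L) {
  stopifnot(W >= 2, B >= 1, percentile > 0, percentile < 100,
            fdr_q > 0, fdr_q < 1, maf_min >= 0, maf_min < 0.5)
  structure(list(W = as.integer(W), B = as.integer(B), percentile = percentile,
                 fdr_q = fdr_q, maf_min = maf_min, thin_cM = thin_cM,
                 min_lines = min_lines, min_complete = min_complete,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# resolve a grouping argument to a factor over lines
resolve_grouping <- function(panel, grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% c("growth_habit", "population"))
    grouping <- panel$lines[[grouping]]
  if (length(grouping) != n_lines(panel))
    stop("grouping must name a metadata column or give one label per line")
  factor(grouping)
}

#' Weir-Cockerham F_ST for haploid samples, per locus
#'
#' ANOVA estimator of theta on haploid allele copies (each inbred line
#' contributes one copy; heterozygous calls are treated as missing). With
#' `r` groups of sizes `n_i` and allele frequencies `p_i`:
#' `n_c = (N - sum(n_i^2)/N) / (r - 1)`,
#' `MSP = sum(n_i (p_i - pbar)^2) / (r - 1)` with `pbar` the weighted mean,
#' `MSG = sum(n_i p_i (1 - p_i)) / sum(n_i - 1)`, and
#' `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)`. Theta is flagged
#' undefined (`NA`) when the denominator is zero (pooled-monomorphic locus).
#'
#' @param panel a `genotype_panel`
#' @param grouping `"growth_habit"`, `"population"`, or a factor over lines
#' @return data.frame, one row per locus: `locus_id`, `chromosome`,
#'   `position_cM`, `theta`, `msp`, `msg`, `n_c`, `n_pops_used`, `n_total`
#' @export
wc_theta <- function(panel, grouping = "growth_habit") {
  g <- resolve_grouping(panel, grouping)
  if (nlevels(g) < 2) stop("grouping must have at least 2 groups")
  m <- panel$calls
  m[!is.na(m) & m == 1L] <- NA_integer_  # het -> missing
  x <- m / 2  # haploid allele indicator in {0, 1}

  lev <- levels(g)
  n_i <- do.call(rbind, lapply(lev, function(l)
    colSums(!is.na(x[g == l, , drop = FALSE]))))
  s_i <- do.call(rbind, lapply(lev, function(l)
    colSums(x[g == l, , drop = FALSE], na.rm = TRUE)))
  p_i <- ifelse(n_i > 0, s_i / n_i, NA)

  theta <- msp <- msg <- ncs <- rep(NA_real_, ncol(x))
  r_used <- ntot <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    use <- n_i[, j] > 0
    r <- sum(use)
    nij <- n_i[use, j]; pij <- p_i[use, j]
    N <- sum(nij)
    r_used[j] <- r; ntot[j] <- N
    if (r < 2 || sum(nij - 1) <= 0) next
    pbar <- sum(nij * pij) / N
    MSP <- sum(nij * (pij - pbar)^2) / (r - 1)
    MSG <- sum(nij * pij * (1 - pij)) / sum(nij - 1)
    n_c <- (N - sum(nij^2) / N) / (r - 1)
    den <- MSP + (n_c - 1) * MSG
    msp[j] <- MSP; msg[j] <- MSG; ncs[j] <- n_c
    if (den > 0) theta[j] <- (MSP - MSG) / den
  }
  data.frame(locus_id = panel$loci$locus_id,
             genome = panel$loci$genome,
             chromosome = panel$loci$chromosome,
             position_cM = panel$loci$position_cM,
             theta = theta, msp = msp, msg = msg, n_c = ncs,
             n_pops_used = r_used, n_total = ntot,
             stringsAsFactors = FALSE)
}

#' Per-chromosome and per-genome summaries of single-locus theta
#'
#' Arithmetic mean and SD of defined theta values per chromosome and per
#' genome, alongside the SD of the W-locus sliding-window means on the same
#' unit (the window SD is NA where a chromosome has fewer than W defined
#' loci).
#'
#' @param results the per-locus data.frame from [wc_theta()]
#' @param W window size for the window-mean SDs
#' @return list of data.frames `by_chromosome`, `by_genome`, plus `overall`
#' @export
fst_summary <- function(results, W = 5) {
  win <- sliding_window_means(results, W)
  unit_summary <- function(split_by) {
    sp <- split(results, results[[split_by]])
    wsp <- if (nrow(win)) split(win, win[[split_by]]) else list()
    do.call(rbind, lapply(names(sp), function(u) {
      th <- sp[[u]]$theta[!is.na(sp[[u]]$theta)]
      wm <- if (u %in% names(wsp)) wsp[[u]]$mean_theta else numeric()
      data.frame(unit = u, n_loci = length(th),
                 mean_theta = if (length(th)) mean(th) else NA,
                 sd_theta = if (length(th) > 1) stats::sd(th) else NA,
                 n_windows = length(wm),
                 sd_window = if (length(wm) > 1) stats::sd(wm) else NA,
                 stringsAsFactors = FALSE)
    }))
  }
  th_all <- results$theta[!is.na(results$theta)]
  list(by_chromosome = unit_summary("chromosome"),
       by_genome = unit_summary("genome"),
       overall = data.frame(n_loci = length(th_all),
                            mean_theta = mean(th_all),
                            sd_theta = stats::sd(th_all),
                            n_windows = nrow(win),
                            sd_window = if (nrow(win) > 1)
                              stats::sd(win$mean_theta) else NA))
}

#' Sliding-window means of single-locus theta
#'
#' Step-1 windows of `W` consecutive mapped loci with defined theta, never
#' spanning chromosomes. Loci with undefined theta are excluded before
#' windows are formed; chromosomes left with fewer than `W` loci contribute
#' no windows.
#'
#' @param results the per-locus data.frame from [wc_theta()] (map order)
#' @param W window size
#' @return data.frame: `genome`, `chromosome`, `start_cM`, `end_cM`,
#'   `loci` (comma-joined ids), `mean_theta`
#' @export
sliding_window_means <- function(results, W = 5) {
  stopifnot(W >= 2)
  res <- results[!is.na(results$theta), , drop = FALSE]
  out <- lapply(split(res, res$chromosome), function(ch) {
    ch <- ch[order(ch$position_cM, ch$locus_id), , drop = FALSE]
    n <- nrow(ch)
    if (n < W) return(NULL)
    starts <- seq_len(n - W + 1)
    data.frame(genome = ch$genome[1], chromosome = ch$chromosome[1],
               start_cM = ch$position_cM[starts],
               end_cM = ch$position_cM[starts + W - 1],
               loci = vapply(starts, function(s)
                 paste(ch$locus_id[s:(s + W - 1)], collapse = ","), ""),
               mean_theta = vapply(starts, function(s)
                 mean(ch$theta[s:(s + W - 1)]), 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(genome = character(), chromosome = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      loci = character(), mean_theta = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bootstrap null threshold for window means
#'
#' Draws `B` sets of `W` loci with replacement from all defined single-locus
#' theta values genome-wide (map structure deliberately ignored: the null is
#' "W random SNPs", not "W adjacent SNPs"), takes each set's mean, and
#' returns the requested empirical percentile of the `B` means.
#'
#' @param results the per-locus data.frame from [wc_theta()]
#' @param W set size
#' @param B number of resamples
#' @param percentile percentile of the null distribution (default 95)
#' @param seed integer seed; fixed seed gives a deterministic threshold
#' @return the threshold (numeric scalar)
#' @export
bootstrap_threshold <- function(results, W = 5, B = 1000, percentile = 95,
                                seed = 1L) {
  th <- results$theta[!is.na(results$theta)]
  if (length(th) < W) stop("fewer defined loci than W")
  set.seed(seed)
  means <- vapply(seq_len(B), function(b) mean(sample(th, W, replace = TRUE)),
                  0)
  unname(stats::quantile(means, percentile / 100))
}

#' Merge above-threshold windows into elevated regions
#'
#' Maximal runs of consecutive windows (per chromosome, in map order) whose
#' mean theta exceeds the threshold are merged into intervals from the first
#' window's start to the last window's end; the interval's mean theta is the
#' mean of its member window means.
#'
#' @param windows data.frame from [sliding_window_means()]
#' @param threshold scalar from [bootstrap_threshold()]
#' @return data.frame: `chromosome`, `start_cM`, `end_cM`, `n_windows`,
#'   `mean_theta`
#' @export
elevated_regions <- function(windows, threshold) {
  empty <- data.frame(chromosome = character(), start_cM = numeric(),
                      end_cM = numeric(), n_windows = integer(),
                      mean_theta = numeric(), stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  out <- lapply(split(windows, windows$chromosome), function(ch) {
    ch <- ch[order(ch$start_cM, ch$end_cM), , drop = FALSE]
    above <- ch$mean_theta > threshold
    if (!any(above)) return(NULL)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(runs$values)
    do.call(rbind, lapply(keep, function(k) {
      idx <- starts[k]:ends[k]
      data.frame(chromosome = ch$chromosome[1],
                 start_cM = min(ch$start_cM[idx]),
                 end_cM = max(ch$end_cM[idx]),
                 n_windows = length(idx),
                 mean_theta = mean(ch$mean_theta[idx]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Sliding-window differentiation scan
#'
#' End-to-end scan between two (or more) groups: haploid Weir-Cockerham
#' theta per locus, W-locus sliding-window means per chromosome, a
#' genome-wide bootstrap percentile threshold, and merged elevated regions.
#'
#' @param panel a `genotype_panel` (typically MAF-filtered)
#' @param grouping `"growth_habit"`, `"population"`, or a factor over lines
#' @param config an [analysis_config()]
#' @return object of class `fst_scan`: `per_locus`, `windows`, `threshold`,
#'   `regions`, `summary`, `config`
#' @export
fst_scan <- function(panel, grouping = "growth_habit",
                     config = analysis_config()) {
  res <- wc_theta(panel, grouping)
  win <- sliding_window_means(res, config$W)
  thr <- bootstrap_threshold(res, config$W, config$B, config$percentile,
                             config$seed)
  reg <- elevated_regions(win, thr)
  structure(list(per_locus = res, windows = win, threshold = thr,
                 regions = reg, summary = fst_summary(res, config$W),
                 config = config),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  ov <- x$summary$overall
  cat("F_ST sliding-window scan\n")
  cat(sprintf("  %d loci with defined theta; mean theta = %.4f (SD %.4f)\n",
              ov$n_loci, ov$mean_theta, ov$sd_theta))
  cat(sprintf("  %d windows of %d loci; bootstrap %gth-percentile threshold = %.4f (B = %d, seed = %d)\n",
              ov$n_windows, x$config$W, x$config$percentile, x$threshold,
              x$config$B, x$config$seed))
  cat(sprintf("  %d elevated region(s)\n", nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' @export
summary.fst_scan <- function(object, ...) object$summary

#' @export
plot.fst_scan <- function(x, ...) {
  win <- x$windows
  if (!nrow(win)) {
    warning("no windows to plot")
    return(invisible(x))
  }
  chrs <- unique(x$per_locus$chromosome)
  offs <- c(0, cumsum(vapply(chrs, function(ch)
    max(x$per_locus$position_cM[x$per_locus$chromosome == ch]) + 10, 0)))
  names(offs) <- c(chrs, "end")
  pos <- win$start_cM + offs[win$chromosome]
  graphics::plot(pos, win$mean_theta, pch = 16, cex = 0.5,
                 xlab = "cumulative map position (cM)",
                 ylab = expression(bar(theta) ~ "(window mean)"), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Hierarchical variance components of allele-indicator variance
#'
#' Two-level nested random-effects ANOVA on haploid 0/1 allele indicators:
#' among growth-habit groups, among populations within groups, and within
#' populations. Per-locus components use the standard unbalanced nested
#' ANOVA coefficients; raw components are summed over loci, negatives are
#' truncated to 0 (flagged), and the totals are expressed as percentages.
#' With `group_level = NULL` (or a single group) the analysis collapses to
#' one level: among populations vs within populations.
#'
#' @param panel a `genotype_panel`
#' @param group_level metadata column for the top stratum
#'   (default `"growth_habit"`), or `NULL` for a one-level analysis
#' @param pop_level metadata column for the nested stratum
#' @param min_lines populations smaller than this are excluded
#' @return list of class `variance_components`: `components` (raw sums),
#'   `percent`, `truncated` (which raw sums were negative), `n_loci`
#' @export
hierarchical_components <- function(panel, group_level = "growth_habit",
                                    pop_level = "population",
                                    min_lines = 5) {
  pop <- factor(panel$lines[[pop_level]])
  keep_pops <- names(which(table(pop) >= min_lines))
  use <- pop %in% keep_pops
  if (!any(use)) stop("no population reaches min_lines")
  panel <- subset_panel(panel, lines = which(use))
  pop <- factor(panel$lines[[pop_level]])
  grp <- if (is.null(group_level)) factor(rep("all", n_lines(panel)))
         else factor(panel$lines[[group_level]])
  two_level <- nlevels(grp) >= 2

  m <- panel$calls
  m[!is.na(m) & m == 1L] <- NA_integer_
  x <- m / 2

  tot <- c(group = 0, pop = 0, within = 0)
  n_used <- 0L
  for (j in seq_len(ncol(x))) {
    xi <- x[, j]
    ok <- !is.na(xi)
    if (sum(ok) < 2) next
    xi <- xi[ok]; gi <- droplevels(grp[ok]); pi_ <- droplevels(pop[ok])
    comp <- nested_components(xi, gi, pi_)
    if (is.null(comp)) next
    tot <- tot + comp
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no locus with enough data for variance components")

  truncated <- tot < 0
  tot[truncated] <- 0
  if (!two_level) tot["group"] <- 0
  pct <- if (sum(tot) > 0) 100 * tot / sum(tot) else c(group = NA, pop = NA,
                                                       within = NA)
  structure(list(
    components = tot,
    percent = stats::setNames(pct, c("among_groups",
                                     "among_pops_within_group",
                                     "within_pops")),
    truncated = truncated, two_level = two_level, n_loci = n_used),
    class = "variance_components")
}

# unbalanced two-fold nested ANOVA components for one locus
# returns c(group, pop, within) raw variance components (may be negative)
nested_components <- function(x, grp, pop) {
  N <- length(x)
  G <- nlevels(grp)
  P <- nlevels(pop)
  if (P < 2) return(NULL)
  xbar <- mean(x)
  gm <- tapply(x, grp, mean); gn <- tapply(x, grp, length)
  pm <- tapply(x, pop, mean); pn <- tapply(x, pop, length)
  pg <- tapply(as.integer(grp), pop, function(v) v[1])  # group of each pop

  ss_within <- sum((x - pm[pop])^2)
  ss_pop <- sum(pn * (pm - gm[pg])^2)
  ss_group <- sum(gn * (gm - xbar)^2)

  df_within <- N - P
  df_pop <- P - G
  df_group <- G - 1

  sum_pn2_by_g <- tapply(pn^2, pg, sum)
  k1 <- if (df_pop > 0) (N - sum(sum_pn2_by_g / gn)) / df_pop else NA
  s2_w <- if (df_within > 0) ss_within / df_within else 0
  s2_p <- if (df_pop > 0) (ss_pop / df_pop - s2_w) / k1 else 0

  if (df_group > 0) {
    k2 <- (sum(sum_pn2_by_g / gn) - sum(pn^2) / N) / df_group
    k3 <- (N - sum(gn^2) / N) / df_group
    s2_g <- (ss_group / df_group - s2_w - k2 * s2_p) / k3
  } else s2_g <- 0
  c(group = s2_g, pop = s2_p, within = s2_w)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Hierarchical variance components (", x$n_loci, " loci)\n", sep = "")
  lab <- c("Among growth-habit groups", "Among populations within group",
           "Within populations")
  for (i in seq_along(lab)) {
    if (i == 1 && !x$two_level) next
    cat(sprintf("  %-32s %6.1f%%%s\n", lab[i], x$percent[i],
                if (x$truncated[i]) " (negative, truncated to 0)" else ""))
  }
  invisible(x)
}
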