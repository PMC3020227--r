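#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` for allele frequencies `p_i`. For a biallelic
#' locus this equals the expected heterozygosity `2p(1-p)` and is bounded by
#' 0.5.
#'
#' @param p numeric vector of allele frequencies summing to 1
#' @return PIC in `[0, 1 - 1/length(p)]`
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("negative allele frequency")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  1 - sum(p^2)
}

# per-locus PIC / MAF / allele count for a subset of lines (haploid, het
# treated as missing); monomorphic loci score PIC = 0, MAF = 0, alleles = 1
locus_stats <- function(panel, line_idx = NULL) {
  m <- panel$calls
  if (!is.null(line_idx)) m <- m[line_idx, , drop = FALSE]
  n1 <- colSums(m == 0L, na.rm = TRUE)
  n2 <- colSums(m == 2L, na.rm = TRUE)
  nt <- n1 + n2
  p <- ifelse(nt > 0, n2 / nt, NA)
  n_alleles <- (n1 > 0) + (n2 > 0)
  data.frame(locus_id = panel$loci$locus_id,
             n_obs = nt,
             p_allele2 = p,
             maf = ifelse(nt > 0, pmin(p, 1 - p), NA),
             n_alleles = ifelse(nt > 0, n_alleles, 0L),
             pic = ifelse(nt > 0, 1 - p^2 - (1 - p)^2, NA),
             polymorphic = n_alleles == 2,
             stringsAsFactors = FALSE)
}

#' Per-stratum diversity statistics
#'
#' For each stratum (breeding population, growth-habit group, or the total
#' panel): number of lines, proportion of loci with two observed alleles,
#' and means over all loci of MAF, observed allele count and PIC.
#' Monomorphic-within-stratum loci contribute MAF 0, 1 allele and PIC 0 to
#' the means (they stay in the denominator), matching panel-wide averaging
#' over a fixed SNP set. Strata with fewer than `min_lines` lines are
#' dropped with a warning.
#'
#' @param panel a `genotype_panel`
#' @param stratification one of `"population"`, `"growth_habit"`, `"total"`
#' @param min_lines smallest stratum size reported (default 5)
#' @return data.frame with one row per stratum, class `diversity_table`
#' @export
diversity_table <- function(panel,
                            stratification = c("population", "growth_habit",
                                               "total"),
                            min_lines = 5) {
  stratification <- match.arg(stratification)
  strata <- switch(stratification,
                   population = split(seq_len(n_lines(panel)),
                                      panel$lines$population),
                   growth_habit = split(seq_len(n_lines(panel)),
                                        panel$lines$growth_habit),
                   total = list(total = seq_len(n_lines(panel))))
  small <- names(strata)[vapply(strata, length, 0L) < min_lines]
  if (length(small)) {
    warning("stratum(a) below min_lines = ", min_lines, " excluded: ",
            paste(small, collapse = ", "))
    strata <- strata[setdiff(names(strata), small)]
  }
  if (!length(strata)) stop("no stratum left after min_lines exclusion")
  rows <- lapply(names(strata), function(s) {
    st <- locus_stats(panel, strata[[s]])
    observed <- st$n_obs > 0
    data.frame(stratum = s,
               n_lines = length(strata[[s]]),
               prop_polymorphic = mean(st$polymorphic[observed]),
               mean_maf = mean(ifelse(observed, st$maf, NA), na.rm = TRUE),
               mean_alleles = mean(st$n_alleles[observed]),
               mean_pic = mean(ifelse(observed, st$pic, NA), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Minor-allele-frequency spectrum of a group
#'
#' Histogram of pooled-group MAF over polymorphic loci. Default 10 bins of
#' width 0.05 on `[0, 0.5]`; bins are half-open `[lo, hi)` with the last bin
#' closed.
#'
#' @param panel a `genotype_panel`
#' @param group a growth-habit label, population label, or `"total"`
#' @param bin_width histogram bin width on `[0, 0.5]`
#' @return list with `breaks`, `counts`, `group`; class `maf_spectrum`
#' @export
maf_spectrum <- function(panel, group, bin_width = 0.05) {
  idx <- if (identical(group, "total")) seq_len(n_lines(panel))
         else which(panel$lines$growth_habit == group |
                      panel$lines$population == group)
  if (!length(idx)) stop("no lines in group '", group, "'")
  st <- locus_stats(panel, idx)
  mafs <- st$maf[st$polymorphic %in% TRUE]
  breaks <- seq(0, 0.5, by = bin_width)
  bin <- findInterval(mafs, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  structure(list(breaks = breaks, counts = counts, group = group),
            class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  cat("MAF spectrum for group '", x$group, "' (", sum(x$counts),
      " polymorphic loci)\n", sep = "")
  lab <- sprintf("[%.2f,%.2f%s", utils::head(x$breaks, -1),
                 x$breaks[-1],
                 c(rep(")", length(x$counts) - 1), "]"))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' Compare two MAF spectra by Pearson chi-square
#'
#' Pearson chi-square on the 2 x B contingency table of bin counts; bins
#' empty in both groups are dropped from the table (and hence from the
#' degrees of freedom).
#'
#' @param spec_a,spec_b `maf_spectrum` objects on identical bin edges
#' @return list `chi2`, `df`, `p`
#' @export
spectrum_chi2 <- function(spec_a, spec_b) {
  if (!isTRUE(all.equal(spec_a$breaks, spec_b$breaks)))
    stop("spectra have different bin edges")
  tab <- rbind(spec_a$counts, spec_b$counts)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2)
    stop("fewer than 2 non-empty bins; use coarser bins")
  if (any(rowSums(tab) == 0))
    stop("a spectrum has zero total count; expected counts would be 0 — ",
         "use coarser bins")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (identical(unname(ct$parameter), 0))
    return(list(chi2 = 0, df = 0L, p = 1))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
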