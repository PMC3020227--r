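#' Construct a genotype panel
#'
#' A `genotype_panel` holds a lines x loci call matrix for a panel of
#' (mostly) inbred lines together with line metadata (population of origin,
#' growth habit) and a genetic map (genome, chromosome, position in cM).
#' Calls are coded `0` (homozygous for allele 1), `1` (heterozygous),
#' `2` (homozygous for allele 2) and `NA` (missing).
#'
#' Loci are stored sorted by (genome, chromosome, position_cM, locus_id) so
#' that window and pair-distance structure is deterministic; ties in map
#' position are broken by locus id.
#'
#' @param calls integer matrix, lines x loci, entries in `{0, 1, 2, NA}`.
#'   Row names (line ids) and column names (locus ids) are taken from
#'   `lines`/`loci` if absent.
#' @param lines data.frame with columns `line_id`, `population`,
#'   `growth_habit`; one row per matrix row.
#' @param loci data.frame with columns `locus_id`, `genome`, `chromosome`,
#'   `position_cM` and optionally `allele1`, `allele2`; one row per matrix
#'   column.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(calls, lines, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)

  need_line <- c("line_id", "population", "growth_habit")
  if (!all(need_line %in% names(lines)))
    stop("line metadata must have columns: ", paste(need_line, collapse = ", "))
  need_loc <- c("locus_id", "genome", "chromosome", "position_cM")
  if (!all(need_loc %in% names(loci)))
    stop("locus map must have columns: ", paste(need_loc, collapse = ", "))
  if (!("allele1" %in% names(loci))) loci$allele1 <- "A"
  if (!("allele2" %in% names(loci))) loci$allele2 <- "B"

  if (nrow(calls) != nrow(lines))
    stop("call matrix has ", nrow(calls), " rows but ", nrow(lines),
         " line records")
  if (ncol(calls) != nrow(loci))
    stop("call matrix has ", ncol(calls), " columns but ", nrow(loci),
         " map entries")
  if (anyDuplicated(lines$line_id))
    stop("duplicated line_id: ",
         paste(unique(lines$line_id[duplicated(lines$line_id)]), collapse = ", "))
  if (anyDuplicated(loci$locus_id))
    stop("duplicated locus_id: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  if (any(loci$position_cM < 0, na.rm = TRUE))
    stop("negative cM position in map")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad))
    stop("non-biallelic call code(s): ", paste(unique(bad), collapse = ", "))
  # each population must map to exactly one growth habit
  ph <- unique(lines[, c("population", "growth_habit")])
  if (anyDuplicated(ph$population))
    stop("population(s) mapped to more than one growth habit: ",
         paste(unique(ph$population[duplicated(ph$population)]), collapse = ", "))

  rownames(calls) <- lines$line_id
  colnames(calls) <- loci$locus_id

  ord <- order(loci$genome, loci$chromosome, loci$position_cM, loci$locus_id)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(loci) <- NULL
  rownames(lines) <- NULL

  structure(list(calls = calls, lines = lines, loci = loci),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$calls), "lines x", ncol(x$calls), "loci\n")
  cat("  populations:", length(unique(x$lines$population)),
      " growth habits:", paste(sort(unique(x$lines$growth_habit)),
                               collapse = "/"), "\n")
  cat("  chromosomes:", length(unique(x$loci$chromosome)),
      " genomes:", paste(sort(unique(x$loci$genome)), collapse = "/"), "\n")
  cs <- summarize_calls(x)
  cat(sprintf("  calls: %.1f%% hom, %.1f%% het, %.1f%% missing\n",
              100 * cs$frac_hom, 100 * cs$frac_het, 100 * cs$frac_missing))
  invisible(x)
}

#' Number of lines / loci in a panel
#' @param panel a `genotype_panel`
#' @return integer count
#' @export
n_lines <- function(panel) nrow(panel$calls)

#' @rdname n_lines
#' @export
n_loci <- function(panel) ncol(panel$calls)

#' Subset a panel by lines or loci
#'
#' @param panel a `genotype_panel`
#' @param lines,loci logical/integer/character index into lines (loci);
#'   `NULL` keeps all.
#' @return a `genotype_panel`
#' @export
subset_panel <- function(panel, lines = NULL, loci = NULL) {
  li <- seq_len(n_lines(panel))
  lo <- seq_len(n_loci(panel))
  if (!is.null(lines)) {
    if (is.character(lines)) lines <- match(lines, panel$lines$line_id)
    li <- li[lines]
  }
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, panel$loci$locus_id)
    lo <- lo[loci]
  }
  genotype_panel(panel$calls[li, lo, drop = FALSE],
                 panel$lines[li, , drop = FALSE],
                 panel$loci[lo, , drop = FALSE])
}

#' Allele frequencies and minor allele frequencies per locus
#'
#' Frequency of allele 2 at each locus, each line contributing one allele
#' copy (inbred lines treated as haploid). Under the default policy
#' heterozygous calls are treated as missing; with `het = "half"` a het call
#' contributes half an allele-2 copy.
#'
#' @param panel a `genotype_panel`
#' @param het heterozygote policy, `"missing"` (default) or `"half"`.
#' @return `allele_freq`: numeric vector of allele-2 frequencies (NaN where
#'   no informative calls); `maf`: `min(p, 1 - p)`.
#' @export
allele_freq <- function(panel, het = c("missing", "half")) {
  het <- match.arg(het)
  m <- panel$calls
  n2 <- colSums(m == 2, na.rm = TRUE)
  nh <- colSums(m == 1, na.rm = TRUE)
  nobs <- colSums(!is.na(m))
  if (het == "missing") {
    p <- n2 / (nobs - nh)
  } else {
    p <- (n2 + 0.5 * nh) / nobs
  }
  names(p) <- panel$loci$locus_id
  p
}

#' @rdname allele_freq
#' @export
maf <- function(panel, het = c("missing", "half")) {
  p <- allele_freq(panel, het)
  pmin(p, 1 - p)
}

#' Treat heterozygous calls as missing
#'
#' Inbred-panel statistics here are computed on haploid allele copies, so
#' residual heterozygous calls (a fraction of a percent in typical panels)
#' are recoded to missing. Idempotent.
#'
#' @param panel a `genotype_panel`
#' @return a `genotype_panel` with every `1` call replaced by `NA`
#' @export
recode_het_missing <- function(panel) {
  m <- panel$calls
  m[!is.na(m) & m == 1L] <- NA_integer_
  genotype_panel(m, panel$lines, panel$loci)
}

#' Summarise call states over a panel
#'
#' Counts and fractions of homozygous, heterozygous and missing calls over
#' the whole call matrix or a subset of loci.
#'
#' @param panel a `genotype_panel`
#' @param loci_subset optional index/character subset of loci
#' @return a `call_summary` list: `n_total`, `n_hom`, `n_het`, `n_missing`
#'   and the corresponding fractions (summing to 1).
#' @export
summarize_calls <- function(panel, loci_subset = NULL) {
  m <- panel$calls
  if (!is.null(loci_subset)) {
    if (is.character(loci_subset))
      loci_subset <- match(loci_subset, panel$loci$locus_id)
    if (!length(loci_subset)) stop("empty loci subset")
    m <- m[, loci_subset, drop = FALSE]
  }
  call_summary(n_hom = sum(m == 0L | m == 2L, na.rm = TRUE),
               n_het = sum(m == 1L, na.rm = TRUE),
               n_missing = sum(is.na(m)))
}

#' Build a call summary from raw counts
#'
#' @param n_hom,n_het,n_missing call-state counts
#' @return a `call_summary` list with counts and fractions
#' @export
call_summary <- function(n_hom, n_het, n_missing) {
  n_total <- n_hom + n_het + n_missing
  structure(list(
    n_total = n_total, n_hom = n_hom, n_het = n_het, n_missing = n_missing,
    frac_hom = if (n_total > 0) n_hom / n_total else 0,
    frac_het = if (n_total > 0) n_het / n_total else 0,
    frac_missing = if (n_total > 0) n_missing / n_total else 0),
    class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  cat(sprintf("calls: %d total; %d hom (%.1f%%), %d het (%.1f%%), %d missing (%.1f%%)\n",
              x$n_total, x$n_hom, 100 * x$frac_hom, x$n_het, 100 * x$frac_het,
              x$n_missing, 100 * x$frac_missing))
  invisible(x)
}

#' Filter loci by missingness, polymorphism and minor allele frequency
#'
#' Rules are applied in order: (1) missing fraction <= `max_missing`;
#' (2) if `keep_polymorphic_only`, at least two alleles observed;
#' (3) MAF above `maf_min` (strict `>` by default, `>=` with
#' `maf_inclusive = TRUE`). MAF uses haploid frequencies with het treated
#' as missing.
#'
#' @param panel a `genotype_panel`
#' @param maf_min minimum minor allele frequency in `[0, 0.5)`
#' @param max_missing maximum per-locus missing-call fraction
#' @param keep_polymorphic_only drop loci with fewer than 2 observed alleles
#' @param maf_inclusive use `>=` instead of strict `>` at the MAF boundary
#' @return a `genotype_panel` with attribute `"filter_report"`: a data.frame
#'   of counts removed per rule in application order.
#' @export
filter_loci <- function(panel, maf_min = 0.05, max_missing = 1,
                        keep_polymorphic_only = TRUE, maf_inclusive = FALSE) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  m <- panel$calls
  keep <- rep(TRUE, ncol(m))

  miss_frac <- colMeans(is.na(m))
  rm_miss <- keep & miss_frac > max_missing
  keep <- keep & !rm_miss

  mono <- rep(FALSE, ncol(m))
  if (keep_polymorphic_only) {
    has1 <- colSums(m == 0L, na.rm = TRUE) + colSums(m == 1L, na.rm = TRUE) > 0
    has2 <- colSums(m == 2L, na.rm = TRUE) + colSums(m == 1L, na.rm = TRUE) > 0
    mono <- keep & !(has1 & has2)
    keep <- keep & !mono
  }

  mafs <- maf(panel)
  low <- if (maf_inclusive) !is.na(mafs) & mafs < maf_min
         else !(!is.na(mafs) & mafs > maf_min)
  low[is.na(mafs)] <- TRUE
  rm_maf <- keep & low
  keep <- keep & !rm_maf

  if (!any(keep))
    stop("all ", ncol(m), " loci removed by filtering; review thresholds ",
         "(maf_min=", maf_min, ", max_missing=", max_missing, ")")

  out <- subset_panel(panel, loci = which(keep))
  attr(out, "filter_report") <- data.frame(
    rule = c("missing_fraction", "monomorphic", "maf"),
    removed = c(sum(rm_miss), sum(mono), sum(rm_maf)),
    stringsAsFactors = FALSE)
  out
}

#' Thin loci to a minimum genetic distance
#'
#' Greedy left-to-right walk per chromosome: keep the first locus, then each
#' next locus at least `min_cM` from the last kept one. Deterministic given
#' the panel's map ordering.
#'
#' @param panel a `genotype_panel`
#' @param min_cM minimum map distance between retained loci
#' @return a thinned `genotype_panel`
#' @export
thin_by_distance <- function(panel, min_cM) {
  stopifnot(min_cM >= 0)
  keep <- logical(n_loci(panel))
  for (chr in unique(panel$loci$chromosome)) {
    idx <- which(panel$loci$chromosome == chr)
    last <- -Inf
    for (i in idx) {
      pos <- panel$loci$position_cM[i]
      if (pos - last >= min_cM) {
        keep[i] <- TRUE
        last <- pos
      }
    }
  }
  subset_panel(panel, loci = which(keep))
}
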