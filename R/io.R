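#' Write a TSV with '#' comment header lines
#'
#' All package writers emit UTF-8, tab-delimited tables with optional header
#' comment lines prefixed by `#`. Used internally by every writer so output
#' bytes are reproducible.
#'
#' @param df data.frame to write
#' @param path output path
#' @param header character vector of comment lines (without leading `#`)
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path, header = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con, sep = "\n")
  # fixed 15-significant-digit formatting keeps reruns byte-identical
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15,
                                               format = "g")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a genotype panel as a TSV trio
#'
#' The panel format is three tab-separated files: a matrix file (first
#' column `line_id`, remaining columns one per locus with calls in
#' `{0,1,2,NA}`), a map file (`locus_id`, `genome`, `chromosome`,
#' `position_cM`, `allele1`, `allele2`) and a metadata file (`line_id`,
#' `population`, `growth_habit`).
#'
#' @param panel a `genotype_panel`
#' @param panel_tsv,map_tsv,meta_tsv output paths
#' @return invisibly, the three paths
#' @export
write_panel <- function(panel, panel_tsv, map_tsv, meta_tsv) {
  mat <- as.data.frame(panel$calls)
  mat <- cbind(line_id = panel$lines$line_id, mat)
  write_tsv(mat, panel_tsv)
  write_tsv(panel$loci[, c("locus_id", "genome", "chromosome", "position_cM",
                           "allele1", "allele2")], map_tsv)
  write_tsv(panel$lines[, c("line_id", "population", "growth_habit")],
            meta_tsv)
  invisible(c(panel_tsv, map_tsv, meta_tsv))
}

#' Read a genotype panel from the TSV trio
#'
#' Every matrix column must have a map entry and every matrix row a metadata
#' entry; violations are hard errors naming the offending id. Loci come back
#' sorted by (genome, chromosome, position_cM, locus_id).
#'
#' @param panel_tsv,map_tsv,meta_tsv paths written by [write_panel()] (or
#'   equivalent)
#' @return a `genotype_panel`
#' @export
read_panel <- function(panel_tsv, map_tsv, meta_tsv) {
  mat <- read_tsv(panel_tsv)
  map <- read_tsv(map_tsv)
  meta <- read_tsv(meta_tsv)
  if (names(mat)[1] != "line_id")
    stop("panel matrix file must start with a line_id column")
  locus_ids <- names(mat)[-1]
  missing_map <- setdiff(locus_ids, map$locus_id)
  if (length(missing_map))
    stop("matrix column(s) absent from map: ",
         paste(missing_map, collapse = ", "))
  missing_meta <- setdiff(mat$line_id, meta$line_id)
  if (length(missing_meta))
    stop("matrix line(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  calls <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(calls))
    stop("non-numeric call code in matrix; calls must be 0, 1, 2 or NA")
  map <- map[match(locus_ids, map$locus_id), , drop = FALSE]
  meta <- meta[match(mat$line_id, meta$line_id), , drop = FALSE]
  genotype_panel(calls, meta, map)
}

#' Read a genotype panel from a VCF
#'
#' Biallelic SNP records only: GT fields `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./. -> NA` (phased separators accepted). Multiallelic
#' records are dropped with a message. cM positions come from the supplied
#' side map (VCF POS is physical, not genetic).
#'
#' @param vcf_path path to a VCF 4.x file
#' @param meta_tsv_path path to the line metadata TSV
#' @param cm_map data.frame with `locus_id`, `genome`, `chromosome`,
#'   `position_cM` (and optionally alleles); locus ids must match VCF ID
#' @return a `genotype_panel` restricted to samples present in the metadata
#' @export
read_vcf <- function(vcf_path, meta_tsv_path, cm_map) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi))
    message("dropping ", sum(multi), " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic SNP records in VCF")

  meta <- read_tsv(meta_tsv_path)
  samples <- intersect(colnames(gt), meta$line_id)
  if (!length(samples))
    stop("no overlap between VCF samples and metadata line ids")
  gt <- gt[, samples, drop = FALSE]

  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  calls <- t(apply(gt, 1, code))          # loci x lines
  calls <- t(calls)                       # lines x loci
  colnames(calls) <- fix$ID
  rownames(calls) <- samples

  cm_map <- as.data.frame(cm_map, stringsAsFactors = FALSE)
  missing_map <- setdiff(fix$ID, cm_map$locus_id)
  if (length(missing_map))
    stop("VCF record(s) absent from cM map: ",
         paste(missing_map, collapse = ", "))
  loci <- cm_map[match(fix$ID, cm_map$locus_id), , drop = FALSE]
  if (!("allele1" %in% names(loci))) loci$allele1 <- fix$REF
  if (!("allele2" %in% names(loci))) loci$allele2 <- fix$ALT
  meta <- meta[match(samples, meta$line_id), , drop = FALSE]
  genotype_panel(calls, meta, loci)
}

#' Write a genotype panel as VCF
#'
#' Companion writer for interoperability: emits a minimal VCF 4.2 with dummy
#' physical positions `round(cM * 1e6)` and the haplotype-coded GT field.
#'
#' @param panel a `genotype_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$lines$line_id),
                     collapse = "\t")), con, sep = "\n")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(n_loci(panel))) {
    g <- panel$calls[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(panel$loci$chromosome[j],
                       format(round(panel$loci$position_cM[j] * 1e6),
                              scientific = FALSE),
                       panel$loci$locus_id[j],
                       panel$loci$allele1[j], panel$loci$allele2[j],
                       ".", "PASS", ".", "GT", gs), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
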