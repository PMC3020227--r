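#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `sim` (a [sim_config()]) or `paths` (a list with
#' `panel_tsv`, `map_tsv`, `meta_tsv`) must be supplied.
#'
#' @param sim a [sim_config()] to generate the input panel, or `NULL`
#' @param paths list of input TSV paths, or `NULL`
#' @param analysis an [analysis_config()]
#' @param stratifications which diversity stratifications to run
#' @param grouping grouping for the differentiation scan
#' @return a `run_config` list
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       analysis = analysis_config(),
                       stratifications = c("total", "growth_habit",
                                           "population"),
                       grouping = "growth_habit") {
  if (is.null(sim) == is.null(paths))
    stop("supply exactly one of a simulation config or input paths")
  structure(list(sim = sim, paths = paths, analysis = analysis,
                 stratifications = stratifications, grouping = grouping),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[!vapply(config, is.function, TRUE)], file = tmp,
       control = c("all", "digits17"))
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages in order: load or simulate the panel; filter loci; diversity
#' tables and MAF spectra; F_ST scan (per-locus, window means, bootstrap
#' threshold, elevated regions) and hierarchical variance components; LD
#' pair table, summaries, decay curve and blocks; report tables. Every
#' output is a '#'-headed TSV carrying the seed and a config hash, and a
#' manifest lists every file with its MD5 checksum, so re-running with the
#' same config reproduces byte-identical outputs.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, a list with the in-memory results and the manifest
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ac <- config$analysis
  hash <- config_hash(config)
  hdr <- c(paste0("panelpopgen pipeline v",
                  as.character(utils::packageVersion("panelpopgen"))),
           paste0("seed=", ac$seed, " config_md5=", hash))
  out <- function(name) file.path(out_dir, name)
  files <- character()
  emit <- function(df, name, extra = character()) {
    write_tsv(df, out(name), header = c(hdr, extra))
    files <<- c(files, name)
  }

  # --- stage: input
  if (!is.null(config$sim)) {
    sim <- simulate_panel(config$sim)
    panel <- sim$panel
    write_panel(panel, out("panel_matrix.tsv"), out("panel_map.tsv"),
                out("panel_meta.tsv"))
    files <- c(files, "panel_matrix.tsv", "panel_map.tsv", "panel_meta.tsv")
    write_truth(sim$truth, out("sim_truth.tsv"))
    files <- c(files, "sim_truth.tsv")
  } else {
    panel <- read_panel(config$paths$panel_tsv, config$paths$map_tsv,
                        config$paths$meta_tsv)
  }

  emit(as.data.frame(unclass(summarize_calls(panel))[1:7]),
       "call_summary.tsv")

  # --- stage: filtering
  filtered <- filter_loci(panel, maf_min = ac$maf_min)
  emit(attr(filtered, "filter_report"), "filter_report.tsv")

  # --- stage: diversity
  div <- list()
  for (s in config$stratifications) {
    dt <- withCallingHandlers(
      diversity_table(filtered, s, min_lines = ac$min_lines),
      warning = function(w) invokeRestart("muffleWarning"))
    div[[s]] <- dt
    emit(dt, paste0("diversity_", s, ".tsv"))
  }
  habits <- sort(unique(filtered$lines$growth_habit))
  spectra <- lapply(habits, function(h) maf_spectrum(filtered, h))
  names(spectra) <- habits
  spec_df <- do.call(rbind, lapply(spectra, function(sp)
    data.frame(group = sp$group, bin_lo = utils::head(sp$breaks, -1),
               bin_hi = sp$breaks[-1], count = sp$counts,
               stringsAsFactors = FALSE)))
  emit(spec_df, "maf_spectra.tsv")
  chi <- if (length(spectra) == 2)
    spectrum_chi2(spectra[[1]], spectra[[2]]) else NULL
  if (!is.null(chi))
    emit(data.frame(chi2 = chi$chi2, df = chi$df, p = chi$p),
         "maf_spectrum_chi2.tsv")

  # --- stage: differentiation
  scan <- fst_scan(filtered, config$grouping, ac)
  emit(scan$per_locus, "fst_per_locus.tsv",
       extra = paste0("threshold=", format(scan$threshold, digits = 15)))
  emit(scan$windows, "fst_windows.tsv")
  emit(scan$regions, "fst_elevated_regions.tsv",
       extra = paste0("threshold=", format(scan$threshold, digits = 15)))
  emit(scan$summary$by_chromosome, "fst_summary_chromosome.tsv")
  emit(scan$summary$by_genome, "fst_summary_genome.tsv")
  vc <- hierarchical_components(filtered, min_lines = ac$min_lines)
  emit(data.frame(component = names(vc$percent),
                  raw = unname(vc$components),
                  percent = unname(vc$percent),
                  truncated = unname(vc$truncated)),
       "variance_components.tsv")

  # --- stage: LD
  ld <- ld_analysis(filtered, ac)
  emit(as.data.frame(ld$pairs), "ld_pairs.tsv")
  smry <- ld$summary
  emit(data.frame(statistic = c("n_intra_pairs", "n_intra_significant",
                                "mean_extent_cM", "median_extent_cM",
                                "prop_loci_with_sig_linked_pair",
                                "n_inter_pairs", "prop_inter_significant",
                                "background_ld", "r2_cutoff_realized"),
                  value = c(smry$n_intra_pairs, smry$n_intra_significant,
                            smry$mean_extent_cM, smry$median_extent_cM,
                            smry$prop_loci_with_sig_linked_pair,
                            smry$n_inter_pairs, smry$prop_inter_significant,
                            smry$background_ld, smry$r2_cutoff_realized)),
       "ld_summary.tsv")
  emit(smry$by_genome, "ld_summary_genome.tsv")
  if (!is.null(ld$decay))
    emit(ld$decay$grid, "ld_decay.tsv",
         extra = sprintf("initial_ld=%.6g half_decay_cM=%s",
                         ld$decay$initial_ld,
                         if (ld$decay$reached)
                           format(ld$decay$half_decay_cM, digits = 15)
                         else "NOT_REACHED"))
  if (!is.null(ld$blocks)) emit(ld$blocks, "ld_blocks.tsv")

  # --- stage: report
  results <- list(panel = panel, filtered = filtered, diversity = div,
                  spectra = spectra, spectrum_chi2 = chi, scan = scan,
                  variance_components = vc, ld = ld)
  rep_files <- make_report(results, out_dir, header = hdr)
  files <- c(files, rep_files)

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, out("manifest.tsv"))
  invisible(c(results, list(manifest = manifest, out_dir = out_dir)))
}

#' Emit publication-style report tables
#'
#' Writes the panel-accounting table (per-genome assayed / retained /
#' polymorphic counts with mean allele number and PIC), the per-population
#' diversity table, the variance-components table, the per-chromosome and
#' per-genome F_ST means/SDs, the elevated-interval table and the LD
#' summary, shaped like the usual panel-characterisation tables.
#'
#' @param results the list produced inside [run_pipeline()]
#' @param out_dir output directory
#' @param header comment-header lines
#' @return character vector of file names written
#' @export
make_report <- function(results, out_dir, header = character()) {
  files <- character()
  emit <- function(df, name) {
    write_tsv(df, file.path(out_dir, name), header = header)
    files <<- c(files, name)
  }
  # genome-level accounting: assayed = input loci, good = post-filter
  panel <- results$panel; filtered <- results$filtered
  st <- locus_stats(filtered)
  acct <- do.call(rbind, lapply(sort(unique(panel$loci$genome)), function(g) {
    assayed <- sum(panel$loci$genome == g)
    keep <- filtered$loci$genome == g
    good <- sum(keep)
    data.frame(genome = g, assayed = assayed, failed = assayed - good,
               good = good, polymorphic = sum(st$polymorphic[keep]),
               mean_alleles = mean(st$n_alleles[keep]),
               mean_pic = mean(st$pic[keep], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  total <- data.frame(genome = "total", assayed = sum(acct$assayed),
                      failed = sum(acct$failed), good = sum(acct$good),
                      polymorphic = sum(acct$polymorphic),
                      mean_alleles = mean(st$n_alleles),
                      mean_pic = mean(st$pic, na.rm = TRUE))
  emit(rbind(acct, total), "report_panel_accounting.tsv")
  if (!is.null(results$diversity$population))
    emit(results$diversity$population, "report_diversity.tsv")
  vc <- results$variance_components
  emit(data.frame(component = names(vc$percent),
                  percent = unname(vc$percent)),
       "report_variance_components.tsv")
  emit(results$scan$summary$by_chromosome, "report_fst_by_chromosome.tsv")
  emit(results$scan$regions, "report_elevated_intervals.tsv")
  emit(results$ld$summary$by_genome, "report_ld_by_genome.tsv")
  files
}

#' Read a plain-text key = value run configuration
#'
#' Minimal TOML-style file: `key = value` lines, `#` comments. Recognised
#' keys are the [sim_config()] and [analysis_config()] scalar arguments
#' plus `panel_tsv`, `map_tsv`, `meta_tsv`, `grouping`. Planted regions use
#' `planted_region = chromosome:start:end:delta` (repeatable).
#'
#' @param path config file path
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))
  keys <- vapply(kv, function(x) if (length(x)) x[2] else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x)) x[3] else NA_character_, "")
  if (anyNA(keys)) stop("unparseable config line: ",
                        ln[which(is.na(keys))[1]])
  get1 <- function(k, default = NULL, as = identity) {
    i <- which(keys == k)
    if (!length(i)) return(default)
    as(vals[i[length(i)]])
  }
  num <- function(v) as.numeric(v)
  ac <- analysis_config(
    W = get1("W", 5, num), B = get1("B", 1000, num),
    percentile = get1("percentile", 95, num),
    fdr_q = get1("fdr_q", 0.01, num), maf_min = get1("maf_min", 0.05, num),
    thin_cM = get1("thin_cM", 4, num),
    min_lines = get1("min_lines", 5, num),
    min_complete = get1("min_complete", 10, num),
    seed = get1("seed", 1, num))
  if (!is.null(get1("panel_tsv"))) {
    rc <- run_config(paths = list(panel_tsv = get1("panel_tsv"),
                                  map_tsv = get1("map_tsv"),
                                  meta_tsv = get1("meta_tsv")),
                     analysis = ac,
                     grouping = get1("grouping", "growth_habit"))
  } else {
    regions <- NULL
    ri <- which(keys == "planted_region")
    if (length(ri)) {
      parts <- strsplit(vals[ri], ":", fixed = TRUE)
      regions <- data.frame(
        chromosome = vapply(parts, `[`, "", 1),
        start_cM = as.numeric(vapply(parts, `[`, "", 2)),
        end_cM = as.numeric(vapply(parts, `[`, "", 3)),
        delta = as.numeric(vapply(parts, `[`, "", 4)),
        stringsAsFactors = FALSE)
    }
    n_chr <- get1("n_chromosomes", 21, num)
    chrs <- default_chromosomes()[seq_len(n_chr), , drop = FALSE]
    sc <- sim_config(
      fst_target = get1("fst_target", 0.10, num),
      n_founders = get1("n_founders", 10, num),
      generations = get1("generations", 5, num),
      het_rate = get1("het_rate", 0.005, num),
      missing_rate = get1("missing_rate", 0.009, num),
      ascertain_maf_min = get1("ascertain_maf_min", 0.05, num),
      chromosomes = chrs,
      loci_per_chromosome =
        default_loci_per_chromosome()[chrs$chromosome],
      planted_regions = regions,
      seed = get1("seed", 1, num))
    rc <- run_config(sim = sc, analysis = ac,
                     grouping = get1("grouping", "growth_habit"))
  }
  rc
}
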