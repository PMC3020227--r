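# random 2x2 gamete table with nonzero margins
random_table <- function() {
  repeat {
    cnt <- c(rmultinom(1, sample(20:60, 1), runif(4, 0.05, 1)))
    if (all(c(cnt[1] + cnt[2], cnt[3] + cnt[4],
              cnt[1] + cnt[3], cnt[2] + cnt[4]) > 0)) return(cnt)
  }
}

test_that("haplotype counts use lines complete and homozygous at both loci", {
  p <- toy_panel(cbind(c(0, 0, 2, 2, NA, 1, 0),
                       c(0, 0, 2, 2, 2, 0, NA)))
  expect_equal(unname(haplotype_counts(p, 1, 2)), c(2, 0, 0, 2))
  # identical columns -> off-diagonal zero; complementary -> diagonal zero
  q <- toy_panel(cbind(c(0, 2, 0, 2), c(0, 2, 0, 2), c(2, 0, 2, 0)))
  expect_equal(unname(haplotype_counts(q, 1, 2)), c(2, 0, 0, 2))
  expect_equal(unname(haplotype_counts(q, 1, 3)), c(0, 2, 2, 0))
  expect_equal(unname(haplotype_counts(q, "s001", "s003")),
               unname(haplotype_counts(q, 1, 3)))
})

test_that("r2 follows the allele-frequency correlation formula", {
  expect_equal(r_squared(c(10, 0, 0, 10)), 1)
  expect_equal(r_squared(c(25, 25, 25, 25)), 0)
  # hand evaluation: D = 0.4 - 0.25 = 0.15, r2 = 0.15^2 / 0.25^2 = 0.36
  expect_equal(r_squared(c(40, 10, 10, 40)), 0.36)
  expect_true(is.na(r_squared(c(10, 10, 0, 0))))  # monomorphic margin

  # equality with the squared Pearson correlation of the 0/1 vectors
  set.seed(17)
  for (i in 1:100) {
    cnt <- random_table()
    a <- rep(c(0, 0, 1, 1), cnt)
    b <- rep(c(0, 1, 0, 1), cnt)
    expect_equal(r_squared(cnt), cor(a, b)^2, tolerance = 1e-12)
  }
})

test_that("D-prime and its likelihood CI behave at the boundaries", {
  # one gamete class absent -> D' = 1
  expect_equal(d_prime_ci(c(10, 5, 0, 5))$dprime, 1)
  expect_equal(d_prime_ci(c(25, 25, 25, 25))$dprime, 0)
  ci <- d_prime_ci(c(40, 10, 10, 40))
  expect_lte(ci$low, ci$dprime + 1e-9)
  expect_gte(ci$high, ci$dprime - 1e-9)
  expect_null(d_prime_ci(c(10, 10, 0, 0)))

  # grid-refinement oracle: default grid within 0.01 of a 10^4-point grid
  set.seed(18)
  for (i in 1:20) {
    cnt <- random_table()
    a <- d_prime_ci(cnt)
    if (is.null(a)) next
    b <- d_prime_ci(cnt, grid_size = 10001)
    expect_lt(abs(a$low - b$low), 0.011)
    expect_lt(abs(a$high - b$high), 0.011)
  }
})

test_that("the exact test reproduces hypergeometric enumeration", {
  # complete association at n = 20: two extreme tables of C(20,10)
  expect_equal(exact_test(c(10, 0, 0, 10)), 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(exact_test(c(5, 5, 5, 5)), 1)  # modal table

  set.seed(19)
  for (i in 1:100) {
    cnt <- random_table()
    expect_equal(exact_test(cnt), enum_exact_p(cnt), tolerance = 1e-12)
  }

  # symmetry under row swap, column swap and transposition
  cnt <- c(12, 3, 7, 18)
  expect_equal(exact_test(cnt), exact_test(cnt[c(3, 4, 1, 2)]))
  expect_equal(exact_test(cnt), exact_test(cnt[c(2, 1, 4, 3)]))
  expect_equal(exact_test(cnt), exact_test(cnt[c(1, 3, 2, 4)]))

  # independent cross-check against the standard two-sided Fisher test
  for (i in 1:20) {
    cnt <- random_table()
    ft <- fisher.test(matrix(cnt, 2, byrow = TRUE))$p.value
    expect_equal(exact_test(cnt), ft, tolerance = 1e-7)
  }
})

test_that("BH FDR matches the step-up rule", {
  r <- bh_fdr(c(0.001, 0.002, 0.5), q = 0.01)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE))
  r1 <- bh_fdr(rep(1, 5), q = 0.05)
  expect_false(any(r1$reject))
  expect_true(all(r1$q_values == 1))
  expect_length(bh_fdr(numeric())$reject, 0)

  set.seed(20)
  for (i in 1:100) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q)$reject, stepup_reject(p, q))
  }
})

test_that("BH at level q controls false rejections on uniform p-values", {
  set.seed(21)
  fr <- vapply(1:200, function(i) mean(bh_fdr(runif(100), 0.01)$reject), 0)
  expect_lt(mean(fr), 0.01 + 3 * sd(fr) / sqrt(200))
})

test_that("the pair table agrees with direct per-pair recomputation", {
  p <- recode_het_missing(random_panel(23, n_lines = 40, n_loci = 12))
  cfg <- analysis_config(maf_min = 0.05, min_complete = 10)
  tab <- ld_pairs(p, cfg)
  mafs <- maf(p)
  kept <- p$loci$locus_id[!is.na(mafs) & mafs > 0.05]
  for (k in sample(nrow(tab), 10)) {
    i <- tab$locus_i[k]; j <- tab$locus_j[k]
    expect_true(all(c(i, j) %in% kept))
    cnt <- haplotype_counts(p, i, j)
    expect_equal(tab$n_complete[k], sum(cnt))
    expect_equal(tab$r2[k], r_squared(cnt))
    expect_equal(tab$p_exact[k], exact_test(cnt))
    ii <- match(i, p$loci$locus_id); jj <- match(j, p$loci$locus_id)
    if (p$loci$chromosome[ii] == p$loci$chromosome[jj])
      expect_equal(tab$distance_cM[k],
                   abs(p$loci$position_cM[ii] - p$loci$position_cM[jj]))
    else expect_true(is.na(tab$distance_cM[k]))
  }
  expect_equal(tab$q_bh, p.adjust(tab$p_exact, "BH"))
})

test_that("LD summaries recompute from the pair table", {
  mk_pairs <- function(df) {
    class(df) <- c("ld_pairs", "data.frame")
    df
  }
  base <- data.frame(
    locus_i = c("a", "a", "b", "x"), locus_j = c("b", "c", "c", "y"),
    chromosome_i = c("1A", "1A", "1A", "1A"),
    chromosome_j = c("1A", "1A", "1A", "2A"),
    genome_i = "A", genome_j = "A",
    distance_cM = c(7, 7, 7, NA), intra = c(TRUE, TRUE, TRUE, FALSE),
    n_complete = 30, r2 = c(0.5, 0.4, 0.3, 0.12),
    dprime = 1, p_exact = 1e-5, q_bh = 1e-4,
    significant = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  s <- ld_summary(mk_pairs(base))
  expect_equal(s$mean_extent_cM, 7)
  expect_equal(s$median_extent_cM, 7)
  expect_equal(s$prop_loci_with_sig_linked_pair, 1)
  expect_equal(s$background_ld, 0.12)  # constant inter-chromosomal r2
  expect_equal(s$prop_inter_significant, 0)
  expect_equal(s$r2_cutoff_realized, 0.3)

  # synthetic panel: summary equals direct recomputation from the table
  p <- recode_het_missing(random_panel(24, n_lines = 50, n_loci = 16))
  tab <- ld_pairs(p, analysis_config())
  s2 <- ld_summary(tab)
  intra <- tab[tab$intra, ]
  inter <- tab[!tab$intra, ]
  sig <- intra[intra$significant, ]
  expect_equal(s2$n_intra_significant, nrow(sig))
  if (nrow(sig)) {
    expect_equal(s2$mean_extent_cM, mean(sig$distance_cM))
    expect_equal(s2$median_extent_cM, median(sig$distance_cM))
  }
  expect_equal(s2$prop_inter_significant, mean(inter$significant))
  expect_equal(s2$background_ld, unname(quantile(inter$r2, 0.95)))

  # per-locus extent variant: max significant distance per locus
  s3 <- ld_summary(mk_pairs(rbind(base,
    within(base[1, ], { locus_j <- "d"; distance_cM <- 20 }))),
    extent = "per_locus")
  # per-locus maxima: a=20, b=7, c=7, d=20
  expect_equal(s3$mean_extent_cM, mean(c(20, 7, 7, 20)))
})

test_that("decay curves find the half-decay distance", {
  mk_pairs <- function(d, r2) data.frame(distance_cM = d, r2 = r2,
                                         intra = TRUE)
  # linear decay from 0.8 at 0 cM to 0 at 80 cM: half-decay ~ 40
  d <- seq(0, 80, length.out = 200)
  dc <- decay_curve(mk_pairs(d, 0.8 * (1 - d / 80)))
  expect_equal(dc$initial_ld, 0.8, tolerance = 0.02)
  expect_equal(dc$half_decay_cM, 40, tolerance = 1)

  # constant r2 never halves
  dc2 <- decay_curve(mk_pairs(d, rep(0.3, 200)))
  expect_false(dc2$reached)
  expect_true(is.na(dc2$half_decay_cM))

  expect_error(decay_curve(mk_pairs(d[1:10], rep(0.3, 10))), "at least 30")

  # closed-form exponential: half-decay at 10 ln 2 = 6.93 cM.  A narrow
  # span limits the flattening bias of the smoother near the origin.
  set.seed(25)
  d3 <- runif(2000, 0, 50)
  r3 <- pmax(0, 0.5 * exp(-d3 / 10) + rnorm(2000, 0, 0.02))
  dc3 <- decay_curve(mk_pairs(d3, r3), span = 0.2)
  expect_lt(abs(dc3$half_decay_cM - 10 * log(2)), 1)

  # half-decay increases with the simulated LD scale
  hd <- vapply(c(5, 10, 20), function(lam) {
    mean(vapply(1:5, function(s) {
      set.seed(1000 * lam + s)
      dd <- runif(1500, 0, 60)
      rr <- pmax(0, 0.5 * exp(-dd / lam) + rnorm(1500, 0, 0.02))
      decay_curve(mk_pairs(dd, rr))$half_decay_cM
    }, 0))
  }, 0)
  expect_true(all(diff(hd) > 0))
})

test_that("block detection matches the confidence-bound rule", {
  # five loci with zero historical recombination: identical columns, n = 50
  col <- c(rep(0L, 25), rep(2L, 25))
  p <- toy_panel(matrix(rep(col, 5), ncol = 5),
                 positions = c(1, 2, 3, 4, 5))
  b <- gabriel_blocks(p)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_loci, 5)
  expect_equal(b$start_cM, 1)
  expect_equal(b$end_cM, 5)

  # independent loci yield no blocks
  set.seed(26)
  q <- toy_panel(matrix(2L * rbinom(50 * 6, 1, 0.5), ncol = 6),
                 positions = 1:6)
  expect_equal(nrow(gabriel_blocks(q)), 0)

  # planted 6-locus low-recombination run inside independent flankers,
  # verified against hand classification of every pair
  set.seed(27)
  n <- 100
  core <- c(rep(0L, 50), rep(2L, 50))
  block_cols <- vapply(1:6, function(j) {
    v <- core
    v[j] <- 2L - v[j]  # one mutation per locus keeps D' CIs tight
    v
  }, integer(n))
  flank <- vapply(1:3, function(j) 2L * rbinom(n, 1, 0.5), integer(n))
  p2 <- toy_panel(cbind(flank[, 1:2], block_cols, flank[, 3, drop = FALSE]),
                  positions = c(1, 4, 8:13, 20))
  b2 <- gabriel_blocks(p2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$start_cM, 8)
  expect_equal(b2$end_cM, 13)
  expect_equal(b2$n_loci, 6)

  # hand classification: every pair inside the block must be strong LD by
  # the CI rule, and the block loci are exactly the planted run
  ids <- strsplit(b2$loci, ",")[[1]]
  pos <- p2$loci$position_cM[match(ids, p2$loci$locus_id)]
  expect_setequal(pos, 8:13)
  for (a in 1:5) for (bb in (a + 1):6) {
    ci <- d_prime_ci(haplotype_counts(p2, ids[a], ids[bb]))
    expect_gte(ci$low, 0.70)
    expect_gte(ci$high, 0.98)
  }
})

test_that("significant linked LD exceeds the background on simulated panels", {
  for (s in 1:3) {
    p <- simulate_panel(test_sim_config(seed = 600 + s, n_chr = 4,
                                        loci_per_chr = 30))$panel
    tab <- ld_pairs(p, analysis_config())
    sig <- tab$r2[tab$intra & tab$significant]
    bg <- quantile(tab$r2[!tab$intra], 0.95)
    if (length(sig)) expect_gte(mean(sig), unname(bg))
  }
})

test_that("r2 matrices are symmetric with unit diagonal", {
  p <- recode_het_missing(random_panel(28, n_lines = 40, n_loci = 10))
  tab <- ld_pairs(p, analysis_config())
  chr <- tab$chromosome_i[tab$intra][1]
  m <- r2_matrix(tab, chr)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
  expect_equal(m[tab$locus_i[tab$intra][1], tab$locus_j[tab$intra][1]],
               tab$r2[tab$intra][1])
})
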