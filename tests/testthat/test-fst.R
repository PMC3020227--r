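# two-population toy: n1 lines with freq p1 of allele 2, n2 with p2
two_pop_panel <- function(n1, p1, n2, p2) {
  mk <- function(n, p) 2L * c(rep(1L, round(n * p)), rep(0L, n - round(n * p)))
  toy_panel(matrix(c(mk(n1, p1), mk(n2, p2)), ncol = 1),
            population = rep(c("P1", "P2"), c(n1, n2)),
            growth_habit = rep(c("spring", "winter"), c(n1, n2)))
}

test_that("theta hits the analytic limits of complete and null differentiation", {
  # fixed opposite alleles -> theta = 1 for any sizes >= 2
  for (sz in list(c(10, 10), c(2, 7), c(5, 3))) {
    p <- two_pop_panel(sz[1], 0, sz[2], 1)
    expect_equal(wc_theta(p, "population")$theta, 1)
  }
  # identical non-degenerate sample frequencies -> MSP = 0, theta <= 0
  p <- two_pop_panel(8, 0.5, 8, 0.5)
  expect_lte(wc_theta(p, "population")$theta, 0)
  # pooled-monomorphic locus flagged undefined
  mono <- two_pop_panel(5, 0, 5, 0)
  expect_true(is.na(wc_theta(mono, "population")$theta))
  expect_error(wc_theta(two_pop_panel(5, 0.5, 5, 0.5), rep("g", 10)),
               "at least 2 groups")
})

test_that("theta equals the brute-force ANOVA variance-component estimate", {
  # the worked 4+4 case
  p <- two_pop_panel(4, 0.75, 4, 0.25)
  g <- factor(p$lines$population)
  x <- p$calls[, 1] / 2
  expect_equal(wc_theta(p, "population")$theta, aov_theta(x, g),
               tolerance = 1e-12)

  # 100 random small instances (2-4 pops, 2-6 lines each, with missing)
  set.seed(42)
  for (i in 1:100) {
    r <- sample(2:4, 1)
    n_i <- sample(2:6, r, replace = TRUE)
    x <- unlist(lapply(n_i, function(n) rbinom(n, 1, runif(1, 0.1, 0.9))))
    g <- factor(rep(seq_len(r), n_i))
    if (runif(1) < 0.3) x[sample(length(x), 1)] <- NA
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) next
    if (any(tapply(ok, g, sum) == 0)) next
    pan <- toy_panel(matrix(2L * x, ncol = 1),
                     population = paste0("P", as.integer(g)),
                     growth_habit = ifelse(as.integer(g) == 1, "spring",
                                           "winter"))
    got <- wc_theta(pan, "population")$theta
    want <- aov_theta(x, g)
    if (is.na(want) || is.nan(want)) next
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("random group labels drive mean theta to zero", {
  sim <- simulate_panel(test_sim_config(seed = 77, n_chr = 10,
                                        loci_per_chr = 50,
                                        n_founders = 500))
  means <- vapply(1:100, function(i) {
    set.seed(i)
    g <- sample(sim$panel$lines$growth_habit)
    mean(wc_theta(sim$panel, g)$theta, na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(means)), 0.01)
})

test_that("per-unit summaries report means, SDs and window SDs", {
  res <- data.frame(locus_id = sprintf("s%02d", 1:12),
                    genome = "A",
                    chromosome = rep(c("1A", "2A"), c(8, 4)),
                    position_cM = c(1:8, 1:4),
                    theta = c(rep(0.3, 8), 0.1, 0.2, 0.3, NA))
  s <- fst_summary(res, W = 5)
  c1 <- s$by_chromosome[s$by_chromosome$unit == "1A", ]
  expect_equal(c1$mean_theta, 0.3)
  expect_equal(c1$sd_theta, 0)        # constant vector
  expect_equal(c1$sd_window, 0)
  c2 <- s$by_chromosome[s$by_chromosome$unit == "2A", ]
  expect_equal(c2$n_loci, 3)          # NA theta excluded
  expect_true(is.na(c2$sd_window))    # fewer than W defined loci
  one <- fst_summary(res[res$locus_id == "s01", , drop = FALSE], W = 5)
  expect_true(is.na(one$by_chromosome$sd_theta))  # single-locus chromosome

  # toy vector vs direct mean/sd
  set.seed(5)
  rv <- data.frame(locus_id = sprintf("r%02d", 1:20), genome = "B",
                   chromosome = "1B", position_cM = 1:20,
                   theta = runif(20, -0.05, 0.6))
  sv <- fst_summary(rv, W = 5)
  expect_equal(sv$overall$mean_theta, mean(rv$theta))
  expect_equal(sv$overall$sd_theta, sd(rv$theta))
})

test_that("sliding windows are chromosome-bounded step-1 means over defined loci", {
  res <- data.frame(locus_id = sprintf("s%02d", 1:7), genome = "A",
                    chromosome = "1A", position_cM = 1:7,
                    theta = c(0, 0, 1, 0, 0, 0, 0))
  w <- sliding_window_means(res, 5)
  expect_equal(w$mean_theta, c(0.2, 0.2, 0.2))
  expect_equal(w$start_cM, 1:3)
  expect_equal(w$end_cM, 5:7)

  # constant theta -> all windows equal; conservation of member means
  res$theta <- 0.37
  expect_true(all(sliding_window_means(res, 5)$mean_theta == 0.37))

  # random vector vs direct rolling mean, undefined loci dropped first
  set.seed(9)
  rv <- data.frame(locus_id = sprintf("r%02d", 1:30), genome = "A",
                   chromosome = rep(c("1A", "2A"), each = 15),
                   position_cM = rep(1:15, 2),
                   theta = runif(30))
  rv$theta[c(4, 20)] <- NA
  w2 <- sliding_window_means(rv, 5)
  roll <- function(v, W) vapply(seq_len(length(v) - W + 1),
                                function(s) mean(v[s:(s + W - 1)]), 0)
  ref <- c(roll(rv$theta[rv$chromosome == "1A" & !is.na(rv$theta)], 5),
           roll(rv$theta[rv$chromosome == "2A" & !is.na(rv$theta)], 5))
  expect_equal(w2$mean_theta, ref)
  # chromosomes shorter than W yield no windows
  expect_equal(nrow(sliding_window_means(rv[1:3, ], 5)), 0)
})

test_that("bootstrap threshold matches a large Monte-Carlo null", {
  cst <- data.frame(locus_id = letters[1:10], genome = "A",
                    chromosome = "1A", position_cM = 1:10, theta = 0.1)
  expect_equal(bootstrap_threshold(cst, W = 5, B = 50, seed = 3), 0.1)

  set.seed(1)
  res <- data.frame(locus_id = sprintf("u%04d", 1:2000), genome = "A",
                    chromosome = "1A", position_cM = 1:2000,
                    theta = runif(2000))
  thr <- bootstrap_threshold(res, W = 5, B = 2e5, percentile = 95, seed = 4)
  # independent oracle: 95th percentile of mean-of-5-uniforms, 1e6 reps
  set.seed(123456)
  oracle <- quantile(colMeans(matrix(runif(5e6), nrow = 5)), 0.95)
  expect_equal(thr, unname(oracle), tolerance = 0.005 / unname(oracle))

  expect_identical(bootstrap_threshold(res, 5, 1000, 95, seed = 9),
                   bootstrap_threshold(res, 5, 1000, 95, seed = 9))
  expect_error(bootstrap_threshold(cst[1:3, ], W = 5), "fewer defined loci")
})

test_that("elevated regions are maximal merges of above-threshold windows", {
  w <- data.frame(genome = "A", chromosome = "5A",
                  start_cM = c(80, 90, 100, 120), end_cM = c(95, 105, 115, 138),
                  loci = "x", mean_theta = c(0.5, 0.6, 0.2, 0.55))
  r <- elevated_regions(w, 0.4)
  expect_equal(nrow(r), 2)
  expect_equal(r$start_cM, c(80, 120))
  expect_equal(r$end_cM, c(105, 138))
  expect_equal(r$mean_theta, c(0.55, 0.55))
  expect_equal(nrow(elevated_regions(w, 0.9)), 0)
  # single above-threshold window spanning 80-138
  w1 <- data.frame(genome = "A", chromosome = "5A", start_cM = 80,
                   end_cM = 138, loci = "x", mean_theta = 0.44)
  r1 <- elevated_regions(w1, 0.2)
  expect_equal(r1[, c("start_cM", "end_cM")],
               data.frame(start_cM = 80, end_cM = 138))
})

test_that("window means reduce variance relative to single loci", {
  sim <- simulate_panel(test_sim_config(seed = 31))
  scan <- fst_scan(sim$panel, "growth_habit", analysis_config(seed = 2))
  bc <- scan$summary$by_chromosome
  ok <- !is.na(bc$sd_window)
  expect_true(all(bc$sd_window[ok] <= bc$sd_theta[ok]))
  # window means conserve member means (already checked by construction):
  # re-derive one window from per-locus values
  w1 <- scan$windows[1, ]
  ids <- strsplit(w1$loci, ",")[[1]]
  expect_equal(w1$mean_theta,
               mean(scan$per_locus$theta[match(ids,
                                               scan$per_locus$locus_id)]))
})

test_that("hierarchical components recover limiting partitions", {
  # two groups fixed for opposite alleles, identical pops within groups
  calls <- matrix(rep(c(0L, 2L), c(20, 20)), ncol = 1)
  p <- toy_panel(cbind(calls, calls, calls),
                 population = rep(c("P1", "P2", "P3", "P4"), each = 10),
                 growth_habit = rep(c("spring", "winter"), each = 20))
  vc <- hierarchical_components(p)
  expect_gt(vc$percent["among_groups"], 99)
  expect_equal(sum(vc$percent), 100, tolerance = 0.01)

  # no structure: among components each small on a 500-locus simulation
  set.seed(6)
  calls2 <- matrix(2L * rbinom(120 * 500, 1, rep(runif(500, 0.2, 0.8),
                                                 each = 120)),
                   nrow = 120)
  p2 <- toy_panel(calls2, positions = seq_len(500),
                  chromosome = rep("1A", 500),
                  population = rep(paste0("P", 1:6), each = 20),
                  growth_habit = rep(c("spring", "winter"), each = 60))
  vc2 <- hierarchical_components(p2)
  expect_lt(vc2$percent["among_groups"], 2)
  expect_lt(vc2$percent["among_pops_within_group"], 2)

  # single-group analysis collapses to two components
  vc3 <- hierarchical_components(subset_panel(
    p2, lines = which(p2$lines$growth_habit == "spring")))
  expect_false(vc3$two_level)
  expect_equal(unname(vc3$percent["among_groups"]), 0)
})

test_that("hierarchical components equal a brute-force sums-of-squares evaluation", {
  set.seed(14)
  # unbalanced 2 groups x 2 pops each, one locus
  n_pp <- c(6, 9, 7, 11)
  pops <- rep(c("P1", "P2", "P3", "P4"), n_pp)
  grps <- rep(c("spring", "winter"), c(15, 18))
  x <- rbinom(33, 1, rep(c(0.2, 0.4, 0.6, 0.8), n_pp))
  p <- toy_panel(matrix(2L * x, ncol = 1), population = pops,
                 growth_habit = grps)
  vc <- hierarchical_components(p, min_lines = 1)

  # brute force with explicit loops
  N <- length(x); G <- 2; P <- 4
  gmean <- tapply(x, grps, mean); pmean <- tapply(x, pops, mean)
  gn <- tapply(x, grps, length); pn <- tapply(x, pops, length)
  pg <- c(P1 = "spring", P2 = "spring", P3 = "winter", P4 = "winter")
  ss_w <- sum((x - pmean[pops])^2)
  ss_p <- sum(pn * (pmean - gmean[pg])^2)
  ss_g <- sum(gn * (gmean - mean(x))^2)
  ms_w <- ss_w / (N - P); ms_p <- ss_p / (P - G); ms_g <- ss_g / (G - 1)
  spn2g <- tapply(pn^2, pg, sum)
  k1 <- (N - sum(spn2g / gn)) / (P - G)
  k2 <- (sum(spn2g / gn) - sum(pn^2) / N) / (G - 1)
  k3 <- (N - sum(gn^2) / N) / (G - 1)
  s2w <- ms_w
  s2p <- (ms_p - ms_w) / k1
  s2g <- (ms_g - ms_w - k2 * s2p) / k3
  raw <- c(group = s2g, pop = s2p, within = s2w)
  raw[raw < 0] <- 0
  expect_equal(unname(vc$components), unname(raw), tolerance = 1e-9)
  expect_equal(unname(vc$percent),
               unname(100 * raw / sum(raw)), tolerance = 1e-9)
})
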