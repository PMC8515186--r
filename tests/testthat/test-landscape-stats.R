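test_that("zone assignment follows the layout segments", {
  lay <- tiny_layout(1)   # Z1 1-4.5Mb / Z2 -37.5 / Z3 -62.5 / Z2 -95.5 / Z1 -100
  z <- assign_zone(tibble::tibble(chrom = "1H",
                                  pos = c(1e6, 5e7, 30e6, 96e6)), lay)
  expect_identical(z$zone, c("Z1", "Z3", "Z2", "Z1"))
  expect_identical(z$arm, c("S", "C", "S", "L"))

  # 1 bp left of the distal Z2/Z1 boundary still belongs to Z2
  b <- lay$end[lay$zone == "Z2" & lay$arm == "L"]
  expect_identical(assign_zone(tibble::tibble(chrom = "1H", pos = b), lay)$zone, "Z2")
  expect_identical(assign_zone(tibble::tibble(chrom = "1H", pos = b + 1), lay)$zone, "Z1")

  expect_error(assign_zone(tibble::tibble(chrom = "1H", pos = 2e8), lay),
               "outside")
  expect_error(assign_zone(tibble::tibble(chrom = "9H", pos = 1), lay),
               "absent")
})

test_that("uniformly placed markers split across zones by physical share", {
  lay <- tiny_layout(1)
  set.seed(3)
  mm <- tibble::tibble(marker = sprintf("m%05d", 1:20000), chrom = "1H",
                       pos = sort(sample.int(1e8, 20000)))
  z <- assign_zone(mm[c("chrom", "pos")], lay)
  shares <- as.vector(table(z$zone)) / nrow(mm)
  phys <- c(0.09, 0.66, 0.25)
  expect_equal(shares, phys, tolerance = 0.05)
})

test_that("zone summary aggregates cM, scores and marker densities", {
  lay <- tiny_layout(1)
  n <- 60
  calls <- matrix("AA", nrow = n, ncol = 20)
  calls[1:6, 11:20] <- "HET"      # events in interval 10-11 (midpoint 10.5 Mbp, Z2)
  g <- geno_from_calls(calls, pos = seq(1e6, 20e6, by = 1e6))
  xo <- call_crossovers(g)
  m <- genetic_map(xo, g)
  zs <- zone_summary(m, lay, xo = xo, marker_map = g$map)
  expect_identical(zs$zone, c("Z1", "Z2", "Z3"))
  expect_equal(zs$co_score[zs$zone == "Z2"], 6)
  expect_equal(zs$cm[zs$zone == "Z2"], sum(m$cm, na.rm = TRUE))
  expect_equal(zs$cm[zs$zone %in% c("Z1", "Z3")], c(0, 0))
  # markers at 1..4 Mbp fall in Z1 (0-4.5 Mbp), the rest in Z2
  expect_equal(zs$n_markers, c(4L, 16L, 0L))
  expect_equal(zs$mbp, c(9, 66, 25))
  expect_equal(zs$snp_per_mbp, c(4 / 9, 16 / 66, 0))

  # empty crossover table -> all zone cM are zero
  g0 <- geno_from_calls(matrix("AA", nrow = 3, ncol = 20),
                        pos = seq(1e6, 20e6, by = 1e6))
  xo0 <- call_crossovers(g0)
  zs0 <- zone_summary(genetic_map(xo0, g0), lay, xo = xo0)
  expect_equal(zs0$cm, c(0, 0, 0))
  expect_equal(zs0$co_score, c(0, 0, 0))
})

test_that("distally loaded simulations concentrate cM in Zone 1", {
  chroms <- tiny_chromosomes(1, cm = 60)
  land <- recomb_landscape(rep("1H", 3), c(1, 4.5e6 + 1, 95.5e6 + 1),
                           c(4.5e6, 95.5e6, 1e8), cm = c(30, 0, 30))
  cfg <- sim_config(n_individuals = 80, chromosomes = chroms, landscape = land,
                    markers_per_mbp = 1, missing_rate = 0,
                    allele_error_rate = 0, seed = 90)
  s <- simulate_f2(cfg)
  m <- genetic_map(call_crossovers(s$geno), s$geno)
  zs <- zone_summary(m, tiny_layout(1))
  expect_gt(zs$cm[zs$zone == "Z1"], 0.9 * sum(zs$cm))
  expect_lt(zs$cm[zs$zone == "Z3"], 0.05 * sum(zs$cm))
})

test_that("zone share percentages are printed-style rounded", {
  sh <- zone_shares(c(Z1 = 570.3, Z2 = 416.7, Z3 = 0.6))
  expect_equal(sh$share_pct, c(57.7, 42.2, 0.1))
  expect_equal(sum(sh$share_frac), 1)
})

test_that("chi-squared zone contingency matches hand-computed Pearson values", {
  # identical populations: chi2 = 0, p = 1 in every zone
  zsc <- tibble::tibble(zone = rep(c("Z1", "Z2"), 2),
                        pop = rep(c("a", "b"), each = 2),
                        score = c(60, 40, 60, 40))
  res <- chi2_zone_proportions(zsc)
  expect_equal(res$chi2, c(0, 0))
  expect_equal(res$p, c(1, 1))

  # [[60,40],[40,60]] -> chi2 = 8, p ~ 0.00468
  zsc2 <- tibble::tibble(zone = rep(c("Z1", "Z2"), 2),
                         pop = rep(c("a", "b"), each = 2),
                         score = c(60, 40, 40, 60))
  res2 <- chi2_zone_proportions(zsc2)
  expect_equal(res2$chi2[1], 8)
  expect_equal(res2$p[1], pchisq(8, 1, lower.tail = FALSE))
  expect_equal(res2$p[1], 0.00468, tolerance = 1e-3)

  # zero marginal -> p undefined
  zsc3 <- tibble::tibble(zone = rep(c("Z1", "Z2"), 2),
                         pop = rep(c("a", "b"), each = 2),
                         score = c(0, 100, 0, 100))
  expect_true(is.na(chi2_zone_proportions(zsc3)$p[1]))
})

test_that("Wilcoxon signed-rank comparison handles exact, tied and degenerate cases", {
  # identical vectors: no non-zero pairs, undefined p
  w0 <- wilcoxon_compare(1:5, 1:5)
  expect_true(is.na(w0$p))
  expect_identical(w0$n_pairs, 0L)

  # all-negative distinct differences: exact two-sided p = 2/2^6
  w <- wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
  expect_equal(w$p, 0.03125)
  expect_identical(w$method, "exact")
  expect_equal(w$statistic, 0)

  # ties fall back to the tie-corrected normal approximation
  wt <- wilcoxon_compare(c(1, 1, 2, 2, 5, 7), c(2, 2, 3, 3, 1, 2))
  expect_identical(wt$method, "normal")
  expect_true(wt$p > 0 && wt$p <= 1)

  # agreement with the standard implementation on clean data
  set.seed(42)
  x <- rnorm(40); y <- rnorm(40)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  got <- wilcoxon_compare(x, y)
  expect_equal(got$p, ref$p.value)
})

test_that("exact signed-rank test keeps its size under the null", {
  set.seed(101)
  reps <- 1000
  p <- replicate(reps, wilcoxon_compare(rnorm(12), rnorm(12))$p)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("bin profile apportions cM pro-rata and conserves the map total", {
  lay <- tiny_layout(1)
  # one interval spanning exactly bins 1-2 equally (0-4 Mbp over 2 Mbp bins)
  m <- as_genetic_map(tibble::tibble(chrom = "1H", left_pos = 1,
                                     right_pos = 4e6, cm = 10))
  bp <- bin_profile(m, lay, n_bins = 50)
  expect_equal(bp$cm[bp$bin == 1], 5, tolerance = 1e-6)
  expect_equal(bp$cm[bp$bin == 2], 5, tolerance = 1e-6)
  expect_equal(sum(bp$cm), 10)

  # conservation on a simulated map
  chroms <- tiny_chromosomes(2, cm = 70)
  cfg <- sim_config(n_individuals = 50, chromosomes = chroms,
                    landscape = uniform_landscape(chroms),
                    markers_per_mbp = 1, seed = 91)
  s <- simulate_f2(cfg)
  mm <- genetic_map(call_crossovers(s$geno), s$geno)
  prof <- bin_profile(mm, tiny_layout(2), n_bins = 50)
  expect_equal(sum(prof$cm), glance(mm)$total_cm, tolerance = 1e-9)
  expect_identical(sort(unique(prof$bin)), 1:50)

  # distally loaded map concentrates in the terminal bins
  land <- recomb_landscape(rep("1H", 3), c(1, 2e6 + 1, 98e6 + 1),
                           c(2e6, 98e6, 1e8), cm = c(35, 0, 35))
  cfgd <- sim_config(n_individuals = 60, chromosomes = tiny_chromosomes(1, cm = 70),
                     landscape = land, markers_per_mbp = 1.5,
                     missing_rate = 0, allele_error_rate = 0, seed = 92)
  sd_ <- simulate_f2(cfgd)
  md <- genetic_map(call_crossovers(sd_$geno), sd_$geno)
  profd <- bin_profile(md, tiny_layout(1), n_bins = 50)
  term <- sum(profd$cm[profd$bin %in% c(1, 50)])
  expect_gt(term / sum(profd$cm), 0.8)
})

test_that("two-population comparison conserves totals and pairs bins", {
  chroms <- tiny_chromosomes(3, cm = 60)
  sim <- simulate_populations(n_individuals = 50, chromosomes = chroms,
                              landscape_a = uniform_landscape(chroms),
                              markers_per_mbp = 1, seed = 17)
  lay <- tiny_layout(3)
  res <- analyze_recombination(sim$pop_a$geno, sim$pop_b$geno, lay)
  cmp <- res$comparison
  # conservation: zone totals and bin totals both equal the genome total
  expect_equal(sum(cmp$zones$cm_a), cmp$genome$cm_a, tolerance = 1e-9)
  expect_equal(sum(cmp$bins$cm_a), cmp$genome$cm_a, tolerance = 1e-9)
  expect_equal(sum(cmp$zones$cm_b), cmp$genome$cm_b, tolerance = 1e-9)
  expect_equal(sum(cmp$bins$cm_b), cmp$genome$cm_b, tolerance = 1e-9)
  # crossover-score totals in zones match the crossover tables
  expect_equal(sum(cmp$zones$co_a), sum(res$pop_a$xo$score))
  expect_equal(sum(cmp$zones$co_b), sum(res$pop_b$xo$score))
  # shares sum to one per population and basis
  sh <- cmp$shares |>
    dplyr::group_by(pop, basis) |>
    dplyr::summarise(s = sum(share_frac), .groups = "drop")
  expect_equal(sh$s, rep(1, 4))
  # broom-style accessors
  expect_identical(nrow(tidy(cmp)), 50L)
  expect_identical(nrow(glance(cmp)), 1L)
})
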