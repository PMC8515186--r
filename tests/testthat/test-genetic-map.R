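test_that("Kosambi map function matches closed-form values", {
  expect_identical(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi_cm(0.1), 10.1366, tolerance = 1e-4)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(kosambi_cm(0.25), 27.4653, tolerance = 1e-4)
  expect_error(kosambi_cm(-0.01), ">= 0")
  expect_warning(out <- kosambi_cm(0.6), "clipped")
  expect_equal(out, 25 * log((1 + 2 * 0.49999) / (1 - 2 * 0.49999)))
  # small-r limit: cM ~ 100 r
  expect_equal(kosambi_cm(1e-6) / (100 * 1e-6), 1, tolerance = 1e-6)
  # monotone and >= 100 r on (0, 0.5)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(diff(kosambi_cm(r)) > 0))
  expect_true(all(kosambi_cm(r) >= 100 * r))
})

test_that("interval recombination fractions are score-weighted quotients", {
  # 90 individuals, 10 markers; place 9 single events in interval 4-5 and one
  # score-2 event in interval 7-8
  n <- 90
  calls <- matrix("AA", nrow = n, ncol = 10)
  for (i in 1:9) calls[i, 5:10] <- "HET"
  calls[10, 8:10] <- "BB"
  g <- geno_from_calls(calls)
  xo <- call_crossovers(g)
  m <- genetic_map(xo, g)
  expect_identical(nrow(m), 9L)
  expect_equal(m$n_informative, rep(90L, 9))
  expect_equal(m$r[4], 9 / 90)
  expect_equal(m$r[7], 2 / 90)
  expect_equal(m$r[c(1:3, 5:6, 8:9)], rep(0, 7))
  expect_equal(m$cm, kosambi_cm(m$r))
  # cumulative positions are non-decreasing and end at the chromosome total
  expect_true(all(diff(m$cum_cm) >= 0))
  expect_equal(max(m$cum_cm), sum(m$cm))
})

test_that("events spanning missing markers land in the midpoint interval", {
  calls <- matrix("AA", nrow = 30, ncol = 9)
  calls[1, 4:6] <- NA          # flanking informative markers 3 and 7
  calls[1, 7:9] <- "HET"
  g <- geno_from_calls(calls)
  xo <- call_crossovers(g)
  expect_identical(xo$left_index, 3L)
  expect_identical(xo$right_index, 7L)
  m <- genetic_map(xo, g)
  # midpoint of markers 3 (3 Mbp) and 7 (7 Mbp) is 5 Mbp -> interval 5-6
  expect_identical(m$n_events[5], 1)
  expect_identical(sum(m$n_events), 1)
  # informative count drops where one flanking call is missing
  expect_identical(m$n_informative[3], 29L)
})

test_that("intervals without informative individuals are excluded from totals", {
  calls <- matrix("AA", nrow = 4, ncol = 4)
  calls[, 2] <- NA
  g <- geno_from_calls(calls)
  xo <- call_crossovers(g)
  expect_warning(m <- genetic_map(xo, g), "no informative")
  expect_true(all(is.na(m$r[1:2])))
  tot <- map_totals(m)
  expect_equal(tot$cm[tot$chrom == "genome"], 0)
})

test_that("map totals are additive and expected CO counts truncate at 50 cM/CO", {
  m <- as_genetic_map(tibble::tibble(
    chrom = rep(c("1H", "2H"), each = 3),
    left_pos = rep(c(1, 10, 20), 2), right_pos = rep(c(10, 20, 30), 2),
    cm = c(10, 20, 30, 5, 15, 25)))
  tot <- map_totals(m)
  expect_equal(tot$cm[tot$chrom == "1H"], 60)
  expect_equal(tot$cm[tot$chrom == "2H"], 45)
  expect_equal(tot$cm[tot$chrom == "genome"], 105)
  expect_equal(tot$cm[tot$chrom == "genome"],
               sum(tot$cm[tot$chrom != "genome"]), tolerance = 1e-12)
  expect_equal(tot$expected_co[tot$chrom == "genome"], 2.1)

  zero <- map_totals(as_genetic_map(tibble::tibble(
    chrom = "1H", left_pos = 1, right_pos = 2, cm = 0)))
  expect_equal(zero$expected_co[zero$chrom == "genome"], 0)

  # truncation, not rounding
  expect_equal(trunc_1dp(20.686), 20.6)
  expect_equal(trunc_1dp(19.752), 19.7)
})

test_that("glance and tidy summarise a map", {
  calls <- rbind(c(rep("AA", 4), rep("HET", 4)), rep("BB", 8), rep("AA", 8),
                 rep("HET", 8))
  g <- geno_from_calls(calls)
  m <- genetic_map(call_crossovers(g), g)
  gl <- glance(m)
  expect_identical(gl$n_chromosomes, 1L)
  expect_equal(gl$total_cm, sum(m$cm))
  td <- tidy(m)
  expect_identical(td$chrom, "1H")
})

test_that("coverage gaps report terminal uncovered fractions", {
  lay <- tiny_layout(2)
  mm <- tibble::tibble(marker = c("a", "b", "c"), chrom = "1H",
                       pos = c(1.1e6, 5e7, 1e8))
  cov <- coverage_gaps(mm, lay)
  r1 <- cov[cov$chrom == "1H", ]
  expect_equal(r1$pct_uncovered_start, 100 * (1.1e6 - 1) / 1e8)
  expect_equal(r1$pct_uncovered_start, 1.1, tolerance = 1e-3)
  expect_equal(r1$pct_uncovered_end, 0)
  r2 <- cov[cov$chrom == "2H", ]
  expect_warning(coverage_gaps(mm, lay), "without markers")
  expect_equal(suppressWarnings(coverage_gaps(mm, lay))$pct_uncovered_start[2], 100)

  # first marker at bp 1 and last at the chromosome end -> 0% both ends
  mm2 <- tibble::tibble(marker = c("a", "b"), chrom = "1H", pos = c(1, 1e8))
  cov2 <- suppressWarnings(coverage_gaps(mm2, lay))
  expect_equal(cov2$pct_uncovered_start[1], 0)
  expect_equal(cov2$pct_uncovered_end[1], 0)

  expect_error(
    coverage_gaps(tibble::tibble(marker = "z", chrom = "1H", pos = 2e8), lay),
    "beyond")
})

test_that("browser exports use 0-based half-open coordinates", {
  calls <- rbind(c(rep("AA", 4), rep("BB", 4)),
                 matrix("AA", nrow = 6, ncol = 8),
                 matrix("HET", nrow = 3, ncol = 8))
  g <- geno_from_calls(calls)
  xo <- call_crossovers(g)
  m <- genetic_map(xo, g)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_map_bedgraph(m, bg)
  ln <- readLines(bg)
  expect_match(ln[1], "bedGraph")
  f <- strsplit(ln[2], "\t")[[1]]
  # first interval: markers at 1 Mbp and 2 Mbp -> [1e6 - 1, 2e6)
  expect_identical(f[1:3], c("1H", "999999", "2000000"))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_crossovers_bed(xo, bed)
  fb <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(fb[1:3], c("1H", "3999999", "5000000"))
  expect_identical(fb[5], "2")
})

test_that("pipeline map total recovers twice the per-gamete genetic length", {
  # modest single-seed version of the parameter-recovery experiment
  chroms <- tiny_chromosomes(2, cm = 80)
  cfg <- sim_config(n_individuals = 150, chromosomes = chroms,
                    landscape = uniform_landscape(chroms),
                    markers_per_mbp = 1.5, missing_rate = 0,
                    allele_error_rate = 0, seed = 70)
  s <- simulate_f2(cfg)
  m <- genetic_map(call_crossovers(s$geno), s$geno)
  total <- glance(m)$total_cm
  # expected 2 * 160 = 320 cM; Poisson noise of the underlying event count
  n_ev <- sum(m$n_events)
  se_cm <- 100 * sqrt(n_ev) / 150
  expect_lt(abs(total - 320), 3 * se_cm + 5)
})
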