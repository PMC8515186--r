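# small single-chromosome world used by several unit tests: 100 Mbp, uniform
# landscape, evenly spread zone layout
tiny_chromosomes <- function(n = 1, cm = 50) {
  tibble::tibble(chrom = paste0(seq_len(n), "H"),
                 length_bp = rep(1e8, n), cm = rep(cm, n))
}

tiny_layout <- function(n = 1) {
  synthetic_layout(tiny_chromosomes(n))
}

# build an xo_geno directly from a character call matrix (individuals x
# markers) and evenly spaced marker positions
geno_from_calls <- function(calls_chr, chrom = "1H", pos = NULL) {
  n_mark <- ncol(calls_chr)
  pos <- pos %||% seq(1e6, by = 1e6, length.out = n_mark)
  map <- tibble::tibble(marker = sprintf("m%03d", seq_len(n_mark)),
                        chrom = chrom, pos = pos)
  xo_geno(calls_chr, map)
}

`%||%` <- rlang::`%||%`

# draw a fixed marker map (a shared array) for replicate simulations
fixed_marker_map <- function(chroms, per_mbp, seed) {
  withr::with_seed(seed, {
    purrr::pmap(chroms, function(chrom, length_bp, ...) {
      n_mark <- round(per_mbp * length_bp / 1e6)
      tibble::tibble(marker = sprintf("M%s_%04d", chrom, seq_len(n_mark)),
                     chrom = chrom,
                     pos = as.numeric(sort(sample.int(length_bp, n_mark))))
    }) |> purrr::list_rbind()
  })
}

# one replicate of a two-population comparison experiment: returns the
# zone-1/zone-2 chi-squared p-values and the terminal-bin Wilcoxon p-values
comparison_rep <- function(mm, chroms, lay, land_a, land_b, n_ind, seed) {
  mk <- function(landx, sd) {
    simulate_f2(sim_config(n_individuals = n_ind, chromosomes = chroms,
                           landscape = landx, marker_map = mm,
                           missing_rate = 0, allele_error_rate = 0,
                           seed = sd))
  }
  sa <- mk(land_a, seed); sb <- mk(land_b, seed + 500000L)
  xa <- call_crossovers(sa$geno); xb <- call_crossovers(sb$geno)
  ma <- genetic_map(xa, sa$geno); mb <- genetic_map(xb, sb$geno)
  zs <- function(m, x) zone_summary(m, lay, xo = x)$co_score
  sc <- dplyr::bind_rows(
    tibble::tibble(zone = c("Z1", "Z2", "Z3"), pop = "a", score = zs(ma, xa)),
    tibble::tibble(zone = c("Z1", "Z2", "Z3"), pop = "b", score = zs(mb, xb)))
  chi <- chi2_zone_proportions(sc)
  bins <- xoscape:::.interval_bins(ma, lay, 50)
  cma <- dplyr::coalesce(ma$cm, 0); cmb <- dplyr::coalesce(mb$cm, 0)
  w1 <- wilcoxon_compare(cma[bins == 1], cmb[bins == 1])
  w50 <- wilcoxon_compare(cma[bins == 50], cmb[bins == 50])
  c(chi_z1 = chi$p[chi$zone == "Z1"], chi_z2 = chi$p[chi$zone == "Z2"],
    w_bin1 = w1$p, w_bin50 = w50$p)
}
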