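#' Per-zone recombination and marker summary
#'
#' Aggregates a genetic map (and optionally a crossover table and marker map)
#' over the Zone 1/2/3 partition of a genome layout. Marker intervals and
#' crossover events are assigned to the zone containing the physical midpoint
#' of their flanking markers; markers are assigned by their own position.
#'
#' @param map An `xo_map` from [genetic_map()].
#' @param layout A [genome_layout()].
#' @param xo Optional `xo_table`; adds per-zone summed crossover scores.
#' @param marker_map Optional marker map tibble; adds per-zone marker counts
#'   and densities (SNP/Mbp).
#' @return Tibble with one row per zone: `zone`, `cm`, and depending on the
#'   optional inputs `co_score`, `n_markers`, `mbp`, `snp_per_mbp`.
#' @export
zone_summary <- function(map, layout, xo = NULL, marker_map = NULL) {
  layout <- validate_layout(layout)
  zones <- tibble(zone = c("Z1", "Z2", "Z3"))
  m <- as_tibble(map)
  m$mid <- (m$left_pos + m$right_pos) / 2
  mz <- assign_zone(tibble(chrom = m$chrom, pos = m$mid), layout)$zone
  out <- tibble(zone = mz, cm = m$cm) |>
    group_by(.data$zone) |>
    summarise(cm = sum(.data$cm, na.rm = TRUE), .groups = "drop") |>
    right_join(zones, by = "zone") |>
    mutate(cm = coalesce(.data$cm, 0)) |>
    arrange(.data$zone)
  if (!is.null(xo)) {
    xo <- as_tibble(xo)
    if (nrow(xo) > 0) {
      xz <- assign_zone(tibble(chrom = xo$chrom,
                               pos = (xo$left_pos + xo$right_pos) / 2),
                        layout)$zone
      sc <- tibble(zone = xz, score = xo$score) |>
        group_by(.data$zone) |>
        summarise(co_score = sum(.data$score), .groups = "drop")
    } else {
      sc <- tibble(zone = character(0), co_score = numeric(0))
    }
    out <- left_join(out, sc, by = "zone") |>
      mutate(co_score = coalesce(.data$co_score, 0))
  }
  zone_mbp <- layout |>
    group_by(.data$zone) |>
    summarise(mbp = sum(.data$end - .data$start + 1) / 1e6, .groups = "drop")
  out <- left_join(out, zone_mbp, by = "zone")
  if (!is.null(marker_map)) {
    mk <- assign_zone(as_tibble(marker_map)[c("chrom", "pos")], layout) |>
      count(.data$zone, name = "n_markers")
    out <- left_join(out, mk, by = "zone") |>
      mutate(n_markers = coalesce(.data$n_markers, 0L),
             snp_per_mbp = .data$n_markers / .data$mbp)
  }
  out
}

#' Zone shares of recombination
#'
#' Converts per-zone totals (cM or crossover scores) to percentage shares,
#' rounded to one decimal as shares are conventionally printed.
#'
#' @param totals Named numeric vector or tibble column of per-zone totals.
#' @return Tibble with `zone`, `total`, `share_pct` (rounded to 1 dp) and
#'   `share_frac` (full precision).
#' @examples
#' zone_shares(c(Z1 = 570.3, Z2 = 416.7, Z3 = 0.6))
#' @export
zone_shares <- function(totals) {
  stopifnot(is.numeric(totals))
  nm <- names(totals) %||% paste0("Z", seq_along(totals))
  frac <- totals / sum(totals)
  tibble(zone = nm, total = unname(totals),
         share_pct = round(100 * unname(frac), 1),
         share_frac = unname(frac))
}

#' Chi-squared test of per-zone crossover proportions
#'
#' For each zone, forms the 2 x 2 contingency table (population x in-zone /
#' out-of-zone crossover scores) and computes the Pearson chi-squared
#' statistic (1 df, no continuity correction unless `correct = TRUE`). A zero
#' marginal leaves the p-value undefined (`NA`).
#'
#' @param zone_scores Tibble with columns `zone`, `pop`, `score` (summed
#'   crossover scores per zone for each of two populations).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return Tibble with `zone`, `chi2`, `df`, `p`.
#' @export
chi2_zone_proportions <- function(zone_scores, correct = FALSE) {
  stopifnot(all(c("zone", "pop", "score") %in% names(zone_scores)))
  pops <- unique(zone_scores$pop)
  if (length(pops) != 2) abort("exactly two populations required")
  if (any(zone_scores$score < 0)) abort("scores must be non-negative")
  tot <- tapply(zone_scores$score, zone_scores$pop, sum)[as.character(pops)]
  if (any(tot <= 0)) abort("each population needs a positive total score")
  rows <- lapply(unique(zone_scores$zone), function(z) {
    inz <- tapply(zone_scores$score[zone_scores$zone == z],
                  zone_scores$pop[zone_scores$zone == z], sum)[as.character(pops)]
    inz[is.na(inz)] <- 0
    tab <- rbind(inz, tot - inz)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble(zone = z, chi2 = NA_real_, df = 1L, p = NA_real_))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    tibble(zone = z, chi2 = unname(ct$statistic), df = 1L,
           p = unname(ct$p.value))
  })
  list_rbind(rows)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired recombination values. Pairs with zero
#' difference are dropped (standard signed-rank convention); with fewer than
#' two non-zero pairs the p-value is undefined. The exact distribution is
#' used for up to `exact_max` untied pairs, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   p-value is computed (default 25).
#' @return One-row tibble with `statistic` (V, sum of positive ranks), `p`,
#'   `n_pairs` (non-zero pairs) and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
#' @export
wilcoxon_compare <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n < 2) {
    return(tibble(statistic = NA_real_, p = NA_real_, n_pairs = n,
                  method = NA_character_))
  }
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = FALSE, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p = wt$p.value, n_pairs = n,
         method = if (use_exact) "exact" else "normal")
}

#' Genome-wide relative bin profile of a genetic map
#'
#' Dissects every chromosome into `n_bins` equal relative physical intervals
#' (bin 1 at the short-arm telomere, bin `n_bins` at the long-arm telomere)
#' and apportions each marker interval's centimorgans to the bins pro-rata by
#' physical overlap, then merges chromosomes so the genome is described by
#' `n_bins` bins. The summed bin cM equals the genome map total.
#'
#' @param map An `xo_map`.
#' @param layout A [genome_layout()] (chromosome lengths).
#' @param n_bins Number of relative bins (default 50, i.e. 2% intervals).
#' @return Tibble with `bin`, `chrom`, `cm`; aggregate over `chrom` for the
#'   genome-wide profile.
#' @export
bin_profile <- function(map, layout, n_bins = 50) {
  .check_number(n_bins, "n_bins", 1)
  n_bins <- as.integer(n_bins)
  lens <- layout_lengths(validate_layout(layout))
  m <- as_tibble(map)
  pieces <- lapply(unique(m$chrom), function(ch) {
    mm <- m[m$chrom == ch, ]
    len <- lens$length_bp[lens$chrom == ch]
    if (length(len) == 0) abort(sprintf("chromosome %s absent from layout", ch))
    # cumulative cM as a piecewise-linear function of bp, evaluated at the
    # bin boundaries: differences give exact pro-rata overlap apportionment
    knots_x <- c(0, mm$left_pos[1], mm$right_pos)
    knots_y <- c(0, 0, cumsum(coalesce(mm$cm, 0)))
    bounds <- seq(0, len, length.out = n_bins + 1)
    cum <- approx(knots_x, knots_y, xout = bounds, rule = 2, ties = "ordered")$y
    tibble(bin = seq_len(n_bins), chrom = ch, cm = diff(cum))
  })
  list_rbind(pieces)
}

# per-interval bin index (midpoint rule) used for interval-paired bin tests
.interval_bins <- function(map, layout, n_bins) {
  lens <- layout_lengths(layout)
  m <- as_tibble(map)
  len <- lens$length_bp[match(m$chrom, lens$chrom)]
  mid <- (m$left_pos + m$right_pos) / 2
  pmin(pmax(ceiling(mid / len * n_bins), 1L), n_bins)
}

#' Compare the recombination landscapes of two populations
#'
#' Runs the full two-population comparison: per-zone cM and crossover-score
#' totals with the chi-squared contingency test of crossover proportions and
#' a per-zone paired Wilcoxon signed-rank test; genome-level Wilcoxon on
#' per-chromosome map lengths; and a per-bin Wilcoxon over the genome-wide
#' relative bin profile. Zone- and genome-level Wilcoxon tests pair
#' per-chromosome values. Bin-level tests pair shared marker intervals
#' within each bin by default (`bin_pairing = "interval"`, requiring the two
#' populations to be genotyped on the same markers, as on a fixed array);
#' `bin_pairing = "chromosome"` pairs per-chromosome bin contributions
#' instead.
#'
#' @param map_a,map_b `xo_map`s of the two populations.
#' @param xo_a,xo_b Their `xo_table`s.
#' @param layout A [genome_layout()].
#' @param n_bins Number of relative bins (default 50).
#' @param bin_pairing `"interval"` (default) or `"chromosome"`.
#' @param correct Continuity correction for the chi-squared tests.
#' @param pop_names Length-2 character vector naming the populations.
#' @return A list of class `xo_comparison` with elements `zones`, `shares`,
#'   `genome`, `bins`, `profile`.
#' @export
compare_populations <- function(map_a, map_b, xo_a, xo_b, layout,
                                n_bins = 50,
                                bin_pairing = c("interval", "chromosome"),
                                correct = FALSE,
                                pop_names = c("pop_a", "pop_b")) {
  bin_pairing <- match.arg(bin_pairing)
  layout <- validate_layout(layout)
  za <- zone_summary(map_a, layout, xo = xo_a)
  zb <- zone_summary(map_b, layout, xo = xo_b)

  chi <- chi2_zone_proportions(bind_rows(
    tibble(zone = za$zone, pop = pop_names[1], score = za$co_score),
    tibble(zone = zb$zone, pop = pop_names[2], score = zb$co_score)),
    correct = correct)

  # per-chromosome zone cM for the paired zone Wilcoxon
  zc <- function(map, xo) {
    m <- as_tibble(map)
    mz <- assign_zone(tibble(chrom = m$chrom,
                             pos = (m$left_pos + m$right_pos) / 2), layout)$zone
    tibble(chrom = m$chrom, zone = mz, cm = coalesce(m$cm, 0)) |>
      group_by(.data$chrom, .data$zone) |>
      summarise(cm = sum(.data$cm), .groups = "drop")
  }
  zca <- zc(map_a, xo_a); zcb <- zc(map_b, xo_b)
  zone_w <- lapply(c("Z1", "Z2", "Z3"), function(z) {
    pairs <- full_join(filter(zca, .data$zone == z),
                       filter(zcb, .data$zone == z),
                       by = c("chrom", "zone"), suffix = c("_a", "_b")) |>
      mutate(across(c("cm_a", "cm_b"), ~coalesce(.x, 0)))
    w <- wilcoxon_compare(pairs$cm_a, pairs$cm_b)
    tibble(zone = z, wilcox_v = w$statistic, wilcox_p = w$p,
           wilcox_n = w$n_pairs)
  }) |> list_rbind()

  zones <- za |>
    select("zone", cm_a = "cm", co_a = "co_score") |>
    left_join(select(zb, "zone", cm_b = "cm", co_b = "co_score"), by = "zone") |>
    left_join(chi, by = "zone") |>
    left_join(zone_w, by = "zone")

  shares <- bind_rows(
    mutate(zone_shares(setNames(za$co_score, za$zone)), pop = pop_names[1],
           basis = "co"),
    mutate(zone_shares(setNames(zb$co_score, zb$zone)), pop = pop_names[2],
           basis = "co"),
    mutate(zone_shares(setNames(za$cm, za$zone)), pop = pop_names[1],
           basis = "cm"),
    mutate(zone_shares(setNames(zb$cm, zb$zone)), pop = pop_names[2],
           basis = "cm"))

  ta <- map_totals(map_a); tb <- map_totals(map_b)
  ga <- ta[ta$chrom == "genome", ]; gb <- tb[tb$chrom == "genome", ]
  chrom_pairs <- full_join(
    select(filter(ta, .data$chrom != "genome"), "chrom", cm_a = "cm"),
    select(filter(tb, .data$chrom != "genome"), "chrom", cm_b = "cm"),
    by = "chrom")
  gw <- wilcoxon_compare(chrom_pairs$cm_a, chrom_pairs$cm_b)
  genome <- tibble(cm_a = ga$cm, cm_b = gb$cm, diff_cm = ga$cm - gb$cm,
                   expected_co_a = ga$expected_co,
                   expected_co_b = gb$expected_co,
                   expected_co_a_1dp = ga$expected_co_1dp,
                   expected_co_b_1dp = gb$expected_co_1dp,
                   wilcox_v = gw$statistic, wilcox_p = gw$p,
                   wilcox_n = gw$n_pairs)

  prof_a <- bin_profile(map_a, layout, n_bins)
  prof_b <- bin_profile(map_b, layout, n_bins)
  profile <- bind_rows(mutate(prof_a, pop = pop_names[1]),
                       mutate(prof_b, pop = pop_names[2]))

  if (bin_pairing == "interval") {
    ia <- as_tibble(map_a); ib <- as_tibble(map_b)
    if (!identical(paste(ia$chrom, ia$left_marker, ia$right_marker),
                   paste(ib$chrom, ib$left_marker, ib$right_marker))) {
      abort("interval pairing requires both populations on identical marker sets")
    }
    bin_idx <- .interval_bins(map_a, layout, n_bins)
    pa <- coalesce(ia$cm, 0); pb <- coalesce(ib$cm, 0)
    bins <- lapply(seq_len(n_bins), function(k) {
      sel <- bin_idx == k
      w <- wilcoxon_compare(pa[sel], pb[sel])
      tibble(bin = k, wilcox_v = w$statistic, wilcox_p = w$p,
             wilcox_n = w$n_pairs)
    }) |> list_rbind()
  } else {
    wide <- full_join(prof_a, prof_b, by = c("bin", "chrom"),
                      suffix = c("_a", "_b"))
    bins <- wide |>
      group_by(bin = .data$bin) |>
      group_modify(function(d, ...) {
        w <- wilcoxon_compare(d$cm_a, d$cm_b)
        tibble(wilcox_v = w$statistic, wilcox_p = w$p, wilcox_n = w$n_pairs)
      }) |>
      ungroup()
  }
  bins <- bins |>
    left_join(prof_a |> group_by(bin = .data$bin) |>
                summarise(cm_a = sum(.data$cm), .groups = "drop"),
              by = "bin") |>
    left_join(prof_b |> group_by(bin = .data$bin) |>
                summarise(cm_b = sum(.data$cm), .groups = "drop"),
              by = "bin") |>
    select("bin", "cm_a", "cm_b", "wilcox_v", "wilcox_p", "wilcox_n")

  structure(list(zones = zones, shares = shares, genome = genome,
                 bins = bins, profile = profile, pop_names = pop_names,
                 n_bins = n_bins),
            class = "xo_comparison")
}

#' @export
print.xo_comparison <- function(x, ...) {
  cat(sprintf("<xo_comparison> %s vs %s\n", x$pop_names[1], x$pop_names[2]))
  g <- x$genome
  cat(sprintf("  genome: %.1f vs %.1f cM (diff %.1f cM), Wilcoxon p = %s\n",
              g$cm_a, g$cm_b, g$diff_cm, format.pval(g$wilcox_p, digits = 3)))
  print(x$zones)
  invisible(x)
}

#' @export
tidy.xo_comparison <- function(x, ...) x$bins

#' @export
glance.xo_comparison <- function(x, ...) x$genome
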