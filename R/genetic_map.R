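#' Kosambi map function
#'
#' Converts a recombination fraction to a genetic distance under the Kosambi
#' map function, d(cM) = 25 * ln((1 + 2r) / (1 - 2r)), which accounts for
#' moderate crossover interference. Values of `r >= 0.5` are clipped to
#' 0.49999 with a warning; negative values are an error.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance(s) in centimorgans.
#' @examples
#' kosambi_cm(c(0, 0.1, 0.25))
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0, na.rm = TRUE)) abort("recombination fraction must be >= 0")
  clip <- !is.na(r) & r >= 0.5
  if (any(clip)) {
    warn(sprintf("%d recombination fraction(s) >= 0.5 clipped to 0.49999",
                 sum(clip)))
    r[clip] <- 0.49999
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Per-interval crossover statistics and Kosambi distances
#'
#' Builds the genetic map of a population: one record per consecutive marker
#' pair per chromosome carrying the summed crossover scores in the interval
#' (`n_events`), the number of individuals informative (non-missing) at both
#' flanking markers (`n_informative`), the recombination fraction
#' `r = n_events / n_informative`, the Kosambi distance `cm` and the
#' cumulative position `cum_cm`. An event whose flanking informative markers
#' are not physically adjacent (missing calls in between) contributes its
#' score to the single interval containing the physical midpoint of its
#' flanking pair. Intervals with no informative individuals get `r = NA` and
#' are excluded from totals with a warning.
#'
#' @param xo An `xo_table` from [call_crossovers()].
#' @param geno The [xo_geno] the table was called from.
#' @return A tibble of class `xo_map` with columns `chrom`, `left_marker`,
#'   `right_marker`, `left_pos`, `right_pos`, `n_events`, `n_informative`,
#'   `r`, `cm`, `cum_cm`.
#' @export
genetic_map <- function(xo, geno) {
  stopifnot(inherits(geno, "xo_geno"))
  map <- geno$map
  calls <- geno$calls
  xo <- as_tibble(xo)
  if (nrow(xo) > 0 &&
      (!all(xo$left_marker %in% map$marker) ||
       !all(xo$right_marker %in% map$marker))) {
    abort("crossover table refers to markers absent from the genotype map")
  }
  chroms <- unique(map$chrom)
  pieces <- lapply(chroms, function(ch) {
    cols <- which(map$chrom == ch)
    m <- length(cols)
    if (m < 2) return(NULL)
    li <- cols[-m]
    obs <- !is.na(calls[, cols, drop = FALSE])
    n_inf <- colSums(obs[, -m, drop = FALSE] & obs[, -1, drop = FALSE])
    ev <- xo[xo$chrom == ch, ]
    n_events <- numeric(m - 1)
    if (nrow(ev) > 0) {
      # adjacent flanking pair -> its own interval; otherwise the interval
      # containing the physical midpoint of the flanking pair
      adj <- ev$right_index == ev$left_index + 1L
      iv <- integer(nrow(ev))
      iv[adj] <- match(ev$left_index[adj], li)
      if (any(!adj)) {
        mid <- (ev$left_pos[!adj] + ev$right_pos[!adj]) / 2
        iv[!adj] <- pmin(pmax(findInterval(mid, map$pos[cols]), 1L), m - 1L)
      }
      agg <- tapply(ev$score, iv, sum)
      n_events[as.integer(names(agg))] <- agg
    }
    tibble(chrom = ch,
           left_marker = map$marker[li],
           right_marker = map$marker[cols[-1]],
           left_pos = map$pos[li],
           right_pos = map$pos[cols[-1]],
           n_events = n_events,
           n_informative = as.integer(n_inf))
  })
  out <- list_rbind(pieces)
  undef <- out$n_informative == 0
  if (any(undef)) {
    warn(sprintf("%d interval(s) with no informative individuals: r undefined, excluded from totals",
                 sum(undef)))
  }
  out$r <- ifelse(undef, NA_real_, out$n_events / pmax(out$n_informative, 1L))
  out$cm <- kosambi_cm(out$r)
  out <- out |>
    group_by(.data$chrom) |>
    mutate(cum_cm = cumsum(coalesce(.data$cm, 0))) |>
    ungroup()
  new_xo_map(out)
}

new_xo_map <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  class(x) <- c("xo_map", class(x))
  x
}

#' Validate a data frame as a genetic map
#'
#' Accepts an externally built per-interval table (e.g. re-loaded from TSV)
#' as an `xo_map`, checking the required columns and recomputing `cum_cm`.
#'
#' @param x Data frame with at least `chrom`, `left_pos`, `right_pos`, `cm`.
#' @return An `xo_map` tibble.
#' @export
as_genetic_map <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "left_pos", "right_pos", "cm") %in% names(x)))
  x <- as_tibble(x) |>
    group_by(.data$chrom) |>
    mutate(cum_cm = cumsum(coalesce(.data$cm, 0))) |>
    ungroup()
  new_xo_map(x)
}

#' Chromosome and genome map totals
#'
#' Sums interval Kosambi distances per chromosome and genome-wide, and
#' converts the genome total to an expected crossover count per meiosis at
#' 50 cM per crossover. The expected count is reported at full precision
#' (`expected_co`) and truncated to one decimal (`expected_co_1dp`), the
#' style used when such counts are quoted in print.
#'
#' @param map An `xo_map`.
#' @return Tibble with one row per chromosome plus a `"genome"` row: `chrom`,
#'   `n_intervals`, `cm`, `expected_co`, `expected_co_1dp`.
#' @export
map_totals <- function(map) {
  stopifnot(is.data.frame(map))
  per <- map |>
    as_tibble() |>
    group_by(chrom = .data$chrom) |>
    summarise(n_intervals = n(), cm = sum(.data$cm, na.rm = TRUE),
              .groups = "drop")
  genome <- tibble(chrom = "genome", n_intervals = sum(per$n_intervals),
                   cm = sum(per$cm))
  out <- bind_rows(per, genome)
  out$expected_co <- out$cm / 50
  out$expected_co_1dp <- trunc_1dp(out$expected_co)
  out
}

#' Truncate to one decimal place
#'
#' `trunc_1dp(20.686)` is `20.6`: truncation, not rounding, matching the
#' presentation of expected crossover counts derived from map lengths.
#'
#' @param x Numeric vector.
#' @return `x` truncated towards zero at the first decimal.
#' @export
trunc_1dp <- function(x) trunc(x * 10) / 10

#' @export
glance.xo_map <- function(x, ...) {
  tot <- map_totals(x)
  g <- tot[tot$chrom == "genome", ]
  tibble(n_chromosomes = nrow(tot) - 1L,
         n_intervals = g$n_intervals,
         total_cm = g$cm,
         expected_co = g$expected_co,
         expected_co_1dp = g$expected_co_1dp)
}

#' @export
tidy.xo_map <- function(x, ...) {
  tot <- map_totals(x)
  tot[tot$chrom != "genome", ]
}

#' Export per-interval centimorgans as BEDGRAPH
#'
#' Writes one BEDGRAPH record per marker interval (0-based half-open
#' coordinates, value = interval cM) for genome-browser viewing. Intervals
#' with undefined cM are skipped.
#'
#' @param map An `xo_map`.
#' @param path Output path.
#' @return `map`, invisibly.
#' @export
write_map_bedgraph <- function(map, path) {
  m <- as_tibble(map)
  m <- m[!is.na(m$cm), ]
  lines <- sprintf("%s\t%d\t%d\t%.6g", m$chrom,
                   as.integer(m$left_pos - 1), as.integer(m$right_pos),
                   m$cm)
  writeLines(c("track type=bedGraph name=\"interval_cM\"", lines), path)
  invisible(map)
}

#' Physical coverage gaps of a marker map
#'
#' Fraction of each chromosome's physical length lying before the first and
#' after the last marker, i.e. the terminal regions where crossovers cannot
#' be observed.
#'
#' @param marker_map Tibble with `marker`, `chrom`, `pos` (e.g. `geno$map`).
#' @param layout A [genome_layout()] providing chromosome lengths.
#' @return Tibble with `chrom`, `length_bp`, `first_pos`, `last_pos`,
#'   `pct_uncovered_start`, `pct_uncovered_end`. Chromosomes in the layout
#'   with no markers are reported 100% uncovered with a warning.
#' @export
coverage_gaps <- function(marker_map, layout) {
  layout <- validate_layout(layout)
  lens <- layout_lengths(layout)
  mm <- as_tibble(marker_map)
  chk <- inner_join(mm, lens, by = "chrom")
  if (nrow(chk) < nrow(mm)) abort("marker chromosome absent from layout")
  if (any(chk$pos > chk$length_bp)) {
    abort("marker position beyond declared chromosome length")
  }
  per <- mm |>
    group_by(.data$chrom) |>
    summarise(first_pos = min(.data$pos), last_pos = max(.data$pos),
              .groups = "drop")
  out <- left_join(lens, per, by = "chrom")
  empty <- is.na(out$first_pos)
  if (any(empty)) {
    warn(sprintf("%d chromosome(s) without markers: 100%% uncovered",
                 sum(empty)))
  }
  out |>
    mutate(pct_uncovered_start = ifelse(empty, 100,
             100 * (.data$first_pos - 1) / .data$length_bp),
           pct_uncovered_end = ifelse(empty, 100,
             100 * (.data$length_bp - .data$last_pos) / .data$length_bp))
}
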