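#' Piecewise-constant recombination landscapes
#'
#' A recombination landscape gives, for each chromosome, the per-gamete
#' genetic length (cM) carried by each physical segment. It is stored as an
#' ordinary tibble with columns `chrom`, `start`, `end` (bp, 1-based, `end`
#' inclusive) and `cm` (per-gamete centimorgans in the segment), with the
#' crossover intensity uniform within a segment. The landscape drives the
#' meiosis simulator and is also the shape against which simulated landscapes
#' are checked.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Segment bounds in bp (1-based; segments of one chromosome
#'   must tile `[1, max(end)]` without gap or overlap).
#' @param cm Per-gamete genetic length of each segment in centimorgans.
#' @return A tibble with columns `chrom`, `start`, `end`, `cm`.
#' @examples
#' recomb_landscape("1H", 1, 1e8, cm = 50)
#' @export
recomb_landscape <- function(chrom, start, end, cm) {
  x <- tibble(chrom = as.character(chrom),
              start = as.numeric(start),
              end = as.numeric(end),
              cm = as.numeric(cm))
  validate_landscape(x)
}

validate_landscape <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "cm") %in% names(x)))
  x <- as_tibble(x)
  if (any(x$cm < 0)) abort("landscape `cm` must be non-negative")
  if (any(x$end < x$start)) abort("landscape segments must have end >= start")
  for (ch in unique(x$chrom)) {
    seg <- x[x$chrom == ch, ]
    seg <- seg[order(seg$start), ]
    if (seg$start[1] != 1) abort(sprintf("chromosome %s: first segment must start at 1", ch))
    if (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1)) {
      abort(sprintf("chromosome %s: landscape segments must tile without gap/overlap", ch))
    }
  }
  arrange(x, .data$chrom, .data$start)
}

#' Barley-like default chromosome set
#'
#' Seven synthetic chromosomes at barley-like physical scale (520--670 Mbp)
#' with a per-gamete genetic length of 72 cM each, so a genome of ~504 cM per
#' gamete (~1008 cM on the pooled two-meioses scale an F2 map measures).
#'
#' @param n_chrom Number of chromosomes (max 7).
#' @param cm_per_chrom Per-gamete genetic length of each chromosome (cM).
#' @return Tibble with columns `chrom`, `length_bp`, `cm`.
#' @export
default_chromosomes <- function(n_chrom = 7, cm_per_chrom = 72) {
  lengths <- c(520, 670, 620, 610, 590, 580, 660) * 1e6
  n_chrom <- as.integer(n_chrom)
  stopifnot(n_chrom >= 1, n_chrom <= 7)
  tibble(chrom = paste0(seq_len(n_chrom), "H"),
         length_bp = lengths[seq_len(n_chrom)],
         cm = rep_len(as.numeric(cm_per_chrom), n_chrom))
}

# relative breakpoints / weights of the default distally-concentrated
# ("U-shaped") landscape: a strong sub-telomeric peak at 2--4.5% of each arm,
# moderate interstitial recombination and a nearly silent pericentromere.
# Weights are the fraction of the chromosome's genetic length per segment.
.ushape_breaks <- c(0, 0.02, 0.045, 0.12, 0.35, 0.65, 0.88, 0.955, 0.98, 1)
.ushape_weights <- c(0.045, 0.21, 0.105, 0.12, 0.04, 0.12, 0.105, 0.21, 0.045)

#' Distally-concentrated default landscape
#'
#' Builds the package's default U-shaped (distally enriched) recombination
#' landscape for a set of chromosomes: each arm carries a sub-telomeric
#' recombination peak, interstitial regions recombine moderately and the
#' pericentromeric third is nearly silent, emulating a large cereal genome.
#'
#' @param chromosomes Tibble with columns `chrom`, `length_bp`, `cm`
#'   (per-gamete cM), e.g. [default_chromosomes()].
#' @param breaks,weights Relative physical breakpoints (fractions of the
#'   chromosome in `[0, 1]`) and the fraction of `cm` assigned to each of the
#'   `length(breaks) - 1` segments.
#' @return A landscape tibble (see [recomb_landscape()]).
#' @examples
#' ushaped_landscape(default_chromosomes(2))
#' @export
ushaped_landscape <- function(chromosomes = default_chromosomes(),
                              breaks = .ushape_breaks,
                              weights = .ushape_weights) {
  stopifnot(length(weights) == length(breaks) - 1L,
            abs(sum(weights) - 1) < 1e-8,
            breaks[1] == 0, breaks[length(breaks)] == 1)
  segs <- pmap(chromosomes, function(chrom, length_bp, cm, ...) {
    bp <- round(breaks * length_bp)
    tibble(chrom = chrom,
           start = bp[-length(bp)] + 1,
           end = bp[-1],
           cm = cm * weights)
  })
  validate_landscape(list_rbind(segs))
}

#' Uniform landscape
#'
#' Constant crossover intensity along each chromosome; mainly useful for
#' calibration experiments and parameter-recovery checks.
#'
#' @inheritParams ushaped_landscape
#' @return A landscape tibble.
#' @export
uniform_landscape <- function(chromosomes = default_chromosomes()) {
  recomb_landscape(chromosomes$chrom, 1, chromosomes$length_bp, chromosomes$cm)
}

#' Per-chromosome genetic lengths of a landscape
#'
#' @param landscape A landscape tibble.
#' @return Tibble with `chrom`, `length_bp`, `cm`.
#' @export
landscape_lengths <- function(landscape) {
  landscape <- validate_landscape(landscape)
  landscape |>
    group_by(.data$chrom) |>
    summarise(length_bp = max(.data$end), cm = sum(.data$cm), .groups = "drop")
}

# split every landscape segment at the supplied absolute bp breakpoints of its
# chromosome, distributing cm pro-rata by physical length
split_landscape_at <- function(landscape, cuts) {
  landscape <- validate_landscape(landscape)
  out <- lapply(unique(landscape$chrom), function(ch) {
    seg <- landscape[landscape$chrom == ch, ]
    cc <- sort(unique(cuts$pos[cuts$chrom == ch]))
    rows <- pmap(seg, function(chrom, start, end, cm, ...) {
      inner <- cc[cc >= start & cc < end]
      edges <- c(start - 1, inner, end)
      w <- diff(edges)
      cm_pieces <- cm * w / (end - start + 1)
      tibble(chrom = chrom, start = edges[-length(edges)] + 1,
             end = edges[-1], cm = cm_pieces)
    })
    list_rbind(rows)
  })
  validate_landscape(list_rbind(out))
}

#' Move interstitial recombination to the chromosome tips
#'
#' Produces a perturbed landscape in which a fraction of the genetic length of
#' the interstitial zone (Z2) of every chromosome is removed pro-rata and
#' re-deposited, half per arm, into the terminal `terminal_frac` of the
#' chromosome. Total genetic length is unchanged. This emulates a distal
#' redistribution of crossovers such as that observed when the RTEL1 helicase
#' is downregulated.
#'
#' @param landscape A landscape tibble.
#' @param layout A genome layout (see [genome_layout()]) supplying the Z2
#'   segment bounds per chromosome.
#' @param fraction Fraction of Z2 genetic length to move (default 0.10).
#' @param terminal_frac Relative size of each terminal target segment
#'   (default 0.02, i.e. the outermost 2% of each arm).
#' @return A landscape tibble with identical per-chromosome totals.
#' @export
shift_distal <- function(landscape, layout, fraction = 0.10, terminal_frac = 0.02) {
  .check_number(fraction, "fraction", 0, 1)
  .check_number(terminal_frac, "terminal_frac", 0, 0.5)
  layout <- validate_layout(layout)
  lens <- landscape_lengths(landscape)
  cuts <- bind_rows(
    tibble(chrom = layout$chrom, pos = layout$end),
    tibble(chrom = lens$chrom, pos = round(terminal_frac * lens$length_bp)),
    tibble(chrom = lens$chrom,
           pos = round((1 - terminal_frac) * lens$length_bp))
  )
  fine <- split_landscape_at(landscape, cuts)
  mid <- (fine$start + fine$end) / 2
  zone <- assign_zone(tibble(chrom = fine$chrom, pos = mid), layout)$zone
  out <- lapply(unique(fine$chrom), function(ch) {
    seg <- fine[fine$chrom == ch, ]
    zz <- zone[fine$chrom == ch]
    len <- lens$length_bp[lens$chrom == ch]
    moved <- fraction * sum(seg$cm[zz == "Z2"])
    seg$cm[zz == "Z2"] <- seg$cm[zz == "Z2"] * (1 - fraction)
    left <- seg$end <= round(terminal_frac * len)
    right <- seg$start > round((1 - terminal_frac) * len)
    for (side in list(left, right)) {
      w <- (seg$end[side] - seg$start[side] + 1)
      seg$cm[side] <- seg$cm[side] + (moved / 2) * w / sum(w)
    }
    seg
  })
  validate_landscape(list_rbind(out))
}
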