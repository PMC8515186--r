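#' Crossover caller configuration
#'
#' The caller scores a crossover whenever the genotype call changes between
#' two consecutive informative markers, provided the change is maintained in
#' the `window` markers on each side: a transition is valid only if the
#' `window` informative calls ending at its left marker all share the left
#' call and the `window` informative calls starting at its right marker all
#' share the right call. A switch between opposite parental homozygotes
#' (AA to BB or BB to AA) implies one crossover in each of the individual's
#' two gametes and is scored 2; every other valid transition is scored 1.
#'
#' @param window Number of confirming markers required on each side of a
#'   transition (default 3).
#' @param missing_policy `"skip_missing"` (default): missing calls are
#'   dropped before windowing, so the window is counted over informative
#'   markers and events are reported at their flanking informative markers.
#'   `"strict"`: a missing call breaks the window and suppresses any
#'   transition whose window it intrudes on.
#' @param end_rule `"truncate"` (default): within `window` markers of a
#'   chromosome end the window uses however many markers exist on that side
#'   (at least one). `"strict"`: the full window is required, discarding
#'   transitions too close to the ends.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(window = 3,
                          missing_policy = c("skip_missing", "strict"),
                          end_rule = c("truncate", "strict")) {
  .check_number(window, "window", 1)
  structure(list(window = as.integer(window),
                 missing_policy = match.arg(missing_policy),
                 end_rule = match.arg(end_rule)),
            class = "caller_config")
}

# core single-sequence caller on integer codes (0/1/2, NA missing).
# Returns a list of equal-length vectors (possibly length 0):
# left/right original marker indices, from/to codes, score.
.xo_call_seq <- function(code, window, skip_missing = TRUE,
                         truncate_ends = TRUE) {
  code <- unname(code)
  if (skip_missing) {
    keep <- which(!is.na(code))
    v <- code[keep]
  } else {
    # missing breaks the window: treat NA as a distinct sentinel run
    keep <- seq_along(code)
    v <- code
    v[is.na(v)] <- -1L
  }
  empty <- list(left = integer(0), right = integer(0), from = integer(0),
                to = integer(0), score = integer(0))
  if (length(v) < 2) return(empty)
  r <- rle(v)
  k <- length(r$lengths)
  if (k < 2) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (truncate_ends) {
    left_ok <- r$lengths >= window | seq_len(k) == 1L
    right_ok <- r$lengths >= window | seq_len(k) == k
  } else {
    left_ok <- r$lengths >= window
    right_ok <- r$lengths >= window
  }
  a <- r$values[-k]; b <- r$values[-1]
  valid <- left_ok[-k] & right_ok[-1] & a >= 0L & b >= 0L
  if (!any(valid)) return(empty)
  li <- ends[-k][valid]; ri <- starts[-1][valid]
  av <- a[valid]; bv <- b[valid]
  list(left = keep[li], right = keep[ri], from = av, to = bv,
       score = ifelse(abs(av - bv) == 2L, 2L, 1L))
}

#' Call crossovers along one genotype call sequence
#'
#' Applies the windowed transition rule to a single individual's calls on one
#' chromosome, given in map order.
#'
#' @param calls Character vector of calls (`"AA"`, `"HET"`, `"BB"`, `NA`) in
#'   marker order.
#' @param config A [caller_config()].
#' @return Tibble with one row per valid crossover event: `left`, `right`
#'   (original marker indices of the flanking informative markers), `from`,
#'   `to` (call codes) and `score` (1, or 2 for a homozygote-to-opposite-
#'   homozygote double event).
#' @examples
#' call_crossover_sequence(c("AA", "AA", "AA", "AA", "HET", "HET", "HET", "HET"))
#' @export
call_crossover_sequence <- function(calls, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  if (length(calls) == 0) {
    return(tibble(left = integer(0), right = integer(0), from = character(0),
                  to = character(0), score = integer(0)))
  }
  code <- .label_to_code(calls)
  if (any(is.na(code) & !is.na(calls))) {
    abort("unknown call code; expected AA, HET, BB or NA")
  }
  ev <- .xo_call_seq(code, config$window,
                     skip_missing = config$missing_policy == "skip_missing",
                     truncate_ends = config$end_rule == "truncate")
  tibble(left = ev$left, right = ev$right,
         from = .code_to_label(ev$from), to = .code_to_label(ev$to),
         score = ev$score)
}

#' Call crossovers across a population
#'
#' Runs the windowed caller on every individual and chromosome of a genotype
#' matrix and returns the concatenated crossover table, sorted by individual,
#' chromosome and left marker.
#'
#' @param geno An [xo_geno] (normally after [qc_filter()]).
#' @param config A [caller_config()].
#' @return Tibble of class `xo_table` with columns `individual`, `chrom`,
#'   `left_marker`, `right_marker`, `left_index`, `right_index` (column
#'   indices into the marker map), `left_pos`, `right_pos` (bp), `from`,
#'   `to`, `score`.
#' @export
call_crossovers <- function(geno, config = caller_config()) {
  stopifnot(inherits(geno, "xo_geno"), inherits(config, "caller_config"))
  map <- geno$map
  calls <- geno$calls
  ids <- rownames(calls)
  skip <- config$missing_policy == "skip_missing"
  trunc <- config$end_rule == "truncate"
  chroms <- unique(map$chrom)
  a_ind <- list(); a_ch <- list(); a_left <- list(); a_right <- list()
  a_from <- list(); a_to <- list(); a_score <- list()
  n_acc <- 0L
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    block <- calls[, cols, drop = FALSE]
    for (i in seq_len(nrow(block))) {
      ev <- .xo_call_seq(block[i, ], config$window, skip, trunc)
      k <- length(ev$score)
      if (k == 0L) next
      n_acc <- n_acc + 1L
      a_ind[[n_acc]] <- rep.int(i, k)
      a_ch[[n_acc]] <- rep.int(match(ch, chroms), k)
      a_left[[n_acc]] <- cols[ev$left]
      a_right[[n_acc]] <- cols[ev$right]
      a_from[[n_acc]] <- ev$from
      a_to[[n_acc]] <- ev$to
      a_score[[n_acc]] <- ev$score
    }
  }
  left_index <- unlist(a_left) %||% integer(0)
  right_index <- unlist(a_right) %||% integer(0)
  out <- tibble(individual = ids[unlist(a_ind) %||% integer(0)],
                chrom = chroms[unlist(a_ch) %||% integer(0)],
                left_marker = map$marker[left_index],
                right_marker = map$marker[right_index],
                left_index = left_index,
                right_index = right_index,
                left_pos = map$pos[left_index],
                right_pos = map$pos[right_index],
                from = .code_to_label(unlist(a_from) %||% integer(0)),
                to = .code_to_label(unlist(a_to) %||% integer(0)),
                score = unlist(a_score) %||% integer(0))
  ord <- order(out$individual, match(out$chrom, chroms), out$left_index)
  out <- out[ord, ]
  class(out) <- c("xo_table", class(out))
  out
}

#' Write a crossover table as TSV
#'
#' @param xo An `xo_table` from [call_crossovers()].
#' @param path Output path.
#' @return `xo`, invisibly.
#' @export
write_crossovers <- function(xo, path) {
  readr::write_tsv(
    select(as_tibble(xo), "individual", "chrom", "left_marker", "left_pos",
           "right_marker", "right_pos", "score"),
    path)
  invisible(xo)
}

#' Export crossover intervals as BED
#'
#' One record per crossover event (0-based half-open interval between the
#' flanking informative markers; the score column carries the event score).
#'
#' @param xo An `xo_table`.
#' @param path Output path.
#' @return `xo`, invisibly.
#' @export
write_crossovers_bed <- function(xo, path) {
  x <- as_tibble(xo)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d", x$chrom,
                   as.integer(x$left_pos - 1), as.integer(x$right_pos),
                   x$individual, x$score)
  writeLines(lines, path)
  invisible(xo)
}

#' Evaluate caller calls against simulation truth
#'
#' Matches each true crossover to called events of the same individual and
#' chromosome whose flanking-marker interval contains the true position; an
#' event can absorb as many true crossovers as its score. Sensitivity is the
#' fraction of true crossovers matched; precision the fraction of called
#' score units matched.
#'
#' @param xo An `xo_table`.
#' @param truth Truth tibble from [simulate_f2()].
#' @return One-row tibble with `n_true`, `n_called_score`, `n_matched`,
#'   `sensitivity`, `precision`.
#' @export
caller_eval <- function(xo, truth) {
  xo <- as_tibble(xo)
  n_true <- nrow(truth)
  n_called <- sum(xo$score)
  matched <- 0L
  if (n_true > 0 && nrow(xo) > 0) {
    key_t <- paste(truth$individual, truth$chrom)
    key_x <- paste(xo$individual, xo$chrom)
    for (k in unique(key_t)) {
      tp <- sort(truth$pos[key_t == k])
      exo <- xo[key_x == k, ]
      if (nrow(exo) == 0) next
      cap <- exo$score
      for (p in tp) {
        hit <- which(cap > 0 & exo$left_pos <= p & exo$right_pos >= p)
        if (length(hit)) {
          cap[hit[1]] <- cap[hit[1]] - 1L
          matched <- matched + 1L
        }
      }
    }
  }
  tibble(n_true = n_true, n_called_score = n_called, n_matched = matched,
         sensitivity = if (n_true > 0) matched / n_true else NA_real_,
         precision = if (n_called > 0) matched / n_called else NA_real_)
}
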