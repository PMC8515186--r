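#' End-to-end recombination analysis
#'
#' Orchestrates the full pipeline for one or two F2 populations: QC
#' filtering, crossover calling, genetic map construction, coverage
#' assessment, and (with two populations) the zone/bin landscape comparison.
#' With simulation truth supplied, the caller is scored against it. A
#' bookkeeping log records marker and individual counts surviving each
#' filter.
#'
#' @param geno_a An [xo_geno] (population A).
#' @param geno_b Optional second population; must share the marker set of
#'   `geno_a` for the comparison stage.
#' @param layout A [genome_layout()].
#' @param qc A [qc_criteria()].
#' @param caller A [caller_config()].
#' @param n_bins Relative bins for the comparison (default 50).
#' @param bin_pairing Pairing unit for bin-level Wilcoxon tests, see
#'   [compare_populations()].
#' @param truth_a,truth_b Optional truth tibbles from [simulate_f2()].
#' @param pop_names Population labels.
#' @return A list of class `xo_analysis` with per-population elements
#'   (`geno`, `xo`, `map`, `totals`, `coverage`, `qc_reports`,
#'   `caller_eval`), the `comparison` (two populations only) and a `log`
#'   tibble of stage counts.
#' @details With two populations the marker filters are applied jointly: a
#'   marker is kept only if it passes QC in both populations (as when a
#'   single array dataset covering both populations is cleaned once), so the
#'   downstream maps are built on an identical marker set. Individuals are
#'   then filtered within each population.
#' @export
analyze_recombination <- function(geno_a, geno_b = NULL, layout,
                                  qc = qc_criteria(),
                                  caller = caller_config(),
                                  n_bins = 50,
                                  bin_pairing = c("interval", "chromosome"),
                                  truth_a = NULL, truth_b = NULL,
                                  pop_names = c("pop_a", "pop_b")) {
  bin_pairing <- match.arg(bin_pairing)
  layout <- validate_layout(layout)
  if (!is.null(geno_b)) {
    sym <- c(setdiff(geno_a$map$marker, geno_b$map$marker),
             setdiff(geno_b$map$marker, geno_a$map$marker))
    if (length(sym)) {
      abort(sprintf("populations genotyped on different marker sets; symmetric difference: %s",
                    paste(head(sym, 10), collapse = ", ")))
    }
  }
  run_one <- function(geno, truth, nm, marker_keep = NULL) {
    if (is.null(marker_keep)) {
      f <- qc_filter(geno, qc)
    } else {
      m <- filter_markers(geno, qc)
      own <- m$geno$map$marker
      extra <- setdiff(own, marker_keep)
      kept <- subset_markers(m$geno, marker_keep)
      i <- filter_individuals(kept, qc)
      f <- list(geno = i$geno,
                marker_report = bind_rows(
                  m$removed,
                  tibble(id = extra, reason = "failed_other_population",
                         statistic = NA_real_, threshold = NA_real_)),
                individual_report = i$removed)
    }
    xo <- call_crossovers(f$geno, caller)
    map <- genetic_map(xo, f$geno)
    list(pop = nm,
         geno = f$geno,
         qc_reports = f[c("marker_report", "individual_report")],
         xo = xo,
         map = map,
         totals = map_totals(map),
         coverage = coverage_gaps(f$geno$map, layout),
         caller_eval = if (!is.null(truth)) {
           caller_eval(xo, semi_join(truth,
             tibble(individual = rownames(f$geno$calls)), by = "individual"))
         },
         log = tibble(pop = nm,
                      markers_in = ncol(geno$calls),
                      markers_kept = ncol(f$geno$calls),
                      individuals_in = nrow(geno$calls),
                      individuals_kept = nrow(f$geno$calls),
                      co_score_total = sum(xo$score)))
  }
  marker_keep <- NULL
  if (!is.null(geno_b)) {
    marker_keep <- intersect(filter_markers(geno_a, qc)$geno$map$marker,
                             filter_markers(geno_b, qc)$geno$map$marker)
  }
  a <- run_one(geno_a, truth_a, pop_names[1], marker_keep)
  res <- list(pop_a = a)
  log <- a$log
  comparison <- NULL
  if (!is.null(geno_b)) {
    b <- run_one(geno_b, truth_b, pop_names[2], marker_keep)
    res$pop_b <- b
    log <- bind_rows(log, b$log)
    comparison <- compare_populations(a$map, b$map, a$xo, b$xo, layout,
                                      n_bins = n_bins,
                                      bin_pairing = bin_pairing,
                                      pop_names = pop_names)
  }
  structure(c(res, list(comparison = comparison, layout = layout, log = log)),
            class = "xo_analysis")
}

#' @export
print.xo_analysis <- function(x, ...) {
  cat("<xo_analysis>\n")
  print(x$log)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Bin-profile plot of one or two populations
#'
#' Plots the genome-wide relative bin profile (summed cM per bin) in the
#' style of a merged-chromosome recombination distribution figure.
#'
#' @param object An `xo_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xo_comparison <- function(object, ...) {
  prof <- object$profile |>
    group_by(.data$bin, .data$pop) |>
    summarise(cm = sum(.data$cm), .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin, y = .data$cm,
                                     colour = .data$pop)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = sprintf("relative physical bin (1..%d)", object$n_bins),
                  y = "genetic length (cM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative genetic-vs-physical map plot
#'
#' @param object An `xo_map`.
#' @param ... Unused.
#' @return A ggplot object, one facet per chromosome.
#' @export
autoplot.xo_map <- function(object, ...) {
  m <- as_tibble(object)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$right_pos / 1e6,
                                  y = .data$cum_cm)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "physical position (Mbp)", y = "cumulative cM") +
    ggplot2::theme_minimal()
}
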