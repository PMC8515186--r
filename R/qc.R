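#' Quality-control criteria for markers and individuals
#'
#' Operationalises "monomorphic and low-quality" filtering of a biparental F2
#' genotype matrix: a marker is removed when it is monomorphic (at most one
#' distinct non-missing call), exceeds a missing-call or heterozygosity
#' ceiling, or fails a 1:2:1 segregation chi-squared test at
#' `distortion_alpha`; an individual is removed when its missing or
#' heterozygous fraction exceeds its ceiling (the F2 expectation is 50%
#' heterozygous calls).
#'
#' @param max_marker_missing Maximum fraction of missing calls per marker.
#' @param max_marker_het Maximum fraction of heterozygous calls per marker.
#' @param distortion_alpha Significance level of the 1:2:1 segregation
#'   chi-squared test (2 df) below which a marker is declared distorted.
#' @param max_ind_missing Maximum fraction of missing calls per individual.
#' @param max_ind_het Maximum fraction of heterozygous calls per individual.
#' @return A list of class `qc_criteria`.
#' @export
qc_criteria <- function(max_marker_missing = 0.10,
                        max_marker_het = 0.85,
                        distortion_alpha = 1e-6,
                        max_ind_missing = 0.20,
                        max_ind_het = 0.80) {
  for (nm in c("max_marker_missing", "max_marker_het", "max_ind_missing",
               "max_ind_het")) {
    .check_number(get(nm), nm, 0, 1)
  }
  .check_number(distortion_alpha, "distortion_alpha", 0, 1)
  if (distortion_alpha == 0) abort("`distortion_alpha` must be in (0, 1]")
  structure(list(max_marker_missing = max_marker_missing,
                 max_marker_het = max_marker_het,
                 distortion_alpha = distortion_alpha,
                 max_ind_missing = max_ind_missing,
                 max_ind_het = max_ind_het),
            class = "qc_criteria")
}

# Pearson 1:2:1 goodness-of-fit p-value per marker given AA/HET/BB counts
.segregation_p <- function(n_aa, n_het, n_bb) {
  n <- n_aa + n_het + n_bb
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(n_aa, n_het, n_bb)
  stat <- rowSums((o - e)^2 / e)
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  p[n == 0] <- NA_real_
  p
}

#' Filter low-quality markers
#'
#' Removes monomorphic markers and markers exceeding the missing-call or
#' heterozygosity ceilings or failing the 1:2:1 segregation test. When a
#' marker fails several checks it is reported once, under the first failing
#' reason in the order monomorphic, missing, het, distortion.
#'
#' @param geno An [xo_geno].
#' @param criteria A [qc_criteria()].
#' @return List with elements `geno` (filtered) and `removed`, a tibble with
#'   columns `id`, `reason`, `statistic`, `threshold`.
#' @export
filter_markers <- function(geno, criteria = qc_criteria()) {
  stopifnot(inherits(geno, "xo_geno"), inherits(criteria, "qc_criteria"))
  calls <- geno$calls
  n_ind <- nrow(calls)
  n_aa <- colSums(calls == 0L, na.rm = TRUE)
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_bb <- colSums(calls == 2L, na.rm = TRUE)
  n_obs <- n_aa + n_het + n_bb
  miss_frac <- 1 - n_obs / n_ind
  het_frac <- ifelse(n_obs > 0, n_het / n_obs, 0)
  n_classes <- (n_aa > 0) + (n_het > 0) + (n_bb > 0)
  seg_p <- .segregation_p(n_aa, n_het, n_bb)

  reason <- rep(NA_character_, ncol(calls))
  statistic <- rep(NA_real_, ncol(calls))
  threshold <- rep(NA_real_, ncol(calls))
  set <- function(sel, why, stat, thr) {
    sel <- sel & is.na(reason)
    reason[sel] <<- why
    statistic[sel] <<- stat[sel]
    threshold[sel] <<- thr
  }
  set(n_classes <= 1L, "monomorphic", as.numeric(n_classes), 1)
  set(miss_frac > criteria$max_marker_missing, "missing", miss_frac,
      criteria$max_marker_missing)
  set(het_frac > criteria$max_marker_het, "het", het_frac,
      criteria$max_marker_het)
  set(!is.na(seg_p) & seg_p < criteria$distortion_alpha, "distortion", seg_p,
      criteria$distortion_alpha)

  drop <- !is.na(reason)
  removed <- tibble(id = colnames(calls)[drop], reason = reason[drop],
                    statistic = statistic[drop], threshold = threshold[drop])
  keep <- which(!drop)
  out <- new_xo_geno(calls[, keep, drop = FALSE], geno$map[keep, ])
  list(geno = out, removed = removed)
}

#' Filter low-quality individuals
#'
#' Removes individuals whose missing-call or heterozygous-call fraction
#' exceeds its ceiling.
#'
#' @inheritParams filter_markers
#' @return List with elements `geno` and `removed` (columns `id`, `reason`,
#'   `statistic`, `threshold`).
#' @export
filter_individuals <- function(geno, criteria = qc_criteria()) {
  stopifnot(inherits(geno, "xo_geno"), inherits(criteria, "qc_criteria"))
  calls <- geno$calls
  n_mark <- ncol(calls)
  n_obs <- rowSums(!is.na(calls))
  miss_frac <- 1 - n_obs / n_mark
  het_frac <- ifelse(n_obs > 0, rowSums(calls == 1L, na.rm = TRUE) / n_obs, 0)

  reason <- rep(NA_character_, nrow(calls))
  statistic <- rep(NA_real_, nrow(calls))
  threshold <- rep(NA_real_, nrow(calls))
  sel <- miss_frac > criteria$max_ind_missing
  reason[sel] <- "missing"; statistic[sel] <- miss_frac[sel]
  threshold[sel] <- criteria$max_ind_missing
  sel2 <- is.na(reason) & het_frac > criteria$max_ind_het
  reason[sel2] <- "het"; statistic[sel2] <- het_frac[sel2]
  threshold[sel2] <- criteria$max_ind_het

  drop <- !is.na(reason)
  removed <- tibble(id = rownames(calls)[drop], reason = reason[drop],
                    statistic = statistic[drop], threshold = threshold[drop])
  out <- new_xo_geno(calls[!drop, , drop = FALSE], geno$map)
  list(geno = out, removed = removed)
}

#' Apply full QC (markers, then individuals)
#'
#' Fixed filtering order: markers first, then individuals.
#'
#' @inheritParams filter_markers
#' @return List with `geno`, `marker_report`, `individual_report`.
#' @export
qc_filter <- function(geno, criteria = qc_criteria()) {
  m <- filter_markers(geno, criteria)
  i <- filter_individuals(m$geno, criteria)
  list(geno = i$geno, marker_report = m$removed, individual_report = i$removed)
}
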