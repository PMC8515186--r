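#' Simulation configuration for a synthetic F2 population
#'
#' Collects everything the F2 simulator needs: population size, chromosome
#' set, recombination landscape, crossover interference, marker placement and
#' the genotyping noise model. Defaults emulate a barley-style study: two
#' populations of 90 individuals genotyped on a fixed array of roughly 11,000
#' polymorphic markers over 7 chromosomes, with crossovers concentrated
#' distally, a 0.2% allele-error rate and 2% missing calls.
#'
#' @param n_individuals Number of F2 individuals.
#' @param chromosomes Tibble with `chrom`, `length_bp`, `cm` (per-gamete cM).
#' @param landscape A landscape tibble ([recomb_landscape()]); defaults to the
#'   distally concentrated [ushaped_landscape()] over `chromosomes`.
#' @param interference_shape Gamma renewal shape `nu` (> 0) on the genetic
#'   scale; `nu = 1` gives a no-interference (Poisson) crossover process,
#'   larger values give positive interference.
#' @param markers_per_mbp Marker density (markers per Mbp, uniformly placed),
#'   ignored when `marker_map` is supplied.
#' @param marker_map Optional explicit marker map tibble (`marker`, `chrom`,
#'   `pos`), e.g. to genotype two populations on an identical array.
#' @param allele_error_rate Probability that a non-missing call is replaced by
#'   one of the other two call codes (uniformly).
#' @param missing_rate Probability that a call is set to missing.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 90,
                       chromosomes = default_chromosomes(),
                       landscape = NULL,
                       interference_shape = 1,
                       markers_per_mbp = 2.6,
                       marker_map = NULL,
                       allele_error_rate = 0.002,
                       missing_rate = 0.02,
                       seed = 1L) {
  .check_number(n_individuals, "n_individuals", 1)
  .check_number(interference_shape, "interference_shape")
  if (interference_shape <= 0) abort("`interference_shape` must be > 0")
  .check_number(allele_error_rate, "allele_error_rate", 0, 1)
  .check_number(missing_rate, "missing_rate", 0, 1)
  .check_number(seed, "seed")
  landscape <- landscape %||% ushaped_landscape(chromosomes)
  landscape <- validate_landscape(landscape)
  lens <- landscape_lengths(landscape)
  if (!is.null(marker_map)) {
    stopifnot(all(c("marker", "chrom", "pos") %in% names(marker_map)))
    bad <- anti_join(marker_map, lens, by = "chrom")
    if (nrow(bad) > 0) abort("marker_map contains chromosomes absent from the landscape")
    mm <- left_join(as_tibble(marker_map), lens, by = "chrom")
    if (any(mm$pos < 1 | mm$pos > mm$length_bp)) {
      abort("marker positions outside chromosome bounds")
    }
  } else {
    .check_number(markers_per_mbp, "markers_per_mbp", 0)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 chromosomes = lens,
                 landscape = landscape,
                 interference_shape = interference_shape,
                 markers_per_mbp = markers_per_mbp,
                 marker_map = marker_map,
                 allele_error_rate = allele_error_rate,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# cumulative genetic map of one chromosome's landscape, for genetic->physical
# inversion; keeps only segments with positive cm so the inverse is unique
.land_cdf <- function(landscape, ch) {
  seg <- landscape[landscape$chrom == ch, ]
  list(total = sum(seg$cm),
       seg = seg[seg$cm > 0, , drop = FALSE],
       cum0 = cumsum(c(0, seg$cm[seg$cm > 0])))
}

# map per-gamete genetic positions (cM from the short-arm end) to bp
.genetic_to_bp <- function(g_cm, cdf) {
  if (length(g_cm) == 0) return(numeric(0))
  idx <- findInterval(g_cm, cdf$cum0, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(cdf$seg))
  s <- cdf$seg[idx, ]
  frac <- (g_cm - cdf$cum0[idx]) / s$cm
  (s$start - 1) + frac * (s$end - s$start + 1)
}

#' Sample crossover positions of one gamete
#'
#' Simulates the crossovers transmitted by a single gamete along one
#' chromosome. Crossovers form a stationary renewal process on the genetic
#' scale with Gamma(`nu`, rate `nu`) inter-event distances (in Morgans), so
#' the expected crossover count equals the chromosome's genetic length / 100
#' and `nu = 1` recovers a homogeneous Poisson process (no interference).
#' Genetic positions are converted to physical bp by inverting the cumulative
#' landscape.
#'
#' @param landscape A landscape tibble restricted to (or containing) the
#'   chromosome of interest.
#' @param chrom Chromosome name; may be omitted when `landscape` has a single
#'   chromosome.
#' @param interference_shape Gamma shape `nu` (> 0).
#' @return Numeric vector of crossover positions (bp), strictly increasing.
#' @examples
#' land <- recomb_landscape("1H", 1, 5e8, cm = 100)
#' set.seed(1)
#' sample_gamete_crossovers(land)
#' @export
sample_gamete_crossovers <- function(landscape, chrom = NULL,
                                     interference_shape = 1) {
  landscape <- validate_landscape(landscape)
  chrom <- chrom %||% unique(landscape$chrom)
  if (length(chrom) != 1) abort("specify a single chromosome")
  if (interference_shape <= 0) abort("`interference_shape` must be > 0")
  cdf <- .land_cdf(landscape, chrom)
  g <- .sample_renewal_morgans(cdf$total / 100, interference_shape)
  sort(.genetic_to_bp(g * 100, cdf))
}

# stationary gamma-renewal event positions on (0, d] Morgans; nu = 1 uses the
# Poisson shortcut, otherwise a 10-Morgan burn-in settles the renewal process
# into stationarity before the origin
.sample_renewal_morgans <- function(d, nu) {
  if (d <= 0) return(numeric(0))
  if (nu == 1) {
    n <- rpois(1, d)
    return(sort(runif(n, 0, d)))
  }
  t0 <- -10
  span <- d - t0
  pts <- numeric(0)
  t <- t0
  repeat {
    gaps <- rgamma(ceiling(span * 2) + 10, shape = nu, rate = nu)
    new <- t + cumsum(gaps)
    pts <- c(pts, new)
    t <- new[length(new)]
    if (t > d) break
  }
  pts[pts > 0 & pts <= d]
}

#' Simulate an F2 population with known crossover truth
#'
#' Each F2 individual is formed from two independently simulated gametes; a
#' gamete starts on a uniformly chosen parental haplotype and switches
#' haplotype at each of its crossover positions. Genotypes at the marker
#' positions are the unordered combination of the two gamete haplotypes
#' (AA / HET / BB). Genotyping noise (allele errors, then missing calls) is
#' applied after the truth records are taken, so the returned truth is exact.
#'
#' @param config A [sim_config()].
#' @return A list of class `xo_sim` with elements `geno` (an [xo_geno]
#'   genotype container), `truth` (tibble `individual`, `gamete`, `chrom`,
#'   `pos` with one row per true crossover) and `config`.
#' @examples
#' sim <- simulate_f2(sim_config(n_individuals = 4,
#'   chromosomes = default_chromosomes(1, cm_per_chrom = 50),
#'   markers_per_mbp = 0.1, seed = 7))
#' sim$geno
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_f2_impl(config))
}

.simulate_f2_impl <- function(config) {
  chroms <- config$chromosomes
  n <- config$n_individuals
  ids <- sprintf("ind_%03d", seq_len(n))

  if (is.null(config$marker_map)) {
    mm <- pmap(chroms, function(chrom, length_bp, ...) {
      n_mark <- max(2L, round(config$markers_per_mbp * length_bp / 1e6))
      pos <- sort(sample.int(length_bp, n_mark))
      tibble(marker = sprintf("M%s_%04d", chrom, seq_len(n_mark)),
             chrom = chrom, pos = as.numeric(pos))
    }) |> list_rbind()
  } else {
    mm <- as_tibble(config$marker_map[c("marker", "chrom", "pos")]) |>
      arrange(factor(.data$chrom, levels = chroms$chrom), .data$pos)
  }

  calls <- matrix(NA_integer_, nrow = n, ncol = nrow(mm),
                  dimnames = list(ids, mm$marker))
  truth <- vector("list", nrow(chroms))

  for (ci in seq_len(nrow(chroms))) {
    ch <- chroms$chrom[ci]
    cdf <- .land_cdf(config$landscape, ch)
    cols <- which(mm$chrom == ch)
    pos <- mm$pos[cols]
    tr_ind <- integer(0); tr_gam <- integer(0); tr_pos <- numeric(0)
    for (i in seq_len(n)) {
      hap <- matrix(0L, nrow = 2, ncol = length(cols))
      for (g in 1:2) {
        co <- sort(.genetic_to_bp(
          .sample_renewal_morgans(cdf$total / 100,
                                  config$interference_shape) * 100, cdf))
        start <- sample(0:1, 1)
        hap[g, ] <- (start + findInterval(pos, co)) %% 2L
        if (length(co)) {
          tr_ind <- c(tr_ind, rep(i, length(co)))
          tr_gam <- c(tr_gam, rep(g, length(co)))
          tr_pos <- c(tr_pos, co)
        }
      }
      calls[i, cols] <- hap[1, ] + hap[2, ]
    }
    truth[[ci]] <- tibble(individual = ids[tr_ind], gamete = tr_gam,
                          chrom = ch, pos = tr_pos)
  }
  truth <- list_rbind(truth) |>
    arrange(.data$individual, .data$chrom, .data$gamete, .data$pos)

  # genotyping noise: missing first, then allele errors on surviving calls
  n_cells <- length(calls)
  if (config$missing_rate > 0) {
    calls[runif(n_cells) < config$missing_rate] <- NA_integer_
  }
  if (config$allele_error_rate > 0) {
    hit <- which(!is.na(calls) & runif(n_cells) < config$allele_error_rate)
    if (length(hit)) {
      # replace by one of the two other codes, uniformly
      shift <- sample(1:2, length(hit), replace = TRUE)
      calls[hit] <- (calls[hit] + shift) %% 3L
    }
  }

  structure(list(geno = new_xo_geno(calls, mm), truth = truth,
                 config = config),
            class = "xo_sim")
}

#' Simulate two populations genotyped on one shared array
#'
#' Convenience preset for a two-population comparison study: both populations
#' share a single marker map (as when two F2 populations are genotyped on the
#' same fixed SNP array) and differ only in their recombination landscape.
#'
#' @param n_individuals Individuals per population.
#' @param chromosomes Chromosome set tibble.
#' @param landscape_a,landscape_b Landscapes of the two populations;
#'   `landscape_b` defaults to `landscape_a`.
#' @param markers_per_mbp Shared marker density.
#' @param allele_error_rate,missing_rate Noise model, shared.
#' @param interference_shape Gamma renewal shape, shared.
#' @param seed Integer seed (the two populations use `seed` and `seed + 1`;
#'   the marker map is drawn under `seed`).
#' @return List with elements `pop_a`, `pop_b` (each an `xo_sim`).
#' @export
simulate_populations <- function(n_individuals = 90,
                                 chromosomes = default_chromosomes(),
                                 landscape_a = ushaped_landscape(chromosomes),
                                 landscape_b = landscape_a,
                                 markers_per_mbp = 2.6,
                                 allele_error_rate = 0.002,
                                 missing_rate = 0.02,
                                 interference_shape = 1,
                                 seed = 1L) {
  mm <- withr::with_seed(seed, {
    pmap(chromosomes, function(chrom, length_bp, ...) {
      n_mark <- max(2L, round(markers_per_mbp * length_bp / 1e6))
      tibble(marker = sprintf("M%s_%04d", chrom, seq_len(n_mark)),
             chrom = chrom,
             pos = as.numeric(sort(sample.int(length_bp, n_mark))))
    }) |> list_rbind()
  })
  mk <- function(land, sd) {
    simulate_f2(sim_config(n_individuals = n_individuals,
                           chromosomes = chromosomes,
                           landscape = land,
                           interference_shape = interference_shape,
                           marker_map = mm,
                           allele_error_rate = allele_error_rate,
                           missing_rate = missing_rate,
                           seed = sd))
  }
  list(pop_a = mk(landscape_a, seed), pop_b = mk(landscape_b, seed + 1L))
}

#' Write / read a simulation configuration as YAML
#'
#' Serialises every field of a [sim_config()] (chromosomes and landscape as
#' records) so a simulation is fully described by a plain-text file plus the
#' marker map.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`; the writer returns
#'   `config` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- list(n_individuals = config$n_individuals,
            interference_shape = config$interference_shape,
            markers_per_mbp = config$markers_per_mbp,
            allele_error_rate = config$allele_error_rate,
            missing_rate = config$missing_rate,
            seed = config$seed,
            chromosomes = lapply(seq_len(nrow(config$chromosomes)),
                                 function(i) as.list(config$chromosomes[i, ])),
            landscape = lapply(seq_len(nrow(config$landscape)),
                               function(i) as.list(config$landscape[i, ])))
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("n_individuals", "seed", "landscape")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("missing config key(s): %s", paste(miss, collapse = ", ")))
  }
  land <- list_rbind(lapply(x$landscape, as_tibble))
  chroms <- list_rbind(lapply(x$chromosomes, as_tibble))
  sim_config(n_individuals = x$n_individuals,
             chromosomes = chroms,
             landscape = land,
             interference_shape = x$interference_shape %||% 1,
             markers_per_mbp = x$markers_per_mbp %||% 2.6,
             allele_error_rate = x$allele_error_rate %||% 0.002,
             missing_rate = x$missing_rate %||% 0.02,
             seed = x$seed)
}

#' Write truth records as JSON lines
#'
#' One JSON object per line with fields `individual`, `gamete`, `chrom`,
#' `pos`.
#'
#' @param truth Truth tibble from [simulate_f2()].
#' @param path Output path.
#' @return `truth`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE), con)
  }
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  list_rbind(lapply(lines, function(l) as_tibble(jsonlite::fromJSON(l))))
}
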