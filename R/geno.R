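#' F2 genotype container
#'
#' Pairs an individuals x markers call matrix with its marker map. Calls are
#' stored internally as integers (0 = AA, 1 = HET, 2 = BB, NA = missing);
#' `AA` denotes the parent-A homozygote and `BB` the parent-B homozygote.
#' Markers are kept in physical order (chromosome, then bp), which is the
#' analysis order throughout the package.
#'
#' @param calls Integer (or character) matrix, individuals in rows, markers in
#'   columns; character matrices may use `"AA"/"HET"/"BB"` or `"A"/"H"/"B"`.
#' @param map Marker map tibble with columns `marker`, `chrom`, `pos`
#'   (bp, 1-based), rows aligned with the columns of `calls`.
#' @return An object of class `xo_geno`.
#' @export
xo_geno <- function(calls, map) {
  if (is.character(calls)) {
    lab <- calls
    lab[lab %in% names(.geno_tokens)] <-
      .geno_tokens[lab[lab %in% names(.geno_tokens)]]
    code <- match(lab, .geno_tokens) - 1L
    code[is.na(lab)] <- NA_integer_
    if (any(!is.na(lab) & is.na(code))) abort("unknown genotype call codes")
    calls <- matrix(code, nrow = nrow(calls), dimnames = dimnames(calls))
  }
  new_xo_geno(calls, map)
}

new_xo_geno <- function(calls, map) {
  stopifnot(is.matrix(calls), is.data.frame(map),
            all(c("marker", "chrom", "pos") %in% names(map)))
  map <- as_tibble(map)
  if (ncol(calls) != nrow(map)) {
    abort("number of call-matrix columns must equal number of markers in the map")
  }
  if (anyDuplicated(map$marker)) abort("duplicated marker ids in map")
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind_%03d", seq_len(nrow(calls)))
  }
  if (anyDuplicated(rownames(calls))) abort("duplicated individual ids")
  colnames(calls) <- map$marker
  storage.mode(calls) <- "integer"
  if (any(!is.na(calls) & (calls < 0L | calls > 2L))) {
    abort("call codes must be 0 (AA), 1 (HET), 2 (BB) or NA")
  }
  structure(list(calls = calls, map = map), class = "xo_geno")
}

#' @export
print.xo_geno <- function(x, ...) {
  cat(sprintf("<xo_geno> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  het <- mean(x$calls == 1L, na.rm = TRUE)
  cat(sprintf("  missing %.2f%%, heterozygous %.2f%% of non-missing calls\n",
              100 * miss, 100 * het))
  invisible(x)
}

#' @export
dim.xo_geno <- function(x) dim(x$calls)

# keep the given markers (map order preserved)
subset_markers <- function(geno, markers) {
  keep <- which(geno$map$marker %in% markers)
  new_xo_geno(geno$calls[, keep, drop = FALSE], geno$map[keep, ])
}

#' Genotype calls as a tidy tibble
#'
#' @param x An `xo_geno`.
#' @param ... Unused.
#' @return Long tibble with columns `individual`, `marker`, `chrom`, `pos`,
#'   `call` (`"AA"/"HET"/"BB"` or `NA`).
#' @export
tidy.xo_geno <- function(x, ...) {
  tibble(individual = rep(rownames(x$calls), times = ncol(x$calls)),
         marker = rep(x$map$marker, each = nrow(x$calls)),
         chrom = rep(x$map$chrom, each = nrow(x$calls)),
         pos = rep(x$map$pos, each = nrow(x$calls)),
         call = .code_to_label(as.vector(x$calls)))
}

#' Write genotypes and marker map as TSV
#'
#' Genotype file: one row per marker in map order, first column `marker`,
#' remaining columns one per individual, calls coded `A` / `H` / `B` / `NA`.
#' Map file: columns `marker`, `chrom`, `pos` (1-based bp).
#'
#' @param geno An [xo_geno].
#' @param geno_path,map_path Output paths.
#' @return `geno`, invisibly.
#' @export
write_genotypes <- function(geno, geno_path, map_path) {
  stopifnot(inherits(geno, "xo_geno"))
  tokens <- matrix(.geno_tokens[.code_to_label(as.vector(geno$calls))],
                   nrow = nrow(geno$calls))
  df <- as_tibble(t(tokens), .name_repair = "minimal")
  names(df) <- rownames(geno$calls)
  df <- bind_cols(tibble(marker = geno$map$marker), df)
  readr::write_tsv(df, geno_path)
  readr::write_tsv(geno$map, map_path)
  invisible(geno)
}

#' Read genotypes and marker map from TSV
#'
#' Reads the dialect written by [write_genotypes()]. Markers are re-sorted to
#' physical order (chromosome in map-file order, then position). Unrecognised
#' call tokens are coerced to missing with a single warning reporting the
#' count; a genotype-file marker absent from the map, or a duplicated
#' individual id, is an error.
#'
#' @param geno_path,map_path Input paths.
#' @return An [xo_geno].
#' @export
read_genotypes <- function(geno_path, map_path) {
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(marker = "c", chrom = "c",
                                                 pos = "d"))
  gdf <- readr::read_tsv(geno_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"),
                         name_repair = "minimal")
  if (names(gdf)[1] != "marker") abort("genotype file must have a `marker` first column")
  ind <- names(gdf)[-1]
  if (anyDuplicated(ind)) {
    abort(sprintf("duplicated individual id(s): %s",
                  paste(unique(ind[duplicated(ind)]), collapse = ", ")))
  }
  missing_from_map <- setdiff(gdf$marker, map$marker)
  if (length(missing_from_map)) {
    abort(sprintf("genotype marker(s) absent from map: %s",
                  paste(missing_from_map, collapse = ", ")))
  }
  map <- map |>
    arrange(factor(.data$chrom, levels = unique(.data$chrom)), .data$pos) |>
    filter(.data$marker %in% gdf$marker)
  tok <- as.matrix(gdf[-1])
  rownames(tok) <- gdf$marker
  tok <- tok[map$marker, , drop = FALSE]
  known <- is.na(tok) | tok %in% c(.geno_tokens, "NA")
  n_bad <- sum(!known)
  if (n_bad > 0) {
    warn(sprintf("%d unrecognised call token(s) coerced to missing", n_bad))
    tok[!known] <- NA_character_
  }
  tok[tok == "NA"] <- NA_character_
  code <- match(tok, .geno_tokens) - 1L
  calls <- matrix(code, nrow = nrow(tok), dimnames = dimnames(tok))
  new_xo_geno(t(calls), map)
}
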