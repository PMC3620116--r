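#' Site-by-library tag count container
#'
#' Holds the dense digestion-frequency matrix of an MSCC experiment: raw
#' integer counts for every cataloged site in every library, the design
#' sheet (library, condition, replicate, barcode), and — after
#' [normalize_counts()] — per-library normalization factors and the
#' normalized matrix. Zero counts are meaningful (fully methylated site or
#' shallow coverage) and are kept.
#'
#' @param sites Tibble with `chrom`, `pos` (one row per site).
#' @param counts Integer matrix, `nrow(sites)` x `nrow(design)`, with
#'   column names equal to `design$library`.
#' @param design Tibble with at least `library`, `condition`, `replicate`.
#' @return An object of class `mscc_counts`.
#' @export
new_mscc_counts <- function(sites, counts, design) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(sites)) abort("counts/sites row mismatch")
  if (ncol(counts) != nrow(design)) abort("counts/design column mismatch")
  if (any(counts < 0)) abort("raw counts must be non-negative")
  if (is.null(colnames(counts))) colnames(counts) <- design$library
  if (!identical(colnames(counts), design$library)) {
    abort("count matrix columns must match design$library")
  }
  structure(
    list(sites = tibble::as_tibble(sites), counts = counts,
         design = tibble::as_tibble(design),
         norm_factors = NULL, normalized = NULL),
    class = "mscc_counts"
  )
}

#' @export
print.mscc_counts <- function(x, ...) {
  cat(sprintf("<mscc_counts> %d sites x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = " vs ")))
  cat(if (is.null(x$normalized)) "  raw counts only\n"
      else "  normalized (factors: mean-total scaling)\n")
  invisible(x)
}

#' @rdname new_mscc_counts
#' @param x An `mscc_counts` object.
#' @param normalized Return normalized values where available.
#' @param ... Unused.
#' @method tidy mscc_counts
#' @export
tidy.mscc_counts <- function(x, normalized = FALSE, ...) {
  m <- if (normalized) {
    if (is.null(x$normalized)) abort("not normalized yet; run normalize_counts()")
    x$normalized
  } else {
    x$counts
  }
  dplyr::bind_cols(x$sites, tibble::as_tibble(m)) %>%
    tidyr::pivot_longer(-c("chrom", "pos"), names_to = "library",
                        values_to = "count") %>%
    dplyr::left_join(x$design, by = "library")
}

# site x library matrix to use for testing: normalized when available
count_values <- function(x, normalized = TRUE) {
  if (normalized && !is.null(x$normalized)) x$normalized else x$counts
}

#' Normalize libraries to a common total
#'
#' Each library is rescaled by a factor proportional to (the inverse of) its
#' total read count: `factor_j = mean(totals) / total_j`, so that every
#' normalized library total equals the mean raw total. Any positive scaling
#' constant yields identical downstream Welch statistics; the mean keeps
#' normalized values on the raw-count scale.
#'
#' @param x An [mscc_counts] object.
#' @return The object with `norm_factors` and `normalized` filled in.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "mscc_counts"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    abort(paste0("library with zero total reads: ",
                 paste(x$design$library[totals == 0], collapse = ", ")))
  }
  factors <- mean(totals) / totals
  x$norm_factors <- stats::setNames(factors, x$design$library)
  x$normalized <- sweep(x$counts, 2, factors, `*`)
  x
}

#' Write / read a count matrix as TSV
#'
#' One row per site (`chrom`, `pos`) and one column per library; raw counts.
#'
#' @param x An [mscc_counts] object.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "mscc_counts"))
  readr::write_tsv(dplyr::bind_cols(x$sites, tibble::as_tibble(x$counts)), path)
  invisible(path)
}

#' @rdname write_counts
#' @param design Design tibble matching the file's library columns.
#' @export
read_counts <- function(path, design) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  libs <- design$library
  missing <- setdiff(libs, names(df))
  if (length(missing) > 0) {
    abort(paste0("count file lacks libraries: ", paste(missing, collapse = ", ")))
  }
  new_mscc_counts(df[, c("chrom", "pos")],
                  as.matrix(df[, libs]), design)
}
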