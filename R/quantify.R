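#' Demultiplex barcoded tag reads
#'
#' A read is assigned to a library iff characters 28-30 equal that library's
#' barcode exactly; 3-nt barcodes leave no safe room for mismatches. Reads
#' shorter than 30 nt are counted malformed; reads whose barcode matches no
#' library are discarded and counted.
#'
#' @param reads Tibble with columns `read_id`, `seq` (or a character vector
#'   of sequences).
#' @param barcode_map Tibble with `library`, `condition`, `replicate`,
#'   `barcode` (distinct barcodes).
#' @return List with `reads` (tibble `read_id`, `tag` = first 27 nt,
#'   `library`, `condition`, `replicate`) and `report` (one row per library
#'   plus totals: reads in, demultiplexed, discarded, malformed).
#' @export
demultiplex <- function(reads, barcode_map) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = sprintf("read_%07d", seq_along(reads)),
                            seq = reads)
  }
  if (anyDuplicated(barcode_map$barcode)) {
    abort("duplicate barcodes in barcode map")
  }
  n_in <- nrow(reads)
  ok_len <- nchar(reads$seq) >= 30L
  n_malformed <- sum(!ok_len)
  kept <- tibble::tibble(
    read_id = reads$read_id[ok_len],
    barcode = substr(reads$seq[ok_len], 28L, 30L),
    tag = substr(reads$seq[ok_len], 1L, 27L)
  )
  assigned <- dplyr::inner_join(kept, barcode_map, by = "barcode")
  n_discarded <- nrow(kept) - nrow(assigned)
  per_lib <- assigned %>%
    dplyr::count(.data$library, name = "demultiplexed") %>%
    dplyr::right_join(barcode_map["library"], by = "library") %>%
    tidyr::replace_na(list(demultiplexed = 0L))
  list(
    reads = assigned[, c("read_id", "tag", "library", "condition", "replicate")],
    report = list(
      reads_in = n_in,
      malformed = n_malformed,
      demultiplexed = nrow(assigned),
      discarded = n_discarded,
      per_library = per_lib
    )
  )
}

# one-mismatch index over the unique sites of a catalog
build_tag_index <- function(catalog) {
  usable <- catalog[catalog$unique %||% rep(TRUE, nrow(catalog)), , drop = FALSE]
  tags <- tibble::tibble(
    chrom = rep(usable$chrom, 2),
    pos = rep(usable$pos, 2),
    strand = rep(c("+", "-"), each = nrow(usable)),
    tag = c(usable$tag_fwd, usable$tag_rev)
  )
  keys <- masked_keys(tags$tag, nchar(tags$tag[1] %||% "")[1])
  keys$chrom <- tags$chrom[keys$idx]
  keys$pos <- tags$pos[keys$idx]
  keys$strand <- tags$strand[keys$idx]
  keys$ref_tag <- tags$tag[keys$idx]
  list(keys = keys[, c("key", "chrom", "pos", "strand", "ref_tag")],
       tag_len = nchar(tags$tag[1] %||% "")[1])
}

#' Map 27-nt tags to catalog sites allowing one mismatch
#'
#' A tag maps to a site if it equals one of the site's two tags exactly, or
#' lies within Hamming distance 1 of the tags of exactly one site. Tags
#' matching several sites at the minimal distance are counted ambiguous and
#' dropped; sites flagged non-unique in the catalog are excluded from the
#' index. Tags whose length differs from the catalog tag length are counted
#' malformed.
#'
#' @param tags Tibble with columns `tag` and `library` (extra columns such
#'   as `read_id` are carried through), or a character vector of tags.
#' @param catalog Catalog with `tag_fwd`, `tag_rev` and `unique` columns.
#' @return List with `assignments` (tibble: input columns plus `chrom`,
#'   `pos`, `strand`, `distance`) and `report` (counts: input, mapped_exact,
#'   mapped_1mm, ambiguous, unmapped, malformed).
#' @export
map_tags <- function(tags, catalog) {
  if (is.character(tags)) tags <- tibble::tibble(tag = tags)
  if (!"library" %in% names(tags)) tags$library <- "library_1"
  if (!all(c("tag_fwd", "tag_rev") %in% names(catalog))) {
    abort("catalog lacks tags; run extract_tags()/mark_unique_tags() first")
  }
  idx <- build_tag_index(catalog)
  n_in <- nrow(tags)
  tags$.qid <- seq_len(n_in)
  ok <- nchar(tags$tag) == idx$tag_len
  n_malformed <- sum(!ok)
  q <- tags[ok, , drop = FALSE]

  if (nrow(q) == 0 || nrow(idx$keys) == 0) {
    hits <- q[0, ]
    hits$chrom <- character(0); hits$pos <- integer(0)
    hits$strand <- character(0); hits$distance <- integer(0)
    return(list(assignments = hits[, setdiff(names(hits), ".qid")],
                report = list(input = n_in, mapped_exact = 0L, mapped_1mm = 0L,
                              ambiguous = 0L, unmapped = n_in - n_malformed,
                              malformed = n_malformed)))
  }

  qkeys <- masked_keys(q$tag, idx$tag_len)
  qkeys$qid <- q$.qid[qkeys$idx]
  qkeys$qtag <- q$tag[qkeys$idx]
  cand <- dplyr::inner_join(qkeys, idx$keys, by = "key",
                            relationship = "many-to-many") %>%
    dplyr::distinct(.data$qid, .data$qtag, .data$chrom, .data$pos,
                    .data$strand, .data$ref_tag)
  cand$distance <- hamming(cand$qtag, cand$ref_tag)

  resolved <- cand %>%
    dplyr::group_by(.data$qid) %>%
    dplyr::filter(.data$distance == min(.data$distance)) %>%
    # both strands of one site can match (near-palindromic tags): keep one
    dplyr::arrange(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::summarise(
      n_sites = dplyr::n_distinct(paste0(.data$chrom, ":", .data$pos)),
      chrom = dplyr::first(.data$chrom),
      pos = dplyr::first(.data$pos),
      strand = dplyr::first(.data$strand),
      distance = dplyr::first(.data$distance),
      .groups = "drop"
    )
  unambiguous <- resolved[resolved$n_sites == 1L, , drop = FALSE]
  n_ambig <- sum(resolved$n_sites > 1L)

  assignments <- dplyr::inner_join(q, unambiguous, by = c(".qid" = "qid"))
  n_exact <- sum(assignments$distance == 0L)
  n_1mm <- sum(assignments$distance == 1L)
  n_unmapped <- nrow(q) - nrow(assignments) - n_ambig

  list(
    assignments = assignments[, setdiff(names(assignments),
                                        c(".qid", "n_sites"))],
    report = list(input = n_in, mapped_exact = n_exact, mapped_1mm = n_1mm,
                  ambiguous = n_ambig, unmapped = n_unmapped,
                  malformed = n_malformed)
  )
}

#' Collapse strand tags into per-site digestion counts
#'
#' Counts from a site's forward and reverse tags are summed into a single
#' digestion frequency per site and library. The matrix is dense over every
#' unique catalog site: sites with no hits carry an explicit zero.
#'
#' @param assignments Assignment tibble from [map_tags()] (needs `chrom`,
#'   `pos`, `library`).
#' @param catalog Site catalog (its unique sites define the matrix rows).
#' @param design Design tibble (`library`, `condition`, `replicate`, ...).
#' @return An [mscc_counts] object with raw counts.
#' @export
collapse_strands <- function(assignments, catalog, design) {
  usable <- if ("unique" %in% names(catalog)) {
    catalog[catalog$unique, , drop = FALSE]
  } else catalog
  sites <- usable[, c("chrom", "pos")]
  keys <- site_key(sites$chrom, sites$pos)
  counts <- matrix(0L, nrow = nrow(sites), ncol = nrow(design),
                   dimnames = list(NULL, design$library))
  if (nrow(assignments) > 0) {
    tab <- assignments %>%
      dplyr::count(.data$chrom, .data$pos, .data$library)
    ri <- match(site_key(tab$chrom, tab$pos), keys)
    ci <- match(tab$library, design$library)
    if (anyNA(ri)) abort("assignments contain sites outside the catalog")
    if (anyNA(ci)) abort("assignments contain libraries outside the design")
    counts[cbind(ri, ci)] <- tab$n
  }
  new_mscc_counts(sites, counts, design)
}

#' Count tags from raw reads in one call
#'
#' Demultiplex, map with one mismatch, collapse strands and normalize.
#' Barcodes only need to be unique within a condition's sequencing pool:
#' when the reads carry a `condition` column (each condition sequenced as
#' its own pooled library, the usual MSCC design), each pool is
#' demultiplexed against its own slice of the design sheet.
#'
#' @param reads Read tibble or character vector (see [demultiplex()]).
#' @param catalog Site catalog with tags and uniqueness flags.
#' @param barcode_map Barcode map / design sheet.
#' @return List with `counts` (normalized [mscc_counts]) and `report`
#'   (demultiplexing and mapping tallies).
#' @export
count_tags <- function(reads, catalog, barcode_map) {
  pooled <- is.data.frame(reads) && "condition" %in% names(reads) &&
    "condition" %in% names(barcode_map) &&
    anyDuplicated(barcode_map$barcode) > 0
  if (pooled) {
    dms <- lapply(unique(barcode_map$condition), function(cc) {
      demultiplex(reads[reads$condition == cc, , drop = FALSE],
                  barcode_map[barcode_map$condition == cc, , drop = FALSE])
    })
    dm <- list(
      reads = dplyr::bind_rows(lapply(dms, `[[`, "reads")),
      report = list(
        reads_in = sum(vapply(dms, function(d) d$report$reads_in, 0)),
        malformed = sum(vapply(dms, function(d) d$report$malformed, 0)),
        demultiplexed = sum(vapply(dms, function(d) d$report$demultiplexed, 0)),
        discarded = sum(vapply(dms, function(d) d$report$discarded, 0)),
        per_library = dplyr::bind_rows(lapply(dms, function(d) d$report$per_library))
      )
    )
  } else {
    dm <- demultiplex(reads, barcode_map)
  }
  mp <- map_tags(dm$reads, catalog)
  counts <- collapse_strands(mp$assignments, catalog, barcode_map) %>%
    normalize_counts()
  list(counts = counts,
       report = list(demultiplex = dm$report, mapping = mp$report))
}
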