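#' Default methylation-sensitive restriction enzyme panel
#'
#' The four MSREs used for methyl-sensitive cut counting: HpaII (CCGG),
#' AciI (CCGC), HpyCH4IV (ACGT) and HinP1I (GCGC). All four cut only when
#' their site is unmethylated and leave a 5'-CG overhang, so each recognition
#' motif contains a CG dinucleotide immediately after the cut.
#'
#' @param enzymes Optional tibble with columns `enzyme`, `motif`,
#'   `cut_offset` (0-based offset of the cut within the motif; the CG
#'   overhang starts at that offset). Defaults to the four-enzyme panel.
#' @return A validated tibble with columns `enzyme`, `motif`, `cut_offset`.
#' @examples
#' enzyme_panel()
#' @export
enzyme_panel <- function(enzymes = NULL) {
  panel <- enzymes %||% tibble::tibble(
    enzyme     = c("HpaII", "AciI", "HpyCH4IV", "HinP1I"),
    motif      = c("CCGG", "CCGC", "ACGT", "GCGC"),
    cut_offset = c(1L, 1L, 1L, 1L)
  )
  req <- c("enzyme", "motif", "cut_offset")
  if (!all(req %in% names(panel))) {
    abort("enzyme panel needs columns enzyme, motif, cut_offset")
  }
  cg <- substr(panel$motif, panel$cut_offset + 1, panel$cut_offset + 2)
  if (any(cg != "CG")) {
    abort(paste0("recognition motif without a CG overhang at the cut: ",
                 paste(panel$motif[cg != "CG"], collapse = ", ")))
  }
  tibble::as_tibble(panel)
}

#' Scan a genome for methylation-sensitive restriction sites
#'
#' Finds every occurrence of every panel motif (both orientations for
#' non-palindromic motifs such as AciI's CCGC) and records the surveyed CG
#' site each cut interrogates. The site is keyed by the 0-based
#' forward-strand coordinate of the C of the CG; cuts on either strand at
#' the same CG collapse to a single catalog entry. Motif windows containing
#' N never match.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @param panel Enzyme panel tibble, see [enzyme_panel()].
#' @param both_strands Scan the reverse-complement image of non-palindromic
#'   motifs (default `TRUE`).
#' @return A tibble (the CG-site catalog) with columns `chrom`, `pos`
#'   (0-based coordinate of the C), and `enzymes` (comma-separated panel
#'   names hitting that CG), sorted by `(chrom, pos)`.
#' @examples
#' scan_restriction_sites(c(chr1 = "TCCGGA"))
#' @export
scan_restriction_sites <- function(genome, panel = enzyme_panel(),
                                   both_strands = TRUE) {
  gs <- as_genome(genome)
  panel <- enzyme_panel(panel)

  hits <- vector("list", 0)
  for (ci in seq_along(gs)) {
    contig <- gs[[ci]]
    cname <- names(gs)[ci]
    for (ei in seq_len(nrow(panel))) {
      motif <- panel$motif[ei]
      off <- panel$cut_offset[ei]
      len <- nchar(motif)
      rc <- revcomp(motif)
      # forward-orientation matches: CG at match_start0 + cut_offset
      m <- Biostrings::matchPattern(motif, contig, fixed = TRUE)
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          chrom = cname,
          pos = BiocGenerics::start(m) - 1L + off,
          enzyme = panel$enzyme[ei]
        )
      }
      # reverse-orientation matches (minus-strand site); the CG overhang of
      # the minus-strand cut maps to forward offset len - cut_offset - 2
      if (both_strands && rc != motif) {
        m2 <- Biostrings::matchPattern(rc, contig, fixed = TRUE)
        if (length(m2) > 0) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            chrom = cname,
            pos = BiocGenerics::start(m2) - 1L + (len - off - 2L),
            enzyme = panel$enzyme[ei]
          )
        }
      }
    }
  }

  if (length(hits) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          enzymes = character()))
  }
  dplyr::bind_rows(hits) %>%
    dplyr::distinct() %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(
      enzymes = paste(sort(unique(.data$enzyme)), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Extract the CG tags flanking each surveyed site
#'
#' The assay sequences `tag_len` (default 27) nucleotides on each side of
#' the cut. `tag_fwd` is the forward-strand sequence starting at the C of
#' the CG and extending 3'; `tag_rev` is the reverse complement of the
#' `tag_len` nucleotides ending at the G of the CG. Sites too close to a
#' contig edge to yield both tags are dropped; the number dropped is kept in
#' the `"n_dropped_edge"` attribute.
#'
#' @param catalog Catalog from [scan_restriction_sites()].
#' @param genome The same genome the catalog was built from.
#' @param tag_len Tag length in nt; must be positive.
#' @return The catalog with `tag_fwd` and `tag_rev` columns added.
#' @export
extract_tags <- function(catalog, genome, tag_len = 27L) {
  if (!is.numeric(tag_len) || length(tag_len) != 1 || tag_len <= 0) {
    abort("`tag_len` must be a positive integer")
  }
  tag_len <- as.integer(tag_len)
  gs <- as_genome(genome)
  missing_chrom <- setdiff(unique(catalog$chrom), names(gs))
  if (length(missing_chrom) > 0) {
    abort(paste0("catalog chromosomes absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }

  widths <- stats::setNames(Biostrings::width(gs), names(gs))
  ok <- catalog$pos + tag_len <= widths[catalog$chrom] &
    catalog$pos >= tag_len - 2L
  n_dropped <- sum(!ok)
  kept <- catalog[ok, , drop = FALSE]
  if (nrow(kept) == 0) {
    kept$tag_fwd <- character(0)
    kept$tag_rev <- character(0)
    attr(kept, "n_dropped_edge") <- n_dropped
    return(kept)
  }

  out <- kept %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      s <- as.character(gs[[key$chrom]])
      df$tag_fwd <- substring(s, df$pos + 1L, df$pos + tag_len)
      df$tag_rev <- revcomp(substring(s, df$pos + 3L - tag_len, df$pos + 2L))
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "n_dropped_edge") <- n_dropped
  out
}

#' Flag sites whose tags are ambiguous under one-mismatch mapping
#'
#' A site is `unique` when neither of its tags lies within Hamming distance
#' 1 of any tag belonging to a different site. Non-unique sites cannot be
#' counted unambiguously by a one-mismatch mapper and are excluded from the
#' counting index.
#'
#' @param catalog Catalog with `tag_fwd`/`tag_rev` from [extract_tags()].
#' @return The catalog with a logical `unique` column added.
#' @export
mark_unique_tags <- function(catalog) {
  if (!all(c("tag_fwd", "tag_rev") %in% names(catalog))) {
    abort("catalog lacks tags; run extract_tags() first")
  }
  n <- nrow(catalog)
  if (n == 0) {
    catalog$unique <- logical(0)
    return(catalog)
  }
  tag_len <- nchar(catalog$tag_fwd[1])
  tags <- tibble::tibble(
    site = rep(seq_len(n), 2),
    tag = c(catalog$tag_fwd, catalog$tag_rev)
  )
  keys <- masked_keys(tags$tag, tag_len)
  keys$site <- tags$site[keys$idx]
  clash <- keys %>%
    dplyr::distinct(.data$key, .data$site) %>%
    dplyr::count(.data$key) %>%
    dplyr::filter(.data$n > 1L)
  bad_sites <- keys %>%
    dplyr::semi_join(clash, by = "key") %>%
    dplyr::distinct(.data$site)
  catalog$unique <- !(seq_len(n) %in% bad_sites$site)
  catalog
}

#' Build the full surveyed-CG catalog for a genome
#'
#' Convenience wrapper: scan, tag extraction and uniqueness screening.
#'
#' @inheritParams scan_restriction_sites
#' @inheritParams extract_tags
#' @return Catalog tibble with columns `chrom`, `pos`, `enzymes`,
#'   `tag_fwd`, `tag_rev`, `unique`.
#' @export
build_catalog <- function(genome, panel = enzyme_panel(), tag_len = 27L) {
  scan_restriction_sites(genome, panel) %>%
    extract_tags(genome, tag_len = tag_len) %>%
    mark_unique_tags()
}

#' Census of CG dinucleotides covered by the enzyme panel
#'
#' Counts forward-strand CG dinucleotides in the genome and the fraction of
#' them interrogated by the restriction panel (the surveyed fraction).
#'
#' @param catalog Site catalog.
#' @param genome Genome the catalog was built from.
#' @return One-row tibble with `total_cg`, `surveyed_cg`, `fraction`.
#' @examples
#' g <- c(chr1 = "TCCGGA")
#' cg_census(scan_restriction_sites(g), g)
#' @export
cg_census <- function(catalog, genome) {
  gs <- as_genome(genome)
  total <- sum(Biostrings::vcountPattern("CG", gs, fixed = TRUE))
  surveyed <- nrow(dplyr::distinct(catalog, .data$chrom, .data$pos))
  tibble::tibble(
    total_cg = total,
    surveyed_cg = surveyed,
    fraction = ifelse(total == 0, NA_real_, surveyed / total)
  )
}

#' Export a catalog as BED (0-based half-open) intervals over each CG
#'
#' @param catalog Site catalog.
#' @return Tibble with BED columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
catalog_to_bed <- function(catalog) {
  tibble::tibble(
    chrom = catalog$chrom,
    start = catalog$pos,
    end = catalog$pos + 2L,
    name = site_key(catalog$chrom, catalog$pos),
    score = 0L,
    strand = "+"
  )
}

#' Export a catalog as GFF3 (1-based, closed) records over each CG
#'
#' @param catalog Site catalog.
#' @return Tibble with GFF3 columns.
#' @export
catalog_to_gff3 <- function(catalog) {
  tibble::tibble(
    seqid = catalog$chrom,
    source = "mscc",
    type = "CG_site",
    start = catalog$pos + 1L,
    end = catalog$pos + 2L,
    score = ".",
    strand = "+",
    phase = ".",
    attributes = paste0("ID=", site_key(catalog$chrom, catalog$pos),
                        if ("enzymes" %in% names(catalog)) {
                          paste0(";enzymes=", catalog$enzymes)
                        } else "")
  )
}
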