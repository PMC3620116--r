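#' Write and read a CG-site catalog as TSV
#'
#' Columns: `chrom`, `pos` (0-based), `enzymes`, `tag_fwd`, `tag_rev`,
#' `unique`.
#'
#' @param catalog Catalog tibble.
#' @param path File path.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}

#' Write a genome as FASTA
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path File path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Quality is constant (the simulator has no quality model).
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param path File path (`.gz` supported).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      strrep("I", nchar(reads$seq))
    ),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' @rdname write_fastq
#' @return `read_fastq()`: tibble with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub(" .*", "", names(x)), seq = as.character(x))
}

#' Export gene models as GFF3
#'
#' One `gene` record plus one `exon` record per exon, 1-based closed
#' coordinates.
#'
#' @param genes Gene annotation from [simulate_genome()].
#' @return Tibble of GFF3 columns.
#' @export
genes_to_gff3 <- function(genes) {
  gene_rows <- tibble::tibble(
    seqid = genes$chrom, source = "mscc", type = "gene",
    start = genes$start, end = genes$end, score = ".",
    strand = genes$strand, phase = ".",
    attributes = paste0("ID=", genes$gene_id)
  )
  exon_rows <- genes %>%
    dplyr::mutate(exon = strsplit(.data$exons, ",")) %>%
    tidyr::unnest("exon") %>%
    tidyr::separate("exon", c("ex_start", "ex_end"), sep = "-",
                    convert = TRUE) %>%
    dplyr::transmute(
      seqid = .data$chrom, source = "mscc", type = "exon",
      start = .data$ex_start, end = .data$ex_end, score = ".",
      strand = .data$strand, phase = ".",
      attributes = paste0("Parent=", .data$gene_id)
    )
  dplyr::bind_rows(gene_rows, exon_rows) %>%
    dplyr::arrange(.data$seqid, .data$start)
}

#' @rdname genes_to_gff3
#' @param path File path.
#' @export
write_gff3 <- function(genes, path) {
  gff <- genes_to_gff3(genes)
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Export gene models as BED12
#'
#' 0-based half-open; blocks are the exons.
#'
#' @param genes Gene annotation.
#' @return Tibble of BED12 columns.
#' @export
genes_to_bed12 <- function(genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- do.call(rbind, lapply(strsplit(g$exons, ",")[[1]], function(e) {
      as.integer(strsplit(e, "-")[[1]])
    }))
    tibble::tibble(
      chrom = g$chrom, start = g$start - 1L, end = g$end,
      name = g$gene_id, score = 0L, strand = g$strand,
      thick_start = g$start - 1L, thick_end = g$end, rgb = "0",
      block_count = nrow(ex),
      block_sizes = paste0(paste(ex[, 2] - ex[, 1] + 1L, collapse = ","), ","),
      block_starts = paste0(paste(ex[, 1] - g$start, collapse = ","), ",")
    )
  })
  dplyr::bind_rows(rows)
}
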