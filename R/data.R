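#' Worked-example GO enrichment table
#'
#' A published genome-scale GO enrichment analysis of Arabidopsis genes
#' whose promoters gained ("met") or lost ("unmet") methylation under
#' simulated drought: for each term the reported p-value, BH q-value,
#' enrichment fold and its (N, B, n, b) quadruple (background genes with
#' any term, background genes with the term, target-set size, target genes
#' with the term). Used as a fixed worked example for
#' [enrichment_fold()].
#'
#' @return Tibble with columns `gene_set`, `ontology`, `term`, `p`, `q`,
#'   `fold`, `N`, `B`, `n`, `b`.
#' @export
go_enrichment_example <- function() {
  path <- system.file("extdata", "go_enrichment_arabidopsis_drought.tsv",
                      package = "mscc", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
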