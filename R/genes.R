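#' Assign DMS to their closest-TSS genes
#'
#' Each differentially methylated site contributes its nearest-TSS gene to
#' the methylated-promoter set ("met") if the site gained methylation, or
#' to the demethylated set ("unmet") if it lost methylation. A gene
#' receiving sites of both directions appears in both sets.
#'
#' @param dms Tibble of DMS with `chrom`, `pos`, `direction`
#'   ("methylated"/"demethylated").
#' @param genes Gene annotation.
#' @return Tibble with `gene_id`, `met`, `unmet` (logical), one row per
#'   gene receiving at least one DMS.
#' @export
assign_closest_gene <- function(dms, genes) {
  if (nrow(genes) == 0) abort("annotation is empty")
  if (nrow(dms) == 0) {
    return(tibble::tibble(gene_id = character(), met = logical(),
                          unmet = logical()))
  }
  d <- distance_to_tss(dms, genes)
  d$direction <- dms$direction
  d %>%
    dplyr::filter(!is.na(.data$nearest_gene)) %>%
    dplyr::group_by(gene_id = .data$nearest_gene) %>%
    dplyr::summarise(
      met = any(.data$direction == "methylated"),
      unmet = any(.data$direction == "demethylated"),
      .groups = "drop"
    )
}

#' Flag genes with a DMS in their TSS-flanking window
#'
#' A gene is differentially methylated under the window rule when any DMS
#' has a signed TSS-relative position inside the closed interval
#' `[-upstream, +downstream]` (strand-aware: negative upstream of the
#' gene). Defaults reproduce a -3 kbp to +2 kbp promoter window.
#'
#' @param genes Gene annotation.
#' @param dms Tibble of DMS sites (`chrom`, `pos`).
#' @param upstream,downstream Window bounds in nt (positive numbers).
#' @return Tibble with `gene_id`, `window_dm` (logical) for every gene.
#' @export
flag_window_dm <- function(genes, dms, upstream = 3000, downstream = 2000) {
  tss <- tss_table(genes)
  flag <- rep(FALSE, nrow(tss))
  if (nrow(dms) > 0) {
    for (i in seq_len(nrow(tss))) {
      on_chrom <- dms$chrom == tss$chrom[i]
      if (!any(on_chrom)) next
      rel <- if (tss$strand[i] == "+") {
        dms$pos[on_chrom] - tss$tss[i]
      } else {
        tss$tss[i] - dms$pos[on_chrom]
      }
      flag[i] <- any(rel >= -upstream & rel <= downstream)
    }
  }
  tibble::tibble(gene_id = tss$gene_id, window_dm = flag)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = counts * 1e9 / (exon_length * library_total)`.
#'
#' @param counts Read counts (vectorized).
#' @param exon_length Exon model length in nt (> 0).
#' @param library_total Mapped reads in the library (> 0).
#' @return RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(counts, exon_length, library_total) {
  if (any(exon_length <= 0)) abort("`exon_length` must be positive")
  if (any(library_total <= 0)) abort("`library_total` must be positive")
  counts * 1e9 / (exon_length * library_total)
}

#' Call differentially expressed genes from a count matrix
#'
#' Converts counts to RPKM, applies a per-gene Welch t test on
#' `log2(RPKM + 1)` between the two conditions, and calls a gene
#' differentially expressed when its fold change (larger of FC and 1/FC of
#' the mean RPKMs) reaches `fold_cut` and its p-value (or BH q-value with
#' `mode = "fdr"`) falls below `alpha`. Direction follows the sign of the
#' mean difference.
#'
#' @param counts Tibble with `gene_id` and one column per library.
#' @param design Design tibble (`library`, `condition`).
#' @param exon_length Vector of exon-model lengths matching `counts` rows.
#' @param fold_cut Fold-change cutoff (default 1.5).
#' @param alpha Significance cutoff (default 0.05).
#' @param mode `"p"` (raw p-value cutoff, default) or `"fdr"` (BH q).
#' @return Tibble with per-gene means, fold, `p`, `q`, `de_status`
#'   ("up"/"down"/"none"; "up" = higher in the second condition).
#' @export
call_de <- function(counts, design, exon_length, fold_cut = 1.5,
                    alpha = 0.05, mode = c("p", "fdr")) {
  mode <- match.arg(mode)
  conds <- unique(design$condition)
  if (length(conds) != 2) abort("design must have exactly two conditions")
  m <- as.matrix(counts[, design$library])
  if (length(exon_length) != nrow(m)) {
    abort("`exon_length` must match the number of genes")
  }
  ctrl <- design$library[design$condition == conds[1]]
  trt <- design$library[design$condition == conds[2]]
  if (length(ctrl) < 2 || length(trt) < 2) {
    abort("need at least two replicates per condition")
  }
  totals <- colSums(m)
  rk <- rpkm(m, exon_length, rep(totals, each = nrow(m)))
  lg <- log2(rk + 1)
  w <- welch_rows(lg[, ctrl, drop = FALSE], lg[, trt, drop = FALSE])
  mean_ctrl <- rowMeans(rk[, ctrl, drop = FALSE])
  mean_trt <- rowMeans(rk[, trt, drop = FALSE])
  fc <- (mean_trt + 1e-9) / (mean_ctrl + 1e-9)
  fold <- pmax(fc, 1 / fc)
  q <- bh_fdr(w$p)
  crit <- if (mode == "p") w$p < alpha else q < alpha
  de <- fold >= fold_cut & crit
  tibble::tibble(
    gene_id = counts$gene_id,
    mean_rpkm_control = mean_ctrl, mean_rpkm_treated = mean_trt,
    fold = fold, p = w$p, q = q,
    de_status = dplyr::case_when(
      de & mean_trt > mean_ctrl ~ "up",
      de & mean_trt < mean_ctrl ~ "down",
      .default = "none"
    )
  )
}

#' Odds ratio of a 2x2 methylation-expression table
#'
#' `OR = (a/c)/(b/d) = a*d / (b*c)` where `a` counts genes both
#' differentially methylated and differentially expressed, `b`
#' methylated-only, `c` expressed-only and `d` neither. If `b` or `c` is
#' zero while `a` and `d` are positive the ratio is `Inf`; a table with an
#' empty margin is undefined and raises an error naming the margin.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return The odds ratio (a single number).
#' @examples
#' odds_ratio(30, 10, 20, 40) # 6
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("contingency cells must be non-negative")
  margins <- c("a+b (methylated)" = a + b, "c+d (not methylated)" = c + d,
               "a+c (expressed)" = a + c, "b+d (not expressed)" = b + d)
  if (any(margins == 0)) {
    abort(paste0("odds ratio undefined: empty margin ",
                 names(margins)[margins == 0][1]))
  }
  if ((b == 0 || c == 0)) return(Inf)
  (a * d) / (b * c)
}

#' Methylation-expression association for a gene universe
#'
#' Builds the per-gene association table (window-rule differential
#' methylation, DE status) and the 2x2 contingency summary with its odds
#' ratio.
#'
#' @param genes Gene annotation.
#' @param dms Tibble of DMS sites.
#' @param de DE table from [call_de()].
#' @param upstream,downstream TSS window, see [flag_window_dm()].
#' @return List with `genes` (per-gene tibble: `gene_id`, `window_dm`,
#'   `de_status`, `de`), `table` (a, b, c, d) and `odds_ratio`.
#' @export
associate_genes <- function(genes, dms, de, upstream = 3000,
                            downstream = 2000) {
  wm <- flag_window_dm(genes, dms, upstream, downstream)
  tab <- wm %>%
    dplyr::inner_join(de[, c("gene_id", "de_status")], by = "gene_id") %>%
    dplyr::mutate(de = .data$de_status != "none")
  a <- sum(tab$window_dm & tab$de)
  b <- sum(tab$window_dm & !tab$de)
  c_ <- sum(!tab$window_dm & tab$de)
  d <- sum(!tab$window_dm & !tab$de)
  list(genes = tab,
       table = tibble::tibble(a = a, b = b, c = c_, d = d),
       odds_ratio = odds_ratio(a, b, c_, d))
}

#' Gene-set enrichment fold
#'
#' `fold = (b/n) / (B/N)`: the frequency of a term among the `n` target
#' genes (`b` of which carry the term) relative to its frequency among the
#' `N` background genes (`B` with the term).
#'
#' @param N Background genes associated with any term.
#' @param B Background genes with this term.
#' @param n Target-set size.
#' @param b Target genes with this term.
#' @return The enrichment fold (vectorized).
#' @examples
#' enrichment_fold(24410, 5797, 6216, 1688) # ~1.14
#' @export
enrichment_fold <- function(N, B, n, b) {
  if (any(B <= 0) || any(n <= 0)) abort("require B > 0 and n > 0")
  if (any(b > pmin(B, n)) || any(n > N) || any(B > N)) {
    abort("invalid quadruple: need b <= min(B, n), n <= N, B <= N")
  }
  (b / n) / (B / N)
}

#' Hypergeometric gene-set enrichment test
#'
#' For each term, counts the (N, B, n, b) quadruple over the background,
#' computes the enrichment fold and the hypergeometric upper tail
#' `P(X >= b)` with `X ~ Hypergeom(N, B, n)`, and BH-adjusts across terms.
#'
#' @param target Character vector of target gene ids (must all be in the
#'   background).
#' @param terms Tibble mapping `term` to `gene_id` (optionally
#'   `term_name`).
#' @param background Character vector of background gene ids; defaults to
#'   every gene appearing in `terms`.
#' @return Tibble per term: `term`, `N`, `B`, `n`, `b`, `fold`, `p`, `q`.
#' @export
enrichment_test <- function(target, terms, background = NULL) {
  if (nrow(terms) == 0) abort("term map is empty")
  background <- unique(background %||% terms$gene_id)
  target <- unique(target)
  missing <- setdiff(target, background)
  if (length(missing) > 0) {
    abort(paste0("target genes absent from background: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else ""))
  }
  terms <- terms[terms$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(target)
  res <- terms %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      B = dplyr::n_distinct(.data$gene_id),
      b = dplyr::n_distinct(intersect(.data$gene_id, target)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      N = N, n = n,
      fold = enrichment_fold(.data$N, .data$B, .data$n, .data$b),
      p = phyper(.data$b - 1, .data$B, .data$N - .data$B, .data$n,
                 lower.tail = FALSE),
      q = bh_fdr(.data$p)
    ) %>%
    dplyr::select("term", "N", "B", "n", "b", "fold", "p", "q") %>%
    dplyr::arrange(.data$p)
  if ("term_name" %in% names(terms)) {
    res <- dplyr::left_join(res,
                            dplyr::distinct(terms, .data$term, .data$term_name),
                            by = "term")
  }
  res
}
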