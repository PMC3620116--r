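#' Transcription start sites of an annotation
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @return Tibble with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
tss_table <- function(genes) {
  if (nrow(genes) == 0) abort("annotation is empty")
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    tss = ifelse(genes$strand == "+", genes$start - 1L, genes$end - 1L),
    strand = genes$strand
  )
}

#' Signed distance from each site to its nearest TSS
#'
#' The nearest TSS is chosen by absolute genomic distance; ties go to the
#' lexicographically smaller gene identifier. The sign is strand-aware:
#' negative upstream of the gene, positive downstream, so a site 100 nt
#' left of a plus-strand TSS scores -100 while the same geometry at a
#' minus-strand TSS scores +100. Sites on contigs without genes get `NA`.
#'
#' @param sites Tibble with `chrom`, `pos` (0-based).
#' @param genes Gene annotation (see [tss_table()]).
#' @return `sites` with `nearest_gene` and `tss_distance` columns added.
#' @export
distance_to_tss <- function(sites, genes) {
  tss <- tss_table(genes)
  out <- sites
  out$nearest_gene <- NA_character_
  out$tss_distance <- NA_real_

  for (ch in unique(sites$chrom)) {
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    si <- which(sites$chrom == ch)
    if (nrow(tt) == 0 || length(si) == 0) next
    # order by position, then gene id, so the first gene at a position is
    # the lexicographic tie-winner
    tt <- tt[order(tt$tss, tt$gene_id), , drop = FALSE]
    keep <- !duplicated(tt$tss)
    tt1 <- tt[keep, , drop = FALSE]
    pos <- sites$pos[si]
    k <- findInterval(pos, tt1$tss)
    lo <- pmax(k, 1L)
    hi <- pmin(k + 1L, nrow(tt1))
    d_lo <- abs(pos - tt1$tss[lo])
    d_hi <- abs(pos - tt1$tss[hi])
    # no TSS on the left: force the right candidate (and vice versa)
    d_lo[k < 1L] <- Inf
    d_hi[k + 1L > nrow(tt1)] <- Inf
    use_hi <- (d_hi < d_lo) |
      (d_hi == d_lo & tt1$gene_id[hi] < tt1$gene_id[lo])
    pick <- ifelse(use_hi, hi, lo)
    g <- tt1[pick, , drop = FALSE]
    signed <- ifelse(g$strand == "+", pos - g$tss, g$tss - pos)
    out$nearest_gene[si] <- g$gene_id
    out$tss_distance[si] <- signed
  }
  out
}

#' 100-bp binned relative-frequency profile of TSS distances
#'
#' Histogram of signed distances over a symmetric span around the TSS,
#' normalized to relative frequency over the in-span sites.
#'
#' @param distances Numeric vector of signed TSS distances, or a tibble
#'   with a `tss_distance` column (as returned by [distance_to_tss()]).
#' @param span Half-width of the profile in nt; must be a positive multiple
#'   of `bin`.
#' @param bin Bin width in nt (default 100).
#' @return Tibble with `bin_start`, `bin_end`, `n`, `freq`; `freq` sums to
#'   1 over in-span sites. The number of sites in span is kept in the
#'   `"n_in_span"` attribute.
#' @export
binned_profile <- function(distances, span = 3000, bin = 100) {
  if (is.data.frame(distances)) distances <- distances$tss_distance
  if (span <= 0 || span %% bin != 0) {
    abort("`span` must be a positive multiple of `bin`")
  }
  d <- distances[!is.na(distances)]
  edges <- seq(-span, span, by = bin)
  inside <- d >= -span & d < span
  idx <- findInterval(d[inside], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  n_in <- sum(counts)
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    n = counts,
    freq = if (n_in > 0) counts / n_in else rep(0, length(counts))
  )
  attr(out, "n_in_span") <- n_in
  out
}

#' Draw a uniform null DMS set by the random-rank construction
#'
#' Assigns each cataloged site an independent uniform random number in
#' `[1, 650000]`, sorts, and takes the first `n` sites — the literal
#' spreadsheet construction of a same-size uniform subset without
#' replacement.
#'
#' @param catalog Site catalog.
#' @param n Number of sites to draw; at most `nrow(catalog)`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Tibble: the selected catalog rows.
#' @export
simulate_null_dms <- function(catalog, n, seed = NULL) {
  if (n > nrow(catalog)) {
    abort(sprintf("n (%d) exceeds catalog size (%d)", n, nrow(catalog)))
  }
  draw <- function() {
    r <- runif(nrow(catalog)) * (650000 - 1) + 1
    catalog[order(r)[seq_len(n)], , drop = FALSE]
  }
  if (is.null(seed)) draw() else with_stream(seed, "null_dms", draw())
}

#' Permutation test of TSS-proximal enrichment
#'
#' The test statistic is the fraction of a site set lying within
#' `window` nt (absolute distance) of a transcription start site. `s`
#' uniform same-size null sets are drawn from the catalog by the
#' random-rank construction and the empirical p-value is
#' `p = (e + 1) / (s + 1)`.
#'
#' With the default rule (`"upper"`), `e` counts null sets whose statistic
#' is at least the observed set's statistic — the standard upper-tail
#' permutation test of the claim that the observed set is enriched near
#' TSS. The alternative rule (`"all-sites"`) instead counts null sets whose
#' statistic is at most the all-site statistic; both are exposed because
#' descriptions of this test differ, and neither is asserted as canonical.
#'
#' @param observed Tibble of observed sites (`chrom`, `pos`); non-empty.
#' @param catalog Full site catalog (the sampling universe).
#' @param genes Gene annotation.
#' @param window Half-width in nt of the TSS-proximal zone (default 500).
#' @param s Number of simulated null sets (default 100).
#' @param rule `"upper"` or `"all-sites"` exceedance rule.
#' @param seed Seed for the null draws.
#' @return An object of class `mscc_perm` with fields `s`, `e`,
#'   `t_observed`, `t_all`, `t_sim`, `p`, `rule`, `window`, `n`.
#' @export
empirical_p <- function(observed, catalog, genes, window = 500, s = 100,
                        rule = c("upper", "all-sites"), seed = 1) {
  rule <- match.arg(rule)
  if (nrow(observed) == 0) abort("observed site set is empty")
  if (s < 1) abort("`s` must be at least 1")

  near_frac <- function(sites, dist_lookup = NULL) {
    d <- distance_to_tss(sites, genes)$tss_distance
    mean(!is.na(d) & abs(d) <= window)
  }
  # distances for the whole catalog once; null sets are row subsets
  d_all <- distance_to_tss(catalog, genes)$tss_distance
  near_all <- !is.na(d_all) & abs(d_all) <= window
  t_all <- mean(near_all)
  t_obs <- near_frac(observed)

  n <- nrow(observed)
  t_sim <- with_stream(seed, "empirical_p", {
    vapply(seq_len(s), function(i) {
      r <- runif(nrow(catalog)) * (650000 - 1) + 1
      mean(near_all[order(r)[seq_len(n)]])
    }, numeric(1))
  })
  e <- if (rule == "upper") sum(t_sim >= t_obs) else sum(t_sim <= t_all)
  structure(
    list(s = s, e = e, t_observed = t_obs, t_all = t_all, t_sim = t_sim,
         p = (e + 1) / (s + 1), rule = rule, window = window, n = n),
    class = "mscc_perm"
  )
}

#' @export
print.mscc_perm <- function(x, ...) {
  cat(sprintf(
    "<mscc_perm> n=%d sites, window=%d nt, s=%d simulations (%s rule)\n",
    x$n, x$window, x$s, x$rule))
  cat(sprintf("  observed near-TSS fraction %.4f (all sites %.4f), e=%d, p=%.4g\n",
              x$t_observed, x$t_all, x$e, x$p))
  invisible(x)
}

#' @rdname empirical_p
#' @param x,... An `mscc_perm` object (for `tidy()`/`glance()`).
#' @method tidy mscc_perm
#' @export
tidy.mscc_perm <- function(x, ...) {
  tibble::tibble(simulation = seq_len(x$s), statistic = x$t_sim)
}

#' @rdname empirical_p
#' @method glance mscc_perm
#' @export
glance.mscc_perm <- function(x, ...) {
  tibble::tibble(s = x$s, e = x$e, t_observed = x$t_observed,
                 t_all = x$t_all, p = x$p, rule = x$rule,
                 window = x$window, n = x$n)
}
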