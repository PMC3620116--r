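# Independent brute-force oracles used across the suite. These are written
# as plain loops over strings/vectors, deliberately sharing no code with the
# package internals they check.

bf_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# slide every motif (and its reverse complement) over every offset
bf_scan <- function(genome, panel = enzyme_panel(), both_strands = TRUE) {
  rows <- list()
  for (cname in names(genome)) {
    s <- genome[[cname]]
    n <- nchar(s)
    for (ei in seq_len(nrow(panel))) {
      motif <- panel$motif[ei]
      off <- panel$cut_offset[ei]
      L <- nchar(motif)
      pats <- list(list(p = motif, cg = off))
      rc <- bf_revcomp(motif)
      if (both_strands && rc != motif) {
        pats <- c(pats, list(list(p = rc, cg = L - off - 2L)))
      }
      for (pat in pats) {
        if (n < L) next
        for (i in seq_len(n - L + 1)) {
          if (substr(s, i, i + L - 1) == pat$p) {
            rows[[length(rows) + 1]] <- data.frame(
              chrom = cname, pos = i - 1L + pat$cg,
              enzyme = panel$enzyme[ei])
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          enzymes = character()))
  }
  df <- unique(do.call(rbind, rows))
  agg <- aggregate(enzyme ~ chrom + pos, data = df,
                   FUN = function(e) paste(sort(unique(e)), collapse = ","))
  out <- tibble::tibble(chrom = agg$chrom, pos = as.integer(agg$pos),
                        enzymes = agg$enzyme)
  out[order(out$chrom, out$pos), ]
}

bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs one-mismatch mapping against a catalog of (site, strand, tag)
bf_map_one <- function(query, ref) {
  d <- vapply(ref$tag, bf_hamming, integer(1), a = query)
  dmin <- min(d)
  if (dmin > 1) return(NULL)
  hit <- ref[d == dmin, , drop = FALSE]
  sites <- unique(paste0(hit$chrom, ":", hit$pos))
  if (length(sites) > 1) return("ambiguous")
  hit[1, c("chrom", "pos")]
}

# nearest TSS by absolute distance, tie to lexicographically smaller id
bf_nearest_tss <- function(chrom, pos, genes) {
  tss <- ifelse(genes$strand == "+", genes$start - 1L, genes$end - 1L)
  on <- which(genes$chrom == chrom)
  if (length(on) == 0) return(list(gene = NA, dist = NA))
  d <- abs(pos - tss[on])
  best <- on[d == min(d)]
  best <- best[order(genes$gene_id[best])][1]
  t0 <- tss[best]
  list(gene = genes$gene_id[best],
       dist = if (genes$strand[best] == "+") pos - t0 else t0 - pos)
}

bf_window_flag <- function(gene, dms, upstream, downstream) {
  t0 <- if (gene$strand == "+") gene$start - 1L else gene$end - 1L
  any(vapply(seq_len(nrow(dms)), function(i) {
    if (dms$chrom[i] != gene$chrom) return(FALSE)
    rel <- if (gene$strand == "+") dms$pos[i] - t0 else t0 - dms$pos[i]
    rel >= -upstream && rel <= downstream
  }, logical(1)))
}

# Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(pmin(p[o][rank_i:m] * m / (rank_i:m), 1))
  }
  q
}

# hypergeometric upper tail by enumeration
bf_hyper_tail <- function(N, B, n, b) {
  sum(vapply(b:min(B, n), function(k) {
    choose(B, k) * choose(N - B, n - k) / choose(N, n)
  }, numeric(1)))
}

skey <- function(d) paste0(d$chrom, ":", d$pos)

# a fabricated catalog + annotation (no genome scan) for tests that only
# need site coordinates
fab_sites <- function(n_sites, contig_len = 1e6, gene_every = 13000,
                      seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(contig_len - 100, n_sites))
  catalog <- tibble::tibble(chrom = "c1", pos = pos)
  tss <- seq(5000, contig_len - 5000, by = gene_every)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_along(tss)),
    chrom = "c1", start = tss + 1L, end = tss + 1000L, strand = "+"
  )
  list(catalog = catalog, genes = genes)
}
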