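#' Configuration for the MSCC experiment simulator
#'
#' Bundles every parameter of the synthetic data generator. The generator
#' emulates the measurement model of a methyl-sensitive cut counting
#' experiment: per-site tag counts inversely proportional to methylation,
#' multiplicative site-specific digestion biases shared across replicates,
#' negative-binomial count noise, a configurable excess of
#' methylation-gain over methylation-loss events between conditions
#' (default 9:1), and preferential placement of differential sites near
#' transcription start sites.
#'
#' Defaults describe a drought-versus-control design with four barcoded
#' replicates per condition, about 12 expected reads per site per replicate
#' (the per-replicate depth of a typical genome-scale MSCC run), and count
#' dispersion calibrated so that two replicates of the same condition show
#' a digestion-frequency r-squared near 0.8 at that depth.
#'
#' @param seed Global seed; each stage draws from a named sub-stream.
#' @param n_contigs,contig_len Genome shape.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param gc_content Genome GC fraction in `[0, 1]`.
#' @param n_replicates Replicates per condition (default 4).
#' @param reads_per_site Expected reads per site per library.
#' @param bias_sd Log-scale SD of the site-specific digestion bias.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); values below 1e-9 give Poisson counts.
#' @param dms_fraction Fraction of surveyed sites differentially methylated.
#' @param direction_ratio Odds of methylation gain vs. loss for a DMS.
#' @param min_delta,max_delta Range of the absolute methylation-level change
#'   planted at a DMS.
#' @param tss_window Window (nt) around a TSS used for preferential DMS
#'   placement.
#' @param tss_strength Multiplier on the placement probability of DMS within
#'   `tss_window` of a TSS (1 = no preference).
#' @param promoter_window Window (nt) around a TSS inside which baseline
#'   methylation is drawn low (promoters are hypomethylated).
#' @param error_rate Fraction of simulated reads carrying one random
#'   substitution.
#' @param barcodes Replicate barcodes (3-mers, pairwise Hamming distance
#'   at least 2).
#' @param n_expr_replicates RNA libraries per condition (default 3).
#' @param expr_reads_per_gene Expected RNA-seq reads per gene per library.
#' @param expr_dispersion Overdispersion of expression counts.
#' @param expr_libsize_cv Log-normal CV of expression library sizes.
#' @param de_fraction Fraction of genes with a planted expression change.
#' @param de_fold Planted expression fold change.
#' @return An object of class `mscc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_len = 50000L,
                       n_genes = 40L,
                       gc_content = 0.36,
                       n_replicates = 4L,
                       reads_per_site = 12,
                       bias_sd = 0.4,
                       dispersion = 0.005,
                       dms_fraction = 0.02,
                       direction_ratio = 9,
                       min_delta = 0.5,
                       max_delta = 0.95,
                       tss_window = 500L,
                       tss_strength = 5,
                       promoter_window = 1000L,
                       error_rate = 0.01,
                       barcodes = c("ACA", "GTG", "TAC", "CGT"),
                       n_expr_replicates = 3L,
                       expr_reads_per_gene = 200,
                       expr_dispersion = 0.05,
                       expr_libsize_cv = 0.2,
                       de_fraction = 0.1,
                       de_fold = 4) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len), n_genes = as.integer(n_genes),
    gc_content = gc_content, n_replicates = as.integer(n_replicates),
    reads_per_site = reads_per_site, bias_sd = bias_sd,
    dispersion = dispersion, dms_fraction = dms_fraction,
    direction_ratio = direction_ratio, min_delta = min_delta,
    max_delta = max_delta, tss_window = as.integer(tss_window),
    tss_strength = tss_strength,
    promoter_window = as.integer(promoter_window),
    error_rate = error_rate, barcodes = barcodes,
    n_expr_replicates = as.integer(n_expr_replicates),
    expr_reads_per_gene = expr_reads_per_gene,
    expr_dispersion = expr_dispersion,
    expr_libsize_cv = expr_libsize_cv,
    de_fraction = de_fraction, de_fold = de_fold
  )
  fracs <- c("gc_content", "dms_fraction", "error_rate", "de_fraction")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]"))
  }
  if (cfg$reads_per_site <= 0) abort("`reads_per_site` must be positive")
  if (cfg$direction_ratio <= 0) abort("`direction_ratio` must be positive")
  if (cfg$n_replicates < 2) abort("at least two replicates per condition")
  if (length(cfg$barcodes) < cfg$n_replicates) {
    abort("need one barcode per replicate")
  }
  if (anyDuplicated(cfg$barcodes)) abort("barcodes must be distinct")
  if (cfg$min_delta <= 0 || cfg$max_delta > 1 || cfg$min_delta > cfg$max_delta) {
    abort("require 0 < min_delta <= max_delta <= 1")
  }
  structure(cfg, class = "mscc_sim_config")
}

#' @export
print.mscc_sim_config <- function(x, ...) {
  cat("<mscc_sim_config>\n")
  cat(sprintf("  genome: %d contig(s) x %d nt, GC %.2f, %d genes\n",
              x$n_contigs, x$contig_len, x$gc_content, x$n_genes))
  cat(sprintf("  design: %d+%d replicates, ~%.0f reads/site/library\n",
              x$n_replicates, x$n_replicates, x$reads_per_site))
  cat(sprintf("  methylome: %.1f%% DMS, %s:1 gain:loss, |delta| in [%.2f, %.2f]\n",
              100 * x$dms_fraction, format(x$direction_ratio),
              x$min_delta, x$max_delta))
  invisible(x)
}

#' Simulate a genome and gene annotation
#'
#' Generates random contigs at the configured GC content and places
#' non-overlapping gene models with strand, TSS and exon structure.
#' Deterministic under the configuration seed.
#'
#' @param config An [sim_config()] object.
#' @return List with `genome` (a `DNAStringSet`) and `genes` (tibble with
#'   `gene_id`, `chrom`, `start`, `end` 1-based inclusive, `strand`, `tss`
#'   0-based, `exons` as "start-end" 1-based comma list, `exon_length`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "mscc_sim_config"))
  with_stream(config$seed, "genome", {
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    contigs <- vapply(seq_len(config$n_contigs), function(i) {
      paste(sample(names(p), config$contig_len, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(contigs) <- paste0("contig_", seq_len(config$n_contigs))
    genome <- Biostrings::DNAStringSet(contigs)

    genes <- tibble::tibble(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), tss = integer(),
                            exons = character(), exon_length = integer())
    if (config$n_genes > 0) {
      per_contig <- diff(round(seq(0, config$n_genes,
                                   length.out = config$n_contigs + 1)))
      rows <- list()
      gid <- 0L
      for (ci in seq_len(config$n_contigs)) {
        ng <- per_contig[ci]
        if (ng == 0) next
        slot <- config$contig_len %/% ng
        if (slot < 900L) {
          abort(sprintf(
            "cannot place %d non-overlapping genes on a %d nt contig",
            ng, config$contig_len))
        }
        for (gi in seq_len(ng)) {
          gid <- gid + 1L
          len <- sample(600:min(2000L, slot - 200L), 1)
          lo <- (gi - 1L) * slot + 1L
          start <- lo + sample.int(slot - len - 100L, 1)
          end <- start + len - 1L
          strand <- sample(c("+", "-"), 1)
          n_ex <- sample(1:3, 1)
          if (n_ex == 1) {
            ex_s <- start; ex_e <- end
          } else {
            cuts <- sort(sample(seq(start + 80L, end - 80L, by = 20L),
                                2L * (n_ex - 1L)))
            ex_s <- c(start, cuts[seq(2, length(cuts), by = 2)] + 1L)
            ex_e <- c(cuts[seq(1, length(cuts), by = 2)], end)
          }
          rows[[gid]] <- tibble::tibble(
            gene_id = sprintf("gene_%04d", gid),
            chrom = names(contigs)[ci],
            start = start, end = end, strand = strand,
            tss = if (strand == "+") start - 1L else end - 1L,
            exons = paste(paste0(ex_s, "-", ex_e), collapse = ","),
            exon_length = as.integer(sum(ex_e - ex_s + 1L))
          )
        }
      }
      genes <- dplyr::bind_rows(rows)
    }
    list(genome = genome, genes = genes)
  })
}

#' Simulate ground-truth methylomes for two conditions
#'
#' Baseline methylation is drawn low near transcription start sites
#' (hypomethylated promoters) and high elsewhere. A `dms_fraction` subset of
#' sites is perturbed in the treated condition: placement probability is
#' boosted `tss_strength`-fold within `tss_window` of a TSS, the direction
#' is methylation gain with odds `direction_ratio`:1, and the absolute level
#' change lies in `[min_delta, max_delta]`.
#'
#' @param catalog Site catalog (needs `chrom`, `pos`).
#' @param genes Gene annotation from [simulate_genome()].
#' @param config An [sim_config()] object.
#' @return Truth tibble: `chrom`, `pos`, `bias`, `level_control`,
#'   `level_treated`, `is_dms`, `direction`.
#' @export
simulate_methylomes <- function(catalog, genes, config) {
  stopifnot(inherits(config, "mscc_sim_config"))
  if (nrow(catalog) == 0) abort("catalog is empty")
  with_stream(config$seed, "methylome", {
    n <- nrow(catalog)
    d <- if (nrow(genes) > 0) {
      distance_to_tss(catalog, genes)$tss_distance
    } else {
      rep(NA_real_, n)
    }
    near_prom <- !is.na(d) & abs(d) <= config$promoter_window
    level <- ifelse(near_prom, rbeta(n, 2, 8), rbeta(n, 8, 2))
    bias <- exp(rnorm(n, 0, config$bias_sd))

    n_dms <- round(config$dms_fraction * n)
    if (config$dms_fraction > 0 && n_dms < 1) {
      warn("dms_fraction * n_sites < 1; no DMS planted")
    }
    is_dms <- rep(FALSE, n)
    direction <- rep(NA_character_, n)
    lev_c <- level
    lev_t <- level
    if (n_dms >= 1) {
      near_tss <- !is.na(d) & abs(d) <= config$tss_window
      w <- 1 + (config$tss_strength - 1) * near_tss
      idx <- sample.int(n, n_dms, prob = w)
      p_gain <- config$direction_ratio / (config$direction_ratio + 1)
      gain <- runif(n_dms) < p_gain
      for (k in seq_len(n_dms)) {
        i <- idx[k]
        if (gain[k]) {
          l1 <- runif(1, 0, 1 - config$min_delta - 0.05)
          delta <- runif(1, config$min_delta, min(config$max_delta, 1 - l1))
          lev_c[i] <- l1
          lev_t[i] <- l1 + delta
          direction[i] <- "methylated"
        } else {
          l1 <- runif(1, config$min_delta + 0.05, 1)
          delta <- runif(1, config$min_delta, min(config$max_delta, l1))
          lev_c[i] <- l1
          lev_t[i] <- l1 - delta
          direction[i] <- "demethylated"
        }
        is_dms[i] <- TRUE
      }
    }
    tibble::tibble(
      chrom = catalog$chrom, pos = catalog$pos, bias = bias,
      level_control = lev_c, level_treated = lev_t,
      is_dms = is_dms, direction = direction
    )
  })
}

# expected count matrix implied by a truth table: library depth split across
# sites in proportion to bias * (1 - methylation level)
expected_mu <- function(truth, config, reads_per_site = NULL) {
  rps <- reads_per_site %||% config$reads_per_site
  depth <- rps * nrow(truth)
  mu_one <- function(level) {
    raw <- truth$bias * (1 - level)
    if (sum(raw) == 0) return(raw)
    raw / sum(raw) * depth
  }
  list(control = mu_one(truth$level_control),
       treated = mu_one(truth$level_treated))
}

#' Simulate the site-by-library tag count matrix
#'
#' Draws negative-binomial counts for every site and library from the truth
#' table's methylation levels and biases: the expected count at a site is
#' proportional to `bias * (1 - level)`, scaled so each library's expected
#' total is `reads_per_site * n_sites`.
#'
#' @param truth Truth table from [simulate_methylomes()].
#' @param config An [sim_config()] object.
#' @param reads_per_site Optional override of the configured depth.
#' @return An [mscc_counts] object (raw counts, not yet normalized).
#' @export
simulate_site_counts <- function(truth, config, reads_per_site = NULL) {
  stopifnot(inherits(config, "mscc_sim_config"))
  with_stream(config$seed, "counts", {
    mu <- expected_mu(truth, config, reads_per_site)
    nr <- config$n_replicates
    n <- nrow(truth)
    draw <- function(m) {
      if (config$dispersion < 1e-9) rpois(n, m)
      else rnbinom(n, mu = m, size = 1 / config$dispersion)
    }
    mats <- c(
      lapply(seq_len(nr), function(j) draw(mu$control)),
      lapply(seq_len(nr), function(j) draw(mu$treated))
    )
    counts <- do.call(cbind, mats)
    design <- tibble::tibble(
      library = c(paste0("control_", seq_len(nr)),
                  paste0("drought_", seq_len(nr))),
      condition = rep(c("control", "drought"), each = nr),
      replicate = rep(seq_len(nr), 2),
      barcode = rep(config$barcodes[seq_len(nr)], 2)
    )
    colnames(counts) <- design$library
    new_mscc_counts(truth[, c("chrom", "pos")], counts, design)
  })
}

#' Simulate barcoded 30-nt tag reads
#'
#' Expands a raw count matrix into reads: each read is the site's 27-nt tag
#' (forward or reverse, equal odds) followed by the replicate's 3-nt
#' barcode. A fraction `error_rate` of reads carries one random
#' substitution. Reads from the two conditions are kept in separate pools,
#' mirroring an experiment where each condition's four barcoded replicate
#' libraries are sequenced together.
#'
#' @param counts An [mscc_counts] object with raw counts.
#' @param catalog Catalog with `tag_fwd`/`tag_rev` for every counted site.
#' @param config An [sim_config()] object.
#' @return List with `reads` (tibble `read_id`, `seq`, `condition`),
#'   `barcode_map` (the design sheet) and `truth` (per-read source site,
#'   strand, library and whether a substitution was injected).
#' @export
simulate_tag_reads <- function(counts, catalog, config) {
  stopifnot(inherits(counts, "mscc_counts"), inherits(config, "mscc_sim_config"))
  key_cat <- site_key(catalog$chrom, catalog$pos)
  key_cnt <- site_key(counts$sites$chrom, counts$sites$pos)
  m <- match(key_cnt, key_cat)
  if (anyNA(m)) abort("counts contain sites absent from the catalog")
  tag_f <- catalog$tag_fwd[m]
  tag_r <- catalog$tag_rev[m]

  with_stream(config$seed, "reads", {
    per_lib <- lapply(seq_len(nrow(counts$design)), function(j) {
      cnt <- counts$counts[, j]
      idx <- rep.int(seq_along(cnt), cnt)
      if (length(idx) == 0) return(NULL)
      fwd <- runif(length(idx)) < 0.5
      tibble::tibble(
        site = idx,
        strand = ifelse(fwd, "+", "-"),
        tag = ifelse(fwd, tag_f[idx], tag_r[idx]),
        library = counts$design$library[j],
        condition = counts$design$condition[j],
        barcode = counts$design$barcode[j]
      )
    })
    reads <- dplyr::bind_rows(per_lib)
    n <- nrow(reads)
    seqs <- paste0(reads$tag, reads$barcode)
    mutated <- runif(n) < config$error_rate
    if (any(mutated)) {
      wi <- which(mutated)
      pos <- sample.int(30L, length(wi), replace = TRUE)
      for (k in seq_along(wi)) {
        i <- wi[k]
        old <- substr(seqs[i], pos[k], pos[k])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        substr(seqs[i], pos[k], pos[k]) <- new
      }
    }
    ord <- sample.int(n)
    list(
      reads = tibble::tibble(
        read_id = sprintf("read_%07d", seq_len(n)),
        seq = seqs[ord],
        condition = reads$condition[ord]
      ),
      barcode_map = counts$design,
      truth = tibble::tibble(
        read_id = sprintf("read_%07d", seq_len(n)),
        chrom = counts$sites$chrom[reads$site[ord]],
        pos = counts$sites$pos[reads$site[ord]],
        strand = reads$strand[ord],
        library = reads$library[ord],
        mutated = mutated[ord]
      )
    )
  })
}

#' Simulate a gene-level expression count matrix
#'
#' Plants fold changes of `de_fold` (up or down with equal odds) on a
#' `de_fraction` subset of genes, with log-normal library-size variation and
#' negative-binomial noise. Expected counts scale with exon length.
#'
#' @param genes Gene annotation from [simulate_genome()].
#' @param config An [sim_config()] object.
#' @return List with `counts` (tibble, one row per gene, one column per
#'   library), `design`, and `truth` (`gene_id`, `is_de`, `fold`,
#'   `direction`).
#' @export
simulate_expression <- function(genes, config) {
  stopifnot(inherits(config, "mscc_sim_config"))
  if (nrow(genes) == 0) abort("no genes to simulate expression for")
  with_stream(config$seed, "expression", {
    ng <- nrow(genes)
    nr <- config$n_expr_replicates
    base <- exp(rnorm(ng, 0, 0.8))
    base <- base * genes$exon_length / mean(genes$exon_length)
    base <- base / mean(base) * config$expr_reads_per_gene

    n_de <- round(config$de_fraction * ng)
    is_de <- rep(FALSE, ng)
    fold <- rep(1, ng)
    dirn <- rep(NA_character_, ng)
    if (n_de >= 1) {
      idx <- sample.int(ng, n_de)
      up <- runif(n_de) < 0.5
      is_de[idx] <- TRUE
      fold[idx] <- ifelse(up, config$de_fold, 1 / config$de_fold)
      dirn[idx] <- ifelse(up, "up", "down")
    }

    design <- tibble::tibble(
      library = c(paste0("control_", seq_len(nr)),
                  paste0("drought_", seq_len(nr))),
      condition = rep(c("control", "drought"), each = nr),
      replicate = rep(seq_len(nr), 2)
    )
    libsize <- exp(rnorm(nrow(design), 0, config$expr_libsize_cv))
    cols <- lapply(seq_len(nrow(design)), function(j) {
      mu <- base * libsize[j]
      if (design$condition[j] == "drought") mu <- mu * fold
      if (config$expr_dispersion < 1e-9) rpois(ng, mu)
      else rnbinom(ng, mu = mu, size = 1 / config$expr_dispersion)
    })
    counts <- tibble::as_tibble(stats::setNames(cols, design$library))
    counts <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id), counts)
    list(counts = counts, design = design,
         truth = tibble::tibble(gene_id = genes$gene_id, is_de = is_de,
                                fold = fold, direction = dirn))
  })
}

#' Run the full simulator
#'
#' Genome, catalog, methylomes, tag counts and expression in one call.
#'
#' @param config An [sim_config()] object.
#' @param reads_per_site Optional depth override passed to
#'   [simulate_site_counts()].
#' @return List with `genome`, `genes`, `catalog`, `truth`, `counts`,
#'   `expression`.
#' @export
simulate_mscc_experiment <- function(config = sim_config(),
                                     reads_per_site = NULL) {
  ga <- simulate_genome(config)
  catalog <- build_catalog(ga$genome)
  truth <- simulate_methylomes(catalog, ga$genes, config)
  counts <- simulate_site_counts(truth, config, reads_per_site)
  expr <- simulate_expression(ga$genes, config)
  list(genome = ga$genome, genes = ga$genes, catalog = catalog,
       truth = truth, counts = counts, expression = expr)
}
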