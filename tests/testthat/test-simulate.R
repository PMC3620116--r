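test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 9, contig_len = 8000, n_genes = 6)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)

  cat1 <- scan_restriction_sites(a$genome)
  ta <- simulate_methylomes(cat1, a$genes, cfg)
  tb <- simulate_methylomes(cat1, b$genes, cfg)
  expect_identical(ta, tb)

  ca <- simulate_site_counts(ta, cfg)
  cb <- simulate_site_counts(tb, cfg)
  expect_identical(ca$counts, cb$counts)

  ea <- simulate_expression(a$genes, cfg)
  eb <- simulate_expression(b$genes, cfg)
  expect_identical(ea$counts, eb$counts)
})

test_that("genome GC content is within 3 binomial sd of target", {
  cfg <- sim_config(seed = 2, n_contigs = 1, contig_len = 100000,
                    n_genes = 0, gc_content = 0.5)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  s <- strsplit(as.character(g$genome)[[1]], "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.5 * 0.5 / 100000))
})

test_that("gene models are non-overlapping with consistent exon structure", {
  cfg <- sim_config(seed = 4, n_contigs = 2, contig_len = 30000, n_genes = 30)
  g <- simulate_genome(cfg)
  for (ch in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  for (i in seq_len(nrow(g$genes))) {
    ex <- do.call(rbind, lapply(strsplit(g$genes$exons[i], ",")[[1]],
                                function(e) as.integer(strsplit(e, "-")[[1]])))
    expect_equal(ex[1, 1], g$genes$start[i])
    expect_equal(ex[nrow(ex), 2], g$genes$end[i])
    expect_equal(sum(ex[, 2] - ex[, 1] + 1L), g$genes$exon_length[i])
  }
  expect_error(simulate_genome(sim_config(contig_len = 2000, n_genes = 50,
                                          n_contigs = 1)),
               "cannot place")
})

test_that("planted direction ratio follows the configured 9:1 odds", {
  sites <- tibble::tibble(chrom = "c1", pos = seq(100L, by = 200L,
                                                  length.out = 4000))
  genes0 <- tibble::tibble(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character())
  cfg <- sim_config(seed = 21, dms_fraction = 0.5, direction_ratio = 9)
  tr <- simulate_methylomes(sites, genes0, cfg)
  n_dms <- sum(tr$is_dms)
  expect_equal(n_dms, 2000)
  n_gain <- sum(tr$direction == "methylated", na.rm = TRUE)
  expect_lt(abs(n_gain - 0.9 * n_dms), 3 * sqrt(n_dms * 0.9 * 0.1))
  # every planted change honours the configured minimum effect
  expect_true(all(abs(tr$level_treated - tr$level_control)[tr$is_dms] >= 0.5))
  # no DMS planted means identical conditions
  tr0 <- simulate_methylomes(sites, genes0, sim_config(dms_fraction = 0))
  expect_identical(tr0$level_control, tr0$level_treated)
})

test_that("tss_strength = 1 places DMS like the background (KS, 20 seeds)", {
  fab <- fab_sites(3000, contig_len = 5e5, gene_every = 9000, seed = 3)
  d_all <- distance_to_tss(fab$catalog, fab$genes)$tss_distance
  rejections <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, dms_fraction = 0.05, tss_strength = 1)
    tr <- simulate_methylomes(fab$catalog, fab$genes, cfg)
    d_dms <- d_all[tr$is_dms]
    p <- suppressWarnings(stats::ks.test(d_dms, d_all)$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("tss_strength > 1 concentrates DMS near the TSS", {
  fab <- fab_sites(3000, contig_len = 5e5, gene_every = 9000, seed = 3)
  d_all <- distance_to_tss(fab$catalog, fab$genes)$tss_distance
  cfg <- sim_config(seed = 31, dms_fraction = 0.05, tss_strength = 8)
  tr <- simulate_methylomes(fab$catalog, fab$genes, cfg)
  near <- abs(d_all) <= cfg$tss_window
  expect_gt(mean(near[tr$is_dms]), 2 * mean(near))
})

test_that("count model: fully methylated sites yield zero reads and library
           totals concentrate at the configured depth", {
  truth <- tibble::tibble(
    chrom = "c1", pos = seq(0L, by = 100L, length.out = 500),
    bias = 1, level_control = 0.5, level_treated = 0.5,
    is_dms = FALSE, direction = NA_character_
  )
  truth$level_control[1] <- 1
  truth$level_treated[1] <- 1
  cfg <- sim_config(seed = 8, reads_per_site = 50)
  x <- simulate_site_counts(truth, cfg)
  expect_true(all(x$counts[1, ] == 0))

  depth <- 50 * nrow(truth)
  mu_site <- depth * (1 - truth$level_control) /
    sum(truth$bias * (1 - truth$level_control)) * truth$bias
  sd_total <- sqrt(sum(mu_site + cfg$dispersion * mu_site^2))
  for (j in seq_len(ncol(x$counts))) {
    expect_lt(abs(sum(x$counts[, j]) - depth), 4 * sd_total)
  }
})

test_that("noise-free equal-level replicates converge to r2 = 1", {
  truth <- tibble::tibble(
    chrom = "c1", pos = seq(0L, by = 100L, length.out = 500),
    bias = 1, level_control = runif(500, 0.1, 0.9),
    level_treated = 0.5, is_dms = FALSE, direction = NA_character_
  )
  cfg <- sim_config(seed = 12, bias_sd = 0, dispersion = 0,
                    reads_per_site = 2000)  # 10^6 reads per library
  x <- simulate_site_counts(truth, cfg)
  r2 <- cor(x$counts[, "control_1"], x$counts[, "control_2"])^2
  expect_gt(r2, 0.99)
})

test_that("simulated reads carry the right structure", {
  cfg <- sim_config(seed = 6, contig_len = 10000, n_genes = 5,
                    error_rate = 0.1)
  sim <- simulate_mscc_experiment(cfg, reads_per_site = 4)
  rd <- simulate_tag_reads(sim$counts, sim$catalog, cfg)
  expect_true(all(nchar(rd$reads$seq) == 30))
  expect_equal(nrow(rd$reads), sum(sim$counts$counts))
  # per-read truth recovers the count matrix exactly
  keys <- skey(sim$counts$sites)
  for (j in seq_len(ncol(sim$counts$counts))) {
    lib <- sim$counts$design$library[j]
    tab <- table(skey(rd$truth)[rd$truth$library == lib])
    rebuilt <- integer(length(keys))
    rebuilt[match(names(tab), keys)] <- as.integer(tab)
    expect_equal(rebuilt, unname(sim$counts$counts[, j]))
  }
  # substitution rate close to the configured error rate
  expect_lt(abs(mean(rd$truth$mutated) - 0.1),
            4 * sqrt(0.1 * 0.9 / nrow(rd$reads)))
})

test_that("expression simulator recovers planted fold changes", {
  cfg0 <- sim_config(seed = 14, contig_len = 20000, n_genes = 20,
                     de_fraction = 0)
  g <- simulate_genome(cfg0)
  # no planted change: fold stays near 1 at high depth
  e0 <- simulate_expression(g$genes, sim_config(seed = 14, de_fraction = 0,
                                                expr_reads_per_gene = 5000,
                                                expr_dispersion = 0.001,
                                                expr_libsize_cv = 0))
  m <- as.matrix(e0$counts[, -1])
  fc0 <- rowMeans(m[, 4:6]) / rowMeans(m[, 1:3])
  expect_true(all(pmax(fc0, 1 / fc0) < 1.5))

  # planted 2-fold changes: observed RPKM ratio within 10% of 2 (20 seeds)
  ratios <- c()
  for (s in 1:20) {
    cfg <- sim_config(seed = 200 + s, contig_len = 20000, n_genes = 20,
                      de_fraction = 0.3, de_fold = 2,
                      expr_reads_per_gene = 5000, expr_dispersion = 0.001,
                      expr_libsize_cv = 0)
    gg <- simulate_genome(cfg)
    ee <- simulate_expression(gg$genes, cfg)
    mm <- as.matrix(ee$counts[, -1])
    tot <- colSums(mm)
    rk <- sweep(mm, 2, tot / 1e6, "/") / (gg$genes$exon_length / 1000)
    up <- which(ee$truth$direction == "up")
    ratios <- c(ratios, rowMeans(rk[up, 4:6, drop = FALSE]) /
                  rowMeans(rk[up, 1:3, drop = FALSE]))
  }
  expect_lt(abs(mean(ratios) - 2), 0.2)
})
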