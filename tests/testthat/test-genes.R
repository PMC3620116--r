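test_that("closest-TSS assignment builds met/unmet sets per direction", {
  genes <- tibble::tibble(gene_id = "geneA", chrom = "c1",
                          start = 5001L, end = 6000L, strand = "+")
  one <- assign_closest_gene(
    tibble::tibble(chrom = "c1", pos = 4800L, direction = "methylated"),
    genes)
  expect_equal(one, tibble::tibble(gene_id = "geneA", met = TRUE,
                                   unmet = FALSE))
  # a gene receiving both directions appears in both sets
  both <- assign_closest_gene(
    tibble::tibble(chrom = "c1", pos = c(4800L, 5200L),
                   direction = c("methylated", "demethylated")),
    genes)
  expect_true(both$met & both$unmet)
})

test_that("closest-TSS assignment matches brute-force nearest search", {
  set.seed(81)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", sample(40)),
    chrom = "c1", start = sort(sample.int(1e5, 40)), strand = "+"
  )
  genes$end <- genes$start + 800L
  dms <- tibble::tibble(chrom = "c1", pos = sample.int(1e5, 200),
                        direction = sample(c("methylated", "demethylated"),
                                           200, TRUE))
  got <- assign_closest_gene(dms, genes)
  met_bf <- unique(vapply(which(dms$direction == "methylated"), function(i) {
    bf_nearest_tss("c1", dms$pos[i], genes)$gene
  }, character(1)))
  expect_setequal(got$gene_id[got$met], met_bf)
})

test_that("window flags are inclusive, strand-aware interval tests", {
  gplus <- tibble::tibble(gene_id = "gp", chrom = "c1", start = 5001L,
                          end = 6000L, strand = "+")   # TSS 5000
  gminus <- tibble::tibble(gene_id = "gm", chrom = "c1", start = 4000L,
                           end = 5001L, strand = "-")  # TSS 5000
  fl <- function(genes, pos) {
    flag_window_dm(genes, tibble::tibble(chrom = "c1", pos = pos))$window_dm
  }
  # plus strand: [-3000, +2000] around TSS 5000 is [2000, 7000]
  expect_true(fl(gplus, 2000L))
  expect_false(fl(gplus, 1999L))
  expect_true(fl(gplus, 7000L))
  expect_false(fl(gplus, 7001L))
  # minus strand mirror: window covers [3000, 8000]
  expect_true(fl(gminus, 8000L))
  expect_false(fl(gminus, 8001L))
  expect_true(fl(gminus, 3000L))
  expect_false(fl(gminus, 2999L))

  # agreement with brute force on a random annotation
  set.seed(83)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:30), chrom = "c1",
    start = sort(sample.int(2e5, 30)),
    strand = sample(c("+", "-"), 30, TRUE)
  )
  genes$end <- genes$start + sample(500:1500, 30, TRUE)
  dms <- tibble::tibble(chrom = "c1", pos = sample.int(2e5, 100))
  got <- flag_window_dm(genes, dms)
  for (i in seq_len(nrow(genes))) {
    expect_equal(got$window_dm[i],
                 bf_window_flag(genes[i, ], dms, 3000, 2000))
  }
})

test_that("rpkm implements reads per kb of exon per million mapped", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)  # doubling the total halves RPKM
  expect_error(rpkm(10, 0, 1e6), "exon_length")
  expect_error(rpkm(10, 1000, 0), "library_total")
})

test_that("DE calling needs both the fold cutoff and significance", {
  design <- tibble::tibble(
    library = c(paste0("control_", 1:3), paste0("drought_", 1:3)),
    condition = rep(c("control", "drought"), each = 3)
  )
  set.seed(85)
  m <- matrix(rpois(60 * 6, 300), ncol = 6,
              dimnames = list(NULL, design$library))
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:60)),
    tibble::as_tibble(m)
  )
  lens <- rep(1000L, 60)
  de <- call_de(counts, design, lens)
  expect_true(all(de$de_status == "none"))  # identical groups
  expect_true(all(call_de(counts, design, lens,
                          fold_cut = Inf)$de_status == "none"))
})

test_that("planted fold changes are recovered concordantly across seeds", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 400 + s, contig_len = 20000, n_genes = 30,
                      de_fraction = 0.2, de_fold = 4,
                      expr_reads_per_gene = 1000, expr_dispersion = 0.02)
    g <- simulate_genome(cfg)
    e <- simulate_expression(g$genes, cfg)
    de <- call_de(e$counts, e$design, g$genes$exon_length)
    planted <- e$truth[e$truth$is_de, ]
    called <- de[match(planted$gene_id, de$gene_id), ]
    total <- total + nrow(planted)
    hits <- hits + sum(called$de_status == planted$direction)
  }
  expect_gte(hits / total, 0.95)
})

test_that("odds ratio follows (a/c)/(b/d) with principled edge handling", {
  expect_equal(odds_ratio(10, 10, 10, 10), 1)
  expect_equal(odds_ratio(30, 10, 20, 40), 6)
  set.seed(87)
  for (i in 1:20) {
    v <- sample.int(50, 4)
    expect_equal(odds_ratio(v[1], v[2], v[3], v[4]),
                 (v[1] / v[3]) / (v[2] / v[4]))
    # transposing the roles (methylation <-> expression) preserves OR
    expect_equal(odds_ratio(v[1], v[3], v[2], v[4]),
                 odds_ratio(v[1], v[2], v[3], v[4]))
  }
  expect_equal(odds_ratio(5, 0, 3, 7), Inf)
  expect_error(odds_ratio(0, 0, 3, 7), "margin")
  expect_error(odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("enrichment fold reproduces printed worked examples", {
  expect_equal(round(enrichment_fold(24410, 5797, 6216, 1688), 2), 1.14)
  expect_equal(round(enrichment_fold(24113, 2, 760, 2), 2), 31.73)
  expect_equal(enrichment_fold(100, 20, 10, 2), 1)  # b/n == B/N
  expect_error(enrichment_fold(10, 0, 5, 0), "B > 0")
  expect_error(enrichment_fold(10, 5, 5, 6), "quadruple")
})

test_that("hypergeometric enrichment equals combinatorial enumeration", {
  genes <- sprintf("g%02d", 1:10)
  terms <- tibble::tibble(term = "T", gene_id = genes[1:5])
  res <- enrichment_test(genes[1:5], terms, background = genes)
  expect_equal(res$p, 1 / choose(10, 5))
  expect_equal(res[, c("N", "B", "n", "b")],
               tibble::tibble(N = 10L, B = 5L, n = 5L, b = 5L),
               ignore_attr = TRUE)

  # B = N and b at its expectation: no enrichment, p = 1
  terms_all <- tibble::tibble(term = "T", gene_id = genes)
  res1 <- enrichment_test(genes[1:4], terms_all, background = genes)
  expect_equal(res1$fold, 1)
  expect_equal(res1$p, 1)

  # enumeration oracle over random small instances
  set.seed(89)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    B <- sample.int(N, 1)
    n <- sample.int(N, 1)
    bg <- sprintf("x%02d", 1:N)
    tm <- tibble::tibble(term = "T", gene_id = bg[seq_len(B)])
    tgt <- sample(bg, n)
    res <- enrichment_test(tgt, tm, background = bg)
    expect_equal(res$p, bf_hyper_tail(N, B, n, res$b), tolerance = 1e-12)
  }

  # p is monotone decreasing in b at fixed (N, B, n)
  ps <- vapply(0:5, function(b) {
    phyper(b - 1, 5, 15, 5, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(enrichment_test(c("zz"), terms, background = genes),
               "absent")
})

test_that("the association wrapper assembles the 2x2 table and OR", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"), chrom = "c1",
    start = c(1001L, 20001L, 40001L, 60001L),
    end = c(2000L, 21000L, 41000L, 61000L), strand = "+"
  )
  dms <- tibble::tibble(chrom = "c1", pos = c(1100L, 20100L))  # g1, g2
  de <- tibble::tibble(gene_id = genes$gene_id,
                       de_status = c("up", "none", "down", "none"))
  as <- associate_genes(genes, dms, de)
  expect_equal(unlist(as$table), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(as$odds_ratio, 1)
})
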