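#' Welch's two-sample t test
#'
#' The per-site test of the pipeline: `t = (mean(x) - mean(y)) /
#' sqrt(s2x/nx + s2y/ny)` with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Group variances are floored at 1e-8 so that
#' integer-count ties at low depth cannot divide by zero.
#'
#' @param x,y Numeric vectors (control and treated replicate values), each
#'   of length at least 2.
#' @return One-row tibble with `t`, `df`, `p`.
#' @examples
#' welch_test(c(10, 12, 11, 13), c(2, 3, 2, 3))
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_test() needs at least 2 values per group")
  }
  res <- welch_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  tibble::tibble(t = res$t, df = res$df, p = res$p)
}

# vectorized Welch over matrix rows; variance floor 1e-8
welch_rows <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- pmax(rowSums((X - mx)^2) / (nx - 1), 1e-8)
  vy <- pmax(rowSums((Y - my)^2) / (ny - 1), 1e-8)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_x = mx, mean_y = my)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment, `q_i = min_(j>=i) p_(j) * m / j` over the
#' p-value ranks.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Site filtering policy
#'
#' Flags each site of a count matrix as detected (at least one raw read in
#' every library) and tested (meets the minimum-read policy: at least
#' `min_reads` raw reads in any single library by default, or in every
#' library with `scope = "every"`).
#'
#' @param x An [mscc_counts] object.
#' @param min_reads Minimum raw read count (default 20).
#' @param scope `"any"` (default: one library suffices) or `"every"`.
#' @return Tibble with `chrom`, `pos`, `detected`, `tested`.
#' @export
filter_sites <- function(x, min_reads = 20, scope = c("any", "every")) {
  stopifnot(inherits(x, "mscc_counts"))
  scope <- match.arg(scope)
  if (min_reads < 0) abort("`min_reads` must be non-negative")
  detected <- apply(x$counts >= 1L, 1, all)
  tested <- if (scope == "any") {
    apply(x$counts >= min_reads, 1, any)
  } else {
    apply(x$counts >= min_reads, 1, all)
  }
  dplyr::bind_cols(x$sites, tibble::tibble(detected = detected,
                                           tested = tested))
}

#' Classify significant sites by direction of methylation change
#'
#' Digestion frequency is inversely proportional to methylation, so a site
#' whose treated mean falls below its control mean gained methylation under
#' treatment ("methylated"); the opposite is "demethylated". Sites not
#' below the FDR threshold, or with exactly tied means (warned), are
#' "none".
#'
#' @param table DMS table with columns `mean_control`, `mean_treated`, `q`.
#' @param threshold FDR threshold.
#' @return The table with a `direction` column.
#' @export
classify_direction <- function(table, threshold = 0.05) {
  sig <- !is.na(table$q) & table$q < threshold
  tied <- sig & table$mean_control == table$mean_treated
  if (any(tied)) {
    warn(sprintf("%d significant site(s) with exactly tied means left 'none'",
                 sum(tied)))
  }
  table$direction <- dplyr::case_when(
    sig & table$mean_treated < table$mean_control ~ "methylated",
    sig & table$mean_treated > table$mean_control ~ "demethylated",
    .default = "none"
  )
  table
}

#' Call differentially methylated sites
#'
#' Per-site Welch t tests of normalized digestion frequencies between the
#' two conditions on the sites passing the read filter, Benjamini-Hochberg
#' FDR across tested sites, and directional classification at the given
#' threshold.
#'
#' @param x An [mscc_counts] object; normalized automatically if needed.
#' @param fdr FDR threshold for classification (default 0.05).
#' @param min_reads,scope Filter policy, see [filter_sites()].
#' @param log_transform Test `log1p` of normalized counts instead of the
#'   counts themselves (off by default).
#' @return An object of class `mscc_dms` with the per-site table
#'   (`tidy()`), summary counts (`glance()`) and the calling parameters.
#' @export
call_dms <- function(x, fdr = 0.05, min_reads = 20,
                     scope = c("any", "every"), log_transform = FALSE) {
  stopifnot(inherits(x, "mscc_counts"))
  scope <- match.arg(scope)
  if (is.null(x$normalized)) x <- normalize_counts(x)
  flags <- filter_sites(x, min_reads = min_reads, scope = scope)

  cond <- x$design$condition
  conds <- unique(cond)
  if (length(conds) != 2) abort("design must have exactly two conditions")
  ctrl <- which(cond == conds[1])
  trt <- which(cond == conds[2])
  if (length(ctrl) < 2 || length(trt) < 2) {
    abort("need at least two replicates per condition")
  }

  vals <- x$normalized
  if (log_transform) vals <- log1p(vals)
  tested <- which(flags$tested)
  table <- dplyr::bind_cols(
    x$sites,
    tibble::tibble(
      mean_control = NA_real_, mean_treated = NA_real_,
      t = NA_real_, df = NA_real_, p = NA_real_, q = NA_real_,
      passed_filter = flags$tested, detected = flags$detected
    )
  )
  if (length(tested) > 0) {
    w <- welch_rows(vals[tested, ctrl, drop = FALSE],
                    vals[tested, trt, drop = FALSE])
    table$mean_control[tested] <- w$mean_x
    table$mean_treated[tested] <- w$mean_y
    table$t[tested] <- w$t
    table$df[tested] <- w$df
    table$p[tested] <- w$p
    table$q[tested] <- bh_fdr(w$p)
  }
  table <- classify_direction(table, threshold = fdr)

  structure(
    list(table = table, fdr = fdr, min_reads = min_reads, scope = scope,
         log_transform = log_transform,
         conditions = stats::setNames(conds, c("control", "treated")),
         n_sites = nrow(table), n_detected = sum(flags$detected),
         n_tested = sum(flags$tested)),
    class = "mscc_dms"
  )
}

#' @export
print.mscc_dms <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mscc_dms> %d sites, %d detected, %d tested\n",
              g$n_sites, g$n_detected, g$n_tested))
  cat(sprintf("  %d DMS at FDR %.2g: %d methylated, %d demethylated\n",
              g$n_dms, x$fdr, g$n_methylated, g$n_demethylated))
  invisible(x)
}

#' @rdname call_dms
#' @param x,... An `mscc_dms` object (for `tidy()`/`glance()`).
#' @method tidy mscc_dms
#' @export
tidy.mscc_dms <- function(x, ...) x$table

#' @rdname call_dms
#' @method glance mscc_dms
#' @export
glance.mscc_dms <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites, n_detected = x$n_detected, n_tested = x$n_tested,
    n_dms = sum(x$table$direction != "none"),
    n_methylated = sum(x$table$direction == "methylated"),
    n_demethylated = sum(x$table$direction == "demethylated"),
    fdr = x$fdr
  )
}

#' Extract the significant sites of a DMS fit
#'
#' @param x An `mscc_dms` object.
#' @param fdr Threshold; defaults to the fit's threshold. A stricter value
#'   reclassifies directions at that threshold.
#' @return Tibble of DMS (direction != "none").
#' @export
dms_sites <- function(x, fdr = NULL) {
  stopifnot(inherits(x, "mscc_dms"))
  tab <- x$table
  if (!is.null(fdr) && fdr != x$fdr) {
    tab <- classify_direction(tab, threshold = fdr)
  }
  tab[tab$direction != "none", , drop = FALSE]
}

#' Pairwise replicate concordance (r-squared)
#'
#' Pearson coefficients of determination between every pair of libraries on
#' a random subset of sites, the all-versus-all reproducibility summary of
#' an MSCC experiment.
#'
#' @param x An [mscc_counts] object (normalized values used if present).
#' @param n_sites Number of randomly selected sites (default 1200); if more
#'   than available, all sites are used with a warning.
#' @param seed Seed for the site subsample.
#' @return Tibble with `library_a`, `library_b`, `r2` for all ordered pairs
#'   (including the diagonal, which is exactly 1).
#' @export
replicate_r2 <- function(x, n_sites = 1200, seed = 1) {
  stopifnot(inherits(x, "mscc_counts"))
  vals <- count_values(x)
  n <- nrow(vals)
  if (n_sites > n) {
    warn(sprintf("n_sites (%d) exceeds available sites (%d); using all",
                 n_sites, n))
    n_sites <- n
  }
  idx <- with_stream(seed, "replicate_r2", sample.int(n, n_sites))
  r <- stats::cor(vals[idx, , drop = FALSE])
  tibble::as_tibble(r^2, rownames = "library_a") %>%
    tidyr::pivot_longer(-"library_a", names_to = "library_b",
                        values_to = "r2")
}
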