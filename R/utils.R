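# internal helpers shared across modules

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr %>%
#' @importFrom stats var setNames rnbinom rpois rbeta runif rnorm rbinom
#'   pt p.adjust phyper cor quantile
NULL

# coerce a genome to a named DNAStringSet; accepts DNAStringSet, named
# character vector, or a path to a FASTA file
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    if (length(genome) == 0) abort("`genome` is empty.")
    if (is.null(names(genome))) {
      names(genome) <- paste0("contig_", seq_along(genome))
    }
    gs <- Biostrings::DNAStringSet(genome)
  } else {
    abort("`genome` must be a DNAStringSet, a named character vector or a FASTA path.")
  }
  if (length(gs) == 0 || sum(Biostrings::width(gs)) == 0) {
    abort("`genome` is empty.")
  }
  bad <- setdiff(
    unique(unlist(strsplit(as.character(gs), ""))),
    c("A", "C", "G", "T", "N")
  )
  if (length(bad) > 0) {
    abort(paste0("genome contains letters outside {A,C,G,T,N}: ",
                 paste(bad, collapse = ", ")))
  }
  gs
}

# vectorized reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between pairs of equal-length strings (vectorized)
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- nchar(a)
  if (any(nchar(b) != n)) abort("hamming(): strings must have equal lengths")
  out <- integer(length(a))
  for (i in seq_len(max(n, 0))) {
    out <- out + (substr(a, i, i) != substr(b, i, i))
  }
  out
}

# masked one-mismatch keys: position i replaced by deletion, prefixed by i.
# Two equal-length strings are at Hamming distance <= 1 iff they share a key.
masked_keys <- function(tags, tag_len = 27L) {
  n <- length(tags)
  keys <- vector("list", tag_len)
  for (i in seq_len(tag_len)) {
    keys[[i]] <- paste0(i, ":", substr(tags, 1, i - 1),
                        substr(tags, i + 1, tag_len))
  }
  tibble::tibble(
    idx = rep(seq_len(n), times = tag_len),
    key = unlist(keys)
  )
}

# deterministic sub-stream seed derived from a global seed and a stage name;
# keeps the result a valid 32-bit integer seed
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)
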