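# Independent oracles used across test files. These deliberately avoid the
# package's own algorithms: the fold oracle enumerates nested pairings by
# plain recursion, and repeat-detector oracles use Biostrings palindrome
# search and a backreference regex.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# maximum number of nested base pairs by exhaustive recursion (no memo)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (oracle_can_pair(ch[k], ch[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        inner <- rec(k + 1L, j - 1L)
        best <- max(best, 1L + left + inner)
      }
    }
    best
  }
  if (length(ch) < 2L) return(0L)
  rec(1L, length(ch))
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# perfect G/C stem with an all-A loop and pads: the only possible pairs are
# the k G:C stem pairs, so the fold is unambiguous.
# Returns a hairpin_candidate skeleton with the mature placed in one arm.
perfect_stem_candidate <- function(k = 12L, loop = 4L, mature_len = 8L,
                                   offset = 2L, arm = "5p") {
  seq <- paste0("AA", strrep("G", k), strrep("A", loop), strrep("C", k), "AA")
  if (arm == "5p") {
    m1 <- 2L + offset
  } else {
    m1 <- 2L + k + loop + offset
  }
  structure(list(contig = "c", start = 0L, end = nchar(seq), strand = "+",
                 seq = seq, mature_span = c(m1, m1 + mature_len - 1L),
                 clipped = FALSE, structure = NULL),
            class = "hairpin_candidate")
}

# brute-force both-strand exact substring scan
oracle_genome_hits <- function(genome, tag) {
  out <- list()
  for (contig in names(genome)) {
    g <- genome[[contig]]
    w <- nchar(tag)
    n <- nchar(g)
    if (w > n) next
    starts1 <- seq_len(n - w + 1L)
    wins <- substring(g, starts1, starts1 + w - 1L)
    for (s in starts1[wins == tag]) {
      out[[length(out) + 1L]] <- data.frame(contig = contig, start = s - 1L,
                                            strand = "+", stringsAsFactors = FALSE)
    }
    rc <- mirstage::rna_revcomp(tag)
    for (s in starts1[wins == rc]) {
      out[[length(out) + 1L]] <- data.frame(contig = contig, start = s - 1L,
                                            strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), strand = character())
}
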