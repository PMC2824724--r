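#' Demultiplex barcoded reads into stage libraries
#'
#' Assigns each read to a stage iff its 5' prefix equals exactly one of the
#' supplied barcodes (exact match, no mismatches); the barcode is removed from
#' assigned reads. Unassignable reads are returned, never dropped.
#'
#' @param reads Data frame with columns `read_id` and `seq` (RNA alphabet),
#'   as returned by [read_sequences()].
#' @param barcodes Named character vector mapping each of the four stage
#'   labels to its barcode; all barcodes must share one length and be
#'   pairwise distinct.
#' @return A list with `assigned` (data frame `read_id`, `stage`, `seq` with
#'   barcodes stripped) and `unassigned` (the remaining reads).
#' @export
demultiplex <- function(reads, barcodes) {
  barcodes <- as_stage_vector(as_rna(barcodes), "barcodes")
  k <- unique(nchar(barcodes))
  if (length(k) != 1L) stop("barcodes must all have the same length")
  if (anyDuplicated(barcodes)) stop("barcodes must be pairwise distinct")
  prefix <- substr(reads$seq, 1L, k)
  stage <- names(barcodes)[match(prefix, barcodes)]
  hit <- !is.na(stage)
  assigned <- data.frame(read_id = reads$read_id[hit],
                         stage = stage[hit],
                         seq = substr(reads$seq[hit], k + 1L, nchar(reads$seq[hit])),
                         stringsAsFactors = FALSE)
  list(assigned = assigned, unassigned = reads[!hit, , drop = FALSE])
}

#' Trim the 3' adapter from demultiplexed reads
#'
#' Locates the leftmost exact occurrence of the adapter's `min_anchor`-length
#' 5' prefix in each read and returns the insert 5' of it. Reads in which the
#' anchor never occurs carry no recognizable adapter and are rejected.
#'
#' @param seqs Character vector of read sequences (barcode already removed).
#' @param adapter Adapter sequence (RNA or DNA letters).
#' @param min_anchor Length of the adapter prefix that must match perfectly
#'   (default 11).
#' @return A list with `insert` (character; `NA` where rejected) and
#'   `rejected` (logical vector).
#' @export
trim_adapter <- function(seqs, adapter, min_anchor = 11L) {
  adapter <- as_rna(adapter)
  if (min_anchor > nchar(adapter)) stop("min_anchor exceeds adapter length")
  anchor <- substr(adapter, 1L, min_anchor)
  pos <- regexpr(anchor, as_rna(seqs), fixed = TRUE)
  rejected <- pos < 0L
  insert <- ifelse(rejected, NA_character_, substr(seqs, 1L, pos - 1L))
  list(insert = insert, rejected = rejected)
}

#' Filter sequences by length
#'
#' Retains sequences with `min_len <= length <= max_len` (both inclusive) and
#' reports how many were removed.
#'
#' @param seqs Character vector (or data frame with a `seq` column).
#' @param min_len,max_len Inclusive length bounds (defaults 18 and 30).
#' @return A list with `kept` (same type as input), `n_removed`, and
#'   `removed` (the discarded entries).
#' @export
length_filter <- function(seqs, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  s <- if (is.data.frame(seqs)) seqs$seq else seqs
  keep <- nchar(s) >= min_len & nchar(s) <= max_len
  if (is.data.frame(seqs)) {
    list(kept = seqs[keep, , drop = FALSE], n_removed = sum(!keep),
         removed = seqs[!keep, , drop = FALSE])
  } else {
    list(kept = seqs[keep], n_removed = sum(!keep), removed = seqs[!keep])
  }
}

#' Collapse per-stage reads to unique tags
#'
#' One row per distinct sequence with its per-stage occurrence counts and
#' total. The sum of all per-stage counts equals the number of input reads.
#'
#' @param stage Character vector of stage labels, one per read.
#' @param seqs Character vector of read sequences (same length as `stage`).
#' @return Data frame with columns `seq`, the four stage labels, and `total`,
#'   ordered by decreasing total then sequence.
#' @export
collapse_unique <- function(stage, seqs) {
  stages <- stage_labels()
  stopifnot(length(stage) == length(seqs), all(stage %in% stages))
  if (length(seqs) == 0L) {
    out <- data.frame(seq = character(), stringsAsFactors = FALSE)
    for (s in stages) out[[s]] <- integer()
    out$total <- integer()
    return(out)
  }
  tab <- table(factor(seqs, levels = unique(seqs)),
               factor(stage, levels = stages))
  tags <- data.frame(seq = rownames(tab), stringsAsFactors = FALSE)
  for (s in stages) tags[[s]] <- as.integer(tab[, s])
  tags$total <- as.integer(rowSums(tab))
  tags <- tags[order(-tags$total, tags$seq), , drop = FALSE]
  rownames(tags) <- NULL
  tags
}

#' Per-stage read-length histograms
#'
#' Counts tags per length bin (18-30 nt) and stage, weighting each length bin
#' by read counts (`mode = "total"`) or by distinct tags (`mode = "unique"`).
#' This reproduces the bimodal 20-22 / 26-29 nt structure of small RNA
#' libraries when present.
#'
#' @param tags Collapsed tag table from [collapse_unique()].
#' @param mode `"total"` or `"unique"`.
#' @param min_len,max_len Histogram support (defaults 18 and 30).
#' @return Integer matrix with one row per length and one column per stage.
#' @export
size_distribution <- function(tags, mode = c("total", "unique"),
                              min_len = 18L, max_len = 30L) {
  mode <- match.arg(mode)
  stages <- stage_labels()
  lens <- min_len:max_len
  h <- matrix(0L, nrow = length(lens), ncol = length(stages),
              dimnames = list(as.character(lens), stages))
  if (nrow(tags) == 0L) return(h)
  tl <- nchar(tags$seq)
  stopifnot(all(tl >= min_len & tl <= max_len))
  for (s in stages) {
    w <- if (mode == "total") tags[[s]] else as.integer(tags[[s]] > 0L)
    h[, s] <- vapply(lens, function(L) sum(w[tl == L]), integer(1))
  }
  h
}
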