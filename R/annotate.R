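#' Build an exact-match genome index
#'
#' Wraps a set of contigs for exact both-strand substring queries via
#' Biostrings preprocessed dictionaries (queries are grouped by tag width so
#' each width uses one constant-width `PDict` scan per strand). Hit order is
#' deterministic: contig, position, strand (`+` before `-`).
#'
#' @param seqs Named character vector of contig sequences (RNA or DNA
#'   letters; names must be unique and non-empty).
#' @return An object of class `genome_index`.
#' @export
build_index <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    stop("contigs must carry unique non-empty names")
  }
  if (any(nchar(seqs) == 0L)) stop("contig sequences must be non-empty")
  fwd <- Biostrings::DNAStringSet(as_dna(seqs))
  names(fwd) <- names(seqs)
  structure(list(fwd = fwd, rev = Biostrings::reverseComplement(fwd),
                 lens = setNames(nchar(seqs), names(seqs))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$fwd), "contig(s),", sum(x$lens), "nt\n")
  invisible(x)
}

#' Query a genome index for exact tag occurrences on both strands
#'
#' @param index A [build_index()] object.
#' @param tags Character vector of query sequences.
#' @return Data frame `tag`, `contig`, `start` (0-based), `strand`, `width`;
#'   minus-strand starts refer to the forward contig coordinate of the hit's
#'   leftmost base. Rows ordered by tag, contig, start, strand.
#' @export
genome_hits <- function(index, tags) {
  stopifnot(inherits(index, "genome_index"))
  out <- list()
  if (length(tags) && length(tags) < 50L) {
    # small query sets: direct fixed-string scans beat dictionary setup
    fwd <- as.character(index$fwd)
    rev <- as.character(index$rev)
    for (ti in seq_along(tags)) {
      dna <- as_dna(tags[ti])
      w <- nchar(dna)
      for (ci in seq_along(fwd)) {
        contig <- names(index$fwd)[ci]
        clen <- index$lens[[contig]]
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") fwd[ci] else rev[ci]
          # lookahead so that overlapping occurrences are all reported
          s1 <- gregexpr(paste0("(?=", dna, ")"), subj, perl = TRUE)[[1L]]
          if (s1[1L] < 0L) next
          s0 <- if (strand == "+") s1 - 1L else clen - (s1 - 1L) - w
          out[[length(out) + 1L]] <- data.frame(
            tag = tags[ti], contig = contig, start = as.integer(s0),
            strand = strand, width = w, stringsAsFactors = FALSE)
        }
      }
    }
  } else if (length(tags)) {
    dna <- as_dna(tags)
    widths <- nchar(dna)
    for (w in sort(unique(widths))) {
      sel <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(dna[sel]))
      for (ci in seq_along(index$fwd)) {
        contig <- names(index$fwd)[ci]
        clen <- index$lens[[contig]]
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") index$fwd[[ci]] else index$rev[[ci]]
          m <- Biostrings::matchPDict(pd, subj)
          starts <- Biostrings::startIndex(m)
          nhit <- if (is.null(starts)) integer(length(sel)) else lengths(starts)
          if (sum(nhit) == 0L) next
          s1 <- unlist(starts)  # 1-based on scanned strand
          s0 <- if (strand == "+") s1 - 1L else clen - (s1 - 1L) - w
          out[[length(out) + 1L]] <- data.frame(
            tag = rep(tags[sel], nhit), contig = contig,
            start = as.integer(s0), strand = strand, width = w,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(), contig = character(), start = integer(),
               strand = character(), width = integer(), stringsAsFactors = FALSE)
  res <- res[order(match(res$tag, tags), res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match a tag against a catalog of known mature miRNAs
#'
#' Edit-distance homolog matching: a tag is assigned to the catalog mature
#' with the fewest edits (Levenshtein), requiring `edits <= max_edits` and a
#' terminal length offset `|nchar(tag) - nchar(mature)| <= max_shift`. Ties
#' break by smaller absolute offset, then lexicographic name. Tolerances
#' default to 2 edits and 3 nt, accommodating the terminal isomiR variants
#' that co-accumulate with a canonical mature.
#'
#' @param tags Character vector of tag sequences.
#' @param catalog Named character vector of mature miRNA sequences.
#' @param max_edits,max_shift Tolerances (defaults 2 and 3).
#' @return Data frame `tag`, `mirna` (NA if no hit), `edits`, `offset`.
#' @export
match_conserved <- function(tags, catalog, max_edits = 2L, max_shift = 3L) {
  stopifnot(!is.null(names(catalog)))
  cat_seq <- as_rna(catalog)
  res <- data.frame(tag = tags, mirna = NA_character_,
                    edits = NA_integer_, offset = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!length(tags) || !length(catalog)) return(res)
  # only tags within max_shift of some catalog length can match at all
  cat_lens <- nchar(cat_seq)
  feas <- which(nchar(tags) >= min(cat_lens) - max_shift &
                  nchar(tags) <= max(cat_lens) + max_shift)
  if (!length(feas)) return(res)
  d <- adist(as_rna(tags[feas]), cat_seq)
  off <- outer(nchar(tags[feas]), cat_lens, "-")
  ok <- d <= max_edits & abs(off) <= max_shift
  ord_name <- order(names(catalog))
  for (k in seq_along(feas)) {
    cand <- which(ok[k, ])
    if (!length(cand)) next
    cand <- cand[order(d[k, cand], abs(off[k, cand]), match(cand, ord_name))]
    best <- cand[1L]
    i <- feas[k]
    res$mirna[i] <- names(catalog)[best]
    res$edits[i] <- d[k, best]
    res$offset[i] <- off[k, best]
  }
  res
}

# internal: which tags occur as exact substrings (either orientation) of any
# sequence in a reference set; returns the name of the first matching
# reference (by set order) or NA. References are short relative to the tag
# table, so all reference substrings in the tag length range are enumerated
# once and the tags hashed against them.
match_reference <- function(tags, refs) {
  hit <- rep(NA_character_, length(tags))
  if (!length(tags) || !length(refs)) return(hit)
  lens <- sort(unique(nchar(tags)))
  subs <- character(); owner <- character()
  for (ri in seq_along(refs)) {
    for (sq in c(as_rna(refs[[ri]]), rna_revcomp(refs[[ri]]))) {
      n <- nchar(sq)
      for (L in lens) {
        if (L > n) next
        a <- seq_len(n - L + 1L)
        subs <- c(subs, substring(sq, a, a + L - 1L))
        owner <- c(owner, rep(names(refs)[ri], length(a)))
      }
    }
  }
  keep <- !duplicated(subs)  # first reference in set order wins
  idx <- match(tags, subs[keep])
  hit[!is.na(idx)] <- owner[keep][idx[!is.na(idx)]]
  hit
}

#' Hierarchical annotation cascade over unique tags
#'
#' Assigns every tag to exactly one category by strict first-match priority:
#' `ncRNA` > `repeat` > `mRNA` > `conserved_miRNA` > `genome_only` >
#' `unmapped`. Reference matching is exact substring containment in either
#' orientation; conserved-miRNA matching uses [match_conserved()]. Published
#' category tables from comparable libraries over-sum their subtotals,
#' implying overlapping categories; this cascade is a strict partition so
#' per-stage category counts always sum to the library totals.
#'
#' @param tags Collapsed tag table ([collapse_unique()]).
#' @param reference_sets Named list with elements `ncRNA`, `repeat`, `mRNA`
#'   (each a named character vector of reference sequences; missing element
#'   is an error) and `known_miRNA` (catalog for [match_conserved()]).
#' @param genome_index A [build_index()] object for the genome.
#' @param max_edits,max_shift Conserved-matching tolerances.
#' @param multimap_cap Tags with more genome hits than this are flagged
#'   `repeat_like` in the evidence column (default 100).
#' @param structural_repeat_screen If TRUE, tags qualifying under
#'   [detect_inverted_repeat()] or [detect_tandem_repeat()] also enter the
#'   `repeat` category (default FALSE).
#' @return List with `assignments` (data frame `seq`, `category`, `evidence`)
#'   and `category_counts` (read-count matrix category x stage, plus
#'   `subtotal` and `Total` rows).
#' @export
annotate_cascade <- function(tags, reference_sets, genome_index,
                             max_edits = 2L, max_shift = 3L,
                             multimap_cap = 100L,
                             structural_repeat_screen = FALSE) {
  needed <- c("ncRNA", "repeat", "mRNA", "known_miRNA")
  missing <- setdiff(needed, names(reference_sets))
  if (length(missing)) {
    stop("missing reference set(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(tags)
  category <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)

  todo <- seq_len(n)
  hit <- match_reference(tags$seq[todo], reference_sets$ncRNA)
  category[todo[!is.na(hit)]] <- "ncRNA"
  evidence[todo[!is.na(hit)]] <- hit[!is.na(hit)]

  todo <- which(is.na(category))
  hit <- match_reference(tags$seq[todo], reference_sets[["repeat"]])
  if (structural_repeat_screen) {
    str_hit <- vapply(tags$seq[todo], function(s) {
      detect_inverted_repeat(s)$found || detect_tandem_repeat(s)$found
    }, logical(1))
    hit[is.na(hit) & str_hit] <- "structural_repeat"
  }
  category[todo[!is.na(hit)]] <- "repeat"
  evidence[todo[!is.na(hit)]] <- hit[!is.na(hit)]

  todo <- which(is.na(category))
  hit <- match_reference(tags$seq[todo], reference_sets$mRNA)
  category[todo[!is.na(hit)]] <- "mRNA"
  evidence[todo[!is.na(hit)]] <- hit[!is.na(hit)]

  todo <- which(is.na(category))
  cons <- match_conserved(tags$seq[todo], reference_sets$known_miRNA,
                          max_edits = max_edits, max_shift = max_shift)
  found <- !is.na(cons$mirna)
  category[todo[found]] <- "conserved_miRNA"
  evidence[todo[found]] <- cons$mirna[found]

  todo <- which(is.na(category))
  if (length(todo)) {
    hits <- genome_hits(genome_index, tags$seq[todo])
    nh <- table(factor(hits$tag, levels = tags$seq[todo]))
    mapped <- as.integer(nh) > 0L
    category[todo[mapped]] <- "genome_only"
    ev <- ifelse(as.integer(nh) > multimap_cap, "repeat_like",
                 paste0("hits=", as.integer(nh)))
    evidence[todo[mapped]] <- ev[mapped]
    category[todo[!mapped]] <- "unmapped"
  }

  stages <- stage_labels()
  cats <- c("ncRNA", "repeat", "mRNA", "conserved_miRNA", "genome_only", "unmapped")
  mat <- matrix(0L, nrow = length(cats), ncol = length(stages),
                dimnames = list(cats, stages))
  for (s in stages) {
    mat[, s] <- vapply(cats, function(cc) sum(tags[[s]][category == cc]), numeric(1))
  }
  mapped_cats <- setdiff(cats, "unmapped")
  mat <- rbind(mat,
               subtotal = colSums(mat[mapped_cats, , drop = FALSE]),
               Total = colSums(mat[cats, , drop = FALSE]))
  list(assignments = data.frame(seq = tags$seq, category = category,
                                evidence = evidence, stringsAsFactors = FALSE),
       category_counts = mat)
}
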