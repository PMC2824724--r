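#' Excise candidate precursor windows around a genome hit
#'
#' For each configured (upstream, downstream) flank pair, returns the genomic
#' window around the mature hit, oriented 5' to 3' on the hit strand.
#' Windows exceeding contig bounds are clipped and flagged.
#'
#' @param genome Named character vector of contig sequences.
#' @param hit A list or one-row data frame with `contig`, `start` (0-based),
#'   `strand`, `width` as produced by [genome_hits()].
#' @param flanks List of `c(up, down)` flank lengths in nt, measured 5' and
#'   3' of the mature on the hit strand. Defaults to
#'   `list(c(20, 150), c(150, 20), c(70, 70))`; precursor hairpins are
#'   typically under ~160 nt, which these windows cover from either arm.
#' @return List of `hairpin_candidate` skeletons: `contig`, `start`, `end`
#'   (0-based half-open, forward coordinates), `strand`, `seq` (window on hit
#'   strand), `mature_span` (1-based within window), `clipped`.
#' @export
excise_windows <- function(genome, hit,
                           flanks = list(c(20L, 150L), c(150L, 20L), c(70L, 70L))) {
  contig_seq <- genome[[hit$contig]]
  clen <- nchar(contig_seq)
  lapply(flanks, function(fl) {
    up <- fl[1L]; down <- fl[2L]
    if (hit$strand == "+") {
      g_up <- up; g_down <- down
    } else {
      g_up <- down; g_down <- up
    }
    w0 <- hit$start - g_up
    w1 <- hit$start + hit$width + g_down  # half-open end
    clipped <- w0 < 0L || w1 > clen
    w0c <- max(0L, w0)
    w1c <- min(clen, w1)
    sq <- substr(contig_seq, w0c + 1L, w1c)
    # offset of mature within the forward-coordinate window
    fwd_off <- hit$start - w0c
    if (hit$strand == "-") {
      sq <- rna_revcomp(sq)
      m1 <- (w1c - (hit$start + hit$width)) + 1L
    } else {
      m1 <- fwd_off + 1L
    }
    structure(list(contig = hit$contig, start = as.integer(w0c),
                   end = as.integer(w1c), strand = hit$strand,
                   seq = as_rna(sq),
                   mature_span = c(m1, m1 + hit$width - 1L),
                   clipped = clipped, structure = NULL),
              class = "hairpin_candidate")
  })
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("hairpin_candidate %s:%d-%d(%s), window %d nt, mature %d-%d\n",
              x$contig, x$start, x$end, x$strand, nchar(x$seq),
              x$mature_span[1], x$mature_span[2]))
  if (!is.null(x$structure)) print(x$structure)
  invisible(x)
}

# internal: fold a candidate's window if not yet folded
fold_candidate <- function(cand, min_loop = 3L, backend = NULL) {
  if (is.null(cand$structure)) cand$structure <- rna_fold(cand$seq, min_loop, backend)
  cand
}

#' Qualify a candidate hairpin as a plausible miRNA precursor
#'
#' A candidate qualifies iff (a) the mature span does not span a terminal
#' loop, (b) at least `paired_fraction_min` of mature bases are paired,
#' (c) every mature partner lies on the opposite side of the mature within a
#' single stem (exactly one terminal loop between the mature and its
#' partners), and (d) that loop's size is at most `loop_max`.
#'
#' @param cand A folded `hairpin_candidate` with `mature_span` set.
#' @param paired_fraction_min Minimum paired fraction of mature bases
#'   (default 0.6).
#' @param loop_max Maximum terminal-loop size in nt (default 30).
#' @return List with `qualified` (logical) and `metrics` (paired_fraction,
#'   loop_size, spans_loop, one_sided, arm).
#' @export
qualify_hairpin <- function(cand, paired_fraction_min = 0.6, loop_max = 30L) {
  cand <- fold_candidate(cand)
  st <- cand$structure
  n <- nchar(cand$seq)
  m1 <- cand$mature_span[1L]; m2 <- cand$mature_span[2L]
  if (m1 < 1L || m2 > n || m1 > m2) stop("mature_span outside window")
  p <- st$pairs
  loops <- hairpin_loops(st)
  spans_loop <- any(loops$a >= m1 & loops$b <= m2)
  mp <- m1:m2
  partners <- p[mp]
  paired_fraction <- mean(partners > 0L)
  q <- partners[partners > 0L]
  one_sided <- length(q) > 0L && (all(q > m2) | all(q < m1))
  arm <- NA_character_
  loop_size <- NA_integer_
  single_stem <- FALSE
  if (one_sided && !spans_loop) {
    if (all(q > m2)) {
      arm <- "5p"
      pm <- max(mp[partners > 0L])
      lo <- pm; hi <- p[pm]
    } else {
      arm <- "3p"
      pm <- min(mp[partners > 0L])
      lo <- p[pm]; hi <- pm
    }
    inside <- loops[loops$a >= lo & loops$b <= hi, , drop = FALSE]
    if (nrow(inside) == 1L) {
      single_stem <- TRUE
      loop_size <- inside$size
    }
  }
  qualified <- !spans_loop && paired_fraction >= paired_fraction_min &&
    one_sided && single_stem && !is.na(loop_size) && loop_size <= loop_max
  list(qualified = qualified,
       metrics = list(paired_fraction = paired_fraction,
                      loop_size = loop_size, spans_loop = spans_loop,
                      one_sided = one_sided, arm = arm))
}

#' Arm placement of the mature within the hairpin
#'
#' `"5p"` iff the mature lies entirely 5' of the terminal loop midpoint,
#' `"3p"` iff entirely 3' of it; a mature spanning the loop is an error.
#'
#' @param cand A folded, qualified `hairpin_candidate`.
#' @return `"5p"` or `"3p"`.
#' @export
arm_of <- function(cand) {
  cand <- fold_candidate(cand)
  q <- qualify_hairpin(cand, paired_fraction_min = 0, loop_max = .Machine$integer.max)
  if (q$metrics$spans_loop) stop("mature spans the terminal loop")
  if (is.na(q$metrics$arm)) stop("mature arm is undefined (no one-sided pairing)")
  q$metrics$arm
}

#' Infer the miRNA-star span under 2-nt 3' overhang duplex geometry
#'
#' The Dicer signature leaves each strand of the miR:miR* duplex extending
#' 2 nt past the paired region at its 3' end. Accordingly the star's 5' end
#' is the partner of (mature 3' end - 2) and its 3' end is the partner of the
#' mature 5' end, plus 2 — in window coordinates, clipped at window bounds
#' (and flagged) when the precursor was excised tightly. Unpaired mature
#' termini are resolved to the nearest paired position inward.
#'
#' @param cand A folded, qualified `hairpin_candidate`.
#' @return List with `start`, `end` (1-based window coordinates), `seq`,
#'   `clipped`.
#' @export
infer_star <- function(cand) {
  cand <- fold_candidate(cand)
  p <- cand$structure$pairs
  n <- nchar(cand$seq)
  m1 <- cand$mature_span[1L]; m2 <- cand$mature_span[2L]
  if (!any(p[m1:m2] > 0L)) stop("mature arm has no paired positions")
  e3 <- m2 - 2L
  while (e3 >= m1 && p[e3] == 0L) e3 <- e3 - 1L
  if (e3 < m1) stop("no paired position at or inward of mature 3' end - 2")
  e5 <- m1
  while (e5 <= m2 && p[e5] == 0L) e5 <- e5 + 1L
  a <- p[e3]
  b <- p[e5] + 2L
  lo <- min(a, b); hi <- max(a, b)
  clipped <- lo < 1L || hi > n
  lo <- max(1L, lo); hi <- min(n, hi)
  list(start = lo, end = hi, seq = substr(cand$seq, lo, hi), clipped = clipped)
}

#' Fold the antisense strand of a precursor window
#'
#' Reverse-complements the window, folds it, and returns a candidate on the
#' opposite strand. The mature span, when supplied, is mirrored into
#' antisense coordinates (the antisense mature is the reverse complement of
#' the sense span).
#'
#' @param cand A `hairpin_candidate` (sense strand).
#' @param min_loop,backend Passed to [rna_fold()].
#' @return A folded `hairpin_candidate` on the opposite strand.
#' @export
fold_antisense <- function(cand, min_loop = 3L, backend = NULL) {
  n <- nchar(cand$seq)
  m <- cand$mature_span
  as_span <- if (!is.null(m)) c(n - m[2L] + 1L, n - m[1L] + 1L) else NULL
  out <- structure(list(contig = cand$contig, start = cand$start, end = cand$end,
                        strand = if (cand$strand == "+") "-" else "+",
                        seq = rna_revcomp(cand$seq),
                        mature_span = as_span, clipped = cand$clipped,
                        structure = NULL),
                   class = "hairpin_candidate")
  fold_candidate(out, min_loop, backend)
}

#' Best qualifying hairpin over the configured flank windows
#'
#' Excises all flank windows for a hit, folds each, and retains the best
#' qualifying candidate — ties broken by higher mature paired fraction, then
#' smaller window.
#'
#' @inheritParams excise_windows
#' @param paired_fraction_min,loop_max Passed to [qualify_hairpin()].
#' @return The winning folded `hairpin_candidate` (with `$qualification`
#'   attached), or `NULL` if no window qualifies.
#' @export
best_hairpin <- function(genome, hit,
                         flanks = list(c(20L, 150L), c(150L, 20L), c(70L, 70L)),
                         paired_fraction_min = 0.6, loop_max = 30L) {
  cands <- excise_windows(genome, hit, flanks)
  best <- NULL
  best_key <- c(-Inf, Inf)
  for (cand in cands) {
    cand <- fold_candidate(cand)
    q <- qualify_hairpin(cand, paired_fraction_min, loop_max)
    if (!q$qualified) next
    key <- c(q$metrics$paired_fraction, -nchar(cand$seq))
    if (key[1L] > best_key[1L] ||
        (key[1L] == best_key[1L] && -key[2L] < -best_key[2L])) {
      best <- cand
      best$qualification <- q
      best_key <- key
    }
  }
  best
}
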