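#' Predict RNA secondary structure by base-pair maximization
#'
#' Dynamic-programming fold (maximum number of nested base pairs) over
#' Watson-Crick and G·U wobble pairs with a minimum hairpin loop of
#' `min_loop` unpaired bases. The traceback is deterministic: when pairing a
#' position ties the unpaired alternative, the pairing is taken, preferring
#' the 5'-most competing partner. Hairpin qualification consumes structure
#' topology (single stem, arm placement, paired fractions), which base-pair
#' maximization captures without a thermodynamic model; an energy backend can
#' be substituted via `backend`.
#'
#' @param seq RNA sequence (length >= 10 for meaningful hairpins; shorter
#'   inputs fold to all-unpaired).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param allow_gu Allow G·U wobble pairs (default TRUE). Note that with
#'   wobble pairs the fold is not symmetric under reverse complement (a G·U
#'   pair maps to A·C); strict Watson-Crick folding (`allow_gu = FALSE`) is.
#' @param backend A function `(seq, min_loop)` returning a compatible
#'   structure list, or `NULL` for the built-in maximizer.
#' @return An object of class `rna_structure`: list with `seq`, `db`
#'   (dot-bracket string), `pairs` (integer vector, 1-based partner or 0) and
#'   `n_pairs`.
#' @export
#' @examples
#' rna_fold("GGGAAAACCC")$db  # "(((....)))"
rna_fold <- function(seq, min_loop = 3L, allow_gu = TRUE, backend = NULL) {
  seq <- as_rna(seq)
  check_rna_alphabet(seq)
  if (!is.null(backend)) {
    res <- backend(seq, min_loop)
  } else {
    res <- .nussinov_fold(seq, as.integer(min_loop), isTRUE(allow_gu))
  }
  structure(list(seq = seq, db = res$db, pairs = as.integer(res$pairs),
                 n_pairs = res$n_pairs),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$db, "  (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

# internal: hairpin (terminal) loops of a structure: pairs (a,b) enclosing no
# other pair; returns data.frame(a, b, size) with interior size b-a-1,
# ordered 5' to 3'
hairpin_loops <- function(st) {
  p <- st$pairs
  opens <- which(p > seq_along(p))
  if (!length(opens)) {
    return(data.frame(a = integer(), b = integer(), size = integer()))
  }
  res <- lapply(as.integer(opens), function(a) {
    b <- p[a]
    inner <- if (b - a > 1L) p[(a + 1L):(b - 1L)] else integer()
    if (!any(inner > 0L)) data.frame(a = a, b = b, size = b - a - 1L) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(a = integer(), b = integer(), size = integer()) else out
}

#' Detect an inverted repeat within a sequence
#'
#' Scans for two complementary arms of at least `min_stem` nt separated by at
#' most `max_loop` nt (strict Watson-Crick complementarity in RNA space),
#' the hallmark of fold-back/palindromic repeats.
#'
#' @param seq RNA sequence.
#' @param min_stem Minimum arm length (default 8).
#' @param max_loop Maximum spacer between the arms (default 8).
#' @return A list with `found` (logical) and, when found, `span` — the
#'   1-based (start, end) of the leftmost, longest-armed occurrence.
#' @export
detect_inverted_repeat <- function(seq, min_stem = 8L, max_loop = 8L) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- c(A = "U", U = "A", G = "C", C = "G", N = " ")
  best <- NULL
  # arm1 = [i, i+L-1], arm2 = [j, j+L-1], arm2 reverse-complements arm1
  for (L in rev(seq_len(max(0L, n %/% 2L)))) {
    if (L < min_stem) break
    for (i in seq_len(n - 2L * L + 1L)) {
      jmax <- min(n - L + 1L, i + L + max_loop)
      for (j in (i + L):jmax) {
        ok <- all(ch[i:(i + L - 1L)] == comp[ch[(j + L - 1L):j]])
        if (ok) {
          best <- c(i, j + L - 1L)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) list(found = FALSE, span = NULL)
  else list(found = TRUE, span = best)
}

#' Detect a tandem repeat within a sequence
#'
#' True iff some unit of at least `min_unit` nt occurs at least `min_copies`
#' times consecutively.
#'
#' @param seq RNA sequence.
#' @param min_unit Minimum repeat-unit length (default 3, must be >= 2).
#' @param min_copies Minimum consecutive copies (default 3, must be >= 2).
#' @return A list with `found` (logical) and, when found, `unit` and `start`
#'   (leftmost occurrence of the shortest qualifying unit).
#' @export
detect_tandem_repeat <- function(seq, min_unit = 3L, min_copies = 3L) {
  if (min_unit < 2L || min_copies < 2L) stop("min_unit and min_copies must be >= 2")
  seq <- as_rna(seq)
  n <- nchar(seq)
  for (u in min_unit:max(min_unit, n %/% min_copies)) {
    if (u * min_copies > n) break
    for (i in seq_len(n - u * min_copies + 1L)) {
      unit <- substr(seq, i, i + u - 1L)
      ok <- TRUE
      for (k in seq_len(min_copies - 1L)) {
        if (substr(seq, i + k * u, i + (k + 1L) * u - 1L) != unit) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(list(found = TRUE, unit = unit, start = i))
    }
  }
  list(found = FALSE, unit = NULL, start = NULL)
}
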