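#' Nucleotide alphabet helpers
#'
#' The package stores sequences internally as uppercase RNA (`U`, never `T`);
#' readers normalize on input and writers emit DNA letters where a format
#' conventionally carries them (FASTA/FASTQ/GFF3). `rna_revcomp()` is the
#' reverse complement in RNA space.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' as_rna("ACGTt")      # "ACGUU"
#' rna_revcomp("ACGU")  # "ACGU"
as_rna <- function(x) {
  chartr("acgtun", "ACGUUN", chartr("T", "U", toupper(x)))
}

#' @rdname as_rna
#' @export
as_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

#' @rdname as_rna
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", as_rna(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# internal: check alphabet, error on violations
check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U,N}: e.g. %s",
                 what, x[which(bad)[1L]]))
  }
  invisible(x)
}
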