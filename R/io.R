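#' Read small RNA sequences from FASTA or FASTQ
#'
#' Parses a FASTA or (4-line record) FASTQ file into a data frame of reads.
#' Sequences are normalized to the package's internal RNA alphabet
#' (`T` becomes `U`, case folded to upper). FASTQ records are structurally
#' validated first — a record whose quality string length differs from its
#' sequence length is a parse error reported with its line number.
#'
#' @param path Path to the sequence file.
#' @param format Either `"fasta"` or `"fastq"`. Defaults to a guess from the
#'   file extension (`.fa/.fasta` vs `.fq/.fastq`).
#' @return A data frame with columns `read_id`, `seq` (RNA alphabet) and,
#'   for FASTQ, `qual`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGGA"), fa)
#' read_sequences(fa)
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    out <- data.frame(read_id = names(set),
                      seq = as_rna(as.character(set)),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    n <- length(lines)
    if (n == 0L) {
      return(data.frame(read_id = character(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE))
    }
    if (n %% 4L != 0L) {
      stop(sprintf("truncated FASTQ record at line %d in %s", (n %/% 4L) * 4L + 1L, path))
    }
    hdr <- lines[seq(1L, n, by = 4L)]
    sq <- lines[seq(2L, n, by = 4L)]
    plus <- lines[seq(3L, n, by = 4L)]
    qual <- lines[seq(4L, n, by = 4L)]
    bad_hdr <- !startsWith(hdr, "@")
    if (any(bad_hdr)) {
      stop(sprintf("malformed FASTQ header at line %d in %s",
                   (which(bad_hdr)[1L] - 1L) * 4L + 1L, path))
    }
    bad_plus <- !startsWith(plus, "+")
    if (any(bad_plus)) {
      stop(sprintf("malformed FASTQ separator at line %d in %s",
                   (which(bad_plus)[1L] - 1L) * 4L + 3L, path))
    }
    bad_q <- nchar(qual) != nchar(sq)
    if (any(bad_q)) {
      stop(sprintf("quality length differs from sequence length at line %d in %s",
                   (which(bad_q)[1L] - 1L) * 4L + 4L, path))
    }
    out <- data.frame(read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
                      seq = as_rna(sq), qual = qual,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (nrow(out)) check_rna_alphabet(out$seq, "read sequence")
  out
}

#' Packaged fixture tables from the silkworm developmental study
#'
#' Returns one of the three published summary tables shipped with the package
#' as tab-separated fixtures: `"T1"` — per-library category read counts of the
#' four stage libraries; `"T2"` — the 14 novel silkworm miRNAs with per-stage
#' miR and miR* read counts; `"T3"` — TPM-normalized per-stage miR and miR*
#' values for the conserved miRNAs. Values are stored exactly as printed.
#'
#' @param table_id One of `"T1"`, `"T2"`, `"T3"`.
#' @return A data frame; numeric count columns, character label columns.
#' @export
#' @examples
#' t1 <- load_fixture("T1")
#' t1[t1$category == "Total", "feeding_larva"]
load_fixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1L ||
      !table_id %in% c("T1", "T2", "T3")) {
    stop("unknown table_id (expected \"T1\", \"T2\" or \"T3\")")
  }
  fname <- c(T1 = "table1_library_categories.tsv",
             T2 = "table2_novel_mirnas.tsv",
             T3 = "table3_conserved_tpm.tsv")[[table_id]]
  path <- system.file("extdata", fname, package = "mirstage", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write and read collapsed unique-tag tables
#'
#' A unique-tag table has one row per distinct 18-30 nt sequence with its
#' per-stage read counts and their total. The TSV round-trips exactly.
#'
#' @param tags Data frame with columns `seq` and the four stage labels
#'   (integer counts); a `total` column is recomputed on write.
#' @param path Output/input TSV path.
#' @return `read_tag_table` returns the tag data frame; `write_tag_table`
#'   returns `path` invisibly.
#' @export
write_tag_table <- function(tags, path) {
  stages <- stage_labels()
  stopifnot(all(c("seq", stages) %in% names(tags)))
  out <- tags[, c("seq", stages)]
  out$total <- as.integer(rowSums(out[, stages, drop = FALSE]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stages <- stage_labels()
  stopifnot(all(c("seq", stages) %in% names(tab)))
  for (s in c(stages, intersect("total", names(tab)))) tab[[s]] <- as.integer(tab[[s]])
  tab
}

#' Write miRNA locus annotations as GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per locus and child `miRNA`
#' features for the mature and (when present) star spans, with 1-based
#' inclusive coordinates on the locus strand. Input coordinates follow the
#' package's internal 0-based half-open convention.
#'
#' @param loci Data frame with columns `name`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `mature_start`, `mature_end`, and
#'   optionally `star_start`, `star_end` (NA when absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_annotations <- function(loci, path) {
  needed <- c("name", "contig", "start", "end", "strand", "mature_start", "mature_end")
  if (nrow(loci) && !all(needed %in% names(loci))) {
    stop("loci lack required coordinate columns: ",
         paste(setdiff(needed, names(loci)), collapse = ", "))
  }
  if (nrow(loci) && any(is.na(loci$contig) | is.na(loci$start) | is.na(loci$end))) {
    stop("locus without genomic coordinates cannot be written")
  }
  lines <- "##gff-version 3"
  gff_line <- function(contig, type, start0, end0, strand, attrs) {
    sprintf("%s\tmirstage\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, type, start0 + 1L, end0, strand, attrs)
  }
  if (nrow(loci)) {
    for (i in seq_len(nrow(loci))) {
      l <- loci[i, ]
      id <- l$name
      lines <- c(lines,
                 gff_line(l$contig, "miRNA_primary_transcript", l$start, l$end,
                          l$strand, sprintf("ID=%s;Name=%s", id, id)),
                 gff_line(l$contig, "miRNA", l$mature_start, l$mature_end, l$strand,
                          sprintf("ID=%s_mature;Name=%s;Parent=%s", id, id, id)))
      if (!is.null(l$star_start) && !is.na(l$star_start)) {
        lines <- c(lines,
                   gff_line(l$contig, "miRNA", l$star_start, l$star_end, l$strand,
                            sprintf("ID=%s_star;Name=%s*;Parent=%s", id, id, id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# internal: FASTA writer for generated references/genomes (DNA letters out)
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(as_dna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# internal: FASTQ writer for generated libraries (DNA letters, flat quality)
write_fastq <- function(ids, seqs, path) {
  if (length(ids) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), as_dna(seqs), "+", qual)), path)
  invisible(path)
}
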