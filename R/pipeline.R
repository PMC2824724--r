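default_thresholds <- function() {
  list(min_anchor = 11L, min_len = 18L, max_len = 30L,
       max_edits = 2L, max_shift = 3L, multimap_cap = 100L,
       structural_repeat_screen = FALSE,
       min_count = 5L, mature_len_min = 18L, mature_len_max = 25L,
       star_tolerance = 2L, coverage_threshold = 0.5,
       paired_fraction_min = 0.6, loop_max = 30L)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with paths to
#' the genome, the four reference sets and the read files, the barcode map,
#' the adapter, an output directory, and optional threshold overrides. Every
#' gap-filling threshold of the pipeline is a named key here so the operative
#' defaults are auditable. Unknown keys are rejected.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated, default-completed config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  required <- c("genome", "refs", "reads", "barcodes", "adapter", "out_dir")
  optional <- c("thresholds", "flanks")
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing)) stop("missing config key(s): ", paste(missing, collapse = ", "))
  ref_names <- c("ncRNA", "repeat", "mRNA", "known_miRNA")
  if (!all(ref_names %in% names(config$refs))) {
    stop("config$refs must name all of: ", paste(ref_names, collapse = ", "))
  }
  for (p in c(config$genome, unlist(config$refs), unlist(config$reads))) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  config$barcodes <- as_stage_vector(unlist(config$barcodes), "barcodes")
  thr <- default_thresholds()
  over <- config$thresholds
  bad <- setdiff(names(over), names(thr))
  if (length(bad)) stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  thr[names(over)] <- over
  config$thresholds <- thr
  if (is.null(config$flanks)) {
    config$flanks <- list(c(20L, 150L), c(150L, 20L), c(70L, 70L))
  }
  config
}

# internal: named vector from a FASTA file
read_named_fasta <- function(path) {
  d <- read_sequences(path, "fasta")
  setNames(d$seq, d$read_id)
}

#' Run the full small RNA analysis pipeline
#'
#' Demultiplex, trim, length-filter, collapse, annotate, discover and
#' profile. Writes to the configured output directory: per-stage category
#' counts (library-summary shape), the novel-locus table, the conserved +
#' novel expression matrix with TPM, family, antisense and rejected-locus
#' reports, size histograms, the collapsed tag table, and a run summary.
#' Conservation invariants (no read is lost or duplicated between stages)
#' are asserted at every step; violation is an error.
#'
#' @param config Config list or YAML path (see [read_pipeline_config()]).
#' @return A list with every intermediate and report, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  thr <- cfg$thresholds
  stages <- stage_labels()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_named_fasta(cfg$genome)
  refs <- lapply(cfg$refs, read_named_fasta)

  reads <- do.call(rbind, lapply(unlist(cfg$reads), read_sequences))
  log <- list(n_input = nrow(reads))

  dm <- demultiplex(reads, cfg$barcodes)
  log$n_assigned <- nrow(dm$assigned)
  log$n_unassigned <- nrow(dm$unassigned)
  stopifnot(log$n_assigned + log$n_unassigned == log$n_input)

  tr <- trim_adapter(dm$assigned$seq, cfg$adapter, thr$min_anchor)
  keep <- !tr$rejected
  log$n_adapter_rejected <- sum(tr$rejected)
  trimmed <- data.frame(stage = dm$assigned$stage[keep],
                        seq = tr$insert[keep], stringsAsFactors = FALSE)
  stopifnot(nrow(trimmed) + log$n_adapter_rejected == log$n_assigned)

  lf <- length_filter(trimmed, thr$min_len, thr$max_len)
  log$n_length_removed <- lf$n_removed
  filtered <- lf$kept
  stopifnot(nrow(filtered) + lf$n_removed == nrow(trimmed))

  # barcode-less tally after length filtering as well (the published ~300k
  # figure does not state its stage, so both tallies are reported)
  un_tr <- trim_adapter(dm$unassigned$seq, cfg$adapter, thr$min_anchor)
  un_len <- nchar(un_tr$insert[!un_tr$rejected]) - nchar(cfg$barcodes[[1L]])
  log$n_unassigned_in_range <- sum(un_len >= thr$min_len & un_len <= thr$max_len,
                                   na.rm = TRUE)

  tags <- collapse_unique(filtered$stage, filtered$seq)
  stage_totals <- setNames(vapply(stages, function(s) sum(tags[[s]]), numeric(1)), stages)
  stopifnot(sum(stage_totals) == nrow(filtered))

  hist_total <- size_distribution(tags, "total", thr$min_len, thr$max_len)
  hist_unique <- size_distribution(tags, "unique", thr$min_len, thr$max_len)
  stopifnot(all(colSums(hist_total) == stage_totals))

  gidx <- build_index(genome)
  casc <- annotate_cascade(tags, refs, gidx,
                           max_edits = thr$max_edits, max_shift = thr$max_shift,
                           multimap_cap = thr$multimap_cap,
                           structural_repeat_screen = thr$structural_repeat_screen)
  stopifnot(all(casc$category_counts["Total", ] == stage_totals))

  # conserved loci: genomic windows for star counting and discovery exclusion
  cons <- conserved_profiles(tags, casc$assignments, refs$known_miRNA,
                             genome, gidx, thr, cfg$flanks)

  disc <- discover_loci(tags, casc$assignments, genome, gidx,
                        min_count = thr$min_count,
                        mature_len_range = thr$mature_len_min:thr$mature_len_max,
                        star_tolerance = thr$star_tolerance,
                        coverage_threshold = thr$coverage_threshold,
                        paired_fraction_min = thr$paired_fraction_min,
                        loop_max = thr$loop_max, flanks = cfg$flanks,
                        exclude_windows = cons$windows)

  anti <- detect_antisense(cons$loci[!is.na(cons$loci$window_seq), , drop = FALSE],
                           tags, gidx,
                           paired_fraction_min = thr$paired_fraction_min,
                           loop_max = thr$loop_max)

  expr <- expression_report(cons, disc, stage_totals)

  mirna_counts <- setNames(vapply(stages, function(s) {
    sum(expr$counts[, s])
  }, numeric(1)), stages)
  frac <- mirna_fraction(mirna_counts, stage_totals)

  out <- list(log = log, tags = tags, stage_totals = stage_totals,
              hist_total = hist_total, hist_unique = hist_unique,
              category_counts = casc$category_counts,
              assignments = casc$assignments,
              conserved = cons, discovery = disc, antisense = anti,
              expression = expr, mirna_fraction = frac)

  # reports
  write_tag_table(tags, file.path(cfg$out_dir, "tags.tsv"))
  write.table(data.frame(category = rownames(casc$category_counts),
                         casc$category_counts, check.names = FALSE),
              file.path(cfg$out_dir, "category_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (h in c("total", "unique")) {
    write.table(data.frame(length = rownames(hist_total),
                           if (h == "total") hist_total else hist_unique,
                           check.names = FALSE),
                file.path(cfg$out_dir, paste0("size_hist_", h, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(disc$loci)) {
    novel <- disc$loci[disc$loci$status %in%
                         c("novel_confirmed", "novel_family_rescued"), , drop = FALSE]
    write.table(novel, file.path(cfg$out_dir, "novel_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(disc$loci[disc$loci$status == "rejected_sirna", , drop = FALSE],
                file.path(cfg$out_dir, "rejected_sirna.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(disc$families, file.path(cfg$out_dir, "families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gff_loci <- novel
    if (nrow(gff_loci)) {
      gff_loci$mature_start <- gff_loci$start
      gff_loci$mature_end <- gff_loci$end
      write_locus_annotations(
        data.frame(name = gff_loci$name, contig = gff_loci$contig,
                   start = gff_loci$start, end = gff_loci$end,
                   strand = gff_loci$strand,
                   mature_start = gff_loci$mature_start,
                   mature_end = gff_loci$mature_end,
                   stringsAsFactors = FALSE),
        file.path(cfg$out_dir, "novel_loci.gff3"))
    }
  }
  write.table(anti, file.path(cfg$out_dir, "antisense.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$table, file.path(cfg$out_dir, "expression_tpm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- c(sprintf("input_reads\t%d", log$n_input),
               sprintf("assigned\t%d", log$n_assigned),
               sprintf("unassigned\t%d", log$n_unassigned),
               sprintf("unassigned_in_length_range\t%d", log$n_unassigned_in_range),
               sprintf("adapter_rejected\t%d", log$n_adapter_rejected),
               sprintf("length_removed\t%d", log$n_length_removed),
               sprintf("%s_total\t%d", stages, as.integer(stage_totals)),
               sprintf("%s_mirna_pct\t%.2f", stages, frac))
  writeLines(summary, file.path(cfg$out_dir, "run_summary.tsv"))
  invisible(out)
}

# internal: conserved miRNA read counts (by cascade evidence), genomic
# windows (best hairpin around each uniquely mapping catalog mature) and
# span-based star counts
conserved_profiles <- function(tags, assignments, catalog, genome, gidx,
                               thr, flanks) {
  stages <- stage_labels()
  is_cons <- assignments$category == "conserved_miRNA"
  counts <- matrix(0, nrow = length(catalog), ncol = 4L,
                   dimnames = list(names(catalog), stages))
  for (s in stages) {
    agg <- tapply(tags[[s]][is_cons], assignments$evidence[is_cons], sum)
    hit <- intersect(names(agg), rownames(counts))
    counts[hit, s] <- agg[hit]
  }
  star_counts <- counts * 0
  windows <- list()
  loci <- data.frame(name = names(catalog), contig = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     strand = NA_character_, mature = unname(as_rna(catalog)),
                     window_seq = NA_character_, stringsAsFactors = FALSE)
  if (length(catalog)) {
    hits <- genome_hits(gidx, as_rna(catalog))
    for (i in seq_along(catalog)) {
      h <- hits[hits$tag == as_rna(catalog[[i]]), , drop = FALSE]
      if (nrow(h) != 1L) next
      cand <- best_hairpin(genome, h[1L, ], flanks,
                           thr$paired_fraction_min, thr$loop_max)
      if (is.null(cand)) next
      loci$contig[i] <- cand$contig
      loci$start[i] <- cand$start
      loci$end[i] <- cand$end
      loci$strand[i] <- cand$strand
      loci$window_seq[i] <- cand$seq
      windows[[length(windows) + 1L]] <- list(contig = cand$contig,
                                              start = cand$start, end = cand$end)
      star <- tryCatch(infer_star(cand), error = function(e) NULL)
      if (!is.null(star)) {
        sc <- span_tag_counts(cand$seq, star$start, star$end, tags,
                              thr$star_tolerance)
        star_counts[i, ] <- sc$counts
      }
    }
  }
  list(loci = loci, counts = counts, star_counts = star_counts,
       windows = windows)
}

# internal: merged conserved + novel expression table with TPM and derived
# statistics
expression_report <- function(cons, disc, stage_totals) {
  stages <- stage_labels()
  rows <- list()
  cnt <- function(name, type, mir, star) {
    r <- data.frame(name = name, type = type, stringsAsFactors = FALSE)
    for (s in stages) r[[paste0(s, "_miR")]] <- mir[[s]]
    for (s in stages) r[[paste0(s, "_miR_star")]] <- star[[s]]
    r
  }
  for (i in seq_len(nrow(cons$loci))) {
    rows[[length(rows) + 1L]] <- cnt(cons$loci$name[i], "conserved",
                                     cons$counts[i, ], cons$star_counts[i, ])
  }
  if (!is.null(disc$loci)) {
    nv <- disc$loci[disc$loci$status %in%
                      c("novel_confirmed", "novel_family_rescued"), , drop = FALSE]
    for (i in seq_len(nrow(nv))) {
      rows[[length(rows) + 1L]] <- cnt(
        nv$name[i], "novel",
        setNames(as.numeric(nv[i, paste0(stages, "_miR")]), stages),
        setNames(as.numeric(nv[i, paste0(stages, "_miR_star")]), stages))
    }
  }
  counts <- do.call(rbind, rows)
  mir_cols <- paste0(stages, "_miR")
  star_cols <- paste0(stages, "_miR_star")
  cm <- as.matrix(counts[, mir_cols]); colnames(cm) <- stages
  sm <- as.matrix(counts[, star_cols]); colnames(sm) <- stages
  rownames(cm) <- rownames(sm) <- counts$name
  tpm <- tpm_normalize(cm, stage_totals)
  tpm_star <- tpm_normalize(sm, stage_totals)
  tab <- counts
  for (s in stages) {
    tab[[paste0(s, "_miR_tpm")]] <- round(tpm[, s], 2)
    tab[[paste0(s, "_miR_star_tpm")]] <- round(tpm_star[, s], 2)
  }
  tab$temporal_class <- apply(cm, 1L, function(v) classify_temporal(setNames(v, stages)))
  tab$star_ratio <- vapply(seq_len(nrow(tab)), function(i) {
    star_ratio(setNames(cm[i, ], stages), setNames(sm[i, ], stages))$ratio
  }, numeric(1))
  tab$star_dominant <- rowSums(sm) > rowSums(cm)
  list(counts = cm, star = sm, tpm = tpm, tpm_star = tpm_star, table = tab)
}
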