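#' Simulation configuration
#'
#' Default study conditions for the synthetic four-stage small RNA dataset:
#' a 20 kb genome at silkworm-like 37.5% GC; 10 planted novel miRNA loci
#' including one seed-sharing family of three; 12 conserved catalog loci (one
#' star-dominant, mirroring the published star-dominant miRNAs); 2 antisense
#' pairs carrying 8 and 1 uniquely-mapping antisense reads (the published
#' antisense evidence counts); 3 siRNA-like inverted-repeat decoys; ncRNA /
#' repeat / mRNA contamination references; four libraries sized
#' proportionally to the published stage libraries and totalling 4e5 reads;
#' log-normal per-locus per-stage abundances (sigma 1.5, reproducing the
#' heavy-tailed shares in which the top miRNA takes 18-40% of miRNA reads);
#' miR*:miR sampling ratio 0.1; terminal-trim length noise; 50% piRNA-like
#' 26-29 nt background; 4-nt stage barcodes and a 3' adapter with ~10%
#' barcode-corrupted (unassignable) reads.
#'
#' @param seed Integer random seed.
#' @param ... Named overrides of any default listed above.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = 20000L,
    gc = 0.375,
    n_novel = 10L,
    novel_family_size = 3L,
    n_conserved = 12L,
    n_star_dominant = 1L,
    star_dominant_ratio = 3,
    n_antisense = 2L,
    antisense_reads = c(8L, 1L),
    n_sirna = 3L,
    n_ncrna_refs = 5L,
    n_repeat_refs = 3L,
    n_mrna_refs = 5L,
    library_sizes = setNames(
      as.integer(round(4e5 * c(1147753, 599279, 289303, 463800) / 2500135)),
      stage_labels()),
    class_fractions = c(pirna = 0.50, ncRNA = 0.15, repeat_ = 0.05,
                        mRNA = 0.05, miRNA = 0.25),
    sigma = 1.5,
    star_ratio = 0.1,
    trim_probs = c(none = 0.8, trim1 = 0.15, trim2 = 0.05),
    barcodes = setNames(c("ACAU", "CGUA", "GUAC", "UACG"), stage_labels()),
    adapter = "UCGUAUGCCGUCUUCUGCUUG",
    min_anchor = 11L,
    read_length = 46L,
    unassigned_frac = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(unlist(cfg$library_sizes) >= 0),
            cfg$unassigned_frac >= 0, cfg$unassigned_frac <= 1,
            abs(sum(cfg$class_fractions) - 1) < 1e-9,
            cfg$n_antisense <= cfg$n_conserved,
            length(cfg$antisense_reads) >= cfg$n_antisense)
  structure(cfg, class = "sim_config")
}

# internal: random RNA string at the configured GC
random_rna <- function(n, gc = 0.375) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# internal: build one planted precursor.
# Layout: pad | mature_arm | loop | partner_arm | pad, where the mature sits
# inside the requested arm and the partner arm is its reverse complement with
# >= 2 forced mismatches in the segment pairing with the mature interior (so
# neither the mature nor its star maps to both strands of its own hairpin)
# plus up to `n_extra_bulge` mismatches elsewhere in the stem. Mismatch
# positions avoid the partners of the mature termini, keeping the 2-nt
# 3' overhang geometry well defined.
build_precursor <- function(mature_len = 22L, arm = "5p", stem = 40L,
                            seed7 = NULL, gc = 0.375, n_extra_bulge = 2L) {
  loop_len <- sample(8:12, 1L)
  pad <- 4L
  mature <- random_rna(mature_len, gc)
  if (!is.null(seed7)) {
    mature <- paste0(substr(mature, 1L, 1L), seed7, substr(mature, 9L, mature_len))
  }
  offset <- sample(3:(stem - mature_len - 2L), 1L)  # mature offset within its arm
  host_arm <- paste0(random_rna(offset - 1L, gc), mature,
                     random_rna(stem - offset - mature_len + 1L, gc))
  partner_arm <- rna_revcomp(host_arm)
  # partner_arm position pairing with host position k is stem - k + 1
  mature_idx <- offset:(offset + mature_len - 1L)
  interior <- mature_idx[5:(mature_len - 5L)]  # keep termini partners paired
  mm <- sort(sample(interior, 2L))
  outside <- setdiff(seq_len(stem), (min(mature_idx) - 3L):(max(mature_idx) + 3L))
  if (length(outside) && n_extra_bulge > 0L) {
    mm <- c(mm, sample(outside, min(n_extra_bulge, length(outside))))
  }
  pa <- strsplit(partner_arm, "", fixed = TRUE)[[1L]]
  for (k in mm) {
    pos <- stem - k + 1L
    base <- substr(host_arm, k, k)
    partner <- chartr("ACGU", "UGCA", base)
    pa[pos] <- sample(setdiff(c("A", "C", "G", "U"),
                              c(partner, if (base == "G") "U",
                                if (base == "U") "G")), 1L)
  }
  partner_arm <- paste(pa, collapse = "")
  if (arm == "5p") {
    precursor <- paste0(random_rna(pad, gc), host_arm, random_rna(loop_len, gc),
                        partner_arm, random_rna(pad, gc))
    m_start <- pad + offset
  } else {
    # host arm (carrying the mature) goes 3' of the loop; its partner, with
    # the mismatches, forms the 5' arm. Host-arm position k sits at
    # pad + stem + loop + k.
    precursor <- paste0(random_rna(pad, gc), partner_arm, random_rna(loop_len, gc),
                        host_arm, random_rna(pad, gc))
    m_start <- pad + stem + loop_len + offset
  }
  list(seq = precursor, mature = mature, mature_start = m_start,
       mature_len = mature_len)
}

#' Generate a synthetic genome with planted loci and references
#'
#' Plants novel, conserved, antisense-capable and siRNA-decoy loci in a
#' random genome and writes decoy ncRNA/repeat/mRNA references alongside.
#' Every planted miRNA precursor is verified by construction with the
#' package's own hairpin machinery: the excised window qualifies under the
#' default thresholds, the mature maps uniquely, and the recorded star is the
#' one 2-nt 3' overhang geometry infers. Loci failing any check are redrawn.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `genome` (named character), `refs` (list of
#'   named reference vectors: ncRNA, repeat, mRNA, known_miRNA), `loci`
#'   (data frame manifest), `weights` (locus x stage abundance weights),
#'   `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  glen <- config$genome_length
  n_loci <- config$n_novel + config$n_conserved + config$n_sirna
  if (glen < n_loci * 400L) stop("genome too short for requested plantings")
  genome_chars <- strsplit(random_rna(glen, config$gc), "", fixed = TRUE)[[1L]]

  slot_width <- 260L
  gap <- (glen - n_loci * slot_width) %/% (n_loci + 1L)
  slot_starts <- gap + (seq_len(n_loci) - 1L) * (slot_width + gap)  # 0-based

  fam_seed <- substr(random_rna(7L, config$gc), 1L, 7L)
  loci <- list()
  catalog <- character()
  li <- 0L

  plant <- function(genome_chars, slot0, type, arm, seed7, star_ratio) {
    # returns list(genome_chars, row) after self-verification, retrying draws
    for (attempt in 1:60) {
      mature_len <- sample(21:22, 1L)
      pc <- build_precursor(mature_len = mature_len, arm = arm,
                            seed7 = seed7, gc = config$gc)
      plen <- nchar(pc$seq)
      p0 <- slot0 + sample.int(slot_width - plen, 1L) - 1L
      gc2 <- genome_chars
      gc2[(p0 + 1L):(p0 + plen)] <- strsplit(pc$seq, "", fixed = TRUE)[[1L]]
      genome2 <- paste(gc2, collapse = "")
      idx <- build_index(c(chr1 = genome2))
      hits <- genome_hits(idx, pc$mature)
      if (nrow(hits) != 1L || hits$strand != "+") next
      cand <- best_hairpin(c(chr1 = genome2), hits[1L, ])
      if (is.null(cand)) next
      star <- infer_star(cand)
      # a sound miR:miR* duplex leaves the star within a few nt of the
      # mature's length; anything else is a degenerate fold
      if (star$clipped || nchar(star$seq) < 18L ||
          nchar(star$seq) > mature_len + 4L) next
      if (nrow(genome_hits(idx, star$seq)) != 1L) next
      # sequence-space margin: the mature, its star and its antisense read
      # must stay clearly outside the conserved-matching tolerance of every
      # catalog mature (and of each other), so trimmed variants cannot drift
      # into a spurious conserved assignment
      probes <- c(pc$mature, star$seq, rna_revcomp(pc$mature))
      pool <- catalog
      if (type == "conserved") pool <- c(pool, pc$mature)
      dmat <- adist(probes, pool)
      if (type == "conserved") dmat[1L, length(pool)] <- 99L  # mature vs itself
      if (length(pool) && any(dmat <= 4L)) next
      arm_obs <- tryCatch(arm_of(cand), error = function(e) NA_character_)
      if (is.na(arm_obs)) next
      row <- data.frame(
        name = NA_character_, type = type, contig = "chr1",
        start = cand$start, end = cand$end, strand = "+",
        mature = pc$mature, star = star$seq, arm = arm_obs,
        star_ratio = star_ratio, window_seq = cand$seq,
        stringsAsFactors = FALSE)
      return(list(genome_chars = gc2, row = row))
    }
    stop("failed to plant a qualifying locus after 60 attempts")
  }

  add_locus <- function(res, name) {
    li <<- li + 1L
    res$row$name <- name
    loci[[li]] <<- res$row
    genome_chars <<- res$genome_chars
  }

  # novel loci: one seed-sharing family, rest singletons
  fam_n <- min(config$novel_family_size, config$n_novel)
  fam_arms <- if (fam_n >= 3L) c(rep("3p", fam_n - 1L), "5p") else rep("3p", fam_n)
  for (i in seq_len(config$n_novel)) {
    in_fam <- i <= fam_n
    res <- plant(genome_chars, slot_starts[li + 1L], "novel",
                 arm = if (in_fam) fam_arms[i] else sample(c("5p", "3p"), 1L),
                 seed7 = if (in_fam) fam_seed else NULL,
                 star_ratio = config$star_ratio)
    add_locus(res, sprintf("novel-true-%d", i))
  }
  # conserved loci (first n_antisense also serve as antisense pairs,
  # first n_star_dominant are star-dominant)
  for (i in seq_len(config$n_conserved)) {
    ratio <- if (i <= config$n_star_dominant) config$star_dominant_ratio else config$star_ratio
    res <- plant(genome_chars, slot_starts[li + 1L], "conserved",
                 arm = sample(c("5p", "3p"), 1L), seed7 = NULL,
                 star_ratio = ratio)
    add_locus(res, sprintf("cons-%d", i))
    catalog[sprintf("cons-%d", i)] <- res$row$mature
  }
  # siRNA decoys: long near-perfect inverted repeats
  for (i in seq_len(config$n_sirna)) {
    res <- plant(genome_chars, slot_starts[li + 1L], "sirna",
                 arm = "5p", seed7 = NULL, star_ratio = config$star_ratio)
    add_locus(res, sprintf("sirna-%d", i))
  }

  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(name = character(), type = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               mature = character(), star = character(), arm = character(),
               star_ratio = numeric(), window_seq = character(),
               stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  genome <- c(chr1 = paste(genome_chars, collapse = ""))

  # final global verification pass on the assembled genome
  if (nrow(loci)) {
    idx <- build_index(genome)
    nh <- table(factor(genome_hits(idx, loci$mature)$tag, levels = loci$mature))
    if (any(as.integer(nh) != 1L)) stop("planted mature lost uniqueness in final genome")
  }

  refs <- list(
    ncRNA = setNames(vapply(seq_len(config$n_ncrna_refs),
                            function(i) random_rna(120L, config$gc), character(1)),
                     paste0("ncRNA-", seq_len(config$n_ncrna_refs))),
    "repeat" = setNames(vapply(seq_len(config$n_repeat_refs),
                               function(i) random_rna(200L, config$gc), character(1)),
                        paste0("repeat-", seq_len(config$n_repeat_refs))),
    mRNA = setNames(vapply(seq_len(config$n_mrna_refs),
                           function(i) random_rna(400L, config$gc), character(1)),
                    paste0("mRNA-", seq_len(config$n_mrna_refs))),
    known_miRNA = catalog
  )

  # per-locus per-stage abundance weights (log-normal, heavy tail)
  mir_loci <- loci[loci$type %in% c("novel", "conserved"), "name"]
  weights <- matrix(exp(stats::rnorm(length(mir_loci) * 4L, 0, config$sigma)),
                    nrow = length(mir_loci), ncol = 4L,
                    dimnames = list(mir_loci, stage_labels()))

  structure(list(genome = genome, refs = refs, loci = loci,
                 weights = weights, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nchar(x$genome), "nt genome;",
      sum(x$loci$type == "novel"), "novel,",
      sum(x$loci$type == "conserved"), "conserved,",
      sum(x$loci$type == "sirna"), "siRNA loci\n")
  invisible(x)
}

# internal: apply 3' terminal trim noise to insert sequences
apply_trim <- function(seqs, trim_probs) {
  tr <- sample(c(0L, 1L, 2L), length(seqs), replace = TRUE, prob = trim_probs)
  substr(seqs, 1L, nchar(seqs) - tr)
}

#' Generate the four barcoded stage libraries
#'
#' Draws reads per stage from the truth manifest: miRNA loci receive reads
#' multinomially under their log-normal stage weights, split between miR and
#' miR* at each locus's ratio with 3' terminal-trim noise; siRNA decoys
#' contribute phased tags tiling their hairpins; antisense loci contribute
#' their fixed uniquely-mapping read counts; ncRNA/repeat/mRNA contamination
#' is drawn as reference substrings; the piRNA-like background is drawn as
#' 26-29 nt fragments of non-locus genome on either strand. Reads are
#' `barcode + insert + adapter`, truncated to the read length, with a
#' configured fraction given corrupted barcodes.
#'
#' @param truth A `sim_truth` from [generate_genome()].
#' @return A `sim_libraries` list: `reads` (data frame `read_id`, `stage`
#'   — the true stage — `seq`, `provenance`), `expected` (realized per-locus
#'   per-stage miR/miR* read counts), `expected_categories` (realized
#'   category x stage matrix as the annotation cascade should reproduce),
#'   `truth`.
#' @export
generate_libraries <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  if (all(config$library_sizes == 0L)) stop("all library sizes are zero")
  set.seed(config$seed + 1L)
  stages <- stage_labels()
  loci <- truth$loci
  mir <- loci[loci$type %in% c("novel", "conserved"), , drop = FALSE]
  sir <- loci[loci$type == "sirna", , drop = FALSE]

  # phased tag sets tiling each siRNA decoy hairpin; the decoy's uniquely
  # mapping mature-like tag leads the set with extra sampling weight so it
  # seeds a candidate locus that the tiling coverage then disqualifies
  sirna_tags <- lapply(seq_len(nrow(sir)), function(i) {
    w <- sir$window_seq[i]
    starts <- seq(1L, nchar(w) - 22L, by = 5L)
    lens <- 20L + (seq_along(starts) %% 3L)
    c(sir$mature[i], substring(w, starts, pmin(starts + lens - 1L, nchar(w))))
  })

  all_reads <- list()
  exp_cat <- matrix(0, nrow = 6L, ncol = 4L,
                    dimnames = list(c("ncRNA", "repeat", "mRNA",
                                      "conserved_miRNA", "genome_only", "unmapped"),
                                    stages))
  for (si in seq_along(stages)) {
    st <- stages[si]
    n <- config$library_sizes[[st]]
    if (n == 0L) next
    ncat <- as.integer(rmultinom(1L, n, config$class_fractions))
    names(ncat) <- names(config$class_fractions)

    seqs <- character(0); prov <- character(0)

    # piRNA-like background from non-locus genome, both strands
    if (ncat[["pirna"]] > 0L) {
      glen <- nchar(truth$genome[[1L]])
      # positions whose 26-29 nt fragment could touch a planted locus
      bad <- rep(FALSE, glen)
      for (j in seq_len(nrow(loci))) {
        bad[max(1L, loci$start[j] - 29L):min(glen, loci$end[j] + 1L)] <- TRUE
      }
      pos <- integer(0)
      lens_ok <- integer(0)
      while (length(pos) < ncat[["pirna"]]) {
        need <- ncat[["pirna"]] - length(pos)
        cand <- sample.int(glen - 30L, need, replace = TRUE)
        cl <- sample(26:29, need, replace = TRUE)
        keep <- !bad[cand]
        pos <- c(pos, cand[keep]); lens_ok <- c(lens_ok, cl[keep])
      }
      pos <- pos[seq_len(ncat[["pirna"]])]
      lens_ok <- lens_ok[seq_len(ncat[["pirna"]])]
      frag <- substring(truth$genome[[1L]], pos, pos + lens_ok - 1L)
      minus <- runif(length(frag)) < 0.5
      frag[minus] <- rna_revcomp(frag[minus])
      seqs <- c(seqs, frag); prov <- c(prov, rep("pirna", length(frag)))
    }
    # contamination classes
    for (cls in c("ncRNA", "repeat_", "mRNA")) {
      k <- ncat[[cls]]
      if (k == 0L) next
      refset <- truth$refs[[if (cls == "repeat_") "repeat" else cls]]
      ref <- sample(names(refset), k, replace = TRUE)
      lens <- sample(18:30, k, replace = TRUE)
      start <- vapply(seq_len(k), function(j) {
        sample.int(nchar(refset[[ref[j]]]) - lens[j] + 1L, 1L)
      }, integer(1))
      frag <- substring(refset[ref], start, start + lens - 1L)
      seqs <- c(seqs, frag)
      prov <- c(prov, rep(sub("_$", "", cls), k))
    }
    # miRNA loci
    k <- ncat[["miRNA"]]
    locus_n <- if (nrow(mir)) {
      as.integer(rmultinom(1L, k, truth$weights[mir$name, st]))
    } else integer()
    for (j in seq_len(nrow(mir))) {
      nj <- locus_n[j]
      if (nj == 0L) next
      r <- mir$star_ratio[j]
      n_star <- rbinom(1L, nj, r / (1 + r))
      n_mir <- nj - n_star
      ins <- c(apply_trim(rep(mir$mature[j], n_mir), config$trim_probs),
               apply_trim(rep(mir$star[j], n_star), config$trim_probs))
      seqs <- c(seqs, ins)
      prov <- c(prov, rep(paste0(mir$name[j], "|miR"), n_mir),
                rep(paste0(mir$name[j], "|star"), n_star))
    }
    # siRNA decoys: modest uniform weight per decoy
    n_sir_reads <- max(0L, as.integer(round(0.004 * n))) # ~0.4% of the library
    for (j in seq_len(nrow(sir))) {
      tagv <- sirna_tags[[j]]
      reps <- as.integer(rmultinom(1L, n_sir_reads, c(5, rep(1, length(tagv) - 1L))))
      ins <- rep(tagv, reps)
      if (!length(ins)) next
      seqs <- c(seqs, ins)
      prov <- c(prov, rep(paste0(sir$name[j], "|sirna"), length(ins)))
    }
    all_reads[[si]] <- data.frame(stage = st, seq = seqs, provenance = prov,
                                  stringsAsFactors = FALSE)
  }

  reads <- do.call(rbind, all_reads)

  # antisense evidence reads on the first n_antisense conserved loci,
  # allocated across stages by the sense locus's stage weights
  as_idx <- which(loci$type == "conserved")[seq_len(config$n_antisense)]
  for (j in seq_along(as_idx)) {
    l <- loci[as_idx[j], ]
    tagseq <- rna_revcomp(l$mature)
    n_as <- config$antisense_reads[j]
    st_alloc <- as.integer(rmultinom(1L, n_as, truth$weights[l$name, ]))
    for (si in seq_along(stages)) {
      if (st_alloc[si] == 0L) next
      reads <- rbind(reads, data.frame(
        stage = stages[si], seq = rep(tagseq, st_alloc[si]),
        provenance = paste0(l$name, "|antisense"), stringsAsFactors = FALSE))
    }
  }

  # expected cascade categories by provenance
  cat_of <- function(prov) {
    base <- sub("\\|.*$", "", prov)
    ifelse(base %in% c("ncRNA", "repeat", "mRNA"), base,
           ifelse(grepl("^cons-", base) & grepl("\\|miR$", prov),
                  "conserved_miRNA", "genome_only"))
  }
  reads$category <- cat_of(reads$provenance)

  # assemble sequencer reads: barcode + insert + adapter, clipped
  n_all <- nrow(reads)
  barcode <- unname(truth$config$barcodes[reads$stage])
  corrupt <- runif(n_all) < config$unassigned_frac
  if (any(corrupt)) {
    rand_bc <- vapply(seq_len(sum(corrupt)), function(i) random_rna(4L, 0.5), character(1))
    while (any(rand_bc %in% config$barcodes)) {
      bad <- rand_bc %in% config$barcodes
      rand_bc[bad] <- vapply(seq_len(sum(bad)), function(i) random_rna(4L, 0.5), character(1))
    }
    barcode[corrupt] <- rand_bc
  }
  full <- paste0(barcode, reads$seq,
                 strrep(config$adapter, 3L))
  reads$read <- substr(full, 1L, config$read_length)
  reads$assignable <- !corrupt
  reads$read_id <- sprintf("r%07d", seq_len(n_all))

  # ground truth of what the pipeline can recover: only reads whose barcode
  # survived intact are assignable, so expectations count those alone
  ar <- reads[reads$assignable, , drop = FALSE]
  for (st in stages) {
    tb <- table(ar$category[ar$stage == st])
    exp_cat[names(tb), st] <- as.integer(tb)
  }
  has_locus <- grepl("|", ar$provenance, fixed = TRUE)
  lr <- ar[has_locus, , drop = FALSE]
  expected <- data.frame(name = character(), type = character(),
                         stage = character(), mir_reads = integer(),
                         star_reads = integer(), stringsAsFactors = FALSE)
  if (nrow(lr)) {
    base <- sub("\\|.*$", "", lr$provenance)
    kind <- sub("^.*\\|", "", lr$provenance)
    name <- ifelse(kind == "antisense", paste0(base, "-AS"), base)
    type_map <- setNames(loci$type, loci$name)
    long <- data.frame(name = name, stage = lr$stage, kind = kind,
                       stringsAsFactors = FALSE)
    agg <- as.data.frame(table(long$name, long$stage, long$kind),
                         stringsAsFactors = FALSE)
    names(agg) <- c("name", "stage", "kind", "reads")
    wide <- stats::reshape(agg, idvar = c("name", "stage"), timevar = "kind",
                           direction = "wide")
    names(wide) <- sub("^reads\\.", "", names(wide))
    for (cc in c("miR", "star", "sirna", "antisense")) {
      if (is.null(wide[[cc]])) wide[[cc]] <- 0L
      wide[[cc]][is.na(wide[[cc]])] <- 0L
    }
    wide$mir_reads <- wide$miR + wide$sirna + wide$antisense
    wide$star_reads <- wide$star
    bb <- sub("-AS$", "", wide$name)
    wide$type <- ifelse(grepl("-AS$", wide$name), "antisense",
                        unname(type_map[bb]))
    expected <- wide[, c("name", "type", "stage", "mir_reads", "star_reads")]
    expected <- expected[order(expected$name, match(expected$stage, stages)), ]
    rownames(expected) <- NULL
  }

  structure(list(reads = reads, expected = expected,
                 expected_categories = exp_cat, truth = truth),
            class = "sim_libraries")
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `refs/*.fa`, one `lib_<stage>.fastq` per stage (reads
#' carrying their barcodes; corrupted-barcode reads included), and
#' `truth.tsv` (the locus manifest).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `sim_libraries` object, invisibly.
#' @export
simulate_dataset <- function(config, out_dir) {
  truth <- generate_genome(config)
  libs <- generate_libraries(truth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "refs"), showWarnings = FALSE)
  write_fasta(truth$genome, file.path(out_dir, "genome.fa"))
  for (nm in c("ncRNA", "repeat", "mRNA", "known_miRNA")) {
    write_fasta(truth$refs[[nm]], file.path(out_dir, "refs", paste0(nm, ".fa")))
  }
  for (st in stage_labels()) {
    sel <- libs$reads$stage == st
    write_fastq(libs$reads$read_id[sel], libs$reads$read[sel],
                file.path(out_dir, paste0("lib_", st, ".fastq")))
  }
  man <- truth$loci
  man$window_seq <- NULL
  write.table(man, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(libs)
}
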