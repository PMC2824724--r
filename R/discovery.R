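#' Seed of a mature miRNA
#'
#' The seed — mature positions 2-8 (1-based, inclusive), the primary
#' target-recognition determinant — defines family membership here: loci with
#' identical seeds belong to one family.
#'
#' @param mature Character vector of mature sequences (each >= 8 nt).
#' @return Character vector of 7-mers.
#' @export
#' @examples
#' seed_of("UGGAAUGUAAAGAAGUAUGGAG")  # "GGAAUGU"
seed_of <- function(mature) {
  mature <- as_rna(mature)
  if (any(nchar(mature) < 8L)) stop("mature sequence shorter than 8 nt has no seed")
  substr(mature, 2L, 8L)
}

#' Cluster miRNA loci into seed families
#'
#' Partitions loci by identical seed. Families of size 1 are allowed. The
#' returned families are ordered by size (descending), then seed
#' (lexicographic), and the per-locus assignment uses that ordering for
#' family ids.
#'
#' @param names Character vector of locus names.
#' @param mature Character vector of mature sequences (parallel to `names`).
#' @return List with `families` (data frame `family`, `seed`, `size`) and
#'   `assignment` (data frame `name`, `seed`, `family`).
#' @export
cluster_families <- function(names, mature) {
  seeds <- seed_of(mature)
  sizes <- table(seeds)
  ord <- order(-as.integer(sizes), names(sizes))
  fam_ids <- setNames(paste0("fam_", seq_along(ord)), names(sizes)[ord])
  families <- data.frame(family = unname(fam_ids),
                         seed = names(sizes)[ord],
                         size = as.integer(sizes)[ord],
                         stringsAsFactors = FALSE)
  assignment <- data.frame(name = names, seed = seeds,
                           family = unname(fam_ids[seeds]),
                           stringsAsFactors = FALSE)
  list(families = families, assignment = assignment)
}

#' Heuristic candidate flags for miRNA-like tags
#'
#' Reporting-only flags capturing the classic mature-miRNA signature: a 5'
#' uridine and a 20-23 nt length. Never used as a hard filter.
#'
#' @param tags Character vector of tag sequences.
#' @return Data frame `seq`, `starts_with_U`, `length_in_20_23`.
#' @export
candidate_screen <- function(tags) {
  tags <- as_rna(tags)
  data.frame(seq = tags,
             starts_with_U = startsWith(tags, "U"),
             length_in_20_23 = nchar(tags) >= 20L & nchar(tags) <= 23L,
             stringsAsFactors = FALSE)
}

# internal: per-stage read counts of all tags equal to window substrings
# spanning [lo,hi] with each terminus within +/- tol; returns list(counts
# per stage, matched tag sequences)
span_tag_counts <- function(window_seq, lo, hi, tags, tol = 2L) {
  stages <- stage_labels()
  counts <- setNames(numeric(length(stages)), stages)
  n <- nchar(window_seq)
  grid <- expand.grid(a = lo + (-tol:tol), b = hi + (-tol:tol))
  grid <- grid[grid$a >= 1L & grid$b <= n & grid$b >= grid$a, , drop = FALSE]
  probes <- unique(substring(window_seq, grid$a, grid$b))
  idx <- match(probes, tags$seq)
  matched <- probes[!is.na(idx)]
  for (i in idx[!is.na(idx)]) counts <- counts + unlist(tags[i, stages])
  list(counts = counts, tags = matched)
}

#' Confirm a candidate locus by observed miRNA-star reads
#'
#' A locus is `novel_confirmed` iff some sequenced tag matches the predicted
#' star span within `star_tolerance` nt at each terminus; otherwise it stays
#' `candidate_unconfirmed`. Matching tags' per-stage counts are aggregated as
#' the locus's miR* counts.
#'
#' @param cand A folded, qualified `hairpin_candidate`.
#' @param star A star span from [infer_star()].
#' @param tags Collapsed tag table.
#' @param star_tolerance Per-terminus tolerance in nt (default 2).
#' @return List with `status`, `star_counts` (per stage), `star_tags`.
#' @export
confirm_novel <- function(cand, star, tags, star_tolerance = 2L) {
  hit <- span_tag_counts(cand$seq, star$start, star$end, tags, star_tolerance)
  status <- if (length(hit$tags)) "novel_confirmed" else "candidate_unconfirmed"
  list(status = status, star_counts = hit$counts, star_tags = hit$tags)
}

#' Rescue unconfirmed loci through their seed family
#'
#' An unconfirmed locus becomes `novel_family_rescued` iff its seed-identical
#' family contains at least `min_confirmed` loci that are `novel_confirmed` —
#' generalizing the observation that star-less family members sharing a seed
#' with several star-confirmed members are credible miRNA genes.
#'
#' @param status Character vector of locus statuses.
#' @param family Character vector of family ids (parallel to `status`).
#' @param min_confirmed Minimum confirmed members required (default 2).
#' @return Updated status vector.
#' @export
rescue_by_family <- function(status, family, min_confirmed = 2L) {
  conf <- tapply(status == "novel_confirmed", family, sum)
  idx <- which(status == "candidate_unconfirmed" &
                 conf[family] >= min_confirmed)
  status[idx] <- "novel_family_rescued"
  status
}

#' Flag family members with atypical arm placement
#'
#' Within a family the mature's arm is normally conserved; members whose arm
#' differs from the family majority are flagged. A tied family gets no flags.
#'
#' @param arm Character vector of arms (`"5p"`/`"3p"`).
#' @param family Character vector of family ids (parallel to `arm`).
#' @return Logical vector of atypical flags.
#' @export
flag_atypical_arm <- function(arm, family) {
  flags <- rep(FALSE, length(arm))
  for (f in unique(family)) {
    i <- which(family == f & !is.na(arm))
    if (length(i) < 2L) next
    n5 <- sum(arm[i] == "5p"); n3 <- sum(arm[i] == "3p")
    if (n5 == n3) next
    maj <- if (n5 > n3) "5p" else "3p"
    flags[i[arm[i] != maj]] <- TRUE
  }
  flags
}

#' Disqualify siRNA-like loci by read tiling
#'
#' A genuine miRNA precursor yields reads concentrated at the mature and star
#' positions; an siRNA-generating locus yields overlapping reads tiling the
#' whole hairpin. The locus is rejected iff the fraction of precursor
#' positions covered by tags lying outside the mature +/-2 / star +/-2
#' windows exceeds `coverage_threshold`.
#'
#' @param cand A `hairpin_candidate`.
#' @param star Star span from [infer_star()] (or NULL when unknown).
#' @param tags Collapsed tag table (all library tags).
#' @param coverage_threshold Maximum tolerated outside-coverage fraction
#'   (default 0.5).
#' @param tag_len_range Lengths of window substrings looked up in the tag
#'   table (default 18:30).
#' @return List with `rejected` (logical) and `outside_coverage` (fraction).
#' @export
disqualify_sirna <- function(cand, star, tags, coverage_threshold = 0.5,
                             tag_len_range = 18:30) {
  n <- nchar(cand$seq)
  m <- cand$mature_span
  allowed <- list(c(m[1L] - 2L, m[2L] + 2L))
  if (!is.null(star)) allowed <- c(allowed, list(c(star$start - 2L, star$end + 2L)))
  covered <- rep(FALSE, n)
  av <- integer(); bv <- integer()
  for (L in tag_len_range) {
    if (L > n) break
    a <- seq_len(n - L + 1L)
    b <- a + L - 1L
    inside <- rep(FALSE, length(a))
    for (iv in allowed) inside <- inside | (a >= iv[1L] & b <= iv[2L])
    av <- c(av, a[!inside]); bv <- c(bv, b[!inside])
  }
  if (length(av)) {
    present <- substring(cand$seq, av, bv) %in% tags$seq
    for (j in which(present)) covered[av[j]:bv[j]] <- TRUE
  }
  frac <- mean(covered)
  list(rejected = frac > coverage_threshold, outside_coverage = frac)
}

#' Detect antisense miRNA loci for known sense loci
#'
#' For each sense locus, folds the antisense strand of its precursor window
#' and reports an antisense locus iff the antisense hairpin qualifies and at
#' least one tag maps uniquely (that window and nowhere else in the genome)
#' within it. Includes the sense/antisense seed comparison.
#'
#' @param loci Data frame of sense loci with `name`, `contig`, `start`,
#'   `end`, `strand`, `mature` and window sequence column `window_seq`.
#' @param tags Collapsed tag table.
#' @param genome_index A [build_index()] of the genome.
#' @param paired_fraction_min,loop_max Qualification thresholds.
#' @param tag_len_range Candidate antisense tag lengths (default 18:30).
#' @return Data frame of antisense loci: `name`, `sense_name`, `strand`,
#'   `n_tags`, per-stage read counts, `mature`, `seed_sense`,
#'   `seed_antisense`, `seed_identical`.
#' @export
detect_antisense <- function(loci, tags, genome_index,
                             paired_fraction_min = 0.6, loop_max = 30L,
                             tag_len_range = 18:30) {
  stages <- stage_labels()
  out <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    cand <- structure(list(contig = l$contig, start = l$start, end = l$end,
                           strand = l$strand, seq = as_rna(l$window_seq),
                           mature_span = NULL, clipped = FALSE, structure = NULL),
                      class = "hairpin_candidate")
    m1 <- regexpr(as_rna(l$mature), cand$seq, fixed = TRUE)
    if (m1 < 0L) next
    cand$mature_span <- c(m1, m1 + nchar(l$mature) - 1L)
    as_cand <- fold_antisense(cand)
    q <- qualify_hairpin(as_cand, paired_fraction_min, loop_max)
    if (!q$qualified) next
    # tags present in the antisense window
    n <- nchar(as_cand$seq)
    window_subs <- function(sq) {
      unlist(lapply(tag_len_range, function(L) {
        if (L > n) return(character())
        substring(sq, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
      }))
    }
    subs <- unique(window_subs(as_cand$seq))
    found <- subs[subs %in% tags$seq]
    if (!length(found)) next
    # uniqueness: exactly one genome placement
    hits <- genome_hits(genome_index, found)
    nh <- table(factor(hits$tag, levels = found))
    uniq <- found[as.integer(nh) == 1L]
    # and exclude tags that are also sense-strand sequences of the window
    uniq <- setdiff(uniq, window_subs(cand$seq))
    if (!length(uniq)) next
    idx <- match(uniq, tags$seq)
    counts <- colSums(tags[idx, stages, drop = FALSE])
    mature_as <- uniq[which.max(tags$total[idx])]
    seed_s <- seed_of(l$mature)
    seed_a <- if (nchar(mature_as) >= 8L) seed_of(mature_as) else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      name = paste0(l$name, "-AS"), sense_name = l$name,
      strand = if (l$strand == "+") "-" else "+",
      n_tags = length(uniq), t(counts), total = sum(counts),
      mature = mature_as, seed_sense = seed_s, seed_antisense = seed_a,
      seed_identical = identical(seed_s, seed_a),
      stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(name = character(), sense_name = character(), strand = character(),
               n_tags = integer(), feeding_larva = numeric(), spinning_larva = numeric(),
               pupa = numeric(), moth = numeric(), total = numeric(),
               mature = character(), seed_sense = character(),
               seed_antisense = character(), seed_identical = logical(),
               stringsAsFactors = FALSE)
  }
}

#' Discover novel miRNA loci from genome-mapped tags
#'
#' Applies the full novel-miRNA annotation chain to unannotated genome-mapped
#' tags: candidate gating (18-25 nt, total count >= `min_count`), precursor
#' excision and fold-back qualification over the flank-window set, star
#' inference under 2-nt 3' overhang geometry, star confirmation against the
#' tag table, siRNA-tiling disqualification, seed-family clustering, family
#' rescue, and atypical-arm flagging.
#'
#' @param tags Collapsed tag table.
#' @param assignments Cascade assignments from [annotate_cascade()].
#' @param genome Named character vector of contig sequences.
#' @param genome_index A [build_index()] of `genome`.
#' @param min_count Minimum total read count to consider a tag (default 5).
#' @param mature_len_range Tag lengths considered as candidate matures
#'   (default 18:25; the Dicer-product range, excluding the 26-29 nt
#'   piRNA-like class).
#' @param star_tolerance,coverage_threshold,paired_fraction_min,loop_max,flanks
#'   Thresholds passed to the respective steps.
#' @param exclude_windows Optional list of known-locus windows (`contig`,
#'   `start`, `end`), e.g. conserved miRNA precursors; tags falling inside
#'   one (either strand — the antisense strand of a known locus is reported
#'   by [detect_antisense()], not re-discovered) never seed a new locus.
#' @return List with `loci` (data frame), `families`, and `candidates`
#'   (list of winning `hairpin_candidate`s, named by locus).
#' @export
discover_loci <- function(tags, assignments, genome, genome_index,
                          min_count = 5L, mature_len_range = 18:25,
                          star_tolerance = 2L, coverage_threshold = 0.5,
                          paired_fraction_min = 0.6, loop_max = 30L,
                          flanks = list(c(20L, 150L), c(150L, 20L), c(70L, 70L)),
                          exclude_windows = list()) {
  stages <- stage_labels()
  sel <- assignments$category == "genome_only" &
    nchar(tags$seq) %in% mature_len_range &
    tags$total >= min_count &
    !is.na(assignments$evidence) & assignments$evidence != "repeat_like"
  cand_tags <- tags[sel, , drop = FALSE]
  cand_tags <- cand_tags[order(-cand_tags$total, cand_tags$seq), , drop = FALSE]

  loci <- list()
  candidates <- list()
  windows <- exclude_windows  # called/known windows absorb later hits
  all_hits <- genome_hits(genome_index, cand_tags$seq)
  hit_n <- table(factor(all_hits$tag, levels = cand_tags$seq))
  k <- 0L
  for (i in seq_len(nrow(cand_tags))) {
    tg <- cand_tags[i, ]
    if (hit_n[[tg$seq]] != 1L) next  # ambiguous placements never seed a locus
    hit <- all_hits[all_hits$tag == tg$seq, ][1L, ]
    inside <- any(vapply(windows, function(w) {
      w$contig == hit$contig &&
        hit$start >= w$start && (hit$start + hit$width) <= w$end
    }, logical(1)))
    if (inside) next  # isomiR/star/tiling read of an already-called locus
    cand <- best_hairpin(genome, hit, flanks, paired_fraction_min, loop_max)
    if (is.null(cand)) next
    star <- infer_star(cand)
    conf <- confirm_novel(cand, star, tags, star_tolerance)
    sir <- disqualify_sirna(cand, star, tags, coverage_threshold)
    mat <- span_tag_counts(cand$seq, cand$mature_span[1L], cand$mature_span[2L],
                           tags, star_tolerance)
    status <- if (sir$rejected) "rejected_sirna" else conf$status
    k <- k + 1L
    name <- sprintf("novel-%d", k)
    arm <- tryCatch(arm_of(cand), error = function(e) NA_character_)
    row <- data.frame(name = name, contig = cand$contig, start = cand$start,
                      end = cand$end, strand = cand$strand,
                      mature = tg$seq, star_seq = star$seq,
                      star_observed = length(conf$star_tags) > 0L,
                      status = status, arm = arm,
                      outside_coverage = sir$outside_coverage,
                      stringsAsFactors = FALSE)
    for (s in stages) row[[paste0(s, "_miR")]] <- mat$counts[[s]]
    for (s in stages) row[[paste0(s, "_miR_star")]] <- conf$star_counts[[s]]
    loci[[k]] <- row
    candidates[[name]] <- cand
    windows[[length(windows) + 1L]] <- list(contig = cand$contig,
                                            start = cand$start, end = cand$end)
  }
  if (!length(loci)) {
    return(list(loci = NULL, families = NULL, candidates = candidates))
  }
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  fam <- cluster_families(loci$name, loci$mature)
  loci$family <- fam$assignment$family
  loci$seed <- fam$assignment$seed
  loci$status <- rescue_by_family(loci$status, loci$family)
  loci$atypical_arm <- flag_atypical_arm(loci$arm, loci$family)
  list(loci = loci, families = fam$families, candidates = candidates)
}
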