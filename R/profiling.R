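# rounding helpers: printed statistics round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
round_half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

#' TPM-normalize a count matrix
#'
#' Transcripts (reads) per million: each stage column is divided by that
#' stage's total 18-30 nt read count (after demultiplexing) and scaled by
#' 1e6.
#'
#' @param counts Numeric matrix (loci x stages, columns named by stage
#'   labels).
#' @param stage_totals Named per-stage totals (all 18-30 nt reads assigned to
#'   the stage).
#' @return Numeric matrix of TPM values with the same shape.
#' @export
tpm_normalize <- function(counts, stage_totals) {
  stage_totals <- as_stage_vector(stage_totals, "stage_totals")
  if (any(stage_totals <= 0)) stop("stage totals must be positive")
  stages <- stage_labels()
  stopifnot(all(stages %in% colnames(counts)))
  out <- counts
  for (s in stages) out[, s] <- counts[, s] / stage_totals[[s]] * 1e6
  out
}

#' miRNA fraction of each stage library
#'
#' Percent of total reads annotated as (conserved + novel) miRNA, rounded
#' half-up to 2 decimals.
#'
#' @param mirna_counts Named per-stage miRNA read counts.
#' @param totals Named per-stage total read counts.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' t1 <- load_fixture("T1")
#' mirna_fraction(
#'   unlist(t1[t1$category == "conserved and novel miRNAs", stage_labels()]),
#'   unlist(t1[t1$category == "Total", stage_labels()]))
mirna_fraction <- function(mirna_counts, totals) {
  mirna_counts <- as_stage_vector(mirna_counts, "mirna_counts")
  totals <- as_stage_vector(totals, "totals")
  if (any(totals <= 0)) stop("totals must be positive")
  round_half_up(mirna_counts / totals * 100, 2L)
}

#' Per-locus share of all miRNA reads in a stage
#'
#' The abundance of each miRNA relative to the overall miRNA population:
#' reads of the miRNA divided by total reads of all miRNAs in that stage.
#'
#' @param counts Numeric matrix (loci x stages).
#' @param stage A stage label.
#' @param top_k Also report the cumulative share of the `top_k` most
#'   abundant loci (default 3).
#' @return List with `share` (named numeric, sums to 1) and `top_share`.
#' @export
relative_abundance <- function(counts, stage, top_k = 3L) {
  if (!stage %in% colnames(counts)) stop("stage absent from matrix: ", stage)
  if (nrow(counts) < 1L) stop("matrix has no loci")
  v <- counts[, stage]
  tot <- sum(v)
  share <- if (tot > 0) v / tot else v * 0
  list(share = share,
       top_share = sum(sort(share, decreasing = TRUE)[seq_len(min(top_k, length(share)))]))
}

#' Stage fold change of an expression profile
#'
#' Ratio of the focal stage's value to the maximum of the other stages
#' (rounded to the nearest integer, half away from zero), with the raw ratio
#' and the ratios against each individual other stage. A profile whose other
#' stages are all zero is "exclusive", not a ratio.
#'
#' @param profile Named per-stage numeric vector.
#' @param focal Focal stage label.
#' @return List with `fold` (integer, NA if exclusive), `raw`, `vs_each`
#'   (named raw ratios), `exclusive` (logical).
#' @export
#' @examples
#' stage_fold_change(
#'   setNames(c(128, 636, 405, 3223), stage_labels()), "moth")$fold  # 5
stage_fold_change <- function(profile, focal) {
  profile <- as_stage_vector(profile, "profile")
  if (!focal %in% names(profile)) stop("unknown focal stage: ", focal)
  others <- profile[setdiff(names(profile), focal)]
  if (all(others == 0)) {
    return(list(fold = NA_real_, raw = NA_real_,
                vs_each = others * NA_real_, exclusive = TRUE))
  }
  raw <- profile[[focal]] / max(others)
  list(fold = round_half_away(raw), raw = raw,
       vs_each = profile[[focal]] / others, exclusive = FALSE)
}

#' miR:miR* abundance ratio of a locus
#'
#' Overall (summed across stages) ratio of star to mature reads, rounded to
#' the nearest integer, with a flag for star-dominant loci (star total
#' exceeding the mature total).
#'
#' @param mir Named per-stage miR counts.
#' @param star Named per-stage miR* counts.
#' @return List with `mir_total`, `star_total`, `ratio` (NA and
#'   `undefined = TRUE` when the miR total is 0), `star_dominant`.
#' @export
star_ratio <- function(mir, star) {
  mir <- as_stage_vector(mir, "mir")
  star <- as_stage_vector(star, "star")
  mt <- sum(mir); st <- sum(star)
  if (mt == 0) {
    return(list(mir_total = mt, star_total = st, ratio = NA_real_,
                undefined = TRUE, star_dominant = st > mt))
  }
  list(mir_total = mt, star_total = st,
       ratio = round_half_away(st / mt), undefined = FALSE,
       star_dominant = st > mt)
}

#' Temporal expression class of a 4-stage profile
#'
#' Assigns exactly one class by precedence:
#' \enumerate{
#'   \item `stage_exclusive(<stage>)` — nonzero in exactly one stage;
#'   \item `stage_preferential(<stage>)` — one stage at least twice every
#'     other stage;
#'   \item `gradual_increase` / `gradual_decrease` — strictly monotone across
#'     the four stages;
#'   \item `group1_oscillating` — up at spinning, down at pupa, up at moth
#'     (the largest published class);
#'   \item `uniform` — max/min ratio at most 2;
#'   \item `unclassified` otherwise.
#' }
#'
#' @param profile Named per-stage numeric vector.
#' @return Character scalar, e.g. `"stage_preferential(pupa)"`.
#' @export
classify_temporal <- function(profile) {
  profile <- as_stage_vector(profile, "profile")
  v <- unname(profile)
  nz <- which(v > 0)
  if (length(nz) == 1L) {
    return(sprintf("stage_exclusive(%s)", names(profile)[nz]))
  }
  for (i in seq_along(v)) {
    if (all(v[i] >= 2 * v[-i]) && v[i] > 0) {
      return(sprintf("stage_preferential(%s)", names(profile)[i]))
    }
  }
  if (all(diff(v) > 0)) return("gradual_increase")
  if (all(diff(v) < 0)) return("gradual_decrease")
  if (v[2] > v[1] && v[3] < v[2] && v[4] > v[3]) return("group1_oscillating")
  if (min(v) > 0 && max(v) / min(v) <= 2) return("uniform")
  "unclassified"
}

#' Dominant sequence variant of a multi-variant miRNA
#'
#' When a table lists several sequence variants under one miRNA name,
#' stage statistics use the variant with the highest total mature read count;
#' the others are reported separately.
#'
#' @param tab Data frame with a `mirna` column and per-stage `<stage>_miR`
#'   columns (fixture table layout).
#' @param name miRNA name.
#' @return The dominant row (one-row data frame).
#' @export
dominant_variant <- function(tab, name) {
  rows <- tab[tab$mirna == name, , drop = FALSE]
  if (!nrow(rows)) stop("miRNA not found: ", name)
  tot <- rowSums(rows[, paste0(stage_labels(), "_miR"), drop = FALSE])
  rows[which.max(tot), , drop = FALSE]
}

# internal: extract per-stage miR or star profile from a fixture-shaped row
row_profile <- function(row, what = c("miR", "miR_star")) {
  what <- match.arg(what)
  setNames(as.numeric(row[, paste0(stage_labels(), "_", what)]), stage_labels())
}
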