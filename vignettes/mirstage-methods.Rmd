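---
title: "Stage-resolved small RNA analysis with mirstage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved small RNA analysis with mirstage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstage)
```

## The problem

Holometabolous insects such as the silkworm (*Bombyx mori*) pass through
morphologically and physiologically distinct stages — feeding larva, spinning
larva, pupa, moth — and microRNAs are among the regulators coordinating
those transitions. Deep sequencing of size-selected small RNAs from each
stage yields, after barcoding and pooled sequencing, a single read set in
which every read is `barcode + insert + 3' adapter`. From that raw material
one wants: per-stage expression of known (conserved) miRNAs; novel miRNA
genes supported by hairpin precursors and sequenced miRNA-star strands;
antisense miRNA loci; and the removal of degradation products and
siRNA-generating loci masquerading as miRNAs.

`mirstage` implements that entire chain as composable R functions plus a
single orchestrator, `run_pipeline()`, and pairs it with a synthetic-data
generator whose ground-truth manifest makes every stage of the pipeline
testable end to end.

## Preprocessing model

* **Demultiplexing** is exact: a read is assigned to a stage iff its 5'
  prefix equals that stage's barcode. No mismatch rescue is attempted —
  barcoded small RNA protocols use short (here 4 nt) barcodes where a single
  error can alias stages, and the cost of discarding ambiguous reads is an
  explicit, reported `unassigned` tally rather than silent misassignment.
* **Adapter trimming** finds the leftmost exact occurrence of the adapter's
  most-proximal 11 nt (`min_anchor`) and keeps the sequence 5' of it. Reads
  without the anchor are rejected (again counted, not dropped silently).
  An anchor at position 0 yields an empty insert that the length filter
  removes.
* **Length filter**: inserts of 18–30 nt (inclusive) are kept — the
  size-selected window of the library protocol, spanning both the miRNA
  (20–22 nt) and piRNA-like (26–29 nt) classes.
* **Collapsing** produces unique tags with per-stage counts. All conservation
  invariants (assigned + unassigned = input; kept + rejected = assigned;
  tag-count sums = read counts) are asserted inside `run_pipeline()`.

## Annotation cascade

Published per-library category tables of this kind over-sum: the categories
(ncRNA, repeats, mRNA, ...) were evidently assigned independently, so one
read can be counted twice. `mirstage` instead enforces a strict first-match
priority partition —

`ncRNA` → `repeat` → `mRNA` → `conserved_miRNA` → `genome_only` → `unmapped`

— which makes category tables exactly reproducible and conservation-checkable.
Reference matching is exact substring containment in either orientation,
the reproducible conservative reading of an unstated BLASTN protocol.
Conserved-miRNA homology allows ≤ 2 edits (Levenshtein) and ≤ 3 nt terminal
length offset, enough to absorb the terminal isomiR variants that
co-accumulate with a canonical mature without inventing looser thresholds.
Structural repeat detectors (inverted and tandem repeats, re-implemented in
the package) are available behind `structural_repeat_screen = TRUE`; the
default keeps the repeat category purely reference-driven so that simulated
category tables are exactly predictable from the generator manifest.

Genome mapping is exact, both strands, with deterministic hit order; tags
with more than `multimap_cap` (default 100) placements are flagged
repeat-like and never seed loci.

## Secondary structure: base-pair maximization

The precursor test consumes structure *topology* — is there a single stem,
does the mature sit on one arm, how much of it is paired, how big is the
loop — not folding free energies. The default backend therefore maximizes
the number of nested base pairs (Watson–Crick plus G·U wobble, minimum
hairpin loop 3) by dynamic programming in C++, with a deterministic
traceback that prefers pairing over leaving a base unpaired and takes the
5'-most partner among ties. An energy-model backend can be plugged in via
the `backend` argument of `rna_fold()` without changing any downstream code.

One caveat worth recording: with wobble pairs enabled the maximal pair count
is *not* invariant under reverse complement (a G·U pair maps to A·C, which
cannot pair). Strict Watson–Crick folding (`allow_gu = FALSE`) restores the
symmetry; the test suite checks the invariance in that mode.

## Hairpin qualification and miR* geometry

A candidate precursor window (flank set `{(20,150), (150,20), (70,70)}` nt
around the mature hit; precursors in this clade are ≲ 160 nt, so the three
windows cover hairpins with the mature on either arm) qualifies iff:

1. the mature does not span a terminal loop;
2. ≥ 60% of mature bases are paired (`paired_fraction_min`);
3. every mature partner lies on the opposite side within a single stem
   (exactly one terminal loop between mature and partners);
4. that loop is ≤ 30 nt.

The best-qualifying window wins, ties broken by higher mature paired
fraction then smaller window.

The star span follows the Dicer/Drosha signature: each strand of the
miR:miR* duplex carries a 2-nt 3' overhang. In window coordinates the star
runs from `partner(mature_3'end − 2)` to `partner(mature_5'end) + 2`.
Mature termini that are themselves unpaired (bulged) are resolved to the
nearest paired position inward — the unstated case in the source procedure;
nearest-inward is the choice that perturbs the duplex register least. Star
spans clipped by the window edge are flagged rather than discarded, rescuing
precursors excised near their boundary. On perfect stems the construction is
an involution up to ±1 nt, which the tests exploit.

## Novel-locus discovery rules

Unannotated genome-mapped tags enter hairpin analysis if they are 18–25 nt
(the Dicer-product range; the 26–29 nt piRNA-like class is structurally
excluded) and carry ≥ 5 reads in total — singleton and doubleton tags are
overwhelmingly degradation noise, and a star-confirmation rule cannot rescue
them anyway. Tags whose placement falls inside an already-called locus
window (or a known conserved-locus window, either strand) are aggregated
into that locus rather than re-folded.

* **Star confirmation**: a candidate becomes `novel_confirmed` iff some
  sequenced tag matches the predicted star within ±2 nt per terminus —
  matching the observed isomiR spread at mature termini.
* **Family rescue**: seeds are mature positions 2–8; loci with identical
  seeds form a family. An unconfirmed locus whose family holds ≥ 2 confirmed
  members is `novel_family_rescued` — the generalization of the published
  worked case (five confirmed members rescuing two star-less ones).
* **Atypical arms**: within a family the mature's arm is conserved; members
  deviating from the family majority are flagged (ties flag nothing).
* **siRNA disqualification**: a locus is `rejected_sirna` iff > 50% of its
  precursor positions are covered by tags outside the mature±2/star±2
  windows — the operational reading of reads "tiling almost the entire
  hairpin". The threshold is configurable.
* **Antisense loci**: for each known locus the antisense strand of its
  precursor window is folded; an antisense locus is reported iff the
  antisense hairpin qualifies and ≥ 1 tag maps uniquely — one placement in
  the whole genome — inside it. Uniqueness is evaluated genome-wide (the
  stricter of the two possible readings) and tags that are also sense-window
  substrings are excluded, so near-palindromic stems cannot self-certify.

## Expression statistics

TPM is reads per million of the stage's total 18–30 nt assigned reads.
Derived statistics follow the conventions of the printed tables they
reproduce:

* percentages round half-up to 2 decimals; ratios and folds round half away
  from zero to integers;
* a stage fold change is the focal stage against the *maximum* of the other
  stages (the only reading consistent with the several printed fold values),
  with per-stage raw ratios also returned; an all-zero complement is
  "exclusive", not a ratio;
* miR:miR* ratios are totals across stages, star-dominance meaning the star
  total exceeds the mature total;
* when one miRNA name carries several sequence variants, statistics use the
  variant with the largest total mature count (`dominant_variant()`);
* temporal classes are assigned with precedence: stage-exclusive →
  stage-preferential (≥ 2× every other stage) → strictly monotone
  increase/decrease → the oscillating up-down-up class → uniform
  (max/min ≤ 2) → unclassified. Every 4-stage profile receives exactly one
  class.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_genome()` and
`generate_libraries()` realize them with a fully recorded manifest.

* Four libraries sized proportionally to the study's four (46% : 24% : 12% :
  19%), totalling 4×10⁵ reads — large enough for stable recovery statistics,
  small enough that a 20-seed replicate study runs in minutes.
* A 20 kb single-contig genome at 37.5% GC (silkworm-like), carrying 10
  novel loci (including one seed-sharing family of three, with one member on
  the opposite arm to exercise the atypical-arm flag), 12 conserved catalog
  loci (one star-dominant at miR*:miR = 3, mirroring the published
  star-dominant miRNAs), 2 antisense pairs carrying 8 and 1 uniquely-mapping
  antisense reads (the published antisense evidence counts), and 3
  siRNA-decoy hairpins whose reads tile their precursors.
* Planted precursors are near-perfect stems with ≥ 2 forced mismatches in
  the mature's partner segment (so neither mature nor star maps to both
  strands of its own hairpin — a perfect palindrome would) plus up to 2
  more elsewhere. Every locus is verified at generation time with the
  package's own hairpin machinery: the window must qualify, the mature and
  star must map uniquely, the recorded star is the one the 2-nt-overhang
  geometry infers, and all planted sequences keep an edit-distance margin
  ≥ 5 from the conserved catalog so trimmed variants cannot drift into a
  spurious conserved assignment. Failing draws are redrawn.
* Per-locus per-stage abundances are log-normal (σ = 1.5), reproducing the
  heavy-tailed shares in which the top miRNA takes tens of percent of all
  miRNA reads; miR* reads are drawn at ratio 0.1 per locus; 3' terminal
  trimming noise (none/−1/−2 at 0.8/0.15/0.05) emulates isomiRs; 50% of
  reads are 26–29 nt piRNA-like background from non-locus genome; ncRNA,
  repeat and mRNA decoy references contribute 15%/5%/5%; ~10% of reads get
  corrupted barcodes and become unassignable, mirroring the reported
  barcode-less fraction.
* The manifest records the realized, *assignable* read counts per locus,
  stage and strand-role — exactly what an ideal pipeline could recover —
  plus the expected category table of the annotation cascade.

What the generator deliberately does **not** model: sequencing substitution
errors (the analysis chain is exact-match by design, so error robustness is
a separate question outside the generator's scope), quality-score
structure, multi-contig genomes, genomic copies of the contamination
references, and piRNA biology beyond the length class.
Passing recovery tests therefore demonstrate the pipeline's logic and
bookkeeping, not robustness to platform noise.

## Problem sizes and determinism

The test suite folds 500 random sequences of ≤ 14 nt against an exhaustive
nested-pairing enumeration, checks star geometry on 100 constructed perfect
stems, and replicates the full-scale recovery study across 20 seeds
(4×10⁵ reads each); unit tests run a shared scaled-down simulation (2×10⁴
reads). All randomness flows through explicit seeds; identical config and
seed give byte-identical genomes, libraries and reports, and the pipeline
itself is deterministic (a rerun reproduces every report file exactly).

## Known limitations

* Exact-match reference filtering understates the ncRNA/repeat/mRNA
  categories relative to alignment with mismatches; the conserved-homolog
  step, not the filters, carries the edit tolerance.
* Base-pair maximization can qualify thermodynamically implausible hairpins;
  the qualification thresholds (paired fraction, single stem, loop size) do
  the real discriminating work, and an energy backend can be substituted.
* Multi-mapping matures never seed loci; a genuine miRNA residing in a
  recently duplicated region would be missed (flagged repeat-like instead).
* With a single library per stage there is no replication, so no
  differential-expression testing is attempted — stage statistics are
  descriptive, as in the study design the package models.
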