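test_that("demultiplex assigns by exact barcode prefix and strips it", {
  bc <- setNames(c("ACAU", "CGUA", "GUAC", "UACG"), stage_labels())
  reads <- data.frame(read_id = c("a", "b", "c"),
                      seq = c("ACAUUGGAAUGU", "CGUAGGGG", "AAAAUGGA"),
                      stringsAsFactors = FALSE)
  dm <- demultiplex(reads, bc)
  expect_equal(dm$assigned$stage, c("feeding_larva", "spinning_larva"))
  expect_equal(dm$assigned$seq, c("UGGAAUGU", "GGGG"))
  expect_equal(dm$unassigned$read_id, "c")
  expect_equal(nrow(dm$assigned) + nrow(dm$unassigned), nrow(reads))
  expect_error(demultiplex(reads, setNames(rep("ACAU", 4), stage_labels())),
               "distinct")
})

test_that("adapter trimming keeps the insert 5' of the leftmost anchor", {
  adapter <- "UCGUAUGCCGUCUUCUGCUUG"
  insert <- "UGGAAUGUAAAGAAGUAUGGAG"  # a 22-nt mature miRNA
  read <- paste0(insert, substr(adapter, 1, 15))
  tr <- trim_adapter(read, adapter, min_anchor = 11L)
  expect_false(tr$rejected)
  expect_equal(tr$insert, insert)

  tr2 <- trim_adapter("ACGUACGUACGUACGUACGU", adapter)
  expect_true(tr2$rejected)

  # adapter at position 0: empty insert survives trimming, dies at the
  # length filter
  tr3 <- trim_adapter(substr(adapter, 1, 15), adapter)
  expect_false(tr3$rejected)
  expect_equal(nchar(tr3$insert), 0L)
  expect_equal(length_filter(tr3$insert)$kept, character(0))

  expect_error(trim_adapter(read, "ACGU", min_anchor = 11L), "min_anchor")
})

test_that("length filter bounds are inclusive and conservation holds", {
  seqs <- strrep("A", c(17, 18, 30, 31))
  lf <- length_filter(seqs)
  expect_equal(nchar(lf$kept), c(18, 30))
  expect_equal(lf$n_removed, 2L)
  expect_length(length_filter(character(0))$kept, 0L)
  expect_error(length_filter(seqs, min_len = 20, max_len = 10), "min_len")
})

test_that("collapse produces one tag per sequence with per-stage counts", {
  tags <- collapse_unique(
    stage = c("pupa", "pupa", "pupa", "moth"),
    seqs = c(strrep("A", 20), strrep("A", 20), strrep("C", 20), strrep("A", 20)))
  expect_equal(nrow(tags), 2L)
  a <- tags[tags$seq == strrep("A", 20), ]
  expect_equal(a$pupa, 2L)
  expect_equal(a$moth, 1L)
  expect_equal(a$total, 3L)
  expect_equal(sum(tags$total), 4L)
})

test_that("size histograms weight by reads or by unique tags", {
  tags <- collapse_unique(stage = rep("pupa", 5), seqs = rep(strrep("G", 22), 5))
  h_tot <- size_distribution(tags, "total")
  h_unq <- size_distribution(tags, "unique")
  expect_equal(h_tot["22", "pupa"], 5L)
  expect_equal(h_unq["22", "pupa"], 1L)
  expect_equal(sum(h_tot), 5L)
  empty <- collapse_unique(character(0), character(0))
  expect_true(all(size_distribution(empty, "total") == 0L))
})

test_that("preprocessing recovers the simulator's planted read structure", {
  s <- shared_sim()
  libs <- s$libs
  reads <- do.call(rbind, lapply(
    file.path(s$dir, paste0("lib_", stage_labels(), ".fastq")), read_sequences))
  cfg <- libs$truth$config
  dm <- demultiplex(reads, cfg$barcodes)
  # per-stage assigned counts equal planted assignable counts
  planted <- table(libs$reads$stage[libs$reads$assignable])
  got <- table(dm$assigned$stage)
  expect_equal(as.integer(got[names(planted)]), as.integer(planted))
  expect_equal(nrow(dm$unassigned), sum(!libs$reads$assignable))

  tr <- trim_adapter(dm$assigned$seq, cfg$adapter, cfg$min_anchor)
  lf <- length_filter(data.frame(stage = dm$assigned$stage[!tr$rejected],
                                 seq = tr$insert[!tr$rejected]))
  tags <- collapse_unique(lf$kept$stage, lf$kept$seq)
  # collapse conservation and equality with the manifest's tag table
  expect_equal(sum(tags$total), sum(libs$reads$assignable))
  ar <- libs$reads[libs$reads$assignable, ]
  want <- collapse_unique(ar$stage, ar$seq)
  expect_equal(tags, want)

  # planted bimodal length mix: local maxima in 20-22 and 26-29
  h <- size_distribution(tags, "total")
  tot <- rowSums(h)
  lens <- as.integer(names(tot))
  m1 <- max(tot[lens >= 20 & lens <= 22])
  m2 <- max(tot[lens >= 26 & lens <= 29])
  expect_gt(m1, max(tot[lens %in% c(19, 23, 24)]))
  expect_gt(m2, max(tot[lens %in% c(24, 25, 30)]))
})
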