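test_that("window excision arithmetic, orientation and clipping", {
  set.seed(21)
  g <- c(chr1 = random_rna_str(500))
  hit <- list(contig = "chr1", start = 200L, strand = "+", width = 22L)
  w <- excise_windows(g, hit, flanks = list(c(70L, 70L)))[[1]]
  expect_equal(nchar(w$seq), 162L)
  expect_equal(w$mature_span, c(71L, 92L))
  expect_equal(substr(w$seq, 71, 92), substr(g[[1]], 201, 222))
  expect_false(w$clipped)

  # minus-strand hit: window is the reverse complement, mature sequence
  # equals the minus-strand tag
  hitm <- list(contig = "chr1", start = 200L, strand = "-", width = 22L)
  wm <- excise_windows(g, hitm, flanks = list(c(20L, 50L)))[[1]]
  expect_equal(nchar(wm$seq), 92L)
  tag <- rna_revcomp(substr(g[[1]], 201, 222))
  expect_equal(substr(wm$seq, wm$mature_span[1], wm$mature_span[2]), tag)

  # hit near the contig start is clipped and flagged
  hit2 <- list(contig = "chr1", start = 10L, strand = "+", width = 22L)
  w2 <- excise_windows(g, hit2, flanks = list(c(70L, 70L)))[[1]]
  expect_true(w2$clipped)
  expect_equal(w2$start, 0L)
})

test_that("hairpin qualification accepts a clean stem and rejects pathologies", {
  cand <- perfect_stem_candidate(k = 12, loop = 4, mature_len = 8, offset = 2)
  q <- qualify_hairpin(cand)
  expect_true(q$qualified)
  expect_equal(q$metrics$paired_fraction, 1)
  expect_equal(q$metrics$loop_size, 4L)
  expect_equal(q$metrics$arm, "5p")

  # mature across the loop
  across <- cand
  across$mature_span <- c(10L, 21L)
  qa <- qualify_hairpin(across)
  expect_false(qa$qualified)
  expect_true(qa$metrics$spans_loop)

  # unstructured sequence: paired fraction below threshold
  set.seed(3)
  flat <- structure(list(contig = "c", start = 0L, end = 20L, strand = "+",
                         seq = strrep("A", 30), mature_span = c(5L, 24L),
                         clipped = FALSE, structure = NULL),
                    class = "hairpin_candidate")
  expect_false(qualify_hairpin(flat)$qualified)
  expect_error(qualify_hairpin(`$<-`(cand, "mature_span", c(0L, 8L))), "mature_span")
})

test_that("arm placement follows the terminal loop midpoint", {
  expect_equal(arm_of(perfect_stem_candidate(arm = "5p")), "5p")
  expect_equal(arm_of(perfect_stem_candidate(arm = "3p")), "3p")
  across <- perfect_stem_candidate(k = 12, loop = 4)
  across$mature_span <- c(10L, 21L)
  expect_error(arm_of(across), "loop")
})

test_that("star inference obeys the published 2-nt 3' overhang geometry", {
  # the worked example: perfect 24-nt stem-loop, mature at 3-10
  cand <- structure(list(contig = "c", start = 0L, end = 24L, strand = "+",
                         seq = "AAGGGGGGGGUUUUCCCCCCCCAA",
                         mature_span = c(3L, 10L), clipped = FALSE,
                         structure = NULL),
                    class = "hairpin_candidate")
  s <- infer_star(cand)
  expect_equal(c(s$start, s$end), c(17L, 24L))
  expect_equal(s$seq, "CCCCCCAA")
  expect_false(s$clipped)

  # mirrored construct: mature on the 3p arm gives a 5p star of equal length
  m <- perfect_stem_candidate(k = 12, loop = 4, mature_len = 8, offset = 2, arm = "3p")
  sm <- infer_star(m)
  expect_lt(sm$end, m$mature_span[1])
  expect_equal(sm$end - sm$start, diff(m$mature_span))

  expect_error(infer_star(`$<-`(cand, "mature_span", c(11L, 14L))), "paired")
})

test_that("star geometry and round-trip hold across constructed perfect stems", {
  set.seed(31)
  cases <- expand.grid(k = c(12L, 14L, 16L, 20L), loop = c(3L, 4L, 6L),
                       arm = c("5p", "3p"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    mlen <- sample(6:8, 1)
    off <- sample.int(cs$k - mlen - 2L, 1)
    cand <- perfect_stem_candidate(cs$k, cs$loop, mlen, off, cs$arm)
    cand <- mirstage:::fold_candidate(cand)
    p <- cand$structure$pairs
    s <- infer_star(cand)
    m1 <- cand$mature_span[1]; m2 <- cand$mature_span[2]
    # 2-nt 3' overhangs on both strands of the duplex: the star starts at
    # the partner of (mature 3' end - 2) and ends 2 nt past the partner of
    # the mature 5' end
    expect_equal(p[m2 - 2L], s$start)
    expect_equal(p[m1], s$end - 2L)
    # star length within 2 nt of the mature length
    expect_lte(abs((s$end - s$start) - (m2 - m1)), 2L)
    # star of the star recovers the mature span within 1 nt per terminus
    c2 <- cand
    c2$mature_span <- c(s$start, s$end)
    s2 <- infer_star(c2)
    expect_lte(abs(s2$start - m1), 1L)
    expect_lte(abs(s2$end - m2), 1L)
  }
})

test_that("antisense folding mirrors the window and is an involution", {
  cand <- perfect_stem_candidate(k = 14, loop = 4, mature_len = 8, offset = 3)
  as1 <- fold_antisense(cand)
  expect_equal(as1$strand, "-")
  expect_equal(as1$seq, rna_revcomp(cand$seq))
  expect_equal(rna_fold(as1$seq)$n_pairs, rna_fold(cand$seq)$n_pairs)
  as2 <- fold_antisense(as1)
  expect_equal(as2$seq, cand$seq)
  expect_equal(as2$strand, "+")
  expect_equal(as2$mature_span, cand$mature_span)
  # the antisense of a qualifying stem also qualifies
  expect_true(qualify_hairpin(as1)$qualified)
})
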