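test_that("genome index finds exact occurrences on both strands", {
  g <- c(chr1 = "ACGUACGU")
  idx <- build_index(g)
  h <- genome_hits(idx, "CGUA")
  # forward occurrence at 1 plus the reverse-complement (UACG) occurrence
  expect_equal(h$start, c(1L, 3L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(nrow(genome_hits(idx, "AAAAAA")), 0L)
  h2 <- genome_hits(idx, "ACGUACGU")
  expect_true(any(h2$start == 0L & h2$strand == "+"))
  expect_error(build_index(c("ACGU")), "names")
})

test_that("index hits equal brute-force both-strand scans on random genomes", {
  set.seed(13)
  g <- c(chr1 = random_rna_str(3000), chr2 = random_rna_str(1500))
  idx <- build_index(g)
  # planted + random tags; > 50 tags also exercises the dictionary path
  tags <- c(vapply(1:30, function(i) {
    contig <- sample(names(g), 1)
    s <- sample.int(nchar(g[[contig]]) - 25L, 1)
    t <- substr(g[[contig]], s, s + sample(17:24, 1))
    if (runif(1) < 0.5) rna_revcomp(t) else t
  }, character(1)), replicate(35, random_rna_str(20)))
  hits <- genome_hits(idx, tags)
  for (t in unique(tags)) {
    want <- oracle_genome_hits(g, t)
    got <- hits[hits$tag == t, c("contig", "start", "strand")]
    rownames(got) <- rownames(want) <- NULL
    want <- want[order(want$contig, want$start, want$strand), ]
    rownames(want) <- NULL
    expect_equal(got, want, info = t)
  }
  # both code paths agree with each other
  few <- genome_hits(idx, tags[1:3])
  expect_equal(few, hits[hits$tag %in% tags[1:3], ][order(match(
    hits$tag[hits$tag %in% tags[1:3]], tags[1:3])), ], ignore_attr = TRUE)
})

test_that("conserved matching tolerates edits and terminal shifts with tie-breaks", {
  catalog <- c("miR-1" = "UGGAAUGUAAAGAAGUAUGGAG",
               "miR-99" = "AACCCGUAGAUCCGAGCUUGUU")
  m <- match_conserved("UGGAAUGUAAAGAAGUAUGGAG", catalog)
  expect_equal(m$mirna, "miR-1")
  expect_equal(m$edits, 0L)
  # one extra terminal nucleotide: same name, offset +1
  m2 <- match_conserved("UGGAAUGUAAAGAAGUAUGGAGA", catalog)
  expect_equal(m2$mirna, "miR-1")
  expect_equal(m2$offset, 1L)
  # far from everything
  expect_true(is.na(match_conserved(strrep("AC", 11), catalog)$mirna))
  # over-shift rejected even at small edit distance
  expect_true(is.na(match_conserved(paste0("UGGAAUGUAAAGAAGUAUGGAG", "AAAA"),
                                    catalog, max_edits = 4)$mirna))
})

test_that("cascade enforces strict category priority and partitions all tags", {
  refs <- list(ncRNA = c(rna1 = paste0("GG", strrep("AU", 12), "CC")),
               "repeat" = c(rep1 = strrep("ACG", 10)),
               mRNA = c(m1 = paste0(strrep("AU", 12), "GGGG")),
               known_miRNA = c("miR-x" = "UGGAAUGUAAAGAAGUAUGGAG"))
  genome <- c(chr1 = paste0(random_rna_str(50), "UUUCCCAUGGUACGUACGUAUU",
                            random_rna_str(50)))
  idx <- build_index(genome)
  tags <- collapse_unique(
    stage = rep("pupa", 4),
    seqs = c(strrep("AU", 10),              # in both ncRNA and mRNA -> ncRNA
             "UGGAAUGUAAAGAAGUAUGGAG",      # conserved
             "UUUCCCAUGGUACGUACGUAUU",      # genome only
             strrep("GA", 10)))             # nowhere -> unmapped
  res <- annotate_cascade(tags, refs, idx)
  got <- setNames(res$assignments$category, res$assignments$seq)
  expect_equal(unname(got[strrep("AU", 10)]), "ncRNA")
  expect_equal(unname(got["UGGAAUGUAAAGAAGUAUGGAG"]), "conserved_miRNA")
  expect_equal(unname(got["UUUCCCAUGGUACGUACGUAUU"]), "genome_only")
  expect_equal(unname(got[strrep("GA", 10)]), "unmapped")
  # partition: category x stage sums equal stage totals
  expect_equal(res$category_counts["Total", "pupa"], 4)
  expect_equal(sum(res$category_counts[1:6, "pupa"]), 4)
  expect_error(annotate_cascade(tags, refs[-1], idx), "missing reference")
})

test_that("cascade reproduces the simulator's per-category read counts", {
  s <- shared_pipeline()
  expect_equal(s$res$category_counts[1:6, ], s$libs$expected_categories)
  # determinism: rerunning the cascade on the same inputs is identical
  tags <- s$res$tags
  refs <- lapply(sim_pipeline_config(s$dir)$refs, function(p) {
    d <- read_sequences(p, "fasta")
    setNames(d$seq, d$read_id)
  })
  idx <- build_index(setNames(read_sequences(file.path(s$dir, "genome.fa"))$seq, "chr1"))
  again <- annotate_cascade(tags, refs, idx)
  expect_identical(again$category_counts, s$res$category_counts)
  expect_identical(again$assignments, s$res$assignments)
})
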