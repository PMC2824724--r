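test_that("seed extraction takes mature positions 2-8", {
  expect_equal(seed_of("UCACUGGGUGCAUGAUGAUUG"), "CACUGGG")
  expect_equal(seed_of("UGGAAUGUAAAGAAGUAUGGAG"), "GGAAUGU")
  expect_error(seed_of("ACGUACG"), "seed")
})

test_that("family clustering partitions loci by identical seed", {
  t2 <- load_fixture("T2")
  fam <- cluster_families(t2$mirna, t2$mature_sequence)
  expect_equal(fam$families$size[1], 7L)           # the mir-2733 family
  expect_equal(sum(fam$families$size == 1L), 7L)   # everything else singleton
  members <- fam$assignment$name[fam$assignment$family == fam$families$family[1]]
  expect_true(all(grepl("2733", members)))
  # all-distinct seeds give singletons; shared-seed plantings give that size
  f2 <- cluster_families(c("a", "b", "c"),
                         c("UAAAAAAGGGGGGGGGGG", "UCCCCCCGGGGGGGGGGG",
                           "GAAAAAACGGGGGGGGGG"))
  expect_equal(f2$families$size, c(1L, 1L, 1L))
  f3 <- cluster_families(c("a", "b", "c"),
                         c("UAAACCCGGGGGGGGGGG", "GAAACCCGUUUGGGGGGG",
                           "CAAACCCGACGUGGGGGG"))
  expect_equal(f3$families$size[1], 3L)
})

test_that("candidate screen flags 5' U and 20-23 nt length, reporting only", {
  sc <- candidate_screen(c("UCAGUCUUGUCGAAUGGUGGGU",   # both flags
                           "ACCCGAGCGGUCUGAGCAAACU",   # not U-start
                           "UCAGUCUUGUCGAAUGGUG"))     # 19 nt
  expect_equal(sc$starts_with_U, c(TRUE, FALSE, TRUE))
  expect_equal(sc$length_in_20_23, c(TRUE, TRUE, FALSE))
})

test_that("star confirmation honors the per-terminus tolerance", {
  set.seed(91)
  w <- random_rna_str(100)
  cand <- structure(list(contig = "c", start = 0L, end = 100L, strand = "+",
                         seq = w, mature_span = c(10L, 30L), clipped = FALSE,
                         structure = NULL),
                    class = "hairpin_candidate")
  star <- list(start = 60L, end = 80L, seq = substr(w, 60, 80), clipped = FALSE)
  tags <- collapse_unique(rep("pupa", 3), rep(star$seq, 3))
  conf <- confirm_novel(cand, star, tags)
  expect_equal(conf$status, "novel_confirmed")
  expect_equal(unname(conf$star_counts["pupa"]), 3)
  # a 1-nt-trimmed star variant still confirms and is aggregated
  tags1 <- collapse_unique(c("pupa", "moth"),
                           c(substr(w, 60, 79), substr(w, 60, 80)))
  conf1 <- confirm_novel(cand, star, tags1)
  expect_equal(conf1$status, "novel_confirmed")
  expect_equal(sum(conf1$star_counts), 2)
  # shifted beyond tolerance: unconfirmed
  conf2 <- confirm_novel(cand, star,
                         collapse_unique("pupa", substr(w, 63, 83)),
                         star_tolerance = 2L)
  expect_equal(conf2$status, "candidate_unconfirmed")
})

test_that("family rescue requires two confirmed seed-mates", {
  status <- c("novel_confirmed", "novel_confirmed", "candidate_unconfirmed",
              "candidate_unconfirmed", "novel_confirmed")
  family <- c("f1", "f1", "f1", "f2", "f2")
  out <- rescue_by_family(status, family)
  expect_equal(out[3], "novel_family_rescued")   # two confirmed mates in f1
  expect_equal(out[4], "candidate_unconfirmed")  # only one in f2
  # singleton stays unconfirmed
  expect_equal(rescue_by_family("candidate_unconfirmed", "s1"),
               "candidate_unconfirmed")
})

test_that("atypical arm flags follow the family majority with a tie rule", {
  fam <- rep("f", 7)
  arms <- c(rep("3p", 5), rep("5p", 2))
  expect_equal(flag_atypical_arm(arms, fam),
               c(rep(FALSE, 5), TRUE, TRUE))
  expect_false(any(flag_atypical_arm(rep("3p", 4), rep("f", 4))))
  expect_false(any(flag_atypical_arm(c("5p", "3p"), c("f", "f"))))
})

test_that("siRNA disqualification keys on coverage outside mature/star spans", {
  set.seed(92)
  w <- random_rna_str(120)
  cand <- structure(list(contig = "c", start = 0L, end = 120L, strand = "+",
                         seq = w, mature_span = c(10L, 30L), clipped = FALSE,
                         structure = NULL),
                    class = "hairpin_candidate")
  star <- list(start = 70L, end = 90L, seq = substr(w, 70, 90), clipped = FALSE)
  # reads only at mature and star: retained with zero outside coverage
  tags <- collapse_unique(rep("pupa", 2),
                          c(substr(w, 10, 30), star$seq))
  d <- disqualify_sirna(cand, star, tags)
  expect_false(d$rejected)
  expect_equal(d$outside_coverage, 0)
  # tiling reads across the hairpin: rejected
  starts <- seq(1L, 100L, by = 4L)
  tiles <- substring(w, starts, starts + 19L)
  tags2 <- collapse_unique(rep("pupa", length(tiles)), tiles)
  d2 <- disqualify_sirna(cand, star, tags2)
  expect_true(d2$rejected)
  expect_gt(d2$outside_coverage, 0.5)
})

test_that("discovery recovers planted loci and rejects decoys on the shared run", {
  s <- shared_pipeline()
  truth <- s$libs$truth
  loci <- s$res$discovery$loci
  novel_true <- truth$loci[truth$loci$type == "novel", ]
  conf <- loci[loci$status %in% c("novel_confirmed", "novel_family_rescued"), ]
  expect_gte(sum(novel_true$mature %in% conf$mature), nrow(novel_true) - 1L)
  # no planted siRNA decoy survives as a miRNA call
  sir_mat <- truth$loci$mature[truth$loci$type == "sirna"]
  expect_false(any(conf$mature %in% sir_mat))
  # the planted seed family is recovered as one family
  fam_members <- truth$loci$name[truth$loci$type == "novel"][1:3]
  fam_seeds <- seed_of(truth$loci$mature[truth$loci$name %in% fam_members])
  expect_equal(length(unique(fam_seeds)), 1L)
  got_fams <- conf$family[conf$mature %in%
                            truth$loci$mature[truth$loci$name %in% fam_members]]
  expect_equal(length(unique(got_fams)), 1L)
})

test_that("antisense loci need unique antisense reads and a qualifying fold", {
  s <- shared_pipeline()
  truth <- s$libs$truth
  exp_as <- s$libs$expected[s$libs$expected$type == "antisense", ]
  exp_tot <- tapply(exp_as$mir_reads, exp_as$name, sum)
  got <- s$res$antisense
  for (nm in names(exp_tot)) {
    if (exp_tot[[nm]] > 0) {
      expect_true(nm %in% got$name)
      expect_equal(got$total[got$name == nm], unname(exp_tot[[nm]]))
    }
  }
  # sense-only loci report no antisense call
  sense_only <- setdiff(paste0(truth$loci$name[truth$loci$type == "conserved"], "-AS"),
                        names(exp_tot)[exp_tot > 0])
  expect_false(any(sense_only %in% got$name))
})
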