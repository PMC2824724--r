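stages <- stage_labels()

test_that("TPM normalization scales by per-stage totals", {
  counts <- matrix(c(5, 0, 10, 2, 1, 0, 3, 8), nrow = 2,
                   dimnames = list(c("a", "b"), stages))
  totals <- setNames(c(1e6, 2e6, 5e5, 1e6), stages)
  tpm <- tpm_normalize(counts, totals)
  expect_equal(tpm["a", "feeding_larva"], 5)
  expect_equal(tpm["b", "spinning_larva"], 1)
  expect_equal(tpm["a", "pupa"], 2)
  expect_error(tpm_normalize(counts, setNames(c(0, 1, 1, 1), stages)), "positive")
})

test_that("miRNA fractions reproduce the published per-stage percentages", {
  t1 <- load_fixture("T1")
  mir <- unlist(t1[t1$category == "conserved and novel miRNAs", stages])
  tot <- unlist(t1[t1$category == "Total", stages])
  frac <- mirna_fraction(mir, tot)
  expect_equal(unname(frac["spinning_larva"]), 11.70)
  expect_equal(unname(frac["moth"]), 15.07)
  expect_equal(unname(mirna_fraction(setNames(c(0, 0, 0, 0), stages),
                                     setNames(rep(10, 4), stages))),
               rep(0, 4))
})

test_that("relative abundance shares sum to one and expose the top share", {
  counts <- matrix(c(30, 60, 10, rep(1, 9)), nrow = 3,
                   dimnames = list(c("x", "y", "z"), stages))
  ra <- relative_abundance(counts, "feeding_larva")
  expect_equal(sum(ra$share), 1)
  expect_equal(unname(ra$share["y"]), 0.6)
  expect_equal(ra$top_share, 1)
  one <- relative_abundance(counts[1, , drop = FALSE], "moth")
  expect_equal(unname(one$share), 1)
  expect_error(relative_abundance(counts, "egg"), "stage absent")
})

test_that("stage fold changes match the published fold claims from the table", {
  t3 <- load_fixture("T3")
  prof <- function(name) {
    r <- dominant_variant(t3, name)
    setNames(as.numeric(r[, paste0(stages, "_miR")]), stages)
  }
  f278 <- stage_fold_change(prof("miR-278"), "pupa")
  expect_equal(f278$fold, 23)  # vs the spinning-larva maximum of the others
  expect_equal(unname(round(f278$vs_each["feeding_larva"])), 63)
  expect_equal(stage_fold_change(prof("miR-100"), "moth")$fold, 5)
  expect_equal(stage_fold_change(prof("miR-31"), "moth")$fold, 3)
  expect_equal(stage_fold_change(prof("miR-184"), "moth")$fold, 3)
  expect_equal(stage_fold_change(setNames(rep(7, 4), stages), "pupa")$fold, 1)
  excl <- stage_fold_change(setNames(c(11, 0, 0, 0), stages), "feeding_larva")
  expect_true(excl$exclusive)
})

test_that("star ratios reproduce the published miR:miR* ratios", {
  t3 <- load_fixture("T3")
  ratio_of <- function(name) {
    r <- dominant_variant(t3, name)
    star_ratio(setNames(as.numeric(r[, paste0(stages, "_miR")]), stages),
               setNames(as.numeric(r[, paste0(stages, "_miR_star")]), stages))
  }
  r33 <- ratio_of("miR-33")
  expect_equal(r33$ratio, 48)
  expect_true(r33$star_dominant)
  expect_equal(ratio_of("miR-281")$ratio, 18)
  expect_equal(ratio_of("miR-10")$ratio, 4)
  eq <- star_ratio(setNames(c(5, 5, 5, 5), stages), setNames(c(5, 5, 5, 5), stages))
  expect_equal(eq$ratio, 1)
  expect_false(eq$star_dominant)
  undef <- star_ratio(setNames(rep(0, 4), stages), setNames(c(1, 0, 0, 0), stages))
  expect_true(undef$undefined)
})

test_that("temporal classification follows the documented precedence", {
  expect_equal(classify_temporal(setNames(c(106, 35, 3981, 22), stages)),
               "stage_preferential(pupa)")
  expect_equal(classify_temporal(setNames(c(11, 0, 0, 0), stages)),
               "stage_exclusive(feeding_larva)")
  expect_equal(classify_temporal(setNames(c(10, 10, 10, 10), stages)), "uniform")
  expect_equal(classify_temporal(setNames(c(1, 3, 9, 80), stages)),
               "stage_preferential(moth)")
  expect_equal(classify_temporal(setNames(c(1, 3, 5, 8), stages)),
               "gradual_increase")
  expect_equal(classify_temporal(setNames(c(9, 7, 5, 2), stages)),
               "gradual_decrease")
  expect_equal(classify_temporal(setNames(c(10, 25, 12, 20), stages)),
               "group1_oscillating")
  # totality on random profiles: exactly one class each
  set.seed(17)
  for (i in 1:50) {
    v <- setNames(sample(0:50, 4, replace = TRUE), stages)
    expect_length(classify_temporal(v), 1L)
  }
})

test_that("multi-variant miRNAs resolve to the most abundant variant", {
  t3 <- load_fixture("T3")
  dom <- dominant_variant(t3, "miR-278")
  expect_equal(dom$mature_sequence, "UCGGUGGGAUCUUCGUCCGUU")
  expect_equal(dom$pupa_miR, 6648)
  expect_error(dominant_variant(t3, "miR-nope"), "not found")
})
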