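# shared miniature study: 6 planted hairpins; 2 own refs, 1 monocot, 3 novel
mini <- local({
  g <- synth_genome(1, 80000, 6, seed = 41)
  tr <- g$truth
  list(g = g, tr = tr,
       own_mat = stats::setNames(tr$mature_seq[1:2],
                                 c("xsy-miR1-5p", "xsy-miR2-5p")),
       own_pre = stats::setNames(tr$precursor[1:2],
                                 c("xsy-MIR1", "xsy-MIR2")),
       mono_pre = stats::setNames(tr$precursor[3], "osy-MIR3"))
})

test_that("the decision tree assigns classes in priority order", {
  tr <- mini$tr
  # the star-arm sequence opposite an annotated mature (novel_arm probe)
  pre1 <- tr$precursor[1]
  arm_len <- (nchar(pre1) - 8) %/% 2
  if (tr$arm[1] == "5p") {
    star <- substr(pre1, nchar(pre1) - arm_len + 11, nchar(pre1) - arm_len + 31)
  } else {
    star <- substr(pre1, 11, 31)
  }
  tags <- make_tags(
    c(tr$mature_seq[1],        # known
      star,                    # novel_arm on xsy-MIR1
      tr$mature_seq[3],        # homolog via osy-MIR3
      tr$mature_seq[5],        # novel_pc
      strrep("AC", 10) ),      # maps nowhere
    list(c(10L, 3L, 5L, 9L, 2L), c(12L, 4L, 6L, 7L, 1L),
         c(11L, 2L, 7L, 8L, 3L)))
  rec <- classify_tags(tags, own_matures = mini$own_mat,
                       own_precursors = mini$own_pre,
                       monocot_precursors = mini$mono_pre,
                       genome = mini$g$genome)
  drops <- attr(rec, "drops")
  expect_equal(nrow(rec) + nrow(drops), nrow(tags))
  cls <- rec$class[match(tags$sequence, rec$sequence)]
  expect_equal(cls[1], "known")
  expect_equal(rec$name[rec$sequence == tags$sequence[1]], "xsy-miR1-5p")
  expect_equal(cls[2], "novel_arm")
  expect_match(rec$name[rec$sequence == tags$sequence[2]], "^xsy-MIR1-p[53]$")
  expect_equal(cls[3], "homolog")
  expect_match(rec$name[rec$sequence == tags$sequence[3]], "^osy-MIR3-p[53]$")
  expect_equal(cls[4], "novel_pc")
  expect_match(rec$name[rec$sequence == tags$sequence[4]],
               "^PC-[53]p-\\d+_\\d+$")
  expect_true(tags$sequence[5] %in% drops$sequence)
  expect_equal(drops$reason[drops$sequence == tags$sequence[5]],
               "no_genome_hit")
})

test_that("a tag matching both an own mature and a monocot set stays known", {
  tags <- make_tags(mini$tr$mature_seq[1], list(5L, 5L, 5L))
  rec <- classify_tags(tags, own_matures = mini$own_mat,
                       own_precursors = mini$own_pre,
                       monocot_matures = stats::setNames(
                         mini$tr$mature_seq[1], "osy-miR99-5p"),
                       monocot_precursors = stats::setNames(
                         mini$tr$precursor[1], "osy-MIR99"),
                       genome = mini$g$genome)
  expect_equal(rec$class, "known")
  expect_equal(rec$name, "xsy-miR1-5p")
})

test_that("length partition: out-of-window tags are dropped with reason", {
  tags <- make_tags(c(strrep("ACGTA", 5), mini$tr$mature_seq[1]),
                    list(c(4L, 8L), c(3L, 2L), c(1L, 1L)))
  rec <- classify_tags(tags, own_matures = mini$own_mat,
                       own_precursors = mini$own_pre,
                       genome = mini$g$genome)
  drops <- attr(rec, "drops")
  expect_equal(drops$reason, "length")
  expect_equal(nrow(rec), 1)
})

test_that("novel candidates need a genome", {
  tags <- make_tags(mini$tr$mature_seq[5], list(5L, 5L, 5L))
  expect_error(classify_tags(tags, own_matures = mini$own_mat,
                             own_precursors = mini$own_pre, genome = NULL),
               "genome")
})

test_that("the high-confidence filter mirrors the reporting rule", {
  rec <- tibble::tibble(
    name = c("cand-a", "cand-b", "cand-c", "cand-d", "cand-e"),
    class = "novel_pc",
    sequence = vapply(1:5, function(i) random_dna_str(21), character(1)),
    length = 21L,
    raw_C0 = c(27L, 4L, 4L, 30L, 12L),
    raw_C1 = c(22L, 10L, 9L, 0L, 11L),
    raw_Cd1 = c(52L, 1L, 1L, 0L, 10L),
    norm_C0 = c(27, 4, 4, 30, 12),
    norm_C1 = c(22, 10, 9, 0, 11),
    norm_Cd1 = c(52, 1, 1, 0, 10),
    mfei = c(0.90, 1.00, 1.00, 1.20, 0.80),
    passes = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  kept <- high_confidence_filter(rec)
  # (27,22,52)/0.90 kept; (4,10,1)/1.00 kept at the >=10 rule;
  # (4,9,1) below threshold; single-library support dropped; low MFEI dropped
  expect_setequal(kept$name, c("cand-a", "cand-b"))
  # the threshold is inclusive: max normalized count exactly 10 passes
  expect_true("cand-b" %in% kept$name)
})

test_that("significance selection takes the minimum over comparisons", {
  rec <- tibble::tibble(name = c("m1", "m2", "m3"), class = "known",
                        sequence = c("A", "C", "G"), length = 1L)
  de1 <- tibble::tibble(name = c("m1", "m2", "m3"),
                        p_value = c(0.20, 0.40, 1.0))
  de2 <- tibble::tibble(name = c("m1", "m2", "m3"),
                        p_value = c(0.01, 0.30, 0.9))
  de3 <- tibble::tibble(name = c("m1", "m2", "m3"),
                        p_value = c(0.15, 0.06, 0.7))
  out <- select_significant(rec, list(de1, de2, de3), alpha = 0.05)
  expect_equal(out$name, "m1")
  all_in <- select_significant(rec, list(de1, de2, de3), alpha = 1)
  expect_equal(nrow(all_in), 3)
  expect_error(select_significant(rec, list()), "ordering")
})

test_that("printed novel-miRNA table is self-consistent under the filter", {
  tbl <- reported_novel_mirnas()
  expect_true(all(nchar(tbl$sequence) == tbl$size))
  expect_true(all(tbl$size >= 20 & tbl$size <= 22))
  expect_true(all(tbl$mfei >= 0.85))
  expect_true(all(pmax(tbl$c0, tbl$c1, tbl$cd1) >= 10))
})
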