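rc <- function(x) stringi::stri_reverse(chartr("ACGT", "TGCA", x))

test_that("expectation score weights symbols and the seed window", {
  L <- 21
  perfect <- strrep("|", L)
  expect_equal(expectation_score(perfect), 0)
  at <- function(p, ch) {
    s <- perfect
    substr(s, p, p) <- ch
    s
  }
  expect_equal(expectation_score(at(15, "o")), 0.5)
  expect_equal(expectation_score(at(5, ".")), 2)
  expect_equal(expectation_score(at(3, "-")), 4)
  expect_equal(expectation_score(at(1, ".")), 1)   # position 1 outside seed
  expect_equal(expectation_score(at(13, "o")), 1)  # seed edge doubled
  expect_equal(expectation_score(at(14, "o")), 0.5)
  expect_error(expectation_score(at(4, "x")), "unknown")
})

test_that("a perfect site is found with expectation 0 and Cleavage mode", {
  set.seed(61)
  mir <- random_dna_str(21, 0.5)
  tx <- paste0(random_dna_str(150), rc(mir), random_dna_str(150))
  hits <- scan_targets_expectation(c(m1 = mir), c(t1 = tx))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$site_start, 151L)
  expect_equal(hits$site_end, 171L)
  expect_equal(hits$pairing, strrep("|", 21))
  expect_equal(hits$inhibition, "Cleavage")
})

test_that("planted edits surface at truth coordinates with forced scores", {
  set.seed(62)
  mir <- random_dna_str(21, 0.5)
  tx <- synth_transcriptome(c(m1 = mir), n_transcripts = 3,
                            sites_per_mirna = 3,
                            mismatch_plan = list(list(list(20, "mismatch")),
                                                 list(list(10, "mismatch")),
                                                 list()),
                            seed = 9)
  hits <- scan_targets_expectation(c(m1 = mir), tx$transcripts)
  hits <- dplyr::arrange(hits, .data$transcript_id)
  tt <- dplyr::arrange(tx$targets, .data$transcript_id)
  expect_equal(hits$site_start, tt$site_start)
  expect_equal(hits$site_end, tt$site_end)
  expect_equal(hits$expectation, tt$expected_expectation)
  # a mismatch at position 20 costs 1; at position 10 it breaks cleavage
  expect_equal(hits$inhibition[tt$n_mismatch == 1 &
                                 grepl("\\.", substr(tt$pairing, 10, 10))],
               "Translation")
})

test_that("scan DP equals brute-force enumeration of gapped alignments", {
  set.seed(63)
  for (rep in 1:60) {
    L <- sample(19:22, 1)
    mir <- random_dna_str(L, runif(1, 0.3, 0.7))
    win <- random_dna_str(sample((L + 1):26, 1), runif(1, 0.3, 0.7))
    got <- scan_targets_expectation(c(m = mir), c(t = win), cutoff = 1e6)
    expect_gt(nrow(got), 0)
    expect_equal(min(got$expectation), oracle_scan_min(mir, win),
                 info = paste(mir, win))
  }
})

test_that("reported pairings recompute to the reported expectation", {
  set.seed(64)
  mir <- random_dna_str(21, 0.5)
  tx <- c(t1 = paste0(random_dna_str(80), rc(mir), random_dna_str(80)))
  hits <- scan_targets_expectation(c(m = mir), tx, cutoff = 20)
  for (i in seq_len(nrow(hits))) {
    expect_equal(expectation_score(hits$pairing[i]), hits$expectation[i])
  }
})

test_that("gapless penalty scheme weights its 2-17 core", {
  set.seed(65)
  # miRNA with G at positions 4 and 20 so wobbles are constructible
  mir <- paste0("AG", "TG", random_dna_str(15, 0.5), "GC")
  site <- rc(mir)
  gu_at <- function(p) {
    s <- site
    q <- nchar(mir) - p + 1
    stopifnot(substr(mir, p, p) == "G")
    substr(s, q, q) <- "T"
    s
  }
  tx <- c(t20 = paste0(random_dna_str(60), gu_at(20), random_dna_str(60)),
          t04 = paste0(random_dna_str(60), gu_at(4), random_dna_str(60)),
          tok = paste0(random_dna_str(60), site, random_dna_str(60)))
  hits <- scan_targets_penalty(c(m = mir), tx)
  hits <- hits[order(hits$transcript_id), ]
  expect_equal(hits$penalty_b[hits$transcript_id == "t04"], 1)
  expect_equal(hits$penalty_b[hits$transcript_id == "t20"], 0.5)
  expect_equal(hits$penalty_b[hits$transcript_id == "tok"], 0)

  # two seed-core mismatches cost 4 and fall over the 2.5 cutoff
  bad <- site
  q1 <- nchar(mir) - 5 + 1; q2 <- nchar(mir) - 9 + 1
  substr(bad, q1, q1) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(site, q1, q1),
                                   chartr("ACGT", "TGCA", substr(mir, 5, 5)),
                                   if (substr(mir, 5, 5) == "G") "T",
                                   if (substr(mir, 5, 5) == "T") "G"))[1]
  substr(bad, q2, q2) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(site, q2, q2),
                                   if (substr(mir, 9, 9) == "G") "T",
                                   if (substr(mir, 9, 9) == "T") "G"))[1]
  tx2 <- c(tb = paste0(random_dna_str(60), bad, random_dna_str(60)))
  h2 <- scan_targets_penalty(c(m = mir), tx2)
  expect_true(!nrow(h2) ||
                all(h2$site_start != 61 | h2$penalty_b <= 2.5))
})

test_that("adding a mispair never lowers either scheme's score", {
  set.seed(66)
  for (rep in 1:20) {
    L <- 21
    pairing <- strrep("|", L)
    base_a <- expectation_score(pairing)
    p <- sample(L, 1)
    worse <- pairing
    substr(worse, p, p) <- sample(c("o", ".", "-"), 1)
    expect_gte(expectation_score(worse), base_a)
  }
})

test_that("intersection keeps overlapping dual-scheme calls only", {
  a <- tibble::tibble(mirna = c("m1", "m1", "m2"),
                      transcript_id = c("G1_T01", "G2_T01", "G1_T01"),
                      site_start = c(100L, 50L, 200L),
                      site_end = c(120L, 70L, 220L),
                      expectation = c(0, 1, 2), n_gap = 0L,
                      pairing = strrep("|", 21),
                      inhibition = "Cleavage")
  b <- tibble::tibble(mirna = c("m1", "m1"),
                      transcript_id = c("G1_T01", "G3_T01"),
                      site_start = c(100L, 10L), site_end = c(120L, 30L),
                      penalty_b = c(0.5, 1), n_gap = 0L,
                      pairing = strrep("|", 21), inhibition = "Cleavage")
  cons <- intersect_predictions(a, b)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$mirna, "m1")
  expect_equal(cons$transcript_id, "G1_T01")
  expect_equal(cons$expectation, 0)
  expect_equal(cons$penalty_b, 0.5)
  expect_equal(cons$gene, "G1")

  # a shifted copy below 50 percent overlap is rejected
  b2 <- b
  b2$site_start[1] <- 112L; b2$site_end[1] <- 132L
  expect_equal(nrow(intersect_predictions(a, b2)), 0)
})

test_that("planted sites intersect while decoys do not", {
  set.seed(67)
  mirs <- stats::setNames(
    vapply(1:4, function(i) random_dna_str(21, 0.5), character(1)),
    paste0("m", 1:4))
  tx <- synth_transcriptome(mirs, n_transcripts = 12, sites_per_mirna = 2,
                            mismatch_plan = list(list(),
                                                 list(list(19, "mismatch"))),
                            seed = 31)
  ha <- scan_targets_expectation(mirs, tx$transcripts)
  hb <- scan_targets_penalty(mirs, tx$transcripts)
  cons <- intersect_predictions(ha, hb)
  got <- unique(paste(cons$mirna, cons$transcript_id))
  want <- unique(paste(tx$targets$mirna, tx$targets$transcript_id))
  expect_setequal(got, want)
  # cutoff coherence
  expect_true(all(cons$expectation <= 5 & cons$penalty_b <= 2.5))
})

test_that("site accessibility proxy is non-negative and zero when open", {
  # unstructured context (no pairable bases in the window): free to open
  tx <- paste0(strrep("A", 40), paste0(strrep("CA", 10), "C"), strrep("A", 40))
  expect_equal(upe_proxy(tx, 41, 61), 0)

  # a site buried in a strong stem costs energy to open
  arm <- "GCGGCCGCATCGGATCGCGGCC"
  stem_tx <- paste0(strrep("A", 10), arm, "TTTT", rc(arm), strrep("A", 10))
  site_start <- 11L; site_end <- 10L + nchar(arm)
  expect_gt(upe_proxy(stem_tx, site_start, site_end), 0)

  set.seed(68)
  for (rep in 1:40) {
    tx <- random_dna_str(120)
    s <- sample(30:70, 1)
    expect_gte(upe_proxy(tx, s, s + 20), 0)
  }
  expect_true(is.na(upe_proxy("ACGTACGTACGTT", 2, 5, flank = 2)))
})
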