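test_that("synthetic genomes honour the construction contract", {
  g <- synth_genome(1, 100000, 10, seed = 1)
  expect_equal(length(g$genome), 1)
  expect_equal(Biostrings::width(g$genome)[1], 100000)
  expect_equal(nrow(g$truth), 10)
  expect_true(all(nchar(g$truth$mature_seq) %in% 20:22))
  expect_true(all(g$truth$arm %in% c("5p", "3p")))
  expect_true(all(g$truth$n_mispair %in% 0:3))
  # hairpin loci are non-overlapping
  o <- order(g$truth$hairpin_start)
  expect_true(all(g$truth$hairpin_start[o][-1] >
                    g$truth$hairpin_end[o][-10]))
  # arm GC within the stated band
  arm_gc <- vapply(seq_len(10), function(i) {
    arm <- substr(g$truth$precursor[i], 1,
                  (nchar(g$truth$precursor[i]) - 6) %/% 2)
    100 * stringi::stri_count_regex(arm, "[GC]") / nchar(arm)
  }, numeric(1))
  expect_true(all(arm_gc > 40 & arm_gc < 70))
})

test_that("the same seed reproduces the genome byte for byte", {
  g1 <- synth_genome(2, 50000, 6, seed = 9)
  g2 <- synth_genome(2, 50000, 6, seed = 9)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  g3 <- synth_genome(2, 50000, 6, seed = 10)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("every planted mature occurs at its truth locus and nowhere outside its hairpin", {
  g <- synth_genome(1, 100000, 10, seed = 2)
  for (i in seq_len(10)) {
    pat <- Biostrings::DNAString(g$truth$mature_seq[i])
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, g$genome[[1]]))
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), g$genome[[1]]))
    stated <- if (g$truth$strand[i] == "+") fwd else rev
    expect_true(g$truth$start[i] %in% stated, info = g$truth$name[i])
    # any second occurrence is the mature's own star arm, inside the
    # hairpin span; nothing in the background may contain the mature
    outside <- setdiff(c(fwd, rev),
                       seq(g$truth$hairpin_start[i] - 25,
                           g$truth$hairpin_end[i] + 25))
    expect_equal(length(outside), 0, info = g$truth$name[i])
  }
})

test_that("too many hairpins for the chromosome is a capacity error", {
  expect_error(synth_genome(1, 1000, 50, seed = 1), "capacity")
})

test_that("treated/control count ratio approaches the planted fold change", {
  tr <- synth_null_truth(40, seed = 3)
  tr <- with_de_truth(tr, baseline = 100, fold_change = 4, seed = 3)
  libs <- synth_libraries(tr, depth = 1e5, dispersion = 0, seed = 4,
                          background_fraction = 0.2)
  counts <- tidyr::pivot_wider(libs$planted_counts[c("name", "library",
                                                     "count")],
                               names_from = "library",
                               values_from = "count")
  ratio <- sum(counts$Cd1) / sum(counts$C1)
  expect_equal(ratio, 4, tolerance = 0.05)
  # and the scale factor fills the planted share of the depth
  expect_equal(sum(counts$C1), 8e4, tolerance = 0.05)
})

test_that("library generation is deterministic down to the FASTQ bytes", {
  tr <- with_de_truth(synth_null_truth(20, seed = 5), baseline = 50, seed = 5)
  mk <- function() {
    libs <- synth_libraries(tr, depth = 1.2e4, seed = 6)
    d <- tempfile()
    write_fastq(libs$reads, d)
    unname(vapply(sort(list.files(d)), function(f)
      unname(tools::md5sum(file.path(d, f))), character(1)))
  }
  expect_identical(mk(), mk())
})

test_that("insufficient depth for a planted miRNA warns but continues", {
  # relative baseline 0.1 of ~4000 total: scaled mean ~0.2 reads at 1e4 depth
  tr <- with_de_truth(synth_null_truth(5, seed = 7),
                      baseline = c(0.1, 1000, 1000, 1000, 1000), seed = 7)
  expect_warning(out <- synth_libraries(tr, depth = 1e4, seed = 8), "depth")
  expect_equal(sort(unique(out$reads$library)), c("C0", "C1", "Cd1"))
})

test_that("reads carry the adapter and miRNA-sized inserts dominate", {
  tr <- with_de_truth(synth_null_truth(30, seed = 11), baseline = 100,
                      seed = 11)
  libs <- synth_libraries(tr, depth = 2e4, seed = 12)
  r <- libs$reads$sequence[libs$reads$library == "C1"]
  expect_true(all(nchar(r) == 36))
  trimmed <- trim_adapter(r)
  expect_gt(mean(!is.na(trimmed)), 0.95)
  lens <- nchar(trimmed[!is.na(trimmed)])
  expect_gt(mean(lens >= 20 & lens <= 24), 0.6)
})

test_that("planted target sites score exactly as recorded", {
  set.seed(13)
  mk_mir <- function() paste0(random_dna_str(14, 0.5), "G",
                              random_dna_str(6, 0.5))  # G at 15 for gu edits
  mirs <- stats::setNames(c(mk_mir(), mk_mir()), c("mA", "mB"))
  tx <- synth_transcriptome(mirs, n_transcripts = 6, sites_per_mirna = 3,
                            mismatch_plan = list(list(),
                                                 list(list(15, "gu")),
                                                 list(list(5, "mismatch"))),
                            seed = 14)
  tt <- tx$targets
  expect_equal(tt$expected_expectation[tt$n_mismatch + tt$n_gu == 0], c(0, 0))
  expect_equal(tt$expected_expectation[tt$n_gu == 1], c(0.5, 0.5))
  expect_equal(tt$expected_expectation[tt$n_mismatch == 1], c(2, 2))
  # truth re-derivable: the recorded site is where the scanner finds it
  hits <- scan_targets_expectation(mirs, tx$transcripts)
  key <- paste(hits$mirna, hits$transcript_id, hits$site_start)
  expect_true(all(paste(tt$mirna, tt$transcript_id, tt$site_start) %in% key))
})

test_that("invalid edit plans are rejected", {
  mir <- c(m = "ACGTACGTACGTACGTACGTA")
  expect_error(synth_transcriptome(mir, 1, 1,
                                   mismatch_plan = list(list(list(25, "mismatch"))),
                                   seed = 1),
               "outside")
  expect_error(synth_transcriptome(mir, 1, 1,
                                   mismatch_plan = list(list(list(1, "gu"))),
                                   seed = 1),
               "G or T")
})

test_that("degradome peak fraction concentrates tags at the cleavage site", {
  set.seed(15)
  mir <- random_dna_str(21, 0.5)
  tx <- synth_transcriptome(c(m = mir), 1, 1, seed = 16)
  deg <- synth_degradome(tx$targets, peak_fraction = 1, n_libraries = 1,
                         depth = 5000, seed = 17)
  expect_equal(nrow(deg), 1)
  expect_equal(deg$position, tx$targets$true_cleavage_pos)
  expect_equal(deg$count, 5000L)
  deg2 <- synth_degradome(tx$targets, peak_fraction = 0.5, n_libraries = 2,
                          depth = 5000, seed = 18)
  expect_identical(deg2, synth_degradome(tx$targets, 0.5, 2, 5000, seed = 18))
})
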