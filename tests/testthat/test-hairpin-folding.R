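test_that("forced structures fold to their model energies", {
  # six GC pairs closing a 3-nt loop: 6 * (-3) + 3
  hp <- fold_best_hairpin(paste0("GGGGGG", "AAA", "CCCCCC"))
  expect_equal(hp$mfe, -15)
  expect_equal(nrow(hp$pairs), 6)
  expect_equal(hp$dot_bracket, "((((((...))))))")
  expect_equal(hp$loop_span, c(7L, 9L))

  # nothing can pair: empty structure at zero energy
  empty <- fold_best_hairpin(strrep("A", 20))
  expect_equal(empty$mfe, 0)
  expect_equal(nrow(empty$pairs), 0)

  # weaker AT stem: 6 * (-2) + 3
  expect_equal(fold_best_hairpin(paste0("AAAAAA", "CCC", "TTTTTT"))$mfe, -9)
})

test_that("input validation rejects bad alphabets and lengths", {
  expect_error(fold_best_hairpin(paste0("ACGTN", strrep("A", 15))),
               "outside")
  expect_error(fold_best_hairpin("ACGT"), "length")
  expect_error(fold_best_hairpin(strrep("ACGT", 150)), "length")
})

test_that("dynamic program equals exhaustive stem-loop enumeration", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(15:24, 1)
    s <- random_dna_str(n, gc = runif(1, 0.3, 0.7))
    expect_equal(fold_best_hairpin(s)$mfe, oracle_fold_mfe(s), info = s)
  }
})

test_that("folding is symmetric under sequence reversal", {
  # reversal maps every pair (i, j) to (n+1-j, n+1-i) with the same bases
  # swapped, so all pair energies (including G:U wobbles) are preserved.
  # Note reverse-COMPLEMENT symmetry does not hold for a wobble-aware
  # model: complementation maps a G.T pair to the unpairable A.C.
  set.seed(7)
  for (rep in 1:25) {
    s <- random_dna_str(sample(20:60, 1))
    rev <- stringi::stri_reverse(s)
    expect_equal(fold_best_hairpin(s)$mfe, fold_best_hairpin(rev)$mfe,
                 info = s)
  }
  # reverse-complement symmetry does hold on wobble-free alphabets
  for (rep in 1:10) {
    s <- paste(sample(c("G", "C", "A"), 40, TRUE,
                      prob = c(0.3, 0.3, 0.4)), collapse = "")
    s <- chartr("A", "C", s)  # {G, C} only: GC/CG pairs alone possible
    rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", s))
    expect_equal(fold_best_hairpin(s)$mfe, fold_best_hairpin(rc)$mfe)
  }
})

test_that("closing a passing hairpin with a GC pair never raises the mfe", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna_str(sample(20:50, 1))
    expect_lte(fold_best_hairpin(paste0("G", s, "C"))$mfe,
               fold_best_hairpin(s)$mfe)
  }
})

test_that("pair lists are valid single stem-loops", {
  set.seed(5)
  for (rep in 1:25) {
    hp <- fold_best_hairpin(random_dna_str(sample(30:80, 1)))
    p <- hp$pairs
    if (nrow(p) == 0) next
    expect_true(all(p[, 2] - p[, 1] >= 4))
    if (nrow(p) > 1) {
      # nested ladder: i ascending while j descending
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) < 0))
    }
    valid <- c("AT", "TA", "GC", "CG", "GT", "TG")
    expect_true(all(paste0(substring(hp$sequence, p[, 1], p[, 1]),
                           substring(hp$sequence, p[, 2], p[, 2])) %in% valid))
  }
})

test_that("mfei arithmetic follows its definition", {
  fake <- list(mfe = -40, sequence = strrep("GCAT", 25))  # 100 nt, 50% GC
  ev <- compute_mfei(fake)
  expect_equal(ev$amfe, 40)
  expect_equal(ev$gc_percent, 50)
  expect_equal(ev$mfei, 0.8)

  expect_equal(compute_mfei(list(mfe = -45,
                                 sequence = paste0(strrep("GC", 22),
                                                   strrep("AT", 28))))$mfei,
               45 / 44, tolerance = 1e-12)
  expect_equal(compute_mfei(list(mfe = 0, sequence = "GCGC"))$mfei, 0)
  expect_error(compute_mfei(list(mfe = -5, sequence = "ATATAT")), "degenerate")
})

test_that("planted precursors pass evaluation and decoys fail as designed", {
  g <- synth_genome(1, 60000, 3, seed = 21)
  for (i in 1:3) {
    loci <- map_to_genome(g$truth$mature_seq[i], g$genome)
    ev <- evaluate_precursor(g$genome, loci[1, ], g$truth$mature_seq[i])
    expect_true(ev$passes, info = g$truth$name[i])
    expect_gte(ev$mfei, 0.85)
    expect_lte(ev$mfe, -18)
  }

  # an all-A "mature" in an unstructured region cannot pass
  chrom <- as.character(g$genome[[1]])
  tagseq <- substr(chrom, 300, 320)
  ev <- evaluate_precursor(
    g$genome, tibble::tibble(chrom = "chr1", strand = "+",
                             start = 300, end = 320), tagseq)
  expect_false(ev$passes)

  # mfei threshold is binding: raise it beyond the observed value
  loci <- map_to_genome(g$truth$mature_seq[1], g$genome)
  ev_ok <- evaluate_precursor(g$genome, loci[1, ], g$truth$mature_seq[1])
  th <- precursor_thresholds(min_mfei = ev_ok$mfei + 0.1)
  ev2 <- evaluate_precursor(g$genome, loci[1, ], g$truth$mature_seq[1], th)
  expect_false(ev2$passes)
})

test_that("a mature spanning the terminal loop fails the arm criterion", {
  # hairpin with the "mature" centred on the loop
  arm <- "GCGCGGCAGGCTAGCCGGCATGCCGGCTAGCCTGCCGCGC"
  stem <- paste0(arm, "AAAAAA", stringi::stri_reverse(chartr("ACGT", "TGCA", arm)))
  hp <- fold_best_hairpin(stem)
  mid <- nchar(stem) / 2
  ev <- xylemiR:::.evaluate_window(hp, mid - 10, mid + 10,
                                   precursor_thresholds())
  expect_false(ev$mature_on_one_arm)
  expect_false(ev$passes)
})
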