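test_that("Fisher two-sided p matches hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 50, 5, 50), 1)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
})

test_that("Fisher p is invariant to row and column swaps and in (0, 1]", {
  set.seed(4)
  for (rep in 1:50) {
    t4 <- rpois(4, 8)
    p <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher_exact_2x2(t4[3], t4[4], t4[1], t4[2]))
    expect_equal(p, fisher_exact_2x2(t4[2], t4[1], t4[4], t4[3]))
  }
})

test_that("Fisher agrees with stats::fisher.test and full enumeration", {
  set.seed(14)
  for (rep in 1:40) {
    t4 <- rpois(4, 10)
    p <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
    pf <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
    expect_equal(p, pf, tolerance = 1e-9, info = paste(t4, collapse = ","))
  }
  # enumeration oracle on a band of small configurations
  for (m in c(3, 7, 12)) for (n in c(4, 9)) for (k in 2:min(m + n, 10)) {
    lo <- max(0, k - n); hi <- min(k, m)
    a <- lo:hi
    mine <- fisher_exact_2x2(a, k - a, m - a, n - k + a)
    expect_equal(mine, oracle_fisher_config(m, n, k), tolerance = 1e-12)
  }
})

test_that("chi-squared matches the closed form and stats::chisq.test", {
  res <- chisq_2x2(10, 990, 40, 960)
  expect_equal(res$statistic, 225 * (2 / 25 + 2 / 975), tolerance = 1e-12)
  expect_equal(res$p_value, 1.7e-5, tolerance = 0.05)
  ct <- stats::chisq.test(matrix(c(10, 990, 40, 960), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)

  expect_equal(chisq_2x2(5, 50, 5, 50)$statistic, 0)
  expect_equal(chisq_2x2(5, 50, 5, 50)$p_value, 1)
  # Yates correction can only raise the p-value
  expect_gt(chisq_2x2(3, 7, 7, 3, yates = TRUE)$p_value,
            chisq_2x2(3, 7, 7, 3)$p_value)
  expect_error(chisq_2x2(0, 0, 5, 5), "expected")
})

test_that("pairwise DE reproduces printed-scale fold changes", {
  tags <- make_tags(c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"),
                    list(c(31L, 10L), c(31L, 10L), c(73L, 1L)))
  tags <- normalize_counts(tags, lib_totals = c(C0 = 1e6, C1 = 1e6,
                                                Cd1 = 1e6))
  de <- pairwise_de(tags, c("C1", "Cd1"))
  # norm 31 -> 73 and 10 -> 1 on the printed scale
  expect_equal(de$log2fc[1], log2(73 / 31), tolerance = 1e-12)
  expect_lt(abs(de$log2fc[1] - 1.23), 0.01)   # printed-scale agreement
  expect_equal(de$log2fc[2], log2(1 / 10), tolerance = 1e-12)
  expect_lt(abs(de$log2fc[2] - (-3.34)), 0.02)
  expect_equal(de$status[1], "up")
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
})

test_that("equal normalized counts give zero fold change and no call", {
  tags <- make_tags("ACGTACGTACGTACGTACGTA", list(50L, 40L, 40L))
  tags <- normalize_counts(tags, lib_totals = c(C0 = 1e5, C1 = 1e5,
                                                Cd1 = 1e5))
  de <- pairwise_de(tags, c("C1", "Cd1"))
  expect_equal(de$log2fc, 0)
  expect_equal(de$status, "none")
})

test_that("reversing the comparison negates log2fc", {
  set.seed(8)
  tags <- make_tags(vapply(1:20, function(i) random_dna_str(21), character(1)),
                    list(rpois(20, 30), rpois(20, 30) + 1L, rpois(20, 60) + 1L))
  tags <- normalize_counts(tags)
  fwd <- pairwise_de(tags, c("C1", "Cd1"))
  rev <- pairwise_de(tags, c("Cd1", "C1"))
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-9)
})

test_that("method selection follows the expected-count rule", {
  tags <- make_tags(c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"),
                    list(c(100L, 2L), c(100L, 2L), c(200L, 3L)))
  tags <- normalize_counts(tags, lib_totals = c(C0 = 1e4, C1 = 1e4,
                                                Cd1 = 1e4))
  de <- pairwise_de(tags, c("C1", "Cd1"))
  expect_equal(de$method, c("chisq", "fisher"))
  de_f <- pairwise_de(tags, c("C1", "Cd1"), method = "fisher")
  expect_true(all(de_f$method == "fisher"))
})

test_that("the pseudocount only touches zero sides", {
  tags <- make_tags(c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"),
                    list(c(0L, 4L), c(0L, 4L), c(8L, 0L)))
  tags <- normalize_counts(tags, lib_totals = c(C0 = 1e6, C1 = 1e6,
                                                Cd1 = 1e6))
  de <- pairwise_de(tags, c("C1", "Cd1"))
  expect_equal(de$log2fc[1], log2(8 / 0.5))
  expect_equal(de$log2fc[2], log2(0.5 / 4))
})

test_that("BH adjustment is optional and only makes calls more conservative", {
  set.seed(21)
  n <- 50
  tags <- make_tags(vapply(seq_len(n), function(i) random_dna_str(21),
                           character(1)),
                    list(rpois(n, 40), rpois(n, 40) + 1L,
                         as.integer(rpois(n, 40) * sample(c(1, 4), n, TRUE)) + 1L))
  tags <- normalize_counts(tags)
  raw <- pairwise_de(tags, c("C1", "Cd1"))
  adj <- pairwise_de(tags, c("C1", "Cd1"), adjust = "BH")
  expect_false("p_adjusted" %in% names(raw))
  expect_true(all(adj$p_adjusted >= adj$p_value))
  expect_true(all(adj$status == "none" | raw$status != "none"))
})

test_that("regulation classes de-duplicate miRNA names across loci", {
  de <- tibble::tibble(
    name = c("miR-a", "miR-a", "miR-b", "miR-c"),
    log2fc = c(2, 2, -3, 0.2), p_value = c(0.01, 0.01, 0.001, 0.5),
    status = c("up", "up", "down", "none"))
  reg <- classify_regulation(de)
  expect_equal(reg$up$name, "miR-a")
  expect_equal(reg$down$name, "miR-b")
  empty <- classify_regulation(de[0, ])
  expect_equal(nrow(empty$up) + nrow(empty$down), 0)
})

test_that("under a Poisson null the DE call rate stays at the nominal level", {
  set.seed(101)
  n <- 800
  mu <- exp(runif(n, log(3), log(300)))
  tags <- make_tags(vapply(seq_len(n), function(i) random_dna_str(21),
                           character(1)),
                    list(rpois(n, mu), rpois(n, mu), rpois(n, mu)))
  tags <- normalize_counts(tags, lib_totals = c(C0 = 1e6, C1 = 1e6,
                                                Cd1 = 1e6))
  de <- pairwise_de(tags, c("C1", "Cd1"))
  rate <- mean(de$status != "none")
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
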