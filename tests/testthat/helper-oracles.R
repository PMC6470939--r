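# Independent oracles used to validate the dynamic programs and exact tests.
# Each is written directly from the model definition, with none of the
# production code's optimizations.

# --- single stem-loop folding: direct O(n^4) recursion over the model -----
# D(i, j) = pair(i, j) + min( +3 terminal loop  [j - i - 1 >= 3],
#                             min over inner pair (k, l):
#                               D(k, l) + 0.5 * ((k-i-1) + (j-l-1)) )
oracle_fold_mfe <- function(seq) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  pe <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1, NA_real_)
  }
  D <- matrix(NA_real_, n, n)
  for (span in 4:(n - 1)) {
    if (span > n - 1) break
    for (i in seq_len(n - span)) {
      j <- i + span
      p <- pe(s[i], s[j])
      if (is.na(p)) next
      best <- 3  # close the terminal loop
      if (span > 4) {
        ks <- (i + 1):(j - 1)
        sub <- D[ks, ks, drop = FALSE] +
          outer(ks - i - 1, j - ks - 1, "+") * 0.5
        m2 <- suppressWarnings(min(sub, na.rm = TRUE))
        if (is.finite(m2) && m2 < best) best <- m2
      }
      D[i, j] <- p + best
    }
  }
  m <- suppressWarnings(min(D, na.rm = TRUE))
  min(0, m)
}

# --- scheme-A scanning: enumerate every gapped alignment -------------------
# gaps only at interior miRNA positions, never opposite banned positions;
# returns the minimum expectation of the miRNA against any window of the
# transcript (same alignment space as the scanner).
oracle_scan_min <- function(mirna, transcript, max_gaps = 2L,
                            seed_range = c(2L, 13L), seed_factor = 2,
                            w_gu = 0.5, w_mm = 1, w_gap = 2,
                            banned = c(10L, 11L)) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  m <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  seedmul <- ifelse(seq_len(L) >= seed_range[1] & seq_len(L) <= seed_range[2],
                    seed_factor, 1)
  pair_w <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(0)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(w_gu)
    w_mm
  }
  gap_ok <- setdiff(2:(L - 1), banned)
  gap_sets <- list(integer(0))
  if (max_gaps >= 1) for (g in gap_ok) gap_sets[[length(gap_sets) + 1]] <- g
  if (max_gaps >= 2 && length(gap_ok) >= 2) {
    cmb <- utils::combn(gap_ok, 2)
    for (c2 in seq_len(ncol(cmb)))
      gap_sets[[length(gap_sets) + 1]] <- cmb[, c2]
  }
  best <- Inf
  for (gs in gap_sets) {
    consumed <- L - length(gs)
    if (consumed > Tn) next
    for (j in consumed:Tn) {        # site_end
      sc <- 0
      tpos <- j
      for (p in seq_len(L)) {
        if (p %in% gs) {
          sc <- sc + w_gap * seedmul[p]
        } else {
          sc <- sc + pair_w(m[p], tx[tpos]) * seedmul[p]
          tpos <- tpos - 1
        }
        if (sc >= best) break
      }
      if (sc < best) best <- sc
    }
  }
  best
}

# --- two-sided Fisher p: exact integer enumeration at fixed margins --------
# configuration (m, n, k) = (col1 total, col2 total, row1 total)
oracle_fisher_config <- function(m, n, k) {
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  w <- choose(m, x) * choose(n, k - x)   # exact integers for margins <= 30
  tot <- sum(w)
  vapply(seq_along(x), function(i) sum(w[w <= w[i]]) / tot, numeric(1))
}

# --- misc ------------------------------------------------------------------
random_dna_str <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a tiny processed-tags tibble built by hand (bypasses read simulation)
make_tags <- function(seqs, counts, libs = c("C0", "C1", "Cd1")) {
  tb <- tibble::tibble(sequence = seqs, length = nchar(seqs))
  for (i in seq_along(libs)) tb[[paste0("raw_", libs[i])]] <- counts[[i]]
  attr(tb, "libraries") <- libs
  class(tb) <- c("xylem_tags", class(tb))
  tb
}
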