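#' Generate a synthetic transcriptome with planted miRNA target sites
#'
#' Builds random cDNA-like transcripts and embeds, for each miRNA,
#' `sites_per_mirna` target sites: the reverse complement of the miRNA with
#' a planned set of edits applied at stated miRNA positions.  Supported edit
#' kinds are `"mismatch"` (a base pairing neither Watson-Crick nor wobble),
#' `"gu"` (turn the pair into a G:U wobble; only valid where the miRNA base
#' is G or T/U), and `"bulge"` (delete the site base opposite that miRNA
#' position, producing a gap column).  Each site is placed on its own
#' transcript (cycling through transcripts); transcripts beyond the planted
#' set are decoys.  The truth table records the expected expectation and
#' penalty scores of each planted site under the default scanning schemes,
#' and the canonical cleavage position (the transcript base pairing miRNA
#' position 10).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param n_transcripts Total transcripts (>= number of planted sites to
#'   keep one site per transcript; extra transcripts are decoys).
#' @param sites_per_mirna Planted sites per miRNA (default 1).
#' @param mismatch_plan A list of per-site edit plans cycled over sites;
#'   each element is a list of `(position, kind)` pairs, e.g.
#'   `list(list(15, "gu"), list(20, "mismatch"))`; `list()` plants a
#'   perfect site.
#' @param seed Integer seed.
#' @param transcript_length Length of every transcript (default 500, >= 200).
#' @return A list: `transcripts` (named character vector, ids
#'   `SYNTG<k>_T01`) and `targets` (truth tibble: `mirna`,
#'   `transcript_id`, `site_start`, `site_end`, `n_mismatch`, `n_gu`,
#'   `n_gap`, `pairing`, `expected_expectation`, `expected_penalty`,
#'   `true_cleavage_pos`, `transcript_len`).
#' @export
synth_transcriptome <- function(mirnas, n_transcripts,
                                sites_per_mirna = 1L,
                                mismatch_plan = list(list()),
                                seed = 1L, transcript_length = 500L) {
  stopifnot(transcript_length >= 200L)
  mirnas <- prep_named_seqs(mirnas, "miRNA")
  set.seed(as.integer(seed))
  n_sites <- length(mirnas) * sites_per_mirna
  if (n_transcripts < n_sites) {
    stop("need at least one transcript per planted site", call. = FALSE)
  }
  ids <- sprintf("SYNTG%03d_T01", seq_len(n_transcripts))
  transcripts <- stats::setNames(
    vapply(seq_len(n_transcripts), function(i)
      random_dna(transcript_length, 0.45), character(1)), ids)

  build_site <- function(mirna, plan) {
    L <- nchar(mirna)
    mvec <- strsplit(mirna, "")[[1]]
    comp <- chartr("ACGT", "TGCA", mvec)      # site base pairing position p
    pairing <- rep("|", L)
    keep <- rep(TRUE, L)
    for (ed in plan) {
      p <- as.integer(ed[[1]]); kind <- ed[[2]]
      if (p < 1 || p > L) stop("edit position outside miRNA length",
                               call. = FALSE)
      if (kind == "mismatch") {
        bad <- setdiff(.dna_bases, c(comp[p],
                                     if (mvec[p] == "G") "T",
                                     if (mvec[p] == "T") "G"))
        comp[p] <- sample(bad, 1)
        pairing[p] <- "."
      } else if (kind == "gu") {
        if (mvec[p] == "G") comp[p] <- "T"
        else if (mvec[p] == "T") comp[p] <- "G"
        else stop("gu edit needs a G or T/U miRNA base at position ", p,
                  call. = FALSE)
        pairing[p] <- "o"
      } else if (kind == "bulge") {
        keep[p] <- FALSE
        pairing[p] <- "-"
      } else stop("unknown edit kind: ", kind, call. = FALSE)
    }
    # site runs 5'->3' on the transcript: miRNA position L pairs site_start
    site <- paste(rev(comp[keep]), collapse = "")
    list(site = site, pairing = paste(pairing, collapse = ""),
         n_mismatch = sum(pairing == "."), n_gu = sum(pairing == "o"),
         n_gap = sum(pairing == "-"))
  }

  targets <- list()
  si <- 0L
  for (m in names(mirnas)) {
    for (s in seq_len(sites_per_mirna)) {
      si <- si + 1L
      plan <- mismatch_plan[[(si - 1L) %% length(mismatch_plan) + 1L]]
      bs <- build_site(mirnas[[m]], plan)
      tid <- ids[si]
      slen <- nchar(bs$site)
      pos <- sample(seq(40L, transcript_length - slen - 40L), 1)
      transcripts[[tid]] <- paste0(
        substr(transcripts[[tid]], 1L, pos - 1L), bs$site,
        substr(transcripts[[tid]], pos + slen, transcript_length))
      site_start <- pos
      site_end <- pos + slen - 1L
      # transcript base pairing miRNA position 10, walked over gap columns
      pv <- strsplit(bs$pairing, "")[[1]]
      consumed <- cumsum(pv != "-")
      cleave <- site_end - (consumed[10] - 1L)
      exp_a <- expectation_score(bs$pairing)
      exp_b <- if (bs$n_gap == 0)
        expectation_score(bs$pairing, seed_range = c(2L, 17L)) else NA_real_
      targets[[si]] <- tibble::tibble(
        mirna = m, transcript_id = tid,
        site_start = as.integer(site_start), site_end = as.integer(site_end),
        n_mismatch = bs$n_mismatch, n_gu = bs$n_gu, n_gap = bs$n_gap,
        pairing = bs$pairing,
        expected_expectation = exp_a, expected_penalty = exp_b,
        true_cleavage_pos = as.integer(cleave),
        transcript_len = as.integer(transcript_length))
    }
  }
  targets <- dplyr::bind_rows(targets)
  if (any(duplicated(targets[c("transcript_id", "site_start")]))) {
    stop("planted sites overlap", call. = FALSE)
  }
  attr(targets, "seed") <- as.integer(seed)
  list(transcripts = transcripts, targets = targets)
}

#' Simulate degradome (PARE) tag-count tables
#'
#' For each planted target, a fraction `peak_fraction` of that transcript's
#' degradome 5'-end tags falls exactly at the true cleavage position; the
#' remaining tags are uniform over the transcript.  `n_libraries`
#' independent libraries are drawn, each with `depth` tags split evenly
#' across the target transcripts.
#'
#' @param targets Truth tibble from [synth_transcriptome()] (needs
#'   `transcript_id`, `true_cleavage_pos`, `transcript_len`).
#' @param peak_fraction Fraction of tags at the cleavage site, in (0, 1].
#'   0 is allowed and yields pure-uniform (null) libraries.
#' @param n_libraries Number of degradome libraries (default 3).
#' @param depth Total tags per library (default 10000).
#' @param seed Integer seed.
#' @return A tibble: `library`, `transcript_id`, `position`, `count`.
#' @export
synth_degradome <- function(targets, peak_fraction = 0.8, n_libraries = 3L,
                            depth = 10000L, seed = 1L) {
  stopifnot(peak_fraction >= 0, peak_fraction <= 1)
  set.seed(as.integer(seed))
  trs <- dplyr::distinct(targets, .data$transcript_id, .data$transcript_len)
  per <- max(1L, floor(depth / nrow(trs)))
  out <- list()
  for (l in seq_len(n_libraries)) {
    lib <- sprintf("deg%d", l)
    for (i in seq_len(nrow(trs))) {
      tid <- trs$transcript_id[i]
      tlen <- trs$transcript_len[i]
      peaks <- targets$true_cleavage_pos[targets$transcript_id == tid]
      n_peak <- stats::rbinom(1, per, peak_fraction)
      # peak tags split evenly over this transcript's true sites
      peak_pos <- if (length(peaks) && n_peak > 0)
        peaks[1L + (seq_len(n_peak) - 1L) %% length(peaks)] else integer(0)
      unif_pos <- sample.int(tlen, per - n_peak, replace = TRUE)
      cnt <- table(c(peak_pos, unif_pos))
      out[[length(out) + 1L]] <- tibble::tibble(
        library = lib, transcript_id = tid,
        position = as.integer(names(cnt)), count = as.integer(cnt))
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$library, .data$transcript_id, .data$position)
}
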