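#' Expectation score of a miRNA/target pairing string
#'
#' Additive complementarity penalty over miRNA positions (5' to 3'):
#' Watson-Crick match 0, G:U wobble 0.5, mismatch 1, gap 2, each doubled
#' when the miRNA position falls inside the seed window (positions 2-13 by
#' default).  Lower is better; a perfect complement scores 0.
#'
#' @param pairing String over `|` (WC), `o` (G:U), `.` (mismatch), `-`
#'   (gap), one symbol per miRNA position from the 5' end.
#' @param seed_range Two integers, the doubled window (default `c(2, 13)`).
#' @param seed_factor Multiplier inside the seed (default 2).
#' @param weights Named list `mismatch`, `gu`, `gap`.
#' @return A single numeric score.
#' @examples
#' expectation_score("||||||||||||||o||||||")  # 0.5: one wobble at pos 15
#' @export
expectation_score <- function(pairing, seed_range = c(2L, 13L),
                              seed_factor = 2,
                              weights = list(mismatch = 1, gu = 0.5, gap = 2)) {
  sym <- strsplit(pairing, "")[[1]]
  bad <- setdiff(unique(sym), c("|", "o", ".", "-"))
  if (length(bad)) stop("unknown pairing symbol: ", bad[1], call. = FALSE)
  w <- c("|" = 0, "o" = weights$gu, "." = weights$mismatch, "-" = weights$gap)
  v <- unname(w[sym])
  pos <- seq_along(sym)
  v[pos >= seed_range[1] & pos <= seed_range[2]] <-
    v[pos >= seed_range[1] & pos <= seed_range[2]] * seed_factor
  sum(v)
}

# shared scan core; returns all windows under the cutoff, then greedy
# non-overlap selection best-first (score, then site_start)
.scan_scheme <- function(mirna, transcript, cutoff, max_gaps,
                         seed_range, seed_factor, weights, gap_banned) {
  hits <- .scan_sites_cpp(mirna, transcript, cutoff, as.integer(max_gaps),
                          as.integer(seed_range[1]), as.integer(seed_range[2]),
                          seed_factor, weights$gu, weights$mismatch,
                          weights$gap %||% 2, as.integer(gap_banned))
  hits <- tibble::as_tibble(hits)
  if (!nrow(hits)) return(hits[0, ])
  hits <- dplyr::arrange(hits, .data$score, .data$site_start)
  taken <- logical(0); keep <- integer(0)
  occupied <- rep(FALSE, nchar(transcript))
  for (i in seq_len(nrow(hits))) {
    span <- hits$site_start[i]:hits$site_end[i]
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep <- c(keep, i)
    }
  }
  dplyr::arrange(hits[keep, ], .data$site_start)
}

.inhibition <- function(pairing) {
  core <- substring(pairing, 9, 11)
  ifelse(core == "|||", "Cleavage", "Translation")
}

#' Scan transcripts for miRNA target sites (expectation scheme)
#'
#' Aligns each miRNA antiparallel against every transcript window (the
#' miRNA's 5' end pairs the site's 3' end) by dynamic programming,
#' minimising the expectation score of [expectation_score()].  Gaps are
#' miRNA positions opposite a deletion in the site; at most `max_gaps` are
#' allowed and none opposite miRNA positions 10-11 (the cleavage-defining
#' duplex core).  All non-overlapping sites with expectation at or below
#' `cutoff` are reported best-first.  The inhibition mode is `Cleavage`
#' when miRNA positions 9-11 are all Watson-Crick paired, else
#' `Translation`.
#'
#' @param mirnas Named character vector of miRNA sequences (DNA or RNA).
#' @param transcripts Named character vector / `DNAStringSet` of cDNAs.
#' @param cutoff Maximum reported expectation (default 5).
#' @param max_gaps Maximum gap columns per site (default 2).
#' @param seed_range,seed_factor,weights See [expectation_score()].
#' @return A `target_hits` tibble: `mirna`, `transcript_id`, `site_start`,
#'   `site_end`, `expectation`, `n_gap`, `pairing`, `inhibition`.
#' @export
scan_targets_expectation <- function(mirnas, transcripts, cutoff = 5,
                                     max_gaps = 2L,
                                     seed_range = c(2L, 13L), seed_factor = 2,
                                     weights = list(mismatch = 1, gu = 0.5,
                                                    gap = 2)) {
  mirnas <- prep_named_seqs(mirnas, "miRNA")
  transcripts <- prep_named_seqs(transcripts, "transcript")
  out <- list()
  for (m in names(mirnas)) {
    for (tr in names(transcripts)) {
      if (nchar(transcripts[[tr]]) < nchar(mirnas[[m]])) next
      hits <- .scan_scheme(mirnas[[m]], transcripts[[tr]], cutoff, max_gaps,
                           seed_range, seed_factor, weights,
                           gap_banned = c(10L, 11L))
      if (nrow(hits)) {
        hits$mirna <- m; hits$transcript_id <- tr
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(site_start = integer(0), site_end = integer(0),
                   score = numeric(0), n_gap = integer(0),
                   pairing = character(0), mirna = character(0),
                   transcript_id = character(0))
  res <- dplyr::rename(res, expectation = "score")
  res$inhibition <- .inhibition(res$pairing)
  res <- res[c("mirna", "transcript_id", "site_start", "site_end",
               "expectation", "n_gap", "pairing", "inhibition")]
  class(res) <- c("target_hits", class(res))
  res
}

#' Scan transcripts for miRNA target sites (gapless penalty scheme)
#'
#' An independent, gapless complementarity scheme: penalties mismatch 1 and
#' G:U 0.5, doubled over miRNA positions 2-17, no gaps; sites with penalty
#' at or below `cutoff` (default 2.5, a "moderate" stringency) are
#' reported.  Running both schemes and intersecting their calls (see
#' [intersect_predictions()]) is substantially more specific than either
#' alone.
#'
#' @inheritParams scan_targets_expectation
#' @param cutoff Maximum reported penalty (default 2.5).
#' @param seed_range Doubled window (default `c(2, 17)`).
#' @return A `target_hits` tibble with column `penalty_b` in place of
#'   `expectation`.
#' @export
scan_targets_penalty <- function(mirnas, transcripts, cutoff = 2.5,
                                 seed_range = c(2L, 17L), seed_factor = 2,
                                 weights = list(mismatch = 1, gu = 0.5)) {
  mirnas <- prep_named_seqs(mirnas, "miRNA")
  transcripts <- prep_named_seqs(transcripts, "transcript")
  out <- list()
  for (m in names(mirnas)) {
    for (tr in names(transcripts)) {
      if (nchar(transcripts[[tr]]) < nchar(mirnas[[m]])) next
      hits <- .scan_scheme(mirnas[[m]], transcripts[[tr]], cutoff,
                           max_gaps = 0L, seed_range, seed_factor,
                           weights = c(weights, list(gap = 2)),
                           gap_banned = integer(0))
      if (nrow(hits)) {
        hits$mirna <- m; hits$transcript_id <- tr
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(site_start = integer(0), site_end = integer(0),
                   score = numeric(0), n_gap = integer(0),
                   pairing = character(0), mirna = character(0),
                   transcript_id = character(0))
  res <- dplyr::rename(res, penalty_b = "score")
  res$inhibition <- .inhibition(res$pairing)
  res <- res[c("mirna", "transcript_id", "site_start", "site_end",
               "penalty_b", "n_gap", "pairing", "inhibition")]
  class(res) <- c("target_hits", class(res))
  res
}

#' Intersect the two target-prediction schemes
#'
#' Keeps (miRNA, transcript) pairs called by both schemes whose sites
#' overlap by at least `min_overlap` of the shorter site, carrying both
#' scores.  When a transcript-to-gene map is available (explicitly, or via
#' the `_Tnn` transcript-id suffix convention), a `gene` column is added
#' for gene-level roll-ups.
#'
#' @param hits_a From [scan_targets_expectation()].
#' @param hits_b From [scan_targets_penalty()].
#' @param min_overlap Minimum fractional site overlap (default 0.5).
#' @param gene_map Optional named character vector, transcript id -> gene id.
#' @return A consensus tibble with both scores and the scheme-A pairing.
#' @export
intersect_predictions <- function(hits_a, hits_b, min_overlap = 0.5,
                                  gene_map = NULL) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(hits_a), tibble::as_tibble(hits_b),
    by = c("mirna", "transcript_id"), suffix = c("_a", "_b"),
    relationship = "many-to-many")
  if (nrow(joined)) {
    ov <- pmin(joined$site_end_a, joined$site_end_b) -
      pmax(joined$site_start_a, joined$site_start_b) + 1
    len <- pmin(joined$site_end_a - joined$site_start_a + 1,
                joined$site_end_b - joined$site_start_b + 1)
    joined <- joined[ov / len >= min_overlap, ]
  }
  out <- tibble::tibble(
    mirna = joined$mirna, transcript_id = joined$transcript_id,
    site_start = joined$site_start_a, site_end = joined$site_end_a,
    expectation = joined$expectation, penalty_b = joined$penalty_b,
    pairing = joined$pairing_a, inhibition = joined$inhibition_a)
  out <- dplyr::distinct(out, .data$mirna, .data$transcript_id,
                         .data$site_start, .keep_all = TRUE)
  out$gene <- transcript_gene(out$transcript_id, gene_map)
  class(out) <- c("target_hits", class(out))
  out
}

#' Transcript-to-gene mapping
#'
#' Uses an explicit map when provided; otherwise applies the id-suffix
#' convention where transcript `GENE_T01` belongs to gene `GENE`.
#'
#' @param transcript_id Character vector of transcript ids.
#' @param gene_map Optional named character vector.
#' @return Character vector of gene ids.
#' @export
transcript_gene <- function(transcript_id, gene_map = NULL) {
  if (!is.null(gene_map)) {
    out <- unname(gene_map[transcript_id])
    out[is.na(out)] <- sub("_T\\d+$", "", transcript_id[is.na(out)])
    return(out)
  }
  sub("_T\\d+$", "", transcript_id)
}

#' Target-site accessibility proxy
#'
#' Energy cost of opening the local structure around a target site: the
#' window site +/- `flank` is folded twice with [fold_best_hairpin()],
#' unconstrained and with the site positions forced unpaired; the
#' difference (constrained minus unconstrained) is returned and is always
#' non-negative.  A proxy for the maximum unpaired energy of a site: 0
#' means the site is predicted accessible.
#'
#' @param transcript A single transcript sequence.
#' @param site_start,site_end 1-based site coordinates.
#' @param flank Window half-width beyond the site (default 17).
#' @return A single non-negative number, or `NA` when the window is shorter
#'   than 15 nt.
#' @export
upe_proxy <- function(transcript, site_start, site_end, flank = 17L) {
  transcript <- dna_norm(transcript)
  lo <- max(1L, site_start - flank)
  hi <- min(nchar(transcript), site_end + flank)
  if (hi - lo + 1L < 15L) return(NA_real_)
  win <- substr(transcript, lo, hi)
  mask <- rep(FALSE, nchar(win))
  mask[(site_start - lo + 1L):(site_end - lo + 1L)] <- TRUE
  open <- fold_best_hairpin(win, constraint = mask)$mfe
  free <- fold_best_hairpin(win)$mfe
  open - free
}

prep_named_seqs <- function(x, what) {
  if (inherits(x, "DNAStringSet") || inherits(x, "RNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  x <- stats::setNames(dna_norm(as.character(x)), names(x))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " sequences must be named", call. = FALSE)
  }
  check_dna(x, what)
  x
}
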