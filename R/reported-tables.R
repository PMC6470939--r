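#' Reported cadmium-responsive miRNA table (bundled)
#'
#' The published per-miRNA normalized read counts (C1 untreated 1 h, Cd1
#' cadmium-treated 1 h), printed log2 fold changes and genomic loci of the
#' cadmium-responsive miRNAs from a maize xylem-sap small-RNA survey,
#' bundled as plain TSV for reanalysis.  Counts are normalized reads per
#' million, rounded to integers as printed; one miRNA (zma-miR398a-3p) maps
#' to two loci and therefore appears twice.
#'
#' @return A tibble: `mirna`, `direction`, `c1`, `cd1`, `log2fc`, `chrom`,
#'   `strand`, `start`, `end`, `hairpin_len`.
#' @export
reported_cd_de_mirnas <- function() {
  path <- system.file("extdata", "reported_cd_de_mirnas.tsv",
                      package = "xylemiR", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Reported high-confidence novel miRNA table (bundled)
#'
#' The published high-confidence novel miRNAs of the same survey: per-library
#' normalized counts (c0, c1, cd1), mature sequence, size and MFEI, bundled
#' as plain TSV.  The stated confidence rule is a normalized count of at
#' least 10 in at least one library together with MFEI >= 0.85.
#'
#' @return A tibble: `mirna`, `c0`, `c1`, `cd1`, `sequence`, `size`, `mfei`.
#' @export
reported_novel_mirnas <- function() {
  path <- system.file("extdata", "reported_novel_mirnas.tsv",
                      package = "xylemiR", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Re-analyse a reported normalized-count table for differential expression
#'
#' Applies the pipeline's DE call (|log2FC| >= `min_abs_log2fc` on
#' normalized counts, pseudocount only at zero) to a two-column
#' normalized-count table such as [reported_cd_de_mirnas()], de-duplicating
#' miRNA names across loci.  Because such tables print normalized counts
#' without raw totals, no count-based test is possible; the returned
#' `log2fc` is recomputed from the printed counts.
#'
#' @param tbl A tibble with `mirna`, `c1`, `cd1` columns.
#' @param min_abs_log2fc Fold-change threshold (default 1).
#' @param pseudocount Applied only to zero sides (default 0.5).
#' @return A tibble with `mirna`, `c1`, `cd1`, `log2fc_recomputed`,
#'   `status`, de-duplicated by miRNA.
#' @export
reanalyze_de_table <- function(tbl, min_abs_log2fc = 1, pseudocount = 0.5) {
  a <- ifelse(tbl$c1 == 0, pseudocount, tbl$c1)
  b <- ifelse(tbl$cd1 == 0, pseudocount, tbl$cd1)
  lfc <- log2(b / a)
  out <- tibble::tibble(mirna = tbl$mirna, c1 = tbl$c1, cd1 = tbl$cd1,
                        log2fc_recomputed = lfc,
                        status = dplyr::case_when(
                          lfc >= min_abs_log2fc ~ "up",
                          lfc <= -min_abs_log2fc ~ "down",
                          TRUE ~ "none"))
  dplyr::distinct(out, .data$mirna, .keep_all = TRUE)
}
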