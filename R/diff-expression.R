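#' Normalize per-library tag counts to a common scale
#'
#' Classic counts-per-million scaling: `norm = raw * scale / lib_total`,
#' with library totals taken after contaminant and length filtering.  Values
#' are carried unrounded; rounding is for display only.
#'
#' @param tags A `xylem_tags` tibble (raw count columns `raw_<lib>`).
#' @param lib_totals Named numeric vector of per-library totals; defaults to
#'   the column sums of the raw counts.
#' @param scale Target total (default 1e6, i.e. reads per million).
#' @return `tags` with one `norm_<lib>` column added per library.
#' @export
normalize_counts <- function(tags, lib_totals = NULL, scale = 1e6) {
  libs <- attr(tags, "libraries") %||%
    sub("^raw_", "", grep("^raw_", names(tags), value = TRUE))
  if (is.null(lib_totals)) {
    lib_totals <- vapply(libs, function(l) sum(tags[[paste0("raw_", l)]]),
                         numeric(1))
  }
  if (any(lib_totals <= 0)) stop("zero library total", call. = FALSE)
  for (l in libs) {
    tags[[paste0("norm_", l)]] <-
      tags[[paste0("raw_", l)]] * scale / lib_totals[[l]]
  }
  attr(tags, "lib_totals") <- lib_totals
  tags
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` by summing all
#' hypergeometric outcomes (at fixed margins) whose probability does not
#' exceed that of the observed table, computed in log space.  This is the
#' standard two-sided rule for single-library count comparisons.  All-zero
#' tables return 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cells (vectorized).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell", call. = FALSE)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c[i]          # first-column margin
    nn <- b[i] + d[i]         # second-column margin
    k <- a[i] + b[i]          # first-row margin
    if (m + nn == 0) { p[i] <- 1; next }
    lo <- max(0, k - nn); hi <- min(k, m)
    x <- lo:hi
    lp <- stats::dhyper(x, m, nn, k, log = TRUE)
    obs <- stats::dhyper(a[i], m, nn, k, log = TRUE)
    p[i] <- min(1, sum(exp(lp[lp <= obs + 1e-7])))
  }
  p
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Pearson's chi-squared statistic with 1 degree of freedom, without
#' continuity correction by default (`yates = TRUE` applies the Yates
#' correction).  Intended for tables where all expected counts are at least
#' 5; smaller tables should use [fisher_exact_2x2()].
#'
#' @inheritParams fisher_exact_2x2
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return A tibble with `statistic` and `p_value` (vectorized).
#' @export
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  N <- a + b + c + d
  e11 <- (a + b) * (a + c) / N
  e12 <- (a + b) * (b + d) / N
  e21 <- (c + d) * (a + c) / N
  e22 <- (c + d) * (b + d) / N
  if (any(c(e11, e12, e21, e22) == 0)) {
    stop("expected count of zero; use fisher_exact_2x2", call. = FALSE)
  }
  adj <- if (yates) pmin(abs(a - e11), 0.5) else 0
  dev <- abs(a - e11) - adj
  stat <- dev^2 * (1 / e11 + 1 / e12 + 1 / e21 + 1 / e22)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

.expected_2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  cbind((a + b) * (a + c) / N, (a + b) * (b + d) / N,
        (c + d) * (a + c) / N, (c + d) * (b + d) / N)
}

#' Pairwise differential expression between two libraries
#'
#' For each tag, builds the 2x2 table (count in library A, remaining library
#' A reads; count in library B, remaining library B reads) on raw counts and
#' tests it: Pearson chi-squared when all four expected counts are at least
#' 5, Fisher's exact test otherwise (`method = "fisher"` forces the exact
#' test everywhere).  The fold change is computed on normalized counts,
#' `log2fc = log2(norm_b / norm_a)`, with a pseudocount (default 0.5)
#' applied only to a zero side.  A tag is `up` if `log2fc >=
#' min_abs_log2fc` and `p <= alpha`, `down` if `log2fc <= -min_abs_log2fc`
#' and `p <= alpha`, else `none`.
#'
#' @param tags A `xylem_tags` tibble with raw (and, if available, norm)
#'   counts; [normalize_counts()] is applied if norm columns are missing.
#' @param lib_pair Character vector of two library ids, `c(a, b)`; the fold
#'   change is b over a.
#' @param alpha Significance threshold (default 0.05).
#' @param min_abs_log2fc Fold-change threshold on the log2 scale (default 1).
#' @param method `"auto"` (expected-count rule), `"fisher"`, or `"chisq"`.
#' @param pseudocount Added to zero sides only (default 0.5).
#' @param adjust Multiple-testing correction: `"none"` (the default; single
#'   libraries, as the design assumes) or `"BH"`, in which case the
#'   Benjamini-Hochberg adjusted p-value is used for the status call and
#'   reported as `p_adjusted`.
#' @param names Optional character vector of per-tag names (e.g. miRNA
#'   annotation names); defaults to the tag sequence.
#' @return A `mirna_de` tibble: `name`, `sequence` (when available),
#'   `norm_a`, `norm_b`, `log2fc`, `p_value`, `method`, `status`.
#' @export
pairwise_de <- function(tags, lib_pair, alpha = 0.05, min_abs_log2fc = 1,
                        method = c("auto", "fisher", "chisq"),
                        pseudocount = 0.5, adjust = c("none", "BH"),
                        names = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(length(lib_pair) == 2)
  ra <- paste0("raw_", lib_pair[1]); rb <- paste0("raw_", lib_pair[2])
  if (!all(c(ra, rb) %in% colnames(tags))) {
    stop("unknown library id in lib_pair", call. = FALSE)
  }
  na_col <- paste0("norm_", lib_pair[1]); nb_col <- paste0("norm_", lib_pair[2])
  if (!all(c(na_col, nb_col) %in% colnames(tags))) {
    tags <- normalize_counts(tags)
  }
  totals <- attr(tags, "lib_totals")
  if (is.null(totals)) {
    libs <- attr(tags, "libraries") %||%
      sub("^raw_", "", grep("^raw_", names(tags), value = TRUE))
    totals <- vapply(libs, function(l) sum(tags[[paste0("raw_", l)]]),
                     numeric(1))
  }
  a <- tags[[ra]]; b <- tags[[rb]]
  ta <- totals[[lib_pair[1]]]; tb <- totals[[lib_pair[2]]]
  exp_min <- apply(.expected_2x2(a, ta - a, b, tb - b), 1, min)
  use_chisq <- switch(method,
                      auto = exp_min >= 5,
                      fisher = rep(FALSE, length(a)),
                      chisq = rep(TRUE, length(a)))
  p <- numeric(length(a))
  if (any(use_chisq)) {
    p[use_chisq] <- chisq_2x2(a[use_chisq], ta - a[use_chisq],
                              b[use_chisq], tb - b[use_chisq])$p_value
  }
  if (any(!use_chisq)) {
    p[!use_chisq] <- fisher_exact_2x2(a[!use_chisq], ta - a[!use_chisq],
                                      b[!use_chisq], tb - b[!use_chisq])
  }
  norm_a <- tags[[na_col]]; norm_b <- tags[[nb_col]]
  la <- ifelse(norm_a == 0, pseudocount, norm_a)
  lb <- ifelse(norm_b == 0, pseudocount, norm_b)
  log2fc <- log2(lb / la)
  p_call <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  status <- dplyr::case_when(
    log2fc >= min_abs_log2fc & p_call <= alpha ~ "up",
    log2fc <= -min_abs_log2fc & p_call <= alpha ~ "down",
    TRUE ~ "none")
  out <- tibble::tibble(
    name = names %||% tags$sequence,
    sequence = if ("sequence" %in% colnames(tags)) tags$sequence else NA_character_,
    norm_a = norm_a, norm_b = norm_b, log2fc = log2fc, p_value = p,
    method = ifelse(use_chisq, "chisq", "fisher"), status = status)
  if (adjust == "BH") out$p_adjusted <- p_call
  attr(out, "comparison") <- lib_pair
  attr(out, "thresholds") <- list(alpha = alpha,
                                  min_abs_log2fc = min_abs_log2fc)
  class(out) <- c("mirna_de", class(out))
  out
}

#' Split DE results into up- and down-regulated miRNA sets
#'
#' Partitions one comparison's results by status and de-duplicates by miRNA
#' name, so a miRNA expressed from several genomic loci counts once.
#'
#' @param results A `mirna_de` tibble from [pairwise_de()].
#' @return A list with tibbles `up` and `down` (one row per distinct name).
#' @export
classify_regulation <- function(results) {
  dedup <- function(x) dplyr::distinct(x, .data$name, .keep_all = TRUE)
  list(up = dedup(dplyr::filter(results, .data$status == "up")),
       down = dedup(dplyr::filter(results, .data$status == "down")))
}

#' @export
glance.mirna_de <- function(x, ...) {
  reg <- classify_regulation(x)
  tibble::tibble(n_tags = nrow(x), n_up = nrow(reg$up),
                 n_down = nrow(reg$down),
                 comparison = paste(attr(x, "comparison"), collapse = "/"))
}

#' @export
tidy.mirna_de <- function(x, ...) {
  tibble::as_tibble(x)
}
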