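#' Expected cleavage position of a target site
#'
#' miRNA-guided cleavage occurs opposite miRNA positions 10-11; the
#' degradome 5'-end tag of the 3' cleavage fragment is expected exactly at
#' the transcript position pairing miRNA position 10.  For a gapless site
#' that is `site_end - 9`; gap columns 5' of the pairing (miRNA positions
#' 1-9) shift it accordingly, which is handled by walking the pairing
#' string.  A gap opposite positions 10-11 leaves the position undefined.
#'
#' @param site_end 1-based 3' end of the site on the transcript (the
#'   position pairing miRNA position 1).
#' @param pairing Pairing string of the site (one symbol per miRNA
#'   position); `NULL` assumes a gapless site.
#' @return Integer transcript position (vectorized over `site_end`).
#' @examples
#' expected_cleavage_pos(121)  # 112 for a gapless 21-nt site at 101-121
#' @export
expected_cleavage_pos <- function(site_end, pairing = NULL) {
  if (is.null(pairing)) return(as.integer(site_end) - 9L)
  n <- max(length(site_end), length(pairing))
  site_end <- rep_len(as.integer(site_end), n)
  pairing <- rep_len(pairing, n)
  vapply(seq_len(n), function(i) {
    pv <- strsplit(pairing[i], "")[[1]]
    if (length(pv) < 11L) stop("pairing shorter than 11 positions",
                               call. = FALSE)
    if (any(pv[10:11] == "-")) {
      stop("cleavage position undefined: gap opposite miRNA positions 10-11",
           call. = FALSE)
    }
    consumed <- cumsum(pv != "-")
    site_end[i] - (consumed[10] - 1L)
  }, integer(1))
}

#' Degradome T-plot category of a position
#'
#' The standard five-tier scheme on one transcript's 5'-end tag profile in
#' one library: `NA` if no tag at the position; 4 if exactly one tag; else,
#' with M the maximum count on the transcript and med the median over
#' positions with at least one tag: 0 if the position holds a unique
#' maximum, 1 if it ties the maximum, 2 if above the median but below the
#' maximum, 3 otherwise.
#'
#' @param tag_counts Tibble/data frame with `position` and `count` for one
#'   transcript and library (positions with zero tags omitted), or a named
#'   numeric vector keyed by position.
#' @param pos Query position (scalar).
#' @return Integer category 0-4, or `NA_integer_`.
#' @export
site_category <- function(tag_counts, pos) {
  if (is.data.frame(tag_counts)) {
    counts <- tag_counts$count
    positions <- tag_counts$position
  } else {
    counts <- unname(tag_counts)
    positions <- as.integer(names(tag_counts))
  }
  counts <- counts[counts > 0]
  positions <- positions[seq_along(counts)]
  if (!length(counts)) return(NA_integer_)
  at <- counts[match(pos, positions)]
  if (is.na(at) || at == 0) return(NA_integer_)
  if (at == 1) return(4L)
  M <- max(counts)
  med <- stats::median(counts)
  if (at == M) {
    if (sum(counts == M) == 1L) return(0L) else return(1L)
  }
  if (at > med) return(2L)
  3L
}

#' Count degradome libraries supporting predicted cleavage sites
#'
#' For each predicted site, evaluates the T-plot category at the expected
#' cleavage position, allowing a tolerance of `pos_tolerance` nt (the best
#' category within the window wins), in every degradome library.  The
#' degradome support count `deg_count` is the number of libraries whose
#' category is at most `category_max`; a site with `deg_count >= 1` is
#' degradome-confirmed.
#'
#' @param sites Tibble of predicted sites with `mirna`, `transcript_id`,
#'   `site_end` and `pairing` (e.g. from [intersect_predictions()]).
#' @param degradome Tag-count tibble: `library`, `transcript_id`,
#'   `position`, `count` (as from [synth_degradome()] or
#'   [read_degradome_tsv()]).
#' @param category_max Highest category counted as support (default 2).
#' @param pos_tolerance Positional tolerance in nt (default 1).
#' @return `sites` with `cleavage_pos`, one `cat_<library>` column per
#'   library, and `deg_count`.
#' @export
degradome_support <- function(sites, degradome, category_max = 2L,
                              pos_tolerance = 1L) {
  libs <- unique(degradome$library)
  sites <- tibble::as_tibble(sites)
  sites$cleavage_pos <- expected_cleavage_pos(sites$site_end, sites$pairing)
  prof <- split(degradome, paste(degradome$library, degradome$transcript_id))
  for (lib in libs) sites[[paste0("cat_", lib)]] <- NA_integer_
  for (i in seq_len(nrow(sites))) {
    for (lib in libs) {
      key <- paste(lib, sites$transcript_id[i])
      tc <- prof[[key]]
      if (is.null(tc)) next   # transcript absent from this library
      cats <- vapply(
        seq(sites$cleavage_pos[i] - pos_tolerance,
            sites$cleavage_pos[i] + pos_tolerance),
        function(p) site_category(tc, p) %||% NA_integer_, integer(1))
      cats <- cats[!is.na(cats)]
      if (length(cats)) sites[[paste0("cat_", lib)]][i] <- min(cats)
    }
  }
  supp <- rep(0L, nrow(sites))
  for (cc in paste0("cat_", libs)) {
    supp <- supp + (!is.na(sites[[cc]]) & sites[[cc]] <= category_max)
  }
  sites$deg_count <- as.integer(supp)
  attr(sites, "degradome_libraries") <- libs
  sites
}

#' Read a degradome per-position count TSV
#'
#' Expected columns: `transcript_id`, `position` (1-based), `count`,
#' `library`.
#'
#' @param path File path.
#' @return A tibble in [degradome_support()] input form.
#' @export
read_degradome_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "position", "count", "library") %in%
                  names(x)))
  tibble::as_tibble(x)
}
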