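#' Trim the 3' sequencing adapter from reads
#'
#' Removes everything from the leftmost adapter occurrence onward.  A full
#' internal occurrence or a prefix of the adapter reaching the 3' end of the
#' read both count, provided the overlap is at least `min_overlap` and the
#' mismatch rate within the overlap is at most `max_mismatch_rate`.  Reads
#' whose insert is shorter than 15 nt after trimming (adapter dimers, junk)
#' and reads with no detectable adapter return `NA`.
#'
#' @param reads Character vector of raw reads (DNA alphabet).
#' @param adapter The 3' adapter sequence; the default is a standard small-RNA
#'   library-prep adapter.
#' @param min_overlap Minimum adapter overlap, at least 5 (default 6).
#' @param max_mismatch_rate Maximum fraction of mismatches within the
#'   matched overlap (default 0.1).
#' @return Character vector of inserts, `NA` where the read is discarded.
#' @examples
#' trim_adapter(paste0(strrep("ACGT", 6), "TGGAATTCTCGGGTGCCAAGG"))
#' @export
trim_adapter <- function(reads, adapter = default_adapter(),
                         min_overlap = 6L, max_mismatch_rate = 0.1) {
  if (length(reads) == 0) return(character(0))
  if (any(!nzchar(reads)) || anyNA(reads)) stop("empty read", call. = FALSE)
  adapter <- dna_norm(adapter)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 5L || nchar(adapter) < min_overlap) {
    stop("need adapter length >= min_overlap >= 5", call. = FALSE)
  }
  reads <- dna_norm(reads)
  alen <- nchar(adapter)
  out <- rep(NA_character_, length(reads))

  # fast path: leftmost exact full occurrence
  loc <- stringi::stri_locate_first_fixed(reads, adapter)[, 1]
  hit <- !is.na(loc)
  out[hit] <- substr(reads[hit], 1L, loc[hit] - 1L)

  # exact adapter prefix running off the 3' end of the read
  todo <- which(!hit)
  if (length(todo) && min(alen - 1L, max(nchar(reads[todo]))) >= min_overlap) {
    rl <- nchar(reads[todo])
    found <- rep(NA_integer_, length(todo))
    for (o in seq(min(alen - 1L, max(rl)), min_overlap, by = -1L)) {
      pre <- substr(adapter, 1L, o)
      cand <- is.na(found) & rl >= o &
        substr(reads[todo], rl - o + 1L, rl) == pre
      found[cand] <- rl[cand] - o
    }
    out[todo] <- ifelse(is.na(found), NA_character_,
                        substr(reads[todo], 1L, found))
  }

  # mismatch-tolerant scan only for what exact matching missed
  if (max_mismatch_rate > 0) {
    todo <- which(is.na(out) & nchar(reads) >= min_overlap)
    for (k in todo) {
      r <- reads[k]; rl <- nchar(r)
      for (i in seq_len(rl - min_overlap + 1L)) {
        o <- min(rl - i + 1L, alen)
        obs <- substr(r, i, i + o - 1L)
        mm <- sum(utf8ToInt(obs) != utf8ToInt(substr(adapter, 1L, o)))
        if (mm <= floor(o * max_mismatch_rate)) {
          out[k] <- substr(r, 1L, i - 1L)
          break
        }
      }
    }
  }
  out[!is.na(out) & nchar(out) < 15L] <- NA_character_
  out
}

#' Default 3' adapter sequence
#'
#' The standard small-RNA kit adapter assumed by the read generator and the
#' trimming defaults; every entry point that trims accepts an override.
#' @return A single adapter string.
#' @export
default_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"

# longest mono- or di-nucleotide repeat covering >= threshold of the tag
is_low_complexity <- function(x, threshold = 0.8) {
  if (!length(x)) return(logical(0))
  run1 <- vapply(stringi::stri_extract_all_regex(x, "(.)\\1*"),
                 function(r) max(nchar(r)), integer(1))
  run2 <- vapply(stringi::stri_extract_all_regex(x, "(..)\\1+"),
                 function(r) if (length(r) == 1 && is.na(r)) 0L else max(nchar(r)),
                 integer(1))
  pmax(run1, run2) / nchar(x) >= threshold
}

# exact substring membership in any contaminant reference, either strand
is_contaminant <- function(tags, contaminants) {
  if (!length(tags)) return(logical(0))
  if (length(contaminants) == 0) return(rep(FALSE, length(tags)))
  contaminants <- dna_norm(as.character(contaminants))
  subj <- Biostrings::DNAStringSet(c(contaminants, revcomp(contaminants)))
  hit <- rep(FALSE, length(tags))
  for (w in unique(nchar(tags))) {
    idx <- which(nchar(tags) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags[idx]))
    cnt <- rowSums(Biostrings::vcountPDict(pd, subj))
    hit[idx] <- cnt > 0
  }
  hit
}

#' Collapse trimmed reads to unique tags and filter them
#'
#' Merges identical insert sequences into unique tags with per-library raw
#' counts, then removes (i) tags exactly matching a contaminant reference as
#' a substring on either strand (rRNA/tRNA/snRNA-like families), (ii)
#' low-complexity tags (a mono- or di-nucleotide repeat covering at least
#' 80 percent of the tag), and (iii) tags outside `length_range`.
#'
#' @param reads A tibble with columns `library` and `sequence` (trimmed
#'   inserts; `NA` rows are ignored), or a named list of character vectors.
#' @param contaminants Contaminant reference sequences (character or
#'   `DNAStringSet`); `NULL` for none.
#' @param length_range Kept tag lengths, inclusive (default 18-30; the
#'   stricter 20-22 window is applied at annotation).
#' @return A `xylem_tags` tibble: `sequence`, `length`, and one raw-count
#'   column `raw_<library>` per library, with a `ledger` attribute counting
#'   reads assigned to each filter class per library.
#' @export
collapse_and_filter <- function(reads, contaminants = NULL,
                                length_range = c(18L, 30L)) {
  if (is.list(reads) && !is.data.frame(reads)) {
    reads <- tibble::tibble(
      library = rep(names(reads), lengths(reads)),
      sequence = unlist(reads, use.names = FALSE))
  }
  stopifnot(all(c("library", "sequence") %in% names(reads)))
  libs <- unique(reads$library)
  reads <- dplyr::filter(reads, !is.na(.data$sequence))
  tags <- dplyr::count(reads, .data$library, .data$sequence, name = "n")
  tags <- tidyr::pivot_wider(tags, names_from = "library",
                             values_from = "n", values_fill = 0L,
                             names_prefix = "raw_")
  for (lib in libs) {
    cn <- paste0("raw_", lib)
    if (!cn %in% names(tags)) tags[[cn]] <- 0L
  }
  tags <- tags[c("sequence", paste0("raw_", libs))]
  tags$length <- nchar(tags$sequence)
  tags <- tags[c("sequence", "length", paste0("raw_", libs))]

  cnt <- colSums(tags[paste0("raw_", libs)])
  in_range <- tags$length >= length_range[1] & tags$length <= length_range[2]
  contam <- is_contaminant(tags$sequence, contaminants)
  lowc <- is_low_complexity(tags$sequence)

  drop_contam <- contam
  drop_lowc <- !contam & lowc
  drop_range <- !contam & !lowc & !in_range
  keep <- !(drop_contam | drop_lowc | drop_range)

  counts_of <- function(mask) {
    if (!any(mask)) return(rep(0L, length(libs)))
    unname(as.integer(colSums(tags[mask, paste0("raw_", libs)])))
  }
  ledger <- tibble::tibble(
    library = libs,
    reads_in = as.integer(cnt),
    contaminant = counts_of(drop_contam),
    low_complexity = counts_of(drop_lowc),
    out_of_range = counts_of(drop_range),
    kept = counts_of(keep))

  out <- tags[keep, , drop = FALSE]
  out <- dplyr::arrange(out, .data$sequence)
  attr(out, "libraries") <- libs
  attr(out, "ledger") <- ledger
  class(out) <- c("xylem_tags", class(out))
  out
}

#' Process raw reads end to end into unique tags
#'
#' Convenience wrapper running [trim_adapter()] then [collapse_and_filter()],
#' with a complete read-conservation ledger: every input read is assigned to
#' exactly one of `kept`, `no_adapter`, `too_short` (insert < 15 nt),
#' `contaminant`, `low_complexity` or `out_of_range`.
#'
#' @inheritParams trim_adapter
#' @inheritParams collapse_and_filter
#' @param reads A tibble with columns `library` and `sequence` (raw reads).
#' @return A `xylem_tags` tibble as from [collapse_and_filter()]; its
#'   `ledger` attribute additionally counts `no_adapter` and `too_short`.
#' @export
process_reads <- function(reads, adapter = default_adapter(),
                          contaminants = NULL, length_range = c(18L, 30L),
                          min_overlap = 6L, max_mismatch_rate = 0.1) {
  stopifnot(all(c("library", "sequence") %in% names(reads)))
  raw <- dna_norm(reads$sequence)
  has_adapter <- !is.na(trim_adapter(raw, adapter, min_overlap,
                                     max_mismatch_rate = 0))
  trimmed <- trim_adapter(raw, adapter, min_overlap, max_mismatch_rate)
  # distinguish "no adapter anywhere" from "adapter found, insert too short"
  loc <- stringi::stri_locate_first_fixed(raw, dna_norm(adapter))[, 1]
  found <- !is.na(trimmed) | !is.na(loc) | has_adapter
  tbl <- tibble::tibble(library = reads$library, sequence = trimmed)
  tags <- collapse_and_filter(tbl, contaminants, length_range)
  ledger <- attr(tags, "ledger")
  per_lib <- function(mask) {
    v <- tapply(mask, reads$library, sum, default = 0L)
    as.integer(v[ledger$library])
  }
  ledger$total_reads <- per_lib(rep(TRUE, nrow(reads)))
  ledger$no_adapter <- per_lib(!found)
  ledger$too_short <- per_lib(found & is.na(trimmed))
  ledger <- ledger[c("library", "total_reads", "no_adapter", "too_short",
                     "contaminant", "low_complexity", "out_of_range", "kept")]
  attr(tags, "ledger") <- ledger
  tags
}
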