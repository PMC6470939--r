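#' Build a miRNA reference table
#'
#' Assembles mature miRNAs, with optional precursor (hairpin) context, into
#' the reference table used by [match_tag()] and [classify_tags()].  The
#' precursor context is what allows 5'/3' end-extended isomiRs (`_L+n`,
#' `_R+n`) to be verified against real flanking bases; without it only
#' trimmed variants can match.
#'
#' @param mature Named character vector (or `DNAStringSet`) of mature miRNA
#'   sequences; names are the reference ids (e.g. `zma-miR156a-5p`).
#' @param precursors Optional named character vector of precursor sequences;
#'   each mature is located in its precursor by id prefix match (the mature
#'   `zma-miR156a-5p` belongs to precursor `zma-MIR156a`) or by exact
#'   substring search.
#' @param priority Priority class for tie-breaks: 1 = own species (known),
#'   2 = other monocot.
#' @return A tibble: `id`, `mature`, `precursor`, `mature_start`, `priority`.
#' @export
mirna_references <- function(mature, precursors = NULL, priority = 1L) {
  mature <- stats::setNames(dna_norm(as.character(mature)), names(mature))
  if (is.null(names(mature)) || any(!nzchar(names(mature)))) {
    stop("mature sequences must be named by miRNA id", call. = FALSE)
  }
  refs <- tibble::tibble(id = names(mature), mature = unname(mature),
                         precursor = NA_character_, mature_start = NA_integer_,
                         priority = as.integer(priority))
  if (!is.null(precursors)) {
    precursors <- stats::setNames(dna_norm(as.character(precursors)),
                                  names(precursors))
    for (k in seq_len(nrow(refs))) {
      hit <- which(vapply(precursors, function(p)
        stringi::stri_detect_fixed(p, refs$mature[k]), logical(1)))
      # prefer the precursor whose name matches the mature's family stem
      if (length(hit) > 1) {
        stem <- toupper(sub("-[35]p$", "", refs$id[k]))
        nm <- toupper(names(precursors)[hit])
        pref <- which(vapply(nm, function(x)
          stringi::stri_detect_fixed(stem, x) ||
            stringi::stri_detect_fixed(x, stem), logical(1)))
        if (length(pref)) hit <- hit[pref[1]] else hit <- hit[1]
      }
      if (length(hit) == 1) {
        refs$precursor[k] <- unname(precursors[hit])
        refs$mature_start[k] <-
          stringi::stri_locate_first_fixed(refs$precursor[k],
                                           refs$mature[k])[, 1]
      }
    }
  }
  refs
}

# all (l_shift, r_shift) variant regions of one reference compatible with a
# tag length; returns tibble(region, l_shift, r_shift)
.variant_regions <- function(ref, tag_len, max_shift) {
  m_len <- nchar(ref$mature)
  out <- list()
  for (l in seq(-max_shift, max_shift)) {
    r <- tag_len - m_len - l
    if (abs(r) > max_shift) next
    if (!is.na(ref$precursor)) {
      s <- ref$mature_start - l
      e <- ref$mature_start + m_len - 1L + r
      if (s < 1L || e > nchar(ref$precursor)) next
      region <- substr(ref$precursor, s, e)
    } else {
      if (l > 0 || r > 0) next  # extensions need precursor context
      region <- substr(ref$mature, 1L - l, m_len + r)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      region = region, l_shift = l, r_shift = r)
  }
  dplyr::bind_rows(out)
}

# isomiR name from match components ("_L+1", "_R-1", "_1ss21GA", in that order)
.variant_name <- function(id, l_shift, r_shift, sub_pos, sub_ref, sub_obs) {
  nm <- id
  if (l_shift != 0) nm <- paste0(nm, sprintf("_L%+d", l_shift))
  if (r_shift != 0) nm <- paste0(nm, sprintf("_R%+d", r_shift))
  if (length(sub_pos)) {
    nm <- paste0(nm, "_", length(sub_pos), "ss",
                 paste0(sub_pos, sub_ref, sub_obs, collapse = ""))
  }
  nm
}

#' Match a tag to reference mature miRNAs with bounded end-shifts
#'
#' Finds, for each tag, the reference mature miRNA it derives from, allowing
#' up to `max_shift` nucleotides of 5'/3' end extension or trimming (checked
#' against precursor context where available) and up to `max_subs` internal
#' substitutions.  The best match minimises (substitutions, total shift),
#' with ties broken by reference priority class (own species before other
#' monocots) and then lexicographic id.  The reconstructed variant name
#' follows isomiR convention: `id`, then `_L+n`/`_L-n`, `_R+n`/`_R-n`, then
#' `_kssPPXY` (position on the tag, reference base, observed base).  An
#' exact match keeps the bare reference id.
#'
#' @param tags Character vector of tag sequences (or a `xylem_tags` tibble).
#' @param references From [mirna_references()].
#' @param max_shift Maximum end shift per side (default 2).
#' @param max_subs Maximum substitutions (default 1).
#' @return A tibble with one row per matched tag: `sequence`,
#'   `reference_id`, `l_shift`, `r_shift`, `n_subs`, `variant_name`.
#'   Unmatched tags are absent.
#' @export
match_tag <- function(tags, references, max_shift = 2L, max_subs = 1L) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- dna_norm(tags)
  check_dna(tags, "tag")
  if (!nrow(references)) {
    return(tibble::tibble(sequence = character(0), reference_id = character(0),
                          l_shift = integer(0), r_shift = integer(0),
                          n_subs = integer(0), variant_name = character(0)))
  }
  res <- vector("list", length(tags))
  # group tags by length; compare against each reference variant region
  tag_tbl <- tibble::tibble(sequence = tags, idx = seq_along(tags))
  best <- NULL
  for (tl in unique(nchar(tags))) {
    sub <- tag_tbl[nchar(tag_tbl$sequence) == tl, ]
    tag_mat <- matrix(unlist(strsplit(sub$sequence, "")), nrow = tl)
    for (k in seq_len(nrow(references))) {
      ref <- references[k, ]
      regions <- .variant_regions(ref, tl, max_shift)
      if (!nrow(regions)) next
      for (v in seq_len(nrow(regions))) {
        reg <- strsplit(regions$region[v], "")[[1]]
        mm <- colSums(tag_mat != reg)
        ok <- which(mm <= max_subs)
        for (i in ok) {
          cand <- list(idx = sub$idx[i],
                       reference_id = ref$id,
                       priority = ref$priority,
                       l_shift = regions$l_shift[v],
                       r_shift = regions$r_shift[v],
                       n_subs = as.integer(mm[i]),
                       region = regions$region[v])
          prev <- res[[cand$idx]]
          if (is.null(prev) ||
              cand$n_subs < prev$n_subs ||
              (cand$n_subs == prev$n_subs &&
                 (abs(cand$l_shift) + abs(cand$r_shift) <
                    abs(prev$l_shift) + abs(prev$r_shift) ||
                  (abs(cand$l_shift) + abs(cand$r_shift) ==
                     abs(prev$l_shift) + abs(prev$r_shift) &&
                   (cand$priority < prev$priority ||
                    (cand$priority == prev$priority &&
                     cand$reference_id < prev$reference_id)))))) {
            res[[cand$idx]] <- cand
          }
        }
      }
    }
  }
  hits <- which(!vapply(res, is.null, logical(1)))
  if (!length(hits)) {
    return(tibble::tibble(sequence = character(0), reference_id = character(0),
                          l_shift = integer(0), r_shift = integer(0),
                          n_subs = integer(0), variant_name = character(0)))
  }
  rows <- lapply(hits, function(i) {
    m <- res[[i]]
    tag <- tags[i]
    pos <- which(strsplit(tag, "")[[1]] != strsplit(m$region, "")[[1]])
    nm <- .variant_name(m$reference_id, m$l_shift, m$r_shift,
                        pos,
                        substring(m$region, pos, pos),
                        substring(tag, pos, pos))
    tibble::tibble(sequence = tag, reference_id = m$reference_id,
                   l_shift = m$l_shift, r_shift = m$r_shift,
                   n_subs = m$n_subs, variant_name = nm)
  })
  dplyr::bind_rows(rows)
}

#' Map tags to exact genomic loci
#'
#' Reports all exact-match loci of each tag on both strands of the genome,
#' up to `max_loci` per tag, in deterministic (chrom, start) order.  Minus
#' strand hits are positions where the tag matches the reverse complement of
#' the plus strand; coordinates are always reported on the plus strand,
#' 1-based inclusive.
#'
#' @param tags Character vector of tag sequences (or a `xylem_tags` tibble).
#' @param genome Named `DNAStringSet` or named character vector.
#' @param max_loci Maximum loci reported per tag (default 20).
#' @return A tibble: `sequence`, `chrom`, `strand`, `start`, `end`.
#' @export
map_to_genome <- function(tags, genome, max_loci = 20L) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- unique(dna_norm(tags))
  check_dna(tags, "tag")
  genome <- as_genome_set(genome)
  out <- list()
  for (w in unique(nchar(tags))) {
    fw <- tags[nchar(tags) == w]
    pats <- c(fw, revcomp(fw))
    strand <- rep(c("+", "-"), each = length(fw))
    origin <- rep(fw, 2)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    for (chrom in names(genome)) {
      mi <- Biostrings::matchPDict(pd, genome[[chrom]])
      starts <- Biostrings::startIndex(mi)
      n_hits <- lengths(starts)
      if (!sum(n_hits)) next
      idx <- rep(seq_along(starts), n_hits)
      st <- unlist(starts, use.names = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        sequence = origin[idx], chrom = chrom, strand = strand[idx],
        start = as.integer(st), end = as.integer(st + w - 1L))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sequence = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0)))
  }
  res <- dplyr::distinct(dplyr::bind_rows(out))
  res <- dplyr::arrange(res, .data$sequence, .data$chrom, .data$start,
                        .data$strand)
  res <- dplyr::slice_head(dplyr::group_by(res, .data$sequence),
                           n = max_loci)
  dplyr::ungroup(res)
}
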