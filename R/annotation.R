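#' Annotation policy defaults
#'
#' @param max_shift,max_subs Variant-matching bounds (see [match_tag()]).
#' @param length_range Tag lengths considered miRNA-sized (default 20-22).
#' @param max_loci Genomic loci examined per tag (default 20).
#' @param thresholds Precursor criteria, see [precursor_thresholds()].
#' @return A named list.
#' @export
annotation_policy <- function(max_shift = 2L, max_subs = 1L,
                              length_range = c(20L, 22L), max_loci = 20L,
                              thresholds = precursor_thresholds()) {
  list(max_shift = max_shift, max_subs = max_subs,
       length_range = length_range, max_loci = max_loci,
       thresholds = thresholds)
}

# locate a tag inside a set of precursors; returns first hit as
# list(precursor_id, start, end) or NULL
.locate_in_precursors <- function(tag, precursors) {
  for (pid in names(precursors)) {
    loc <- stringi::stri_locate_first_fixed(precursors[[pid]], tag)
    if (!is.na(loc[1, 1])) {
      return(list(id = pid, start = loc[1, 1], end = loc[1, 2]))
    }
  }
  NULL
}

# arm of a subsequence [s, e] within a precursor, by midpoint rule
.arm_of <- function(s, e, pre_len) {
  if ((s + e) / 2 <= pre_len / 2) "5p" else "3p"
}

# does a precursor occur in the genome (exact, either strand)?
.precursor_in_genome <- function(pre, genome) {
  pat <- Biostrings::DNAString(pre)
  for (ci in seq_along(genome)) {
    if (Biostrings::countPattern(pat, genome[[ci]]) > 0) return(TRUE)
    if (Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                 genome[[ci]]) > 0) return(TRUE)
  }
  FALSE
}

# structural evaluation of a known precursor sequence with the tag at [s, e]
.evaluate_known_precursor <- function(pre, s, e, thresholds) {
  hp <- fold_best_hairpin(pre)
  ev <- .evaluate_window(hp, s, e, thresholds)
  ev$window <- pre
  ev
}

#' Classify miRNA-sized tags into annotation classes
#'
#' Implements the annotation decision tree, in strict priority order:
#' 1. a variant match to an own-species mature miRNA makes the tag
#'    `known` (named by isomiR convention);
#' 2. an exact hit inside an own-species precursor on the arm opposite the
#'    annotated mature makes it `novel_arm` (named `PRECURSOR-p5`/`-p3`);
#' 3. a variant match to another monocot's mature, or a hit in a monocot
#'    precursor, whose precursor also occurs in the own genome, makes it
#'    `homolog`;
#' 4. otherwise the tag is mapped to the genome and each locus evaluated as
#'    a precursor ([evaluate_precursor()]); a passing locus makes it
#'    `novel_pc`, named `PC-{5p|3p}-{serial}_{total raw count}` with
#'    serials assigned in (chrom, start) order for reproducibility.
#' Unclassified tags are dropped with a reason (`length`, `no_genome_hit`,
#' `structure_fail`), so classes plus drops always partition the input.
#'
#' @param tags A `xylem_tags` tibble (or character vector of sequences).
#' @param own_matures Named character vector of own-species mature miRNAs
#'   (or `NULL`).
#' @param own_precursors Named character vector of own-species precursors.
#' @param monocot_matures,monocot_precursors Reference sets of other
#'   monocot species.
#' @param genome Named `DNAStringSet` (required for steps 3-4 if reached).
#' @param policy From [annotation_policy()].
#' @return A `mirna_records` tibble: `name`, `class`, `sequence`, count
#'   columns carried over, `chrom`, `strand`, `start`, `end`, `mfei`,
#'   `mfe`, `passes`; dropped tags in the `drops` attribute.
#' @export
classify_tags <- function(tags, own_matures = NULL, own_precursors = NULL,
                          monocot_matures = NULL, monocot_precursors = NULL,
                          genome = NULL, policy = annotation_policy()) {
  if (is.character(tags)) {
    tags <- tibble::tibble(sequence = dna_norm(tags),
                           length = nchar(tags), raw_all = 1L)
  }
  tags <- tibble::as_tibble(tags)
  count_cols <- grep("^(raw|norm)_", names(tags), value = TRUE)
  raw_cols <- grep("^raw_", names(tags), value = TRUE)

  in_range <- tags$length >= policy$length_range[1] &
    tags$length <= policy$length_range[2]
  drops <- tibble::tibble(sequence = tags$sequence[!in_range],
                          reason = "length")
  work <- tags[in_range, , drop = FALSE]
  n <- nrow(work)
  cls <- rep(NA_character_, n)
  nm <- rep(NA_character_, n)
  loc <- tibble::tibble(chrom = rep(NA_character_, n),
                        strand = NA_character_, start = NA_integer_,
                        end = NA_integer_)
  ev_tbl <- tibble::tibble(mfe = rep(NA_real_, n), mfei = NA_real_,
                           passes = NA, arm = NA_character_)

  own_pre <- if (!is.null(own_precursors))
    stats::setNames(dna_norm(as.character(own_precursors)),
                    names(own_precursors)) else NULL
  mono_pre <- if (!is.null(monocot_precursors))
    stats::setNames(dna_norm(as.character(monocot_precursors)),
                    names(monocot_precursors)) else NULL

  # --- step 1: known ------------------------------------------------------
  if (!is.null(own_matures) && length(own_matures)) {
    own_refs <- mirna_references(own_matures, own_pre, priority = 1L)
    m1 <- match_tag(work$sequence, own_refs, policy$max_shift,
                    policy$max_subs)
    idx <- match(work$sequence, m1$sequence)
    hit <- !is.na(idx)
    cls[hit] <- "known"
    nm[hit] <- m1$variant_name[idx[hit]]
    # structural context from the known precursor when available
    for (i in which(hit)) {
      rid <- m1$reference_id[idx[i]]
      ref <- own_refs[own_refs$id == rid, ]
      if (!is.na(ref$precursor[1])) {
        p <- stringi::stri_locate_first_fixed(ref$precursor[1],
                                              work$sequence[i])
        if (!is.na(p[1, 1])) {
          ev <- .evaluate_known_precursor(ref$precursor[1], p[1, 1], p[1, 2],
                                          policy$thresholds)
          ev_tbl$mfe[i] <- ev$mfe; ev_tbl$mfei[i] <- ev$mfei
          ev_tbl$passes[i] <- ev$passes
        }
      }
    }
  }

  # --- step 2: novel arm-derived candidates -------------------------------
  todo <- which(is.na(cls))
  if (length(todo) && !is.null(own_pre)) {
    own_mat <- if (!is.null(own_matures))
      stats::setNames(dna_norm(as.character(own_matures)),
                      names(own_matures)) else character(0)
    for (i in todo) {
      hit <- .locate_in_precursors(work$sequence[i], own_pre)
      if (is.null(hit)) next
      pre <- own_pre[[hit$id]]
      pre_len <- nchar(pre)
      tag_arm <- .arm_of(hit$start, hit$end, pre_len)
      # arm of the annotated mature(s) of this precursor
      mat_arms <- character(0)
      overlaps_mature <- FALSE
      for (ms in own_mat) {
        mp <- stringi::stri_locate_first_fixed(pre, ms)
        if (!is.na(mp[1, 1])) {
          mat_arms <- c(mat_arms, .arm_of(mp[1, 1], mp[1, 2], pre_len))
          if (hit$start <= mp[1, 2] && hit$end >= mp[1, 1])
            overlaps_mature <- TRUE
        }
      }
      if (!length(mat_arms) || overlaps_mature || tag_arm %in% mat_arms) next
      cls[i] <- "novel_arm"
      nm[i] <- paste0(hit$id, "-p", substr(tag_arm, 1, 1))
      ev <- .evaluate_known_precursor(pre, hit$start, hit$end,
                                      policy$thresholds)
      ev_tbl$mfe[i] <- ev$mfe; ev_tbl$mfei[i] <- ev$mfei
      ev_tbl$passes[i] <- ev$passes
      ev_tbl$arm[i] <- tag_arm
    }
  }

  # --- step 3: monocot homologs -------------------------------------------
  todo <- which(is.na(cls))
  if (length(todo) && (!is.null(monocot_matures) || !is.null(mono_pre))) {
    mono_refs <- if (!is.null(monocot_matures) && length(monocot_matures))
      mirna_references(monocot_matures, mono_pre, priority = 2L) else NULL
    m3 <- if (!is.null(mono_refs))
      match_tag(work$sequence[todo], mono_refs, policy$max_shift,
                policy$max_subs) else NULL
    for (i in todo) {
      hom_name <- NULL; hom_pre <- NULL; hom_span <- NULL
      if (!is.null(m3)) {
        j <- match(work$sequence[i], m3$sequence)
        if (!is.na(j)) {
          rid <- m3$reference_id[j]
          pre <- mono_refs$precursor[mono_refs$id == rid][1]
          if (!is.na(pre)) {
            hom_name <- m3$variant_name[j]; hom_pre <- pre
            p <- stringi::stri_locate_first_fixed(pre, work$sequence[i])
            if (!is.na(p[1, 1])) hom_span <- c(p[1, 1], p[1, 2])
          }
        }
      }
      if (is.null(hom_name) && !is.null(mono_pre)) {
        hit <- .locate_in_precursors(work$sequence[i], mono_pre)
        if (!is.null(hit)) {
          arm <- .arm_of(hit$start, hit$end, nchar(mono_pre[[hit$id]]))
          hom_name <- paste0(hit$id, "-p", substr(arm, 1, 1))
          hom_pre <- mono_pre[[hit$id]]
          hom_span <- c(hit$start, hit$end)
        }
      }
      if (is.null(hom_name)) next
      if (is.null(genome) || !.precursor_in_genome(hom_pre, genome)) next
      cls[i] <- "homolog"
      nm[i] <- hom_name
      if (!is.null(hom_span)) {
        ev <- .evaluate_known_precursor(hom_pre, hom_span[1], hom_span[2],
                                        policy$thresholds)
        ev_tbl$mfe[i] <- ev$mfe; ev_tbl$mfei[i] <- ev$mfei
        ev_tbl$passes[i] <- ev$passes
      }
    }
  }

  # --- step 4: novel candidates with passing hairpins ---------------------
  todo <- which(is.na(cls))
  if (length(todo)) {
    if (is.null(genome)) {
      stop("configuration error: a genome is required to evaluate novel ",
           "miRNA candidates", call. = FALSE)
    }
    loci <- map_to_genome(work$sequence[todo], genome, policy$max_loci)
    for (i in todo) {
      lt <- loci[loci$sequence == work$sequence[i], , drop = FALSE]
      if (!nrow(lt)) { cls[i] <- "drop"; nm[i] <- "no_genome_hit"; next }
      placed <- FALSE
      for (r in seq_len(nrow(lt))) {
        ev <- evaluate_precursor(genome, lt[r, ], work$sequence[i],
                                 policy$thresholds)
        if (isTRUE(ev$passes)) {
          cls[i] <- "novel_pc"
          loc$chrom[i] <- lt$chrom[r]; loc$strand[i] <- lt$strand[r]
          loc$start[i] <- lt$start[r]; loc$end[i] <- lt$end[r]
          ev_tbl$mfe[i] <- ev$mfe; ev_tbl$mfei[i] <- ev$mfei
          ev_tbl$passes[i] <- TRUE
          # arm: which side of the folded window's loop holds the mature
          ev_tbl$arm[i] <- .pc_arm(ev, lt[r, ], work$sequence[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) { cls[i] <- "drop"; nm[i] <- "structure_fail" }
    }
  }

  # locations for known/arm/homolog classes: exact genome hit when available
  if (!is.null(genome)) {
    need <- which(cls %in% c("known", "novel_arm", "homolog") &
                    is.na(loc$chrom))
    if (length(need)) {
      loci <- map_to_genome(work$sequence[need], genome, 1L)
      for (i in need) {
        lt <- loci[loci$sequence == work$sequence[i], , drop = FALSE]
        if (nrow(lt)) {
          loc$chrom[i] <- lt$chrom[1]; loc$strand[i] <- lt$strand[1]
          loc$start[i] <- lt$start[1]; loc$end[i] <- lt$end[1]
        }
      }
    }
  }

  dropped <- cls == "drop"
  drops <- dplyr::bind_rows(drops,
                            tibble::tibble(sequence = work$sequence[dropped],
                                           reason = nm[dropped]))
  keep <- which(!dropped)
  out <- tibble::tibble(name = nm[keep], class = cls[keep],
                        sequence = work$sequence[keep],
                        length = work$length[keep])
  for (cc in count_cols) out[[cc]] <- work[[cc]][keep]
  out <- dplyr::bind_cols(out, loc[keep, ], ev_tbl[keep, ])

  # isomiR tags on the same precursor arm share a PRECURSOR-pN name; keep
  # one record per name (most abundant tag representative, counts summed)
  dup_cls <- out$class %in% c("novel_arm", "homolog")
  if (any(duplicated(out$name[dup_cls]))) {
    raw_here <- grep("^raw_", names(out), value = TRUE)
    tot <- if (length(raw_here))
      rowSums(out[, raw_here, drop = FALSE]) else rep(1, nrow(out))
    keep_row <- rep(TRUE, nrow(out))
    for (nm2 in unique(out$name[dup_cls][duplicated(out$name[dup_cls])])) {
      rows <- which(out$name == nm2)
      rep_row <- rows[which.max(tot[rows])]
      for (cc in count_cols) out[[cc]][rep_row] <- sum(out[[cc]][rows])
      keep_row[setdiff(rows, rep_row)] <- FALSE
    }
    out <- out[keep_row, , drop = FALSE]
  }

  # PC serials in deterministic genome order; name carries total raw count
  pc <- which(out$class == "novel_pc")
  if (length(pc)) {
    ord <- pc[order(out$chrom[pc], out$start[pc], out$strand[pc])]
    total <- if (length(raw_cols))
      rowSums(out[ord, raw_cols, drop = FALSE]) else rep(1L, length(ord))
    out$name[ord] <- sprintf("PC-%s-%d_%d",
                             ifelse(is.na(out$arm[ord]), "5p", out$arm[ord]),
                             seq_along(ord), as.integer(total))
  }
  attr(out, "drops") <- drops
  attr(out, "libraries") <- attr(tags, "libraries")
  attr(out, "lib_totals") <- attr(tags, "lib_totals")
  class(out) <- c("mirna_records", class(out))
  out
}

# arm of the mature within the best window of a novel_pc evaluation
.pc_arm <- function(ev, locus, tag_seq) {
  win <- ev$window[1]
  if (is.na(win)) return(NA_character_)
  p <- stringi::stri_locate_first_fixed(win, tag_seq)
  if (is.na(p[1, 1])) return(NA_character_)
  hp <- fold_best_hairpin(win)
  if (anyNA(hp$loop_span)) return(NA_character_)
  if (p[1, 2] < hp$loop_span[1]) "5p" else "3p"
}

#' Keep high-confidence miRNA records
#'
#' Applies the confidence filter used for reporting novel miRNAs: a
#' normalized count of at least `min_reads` in at least one library, an
#' MFEI of at least `min_mfei` with the structural criteria satisfied, and
#' sequencing support (at least one raw read) in at least `min_libraries`
#' libraries.  Records without a structural evaluation (e.g. known miRNAs
#' matched by sequence only) are excluded — this filter is about hairpin
#' confidence.
#'
#' @param records A `mirna_records` tibble (with `norm_*` columns; run
#'   [normalize_counts()] first).
#' @param min_reads Normalized-count threshold, inclusive (default 10).
#' @param min_mfei MFEI threshold (default 0.85).
#' @param min_libraries Minimum libraries with raw support (default 2).
#' @return The filtered subset.
#' @export
high_confidence_filter <- function(records, min_reads = 10, min_mfei = 0.85,
                                   min_libraries = 2L) {
  norm_cols <- grep("^norm_", names(records), value = TRUE)
  raw_cols <- grep("^raw_", names(records), value = TRUE)
  if (!length(norm_cols)) {
    stop("records carry no normalized counts; run normalize_counts() first",
         call. = FALSE)
  }
  nmax <- do.call(pmax, c(records[norm_cols], list(na.rm = TRUE)))
  nlibs <- rowSums(records[raw_cols] > 0)
  ok <- nmax >= min_reads &
    !is.na(records$mfei) & records$mfei >= min_mfei &
    !is.na(records$passes) & records$passes &
    nlibs >= min_libraries
  records[ok, , drop = FALSE]
}

#' Keep miRNAs significantly expressed in at least one comparison
#'
#' @param records A `mirna_records` tibble.
#' @param de_results A list of `mirna_de` tibbles ([pairwise_de()]), one per
#'   library pair; the minimum p-value over comparisons is used.
#' @param alpha Significance threshold (default 0.05).
#' @return The filtered subset, with a `p_min` column.
#' @export
select_significant <- function(records, de_results, alpha = 0.05) {
  if (!length(de_results)) {
    stop("ordering error: run pairwise_de over library pairs first",
         call. = FALSE)
  }
  if (inherits(de_results, "mirna_de")) de_results <- list(de_results)
  pmin_tbl <- dplyr::bind_rows(lapply(de_results, function(d)
    tibble::tibble(name = d$name, p = d$p_value)))
  pmin_tbl <- dplyr::summarise(dplyr::group_by(pmin_tbl, .data$name),
                               p_min = min(.data$p), .groups = "drop")
  out <- dplyr::left_join(records, pmin_tbl, by = "name")
  out <- out[!is.na(out$p_min) & out$p_min <= alpha, , drop = FALSE]
  out
}
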