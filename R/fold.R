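#' Fold the best single stem-loop of a sequence
#'
#' Finds the minimum-energy single stem-loop structure of a candidate
#' precursor window under the additive SLF-1 energy model: base pairs
#' contribute GC/CG -3.0, AT/TA -2.0, GT/TG -1.0 (model kcal/mol), closing
#' the terminal loop costs +3.0, and every unpaired nucleotide interior to
#' the stem (bulges and internal loops) costs +0.5.  Nucleotides outside the
#' outermost pair are free.  If no structure achieves negative energy the
#' empty structure (mfe = 0) is returned.  The optimum is computed by an
#' exact dynamic program over all nested pair ladders; ties are broken toward
#' more pairs, then toward the lexicographically smallest pair list.
#'
#' SLF-1 deliberately trades nearest-neighbor thermodynamic accuracy for a
#' fixed, fully specified and oracle-testable model of stem-loop stability;
#' `backend` allows plugging a thermodynamic folder with the same contract
#' (a function of the sequence returning `mfe`, `pairs`, `loop`).
#'
#' @param seq A single DNA/RNA string, 15-400 nt, alphabet ACGT (U accepted
#'   and converted).
#' @param constraint Optional logical vector, one entry per nucleotide;
#'   `TRUE` positions are forbidden from pairing (used, e.g., to force a
#'   target site open when estimating site accessibility).
#' @param backend Folding backend; the default `"slf1"` is the built-in
#'   model.  A function may be supplied instead.
#' @return An object of class `hairpin`: a list with `sequence`, `pairs`
#'   (two-column matrix of 1-based pair positions, 5' arm ascending), `mfe`,
#'   `loop_span` (first and last position of the terminal loop, `NA` for the
#'   empty structure) and `dot_bracket`.
#' @examples
#' fold_best_hairpin(paste0("GGGGGG", "AAA", "CCCCCC"))$mfe  # -15
#' @export
fold_best_hairpin <- function(seq, constraint = NULL, backend = "slf1") {
  stopifnot(length(seq) == 1)
  seq <- dna_norm(seq)
  check_dna(seq)
  n <- nchar(seq)
  if (n < 15 || n > 400) {
    stop("sequence length must be in [15, 400], got ", n, call. = FALSE)
  }
  if (is.function(backend)) {
    res <- backend(seq)
  } else {
    banned <- constraint %||% logical(0)
    res <- .fold_slf1_cpp(seq, as.logical(banned))
  }
  pairs <- res$pairs
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  structure(
    list(sequence = seq,
         pairs = pairs,
         mfe = res$mfe,
         loop_span = res$loop,
         dot_bracket = paste(db, collapse = "")),
    class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat("<hairpin> ", nchar(x$sequence), " nt, ", nrow(x$pairs), " pairs, mfe ",
      format(x$mfe, nsmall = 1), "\n", sep = "")
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hairpin <- function(x, ...) {
  tibble::tibble(
    i = as.integer(x$pairs[, 1]),
    j = as.integer(x$pairs[, 2]),
    pair = paste0(substring(x$sequence, x$pairs[, 1], x$pairs[, 1]),
                  substring(x$sequence, x$pairs[, 2], x$pairs[, 2])))
}

#' @export
glance.hairpin <- function(x, ...) {
  ev <- compute_mfei(x)
  tibble::tibble(length = nchar(x$sequence), n_pairs = nrow(x$pairs),
                 mfe = x$mfe, amfe = ev$amfe, gc_percent = ev$gc_percent,
                 mfei = ev$mfei)
}

#' Stability indices of a folded hairpin
#'
#' Computes the adjusted minimum free energy `amfe = -mfe / length * 100`
#' and the minimum free energy index `mfei = amfe / gc_percent`, the
#' classical plant pre-miRNA stability filter (genuine precursors typically
#' show MFEI at or above 0.85, the default threshold downstream).  GC content
#' is computed over the full folded window.
#'
#' @param structure A `hairpin` from [fold_best_hairpin()], or a list with
#'   elements `mfe` and `sequence`.
#' @return A one-row tibble with `mfe`, `amfe`, `gc_percent`, `mfei`.
#' @export
compute_mfei <- function(structure) {
  mfe <- structure$mfe
  seq <- structure$sequence
  gc <- gc_percent(seq)
  if (gc == 0) stop("degenerate sequence: GC content is zero", call. = FALSE)
  amfe <- -mfe / nchar(seq) * 100
  tibble::tibble(mfe = mfe, amfe = amfe, gc_percent = gc, mfei = amfe / gc)
}

#' Default precursor-evaluation thresholds
#'
#' @param min_mfei Minimum MFEI (default 0.85).
#' @param max_mfe Maximum model free energy (default -18.0).
#' @param max_duplex_mismatch Maximum mature positions unpaired in the
#'   mature/star duplex (default 4).
#' @param max_asym_bulge Maximum asymmetric bulge (nt) inside the duplex
#'   (default 2).
#' @param flank Flanking window half-width in nt (default 120).
#' @return A named list of thresholds.
#' @export
precursor_thresholds <- function(min_mfei = 0.85, max_mfe = -18,
                                 max_duplex_mismatch = 4L,
                                 max_asym_bulge = 2L, flank = 120L) {
  list(min_mfei = min_mfei, max_mfe = max_mfe,
       max_duplex_mismatch = as.integer(max_duplex_mismatch),
       max_asym_bulge = as.integer(max_asym_bulge), flank = as.integer(flank))
}

# criteria for one folded window; mat_lo/mat_hi are 1-based positions of the
# mature tag inside the window
.evaluate_window <- function(hp, mat_lo, mat_hi, thresholds) {
  ev <- compute_mfei(hp)
  n_pairs <- nrow(hp$pairs)
  partner <- integer(nchar(hp$sequence))
  if (n_pairs) {
    partner[hp$pairs[, 1]] <- hp$pairs[, 2]
    partner[hp$pairs[, 2]] <- hp$pairs[, 1]
  }
  loop <- hp$loop_span
  mat_pos <- seq(mat_lo, mat_hi)
  on_arm <- n_pairs > 0 && !anyNA(loop) &&
    (mat_hi < loop[1] || mat_lo > loop[2])
  duplex_mm <- sum(partner[mat_pos] == 0L)
  # asymmetry between consecutive paired mature positions and their partners
  paired <- mat_pos[partner[mat_pos] != 0L]
  max_asym <- 0L
  if (length(paired) >= 2) {
    di <- diff(paired) - 1L
    dj <- abs(diff(partner[paired])) - 1L
    max_asym <- max(abs(di - dj))
  }
  passes <- on_arm &&
    duplex_mm <= thresholds$max_duplex_mismatch &&
    max_asym <= thresholds$max_asym_bulge &&
    hp$mfe <= thresholds$max_mfe &&
    ev$mfei >= thresholds$min_mfei
  tibble::tibble(
    window_length = nchar(hp$sequence),
    mfe = hp$mfe, amfe = ev$amfe, gc_percent = ev$gc_percent, mfei = ev$mfei,
    mature_on_one_arm = on_arm,
    duplex_mismatches = as.integer(duplex_mm),
    max_asym_bulge = as.integer(max_asym),
    passes = passes)
}

#' Evaluate a genomic locus as a miRNA precursor
#'
#' Extracts candidate precursor windows around a mapped tag, folds each with
#' [fold_best_hairpin()], and applies plant pre-miRNA criteria: the mature
#' tag must lie fully within one arm (not in the terminal loop), at most
#' `max_duplex_mismatch` mature positions may be unpaired against the star
#' arm, no asymmetric bulge larger than `max_asym_bulge` nt may interrupt the
#' mature/star duplex, and the window must satisfy `mfe <= max_mfe` and
#' `mfei >= min_mfei`.  Three window anchorings are tried (tag centred; tag
#' at the 5' end with `2*flank` downstream; tag at the 3' end with `2*flank`
#' upstream), since a mature miRNA may sit on either arm of its hairpin; the
#' best window (passing first, then highest MFEI) is reported.
#'
#' @param genome A named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosomes.
#' @param tag_locus One-row tibble/list with `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive).
#' @param tag_seq The tag sequence (must occur at the locus on the given
#'   strand).
#' @param thresholds From [precursor_thresholds()].
#' @return A one-row tibble (fields of the window evaluation plus `window`,
#'   the folded sequence, and `passes`).
#' @export
evaluate_precursor <- function(genome, tag_locus, tag_seq,
                               thresholds = precursor_thresholds()) {
  genome <- as_genome_set(genome)
  tag_seq <- dna_norm(tag_seq)
  chrom <- as.character(tag_locus$chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom, call. = FALSE)
  chrom_len <- Biostrings::width(genome[chrom])
  flank <- thresholds$flank
  s <- as.integer(tag_locus$start); e <- as.integer(tag_locus$end)
  windows <- list(c(s - flank, e + flank),
                  c(s, e + 2L * flank),
                  c(s - 2L * flank, e))
  best <- NULL
  for (w in windows) {
    lo <- max(1L, w[1]); hi <- min(chrom_len, w[2])
    if (hi - lo + 1L < 15L) next
    win <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
    mat_lo <- s - lo + 1L; mat_hi <- e - lo + 1L
    if (identical(as.character(tag_locus$strand), "-")) {
      win <- revcomp(win)
      n <- nchar(win)
      tmp <- n - mat_hi + 1L
      mat_hi <- n - mat_lo + 1L
      mat_lo <- tmp
    }
    if (substring(win, mat_lo, mat_hi) != tag_seq) next
    hp <- fold_best_hairpin(win)
    ev <- .evaluate_window(hp, mat_lo, mat_hi, thresholds)
    ev$window <- win
    if (is.null(best) ||
        (ev$passes && !best$passes) ||
        (ev$passes == best$passes && ev$mfei > best$mfei)) {
      best <- ev
    }
  }
  if (is.null(best)) {
    best <- tibble::tibble(window_length = NA_integer_, mfe = NA_real_,
                           amfe = NA_real_, gc_percent = NA_real_,
                           mfei = NA_real_, mature_on_one_arm = FALSE,
                           duplex_mismatches = NA_integer_,
                           max_asym_bulge = NA_integer_, passes = FALSE,
                           window = NA_character_)
  }
  best
}

# coerce character vectors or DNAStringSet to DNAStringSet
as_genome_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) stop("genome sequences must be named", call. = FALSE)
    return(Biostrings::DNAStringSet(x))
  }
  stop("genome must be a DNAStringSet or named character vector", call. = FALSE)
}
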