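#' Generate a synthetic genome with planted miRNA hairpins
#'
#' Builds random chromosomes and embeds `n_hairpins` non-overlapping
#' stem-loop loci, each of the form `arm + loop(6-12 nt) +
#' reverse-complement(arm)` with 0-3 planted mispairs in the star arm, arm
#' length 55-90 nt and arm GC content drawn in \[40, 65\] percent.  A mature
#' 20-22-mer is placed fully within one arm (the 5p or 3p arm at random) and
#' is guaranteed to occur in the final genome only at its truth locus
#' (colliding hairpins are redrawn).  Hairpins are planted on either strand.
#' Everything is reproducible from `seed`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (>= 1000 nt).
#' @param n_hairpins Number of planted hairpin loci.
#' @param seed Integer seed.
#' @param gc_background Background GC fraction (default 0.45).
#' @param margin Minimum spacing between loci and from chromosome ends
#'   (default 300 nt, enough for downstream 120-nt flank windows).
#' @return A list with `genome` (a named `DNAStringSet`) and `truth`
#'   (a tibble: `name`, `mature_seq`, `arm`, `chrom`, `strand`, `start`,
#'   `end`, `hairpin_start`, `hairpin_end`, `precursor`,
#'   `mature_start_in_precursor`, `n_mispair`).
#' @export
synth_genome <- function(n_chromosomes = 1L, chrom_length = 100000L,
                         n_hairpins = 10L, seed = 1L,
                         gc_background = 0.45, margin = 300L) {
  stopifnot(chrom_length >= 1000L, n_hairpins >= 1L)
  set.seed(as.integer(seed))
  max_hp <- 2L * 90L + 12L
  capacity <- n_chromosomes * floor((chrom_length - margin) / (max_hp + margin))
  if (n_hairpins > capacity) {
    stop("capacity error: ", n_hairpins, " hairpins do not fit without ",
         "overlap in ", n_chromosomes, " x ", chrom_length, " nt", call. = FALSE)
  }
  chroms <- stats::setNames(
    vapply(seq_len(n_chromosomes), function(i)
      random_dna(chrom_length, gc_background), character(1)),
    paste0("chr", seq_len(n_chromosomes)))

  draw_hairpin <- function() {
    # arms are drawn from the strong end of the plant pre-miRNA range: the
    # planted stem must be the unique energy optimum of its 260-nt
    # evaluation window (random windows fold to roughly -155..-180 under
    # the SLF-1 model), otherwise the planted truth is not re-derivable
    arm_len <- sample(80:90, 1)
    gc <- stats::runif(1, 0.55, 0.65)
    arm5 <- random_dna(arm_len, gc)
    loop <- random_dna(sample(6:12, 1), 0.3)
    arm3 <- revcomp(arm5)
    n_mis <- sample(0:3, 1)
    if (n_mis > 0) {
      pos <- sample(arm_len, n_mis)
      a3 <- strsplit(arm3, "")[[1]]
      for (p in pos) {
        a3[p] <- sample(setdiff(.dna_bases, a3[p]), 1)
      }
      arm3 <- paste(a3, collapse = "")
    }
    hairpin <- paste0(arm5, loop, arm3)
    hp_len <- nchar(hairpin)
    mat_len <- sample(20:22, 1)
    arm <- sample(c("5p", "3p"), 1)
    # the mature must sit within the evaluation flank (120 nt) of both
    # hairpin ends, or the stem can never be folded together with its star
    # arm in any tag-anchored window
    lo_arm <- if (arm == "5p") 1L else arm_len + nchar(loop) + 1L
    hi_arm <- if (arm == "5p") arm_len else hp_len
    lo_ok <- max(lo_arm, hp_len - mat_len + 1L - 118L)
    hi_ok <- min(hi_arm - mat_len + 1L, 119L)
    mat_start <- if (lo_ok <= hi_ok)
      sample(seq(lo_ok, hi_ok), 1) else lo_arm
    list(hairpin = hairpin, arm = arm, mat_start = mat_start,
         mature = substr(hairpin, mat_start, mat_start + mat_len - 1L),
         n_mispair = n_mis)
  }

  # assign loci round-robin over chromosomes with even spacing
  per_chrom <- table(rep(names(chroms), length.out = n_hairpins))
  truth <- list()
  k <- 0L
  for (cn in names(chroms)) {
    nh <- if (cn %in% names(per_chrom)) per_chrom[[cn]] else 0L
    if (nh == 0) next
    slot <- floor((chrom_length - 2 * margin) / nh)
    for (s in seq_len(nh)) {
      k <- k + 1L
      for (try in 1:25) {
        hp <- draw_hairpin()
        hlen <- nchar(hp$hairpin)
        lo <- margin + (s - 1L) * slot +
          sample(max(1L, slot - hlen - margin), 1)
        hi <- lo + hlen - 1L
        strand <- sample(c("+", "-"), 1)
        planted <- if (strand == "+") hp$hairpin else revcomp(hp$hairpin)
        chroms[[cn]] <- paste0(substr(chroms[[cn]], 1L, lo - 1L), planted,
                               substr(chroms[[cn]], hi + 1L, chrom_length))
        mat_len <- nchar(hp$mature)
        if (strand == "+") {
          mstart <- lo + hp$mat_start - 1L
        } else {
          mstart <- hi - (hp$mat_start + mat_len - 1L) + 1L
        }
        truth[[k]] <- tibble::tibble(
          name = sprintf("syn-miR%d", k), mature_seq = hp$mature,
          arm = hp$arm, chrom = cn, strand = strand,
          start = as.integer(mstart), end = as.integer(mstart + mat_len - 1L),
          hairpin_start = as.integer(lo), hairpin_end = as.integer(hi),
          precursor = hp$hairpin,
          mature_start_in_precursor = as.integer(hp$mat_start),
          n_mispair = as.integer(hp$n_mispair))
        break
      }
    }
  }
  truth <- dplyr::bind_rows(truth)

  # redraw any hairpin whose mature collides with background or another
  # hairpin (unique truth loci are part of the generator contract); the
  # mature's own star arm is close to its reverse complement and may match
  # it exactly when no mispair falls opposite the mature, so occurrences
  # inside the hairpin's own span are not collisions
  count_outside_hits <- function(i) {
    pat <- Biostrings::DNAString(truth$mature_seq[i])
    total <- 0L
    for (cn in names(chroms)) {
      subj <- Biostrings::DNAString(chroms[[cn]])
      st <- c(Biostrings::start(Biostrings::matchPattern(pat, subj)),
              Biostrings::start(Biostrings::matchPattern(
                Biostrings::reverseComplement(pat), subj)))
      if (cn == truth$chrom[i]) {
        st <- st[st < truth$hairpin_start[i] - 25L |
                   st > truth$hairpin_end[i] + 25L]
      }
      total <- total + length(st)
    }
    total
  }
  for (pass in 1:10) {
    n_hits <- vapply(seq_len(nrow(truth)), count_outside_hits, integer(1))
    bad <- which(n_hits != 0L | duplicated(truth$mature_seq))
    if (!length(bad)) break
    for (i in bad) {
      cn <- truth$chrom[i]
      lo <- truth$hairpin_start[i]
      old_len <- truth$hairpin_end[i] - lo + 1L
      hp <- NULL
      for (try in 1:25) {
        cand <- draw_hairpin()
        if (nchar(cand$hairpin) <= old_len) { hp <- cand; break }
      }
      if (is.null(hp)) next
      hlen <- nchar(hp$hairpin)
      strand <- truth$strand[i]
      planted <- if (strand == "+") hp$hairpin else revcomp(hp$hairpin)
      pad <- if (hlen < old_len) random_dna(old_len - hlen, gc_background) else ""
      # keep the locus span fixed so other coordinates stay valid
      chroms[[cn]] <- paste0(substr(chroms[[cn]], 1L, lo - 1L), planted, pad,
                             substr(chroms[[cn]], lo + old_len,
                                    nchar(chroms[[cn]])))
      mat_len <- nchar(hp$mature)
      hi <- lo + hlen - 1L
      if (strand == "+") {
        mstart <- lo + hp$mat_start - 1L
      } else {
        mstart <- hi - (hp$mat_start + mat_len - 1L) + 1L
      }
      truth$mature_seq[i] <- hp$mature
      truth$arm[i] <- hp$arm
      truth$start[i] <- as.integer(mstart)
      truth$end[i] <- as.integer(mstart + mat_len - 1L)
      truth$hairpin_end[i] <- as.integer(hi)
      truth$precursor[i] <- hp$hairpin
      truth$mature_start_in_precursor[i] <- as.integer(hp$mat_start)
      truth$n_mispair[i] <- as.integer(hp$n_mispair)
    }
  }
  attr(truth, "seed") <- as.integer(seed)
  list(genome = Biostrings::DNAStringSet(chroms), truth = truth)
}

#' Attach differential-expression ground truth to planted miRNAs
#'
#' Adds `baseline` (relative abundance; proportional to the expected read
#' count of each miRNA in the untreated libraries) and `fold_change`
#' (multiplier applied in the Cd-treated library) columns to a truth table.
#' Defaults draw baselines from a truncated Pareto distribution (alpha = 1,
#' range 1-1000), the heavily right-skewed abundance profile typical of
#' small-RNA tag counts, and set all fold changes to 1 (a null
#' configuration).
#'
#' @param truth Truth tibble from [synth_genome()] (or [synth_null_truth()]).
#' @param baseline Numeric vector (recycled) or `NULL` for Pareto defaults.
#' @param fold_change Numeric vector (recycled), all > 0; default 1.
#' @param seed Seed used only when baselines are drawn.
#' @return The truth tibble with `baseline` and `fold_change` columns.
#' @export
with_de_truth <- function(truth, baseline = NULL, fold_change = 1,
                          seed = 1L) {
  n <- nrow(truth)
  if (is.null(baseline)) {
    set.seed(as.integer(seed))
    u <- stats::runif(n)
    lo <- 1; hi <- 1000  # truncated Pareto, alpha = 1
    baseline <- lo * hi / (hi - u * (hi - lo))
  }
  stopifnot(all(fold_change > 0), all(baseline > 0))
  truth$baseline <- rep_len(baseline, n)
  truth$fold_change <- rep_len(fold_change, n)
  truth
}

#' Minimal truth table of free-floating synthetic tags
#'
#' Generates `n` random 20-22-nt mature sequences with no genome or
#' precursor context, for large-scale count simulations (e.g. null
#' calibration of the differential-expression stage) where hairpin loci are
#' not needed.
#'
#' @param n Number of tags.
#' @param seed Integer seed.
#' @return A truth tibble compatible with [synth_libraries()].
#' @export
synth_null_truth <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  seqs <- character(n)
  for (i in seq_len(n)) seqs[i] <- random_dna(sample(20:22, 1), 0.45)
  while (anyDuplicated(seqs)) {
    d <- which(duplicated(seqs))
    for (i in d) seqs[i] <- random_dna(sample(20:22, 1), 0.45)
  }
  tibble::tibble(name = sprintf("tag%d", seq_len(n)), mature_seq = seqs,
                 arm = NA_character_, chrom = NA_character_,
                 strand = NA_character_, start = NA_integer_,
                 end = NA_integer_, hairpin_start = NA_integer_,
                 hairpin_end = NA_integer_, precursor = NA_character_,
                 mature_start_in_precursor = NA_integer_,
                 n_mispair = NA_integer_)
}
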