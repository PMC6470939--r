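#' Simulate three small-RNA sequencing libraries with planted truth
#'
#' Draws per-library read counts for each planted miRNA from a negative
#' binomial with mean proportional to its `baseline` in the two untreated
#' libraries (C0, C1) and `baseline * fold_change` in the Cd-treated
#' library (Cd1); `dispersion` is the NB overdispersion (variance =
#' mu + dispersion * mu^2; 0 gives Poisson).  A common scale factor makes
#' planted reads fill `depth * (1 - background_fraction)` reads, the rest
#' being background: fragments drawn from a finite pool of distinct
#' genomic/random sequences with Zipf-weighted abundances, plus fragments of
#' the bundled synthetic contaminant set (rRNA/tRNA-like).  miRNA reads
#' include 5'/3' end-variant isoforms at configurable rates (verified
#' against precursor context for extensions).  Every read carries the 3'
#' adapter and is truncated to `read_length` (single-end short-read style).
#'
#' @param truth Truth tibble with `baseline` and `fold_change` columns (see
#'   [with_de_truth()]).
#' @param depth Reads per library (>= 10000).
#' @param dispersion NB dispersion (default 0.1).
#' @param seed Integer seed; identical seeds and configs give identical
#'   output, byte for byte.
#' @param libraries Library ids; the last one receives the fold change
#'   (default `c("C0", "C1", "Cd1")`).
#' @param background_fraction Fraction of reads that are background or
#'   contaminant (default 0.2).
#' @param contaminant_share Share of the background that is contaminant
#'   derived (default 0.5).
#' @param genome Optional genome (`DNAStringSet`) used to draw the
#'   background pool; random sequence is used otherwise.
#' @param pool_size Number of distinct background fragments (default 300).
#' @param adapter 3' adapter appended to every insert.
#' @param read_length Final read length (default 36).
#' @param variant_rates Named isoform rates: `exact`, `r_trim`, `r_ext`,
#'   `l_trim`, `l_ext` (renormalized; extensions fall back to exact without
#'   precursor context).
#' @param contaminants Contaminant sequences; defaults to the bundled
#'   synthetic set.
#' @return A list: `reads` (tibble `library`, `sequence` of raw reads),
#'   `planted_counts` (tibble `name`, `library`, `count`, `mean`),
#'   `config` (echo of all parameters).
#' @export
synth_libraries <- function(truth, depth = 1e6, dispersion = 0.1, seed = 1L,
                            libraries = c("C0", "C1", "Cd1"),
                            background_fraction = 0.2,
                            contaminant_share = 0.5,
                            genome = NULL, pool_size = 300L,
                            adapter = default_adapter(), read_length = 36L,
                            variant_rates = c(exact = 0.72, r_trim = 0.10,
                                              r_ext = 0.08, l_trim = 0.06,
                                              l_ext = 0.04),
                            contaminants = synthetic_contaminants()) {
  stopifnot(depth >= 10000)
  if (!all(c("baseline", "fold_change") %in% names(truth))) {
    stop("truth needs baseline/fold_change columns; see with_de_truth()",
         call. = FALSE)
  }
  stopifnot(all(truth$baseline > 0))
  set.seed(as.integer(seed))
  n_mi <- nrow(truth)
  scale_f <- depth * (1 - background_fraction) / sum(truth$baseline)
  variant_rates <- variant_rates / sum(variant_rates)

  # isoform sequence for one miRNA and one variant kind
  iso_seq <- function(i, kind) {
    mat <- truth$mature_seq[i]
    pre <- truth$precursor[i]
    ms <- truth$mature_start_in_precursor[i]
    L <- nchar(mat)
    switch(kind,
      exact = mat,
      r_trim = substr(mat, 1L, L - 1L),
      l_trim = substr(mat, 2L, L),
      r_ext = if (!is.na(pre) && ms + L <= nchar(pre))
        substr(pre, ms, ms + L) else mat,
      l_ext = if (!is.na(pre) && ms >= 2L)
        substr(pre, ms - 1L, ms + L - 1L) else mat)
  }
  iso_mat <- t(vapply(seq_len(n_mi), function(i)
    vapply(names(variant_rates), function(k) iso_seq(i, k), character(1)),
    character(length(variant_rates))))

  # background pool: distinct fragments with Zipf-weighted abundances
  pool <- character(pool_size)
  if (!is.null(genome)) {
    glens <- Biostrings::width(genome)
    for (k in seq_len(pool_size)) {
      ci <- sample(length(genome), 1)
      w <- sample(18:30, 1)
      st <- sample(glens[ci] - w, 1)
      pool[k] <- as.character(Biostrings::subseq(genome[[ci]], st, st + w - 1L))
    }
  } else {
    for (k in seq_len(pool_size)) pool[k] <- random_dna(sample(18:30, 1), 0.45)
  }
  pool_w <- 1 / seq_len(pool_size)
  contaminants <- dna_norm(as.character(contaminants))

  reads <- list()
  planted <- list()
  low_mean <- FALSE
  for (lib in libraries) {
    mult <- if (lib == libraries[length(libraries)]) truth$fold_change else 1
    mu <- truth$baseline * mult * scale_f
    if (any(mu < 1)) low_mean <- TRUE
    counts <- if (dispersion <= 0) stats::rpois(n_mi, mu) else
      stats::rnbinom(n_mi, mu = mu, size = 1 / dispersion)
    planted[[lib]] <- tibble::tibble(name = truth$name, library = lib,
                                     count = as.integer(counts), mean = mu)
    # miRNA-derived inserts with end-variant isoforms
    kinds <- sample.int(length(variant_rates), sum(counts), replace = TRUE,
                        prob = variant_rates)
    mi_idx <- rep(seq_len(n_mi), counts)
    inserts_mi <- iso_mat[cbind(mi_idx, kinds)]

    # background is a fixed share of the target depth in every library, so
    # the treated library keeps its contaminant/background complexity even
    # when up-regulated miRNAs push its total slightly above depth
    n_bg <- as.integer(round(depth * background_fraction))
    n_contam <- round(n_bg * contaminant_share)
    n_pool <- n_bg - n_contam
    inserts_bg <- pool[sample.int(pool_size, n_pool, replace = TRUE,
                                  prob = pool_w)]
    cl <- nchar(contaminants)
    ci <- sample(length(contaminants), n_contam, replace = TRUE,
                 prob = cl / sum(cl))
    w <- sample(18:30, n_contam, replace = TRUE)
    w <- pmin(w, cl[ci])
    st <- 1L + floor(stats::runif(n_contam) * (cl[ci] - w + 1L))
    inserts_ct <- substr(contaminants[ci], st, st + w - 1L)

    inserts <- c(inserts_mi, inserts_bg, inserts_ct)
    reads[[lib]] <- tibble::tibble(
      library = lib,
      sequence = substr(paste0(inserts, adapter), 1L, read_length))
  }
  if (low_mean) {
    warning("depth too small to represent every planted miRNA at mean >= 1",
            call. = FALSE)
  }
  list(reads = dplyr::bind_rows(reads),
       planted_counts = dplyr::bind_rows(planted),
       config = list(depth = depth, dispersion = dispersion, seed = seed,
                     libraries = libraries,
                     background_fraction = background_fraction,
                     contaminant_share = contaminant_share,
                     pool_size = pool_size, adapter = adapter,
                     read_length = read_length,
                     variant_rates = as.list(variant_rates)))
}

#' Bundled synthetic contaminant reference set
#'
#' A small set of synthetic rRNA/tRNA/snRNA-like sequences shipped as plain
#' FASTA, used as the default contaminant filter reference and as the
#' contaminant source in the read simulator.  These are synthetic stand-ins
#' (see the file name), not database sequences.
#'
#' @return A named character vector of sequences.
#' @export
synthetic_contaminants <- function() {
  path <- system.file("extdata", "synthetic_contaminants.fa",
                      package = "xylemiR", mustWork = TRUE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write per-library FASTQ files
#'
#' Plain single-end FASTQ with a constant Phred+33 quality of `I`; one file
#' `<library>.fastq` per library.  Output is deterministic given the input
#' order.
#'
#' @param reads Tibble with `library` and `sequence`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lib in unique(reads$library)) {
    seqs <- reads$sequence[reads$library == lib]
    path <- file.path(dir, paste0(lib, ".fastq"))
    ids <- sprintf("@%s_%d", lib, seq_along(seqs))
    qual <- strrep("I", nchar(seqs))
    writeLines(rbind(ids, seqs, "+", qual), path, sep = "\n")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-library FASTQ/FASTA files into a read tibble
#'
#' @param paths Named character vector of file paths; names are library ids.
#' @return Tibble with `library` and `sequence`.
#' @export
read_libraries <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "",
                        basename(paths))
  }
  out <- lapply(names(paths), function(lib) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", paths[[lib]])) "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(paths[[lib]], format = fmt)
    tibble::tibble(library = lib, sequence = as.character(x))
  })
  dplyr::bind_rows(out)
}

#' Write a named sequence set as FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  writeLines(rbind(paste0(">", names(seqs)), unname(seqs)), path)
  invisible(path)
}

#' Write planted hairpin loci as GFF3
#'
#' 1-based inclusive coordinates, one `miRNA_primary_transcript` feature per
#' planted hairpin and one `miRNA` feature per mature locus.
#'
#' @param truth Truth tibble from [synth_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_gff <- function(truth, path) {
  hp <- sprintf("%s\txylemiR\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s_hairpin",
                truth$chrom, truth$hairpin_start, truth$hairpin_end,
                truth$strand, truth$name)
  mat <- sprintf("%s\txylemiR\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                 truth$chrom, truth$start, truth$end, truth$strand, truth$name)
  writeLines(c("##gff-version 3", hp, mat), path)
  invisible(path)
}
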