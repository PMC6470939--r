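#' Pipeline configuration
#'
#' Collects all inputs and thresholds of the pipeline into one list that
#' serializes cleanly to JSON (see [run_pipeline()]'s manifest).  Inputs may
#' be file paths (FASTQ/FASTA/TSV) or in-memory objects (tibbles, named
#' vectors, `DNAStringSet`).
#'
#' @param reads Named vector of FASTQ/FASTA paths (names = library ids) or
#'   a tibble with `library`/`sequence`.
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param own_matures,own_precursors,monocot_matures,monocot_precursors
#'   Reference FASTA paths or named vectors (any may be `NULL`).
#' @param transcripts Transcriptome cDNA FASTA path or named vector.
#' @param degradome Degradome count TSV path or tibble (optional).
#' @param gene_annotations Named character vector gene id -> description
#'   (optional; drives the functional-bin report).
#' @param outdir Output directory.
#' @param libraries Ordered library ids (default C0, C1, Cd1); the DE
#'   comparison is the last two.
#' @param adapter 3' adapter for trimming.
#' @param rng_seed Integer seed echoed into the manifest.
#' @param alpha,min_abs_log2fc DE thresholds.
#' @param expectation_cutoff,penalty_cutoff Target-scheme cutoffs.
#' @param category_max,pos_tolerance Degradome support settings.
#' @param length_range Tag length window kept at processing.
#' @param annotation Policy from [annotation_policy()].
#' @return A `xylem_config` list.
#' @export
xylem_config <- function(reads, genome, own_matures = NULL,
                         own_precursors = NULL, monocot_matures = NULL,
                         monocot_precursors = NULL, transcripts = NULL,
                         degradome = NULL, gene_annotations = NULL,
                         outdir = tempfile("xylemir_run_"),
                         libraries = c("C0", "C1", "Cd1"),
                         adapter = default_adapter(), rng_seed = 1L,
                         alpha = 0.05, min_abs_log2fc = 1,
                         expectation_cutoff = 5, penalty_cutoff = 2.5,
                         category_max = 2L, pos_tolerance = 1L,
                         length_range = c(18L, 30L),
                         annotation = annotation_policy()) {
  structure(list(
    reads = reads, genome = genome, own_matures = own_matures,
    own_precursors = own_precursors, monocot_matures = monocot_matures,
    monocot_precursors = monocot_precursors, transcripts = transcripts,
    degradome = degradome, gene_annotations = gene_annotations,
    outdir = outdir, libraries = libraries, adapter = adapter,
    rng_seed = as.integer(rng_seed), alpha = alpha,
    min_abs_log2fc = min_abs_log2fc,
    expectation_cutoff = expectation_cutoff,
    penalty_cutoff = penalty_cutoff, category_max = category_max,
    pos_tolerance = pos_tolerance, length_range = length_range,
    annotation = annotation), class = "xylem_config")
}

.load_seqs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    return(stats::setNames(as.character(s), sub("\\s.*$", "", names(s))))
  }
  if (inherits(x, "DNAStringSet")) {
    return(stats::setNames(as.character(x), names(x)))
  }
  x
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full xylem-sap miRNA pipeline
#'
#' Executes the stages in order — read processing, annotation, differential
#' expression, target prediction, degradome evidence, reporting — writing
#' one TSV per stage plus a JSON manifest (seed, thresholds, input hashes,
#' per-stage record counts) to `config$outdir`.  Re-running with the same
#' config and inputs reproduces the outputs byte for byte.
#'
#' @param config A [xylem_config()].
#' @return Invisibly, a list with every stage result (`tags`, `records`,
#'   `de`, `hits_a`, `hits_b`, `consensus`, `supported`, `reports`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "xylem_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(rng_seed = config$rng_seed,
                   libraries = as.list(config$libraries),
                   thresholds = list(
                     alpha = config$alpha,
                     min_abs_log2fc = config$min_abs_log2fc,
                     expectation_cutoff = config$expectation_cutoff,
                     penalty_cutoff = config$penalty_cutoff,
                     category_max = config$category_max,
                     pos_tolerance = config$pos_tolerance,
                     length_range = as.list(config$length_range),
                     annotation = config$annotation))
  hash_input <- function(x) {
    if (is.character(x) && length(x) >= 1 && all(file.exists(x))) {
      as.list(tools::md5sum(x))
    } else if (!is.null(x)) "in-memory" else NULL
  }
  manifest$inputs <- list(reads = hash_input(unlist(config$reads)),
                          genome = hash_input(config$genome),
                          transcripts = hash_input(config$transcripts),
                          degradome = hash_input(config$degradome))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- process ------------------------------------------------------------
  tags <- run_stage("process", {
    reads <- config$reads
    if (is.character(reads)) reads <- read_libraries(reads)
    contams <- synthetic_contaminants()
    tags <- process_reads(reads, adapter = config$adapter,
                          contaminants = contams,
                          length_range = config$length_range)
    tags <- normalize_counts(tags)
    .write_tsv(tags, file.path(config$outdir, "tags.tsv"))
    .write_tsv(attr(tags, "ledger"),
               file.path(config$outdir, "filter_ledger.tsv"))
    tags
  })
  manifest$stages$process <- list(n_tags = nrow(tags))

  # --- annotate -----------------------------------------------------------
  genome <- if (is.character(config$genome) && length(config$genome) == 1 &&
                  file.exists(config$genome))
    Biostrings::readDNAStringSet(config$genome) else
      as_genome_set(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  records <- run_stage("annotate", {
    rec <- classify_tags(tags,
                         own_matures = .load_seqs(config$own_matures),
                         own_precursors = .load_seqs(config$own_precursors),
                         monocot_matures = .load_seqs(config$monocot_matures),
                         monocot_precursors =
                           .load_seqs(config$monocot_precursors),
                         genome = genome, policy = config$annotation)
    .write_tsv(rec, file.path(config$outdir, "annotation.tsv"))
    .write_tsv(attr(rec, "drops"),
               file.path(config$outdir, "annotation_drops.tsv"))
    rec
  })
  manifest$stages$annotate <-
    c(as.list(table(records$class)),
      list(n_dropped = nrow(attr(records, "drops"))))

  # --- differential expression -------------------------------------------
  de <- run_stage("de", {
    libs <- config$libraries
    pairs <- utils::combn(libs, 2, simplify = FALSE)
    de <- lapply(pairs, function(p)
      pairwise_de(records, p, alpha = config$alpha,
                  min_abs_log2fc = config$min_abs_log2fc,
                  names = records$name))
    names(de) <- vapply(pairs, paste, character(1), collapse = "_")
    for (nm in names(de)) {
      .write_tsv(de[[nm]], file.path(config$outdir,
                                     paste0("de_", nm, ".tsv")))
    }
    de
  })
  main_pair <- paste(utils::tail(config$libraries, 2), collapse = "_")
  reg <- classify_regulation(de[[main_pair]])
  manifest$stages$de <- list(comparison = main_pair,
                             n_up = nrow(reg$up), n_down = nrow(reg$down))

  # --- targets ------------------------------------------------------------
  hits_a <- hits_b <- consensus <- NULL
  if (!is.null(config$transcripts)) {
    res <- run_stage("targets", {
      transcripts <- .load_seqs(config$transcripts)
      signif <- select_significant(records, de, alpha = config$alpha)
      mirnas <- stats::setNames(signif$sequence, signif$name)
      mirnas <- mirnas[!duplicated(names(mirnas))]
      hits_a <- scan_targets_expectation(mirnas, transcripts,
                                         cutoff = config$expectation_cutoff)
      hits_b <- scan_targets_penalty(mirnas, transcripts,
                                     cutoff = config$penalty_cutoff)
      consensus <- intersect_predictions(hits_a, hits_b)
      .write_tsv(hits_a, file.path(config$outdir, "targets_expectation.tsv"))
      .write_tsv(hits_b, file.path(config$outdir, "targets_penalty.tsv"))
      .write_tsv(consensus, file.path(config$outdir, "targets_consensus.tsv"))
      list(a = hits_a, b = hits_b, consensus = consensus)
    })
    hits_a <- res$a; hits_b <- res$b; consensus <- res$consensus
    manifest$stages$targets <- list(
      n_hits_a = nrow(hits_a), n_hits_b = nrow(hits_b),
      n_consensus = nrow(consensus),
      n_genes = length(unique(consensus$gene)))
  }

  # --- degradome ----------------------------------------------------------
  supported <- NULL
  if (!is.null(config$degradome) && !is.null(consensus)) {
    supported <- run_stage("degradome", {
      deg <- config$degradome
      if (is.character(deg)) deg <- read_degradome_tsv(deg)
      supp <- degradome_support(consensus, deg,
                                category_max = config$category_max,
                                pos_tolerance = config$pos_tolerance)
      .write_tsv(supp, file.path(config$outdir, "degradome_support.tsv"))
      supp
    })
    manifest$stages$degradome <- list(
      n_confirmed = sum(supported$deg_count >= 1))
  }

  # --- report -------------------------------------------------------------
  reports <- run_stage("report", {
    write_reports(records = records, de = de[[main_pair]],
                  supported = supported %||% consensus,
                  gene_annotations = config$gene_annotations,
                  outdir = config$outdir)
  })
  manifest$stages$report <- lapply(reports, nrow)

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tags = tags, records = records, de = de,
                 hits_a = hits_a, hits_b = hits_b, consensus = consensus,
                 supported = supported, reports = reports,
                 manifest = manifest))
}

#' Default keyword table for functional binning
#'
#' Maps lowercase substrings of gene descriptions to the fixed functional
#' vocabulary used in the reports (first match by table order wins).
#'
#' @return A tibble with `keyword` and `bin`.
#' @export
default_keyword_table <- function() {
  tibble::tribble(
    ~keyword, ~bin,
    "laccase", "Secondary metabolism",
    "isopentenyl", "Secondary metabolism",
    "mate efflux", "Metal handling",
    "major facilitator", "Metal handling",
    "heavy-metal", "Metal handling",
    "heavy metal", "Metal handling",
    "abc transporter", "Metal handling",
    "metal", "Metal handling",
    "auxin", "Phytohormone",
    "f-box", "Phytohormone",
    "aldehyde oxidase", "Phytohormone",
    "transport inhibitor response", "Phytohormone",
    "myb", "Transcription factors",
    "wrky", "Transcription factors",
    "nac", "Transcription factors",
    "bhlh", "Transcription factors",
    "homeobox", "Transcription factors",
    "zinc finger", "Transcription factors",
    "squamosa promoter binding", "Transcription factors",
    "nuclear transcription factor", "Transcription factors",
    "gras", "Transcription factors",
    "ap2", "Transcription factors",
    "transcription factor", "Transcription factors",
    "kinase", "Signaling",
    "calcium", "Signaling",
    "calcineurin", "Signaling",
    "calmodulin", "Signaling",
    "cam-binding", "Signaling",
    "iq-domain", "Signaling",
    "phosphatase", "Signaling",
    "dnaj", "Abiotic stress",
    "heat", "Abiotic stress",
    "dehydration", "Abiotic stress",
    "wound", "Abiotic stress",
    "methyltransferase", "Abiotic stress")
}

#' Assign genes to functional bins by keyword
#'
#' A deliberately simple, auditable stand-in for ontology-based enrichment:
#' the first keyword (by table order) found in the lowercased description
#' assigns the bin; unmatched genes go to `Other`.  Assignment is a pure
#' function of the annotation text.
#'
#' @param gene_annotations Named character vector, gene id -> description.
#' @param keyword_table From [default_keyword_table()] (columns `keyword`,
#'   `bin`).
#' @return A tibble with `gene_id`, `description`, `bin`.
#' @export
assign_bins <- function(gene_annotations,
                        keyword_table = default_keyword_table()) {
  desc <- tolower(gene_annotations)
  bins <- rep("Other", length(desc))
  unset <- rep(TRUE, length(desc))
  for (i in seq_len(nrow(keyword_table))) {
    hit <- unset & stringi::stri_detect_fixed(desc, keyword_table$keyword[i])
    bins[hit] <- keyword_table$bin[i]
    unset[hit] <- FALSE
  }
  tibble::tibble(gene_id = names(gene_annotations),
                 description = unname(gene_annotations), bin = bins)
}

#' Write the report tables of a pipeline run
#'
#' Emits the high-confidence novel miRNA table (name, per-library
#' normalized counts, sequence, size, MFEI), the differential-expression
#' table (with loci), the consensus-target table (with degradome support
#' when available), the functional-bin summary, and a one-line-per-table
#' text summary whose counts equal the row counts of the written files.
#'
#' @param records `mirna_records` (normalized).
#' @param de A `mirna_de` tibble (the main comparison).
#' @param supported Consensus targets, optionally with `deg_count`.
#' @param gene_annotations Optional named vector for binning.
#' @param outdir Output directory.
#' @return Invisibly, a named list of the report tibbles.
#' @export
write_reports <- function(records, de, supported = NULL,
                          gene_annotations = NULL, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  norm_cols <- grep("^norm_", names(records), value = TRUE)
  novel <- records[records$class %in% c("novel_arm", "homolog", "novel_pc"), ]
  novel_hc <- high_confidence_filter(novel)
  tbl1 <- dplyr::select(novel_hc, "name", dplyr::all_of(norm_cols),
                        "sequence", size = "length", "mfei")
  tbl1$mfei <- round(tbl1$mfei, 2)

  reg <- classify_regulation(de)
  tbl2 <- dplyr::bind_rows(up = reg$up, down = reg$down, .id = "direction")
  tbl2 <- dplyr::left_join(
    tbl2, dplyr::distinct(records[c("name", "chrom", "strand",
                                    "start", "end")], .data$name,
                          .keep_all = TRUE), by = "name")

  tbl4 <- if (!is.null(supported)) tibble::as_tibble(supported) else
    tibble::tibble()
  bins <- if (!is.null(gene_annotations) && nrow(tbl4) &&
                "gene" %in% names(tbl4)) {
    ann <- gene_annotations[intersect(unique(tbl4$gene),
                                      names(gene_annotations))]
    assign_bins(ann)
  } else tibble::tibble()

  .write_tsv(tbl1, file.path(outdir, "report_novel_high_confidence.tsv"))
  .write_tsv(tbl2, file.path(outdir, "report_de_mirnas.tsv"))
  .write_tsv(tbl4, file.path(outdir, "report_targets.tsv"))
  .write_tsv(bins, file.path(outdir, "report_functional_bins.tsv"))
  summary_lines <- c(
    sprintf("high_confidence_novel\t%d", nrow(tbl1)),
    sprintf("de_mirnas\t%d", nrow(tbl2)),
    sprintf("consensus_targets\t%d", nrow(tbl4)),
    sprintf("binned_genes\t%d", nrow(bins)))
  writeLines(summary_lines, file.path(outdir, "report_summary.txt"))
  invisible(list(novel_high_confidence = tbl1, de_mirnas = tbl2,
                 targets = tbl4, functional_bins = bins))
}
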