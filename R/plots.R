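#' Plot the tag length distribution per library
#'
#' Read-weighted length histogram of the unique tags, the standard first
#' look at a small-RNA library (Dicer products concentrate at 20-24 nt).
#'
#' @param object A `xylem_tags` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xylem_tags <- function(object, ...) {
  libs <- attr(object, "libraries") %||%
    sub("^raw_", "", grep("^raw_", names(object), value = TRUE))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("length", paste0("raw_", libs))],
    cols = dplyr::all_of(paste0("raw_", libs)),
    names_to = "library", values_to = "reads", names_prefix = "raw_")
  long <- dplyr::summarise(dplyr::group_by(long, .data$length, .data$library),
                           reads = sum(.data$reads), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$length, .data$reads,
                                     fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tag length (nt)", y = "reads",
                  title = "Tag length distribution") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a pairwise differential-expression result
#'
#' @param object A `mirna_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirna_de <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th$min_abs_log2fc,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(th$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste("Differential expression:",
                                paste(attr(object, "comparison"),
                                      collapse = " vs "))) +
    ggplot2::theme_minimal()
}

#' Arc diagram of a folded hairpin
#'
#' @param object A `hairpin` from [fold_best_hairpin()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hairpin <- function(object, ...) {
  n <- nchar(object$sequence)
  base <- tibble::tibble(x = seq_len(n))
  p <- ggplot2::ggplot(base, ggplot2::aes(.data$x, 0)) +
    ggplot2::geom_point(size = 0.3, colour = "grey40")
  if (nrow(object$pairs)) {
    arcs <- tidy(object)
    arcs$xm <- (arcs$i + arcs$j) / 2
    arcs$h <- (arcs$j - arcs$i) / 2
    p <- p + ggplot2::geom_curve(
      data = arcs, ggplot2::aes(x = .data$i, y = 0, xend = .data$j, yend = 0),
      curvature = -0.5, linewidth = 0.2, colour = "#2c3e50", inherit.aes = FALSE)
  }
  p + ggplot2::labs(x = "position (nt)", y = NULL,
                    title = sprintf("Stem-loop, mfe %.1f", object$mfe)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Degradome T-plot for one transcript and library
#'
#' Per-position degradome 5'-end tag counts with the expected cleavage
#' position highlighted — the visual form of the category assignment in
#' [site_category()].
#'
#' @param degradome Tag-count tibble (`library`, `transcript_id`,
#'   `position`, `count`).
#' @param transcript_id Transcript to plot.
#' @param library Library to plot (default: first present).
#' @param cleavage_pos Optional expected cleavage position to mark.
#' @return A ggplot.
#' @export
plot_tplot <- function(degradome, transcript_id, library = NULL,
                       cleavage_pos = NULL) {
  lib <- library %||% degradome$library[1]
  d <- degradome[degradome$transcript_id == transcript_id &
                   degradome$library == lib, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          colour = "grey30") +
    ggplot2::labs(x = "transcript position", y = "5'-end tags",
                  title = paste("T-plot:", transcript_id, "in", lib)) +
    ggplot2::theme_minimal()
  if (!is.null(cleavage_pos)) {
    p <- p + ggplot2::geom_vline(xintercept = cleavage_pos,
                                 colour = "#c0392b", linetype = "dashed")
  }
  p
}
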