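#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot community composition from a partition report
#'
#' Bar chart of fungal transcript counts per phylum group.
#'
#' @param object A `partition_report` from [partition_transcriptome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partition_report <- function(object, ...) {
  dat <- dplyr::mutate(
    object$counts,
    phylum_group = factor(.data$phylum_group,
                          levels = setdiff(phylum_group_levels(), "NOT_APPLICABLE"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phylum_group, y = .data$n)) +
    ggplot2::geom_col(fill = "#4c72b0") +
    ggplot2::labs(x = NULL, y = "fungal transcripts",
                  title = "Community composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a parameter sweep as TPR/FPR curves
#'
#' TPR against FPR per class across the swept E-value and top-N grid.
#'
#' @param object A `benchmark_report` from [sweep_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$TPR))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$FPR, y = .data$TPR,
    colour = factor(.data$top_n), shape = factor(.data$e_value_max)
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(colour = "top N", shape = "E-value max",
                  title = "Classifier benchmark") +
    ggplot2::lims(x = c(0, NA), y = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Significance profile of the tested terms: -log10 p-value per term,
#' colored by the significance flag.
#'
#' @param object An `enrichment_result` from [hypergeometric_enrichment()].
#' @param max_terms Show at most this many top terms (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, max_terms = 25, ...) {
  dat <- utils::head(dplyr::arrange(tidy(object), .data$p_value), max_terms)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = -log10(.data$p_value), y = .data$term, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  title = "Term enrichment") +
    ggplot2::theme_minimal()
}

#' Plot tissue-specificity profiles
#'
#' Histogram of the maximum SPM per transcript with the calling threshold
#' marked; tissue-specific transcripts fall to the right of the line.
#'
#' @param spm SPM tibble from [spm_profile()].
#' @param threshold Calling threshold to mark (default 0.95).
#' @return A ggplot object.
#' @export
plot_spm_distribution <- function(spm, threshold = 0.95) {
  dat <- spm |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(max_spm = max(.data$spm), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$max_spm)) +
    ggplot2::geom_histogram(bins = 50, fill = "#55a868") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "max SPM per transcript", y = "transcripts",
                  title = "Tissue specificity") +
    ggplot2::theme_minimal()
}
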