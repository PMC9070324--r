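#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a partition report
#'
#' Returns the per-transcript calls as a tibble, one row per transcript.
#'
#' @param x A `partition_report` from [partition_transcriptome()].
#' @param ... Unused.
#' @return A tibble of per-transcript calls.
#' @export
tidy.partition_report <- function(x, ...) {
  as_tibble(x$calls)
}

#' One-row summary of a partition report
#'
#' @param x A `partition_report`.
#' @param ... Unused.
#' @return A one-row tibble: transcript counts per origin, per-group fungal
#'   counts, and `total_fungal`.
#' @export
glance.partition_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts, names_from = "phylum_group",
                             values_from = "n")
  bind_cols(
    tibble(
      n_transcripts = nrow(x$calls),
      n_host = sum(x$calls$origin == "HOST"),
      n_unclassified = sum(x$calls$origin == "UNCLASSIFIED"),
      total_fungal = x$total_fungal
    ),
    wide
  )
}

#' Tidy an enrichment result
#'
#' Enrichment results are already tibbles; `tidy()` strips the subclass.
#'
#' @param x An `enrichment_result` from [hypergeometric_enrichment()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_terms`, `n_significant`, `min_p_value`,
#'   group and background sizes.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    min_p_value = if (nrow(x) > 0) min(x$p_value) else NA_real_,
    n_group = if (nrow(x) > 0) x$n[1] else NA_integer_,
    n_background = if (nrow(x) > 0) x$N[1] else NA_integer_
  )
}

# internal: drop result subclasses without touching tibble classes
unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("enrichment_result", "benchmark_report"))
  x
}
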