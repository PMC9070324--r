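#' Select the representative (longest qualifying) isoform per locus
#'
#' Reproduces the transcript-set construction used for de novo plant
#' assemblies: per locus, among isoforms whose mean TPM across all samples is
#' strictly greater than `tpm_min` and whose annotated ORF length passes
#' `orf_min_nt`, keep the isoform with the greatest sequence length. Loci with
#' no qualifying isoform are dropped, so the output has at most one row per
#' locus.
#'
#' The ORF gate is inclusive (`>= orf_min_nt`) by default, which reconciles a
#' minimum retained CDS length equal to the threshold itself; set
#' `orf_strict = TRUE` for a strict `>` gate. Transcripts missing from the
#' expression table are treated as failing the TPM gate (reported via a
#' message); expression is never imputed.
#'
#' @param transcripts Tibble from [read_fasta()] (needs `transcript_id`,
#'   `locus_id`, `length_nt`, `orf_length_nt`).
#' @param expr Long expression tibble (see [read_expression_table()]).
#' @param tpm_min Mean-TPM threshold, exclusive (default 1).
#' @param orf_min_nt ORF length threshold in nucleotides (default 255).
#' @param orf_strict Use strict `>` for the ORF gate (default `FALSE`).
#' @return A tibble of representative transcripts, a subset of the input rows.
#' @export
select_representative_isoforms <- function(transcripts, expr, tpm_min = 1,
                                           orf_min_nt = 255, orf_strict = FALSE) {
  mean_tpm <- expr |>
    group_by(.data$transcript_id) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
  scored <- left_join(transcripts, mean_tpm, by = "transcript_id")
  n_missing <- sum(is.na(scored$mean_tpm))
  if (n_missing > 0) {
    inform(paste0(
      n_missing, " transcript(s) missing from the expression table; ",
      "treated as failing the TPM gate"
    ))
  }
  orf_ok <- if (orf_strict) scored$orf_length_nt > orf_min_nt else scored$orf_length_nt >= orf_min_nt
  scored |>
    filter(!is.na(.data$mean_tpm), .data$mean_tpm > tpm_min, orf_ok) |>
    group_by(.data$locus_id) |>
    arrange(desc(.data$length_nt), .data$transcript_id, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(match(.data$transcript_id, transcripts$transcript_id)) |>
    select(-"mean_tpm")
}

#' Assembly summary statistics
#'
#' Computes the descriptors used to summarize a transcript set: the number of
#' transcripts, the arithmetic mean sequence length, the N50 (the largest
#' length `L` such that transcripts of length `>= L` together contain at least
#' half of all assembled bases), and the minimum and maximum annotated CDS
#' (ORF) lengths.
#'
#' @param transcripts Tibble with `length_nt` and `orf_length_nt` columns.
#' @return A one-row tibble: `n_transcripts`, `mean_length_bp`, `n50_bp`,
#'   `min_cds_bp`, `max_cds_bp`.
#' @export
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = c("a", "b", "c"),
#'   length_nt = c(258L, 579L, 3099L),
#'   orf_length_nt = c(258L, 579L, 3099L)
#' )
#' assembly_summary(tx)  # N50 is 3099
assembly_summary <- function(transcripts) {
  if (nrow(transcripts) == 0) abort("assembly_summary() needs at least one transcript")
  tibble(
    n_transcripts = nrow(transcripts),
    mean_length_bp = mean(transcripts$length_nt),
    n50_bp = n50(transcripts$length_nt),
    min_cds_bp = min(transcripts$orf_length_nt),
    max_cds_bp = max(transcripts$orf_length_nt)
  )
}

#' N50 of a set of lengths
#'
#' The largest length `L` present in the set such that members of length
#' `>= L` sum to at least half the total length.
#'
#' @param lengths Positive numeric vector.
#' @return A single length from `lengths`.
#' @export
#' @examples
#' n50(c(258, 579, 3099))
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("n50() needs at least one length")
  ls <- sort(lengths, decreasing = TRUE)
  ls[which(cumsum(ls) >= sum(ls) / 2)[1]]
}
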