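#' Replicate-mean expression per tissue
#'
#' Arithmetic mean of TPM over replicates within each tissue, the expression
#' summary used by all downstream specificity analyses. Transcripts absent
#' from the expression table are absent from the result (no imputed zeros);
#' all-zero transcripts are retained.
#'
#' @param expr Long expression tibble (see [read_expression_table()]).
#' @return A tibble with columns `transcript_id`, `tissue`, `mean_tpm`.
#' @export
mean_tissue_expression <- function(expr) {
  expr |>
    group_by(.data$transcript_id, .data$tissue) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
}

#' SPM tissue-specificity profiles
#'
#' The specificity measure SPM of tissue `t` is the cosine of the
#' transcript's tissue-mean expression vector with the unit vector of `t`:
#' `SPM_t = x_t / sqrt(sum_u x_u^2)`. Squared SPM values sum to one for any
#' transcript with non-zero expression, so at most one tissue can exceed
#' `1/sqrt(2)` and a call above a threshold near 1 is unique. Transcripts
#' whose expression is zero in every tissue have no profile and are dropped
#' (with a message).
#'
#' @param tissue_means Tibble from [mean_tissue_expression()].
#' @return A tibble with columns `transcript_id`, `tissue`, `spm`.
#' @export
#' @examples
#' tm <- tibble::tibble(
#'   transcript_id = "t1", tissue = c("leaf", "stem", "root"),
#'   mean_tpm = c(1, 0, 10)
#' )
#' spm_profile(tm)  # root SPM = 10 / sqrt(101)
spm_profile <- function(tissue_means) {
  if (any(tissue_means$mean_tpm < 0)) abort("negative expression value")
  n_tissues <- length(unique(tissue_means$tissue))
  if (n_tissues < 2) abort("SPM needs at least 2 tissues")
  out <- tissue_means |>
    group_by(.data$transcript_id) |>
    mutate(norm = sqrt(sum(.data$mean_tpm^2))) |>
    ungroup()
  n_zero <- length(unique(out$transcript_id[out$norm == 0]))
  if (n_zero > 0) {
    inform(paste0(n_zero, " transcript(s) with all-zero expression have no SPM profile"))
  }
  out |>
    filter(.data$norm > 0) |>
    mutate(spm = .data$mean_tpm / .data$norm) |>
    select("transcript_id", "tissue", "spm")
}

#' Call tissue-specific transcripts from SPM profiles
#'
#' A transcript is specific to the unique tissue whose SPM strictly exceeds
#' `threshold`; transcripts with no tissue above the threshold (including
#' transcripts absent from the profile) get `NA`.
#'
#' @param spm Tibble from [spm_profile()].
#' @param threshold SPM threshold, exclusive (default 0.95).
#' @return A tibble with columns `transcript_id`, `specific_tissue`
#'   (`NA` when not tissue-specific).
#' @export
call_tissue_specific <- function(spm, threshold = 0.95) {
  spm |>
    group_by(.data$transcript_id) |>
    summarise(
      specific_tissue = if (max(.data$spm) > threshold) {
        .data$tissue[which.max(.data$spm)]
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}

#' Hypergeometric term enrichment against a custom background
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least `k` term-annotated transcripts in a group of size `n` drawn from a
#' background of size `N` containing `K` annotated transcripts,
#' `p = P(X >= k)`. This is a one-sided enrichment test (not depletion). By
#' default raw p-values are compared against `alpha`; Benjamini-Hochberg
#' correction is available because testing many terms without correction is
#' anticonservative.
#'
#' @param annotations Annotation tibble (`transcript_id`, `source`, `term`,
#'   `score`); a transcript may carry several terms.
#' @param group Character vector of transcript ids forming the test group;
#'   must be a subset of `background`.
#' @param background Character vector of transcript ids forming the
#'   background (e.g., all fungal transcripts).
#' @param source Optional annotation source to restrict to (e.g., `"KO"`).
#' @param alpha Significance level (default 0.05, exclusive).
#' @param correction `"none"` (default) or `"BH"`.
#' @return An `enrichment_result` tibble sorted by p-value then term:
#'   `term`, `k`, `n`, `K`, `N`, `p_value`, `p_adjusted`, `significant`.
#' @export
hypergeometric_enrichment <- function(annotations, group, background,
                                      source = NULL, alpha = 0.05,
                                      correction = c("none", "BH")) {
  correction <- match.arg(correction)
  group <- unique(group)
  background <- unique(background)
  outside <- setdiff(group, background)
  if (length(outside) > 0) {
    abort(paste0("group transcript '", outside[1], "' is not in the background"))
  }
  ann <- annotations
  if (!is.null(source)) ann <- filter(ann, .data$source %in% !!source)
  ann <- ann |>
    filter(.data$transcript_id %in% background) |>
    distinct(.data$transcript_id, .data$term)
  n_ <- length(group)
  big_n <- length(background)
  res <- ann |>
    group_by(.data$term) |>
    summarise(
      K = n(),
      k = sum(.data$transcript_id %in% group),
      .groups = "drop"
    ) |>
    mutate(
      n = n_, N = big_n,
      p_value = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                       lower.tail = FALSE)
    )
  res$p_adjusted <- if (correction == "BH") p.adjust(res$p_value, "BH") else res$p_value
  out <- res |>
    mutate(significant = .data$p_adjusted < alpha) |>
    select("term", "k", "n", "K", "N", "p_value", "p_adjusted", "significant") |>
    arrange(.data$p_value, .data$term)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Filter transporter hits by E-value and coverage
#'
#' Retains a transcript when its best-ranked hit against a transporter
#' classification reference satisfies `e_value <= e_value_max` and query
#' coverage `>= min_coverage` (both inclusive, matching "a threshold E-value
#' of 1e-5 and an alignment coverage of at least 70%"). The transporter
#' family is taken from that best-ranked hit; ties at the best hit resolve by
#' the deterministic rank key.
#'
#' @param hits Hit tibble whose subject ids are transporter family labels.
#' @param e_value_max E-value cutoff, inclusive (default 1e-5).
#' @param min_coverage Coverage threshold, inclusive (default 0.70).
#' @return A tibble of retained transcripts: `transcript_id`, `family`,
#'   `e_value`, `query_coverage`.
#' @export
filter_transporter_hits <- function(hits, e_value_max = 1e-5, min_coverage = 0.70) {
  rank_hits(hits) |>
    filter(.data$hit_rank == 1,
           .data$e_value <= e_value_max,
           .data$query_coverage >= min_coverage) |>
    select(transcript_id = "query_id", family = "subject_id",
           "e_value", "query_coverage")
}

#' Count secreted CAZymes by class and phylum group
#'
#' A transcript contributes when it carries at least one CAZy family
#' annotation and a signal-peptide score strictly above `sp_score_min`
#' (secreted). Counts are keyed by CAZy class prefix — GH, GT, PL, CE, AA,
#' CBM — and the transcript's phylum group from the partition; a transcript
#' annotated with several families of the same class counts once per class.
#' Unparseable CAZy family strings are skipped with a warning.
#'
#' @param annotations Annotation tibble with `CAZY` terms (family strings
#'   like `GH18`, `AA9`) and `SIGNALP` scores.
#' @param calls Per-transcript calls tibble with `transcript_id` and
#'   `phylum_group` (e.g., `partition_report$calls`).
#' @param sp_score_min Signal-peptide score threshold, exclusive
#'   (default 0.5).
#' @return A tibble `cazy_class`, `phylum_group`, `n`.
#' @export
summarize_secreted_cazymes <- function(annotations, calls, sp_score_min = 0.5) {
  secreted <- annotations |>
    filter(.data$source == "SIGNALP", .data$score > sp_score_min) |>
    pull(.data$transcript_id)
  cazy <- annotations |>
    filter(.data$source == "CAZY", .data$transcript_id %in% secreted) |>
    mutate(cazy_class = stringr::str_extract(.data$term, "^(GH|GT|PL|CE|AA|CBM)(?=[0-9])"))
  n_bad <- sum(is.na(cazy$cazy_class))
  if (n_bad > 0) {
    warn(paste0(n_bad, " unparseable CAZy family string(s) skipped"))
    cazy <- filter(cazy, !is.na(.data$cazy_class))
  }
  cazy |>
    distinct(.data$transcript_id, .data$cazy_class) |>
    left_join(select(calls, "transcript_id", "phylum_group"), by = "transcript_id") |>
    count(.data$cazy_class, .data$phylum_group, name = "n")
}

#' Community summary percentages
#'
#' Headline percentages over a partitioned fungal community: the share of
#' each phylum group, the share of transcripts assigned to a reference genus,
#' and the share of transcripts carrying at least one HSP annotation. All
#' percentages are computed at full precision on a 0-100 scale; rounding is
#' left to presentation. The genus denominator defaults to all fungal
#' transcripts but can be switched to Ascomycota only.
#'
#' @param partition A `partition_report` from [partition_transcriptome()],
#'   or a calls tibble with `origin` and `phylum_group` columns.
#' @param genus_assignments Optional tibble from [assign_to_reference_set()]
#'   (`query_id`, `assigned`).
#' @param annotations Optional annotation tibble; used for the HSP share.
#' @param genus_denominator `"total_fungal"` (default) or `"ascomycota"`.
#' @return A tibble `metric`, `value` (percentages on a 0-100 scale).
#' @export
community_summary <- function(partition, genus_assignments = NULL,
                              annotations = NULL,
                              genus_denominator = c("total_fungal", "ascomycota")) {
  genus_denominator <- match.arg(genus_denominator)
  calls <- if (inherits(partition, "partition_report")) partition$calls else partition
  fungal <- filter(calls, .data$origin == "FUNGAL")
  total_fungal <- nrow(fungal)
  if (total_fungal == 0) abort("community_summary() needs at least one fungal transcript")
  groups <- setdiff(phylum_group_levels(), "NOT_APPLICABLE")
  shares <- purrr::map_dfr(groups, function(g) {
    tibble(
      metric = paste0("pct_", tolower(g)),
      value = 100 * sum(fungal$phylum_group == g) / total_fungal
    )
  })
  out <- shares
  if (!is.null(genus_assignments)) {
    denom <- if (genus_denominator == "ascomycota") {
      sum(fungal$phylum_group == "ASCOMYCOTA")
    } else {
      total_fungal
    }
    n_assigned <- sum(genus_assignments$assigned &
                        genus_assignments$query_id %in% fungal$transcript_id)
    out <- bind_rows(out, tibble(metric = "pct_genus", value = 100 * n_assigned / denom))
  }
  if (!is.null(annotations)) {
    hsp_ids <- unique(annotations$transcript_id[annotations$source == "HSP"])
    n_hsp <- sum(fungal$transcript_id %in% hsp_ids)
    out <- bind_rows(out, tibble(metric = "pct_hsp", value = 100 * n_hsp / total_fungal))
  }
  out
}
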