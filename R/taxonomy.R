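#' Host-versus-fungus separation by top-hit voting
#'
#' Classifies each query as `FUNGAL`, `HOST`, or `UNCLASSIFIED` from the
#' taxonomic labels of its best-ranked homology hits. Hits with
#' `e_value > e_value_max` are discarded; the vote is taken over the first
#' `min(top_n, available)` remaining hits (ranked by the deterministic key,
#' see [rank_hits()]). A query is `FUNGAL` when the fraction of voting hits
#' with a fungal lineage is at least `fungal_fraction`, `HOST` otherwise, and
#' `UNCLASSIFIED` when fewer than `min_hits` hits survive the E-value gate.
#' With the defaults this is the "at least 70% of the top 10 hits are fungal"
#' rule; voting over all available hits when fewer than `top_n` qualify avoids
#' silently dropping transcripts with few database relatives.
#'
#' @param hits Hit tibble (any number of queries); will be (re)ranked.
#' @param top_n Number of top hits that vote (default 10).
#' @param fungal_fraction Minimum fungal fraction for a `FUNGAL` call
#'   (default 0.70, inclusive).
#' @param e_value_max E-value cutoff applied before voting (default 1e-10).
#' @param min_hits Minimum number of qualifying hits required to vote
#'   (default 1).
#' @return A tibble with one row per query: `query_id`, `origin`, `n_votes`,
#'   `n_fungal`.
#' @export
vote_host_vs_fungus <- function(hits, top_n = 10, fungal_fraction = 0.70,
                                e_value_max = 1e-10, min_hits = 1) {
  if (top_n < 1) abort("top_n must be >= 1")
  if (fungal_fraction <= 0 || fungal_fraction > 1) {
    abort("fungal_fraction must lie in (0, 1]")
  }
  all_queries <- unique(hits$query_id)
  voting <- hits |>
    filter(.data$e_value <= e_value_max) |>
    rank_hits() |>
    filter(.data$hit_rank <= top_n) |>
    mutate(fungal = lineage_is_fungal(.data$lineage)) |>
    group_by(.data$query_id) |>
    summarise(n_votes = n(), n_fungal = sum(.data$fungal), .groups = "drop")
  tibble(query_id = all_queries) |>
    left_join(voting, by = "query_id") |>
    mutate(
      n_votes = coalesce(.data$n_votes, 0L),
      n_fungal = as.integer(coalesce(.data$n_fungal, 0L)),
      origin = case_when(
        .data$n_votes < min_hits ~ "UNCLASSIFIED",
        .data$n_fungal / .data$n_votes >= fungal_fraction ~ "FUNGAL",
        TRUE ~ "HOST"
      )
    ) |>
    select("query_id", "origin", "n_votes", "n_fungal")
}

#' Phylum-level consensus classification of fungal transcripts
#'
#' Assigns each query to one of the four community groups — `ASCOMYCOTA`,
#' `BASIDIOMYCOTA`, `ASCO_OR_BASIDIO`, `OTHER_FUNGI` — from hits against a
#' fungal reference with per-subject phylum labels. Hits are filtered at
#' `e_value_max`, truncated to the top `top_n`, and categorized by subject
#' phylum (`Ascomycota`, `Basidiomycota`, anything else — including a missing
#' phylum rank — counts as other).
#'
#' Under the default `"unanimity"` rule a phylum is called only on unanimous
#' evidence: all voting hits Ascomycota gives `ASCOMYCOTA`, all Basidiomycota
#' gives `BASIDIOMYCOTA`, no hit to either main phylum gives `OTHER_FUNGI`,
#' and any other mixture gives the ambiguous class `ASCO_OR_BASIDIO`. With
#' `other_hits = "ignore"` hits outside the two main phyla do not break
#' unanimity (a unanimous-Ascomycota-plus-other vote still gives
#' `ASCOMYCOTA`). Under the `"majority"` rule a phylum is called when its
#' fraction of the voting hits reaches `majority_fraction`.
#'
#' Queries with no qualifying hits get `NOT_APPLICABLE`.
#'
#' @param hits Hit tibble against a fungal reference; will be (re)ranked.
#' @param e_value_max E-value cutoff (default 1e-10).
#' @param top_n Number of voting hits (default 10).
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @param majority_fraction Fraction required under the majority rule
#'   (default 0.5, inclusive).
#' @param other_hits `"strict"` (default; any discordant hit breaks
#'   unanimity) or `"ignore"` (hits outside the two main phyla are ignored by
#'   the unanimity decision).
#' @return A tibble with one row per query: `query_id`, `phylum_group`,
#'   `n_votes`, `n_asco`, `n_basidio`, `n_other`.
#' @export
classify_phylum <- function(hits, e_value_max = 1e-10, top_n = 10,
                            rule = c("unanimity", "majority"),
                            majority_fraction = 0.5,
                            other_hits = c("strict", "ignore")) {
  rule <- match.arg(rule)
  other_hits <- match.arg(other_hits)
  if (top_n < 1) abort("top_n must be >= 1")
  all_queries <- unique(hits$query_id)
  votes <- hits |>
    filter(.data$e_value <= e_value_max) |>
    rank_hits() |>
    filter(.data$hit_rank <= top_n) |>
    mutate(category = phylum_category(.data$lineage)) |>
    group_by(.data$query_id) |>
    summarise(
      n_votes = n(),
      n_asco = sum(.data$category == "ASCO"),
      n_basidio = sum(.data$category == "BASIDIO"),
      n_other = sum(.data$category == "OTHER"),
      .groups = "drop"
    )
  out <- tibble(query_id = all_queries) |>
    left_join(votes, by = "query_id") |>
    mutate(across(c("n_votes", "n_asco", "n_basidio", "n_other"),
                  ~ as.integer(coalesce(.x, 0L))))
  out$phylum_group <- consensus_call(
    out$n_votes, out$n_asco, out$n_basidio, out$n_other,
    rule = rule, majority_fraction = majority_fraction, other_hits = other_hits
  )
  select(out, "query_id", "phylum_group", "n_votes", "n_asco", "n_basidio", "n_other")
}

# internal: per-hit category from the subject lineage
phylum_category <- function(lineage) {
  phylum <- lineage_phylum(lineage)
  case_when(
    phylum == "Ascomycota" ~ "ASCO",
    phylum == "Basidiomycota" ~ "BASIDIO",
    TRUE ~ "OTHER"
  )
}

# internal: vectorized consensus rule over vote counts
consensus_call <- function(n_votes, n_asco, n_basidio, n_other,
                           rule, majority_fraction, other_hits) {
  if (rule == "unanimity") {
    if (other_hits == "strict") {
      case_when(
        n_votes == 0 ~ "NOT_APPLICABLE",
        n_asco == n_votes ~ "ASCOMYCOTA",
        n_basidio == n_votes ~ "BASIDIOMYCOTA",
        n_asco == 0 & n_basidio == 0 ~ "OTHER_FUNGI",
        TRUE ~ "ASCO_OR_BASIDIO"
      )
    } else {
      case_when(
        n_votes == 0 ~ "NOT_APPLICABLE",
        n_asco > 0 & n_basidio == 0 ~ "ASCOMYCOTA",
        n_basidio > 0 & n_asco == 0 ~ "BASIDIOMYCOTA",
        n_asco == 0 & n_basidio == 0 ~ "OTHER_FUNGI",
        TRUE ~ "ASCO_OR_BASIDIO"
      )
    }
  } else {
    case_when(
      n_votes == 0 ~ "NOT_APPLICABLE",
      n_asco / n_votes >= majority_fraction ~ "ASCOMYCOTA",
      n_basidio / n_votes >= majority_fraction ~ "BASIDIOMYCOTA",
      n_asco + n_basidio > 0 ~ "ASCO_OR_BASIDIO",
      TRUE ~ "OTHER_FUNGI"
    )
  }
}

#' Assign queries to a reference taxon set by threshold filtering
#'
#' A query is assigned to the reference set (e.g., the concatenated genomes
#' of one genus) when it has at least one hit with `e_value < e_value_max`
#' and query coverage strictly above `min_coverage`. The best subject is the
#' top-ranked qualifying hit under the deterministic rank key.
#'
#' @param hits Hit tibble against the reference set; will be (re)ranked.
#' @param e_value_max E-value cutoff, exclusive (default 1e-10).
#' @param min_coverage Coverage threshold (default 0.70).
#' @param strict_coverage Use strict `>` for the coverage gate (default
#'   `TRUE`, matching "coverage above 70%").
#' @return A tibble with one row per query: `query_id`, `assigned`,
#'   `best_subject`, `best_e_value`, `best_coverage` (the latter three `NA`
#'   when not assigned).
#' @export
assign_to_reference_set <- function(hits, e_value_max = 1e-10,
                                    min_coverage = 0.70, strict_coverage = TRUE) {
  all_queries <- unique(hits$query_id)
  ranked <- rank_hits(hits)
  cov_ok <- if (strict_coverage) ranked$query_coverage > min_coverage else ranked$query_coverage >= min_coverage
  best <- ranked |>
    filter(.data$e_value < e_value_max, cov_ok) |>
    group_by(.data$query_id) |>
    slice_min(.data$hit_rank, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("query_id", best_subject = "subject_id",
           best_e_value = "e_value", best_coverage = "query_coverage")
  tibble(query_id = all_queries) |>
    left_join(best, by = "query_id") |>
    mutate(assigned = !is.na(.data$best_subject)) |>
    select("query_id", "assigned", "best_subject", "best_e_value", "best_coverage")
}

#' Partition a transcriptome into host and fungal compartments
#'
#' Orchestrates the two classifiers: every transcript is first voted host or
#' fungal from `host_hits` (hits against a mixed host/fungus protein
#' reference, see [vote_host_vs_fungus()]); transcripts voted `FUNGAL` are
#' then assigned a phylum group from `fungal_hits` (hits against a fungal
#' reference, see [classify_phylum()]). Fungal transcripts with no qualifying
#' hits in `fungal_hits` keep `phylum_group = "NOT_APPLICABLE"`; host and
#' unclassified transcripts always carry `NOT_APPLICABLE`.
#'
#' @param transcripts Tibble with a `transcript_id` column (e.g., the output
#'   of [select_representative_isoforms()]).
#' @param host_hits Hit tibble for the separation stage, keyed by
#'   `query_id = transcript_id`.
#' @param fungal_hits Hit tibble for the phylum stage.
#' @param top_n,fungal_fraction,e_value_max,min_hits Voting parameters, see
#'   [vote_host_vs_fungus()].
#' @param phylum_e_value_max,phylum_top_n,rule,majority_fraction,other_hits
#'   Phylum-stage parameters, see [classify_phylum()].
#' @return A `partition_report` object: a list with `calls` (one row per
#'   transcript: `transcript_id`, `origin`, `phylum_group`, evidence counts),
#'   `counts` (transcripts per phylum group), and `total_fungal`.
#' @export
partition_transcriptome <- function(transcripts, host_hits, fungal_hits,
                                    top_n = 10, fungal_fraction = 0.70,
                                    e_value_max = 1e-10, min_hits = 1,
                                    phylum_e_value_max = 1e-10, phylum_top_n = 10,
                                    rule = "unanimity", majority_fraction = 0.5,
                                    other_hits = "strict") {
  ids <- transcripts$transcript_id
  votes <- vote_host_vs_fungus(host_hits, top_n = top_n,
                               fungal_fraction = fungal_fraction,
                               e_value_max = e_value_max, min_hits = min_hits)
  calls <- tibble(transcript_id = ids) |>
    left_join(votes, by = c(transcript_id = "query_id")) |>
    mutate(
      origin = coalesce(.data$origin, "UNCLASSIFIED"),
      n_votes = as.integer(coalesce(.data$n_votes, 0L)),
      n_fungal = as.integer(coalesce(.data$n_fungal, 0L))
    )
  fungal_ids <- calls$transcript_id[calls$origin == "FUNGAL"]
  phylum <- classify_phylum(
    semi_join(fungal_hits, tibble(query_id = fungal_ids), by = "query_id"),
    e_value_max = phylum_e_value_max, top_n = phylum_top_n, rule = rule,
    majority_fraction = majority_fraction, other_hits = other_hits
  )
  calls <- calls |>
    left_join(select(phylum, "query_id", "phylum_group",
                     "n_asco", "n_basidio", "n_other"),
              by = c(transcript_id = "query_id")) |>
    mutate(
      phylum_group = if_else(.data$origin == "FUNGAL",
                             coalesce(.data$phylum_group, "NOT_APPLICABLE"),
                             "NOT_APPLICABLE"),
      across(c("n_asco", "n_basidio", "n_other"), ~ as.integer(coalesce(.x, 0L)))
    ) |>
    select("transcript_id", "origin", "phylum_group",
           "n_votes", "n_fungal", "n_asco", "n_basidio", "n_other")
  n_na_fungal <- sum(calls$origin == "FUNGAL" & calls$phylum_group == "NOT_APPLICABLE")
  if (n_na_fungal > 0) {
    inform(paste0(n_na_fungal, " fungal transcript(s) had no qualifying phylum-stage hits"))
  }
  groups <- setdiff(phylum_group_levels(), "NOT_APPLICABLE")
  counts <- tibble(phylum_group = groups) |>
    left_join(count(filter(calls, .data$origin == "FUNGAL"), .data$phylum_group),
              by = "phylum_group") |>
    mutate(n = as.integer(coalesce(.data$n, 0L)))
  structure(
    list(
      calls = calls,
      counts = counts,
      total_fungal = sum(calls$origin == "FUNGAL")
    ),
    class = "partition_report"
  )
}

#' @export
print.partition_report <- function(x, ...) {
  cat("Transcriptome partition report\n")
  cat("  transcripts:", nrow(x$calls), "\n")
  cat("  fungal:", x$total_fungal, "  host:", sum(x$calls$origin == "HOST"),
      "  unclassified:", sum(x$calls$origin == "UNCLASSIFIED"), "\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("    %-16s %d\n", x$counts$phylum_group[i], x$counts$n[i]))
  }
  invisible(x)
}
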