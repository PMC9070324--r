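#' Build labeled query and reference sets with self-exclusion
#'
#' Samples a labeled query set (without replacement, seeded) from a pool of
#' labeled sequences and returns the remainder as the reference set, so the
#' two are disjoint: a classifier evaluated on the query set can never match
#' a sequence to itself. Defaults follow the benchmark construction of 2,000
#' Ascomycota plus 700 Basidiomycota coding sequences drawn from a large
#' fungal genome collection.
#'
#' @param pool Tibble with columns `sequence_id` and `true_label`
#'   (`ASCO`/`BASIDIO`/`OTHER`); `sequence_id` must be unique.
#' @param n_asco,n_basidio Query-set sizes per label (defaults 2000 and 700).
#' @param seed Integer seed for the sampling.
#' @return A list with `query_set` and `reference_set`, both tibbles shaped
#'   like `pool`.
#' @export
build_benchmark_sets <- function(pool, n_asco = 2000, n_basidio = 700, seed) {
  if (anyDuplicated(pool$sequence_id)) abort("pool sequence_ids must be unique")
  avail_asco <- sum(pool$true_label == "ASCO")
  avail_basidio <- sum(pool$true_label == "BASIDIO")
  if (avail_asco < n_asco) {
    abort(paste0("pool has ", avail_asco, " ASCO entries; ", n_asco, " requested"))
  }
  if (avail_basidio < n_basidio) {
    abort(paste0("pool has ", avail_basidio, " BASIDIO entries; ", n_basidio, " requested"))
  }
  picked <- withr::with_seed(seed, {
    c(
      sample(pool$sequence_id[pool$true_label == "ASCO"], n_asco),
      sample(pool$sequence_id[pool$true_label == "BASIDIO"], n_basidio)
    )
  })
  list(
    query_set = filter(pool, .data$sequence_id %in% picked),
    reference_set = filter(pool, !.data$sequence_id %in% picked)
  )
}

#' Evaluate phylum calls against a labeled truth set
#'
#' One-vs-rest confusion matrices per class over the four community groups.
#' For class `c`: TP are truth-`c` queries called `c`, FN truth-`c` queries
#' called anything else (including `ASCO_OR_BASIDIO` and `NOT_APPLICABLE`),
#' FP non-`c` truths called `c`, TN the remainder. TPR = TP/(TP+FN) and
#' FPR = FP/(FP+TN), `NA` when the denominator is zero (e.g., TPR of a class
#' that never occurs as a truth label).
#'
#' @param calls Tibble with `query_id` and `phylum_group` (e.g., from
#'   [classify_phylum()]); every truth entry must have a call.
#' @param truth Labeled pool tibble: `sequence_id`, `true_label`
#'   (`ASCO`/`BASIDIO`/`OTHER`).
#' @return A tibble with one row per class: `class`, `TP`, `FP`, `FN`, `TN`,
#'   `TPR`, `FPR`.
#' @export
evaluate_classifier <- function(calls, truth) {
  unknown <- setdiff(calls$query_id, truth$sequence_id)
  if (length(unknown) > 0) {
    abort(paste0("call for unknown query: '", unknown[1], "'"))
  }
  missing <- setdiff(truth$sequence_id, calls$query_id)
  if (length(missing) > 0) {
    abort(paste0("no call for query: '", missing[1], "'"))
  }
  truth_class <- c(ASCO = "ASCOMYCOTA", BASIDIO = "BASIDIOMYCOTA", OTHER = "OTHER_FUNGI")
  joined <- truth |>
    left_join(calls, by = c(sequence_id = "query_id")) |>
    mutate(truth_group = unname(truth_class[.data$true_label]))
  classes <- setdiff(phylum_group_levels(), "NOT_APPLICABLE")
  purrr::map_dfr(classes, function(cl) {
    is_truth <- joined$truth_group == cl
    is_call <- joined$phylum_group == cl
    tp <- sum(is_truth & is_call)
    fn <- sum(is_truth & !is_call)
    fp <- sum(!is_truth & is_call)
    tn <- sum(!is_truth & !is_call)
    tibble(
      class = cl, TP = tp, FP = fp, FN = fn, TN = tn,
      TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_
    )
  })
}

#' Sweep classification parameters over an E-value by top-N grid
#'
#' Runs [classify_phylum()] at every point of the parameter grid and
#' evaluates the calls against the truth labels, reproducing the sensitivity
#' analysis used to tune the phylum classifier (E-value cutoffs of 1e-10 and
#' 1e-20 crossed with the number of voting hits). Rows are sorted by
#' `(e_value_max, top_n, rule, class)` for reproducibility.
#'
#' @param hits Hit tibble for all queries in `truth`.
#' @param truth Labeled pool tibble: `sequence_id`, `true_label`.
#' @param e_value_grid Numeric vector of E-value cutoffs
#'   (default `c(1e-10, 1e-20)`).
#' @param top_n_grid Integer vector of voting-hit counts
#'   (default `c(1, 3, 5, 10)`).
#' @param rules Character vector of consensus rules (default `"unanimity"`).
#' @param other_hits Passed to [classify_phylum()].
#' @return A `benchmark_report` tibble: one row per (grid point, class) with
#'   the confusion counts and TPR/FPR.
#' @export
sweep_parameters <- function(hits, truth, e_value_grid = c(1e-10, 1e-20),
                             top_n_grid = c(1, 3, 5, 10),
                             rules = "unanimity", other_hits = "strict") {
  if (length(e_value_grid) == 0 || length(top_n_grid) == 0 || length(rules) == 0) {
    abort("parameter grids must be non-empty")
  }
  grid <- tidyr::expand_grid(
    e_value_max = e_value_grid, top_n = top_n_grid, rule = rules
  )
  rows <- purrr::pmap_dfr(grid, function(e_value_max, top_n, rule) {
    calls <- classify_phylum(hits, e_value_max = e_value_max, top_n = top_n,
                             rule = rule, other_hits = other_hits)
    # queries with no hit rows at all still need a NOT_APPLICABLE call
    calls <- tibble(query_id = truth$sequence_id) |>
      left_join(calls, by = "query_id") |>
      mutate(phylum_group = coalesce(.data$phylum_group, "NOT_APPLICABLE"))
    evaluate_classifier(calls, truth) |>
      mutate(e_value_max = e_value_max, top_n = top_n, rule = rule, .before = 1)
  })
  out <- arrange(rows, .data$e_value_max, .data$top_n, .data$rule, .data$class)
  class(out) <- c("benchmark_report", class(out))
  out
}
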