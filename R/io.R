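#' Read assembled transcripts from FASTA
#'
#' Reads a FASTA file of assembled transcripts into a tibble, one row per
#' entry, preserving input order. The header token up to the first whitespace
#' is taken as the transcript id; sequences are uppercased. The locus id is
#' the transcript id with a trailing Trinity-style isoform suffix (`_i<d>`)
#' stripped, or the id itself when no suffix is present.
#'
#' @param path Path to a FASTA file.
#' @param orf_lengths Optional named numeric vector or two-column data frame
#'   (`transcript_id`, `orf_length_nt`) of annotated ORF lengths in
#'   nucleotides; transcripts without an entry get `orf_length_nt = 0`
#'   (no ORF annotated).
#' @return A tibble with columns `transcript_id`, `locus_id`, `sequence`,
#'   `length_nt`, `orf_length_nt`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">AF_DN1_c0_g1_i1", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path, orf_lengths = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(
      transcript_id = character(), locus_id = character(),
      sequence = character(), length_nt = integer(), orf_length_nt = integer()
    ))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate transcript id in FASTA: '", dup[1], "'"))
  }
  out <- tibble(
    transcript_id = ids,
    locus_id = strip_isoform_suffix(ids),
    sequence = unname(toupper(as.character(seqs))),
    length_nt = Biostrings::width(seqs)
  )
  out$orf_length_nt <- lookup_orf_lengths(out$transcript_id, orf_lengths)
  out
}

#' Write transcripts to FASTA
#'
#' Inverse of [read_fasta()]: writes `transcript_id` headers and sequences,
#' wrapped at a fixed line width, so that a read/write round trip reproduces
#' ids and sequences exactly.
#'
#' @param transcripts Tibble with columns `transcript_id` and `sequence`.
#' @param path Output file path.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 60) {
  stopifnot(all(c("transcript_id", "sequence") %in% names(transcripts)))
  x <- Biostrings::DNAStringSet(transcripts$sequence)
  names(x) <- transcripts$transcript_id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# internal: strip trailing Trinity-style isoform suffix `_i<d>`
strip_isoform_suffix <- function(ids) sub("_i[0-9]+$", "", ids)

# internal: resolve optional ORF length annotation to an integer vector
lookup_orf_lengths <- function(ids, orf_lengths) {
  if (is.null(orf_lengths)) return(rep(0L, length(ids)))
  if (is.data.frame(orf_lengths)) {
    orf_lengths <- setNames(orf_lengths$orf_length_nt, orf_lengths$transcript_id)
  }
  out <- unname(orf_lengths[ids])
  out[is.na(out)] <- 0
  as.integer(out)
}

# columns of the extended BLAST tabular dialect: outfmt-6 plus qlen and lineage
hit_table_columns <- function() {
  c(
    "query_id", "subject_id", "percent_identity", "alignment_length",
    "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
    "e_value", "bit_score", "query_length", "lineage"
  )
}

#' Read an extended homology-hit table
#'
#' Reads a headerless tab-separated hit table in the extended BLAST tabular
#' dialect: the 12 standard `outfmt 6` columns followed by the query length
#' and the subject taxonomic lineage (see [lineage_is_fungal()] for the
#' lineage serialization). Hits are returned ranked within each query by the
#' deterministic key: ascending E-value, then descending bit score, then
#' ascending subject id; `hit_rank` gives the 1-based rank. Query coverage is
#' derived as `min(1, alignment_length * unit / query_length)` where `unit`
#' is 3 for amino-acid alignment lengths against a nucleotide query and 1
#' otherwise.
#'
#' @param path Path to the TSV file (no header row).
#' @param alignment_units Either `"nucleotide"` (default) or `"amino_acid"`;
#'   amino-acid alignment lengths are converted to nucleotide units before
#'   computing coverage.
#' @return A tibble of hits with the 14 dialect columns plus `query_coverage`
#'   and `hit_rank`.
#' @export
read_hit_table <- function(path, alignment_units = c("nucleotide", "amino_acid")) {
  alignment_units <- match.arg(alignment_units)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(rank_hits(empty_hit_table()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != length(hit_table_columns()))
  if (length(bad) > 0) {
    abort(paste0(
      "line ", bad[1], ": expected ", length(hit_table_columns()),
      " tab-separated columns, found ", n_fields[bad[1]]
    ))
  }
  m <- matrix(unlist(fields), ncol = length(hit_table_columns()), byrow = TRUE)
  colnames(m) <- hit_table_columns()
  hits <- as_tibble(m)
  num_cols <- c(
    "percent_identity", "alignment_length", "mismatches", "gap_opens",
    "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score",
    "query_length"
  )
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v)) {
      abort(paste0(
        "line ", which(is.na(v))[1], ": non-numeric value in column '", col, "'"
      ))
    }
    hits[[col]] <- v
  }
  int_cols <- c("alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end", "query_length")
  hits[int_cols] <- lapply(hits[int_cols], as.integer)
  check_lineages(hits$lineage)
  validate_hit_table(hits)
  rank_hits(hits, alignment_units = alignment_units)
}

#' Rank hits by the deterministic key
#'
#' Orders a hit tibble within each query by ascending E-value, then descending
#' bit score, then ascending subject id lexicographically, and (re)derives
#' `hit_rank` and `query_coverage`. The key is a total order, so ranking is
#' independent of input row order. All voting and filtering functions assume
#' this ordering; they call it themselves, so users only need it when
#' assembling hit tibbles by hand.
#'
#' @param hits Hit tibble with at least `query_id`, `subject_id`, `e_value`,
#'   `bit_score`, `alignment_length`, `query_length`.
#' @inheritParams read_hit_table
#' @return The ranked tibble with `hit_rank` and `query_coverage` columns.
#' @export
rank_hits <- function(hits, alignment_units = c("nucleotide", "amino_acid")) {
  alignment_units <- match.arg(alignment_units)
  unit <- if (alignment_units == "amino_acid") 3 else 1
  hits |>
    mutate(query_coverage = pmin(1, .data$alignment_length * unit / .data$query_length)) |>
    arrange(.data$query_id, .data$e_value, desc(.data$bit_score), .data$subject_id) |>
    group_by(.data$query_id) |>
    mutate(hit_rank = row_number()) |>
    ungroup()
}

# internal: structural checks shared by readers and simulators
validate_hit_table <- function(hits) {
  if (any(hits$e_value < 0)) abort("E-values must be non-negative")
  if (any(hits$alignment_length < 1)) abort("alignment lengths must be >= 1")
  if (any(hits$query_length < 1)) abort("query lengths must be >= 1")
  invisible(hits)
}

# internal: zero-row hit tibble in canonical shape
empty_hit_table <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), e_value = numeric(), bit_score = numeric(),
    query_length = integer(), lineage = character()
  )
}

#' Write a hit table in the extended tabular dialect
#'
#' @param hits Ranked hit tibble (see [read_hit_table()]).
#' @param path Output TSV path (headerless).
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[hit_table_columns()], path, col_names = FALSE)
  invisible(path)
}

#' Read an expression table and its sample sheet
#'
#' Reads a TPM matrix (TSV with header `transcript_id` followed by sample
#' ids) together with a sample sheet (TSV with columns `sample_id`, `tissue`,
#' `replicate`) and returns a long tibble joining the two. Transcripts absent
#' from the matrix are simply absent from the result; no implicit zeros are
#' created.
#'
#' @param matrix_path Path to the TPM matrix TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return A long tibble with columns `transcript_id`, `sample_id`, `tpm`,
#'   `tissue`, `replicate`.
#' @export
read_expression_table <- function(matrix_path, samples_path) {
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               sample_id = readr::col_character(),
                               tissue = readr::col_character(),
                               replicate = readr::col_integer()
                             ))
  if (names(mat)[1] != "transcript_id") {
    abort("expression matrix must start with a 'transcript_id' column")
  }
  expression_table(mat, samples)
}

#' Assemble an expression table from a wide matrix and a sample sheet
#'
#' @param mat Wide tibble: `transcript_id` plus one numeric column per sample.
#' @param samples Sample sheet tibble: `sample_id`, `tissue`, `replicate`.
#' @return Long tibble as in [read_expression_table()].
#' @export
expression_table <- function(mat, samples) {
  matrix_samples <- setdiff(names(mat), "transcript_id")
  missing_from_sheet <- setdiff(matrix_samples, samples$sample_id)
  if (length(missing_from_sheet) > 0) {
    abort(paste0("sample '", missing_from_sheet[1], "' in matrix is missing from the sample sheet"))
  }
  missing_from_matrix <- setdiff(samples$sample_id, matrix_samples)
  if (length(missing_from_matrix) > 0) {
    abort(paste0("sample '", missing_from_matrix[1], "' in sheet is missing from the matrix"))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  long <- tidyr::pivot_longer(mat, -"transcript_id",
                              names_to = "sample_id", values_to = "tpm")
  if (any(long$tpm < 0, na.rm = TRUE)) abort("negative TPM value in expression matrix")
  if (anyNA(long$tpm)) abort("missing TPM value in expression matrix")
  left_join(long, samples, by = "sample_id")
}

#' Write an expression table back to matrix + sample sheet files
#'
#' @param expr Long expression tibble (see [read_expression_table()]).
#' @param matrix_path,samples_path Output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_table <- function(expr, matrix_path, samples_path) {
  mat <- expr |>
    select("transcript_id", "sample_id", "tpm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "tpm")
  readr::write_tsv(mat, matrix_path)
  samples <- distinct(expr, .data$sample_id, .data$tissue, .data$replicate)
  readr::write_tsv(samples, samples_path)
  invisible(matrix_path)
}

#' Read an annotation table
#'
#' Reads a TSV of term assignments with columns `transcript_id`, `source`,
#' `term`, `score` (score may be empty/NA). Sources are the annotation
#' channels the pipeline consumes: `KO`, `CDD`, `CAZY`, `TCDB`, `HSP`,
#' `SIGNALP`, `GENUS`. `(transcript_id, source, term)` triples must be
#' unique and `SIGNALP` scores must lie in `[0, 1]`.
#'
#' @param path Path to the annotation TSV (with header).
#' @return A tibble with the four annotation columns.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = readr::col_character(),
                           source = readr::col_character(),
                           term = readr::col_character(),
                           score = readr::col_double()
                         ))
  validate_annotations(ann)
}

# internal: invariants on annotation records
validate_annotations <- function(ann) {
  allowed <- c("KO", "CDD", "CAZY", "TCDB", "HSP", "SIGNALP", "GENUS")
  bad <- setdiff(unique(ann$source), allowed)
  if (length(bad) > 0) abort(paste0("unknown annotation source: '", bad[1], "'"))
  if (anyDuplicated(ann[c("transcript_id", "source", "term")])) {
    abort("duplicate (transcript_id, source, term) annotation record")
  }
  sp <- ann$score[ann$source == "SIGNALP"]
  if (anyNA(sp) || any(sp < 0 | sp > 1)) {
    abort("SIGNALP records must carry a score in [0, 1]")
  }
  ann
}
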