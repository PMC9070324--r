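#' Published community statistics for three fiber-producing agave cultivars
#'
#' Machine-readable twins of the printed summary tables for the fungal
#' communities recovered from the root/stem/leaf transcriptomes of
#' *Agave fourcroydes*, *A. sisalana*, and hybrid 11648. These are reference
#' values for consistency arithmetic (row sums, pooled phylum shares, genus
#' and HSP percentages), not outputs of this package.
#'
#' @return A list of tibbles:
#' \describe{
#'   \item{assembly}{Per-cultivar assembly descriptors of the fungal
#'     transcript sets: count, mean length, N50, min/max CDS length.}
#'   \item{phylum_counts}{Transcript counts per community group
#'     (Ascomycota / Basidiomycota / Asco or Basidio / Other fungi) and the
#'     printed totals.}
#'   \item{genus_counts}{Transcripts assigned to the genus *Talaromyces*
#'     per cultivar.}
#'   \item{hsp_pct}{Printed percentage of fungal transcripts annotated as
#'     heat shock proteins per cultivar.}
#' }
#' @export
#' @examples
#' agave_community_tables()$phylum_counts
agave_community_tables <- function() {
  cultivars <- c("A. fourcroydes", "A. sisalana", "Hybrid 11648")
  list(
    assembly = tibble(
      cultivar = cultivars,
      n_fungal_transcripts = c(2996L, 4313L, 3433L),
      mean_length_bp = c(545, 540, 529),
      n50_bp = c(579L, 570L, 552L),
      max_cds_bp = c(3099L, 3210L, 2649L),
      min_cds_bp = c(258L, 255L, 264L)
    ),
    phylum_counts = tibble(
      cultivar = cultivars,
      ASCOMYCOTA = c(1927L, 3012L, 1986L),
      BASIDIOMYCOTA = c(797L, 1036L, 1179L),
      ASCO_OR_BASIDIO = c(19L, 23L, 18L),
      OTHER_FUNGI = c(253L, 242L, 250L),
      total = c(2996L, 4313L, 3433L)
    ),
    genus_counts = tibble(
      cultivar = cultivars,
      n_talaromyces = c(291L, 662L, 371L)
    ),
    hsp_pct = tibble(
      cultivar = cultivars,
      pct_hsp = c(6.21, 4.92, 5.71)
    )
  )
}

#' Per-cultivar totals and pooled phylum shares from group counts
#'
#' Consistency arithmetic over a table of per-community group counts: the
#' per-cultivar total (sum of the four groups) and the pooled share of each
#' group across all cultivars, as a percentage of all fungal transcripts.
#'
#' @param phylum_counts Tibble with a `cultivar` column and one integer
#'   column per community group (as in
#'   `agave_community_tables()$phylum_counts`; a `total` column, if present,
#'   is ignored in the arithmetic).
#' @return A list with `totals` (tibble `cultivar`, `total`) and `pooled`
#'   (tibble `phylum_group`, `n`, `pct` on a 0-100 scale).
#' @export
phylum_share_summary <- function(phylum_counts) {
  groups <- intersect(setdiff(phylum_group_levels(), "NOT_APPLICABLE"),
                      names(phylum_counts))
  if (length(groups) == 0) abort("no community group columns found")
  counts <- phylum_counts[groups]
  totals <- tibble(
    cultivar = phylum_counts$cultivar,
    total = as.integer(rowSums(counts))
  )
  grand <- sum(counts)
  pooled <- tibble(
    phylum_group = groups,
    n = as.integer(unname(colSums(counts))),
    pct = unname(100 * colSums(counts) / grand)
  )
  list(totals = totals, pooled = pooled)
}
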