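# Builders for small hand-made fixtures used across the suite.

FUNGAL_LINEAGE <- "superkingdom:Eukaryota;kingdom:Fungi;phylum:Ascomycota"
BASIDIO_LINEAGE <- "superkingdom:Eukaryota;kingdom:Fungi;phylum:Basidiomycota"
OTHER_FUNGAL_LINEAGE <- "superkingdom:Eukaryota;kingdom:Fungi;phylum:Mucoromycota"
PLANT_LINEAGE <- "superkingdom:Eukaryota;kingdom:Viridiplantae;phylum:Streptophyta"

# one row per hit; vectorized over every argument
make_hits <- function(query_id, e_value, bit_score = 100,
                      lineage = FUNGAL_LINEAGE, subject_id = NULL,
                      query_length = 300L, coverage = 0.9) {
  n <- max(lengths(list(query_id, e_value, bit_score, lineage)))
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(n))
  alen <- pmax(1L, as.integer(round(coverage * query_length)))
  tibble::tibble(
    query_id = rep_len(query_id, n),
    subject_id = rep_len(subject_id, n),
    percent_identity = 90,
    alignment_length = rep_len(alen, n),
    mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = rep_len(alen, n),
    s_start = 1L, s_end = rep_len(alen, n),
    e_value = rep_len(e_value, n),
    bit_score = rep_len(bit_score, n),
    query_length = rep_len(as.integer(query_length), n),
    lineage = rep_len(lineage, n)
  )
}

# hit set for one query: k fungal + (n - k) plant hits, all significant
make_vote_table <- function(n, k, query_id = "q1", e_value = 1e-30) {
  if (n == 0) {
    return(make_hits(query_id, e_value = 1, lineage = PLANT_LINEAGE))
  }
  make_hits(query_id, e_value = e_value,
            lineage = rep(c(FUNGAL_LINEAGE, PLANT_LINEAGE), c(k, n - k)))
}

# hit set for one query with given phylum-category counts
make_phylum_table <- function(n_asco, n_basidio, n_other, query_id = "q1",
                              e_value = 1e-30) {
  make_hits(query_id, e_value = e_value,
            lineage = rep(c(FUNGAL_LINEAGE, BASIDIO_LINEAGE, OTHER_FUNGAL_LINEAGE),
                          c(n_asco, n_basidio, n_other)))
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric p-value:
# all C(N, n) draws of a group from a background with K annotated members
enumerate_hypergeom_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# brute-force N50: largest length L in the set with sum(lengths >= L) >= total/2
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# brute-force voting rule over a (n, k) vote table
oracle_vote <- function(n_votes, n_fungal, fungal_fraction = 0.70, min_hits = 1) {
  if (n_votes < min_hits) return("UNCLASSIFIED")
  if (n_fungal / n_votes >= fungal_fraction) "FUNGAL" else "HOST"
}
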