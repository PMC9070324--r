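#' Design of a synthetic community simulation
#'
#' Collects every knob of the ground-truth generators in one validated list.
#' The defaults emulate one study community at desk scale: a transcriptome of
#' 3,000 loci of which 12% are fungal, split 64/28/8 between Ascomycota,
#' Basidiomycota, and other fungi; three tissues with three replicates each;
#' fungal transcripts overwhelmingly root-specific (so that roughly 58% of
#' all root-specific transcripts are fungal); a 12% genus-assignment rate
#' among fungal transcripts and a 5.6% HSP annotation rate. All generators
#' are pure functions of (design, seed).
#'
#' @param n_host,n_asco,n_basidio,n_other Locus counts per origin/phylum.
#' @param extra_isoform_prob Probability that a locus carries one extra
#'   non-representative isoform (shorter, or failing the TPM or ORF gate).
#' @param length_meanlog,length_sdlog Log-normal parameters of transcript
#'   lengths (nt); lengths are floored at 320 nt so representative ORFs pass
#'   the default 255 nt gate.
#' @param hits_mean,hits_max Mean and cap of the per-query number of
#'   significant hits.
#' @param label_noise_eps Per-hit probability that the hit's lineage is
#'   replaced by a uniformly random wrong-category lineage.
#' @param decoy_fraction Expected fraction of additional decoy hits whose
#'   E-value lies above the significance range.
#' @param true_evalue_log10,decoy_evalue_log10 Log10 E-value ranges for
#'   significant and decoy hits.
#' @param tissues,replicates Sample layout of the expression matrix.
#' @param fungal_root_specific_fraction Probability that a fungal locus is
#'   root-specific.
#' @param host_specific_fraction Probability that a host locus is
#'   tissue-specific (tissue drawn uniformly).
#' @param specific_high_tpm,specific_low_tpm Mean TPM of a tissue-specific
#'   transcript in its tissue and elsewhere; the ratio puts the noise-free
#'   SPM well above the 0.95 calling threshold.
#' @param baseline_tpm Mean TPM of non-specific transcripts in every tissue.
#' @param nonqualifying_tpm Mean TPM of isoforms designed to fail the TPM
#'   gate.
#' @param replicate_sigma sdlog of the mean-one multiplicative log-normal
#'   replicate noise.
#' @param n_ko_terms,ko_prob_range,n_cdd_terms,cdd_prob_range Number of
#'   KO/CDD terms and the range their background assignment probabilities
#'   are drawn from.
#' @param enriched_terms Tibble (`term`, `source`, `group`, `multiplier`):
#'   terms whose assignment probability is multiplied inside the named
#'   phylum group (planted enrichment).
#' @param hsp_fraction Probability that a fungal transcript carries an HSP
#'   annotation.
#' @param cazy_fraction,cazy_families Probability that a fungal transcript
#'   carries a CAZy family, and the family pool.
#' @param signalp_secreted_fraction Fraction of fungal transcripts drawn
#'   from the secreted signal-peptide score distribution.
#' @param signalp_beta_secreted,signalp_beta_background Beta parameters of
#'   the signal-peptide score for secreted and non-secreted transcripts.
#' @param genus_fraction Probability that an Ascomycota transcript truly
#'   belongs to the reference genus.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_host = 2640, n_asco = 230, n_basidio = 100,
                              n_other = 30,
                              extra_isoform_prob = 0.3,
                              length_meanlog = log(500), length_sdlog = 0.45,
                              hits_mean = 8, hits_max = 10,
                              label_noise_eps = 0.02,
                              decoy_fraction = 0.1,
                              true_evalue_log10 = c(-180, -25),
                              decoy_evalue_log10 = c(-8, -2),
                              tissues = c("leaf", "stem", "root"),
                              replicates = 3,
                              fungal_root_specific_fraction = 0.9,
                              host_specific_fraction = 0.27,
                              specific_high_tpm = 60, specific_low_tpm = 0.5,
                              baseline_tpm = 8, nonqualifying_tpm = 0.3,
                              replicate_sigma = 0.3,
                              n_ko_terms = 30, ko_prob_range = c(0.01, 0.08),
                              n_cdd_terms = 30, cdd_prob_range = c(0.01, 0.08),
                              enriched_terms = tibble(
                                term = c("KO_ENR1", "KO_ENR2"),
                                source = "KO",
                                group = "ASCOMYCOTA",
                                multiplier = 6
                              ),
                              hsp_fraction = 0.056,
                              cazy_fraction = 0.10,
                              cazy_families = c(
                                "GH18", "GH16", "GH17", "GH10", "GH11", "GH43",
                                "GH76", "GH79", "GH128", "GT2", "GT4", "CE1",
                                "AA9", "AA3", "PL1", "CBM1"
                              ),
                              signalp_secreted_fraction = 0.25,
                              signalp_beta_secreted = c(8, 2),
                              signalp_beta_background = c(2, 8),
                              genus_fraction = 0.12) {
  design <- as.list(environment())
  fracs <- c(
    design$extra_isoform_prob, design$label_noise_eps, design$decoy_fraction,
    design$fungal_root_specific_fraction, design$host_specific_fraction,
    design$hsp_fraction, design$cazy_fraction, design$signalp_secreted_fraction,
    design$genus_fraction
  )
  if (any(fracs < 0 | fracs >= 1 + 1e-12)) abort("design fractions must lie in [0, 1)")
  counts <- c(design$n_host, design$n_asco, design$n_basidio, design$n_other)
  if (any(counts < 0)) abort("design counts must be >= 0")
  if (length(design$tissues) < 2) abort("at least 2 tissues required")
  if (design$replicates < 1) abort("at least 1 replicate required")
  structure(design, class = "simulation_design")
}

# Split one root seed into independent per-generator streams. The scheme is
# fixed: stream k of seed s is (s * 1009 + k * 9973) mod 2^31 - 1, with k the
# position of the stream name in the registry below.
sim_streams <- function() {
  c("transcripts", "separation_hits", "phylum_hits", "expression",
    "annotations", "genus_hits", "reference_pool", "benchmark", "calibration")
}

#' Derive a per-generator seed from a root seed
#'
#' @param seed Integer root seed.
#' @param stream One of `"transcripts"`, `"separation_hits"`,
#'   `"phylum_hits"`, `"expression"`, `"annotations"`, `"genus_hits"`,
#'   `"reference_pool"`, `"benchmark"`, `"calibration"`.
#' @return An integer seed below 2^31.
#' @export
sub_seed <- function(seed, stream) {
  k <- match(match.arg(stream, sim_streams()), sim_streams())
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

# internal: n random nucleotide sequences of the given lengths
random_sequences <- function(lengths) {
  letters4 <- c("A", "C", "G", "T")
  chars <- sample(letters4, sum(lengths), replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  vapply(seq_along(lengths), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Generate transcripts and the ground-truth table
#'
#' Builds the transcript set a simulated assembly would deliver: one
#' representative isoform per locus (ORF and expression gates passing by
#' construction) plus, for a fraction of loci, one extra isoform that the
#' representative-selection filter must reject — a shorter qualifying
#' isoform, an isoform failing the TPM gate, or one failing the ORF gate.
#' Sequence content is random: every downstream computation operates on hit
#' tables and annotations, not on the sequence itself.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @param sequences Generate nucleotide sequences (default `TRUE`; disable
#'   for speed when only the tabular outputs are needed).
#' @return A list with `transcripts` (tibble as from [read_fasta()]) and
#'   `truth` (tibble: `transcript_id`, `locus_id`, `is_representative`,
#'   `origin`, `phylum_label`, `genus_flag`, `specific_tissue`).
#' @export
generate_transcripts <- function(design, seed, sequences = TRUE) {
  withr::with_seed(seed, {
    n_loci <- design$n_host + design$n_asco + design$n_basidio + design$n_other
    origin <- rep(c("HOST", "FUNGAL"),
                  c(design$n_host, design$n_asco + design$n_basidio + design$n_other))
    phylum <- c(
      rep(NA_character_, design$n_host),
      rep(c("ASCO", "BASIDIO", "OTHER"),
          c(design$n_asco, design$n_basidio, design$n_other))
    )
    locus_id <- sprintf("AG_DN%05d_c0_g1", seq_len(n_loci))
    rep_len <- pmax(320L, as.integer(round(
      rlnorm(n_loci, design$length_meanlog, design$length_sdlog)
    )))
    genus_flag <- origin == "FUNGAL" & phylum == "ASCO" &
      runif(n_loci) < design$genus_fraction
    genus_flag[is.na(genus_flag)] <- FALSE
    spec_tissue <- rep(NA_character_, n_loci)
    is_fungal <- origin == "FUNGAL"
    root_specific <- is_fungal & runif(n_loci) < design$fungal_root_specific_fraction
    spec_tissue[root_specific] <- "root"
    host_specific <- !is_fungal & runif(n_loci) < design$host_specific_fraction
    spec_tissue[host_specific] <- sample(design$tissues, sum(host_specific),
                                         replace = TRUE)

    reps <- tibble(
      transcript_id = paste0(locus_id, "_i1"),
      locus_id = locus_id,
      length_nt = rep_len,
      orf_length_nt = as.integer(round(0.85 * rep_len)),
      is_representative = TRUE,
      iso_type = "representative",
      origin = origin, phylum_label = phylum,
      genus_flag = genus_flag, specific_tissue = spec_tissue
    )

    has_extra <- runif(n_loci) < design$extra_isoform_prob
    extra_type <- sample(c("shorter", "tpm_fail", "orf_fail"),
                         sum(has_extra), replace = TRUE)
    ex <- reps[has_extra, ]
    ex$transcript_id <- paste0(ex$locus_id, "_i2")
    ex$is_representative <- FALSE
    ex$iso_type <- extra_type
    ex$length_nt <- as.integer(ifelse(
      extra_type == "shorter", ex$length_nt - 37L,
      ifelse(extra_type == "tpm_fail", ex$length_nt + 100L, ex$length_nt + 50L)
    ))
    ex$orf_length_nt <- as.integer(ifelse(
      extra_type == "orf_fail", 200L, ex$length_nt
    ))
    ex$specific_tissue <- NA_character_
    ex$genus_flag <- FALSE

    truth <- bind_rows(reps, ex) |> arrange(.data$locus_id, .data$transcript_id)
    transcripts <- truth |>
      select("transcript_id", "locus_id", "length_nt", "orf_length_nt")
    transcripts$sequence <- if (sequences) {
      random_sequences(transcripts$length_nt)
    } else {
      NA_character_
    }
    transcripts <- select(transcripts, "transcript_id", "locus_id", "sequence",
                          "length_nt", "orf_length_nt")
    list(transcripts = transcripts, truth = truth)
  })
}

#' Generate a labeled reference pool
#'
#' Random sequences with phylum labels, emulating the coding sequences of a
#' large fungal genome collection used to build benchmark query and
#' reference sets.
#'
#' @param n_asco,n_basidio,n_other Entries per label.
#' @param seed Integer seed.
#' @param length_meanlog,length_sdlog Log-normal length parameters (nt).
#' @param sequences Generate sequence strings (default `TRUE`).
#' @return A tibble: `sequence_id`, `true_label`, `length_nt`, `sequence`.
#' @export
generate_reference_pool <- function(n_asco = 2000, n_basidio = 700,
                                    n_other = 300, seed,
                                    length_meanlog = log(500),
                                    length_sdlog = 0.45, sequences = TRUE) {
  withr::with_seed(seed, {
    n <- n_asco + n_basidio + n_other
    label <- rep(c("ASCO", "BASIDIO", "OTHER"), c(n_asco, n_basidio, n_other))
    prefix <- c(ASCO = "REFA", BASIDIO = "REFB", OTHER = "REFO")[label]
    idx <- stats::ave(seq_len(n), label, FUN = seq_along)
    out <- tibble(
      sequence_id = sprintf("%s_%05d", prefix, idx),
      true_label = label,
      length_nt = pmax(300L, as.integer(round(rlnorm(n, length_meanlog, length_sdlog))))
    )
    out$sequence <- if (sequences && n > 0) random_sequences(out$length_nt) else NA_character_
    out
  })
}

#' Simulate a ranked homology-hit table with label noise
#'
#' For each query, draws a Poisson-distributed number of significant hits
#' (capped at `hits_max`) plus a binomial number of decoy hits whose E-value
#' lies above the significance range. Each hit's lineage reflects the
#' query's true category with probability `1 - label_noise_eps`, otherwise a
#' uniformly random wrong category from the stage's category space:
#' `{PLANT, ASCO, BASIDIO, OTHER}` at the separation stage,
#' `{ASCO, BASIDIO, OTHER}` at the phylum stage. Queries drawing zero hits
#' are absent from the table.
#'
#' @param queries Tibble with `query_id`, `category` (a member of the
#'   stage's category space) and optionally `query_length`.
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @param stage `"separation"` or `"phylum"`.
#' @return A ranked hit tibble (see [read_hit_table()]).
#' @export
simulate_hit_table <- function(queries, design, seed,
                               stage = c("separation", "phylum")) {
  stage <- match.arg(stage)
  space <- if (stage == "separation") {
    c("PLANT", "ASCO", "BASIDIO", "OTHER")
  } else {
    c("ASCO", "BASIDIO", "OTHER")
  }
  bad <- setdiff(unique(queries$category), space)
  if (length(bad) > 0) {
    abort(paste0("query category '", bad[1], "' outside the ", stage, " space"))
  }
  withr::with_seed(seed, {
    nq <- nrow(queries)
    if (nq == 0) return(rank_hits(empty_hit_table()))
    qlen <- if ("query_length" %in% names(queries)) {
      queries$query_length
    } else {
      pmax(300L, as.integer(round(rlnorm(nq, design$length_meanlog, design$length_sdlog))))
    }
    m_true <- pmin(design$hits_max, 1L + rpois(nq, design$hits_mean - 1))
    m_decoy <- rbinom(nq, design$hits_max, design$decoy_fraction)
    idx <- rep(seq_len(nq), m_true + m_decoy)
    is_decoy <- unlist(lapply(seq_len(nq), function(i) {
      rep(c(FALSE, TRUE), c(m_true[i], m_decoy[i]))
    }))
    n_hits <- length(idx)
    if (n_hits == 0) return(rank_hits(empty_hit_table()))
    truth_cat <- queries$category[idx]
    flip <- runif(n_hits) < design$label_noise_eps
    wrong <- vapply(truth_cat[flip], function(ct) {
      sample(setdiff(space, ct), 1)
    }, character(1))
    category <- truth_cat
    category[flip] <- wrong
    log10_e <- ifelse(
      is_decoy,
      runif(n_hits, design$decoy_evalue_log10[1], design$decoy_evalue_log10[2]),
      runif(n_hits, design$true_evalue_log10[1], design$true_evalue_log10[2])
    )
    e_value <- 10^log10_e
    coverage <- runif(n_hits, 0.5, 1)
    alen <- pmax(1L, as.integer(round(coverage * qlen[idx])))
    hits <- tibble(
      query_id = queries$query_id[idx],
      subject_id = sprintf("SUBJ_%s_%06d", category,
                           sample.int(999999L, n_hits, replace = TRUE)),
      percent_identity = round(runif(n_hits, 70, 100), 1),
      alignment_length = alen,
      mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
      e_value = e_value,
      bit_score = round(-2 * log10_e + runif(n_hits, 0, 10), 1),
      query_length = as.integer(qlen[idx]),
      lineage = lineage_for_category(category)
    )
    rank_hits(hits)
  })
}

#' Generate a tissue-structured expression matrix
#'
#' Transcripts flagged tissue-specific in the truth table get their mean TPM
#' concentrated in that tissue (`specific_high_tpm` there,
#' `specific_low_tpm` elsewhere), so the noise-free SPM is far above the
#' 0.95 calling threshold; non-specific transcripts get a balanced
#' `baseline_tpm`; isoforms designed to fail the TPM gate get
#' `nonqualifying_tpm` everywhere. Replicate noise is multiplicative
#' mean-one log-normal with sdlog `replicate_sigma`.
#'
#' @param truth Truth tibble from [generate_transcripts()].
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return A list with `expression` (long tibble: `transcript_id`,
#'   `sample_id`, `tpm`, `tissue`, `replicate`) and `samples` (sample
#'   sheet tibble).
#' @export
generate_expression_matrix <- function(truth, design, seed) {
  withr::with_seed(seed, {
    samples <- tidyr::expand_grid(
      tissue = design$tissues,
      replicate = seq_len(design$replicates)
    ) |>
      mutate(sample_id = paste0(.data$tissue, "_r", .data$replicate)) |>
      select("sample_id", "tissue", "replicate")
    grid <- tidyr::expand_grid(
      transcript_id = truth$transcript_id,
      sample_id = samples$sample_id
    ) |>
      left_join(samples, by = "sample_id") |>
      left_join(select(truth, "transcript_id", "iso_type", "specific_tissue"),
                by = "transcript_id")
    base <- with(grid, ifelse(
      iso_type == "tpm_fail", design$nonqualifying_tpm,
      ifelse(is.na(specific_tissue), design$baseline_tpm,
             ifelse(specific_tissue == tissue,
                    design$specific_high_tpm, design$specific_low_tpm))
    ))
    sdlog <- design$replicate_sigma
    noise <- rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    expression <- grid |>
      mutate(tpm = base * noise) |>
      select("transcript_id", "sample_id", "tpm", "tissue", "replicate")
    list(expression = expression, samples = samples)
  })
}

#' Generate annotation tables with planted term enrichment
#'
#' Assigns KO and CDD terms to fungal representative transcripts with
#' term-specific background probabilities drawn from the design's ranges;
#' terms listed in `enriched_terms` have their assignment probability
#' multiplied inside the designated phylum group (planted enrichment, odds
#' multiplier 1 = null). Also assigns HSP flags, CAZy families, and
#' Beta-distributed signal-peptide scores.
#'
#' @param truth Truth tibble from [generate_transcripts()].
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return An annotation tibble: `transcript_id`, `source`, `term`, `score`.
#' @export
generate_annotation_tables <- function(truth, design, seed) {
  withr::with_seed(seed, {
    fungal <- filter(truth, .data$is_representative, .data$origin == "FUNGAL")
    if (nrow(fungal) == 0) {
      return(tibble(transcript_id = character(), source = character(),
                    term = character(), score = numeric()))
    }
    group_of <- c(ASCO = "ASCOMYCOTA", BASIDIO = "BASIDIOMYCOTA", OTHER = "OTHER_FUNGI")
    fungal_group <- unname(group_of[fungal$phylum_label])

    draw_terms <- function(src, n_terms, prob_range) {
      # planted terms keep their designed names; the rest are numbered
      enr <- filter(design$enriched_terms, .data$source == src)
      n_plain <- max(0, n_terms - nrow(enr))
      terms <- c(enr$term, sprintf("%s_%04d", src, seq_len(n_plain)))
      q <- runif(length(terms), prob_range[1], prob_range[2])
      purrr::map_dfr(seq_along(terms), function(j) {
        p <- rep(q[j], nrow(fungal))
        hit <- which(enr$term == terms[j])
        if (length(hit) == 1) {
          p[fungal_group == enr$group[hit]] <-
            pmin(0.95, q[j] * enr$multiplier[hit])
        }
        keep <- runif(nrow(fungal)) < p
        tibble(transcript_id = fungal$transcript_id[keep],
               source = src, term = terms[j], score = NA_real_)
      })
    }
    ko <- draw_terms("KO", design$n_ko_terms, design$ko_prob_range)
    cdd <- draw_terms("CDD", design$n_cdd_terms, design$cdd_prob_range)

    hsp <- tibble(
      transcript_id = fungal$transcript_id[runif(nrow(fungal)) < design$hsp_fraction],
      source = "HSP", term = "HSP_domain", score = NA_real_
    )
    has_cazy <- runif(nrow(fungal)) < design$cazy_fraction
    cazy <- tibble(
      transcript_id = fungal$transcript_id[has_cazy],
      source = "CAZY",
      term = sample(design$cazy_families, sum(has_cazy), replace = TRUE),
      score = NA_real_
    )
    secreted <- runif(nrow(fungal)) < design$signalp_secreted_fraction
    sp_score <- ifelse(
      secreted,
      rbeta(nrow(fungal), design$signalp_beta_secreted[1], design$signalp_beta_secreted[2]),
      rbeta(nrow(fungal), design$signalp_beta_background[1], design$signalp_beta_background[2])
    )
    signalp <- tibble(
      transcript_id = fungal$transcript_id,
      source = "SIGNALP", term = "signal_peptide", score = sp_score
    )
    validate_annotations(
      distinct(bind_rows(ko, cdd, hsp, cazy, signalp),
               .data$transcript_id, .data$source, .data$term, .keep_all = TRUE)
    )
  })
}

# internal: hit-table rows for the planted design of simulate_genus_hits
genus_hit_rows <- function(query_id, qlen, log10_e, coverage, subject_id) {
  alen <- pmax(1L, as.integer(round(coverage * qlen)))
  tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = 95, alignment_length = alen,
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = alen,
    s_start = 1L, s_end = alen,
    e_value = 10^log10_e, bit_score = round(-2 * log10_e, 1),
    query_length = as.integer(qlen),
    lineage = lineage_for_category("ASCO")
  )
}

#' Simulate hits against a genus reference set
#'
#' Ascomycota transcripts flagged as genus members in the truth table get
#' qualifying hits (E-value far below 1e-10, coverage above 0.70); the rest
#' either have no hit or a single disqualifying one (low coverage or weak
#' E-value), so threshold-based assignment recovers the flag exactly.
#'
#' @param truth Truth tibble from [generate_transcripts()].
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return A ranked hit tibble over Ascomycota representative transcripts.
#' @export
simulate_genus_hits <- function(truth, design, seed) {
  withr::with_seed(seed, {
    asco <- filter(truth, .data$is_representative, .data$origin == "FUNGAL",
                   .data$phylum_label == "ASCO")
    qlen <- pmax(300L, as.integer(round(
      rlnorm(nrow(asco), design$length_meanlog, design$length_sdlog)
    )))
    members <- which(asco$genus_flag)
    rows_member <- genus_hit_rows(
      asco$transcript_id[members], qlen[members],
      runif(length(members), -60, -15),
      runif(length(members), 0.75, 0.95),
      sprintf("GENREF_%05d", sample.int(99999L, length(members), replace = TRUE))
    )
    non <- which(!asco$genus_flag)
    has_noise_hit <- runif(length(non)) < 0.5
    nn <- non[has_noise_hit]
    low_cov <- runif(length(nn)) < 0.5
    rows_non <- genus_hit_rows(
      asco$transcript_id[nn], qlen[nn],
      ifelse(low_cov, runif(length(nn), -60, -15), runif(length(nn), -8, -3)),
      ifelse(low_cov, runif(length(nn), 0.30, 0.65), runif(length(nn), 0.75, 0.95)),
      sprintf("GENREF_%05d", sample.int(99999L, length(nn), replace = TRUE))
    )
    rank_hits(bind_rows(rows_member, rows_non))
  })
}

#' Simulate a complete community with ground truth
#'
#' Orchestrates every generator with independent seed streams derived from
#' one root seed (see [sub_seed()]): transcripts and truth, separation- and
#' phylum-stage hit tables, the expression matrix and sample sheet,
#' annotation tables, and genus-reference hits. Two calls with the same
#' design and seed produce identical objects.
#'
#' @param design A [simulation_design()].
#' @param seed Integer root seed.
#' @param sequences Generate nucleotide sequences (default `TRUE`).
#' @return A list: `design`, `seed`, `transcripts`, `truth`,
#'   `separation_hits`, `phylum_hits`, `expression`, `samples`,
#'   `annotations`, `genus_hits`.
#' @export
simulate_community <- function(design = simulation_design(), seed,
                               sequences = TRUE) {
  tx <- generate_transcripts(design, sub_seed(seed, "transcripts"), sequences)
  reps <- filter(tx$truth, .data$is_representative)
  sep_queries <- tibble(
    query_id = reps$transcript_id,
    category = if_else(reps$origin == "HOST", "PLANT", reps$phylum_label)
  ) |>
    left_join(select(tx$transcripts, "transcript_id", query_length = "length_nt"),
              by = c(query_id = "transcript_id"))
  separation_hits <- simulate_hit_table(sep_queries, design,
                                        sub_seed(seed, "separation_hits"),
                                        stage = "separation")
  phy_queries <- filter(sep_queries, .data$category != "PLANT")
  phylum_hits <- simulate_hit_table(phy_queries, design,
                                    sub_seed(seed, "phylum_hits"),
                                    stage = "phylum")
  expr <- generate_expression_matrix(tx$truth, design, sub_seed(seed, "expression"))
  annotations <- generate_annotation_tables(tx$truth, design,
                                            sub_seed(seed, "annotations"))
  genus_hits <- simulate_genus_hits(tx$truth, design, sub_seed(seed, "genus_hits"))
  list(
    design = design, seed = seed,
    transcripts = tx$transcripts, truth = tx$truth,
    separation_hits = separation_hits, phylum_hits = phylum_hits,
    expression = expr$expression, samples = expr$samples,
    annotations = annotations, genus_hits = genus_hits
  )
}

#' Write a simulated community to plain-text files
#'
#' Writes the FASTA, hit tables, expression matrix, sample sheet, annotation
#' table, and truth table of a [simulate_community()] result into a
#' directory. Output bytes are a pure function of (design, seed).
#'
#' @param sim Result of [simulate_community()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  if (!anyNA(sim$transcripts$sequence)) {
    write_fasta(sim$transcripts, p("transcripts.fasta"))
  }
  write_hit_table(sim$separation_hits, p("separation_hits.tsv"))
  write_hit_table(sim$phylum_hits, p("phylum_hits.tsv"))
  write_hit_table(sim$genus_hits, p("genus_hits.tsv"))
  write_expression_table(sim$expression, p("expression.tsv"), p("samples.tsv"))
  readr::write_tsv(sim$annotations, p("annotations.tsv"))
  readr::write_tsv(sim$truth, p("truth.tsv"))
  invisible(outdir)
}

#' Null calibration of the enrichment test
#'
#' Repeats an enrichment analysis with terms assigned uniformly at random
#' (no planted enrichment) and returns the fraction of terms significant at
#' raw `p < alpha` per analysis. With term frequencies high enough that the
#' hypergeometric statistic is effectively continuous, the mean fraction is
#' close to `alpha`; for rare terms the discrete test is conservative and
#' the fraction falls below `alpha`.
#'
#' @param n_background Background size per analysis.
#' @param n_group Group size per analysis.
#' @param n_terms Terms per analysis.
#' @param term_prob_range Range of per-term assignment probabilities.
#' @param n_analyses Number of simulated analyses.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with one row per analysis: `analysis`,
#'   `fraction_significant`.
#' @export
calibrate_enrichment_null <- function(n_background = 30000, n_group = 15000,
                                      n_terms = 30,
                                      term_prob_range = c(0.3, 0.6),
                                      n_analyses = 200, alpha = 0.05, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("t%06d", seq_len(n_background))
    terms <- sprintf("KO_%04d", seq_len(n_terms))
    frac <- vapply(seq_len(n_analyses), function(a) {
      q <- runif(n_terms, term_prob_range[1], term_prob_range[2])
      group <- sample(ids, n_group)
      member <- which(matrix(runif(n_background * n_terms), n_background) <
                        rep(q, each = n_background), arr.ind = TRUE)
      ann <- tibble(
        transcript_id = ids[member[, 1]], source = "KO",
        term = terms[member[, 2]], score = NA_real_
      )
      res <- hypergeometric_enrichment(ann, group, ids, alpha = alpha)
      mean(res$significant)
    }, numeric(1))
    tibble(analysis = seq_len(n_analyses), fraction_significant = frac)
  })
}
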