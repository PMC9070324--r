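small_design <- function(...) {
  simulation_design(n_host = 120, n_asco = 40, n_basidio = 20, n_other = 10, ...)
}

test_that("simulations are pure functions of design and seed", {
  d <- small_design()
  a <- simulate_community(d, seed = 3, sequences = FALSE)
  b <- simulate_community(d, seed = 3, sequences = FALSE)
  for (part in c("transcripts", "truth", "separation_hits", "phylum_hits",
                 "expression", "annotations", "genus_hits")) {
    expect_identical(a[[part]], b[[part]], label = part)
  }
  c <- simulate_community(d, seed = 4, sequences = FALSE)
  expect_false(identical(a$separation_hits, c$separation_hits))
})

test_that("truth covers every transcript exactly once with designed counts", {
  d <- small_design()
  sim <- simulate_community(d, seed = 12, sequences = FALSE)
  expect_setequal(sim$truth$transcript_id, sim$transcripts$transcript_id)
  expect_false(any(duplicated(sim$truth$transcript_id)))
  reps <- dplyr::filter(sim$truth, is_representative)
  expect_equal(nrow(reps), 190)
  expect_equal(sum(reps$origin == "HOST"), 120)
  tab <- table(reps$phylum_label)
  expect_equal(unname(tab[c("ASCO", "BASIDIO", "OTHER")]), c(40L, 20L, 10L),
               ignore_attr = TRUE)
})

test_that("generated reference pools honor counts, labels, and the seed", {
  pool <- generate_reference_pool(n_asco = 30, n_basidio = 10, n_other = 5,
                                  seed = 2, sequences = TRUE)
  expect_equal(nrow(pool), 45)
  expect_equal(sum(pool$true_label == "ASCO"), 30)
  expect_false(any(duplicated(pool$sequence_id)))
  expect_true(all(nchar(pool$sequence) == pool$length_nt))
  again <- generate_reference_pool(n_asco = 30, n_basidio = 10, n_other = 5,
                                   seed = 2, sequences = TRUE)
  expect_identical(pool, again)
  none <- generate_reference_pool(0, 0, 0, seed = 2)
  expect_equal(nrow(none), 0)
})

test_that("hit tables reflect the query's true category in the noise-free limit", {
  d <- small_design(label_noise_eps = 0)
  queries <- tibble::tibble(query_id = c("f1", "f2", "h1"),
                            category = c("ASCO", "BASIDIO", "PLANT"))
  hits <- simulate_hit_table(queries, d, seed = 8, stage = "separation")
  sig <- dplyr::filter(hits, e_value <= 1e-10)
  fungal <- lineage_is_fungal(sig$lineage)
  expect_true(all(fungal[sig$query_id != "h1"]))
  expect_true(all(!fungal[sig$query_id == "h1"]))
  expect_error(
    simulate_hit_table(tibble::tibble(query_id = "x", category = "PLANT"),
                       d, seed = 1, stage = "phylum"),
    "outside the phylum space"
  )
})

test_that("expression matrices encode the designed tissue structure", {
  d <- small_design(replicate_sigma = 0)
  tx <- generate_transcripts(d, seed = 5, sequences = FALSE)
  expr <- generate_expression_matrix(tx$truth, d, seed = 6)
  expect_equal(nrow(expr$samples), 9)  # 3 tissues x 3 replicates
  spm <- suppressMessages(spm_profile(mean_tissue_expression(expr$expression)))
  calls <- call_tissue_specific(spm)
  truth <- dplyr::filter(tx$truth, is_representative)
  merged <- dplyr::left_join(truth, calls, by = "transcript_id")
  # with zero replicate noise the designed specificity is recovered exactly
  expect_equal(merged$specific_tissue.y, merged$specific_tissue.x)
  # balanced transcripts sit at SPM = 1/sqrt(3)
  flat_id <- merged$transcript_id[is.na(merged$specific_tissue.x)][1]
  flat <- spm$spm[spm$transcript_id == flat_id]
  expect_equal(flat, rep(1 / sqrt(3), 3), tolerance = 1e-12)
})

test_that("annotation generation plants enrichment and respects the null", {
  d <- small_design()
  tx <- generate_transcripts(d, seed = 9, sequences = FALSE)
  ann <- generate_annotation_tables(tx$truth, d, seed = 10)
  expect_true(all(ann$source %in% c("KO", "CDD", "CAZY", "HSP", "SIGNALP")))
  fungal <- dplyr::filter(tx$truth, is_representative, origin == "FUNGAL")
  expect_setequal(
    dplyr::filter(ann, source == "SIGNALP")$transcript_id,
    fungal$transcript_id
  )
  # planted terms exist under their designed names
  expect_true(all(c("KO_ENR1", "KO_ENR2") %in% ann$term))
  # empty truth gives an empty table
  empty <- generate_annotation_tables(tx$truth[0, ], d, seed = 10)
  expect_equal(nrow(empty), 0)
})

test_that("the noise-free pipeline recovers the planted community exactly", {
  d <- small_design(label_noise_eps = 0)
  sim <- simulate_community(d, seed = 21, sequences = FALSE)
  reps <- select_representative_isoforms(sim$transcripts, sim$expression)
  truth <- dplyr::filter(sim$truth, is_representative)
  expect_setequal(reps$transcript_id, truth$transcript_id)

  part <- partition_transcriptome(reps, sim$separation_hits, sim$phylum_hits)
  merged <- dplyr::left_join(part$calls, truth, by = "transcript_id")
  expect_true(all(merged$origin.x[merged$origin.y == "HOST"] == "HOST"))
  expect_true(all(merged$origin.x[merged$origin.y == "FUNGAL"] == "FUNGAL"))
  group_of <- c(ASCO = "ASCOMYCOTA", BASIDIO = "BASIDIOMYCOTA",
                OTHER = "OTHER_FUNGI")
  fungal <- dplyr::filter(merged, origin.y == "FUNGAL")
  expect_equal(fungal$phylum_group, unname(group_of[fungal$phylum_label]))

  # genus assignment equals the planted flags
  ga <- assign_to_reference_set(sim$genus_hits)
  flagged <- dplyr::left_join(ga, truth, by = c(query_id = "transcript_id"))
  expect_equal(flagged$assigned, flagged$genus_flag)

  # planted terms are recovered as the top-enriched
  fungal_ids <- part$calls$transcript_id[part$calls$origin == "FUNGAL"]
  asco_ids <- part$calls$transcript_id[part$calls$phylum_group == "ASCOMYCOTA"]
  enr <- hypergeometric_enrichment(sim$annotations, asco_ids, fungal_ids,
                                   source = "KO")
  expect_true(all(c("KO_ENR1", "KO_ENR2") %in% enr$term[enr$significant]))
})

test_that("written simulations are byte-identical under the same seed", {
  d <- small_design()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_community(d, seed = 33), dir1)
  write_simulation(simulate_community(d, seed = 33), dir2)
  files <- list.files(dir1)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("seed streams are distinct and reproducible", {
  expect_equal(sub_seed(7, "expression"), sub_seed(7, "expression"))
  streams <- c("transcripts", "separation_hits", "phylum_hits", "expression",
               "annotations", "genus_hits", "reference_pool", "benchmark")
  seeds <- vapply(streams, function(s) sub_seed(7, s), integer(1))
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("design validation rejects out-of-range parameters", {
  expect_error(simulation_design(label_noise_eps = 1.2), "fractions")
  expect_error(simulation_design(n_host = -1), "counts")
  expect_error(simulation_design(tissues = "root"), "2 tissues")
  expect_error(simulation_design(replicates = 0), "replicate")
})
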