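test_that("tissue means average replicates and keep zeros", {
  expr <- tibble::tibble(
    transcript_id = "t1",
    sample_id = paste0("root_r", 1:3),
    tpm = c(1, 2, 3), tissue = "root", replicate = 1:3
  )
  tm <- mean_tissue_expression(expr)
  expect_equal(tm$mean_tpm, 2)
  zero <- dplyr::mutate(expr, tpm = 0)
  expect_equal(mean_tissue_expression(zero)$mean_tpm, 0)
})

test_that("SPM profiles match closed forms and normalize to unit length", {
  tm <- tibble::tibble(
    transcript_id = rep(c("unit", "flat", "near"), each = 3),
    tissue = rep(c("leaf", "stem", "root"), 3),
    mean_tpm = c(0, 0, 10, 1, 1, 1, 1, 0, 10)
  )
  spm <- spm_profile(tm)
  get <- function(id, tis) spm$spm[spm$transcript_id == id & spm$tissue == tis]
  expect_equal(get("unit", "root"), 1)
  expect_equal(get("unit", "leaf"), 0)
  expect_equal(get("flat", "leaf"), 1 / sqrt(3))
  expect_equal(get("near", "root"), 10 / sqrt(101))
  expect_error(spm_profile(dplyr::mutate(tm, mean_tpm = -1)), "negative")
  expect_error(spm_profile(dplyr::filter(tm, tissue == "root")), "2 tissues")
})

test_that("all-zero transcripts have no SPM profile", {
  tm <- tibble::tibble(
    transcript_id = rep(c("dead", "live"), each = 2),
    tissue = rep(c("leaf", "root"), 2),
    mean_tpm = c(0, 0, 1, 2)
  )
  expect_message(spm <- spm_profile(tm), "all-zero")
  expect_setequal(unique(spm$transcript_id), "live")
})

test_that("squared SPM sums to one and SPM is scale-invariant", {
  withr::with_seed(7, {
    for (i in 1:50) {
      x <- runif(4, 0, 100)
      tm <- tibble::tibble(transcript_id = "t", tissue = paste0("T", 1:4),
                           mean_tpm = x)
      spm <- spm_profile(tm)
      expect_lt(abs(sum(spm$spm^2) - 1), 1e-12)
      scaled <- spm_profile(dplyr::mutate(tm, mean_tpm = mean_tpm * 37.5))
      expect_equal(scaled$spm, spm$spm)
    }
  })
})

test_that("tissue-specific calls use a strict threshold and are unique", {
  spm <- tibble::tibble(
    transcript_id = rep(c("spec", "edge"), each = 2),
    tissue = rep(c("root", "leaf"), 2),
    spm = c(0.995, sqrt(1 - 0.995^2), 0.95, sqrt(1 - 0.95^2))
  )
  calls <- call_tissue_specific(spm)
  expect_equal(calls$specific_tissue[calls$transcript_id == "spec"], "root")
  expect_true(is.na(calls$specific_tissue[calls$transcript_id == "edge"]))
})

test_that("hypergeometric enrichment matches the combinatorial identity", {
  ann <- tibble::tibble(
    transcript_id = paste0("t", 1:4), source = "KO",
    term = "K1", score = NA_real_
  )
  bg <- paste0("t", 1:10)
  grp <- paste0("t", 1:5)  # contains all 4 annotated members
  res <- hypergeometric_enrichment(ann, grp, bg)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$k, 4)
  expect_equal(res$K, 4)

  # k = 0: the whole tail, p = 1
  res0 <- hypergeometric_enrichment(ann, paste0("t", 6:10), bg)
  expect_equal(res0$p_value, 1)
  # forced outcome k = K = n = N
  resf <- hypergeometric_enrichment(ann, paste0("t", 1:4), paste0("t", 1:4))
  expect_equal(resf$p_value, 1)

  expect_error(hypergeometric_enrichment(ann, "t99", bg), "not in the background")
})

test_that("enrichment p-values equal exhaustive enumeration for small backgrounds", {
  # spot grid here; the full N <= 12 sweep runs in the acceptance suite
  cases <- expand.grid(N = c(6, 8, 10), n = c(3, 5), K = c(2, 4))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; n <- cases$n[i]; K <- cases$K[i]
    bg <- sprintf("t%02d", 1:N)
    ann <- tibble::tibble(transcript_id = bg[1:K], source = "KO",
                          term = "K1", score = NA_real_)
    for (k in max(0, n - (N - K)):min(n, K)) {
      grp <- bg[c(seq_len(k), if (n > k) K + seq_len(n - k))]
      res <- hypergeometric_enrichment(ann, grp, bg)
      expect_equal(res$p_value, enumerate_hypergeom_tail(k, K, N, n),
                   tolerance = 1e-12,
                   info = sprintf("N=%d n=%d K=%d k=%d", N, n, K, k))
    }
  }
})

test_that("BH correction is optional and never anti-adjusts", {
  withr::with_seed(21, {
    bg <- sprintf("t%03d", 1:100)
    grp <- sample(bg, 40)
    ann <- purrr::map_dfr(1:10, function(j) {
      tibble::tibble(transcript_id = sample(bg, 20), source = "KO",
                     term = paste0("K", j), score = NA_real_)
    })
    raw <- hypergeometric_enrichment(ann, grp, bg)
    bh <- hypergeometric_enrichment(ann, grp, bg, correction = "BH")
    expect_equal(raw$p_value, bh$p_value)
    expect_true(all(bh$p_adjusted >= bh$p_value - 1e-15))
    expect_true(sum(bh$significant) <= sum(raw$significant))
  })
})

test_that("transporter filtering gates the best-ranked hit inclusively", {
  keep <- make_hits("t1", e_value = 1e-6, coverage = 0.72, subject_id = "FAM.1")
  expect_equal(filter_transporter_hits(keep)$family, "FAM.1")
  low_cov <- make_hits("t2", e_value = 1e-6, coverage = 0.69)
  expect_equal(nrow(filter_transporter_hits(low_cov)), 0)
  weak <- make_hits("t3", e_value = 1e-4, coverage = 0.9)
  expect_equal(nrow(filter_transporter_hits(weak)), 0)
  # inclusive boundaries retain exact-threshold hits
  edge <- make_hits("t4", e_value = 1e-5, coverage = 0.70)
  expect_equal(nrow(filter_transporter_hits(edge)), 1)
  # family comes from the best-ranked hit
  two <- make_hits("t5", e_value = c(1e-20, 1e-8), coverage = 0.9,
                   subject_id = c("BEST", "WORSE"))
  expect_equal(filter_transporter_hits(two)$family, "BEST")
})

test_that("secreted CAZyme counts respect the signal-peptide gate and class parsing", {
  ann <- tibble::tibble(
    transcript_id = c("a", "a", "b", "b", "c", "c", "d"),
    source = c("CAZY", "SIGNALP", "CAZY", "SIGNALP", "CAZY", "SIGNALP", "CAZY"),
    term = c("GH18", "sp", "AA9", "sp", "GH16", "sp", "GH10"),
    score = c(NA, 0.8, NA, 0.5, NA, 0.9, NA)
  )
  calls <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    phylum_group = c("BASIDIOMYCOTA", "BASIDIOMYCOTA", "ASCOMYCOTA", "ASCOMYCOTA")
  )
  out <- summarize_secreted_cazymes(ann, calls)
  expect_equal(nrow(out), 2)  # b excluded (score not > 0.5), d has no SIGNALP
  expect_equal(out$n[out$cazy_class == "GH" & out$phylum_group == "BASIDIOMYCOTA"], 1L)
  expect_equal(out$n[out$cazy_class == "GH" & out$phylum_group == "ASCOMYCOTA"], 1L)

  bad <- dplyr::bind_rows(ann, tibble::tibble(
    transcript_id = "a", source = "CAZY", term = "NOTAFAM", score = NA_real_
  ))
  expect_warning(summarize_secreted_cazymes(bad, calls), "unparseable")
})

test_that("community summaries compute percentage shares", {
  calls <- tibble::tibble(
    transcript_id = paste0("t", 1:8),
    origin = c(rep("FUNGAL", 6), "HOST", "HOST"),
    phylum_group = c(rep("ASCOMYCOTA", 4), "BASIDIOMYCOTA", "OTHER_FUNGI",
                     "NOT_APPLICABLE", "NOT_APPLICABLE")
  )
  genus <- tibble::tibble(query_id = c("t1", "t2", "t7"),
                          assigned = c(TRUE, TRUE, TRUE))
  ann <- tibble::tibble(transcript_id = c("t1", "t5"), source = "HSP",
                        term = "HSP_domain", score = NA_real_)
  s <- community_summary(calls, genus, ann)
  v <- setNames(s$value, s$metric)
  expect_equal(unname(v["pct_ascomycota"]), 100 * 4 / 6)
  # the host transcript t7 never counts toward genus assignment
  expect_equal(unname(v["pct_genus"]), 100 * 2 / 6)
  expect_equal(unname(v["pct_hsp"]), 100 * 2 / 6)
  asco_denom <- community_summary(calls, genus, ann,
                                  genus_denominator = "ascomycota")
  expect_equal(asco_denom$value[asco_denom$metric == "pct_genus"], 100 * 2 / 4)
  expect_error(community_summary(dplyr::mutate(calls, origin = "HOST")),
               "at least one fungal")
})

test_that("enrichment results carry broom-style summaries and plots", {
  ann <- tibble::tibble(transcript_id = paste0("t", 1:4), source = "KO",
                        term = "K1", score = NA_real_)
  res <- hypergeometric_enrichment(ann, paste0("t", 1:5), paste0("t", 1:10))
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(gl$n_terms, 1)
  expect_equal(gl$n_significant, 1)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
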