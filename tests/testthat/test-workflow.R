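test_that("workflow config validates inputs", {
  expect_error(workflow_config(e_cutoff_h3 = 0), "positive")
  expect_error(workflow_config(fp_grid = c(5L, 1L)), "ascending")
  cfg <- workflow_config()
  expect_equal(cfg$e_cutoff_h3, 0.1)
  expect_equal(cfg$e_cutoff_h2, 24)
})

test_that("FPR assignment picks the nearer log10 margin with sentinels", {
  t <- build_calibration_table(
    pos_evalues = 1e-12,
    neg_evalues = c(1e-9, 1e-6, 1e-4, 2e-3, 1e-2),
    alpha = 1, n_neg = 5, fp_grid = c(1L, 2L, 3L, 4L, 5L))
  # far below the first boundary
  expect_equal(assign_fpr(1e-30, t)$fp, "FP<1")
  expect_equal(assign_fpr(1e-30, t)$fpr, 0)
  # beyond the last defined boundary
  expect_equal(assign_fpr(1, t)$fp, "beyond-grid")
  # exact boundary
  expect_equal(assign_fpr(1e-6, t)$fp, 2L)
  expect_equal(assign_fpr(1e-6, t)$fpr, 2 / 5)
  # boundaries at FP 2 and 3 are 1e-6 and 1e-4: log-midpoint is 1e-5,
  # the tie goes to the less significant margin
  expect_equal(assign_fpr(1e-5, t)$fp, 3L)
  expect_equal(assign_fpr(3e-6, t)$fp, 2L)
  expect_equal(assign_fpr(5e-5, t)$fp, 3L)
  t_empty <- build_calibration_table(1e-12, c(Inf, Inf), 1, 2, c(1L, 2L))
  expect_error(assign_fpr(1e-5, t_empty), "no FP-grid boundaries")
})

test_that("stage 1 extremes split the library as configured", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  ids <- names(lib$models)
  q <- c(q1 = paste0("GGGG", lib$models[[ids[1]]]$consensus, "GGGG"))
  cfg <- workflow_config(fp_grid = c(1L, 2L, 3L, 5L, 8L))
  all_h3 <- setNames(rep("H3", length(ids)), ids)
  s <- run_stage1(q, calib, all_h3, cfg)
  expect_equal(s$N, 0L)
  expect_equal(s$M, lib$n_total)
  expect_true(ids[1] %in% s$K_models)
  expect_equal(nrow(s$h2_hits), 0)
  all_h2 <- setNames(rep("H2", length(ids)), ids)
  s2 <- run_stage1(q, calib, all_h2, cfg)
  expect_equal(length(s2$K_models), 0L)
  expect_equal(s2$M, 0L)
  expect_true(ids[1] %in% s2$h2_hits$model_id)
})

test_that("stage 2 re-alignments obey the glocal contract and compose", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  ids <- names(lib$models)
  cfg <- workflow_config(fp_grid = c(1L, 2L, 3L, 5L, 8L))
  q <- c(q1 = paste0("AAAA", lib$models[[ids[2]]]$consensus, "AAAA"))
  builds <- setNames(rep("H3", length(ids)), ids)
  s1 <- run_stage1(q, calib, builds, cfg)
  s2 <- run_stage2(s1$h3_hits, q, calib, cfg)
  expect_equal(nrow(s2$realignments),
               nrow(unique(s1$h3_hits[, c("query_id", "model_id")])))
  for (i in seq_len(nrow(s2$realignments))) {
    mid <- s2$realignments$model_id[i]
    m <- lib$models[[mid]]
    expect_equal(s2$realignments$hmm_from[i], 1L)
    expect_equal(s2$realignments$hmm_to[i], m$L)
    # composition oracle: direct viterbi_glocal + evalue
    a <- viterbi_glocal(m$glocal_build, q[["q1"]])
    expect_equal(s2$realignments$bit_score[i], a$bit_score)
    expect_equal(s2$realignments$evalue[i],
                 evalue(a$bit_score, m$evd_glocal, calib$Z))
  }
  empty <- run_stage2(xcal:::.empty_hits(), q, calib, cfg)
  expect_equal(nrow(empty$realignments), 0)
})

test_that("pipeline extremes reproduce pure-glocal and local-detection sets", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  ids <- names(lib$models)
  spec <- get_fixture_spec()
  qs <- generate_query_set(lib, spec)
  queries <- qs$queries[1:6]
  cfg <- workflow_config(fp_grid = c(1L, 2L, 3L, 5L, 8L))

  # N = n_total: pure glocal annotation, identical to a direct glocal scan
  all_h2 <- setNames(rep("H2", length(ids)), ids)
  r_h2 <- run_pipeline(queries, calib, all_h2, cfg)
  expect_equal(r_h2$summary$K, 0L)
  ref <- do.call(rbind, lapply(ids, function(mid)
    search_model_vs_seqdb(lib$models[[mid]], "H2", queries, calib$Z,
                          e_cutoff = cfg$e_cutoff_h2)))
  ref_key <- sort(paste(ref$query_id, ref$model_id, ref$evalue))
  got_key <- sort(paste(r_h2$annotations$query_id, r_h2$annotations$model_id,
                        r_h2$annotations$evalue_h2))
  expect_identical(got_key, ref_key)
  expect_true(all(r_h2$annotations$hmm_from == 1L))

  # N = 0: detection set equals the local scan's, all records re-aligned
  all_h3 <- setNames(rep("H3", length(ids)), ids)
  r_h3 <- run_pipeline(queries, calib, all_h3, cfg)
  local_ref <- do.call(rbind, lapply(ids, function(mid)
    search_model_vs_seqdb(lib$models[[mid]], "H3", queries, calib$Z,
                          e_cutoff = cfg$e_cutoff_h3)))
  expect_setequal(paste(r_h3$annotations$query_id, r_h3$annotations$model_id),
                  unique(paste(local_ref$query_id, local_ref$model_id)))
  Ls <- vapply(r_h3$annotations$model_id, function(m) lib$models[[m]]$L,
               integer(1))
  expect_true(all(r_h3$annotations$hmm_from == 1L))
  expect_equal(r_h3$annotations$hmm_to, unname(Ls))
  expect_true(all(r_h3$summary$K <= r_h3$summary$M))

  # determinism: identical inputs give identical annotation tables
  r_h3b <- run_pipeline(queries, calib, all_h3, cfg)
  expect_identical(r_h3$annotations, r_h3b$annotations)

  # mixed configuration detects at least what the pure-local one does
  sel <- select_library(calib, A = c(1L, 2L, 3L, 5L, 8L))
  r_mix <- run_pipeline(queries, calib, sel, cfg)
  expect_true(all(paste(r_h3$annotations$query_id, r_h3$annotations$model_id)
                  %in% paste(r_mix$annotations$query_id,
                             r_mix$annotations$model_id)))
})

test_that("annotation tables render FP sentinels and round-trip", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  ids <- names(lib$models)
  q <- c(q1 = paste0("AA", lib$models[[ids[1]]]$consensus, "AA"))
  cfg <- workflow_config(fp_grid = c(1L, 2L, 3L, 5L, 8L))
  r <- run_pipeline(q, calib, setNames(rep("H3", length(ids)), ids), cfg)
  p <- tempfile(fileext = ".tsv")
  write_annotation_table(r$annotations, p)
  tab <- read.delim(p, colClasses = "character")
  expect_equal(names(tab)[1:10],
               c("query_id", "model_id", "hmm_from", "hmm_to", "seq_from",
                 "seq_to", "evalue_h2", "evalue_h3", "fp", "fpr"))
  expect_true(all(c("fp_h2", "fp_h3") %in% names(tab)))
  expect_false(any(tab$fp == "beyond-grid"))
})

test_that("concordance screen tolerates small FP shifts and flags skew", {
  s <- concordance_screen(fp_h2 = c(5, 1, 10, 20, "FP<1"),
                          fp_h3 = c(5, 15, 7, 24, 3))
  expect_equal(s$n_pairs, 4)
  expect_equal(s$n_sentinel, 1)
  dt <- s$diff_table
  expect_true(dt$concordant[dt$fp_h2 == 5])          # diff 0
  expect_true(dt$concordant[dt$fp_h2 == 10])         # diff +3 within +/-4
  expect_true(dt$concordant[dt$fp_h2 == 20])         # diff -4: at tolerance
  expect_false(dt$flagged[dt$fp_h2 == 20])
  expect_false(dt$concordant[dt$fp_h2 == 1])         # diff -14
  expect_true(dt$flagged[dt$fp_h2 == 1])             # < -4: flagged
  expect_equal(s$n_flagged, 1)
})
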