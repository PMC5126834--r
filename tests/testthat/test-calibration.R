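test_that("query sets hold alpha degapped seeds and all other consensi", {
  spec <- fixture_spec(n_models = 4, length_range = c(20, 30), alpha = 5,
                       conservation = 0.9, rng_seed = 3L)
  lib <- generate_mini_library(spec)
  qs <- make_query_set(lib, names(lib$models)[2])
  expect_length(qs$positives, 5)
  expect_length(qs$negatives, 3)
  expect_false(any(grepl("-", qs$positives, fixed = TRUE)))
  expect_false(paste0("cons_", qs$target_model_id) %in% names(qs$negatives))
  expect_error(make_query_set(lib, "nope"), "not in library")
})

test_that("hit stratification follows the maximal-overlap pairing rule", {
  gh <- data.frame(query_id = c("q1", "q2"), model_id = "m",
                   hmm_from = c(1L, 1L), hmm_to = c(100L, 100L),
                   evalue = 1e-5)
  lh <- data.frame(query_id = c("q1", "q1", "q3"), model_id = "m",
                   hmm_from = c(1L, 40L, 10L), hmm_to = c(30L, 90L, 20L),
                   evalue = 1e-4)
  s <- stratify_hits(gh, lh)
  expect_equal(nrow(s$paired), 1)
  expect_equal(s$paired$l_idx, 2)          # [40,90] overlap 51 beats [1,30]
  expect_equal(s$orphaned_glocal, 2L)      # q2 has no local counterpart
  expect_equal(sort(s$orphaned_local), c(1L, 3L))
  # disjoint model spans never pair
  lh2 <- data.frame(query_id = "q1", model_id = "m",
                    hmm_from = 101L, hmm_to = 120L, evalue = 1)
  expect_equal(nrow(stratify_hits(gh, lh2)$paired), 0)
})

test_that("glocal-to-local reconstruction: identity window and re-summation", {
  m <- random_model(4, alpha = 4, seed = 77)
  evd <- structure(list(mu = 0, lambda = 0.5), class = "evd_params")
  q <- "KWYECDEF"
  a <- viterbi_glocal(m$glocal_build, q)
  full <- reconstruct_glocal_to_local(a, c(1, 4), evd, Z = 100)
  expect_equal(full$bit_score, a$bit_score, tolerance = 1e-9)
  expect_equal(full$evalue, evalue(a$bit_score, evd, 100), tolerance = 1e-12)
  win <- reconstruct_glocal_to_local(a, c(2, 3), evd, Z = 100)
  expect_equal(win$bit_score, a$emis[2] + a$emis[3] + a$trans[2],
               tolerance = 1e-9)
  expect_error(reconstruct_glocal_to_local(a, c(10, 20), evd, 100), "overlap")
})

test_that("fpr_of_fp is rank over negatives", {
  expect_equal(fpr_of_fp(0, 100), 0)
  expect_equal(fpr_of_fp(c(1, 15), 16294), c(1, 15) / 16294)
  expect_error(fpr_of_fp(17, 16), "within")
})

test_that("calibration tables match a brute-force recount at every threshold", {
  withr::with_seed(8, {
    for (rep in 1:4) {
      alpha <- sample(3:8, 1); n_neg <- sample(5:15, 1)
      pos <- c(10^runif(alpha - 1, -9, 1), Inf)   # one non-detection
      neg <- 10^runif(n_neg, -6, 3)
      t <- build_calibration_table(pos, neg, alpha, n_neg)
      for (i in seq_len(nrow(t$roc_points))) {
        e <- t$roc_points$threshold[i]
        expect_equal(t$roc_points$fpr[i], sum(neg <= e) / n_neg)
        expect_equal(t$roc_points$tpr[i], sum(pos <= e) / alpha)
      }
      expect_true(all(diff(t$roc_points$fpr) >= 0))
      expect_true(all(diff(t$roc_points$tpr) >= 0))
      # precision * (TP + FP) = TP at every PR point
      pr <- t$pr_points
      roc <- t$roc_points[t$roc_points$tp + t$roc_points$fp > 0, ]
      expect_equal(pr$precision * (roc$tp + roc$fp), roc$tp)
    }
  })
})

test_that("FP-grid boundaries are order statistics of the negatives", {
  t <- build_calibration_table(pos_evalues = c(1e-12, 1e-11),
                               neg_evalues = c(1e-8, 1e-5, 1e-3),
                               alpha = 2, n_neg = 3, fp_grid = c(1L, 2L, 3L))
  expect_equal(unname(t$fp_grid_boundaries), c(1e-8, 1e-5, 1e-3))
  expect_equal(unname(t$fp_grid_boundaries["2"]), 1e-5)
  # perfect separation: TPR = 1 at FPR = 1/n_neg, precision 1 before it
  expect_equal(t$roc_points$tpr[t$roc_points$fpr == 1 / 3][1], 1)
  expect_equal(t$pr_points$precision[1], 1)
  # fewer detected negatives than the grid point -> boundary absent
  t2 <- build_calibration_table(c(1e-4), c(1e-3, Inf), 1, 2,
                                fp_grid = c(1L, 2L))
  expect_true(is.na(t2$fp_grid_boundaries["2"]))
})

test_that("per-model calibration reconstructs identically over full windows", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  mid <- names(lib$models)[1]
  m <- lib$models[[mid]]
  qs <- make_query_set(lib, mid)
  all_q <- c(qs$positives, qs$negatives)
  h2 <- search_model_vs_seqdb(m, "H2", all_q, Z = lib$n_total,
                              keep_alignments = TRUE)
  h3 <- search_model_vs_seqdb(m, "H3", all_q, Z = lib$n_total)
  s <- stratify_hits(h2, h3)
  expect_gt(nrow(s$paired), 0)
  for (i in seq_len(nrow(s$paired))) {
    gi <- s$paired$g_idx[i]
    rec <- reconstruct_glocal_to_local(h2$alignment[[gi]], c(1L, m$L),
                                       m$evd_glocal, calib$Z)
    expect_equal(rec$bit_score, h2$bit_score[gi], tolerance = 1e-9)
    expect_equal(rec$evalue, h2$evalue[gi], tolerance = 1e-9)
  }
})

test_that("coverage per model averages model-span fractions of detected hits", {
  t <- build_calibration_table(c(1e-9, 1e-8), c(1e-4, 1e-2, 1), 2, 3)
  hits <- data.frame(query_id = c("a", "b"), hmm_from = c(1L, 1L),
                     hmm_to = c(80L, 90L), evalue = c(1e-9, 1e-8))
  expect_equal(coverage_per_model(hits, 100, fpr_threshold = 1 / 3, t), 0.85)
  full <- data.frame(query_id = "a", hmm_from = 1L, hmm_to = 100L,
                     evalue = 1e-9)
  expect_equal(coverage_per_model(full, 100, 1 / 3, t), 1.0)
  none <- data.frame(query_id = "a", hmm_from = 1L, hmm_to = 100L, evalue = 10)
  expect_true(is.na(coverage_per_model(none, 100, 1 / 3, t)))
})

test_that("library FPR-to-E-value profile takes per-FP medians across models", {
  mk <- function(negs) list(
    table_h2 = build_calibration_table(1e-10, negs, 1, length(negs),
                                       fp_grid = c(1L, 2L), build = "H2"),
    table_h3 = build_calibration_table(1e-10, negs * 1e-6, 1, length(negs),
                                       fp_grid = c(1L, 2L), build = "H3"))
  models <- list(a = mk(c(1e-3, 1e-1)), b = mk(c(1e-2, 1)),
                 c = mk(c(1e-1, 10)))
  prof <- library_fpr_evalue_profile(models, fp_grid = c(1L, 2L))
  h2fp1 <- prof[prof$build == "H2" & prof$fp == 1, ]
  expect_equal(h2fp1$median_evalue, 1e-2)
  expect_equal(h2fp1$n_models, 3)
  # the build with weaker separation needs more stringent (smaller) cutoffs
  h3fp1 <- prof[prof$build == "H3" & prof$fp == 1, ]
  expect_lt(h3fp1$median_evalue, h2fp1$median_evalue)
})

test_that("calibration serializes to per-model tables plus a JSON summary", {
  calib <- get_fixture_calibration()
  d <- tempfile()
  write_calibration(calib, d)
  mid <- names(calib$models)[1]
  tab <- read.delim(file.path(d, paste0(mid, "_h2.tsv")))
  expect_true(all(c("pos", "neg", "boundary") %in% tab$kind))
  j <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(j$n_neg, calib$n_neg)
  expect_equal(length(j$models), length(calib$models))
})
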