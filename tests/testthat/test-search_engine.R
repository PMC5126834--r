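test_that("single-path closed forms hold for L = 1 models", {
  seed <- seed_alignment("m1", c("C", "C", "C"))
  pc <- 1e-9  # near-deterministic transitions
  g <- build_profile(seed, "glocal", pseudocount = pc)
  q <- unname(g$match_emissions[1, "C"])
  a <- viterbi_glocal(g, "C")
  expect_equal(a$bit_score, log2(20 * q), tolerance = 1e-9)
  expect_equal(a$model_span, c(1L, 1L))
  expect_equal(a$seq_span, c(1L, 1L))
  # local differs only by entry/exit terms: log2(1/L) = 0 for L = 1
  l <- build_profile(seed, "local", pseudocount = pc)
  r <- viterbi_local_multihit(l, "C")
  expect_length(r$domains, 1)
  expect_equal(r$domains[[1]]$bit_score, log2(20 * q), tolerance = 1e-9)
  # empty sequence: glocal all-delete path allowed; local finds nothing
  e <- viterbi_glocal(g, "")
  expect_equal(e$seq_span, c(0L, 0L))
  expect_length(viterbi_local_multihit(l, "")$domains, 0)
})

test_that("L = 2 model vs length-1 sequence: best of the two one-delete paths", {
  m <- random_model(2, alpha = 4, gap_rate = 0.3, seed = 11)
  g <- m$glocal_build
  sc <- xcal:::.profile_scores(g)
  for (res in c("A", "W", "C")) {
    x <- xcal:::encode_seq(res)
    p_md <- sc$log_bm + sc$mat[1, x] + sc$tr$md[1]          # M1 -> D2
    p_dm <- sc$log_bd + sc$tr$dm[1] + sc$mat[2, x]          # D1 -> M2
    expect_equal(viterbi_glocal(g, res)$bit_score, max(p_md, p_dm))
  }
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  # spot subset here; the full sweep runs in the acceptance suite
  seqs <- all_seqs_upto(c("A", "C", "D", "E"), 3)
  for (s in c(21, 22)) {
    m <- random_model(L = s - 20, alpha = 3, gap_rate = 0.25, seed = s)
    for (q in seqs) {
      expect_equal(viterbi_glocal(m$glocal_build, q)$bit_score,
                   enumerate_glocal_score(m$glocal_build, q),
                   tolerance = 1e-9)
      expect_equal(viterbi_local_multihit(m$local_build, q)$total_score,
                   enumerate_local_score(m$local_build, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("glocal alignments honour the full-model contract and decompose", {
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- random_model(L = sample(3:20, 1), seed = 100 + i)
      q <- paste(sample(xcal:::AA, sample(5:40, 1), replace = TRUE),
                 collapse = "")
      a <- viterbi_glocal(m$glocal_build, q)
      expect_equal(a$model_span, c(1L, m$L))
      expect_equal(a$entry_score + sum(a$emis) + sum(a$trans) + a$exit_score,
                   a$bit_score, tolerance = 1e-6)
    }
  })
})

test_that("multihit local reports ordered non-overlapping domains", {
  seed <- seed_alignment("m", rep("ACDEFGHIKLMNPQRSTVWY", 4))
  l <- build_profile(seed, "local")
  q <- paste0("ACDEFGHIKLMNPQRSTVWY", "GGGGGGGGGG", "ACDEFGHIKLMNPQRSTVWY")
  r <- viterbi_local_multihit(l, q)
  expect_length(r$domains, 2)
  spans <- t(vapply(r$domains, function(d) d$seq_span, integer(2)))
  expect_true(all(diff(spans[, 1]) > 0))
  expect_true(spans[1, 2] < spans[2, 1])
  for (d in r$domains) {
    expect_true(d$model_span[1] >= 1 && d$model_span[2] <= l$L)
    expect_equal(d$entry_score + sum(d$emis) + sum(d$trans) + d$exit_score,
                 d$bit_score, tolerance = 1e-6)
  }
  # total = domain scores + restart penalty
  expect_equal(r$total_score,
               sum(vapply(r$domains, function(d) d$bit_score, numeric(1))) +
                 (length(r$domains) - 1) * log2(l$loop_prob),
               tolerance = 1e-6)
})

test_that("E-values are monotone in score, linear in Z, Gumbel-formed", {
  evd <- structure(list(mu = 3, lambda = 0.7), class = "evd_params")
  s <- seq(2, 20, by = 1.5)  # range where the tail probability is not saturated
  e <- evalue(s, evd, Z = 16295)
  expect_true(all(diff(e) < 0))
  expect_equal(evalue(10, evd, Z = 200), 2 * evalue(10, evd, Z = 100))
  expect_equal(evalue(evd$mu, evd, Z = 16295), 16295 * (1 - exp(-1)))
  expect_lt(evalue(1e6, evd, Z = 16295), 1e-12)
  expect_error(evalue(1, evd, Z = 0), "Z")
})

test_that("Gumbel ML fit recovers parameters and is location-equivariant", {
  x <- withr::with_seed(99, rgumbel_inv(5000, mu = 0, lambda = 0.693))
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$lambda - 0.693) / 0.693, 0.10)
  expect_lt(abs(fit$mu), 0.15)
  shifted <- fit_gumbel(x + 11.5)
  expect_equal(shifted$mu, fit$mu + 11.5, tolerance = 1e-6)
  expect_equal(shifted$lambda, fit$lambda, tolerance = 1e-6)
  expect_error(fit_gumbel(rep(2, 100)), "degenerate")
})

test_that("calibrate_evd is deterministic and rejects tiny samples", {
  m <- random_model(8, seed = 13)
  e1 <- calibrate_evd(m, "glocal", n_samples = 60, rng_seed = 5)
  e2 <- calibrate_evd(m, "glocal", n_samples = 60, rng_seed = 5)
  expect_identical(e1, e2)
  e3 <- calibrate_evd(m, "glocal", n_samples = 60, rng_seed = 6)
  expect_false(identical(e1$mu, e3$mu))
  expect_gt(e1$lambda, 0)
  expect_error(calibrate_evd(m, "glocal", n_samples = 10), ">= 50")
})

test_that("model-vs-database search respects cutoffs and finds seed positives", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  m <- lib$models[[1]]
  pos <- setNames(vapply(m$seed$rows, xcal:::degap, character(1)),
                  paste0("p", seq_along(m$seed$rows)))
  hits <- search_model_vs_seqdb(m, "H2", pos, Z = lib$n_total)
  expect_equal(sort(unique(hits$query_id)), sort(names(pos)))
  expect_true(all(hits$evalue <= 1000))
  # superset property of a looser cutoff
  strict <- search_model_vs_seqdb(m, "H3", pos, Z = lib$n_total, e_cutoff = 0.1)
  loose <- search_model_vs_seqdb(m, "H3", pos, Z = lib$n_total, e_cutoff = 1000)
  expect_true(nrow(loose) >= nrow(strict))
  key <- function(h) paste(h$query_id, h$seq_from, h$seq_to)
  expect_true(all(key(strict) %in% key(loose)))
  expect_equal(nrow(search_model_vs_seqdb(m, "H2", character(0), Z = 10)), 0)
  expect_equal(nrow(search_model_vs_seqdb(m, "H2", pos, Z = 10, e_cutoff = 0)), 0)
})

test_that("scan_sequence hits an implanted consensus and honours empty cases", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  builds <- setNames(rep("H3", lib$n_total), names(lib$models))
  target <- names(lib$models)[3]
  q <- paste0("GGGGG", lib$models[[target]]$consensus, "GGGGG")
  hits <- scan_sequence(lib, builds, q, Z = lib$n_total, query_id = "q1")
  expect_true(target %in% hits$model_id)
  expect_equal(hits$model_id[which.min(hits$evalue)], target)
  none <- scan_sequence(lib, builds, q, e_cutoffs = c(H2 = 0, H3 = 0))
  expect_equal(nrow(none), 0)
})

test_that("hit tables round-trip through the tab-separated format", {
  calib <- get_fixture_calibration()
  lib <- calib$library
  m <- lib$models[[2]]
  hits <- search_model_vs_seqdb(m, "H3", c(q1 = m$consensus), Z = lib$n_total)
  p <- tempfile(fileext = ".tsv")
  write_hit_table(hits, p)
  back <- read_hit_table(p)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-6)
  expect_equal(back$seq_from, hits$seq_from)
})
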