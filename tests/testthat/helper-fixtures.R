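# Shared fixtures: random small profiles for property tests, and a lazily
# built calibrated mini-library reused across test files.

# a random seed alignment (possibly gapped) and its two builds
random_model <- function(L, alpha = 5, gap_rate = 0.15, seed = 1,
                         model_id = paste0("rnd", seed)) {
  withr::with_seed(seed, {
    rows <- vapply(seq_len(alpha), function(i) {
      ch <- sample(xcal:::AA, L, replace = TRUE)
      gap <- runif(L) < gap_rate
      # keep at least one residue per column across rows handled by chance;
      # a fully-gapped column is legal for the estimator anyway
      ch[gap] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    domain_model(seed_alignment(model_id, rows))
  })
}

.fixture_cache <- new.env(parent = emptyenv())

# 10-model calibrated library (deterministic), shared across tests
get_fixture_calibration <- function() {
  if (is.null(.fixture_cache$calib)) {
    spec <- fixture_spec(n_models = 10, length_range = c(40, 60), alpha = 6,
                         conservation = 0.9, rng_seed = 42L)
    lib <- generate_mini_library(spec)
    .fixture_cache$spec <- spec
    .fixture_cache$lib <- lib
    .fixture_cache$calib <- calibrate_library(lib, n_samples = 100,
                                              rng_seed = 7L)
  }
  .fixture_cache$calib
}

get_fixture_spec <- function() { get_fixture_calibration(); .fixture_cache$spec }
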