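# Alignment engine: R wrappers around the compiled Viterbi kernels.
#
# All scoring is in log2-odds (bits) against the residue background, so
# flanking and inter-domain residues contribute zero and transition
# probabilities contribute their plain log2.

# precompute the score parameterization of a profile; memoized on the object
.profile_scores <- function(hmm) {
  sc <- attr(hmm, "scores")
  if (!is.null(sc)) return(sc)
  bg <- hmm$background
  mat <- log2(sweep(hmm$match_emissions, 2L, bg, "/"))
  ins <- log2(sweep(hmm$insert_emissions, 2L, bg, "/"))
  mat <- cbind(mat, 0)  # 21st column: ambiguity codes score background
  ins <- cbind(ins, 0)
  lg <- function(v) { v <- log2(v); v[is.na(v)] <- -Inf; v }
  tr <- lapply(hmm$transitions, lg)
  sc <- list(mat = mat, ins = ins, tr = tr)
  if (hmm$mode == "glocal") {
    sc$log_bm <- log2(hmm$entry[["bm"]])
    sc$log_bd <- log2(hmm$entry[["bd"]])
  } else {
    sc$log_entry <- log2(hmm$entry[1])        # uniform 1/L
    sc$log_loop <- log2(hmm$loop_prob)
  }
  sc
}

#' Cache the score parameterization of both builds of a model
#'
#' Optional speed helper: alignment functions recompute log-odds matrices on
#' the fly unless the profile carries a cached `"scores"` attribute.
#'
#' @param model a `domain_model`.
#' @return the model with cached scores on both builds.
#' @export
cache_scores <- function(model) {
  attr(model$glocal_build, "scores") <- .profile_scores(model$glocal_build)
  attr(model$local_build, "scores") <- .profile_scores(model$local_build)
  model
}

.as_codes <- function(seq) {
  if (is.character(seq)) encode_seq(seq) - 1L else as.integer(seq) - 1L
}

#' Glocal Viterbi alignment of a sequence to a profile
#'
#' Finds the highest log2-odds path that traverses every match position
#' 1..L exactly once (through match or delete states), with flanking
#' residues scored at background. The alignment therefore always has
#' `model_span = [1, L]` — the glocal contract. An empty sequence is allowed
#' and yields the all-delete path.
#'
#' @param hmm a glocal-mode `profile_hmm`.
#' @param seq residue string (possibly empty).
#' @param query_id optional identifier recorded on the result.
#' @return a `scored_alignment`: list with `bit_score`, `seq_span`
#'   (`c(from, to)`, 1-based inclusive; `c(0, 0)` for the all-delete path),
#'   `model_span = c(1, L)`, per-position contributions (`emis`, `trans`),
#'   `entry_score`, `exit_score`, and `col_state` (1 = match, 2 = delete).
#' @export
viterbi_glocal <- function(hmm, seq, query_id = NA_character_) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (hmm$mode != "glocal") stop("viterbi_glocal requires a glocal-mode build")
  sc <- .profile_scores(hmm)
  r <- .viterbi_glocal_cpp(.as_codes(seq), sc$mat, sc$ins,
                           sc$tr$mm, sc$tr$mi, sc$tr$md,
                           sc$tr$im, sc$tr$ii, sc$tr$dm, sc$tr$dd,
                           sc$log_bm, sc$log_bd)
  structure(list(query_id = query_id, model_id = hmm$model_id,
                 mode = "glocal", bit_score = r$score,
                 seq_span = c(r$seq_from, r$seq_to),
                 model_span = c(1L, hmm$L),
                 emis = r$emis, trans = r$trans,
                 entry_score = r$entry_score, exit_score = r$exit_score,
                 col_state = r$col_state, col_res = r$col_res),
            class = "scored_alignment")
}

#' Multihit local Viterbi alignment
#'
#' Entry is allowed at any match position (uniform probability 1/L), exit is
#' free after any match position, and after an exit the model may restart
#' with probability `loop_prob` (a restart costs `log2(loop_prob)` bits).
#' Delete states are internal only. Domains are non-overlapping on the
#' sequence and ordered by sequence position; the total score is the sum of
#' the domain scores plus the restart terms. A sequence with no
#' positive-scoring path yields zero domains.
#'
#' @inheritParams viterbi_glocal
#' @param hmm a local-mode `profile_hmm`.
#' @return list with `total_score`, and `domains`: a list of
#'   `scored_alignment` objects (each with its own `model_span` possibly a
#'   strict subinterval of `[1, L]`).
#' @export
viterbi_local_multihit <- function(hmm, seq, query_id = NA_character_) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (hmm$mode != "local") stop("viterbi_local_multihit requires a local-mode build")
  sc <- .profile_scores(hmm)
  r <- .viterbi_local_cpp(.as_codes(seq), sc$mat, sc$ins,
                          sc$tr$mm, sc$tr$mi, sc$tr$md,
                          sc$tr$im, sc$tr$ii, sc$tr$dm, sc$tr$dd,
                          sc$log_entry, sc$log_loop)
  domains <- lapply(r$domains, function(d)
    structure(list(query_id = query_id, model_id = hmm$model_id,
                   mode = "local", bit_score = d$score,
                   seq_span = c(d$seq_from, d$seq_to),
                   model_span = c(d$model_from, d$model_to),
                   emis = d$emis, trans = d$trans,
                   entry_score = d$entry_score, exit_score = d$exit_score),
              class = "scored_alignment"))
  list(total_score = r$score, best_raw_score = r$best_raw, domains = domains)
}

#' @export
print.scored_alignment <- function(x, ...) {
  cat(sprintf("scored_alignment %s ~ %s [%s]: %.2f bits, seq %d-%d, model %d-%d\n",
              x$query_id, x$model_id, x$mode, x$bit_score,
              x$seq_span[1], x$seq_span[2], x$model_span[1], x$model_span[2]))
  invisible(x)
}

#' Gumbel E-value of a bit score
#'
#' `E = Z * (1 - exp(-exp(-lambda * (s - mu))))`: the expected number of
#' chance hits at least as strong in a database of `Z` sequences under a
#' Gumbel (EVD) null. Monotone decreasing in `s`, linear in `Z`.
#'
#' @param bit_score alignment score in bits (vectorized).
#' @param evd an `evd_params` object (or list with `mu`, `lambda`).
#' @param Z database size (>= 1).
#' @return non-negative E-value(s).
#' @export
evalue <- function(bit_score, evd, Z) {
  if (Z < 1) stop("Z must be >= 1")
  if (is.null(evd)) stop("model is not calibrated (no EVD parameters)")
  p <- -expm1(-exp(-evd$lambda * (bit_score - evd$mu)))
  Z * p
}

#' Fit Gumbel parameters to a score sample
#'
#' Maximum-likelihood fit of the Gumbel (max-EVD) location `mu` and scale
#' `lambda = 1/beta`. The scale solves the standard profile-likelihood
#' equation `beta = mean(s) - sum(s * w) / sum(w)` with
#' `w = exp(-s / beta)`; it is found by Newton iteration (numerical
#' derivative, moment-based start `beta0 = sd * sqrt(6) / pi`) with a
#' bisection fallback. Scores are centered first, which makes the fit
#' location-equivariant to floating-point accuracy.
#'
#' @param scores numeric vector of at least 10 non-constant scores.
#' @return list with `mu`, `lambda`, `n_samples`.
#' @export
fit_gumbel <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 10) stop("need at least 10 scores")
  if (sd(scores) < 1e-12) stop("degenerate (constant) score sample")
  ctr <- mean(scores)
  s <- scores - ctr
  f <- function(beta) {
    w <- exp(-s / beta)
    beta - mean(s) + sum(s * w) / sum(w)
  }
  beta <- sd(s) * sqrt(6) / pi
  for (it in 1:100) {
    fb <- f(beta)
    h <- beta * 1e-6
    d <- (f(beta + h) - fb) / h
    step <- fb / d
    new <- beta - step
    if (!is.finite(new) || new <= 0) new <- beta / 2
    if (abs(new - beta) < 1e-12 * max(1, beta)) { beta <- new; break }
    beta <- new
  }
  if (!is.finite(f(beta)) || abs(f(beta)) > 1e-6) {
    lo <- beta / 100; hi <- beta * 100
    if (f(lo) * f(hi) < 0)
      beta <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    else stop("Gumbel scale fit did not converge")
  }
  mu <- -beta * log(mean(exp(-s / beta))) + ctr
  list(mu = mu, lambda = 1 / beta, n_samples = n)
}

#' Calibrate the Gumbel null of one build by simulation
#'
#' Draws `n_samples` i.i.d. sequences from the residue background (lengths
#' uniform over `[0.5 L, 2 L]`, bracketing typical query envelopes), scores
#' each with the build's Viterbi (glocal score, or total multihit local
#' score), and fits the Gumbel null by maximum likelihood. Deterministic
#' given `rng_seed`.
#'
#' @param model a `domain_model`.
#' @param mode `"glocal"` or `"local"` — which build to calibrate.
#' @param n_samples number of null sequences (>= 50).
#' @param rng_seed integer seed; the global RNG state is left untouched.
#' @return an `evd_params` object: `mu`, `lambda`, `n_samples`, `rng_seed`.
#' @export
calibrate_evd <- function(model, mode = c("glocal", "local"),
                          n_samples = 200, rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "domain_model"))
  if (n_samples < 50) stop("n_samples must be >= 50")
  hmm <- if (mode == "glocal") model$glocal_build else model$local_build
  L <- hmm$L
  bg <- hmm$background
  scores <- withr::with_seed(rng_seed, {
    lens <- sample(seq(max(1L, floor(0.5 * L)), ceiling(2 * L)),
                   n_samples, replace = TRUE)
    vapply(lens, function(len) {
      s <- paste(sample(AA, len, replace = TRUE, prob = bg), collapse = "")
      if (mode == "glocal") viterbi_glocal(hmm, s)$bit_score
      # local null scores use the best untruncated domain score: the total is
      # clipped at 0 (no domain reported), which would degenerate the fit
      else viterbi_local_multihit(hmm, s)$best_raw_score
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  structure(list(mu = fit$mu, lambda = fit$lambda,
                 n_samples = n_samples, rng_seed = rng_seed),
            class = "evd_params")
}

#' @export
print.evd_params <- function(x, ...) {
  cat(sprintf("evd_params: mu = %.3f bits, lambda = %.4f (n = %d, seed = %d)\n",
              x$mu, x$lambda, x$n_samples, x$rng_seed))
  invisible(x)
}

# internal: empty hit table with the canonical columns
.empty_hits <- function() {
  data.frame(query_id = character(0), model_id = character(0),
             build = character(0), seq_from = integer(0), seq_to = integer(0),
             hmm_from = integer(0), hmm_to = integer(0),
             bit_score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

.hit_row <- function(aln, build, ev) {
  data.frame(query_id = aln$query_id, model_id = aln$model_id, build = build,
             seq_from = aln$seq_span[1], seq_to = aln$seq_span[2],
             hmm_from = aln$model_span[1], hmm_to = aln$model_span[2],
             bit_score = aln$bit_score, evalue = ev,
             stringsAsFactors = FALSE)
}

#' Search one model against a sequence database
#'
#' Aligns every sequence to one build of the model and reports hits with
#' `E <= e_cutoff` (default 1000, capturing as many hits as possible for
#' calibration). Glocal yields at most one hit per sequence; local multihit
#' may yield several (one row per domain, each E-value from its own domain
#' bit score).
#'
#' @param model a calibrated `domain_model`.
#' @param build `"H2"` (glocal) or `"H3"` (local).
#' @param seqs named character vector of query sequences.
#' @param Z database size for E-values.
#' @param e_cutoff report hits with E-value at or below this.
#' @param keep_alignments if TRUE attach the `scored_alignment` objects as a
#'   list column `alignment` (needed for reconstruction).
#' @return hit table: `query_id`, `model_id`, `build`, `seq_from`, `seq_to`,
#'   `hmm_from`, `hmm_to`, `bit_score`, `evalue` (coordinates 1-based
#'   inclusive), sorted by E-value.
#' @export
search_model_vs_seqdb <- function(model, build = c("H2", "H3"), seqs, Z,
                                  e_cutoff = 1000, keep_alignments = FALSE) {
  build <- match.arg(build)
  if (!length(seqs) || e_cutoff <= 0) return(.empty_hits())
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  evd <- if (build == "H2") model$evd_glocal else model$evd_local
  if (is.null(evd)) stop("model ", model$model_id, " is not calibrated for build ", build)
  hmm <- if (build == "H2") model$glocal_build else model$local_build
  rows <- list(); alns <- list()
  for (qid in names(seqs)) {
    if (build == "H2") {
      aln <- viterbi_glocal(hmm, seqs[[qid]], query_id = qid)
      ev <- evalue(aln$bit_score, evd, Z)
      if (ev <= e_cutoff) { rows[[length(rows) + 1L]] <- .hit_row(aln, build, ev)
                            alns[[length(alns) + 1L]] <- aln }
    } else {
      res <- viterbi_local_multihit(hmm, seqs[[qid]], query_id = qid)
      for (aln in res$domains) {
        ev <- evalue(aln$bit_score, evd, Z)
        if (ev <= e_cutoff) { rows[[length(rows) + 1L]] <- .hit_row(aln, build, ev)
                              alns[[length(alns) + 1L]] <- aln }
      }
    }
  }
  if (!length(rows)) return(.empty_hits())
  hits <- do.call(rbind, rows)
  if (keep_alignments) hits$alignment <- I(alns)
  hits[order(hits$evalue), , drop = FALSE]
}

#' Scan one query sequence against a library
#'
#' For each model, searches the build selected for it (`"H2"` glocal or
#' `"H3"` local) and keeps hits at or below that build's E-value cutoff.
#'
#' @param library a `domain_library` with calibrated models.
#' @param selected_builds named character vector `model_id -> "H2"/"H3"`
#'   covering every model.
#' @param seq the query sequence.
#' @param Z database size for E-values.
#' @param e_cutoffs named numeric, cutoffs per build
#'   (default `c(H2 = 24, H3 = 0.1)`).
#' @param query_id identifier recorded in the hit table.
#' @param keep_alignments attach alignments as a list column.
#' @return hit table sorted by E-value (possibly empty).
#' @export
scan_sequence <- function(library, selected_builds, seq, Z = library$n_total,
                          e_cutoffs = c(H2 = 24, H3 = 0.1),
                          query_id = "query", keep_alignments = FALSE) {
  stopifnot(inherits(library, "domain_library"))
  out <- list()
  for (mid in names(library$models)) {
    b <- selected_builds[[mid]]
    if (is.null(b)) stop("no build selected for model ", mid)
    h <- search_model_vs_seqdb(library$models[[mid]], b,
                               setNames(seq, query_id), Z,
                               e_cutoff = e_cutoffs[[b]],
                               keep_alignments = keep_alignments)
    if (nrow(h)) out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits[order(hits$evalue), , drop = FALSE]
}
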