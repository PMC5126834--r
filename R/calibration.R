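# Per-model calibration: build-specific E-values are made comparable through
# false-positive ranks on a shared negative set (the consensus sequences of
# every other model in the library).

#' Build the calibration query set for one model
#'
#' Positives are the model's own seed sequences with gaps stripped (alpha
#' sequences); negatives are the consensus sequences of every other model in
#' the library (`n_total - 1` of them).
#'
#' @param library a `domain_library`.
#' @param target_model_id the model being calibrated.
#' @return list with `target_model_id`, `positives` and `negatives` (named
#'   character vectors) and `alpha`.
#' @export
make_query_set <- function(library, target_model_id) {
  stopifnot(inherits(library, "domain_library"))
  m <- library$models[[target_model_id]]
  if (is.null(m)) stop("model not in library: ", target_model_id)
  pos <- setNames(vapply(m$seed$rows, degap, character(1)), m$seed$row_ids)
  others <- setdiff(names(library$models), target_model_id)
  neg <- setNames(
    vapply(others, function(id) library$models[[id]]$consensus, character(1)),
    paste0("cons_", others))
  list(target_model_id = target_model_id, positives = pos, negatives = neg,
       alpha = length(pos))
}

.span_overlap <- function(a, b) {
  max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
}

#' Stratify glocal and local hits into paired and orphaned sets
#'
#' Pairing happens within the same (query, model): local hits whose model
#' span overlaps the query's glocal hit (at least one shared model position)
#' are candidates; the candidate with maximal model-span overlap is paired
#' (ties go to the smaller `hmm_from`); all remaining hits on either side are
#' orphaned.
#'
#' @param glocal_hits,local_hits hit tables from [search_model_vs_seqdb()]
#'   for the same model (glocal table has at most one row per query).
#' @return list with `paired` (data.frame of index pairs `g_idx`, `l_idx`
#'   into the two tables plus `query_id` and `overlap`), `orphaned_glocal`
#'   and `orphaned_local` (row indices).
#' @export
stratify_hits <- function(glocal_hits, local_hits) {
  paired <- data.frame(query_id = character(0), g_idx = integer(0),
                       l_idx = integer(0), overlap = integer(0))
  used_l <- logical(nrow(local_hits))
  used_g <- logical(nrow(glocal_hits))
  for (gi in seq_len(nrow(glocal_hits))) {
    q <- glocal_hits$query_id[gi]
    gspan <- c(glocal_hits$hmm_from[gi], glocal_hits$hmm_to[gi])
    cand <- which(local_hits$query_id == q & !used_l)
    if (!length(cand)) next
    ov <- vapply(cand, function(li)
      .span_overlap(gspan, c(local_hits$hmm_from[li], local_hits$hmm_to[li])),
      integer(1))
    cand <- cand[ov > 0L]; ov <- ov[ov > 0L]
    if (!length(cand)) next
    ord <- order(-ov, local_hits$hmm_from[cand])
    pick <- cand[ord[1]]
    used_l[pick] <- TRUE; used_g[gi] <- TRUE
    paired <- rbind(paired, data.frame(query_id = q, g_idx = gi, l_idx = pick,
                                       overlap = ov[ord[1]]))
  }
  list(paired = paired,
       orphaned_glocal = which(!used_g),
       orphaned_local = which(!used_l))
}

#' Reconstruct a glocal alignment over a local model window
#'
#' Mimics the local alignment of a paired hit by restricting the glocal
#' alignment's stored per-position contributions to the overlap window
#' `[a, b]` on the model: the truncated bit score is the sum of the
#' per-position emission contributions for positions `a..b` plus the
#' transition contributions between them; the entry (exit) term is included
#' only when the window reaches position 1 (L), so the identity window
#' `[1, L]` reproduces the original glocal score exactly. The new E-value is
#' derived from the same glocal Gumbel null.
#'
#' @param glocal a glocal `scored_alignment` (carries `emis`/`trans`).
#' @param local_model_span `c(from, to)` of the local counterpart, clipped to
#'   `[1, L]`; an empty intersection is an error.
#' @param evd_glocal the glocal build's `evd_params`.
#' @param Z database size.
#' @return list with `bit_score` and `evalue`.
#' @export
reconstruct_glocal_to_local <- function(glocal, local_model_span, evd_glocal, Z) {
  stopifnot(inherits(glocal, "scored_alignment"), glocal$mode == "glocal")
  L <- glocal$model_span[2]
  a <- max(1L, local_model_span[1]); b <- min(L, local_model_span[2])
  if (a > b) stop("empty overlap between window and model positions")
  s <- sum(glocal$emis[a:b])
  if (b > a) s <- s + sum(glocal$trans[a:(b - 1L)])
  if (a == 1L) s <- s + glocal$entry_score
  if (b == L) s <- s + glocal$exit_score
  list(bit_score = s, evalue = evalue(s, evd_glocal, Z))
}

#' False-positive rate of a false-positive rank
#'
#' `FPR = fp / n_neg`, where `fp` is the rank of a negative E-value in the
#' ascending sort and `n_neg` the number of negative sequences
#' (`n_total - 1`).
#'
#' @param fp false-positive count(s), `0 <= fp <= n_neg`.
#' @param n_neg number of negatives.
#' @return numeric FPR(s).
#' @export
fpr_of_fp <- function(fp, n_neg) {
  if (any(fp < 0) || any(fp > n_neg)) stop("fp must be within [0, n_neg]")
  fp / n_neg
}

#' Build the calibration table for one model and build
#'
#' Negative E-values are sorted ascending; the rank of a negative is its FP
#' value, so the k-th smallest negative E-value is the E-value boundary at
#' FP = k. Thresholds are swept over the distinct observed E-values (ties
#' absorbed together); at threshold e, `FP = #(neg <= e)`,
#' `TP = #(pos <= e)`, `FPR = FP/n_neg`, `TPR = TP/alpha`,
#' `precision = TP/(TP+FP)`. Undetected queries carry `E = +Inf` and never
#' count as detected.
#'
#' @param pos_evalues per-positive-query E-values (+Inf for non-detections).
#' @param neg_evalues per-negative-query E-values (+Inf for non-detections).
#' @param alpha number of positives (>= 1).
#' @param n_neg number of negatives (>= 1).
#' @param fp_grid FP counts at which E-value boundaries are recorded.
#' @param model_id,build identifiers stored on the table.
#' @return a `calibration_table`: list with sorted `neg_evalues`,
#'   `pos_evalues`, `roc_points` (FPR, TPR per threshold), `pr_points`
#'   (recall, precision), `fp_grid_boundaries` (named numeric; `NA` where
#'   fewer than k negatives were detected), `alpha`, `n_neg`.
#' @export
build_calibration_table <- function(pos_evalues, neg_evalues, alpha, n_neg,
                                    fp_grid = default_fp_grid(),
                                    model_id = NA_character_,
                                    build = NA_character_) {
  if (alpha < 1 || n_neg < 1) stop("alpha and n_neg must be >= 1")
  pos <- as.numeric(pos_evalues); neg <- sort(as.numeric(neg_evalues))
  thr <- sort(unique(c(pos[is.finite(pos)], neg[is.finite(neg)])))
  fp <- vapply(thr, function(e) sum(neg <= e), numeric(1))
  tp <- vapply(thr, function(e) sum(pos <= e), numeric(1))
  roc <- data.frame(threshold = thr, fp = fp, tp = tp,
                    fpr = fp / n_neg, tpr = tp / alpha)
  pr <- roc[roc$tp + roc$fp > 0, , drop = FALSE]
  pr <- data.frame(threshold = pr$threshold, recall = pr$tpr,
                   precision = ifelse(pr$tp + pr$fp > 0,
                                      pr$tp / (pr$tp + pr$fp), NA_real_))
  nb <- setNames(rep(NA_real_, length(fp_grid)), fp_grid)
  det <- neg[is.finite(neg)]
  ok <- fp_grid <= length(det)
  nb[ok] <- det[fp_grid[ok]]
  structure(list(model_id = model_id, build = build,
                 neg_evalues = neg, pos_evalues = pos,
                 roc_points = roc, pr_points = pr,
                 fp_grid = fp_grid, fp_grid_boundaries = nb,
                 alpha = alpha, n_neg = n_neg),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration_table %s [%s]: alpha = %d, %d/%d negatives detected\n",
              x$model_id, x$build, x$alpha, sum(is.finite(x$neg_evalues)), x$n_neg))
  invisible(x)
}

#' The FPR(FP) interval grid
#'
#' FP counts bounding the FPR intervals used for standardized FP assignment.
#'
#' @return integer vector `c(1, 5, 10, 15, 20, 25, 30, 40, ..., 100)`.
#' @export
default_fp_grid <- function() {
  c(1L, 5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L)
}

#' The default FP set A for build selection
#'
#' @return integer vector `c(1, 5, 10, 20, ..., 100)`.
#' @export
default_fp_set <- function() {
  c(1L, 5L, 10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L)
}

# per-query best E-value; queries absent from the hit table get +Inf
.per_query_evalue <- function(hits, query_ids) {
  e <- setNames(rep(Inf, length(query_ids)), query_ids)
  if (nrow(hits)) {
    agg <- tapply(hits$evalue, hits$query_id, min)
    e[names(agg)] <- agg
  }
  e
}

#' Calibrate one model of a library (both builds)
#'
#' Runs the full per-model calibration: (1) search the model's query set
#' (alpha seed positives + all other consensus negatives) with both builds at
#' `E <= e_cutoff`; (2) stratify hits into paired/orphaned and, for every
#' paired hit, reconstruct the glocal alignment over the local counterpart's
#' model window to re-derive a comparable glocal E-value; (3) build per-build
#' calibration tables (ROC/PR points and FP-grid E-value boundaries). The
#' glocal table uses reconstructed E-values for paired hits and original
#' E-values for orphaned glocal hits; the local table uses the local E-values
#' as observed.
#'
#' @param library a `domain_library`.
#' @param model_id the model to calibrate (must have EVD params set; see
#'   [calibrate_library()]).
#' @param Z database size for E-values (default `n_total`, mirroring a
#'   search against the whole library).
#' @param e_cutoff hit-capture cutoff (default 1000).
#' @param fp_grid FP counts for boundary E-values.
#' @return list with `table_h2`, `table_h3` (calibration tables),
#'   `stratified` (counts), `pos_hits_h3` (local positive hit table with
#'   model spans, for coverage statistics).
#' @export
calibrate_model <- function(library, model_id, Z = library$n_total,
                            e_cutoff = 1000, fp_grid = default_fp_grid()) {
  m <- library$models[[model_id]]
  if (is.null(m)) stop("model not in library: ", model_id)
  if (is.null(m$evd_glocal) || is.null(m$evd_local))
    stop("model ", model_id, " has no EVD parameters; run calibrate_library()")
  qs <- make_query_set(library, model_id)
  all_q <- c(qs$positives, qs$negatives)
  h2 <- search_model_vs_seqdb(m, "H2", all_q, Z, e_cutoff,
                              keep_alignments = TRUE)
  h3 <- search_model_vs_seqdb(m, "H3", all_q, Z, e_cutoff)
  strat <- stratify_hits(h2, h3)

  # glocal E-values: reconstructed where paired, original where orphaned
  e_h2 <- h2$evalue
  if (nrow(strat$paired)) for (i in seq_len(nrow(strat$paired))) {
    gi <- strat$paired$g_idx[i]; li <- strat$paired$l_idx[i]
    rec <- reconstruct_glocal_to_local(
      h2$alignment[[gi]], c(h3$hmm_from[li], h3$hmm_to[li]),
      m$evd_glocal, Z)
    e_h2[gi] <- rec$evalue
  }
  h2e <- h2; h2e$evalue <- e_h2; h2e$alignment <- NULL

  qids <- names(all_q)
  per_q_h2 <- .per_query_evalue(h2e, qids)
  per_q_h3 <- .per_query_evalue(h3, qids)
  is_pos <- qids %in% names(qs$positives)

  t2 <- build_calibration_table(per_q_h2[is_pos], per_q_h2[!is_pos],
                                qs$alpha, library$n_neg, fp_grid,
                                model_id = model_id, build = "H2")
  t3 <- build_calibration_table(per_q_h3[is_pos], per_q_h3[!is_pos],
                                qs$alpha, library$n_neg, fp_grid,
                                model_id = model_id, build = "H3")
  list(model_id = model_id,
       table_h2 = t2, table_h3 = t3,
       stratified = list(n_paired = nrow(strat$paired),
                         n_orphaned_glocal = length(strat$orphaned_glocal),
                         n_orphaned_local = length(strat$orphaned_local)),
       pos_hits_h3 = h3[h3$query_id %in% names(qs$positives), , drop = FALSE])
}

#' Calibrate a whole domain library
#'
#' Fits the Gumbel null of both builds of every model (seeded, deterministic)
#' and runs [calibrate_model()] for each. This is the slow, run-once step of
#' the method.
#'
#' @param library a `domain_library`.
#' @param n_samples null-sample size per EVD fit.
#' @param rng_seed base seed; model i's builds use `rng_seed + 2 i` and
#'   `rng_seed + 2 i + 1`.
#' @param Z,e_cutoff,fp_grid passed to [calibrate_model()].
#' @return a `library_calibration`: list with `library` (EVD-annotated),
#'   `models` (per-model calibration results), `Z`, `fp_grid`, `n_neg`.
#' @export
calibrate_library <- function(library, n_samples = 200, rng_seed = 1L,
                              Z = library$n_total, e_cutoff = 1000,
                              fp_grid = default_fp_grid()) {
  stopifnot(inherits(library, "domain_library"))
  ids <- names(library$models)
  for (i in seq_along(ids)) {
    m <- cache_scores(library$models[[ids[i]]])
    m$evd_glocal <- calibrate_evd(m, "glocal", n_samples,
                                  rng_seed = rng_seed + 2L * i)
    m$evd_local <- calibrate_evd(m, "local", n_samples,
                                 rng_seed = rng_seed + 2L * i + 1L)
    library$models[[ids[i]]] <- m
  }
  calibs <- lapply(ids, function(id)
    calibrate_model(library, id, Z = Z, e_cutoff = e_cutoff,
                    fp_grid = fp_grid))
  structure(list(library = library, models = setNames(calibs, ids),
                 Z = Z, fp_grid = fp_grid, n_neg = library$n_neg,
                 rng_seed = rng_seed),
            class = "library_calibration")
}

#' @export
print.library_calibration <- function(x, ...) {
  cat("library_calibration:", length(x$models), "models, Z =", x$Z, "\n")
  invisible(x)
}

#' Average domain coverage per model
#'
#' Mean, over the positive hits detected within an FPR threshold, of the
#' fraction of the model covered by the hit's model span
#' (`(hmm_to - hmm_from + 1) / L`); 1 means full-domain coverage everywhere.
#' With no detected hit the statistic is undefined and `NA` is returned.
#'
#' @param positive_hits hit table of positive-query hits (local build).
#' @param model_length model length L.
#' @param fpr_threshold FPR defining detection; a hit is detected if its
#'   E-value is at or below the negative E-value boundary at
#'   `FP = floor(fpr_threshold * n_neg)` (strictly below the first negative
#'   when that FP is 0).
#' @param table the model's `calibration_table` (provides the boundary).
#' @return mean coverage in (0, 1], or `NA_real_` if no hit is detected.
#' @export
coverage_per_model <- function(positive_hits, model_length, fpr_threshold,
                               table) {
  stopifnot(inherits(table, "calibration_table"), model_length >= 1)
  fp <- floor(fpr_threshold * table$n_neg + 1e-9)
  det <- table$neg_evalues[is.finite(table$neg_evalues)]
  if (fp >= 1 && length(det)) {
    e_cut <- det[min(fp, length(det))]
    sel <- positive_hits$evalue <= e_cut
  } else {
    e_cut <- if (length(det)) det[1] else Inf
    sel <- positive_hits$evalue < e_cut
  }
  hits <- positive_hits[sel, , drop = FALSE]
  if (!nrow(hits)) return(NA_real_)
  mean((hits$hmm_to - hits$hmm_from + 1) / model_length)
}

#' Library-wide FPR-to-E-value profile
#'
#' For each build and each FP count of the grid, the median and interquartile
#' range of the per-model E-value boundary (the FP-th smallest negative
#' E-value), across the models for which that boundary exists.
#'
#' @param calibration a `library_calibration` (or list of per-model results).
#' @param fp_grid FP counts (default the calibration's grid).
#' @return data.frame with `build`, `fp`, `fpr`, `median_evalue`,
#'   `iqr_evalue`, `n_models`.
#' @export
library_fpr_evalue_profile <- function(calibration, fp_grid = NULL) {
  models <- if (inherits(calibration, "library_calibration"))
    calibration$models else calibration
  n_neg <- models[[1]]$table_h2$n_neg
  fp_grid <- fp_grid %||% models[[1]]$table_h2$fp_grid
  rows <- list()
  for (build in c("H2", "H3")) {
    tf <- if (build == "H2") "table_h2" else "table_h3"
    for (fp in fp_grid) {
      bs <- vapply(models, function(m) {
        det <- m[[tf]]$neg_evalues[is.finite(m[[tf]]$neg_evalues)]
        if (fp <= length(det)) det[fp] else NA_real_
      }, numeric(1))
      bs <- bs[!is.na(bs)]
      if (!length(bs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        build = build, fp = fp, fpr = fp / n_neg,
        median_evalue = median(bs),
        iqr_evalue = unname(diff(quantile(bs, c(0.25, 0.75)))),
        n_models = length(bs))
    }
  }
  do.call(rbind, rows)
}
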