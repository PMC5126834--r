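# The three-stage annotation workflow: split-library scan, glocal
# full-domain re-alignment of the local hits, standardized FPR(FP)
# assignment, plus the cross-build concordance screen.

#' Workflow configuration
#'
#' @param e_cutoff_h3 upper E-value limit for the local (H3) scan
#'   (default 0.1).
#' @param e_cutoff_h2 upper E-value limit for the glocal (H2) scan
#'   (default 24).
#' @param Z database size for E-values (default: library size at run time).
#' @param fp_grid FP counts bounding the FPR intervals
#'   (default [default_fp_grid()]).
#' @param top_n_override optional: use only the top-n most sensitive
#'   H2-selected models as H2, the rest as H3.
#' @param time_h2_reference if TRUE, additionally time (without using) a
#'   glocal scan over the H3 sub-library so the speed model's `M_h2` term can
#'   be measured in the same run.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(e_cutoff_h3 = 0.1, e_cutoff_h2 = 24, Z = NULL,
                            fp_grid = default_fp_grid(),
                            top_n_override = NULL,
                            time_h2_reference = FALSE) {
  if (e_cutoff_h3 <= 0 || e_cutoff_h2 <= 0) stop("cutoffs must be positive")
  if (is.unsorted(fp_grid, strictly = TRUE)) stop("fp_grid must be ascending")
  structure(list(e_cutoff_h3 = e_cutoff_h3, e_cutoff_h2 = e_cutoff_h2,
                 Z = Z, fp_grid = fp_grid, top_n_override = top_n_override,
                 time_h2_reference = time_h2_reference),
            class = "workflow_config")
}

#' Stage 1: split-library scan
#'
#' Scans every query against the H3 sub-library (local mode, cutoff
#' `e_cutoff_h3`) and the H2 sub-library (glocal mode, cutoff `e_cutoff_h2`).
#'
#' @param queries named character vector of query sequences.
#' @param calibration a `library_calibration`.
#' @param builds named character vector `model_id -> "H2"/"H3"` (from
#'   [selected_builds()]).
#' @param config a `workflow_config`.
#' @return list with `h3_hits` and `h2_hits` (hit tables), `K_models`
#'   (distinct models with at least one H3 hit), `L_hits` (number of glocal
#'   hits from the H2 sub-library), `N`, `M`, and per-model stage timings
#'   `t_h3` / `t_h2_native` (seconds).
#' @export
run_stage1 <- function(queries, calibration, builds, config = workflow_config()) {
  stopifnot(inherits(calibration, "library_calibration"))
  lib <- calibration$library
  if (!all(names(lib$models) %in% names(builds)))
    stop("builds must cover every model in the library")
  Z <- config$Z %||% lib$n_total
  h3_models <- names(builds)[builds == "H3"]
  h2_models <- names(builds)[builds == "H2"]
  scan_sub <- function(model_ids, build, cutoff) {
    out <- list(); tms <- setNames(numeric(length(model_ids)), model_ids)
    for (mid in model_ids) {
      t0 <- proc.time()[["elapsed"]]
      h <- search_model_vs_seqdb(lib$models[[mid]], build, queries, Z,
                                 e_cutoff = cutoff)
      tms[mid] <- proc.time()[["elapsed"]] - t0
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
    list(hits = if (length(out)) do.call(rbind, out) else .empty_hits(),
         times = tms)
  }
  s3 <- scan_sub(h3_models, "H3", config$e_cutoff_h3)
  s2 <- scan_sub(h2_models, "H2", config$e_cutoff_h2)
  t_h2_ref <- NULL
  if (isTRUE(config$time_h2_reference)) {
    ref <- scan_sub(h3_models, "H2", Inf)
    t_h2_ref <- ref$times
  }
  list(h3_hits = s3$hits, h2_hits = s2$hits,
       K_models = unique(s3$hits$model_id),
       L_hits = nrow(s2$hits),
       N = length(h2_models), M = length(h3_models),
       t_h3 = s3$times, t_h2_native = s2$times, t_h2_reference = t_h2_ref)
}

#' Stage 2: glocal full-domain re-alignment of the local hits
#'
#' For every distinct (query, model) pair detected by the H3 scan, the query
#' is re-aligned glocally against that model, yielding a full-domain
#' (`model_span = [1, L]`) alignment and an E-value under the model's glocal
#' Gumbel null.
#'
#' @param h3_hits hit table from stage 1.
#' @param queries the query sequences (named).
#' @param calibration a `library_calibration`.
#' @param config a `workflow_config`.
#' @return list with `realignments` (hit-table rows, build `"H2"`, one per
#'   (query, model) pair) and per-model timings `t_h2_realign`.
#' @export
run_stage2 <- function(h3_hits, queries, calibration,
                       config = workflow_config()) {
  lib <- calibration$library
  Z <- config$Z %||% lib$n_total
  pairs <- unique(h3_hits[, c("query_id", "model_id")])
  rows <- list(); tms <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    qid <- pairs$query_id[i]; mid <- pairs$model_id[i]
    m <- lib$models[[mid]]
    t0 <- proc.time()[["elapsed"]]
    aln <- viterbi_glocal(m$glocal_build, queries[[qid]], query_id = qid)
    ev <- evalue(aln$bit_score, m$evd_glocal, Z)
    tms[mid] <- (tms[mid] %|na|% 0) + proc.time()[["elapsed"]] - t0
    rows[[i]] <- .hit_row(aln, "H2", ev)
  }
  list(realignments = if (length(rows)) do.call(rbind, rows) else .empty_hits(),
       t_h2_realign = tms)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Assign a standardized FP (and FPR) to an E-value
#'
#' Locates the E-value within the calibrated FP-grid boundary E-values of
#' the model and returns the nearer margin of its interval, with nearness
#' measured in log10 E-value; an exact log-midpoint tie goes to the less
#' significant (larger-FP) margin. E-values below the first boundary return
#' the sentinel `"FP<1"`; E-values above the largest defined boundary return
#' `"beyond-grid"`.
#'
#' @param hit_evalue the hit's E-value.
#' @param table the model's `calibration_table` for the build that produced
#'   the E-value.
#' @param fp_grid FP counts (default: the table's grid).
#' @return list with `fp` (integer, or the character sentinel) and `fpr`
#'   (`fp / n_neg`; 0 for `"FP<1"`, `NA` for `"beyond-grid"`).
#' @export
assign_fpr <- function(hit_evalue, table, fp_grid = table$fp_grid) {
  stopifnot(inherits(table, "calibration_table"))
  b <- table$fp_grid_boundaries[as.character(fp_grid)]
  ok <- !is.na(b)
  if (!any(ok)) stop("no FP-grid boundaries defined for model ",
                     table$model_id, " [", table$build, "]")
  fps <- fp_grid[ok]; bs <- unname(b[ok])
  if (hit_evalue < bs[1]) return(list(fp = "FP<1", fpr = 0))
  if (hit_evalue > bs[length(bs)]) return(list(fp = "beyond-grid", fpr = NA_real_))
  i <- findInterval(hit_evalue, bs)  # bs[i] <= e <= bs[i+1] (or e == bs[i])
  if (hit_evalue == bs[i]) {
    fp <- fps[i]
  } else {
    dl <- log10(hit_evalue) - log10(bs[i])
    dr <- log10(bs[i + 1]) - log10(hit_evalue)
    fp <- if (dl < dr) fps[i] else fps[i + 1]  # tie -> larger FP
  }
  list(fp = fp, fpr = fp / table$n_neg)
}

#' Run the three-stage annotation workflow
#'
#' Stage 1 scans the queries against the H2 (glocal) and H3 (local)
#' sub-libraries at their build-specific cutoffs; stage 2 re-aligns every
#' (query, model) pair detected by the local scan into a full-domain glocal
#' alignment; stage 3 assigns standardized FP/FPR values from the calibrated
#' boundary E-values. Every final record satisfies the glocal contract
#' (`hmm_from = 1`, `hmm_to = L`).
#'
#' @param queries named character vector of query sequences.
#' @param calibration a `library_calibration`.
#' @param selection a `library_selection` (or a named builds vector).
#' @param config a `workflow_config`.
#' @return list with `annotations` (data.frame: `query_id`, `model_id`,
#'   `hmm_from`, `hmm_to`, `seq_from`, `seq_to`, `evalue_h2`, `evalue_h3`,
#'   `fp`, `fpr`, `fp_h2`, `fp_h3`, `source_build`) and `summary` (N, M, K,
#'   L counts and stage timings).
#' @export
run_pipeline <- function(queries, calibration, selection,
                         config = workflow_config()) {
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  builds <- if (inherits(selection, "library_selection"))
    selected_builds(selection, top_n = config$top_n_override) else selection
  s1 <- run_stage1(queries, calibration, builds, config)
  s2 <- run_stage2(s1$h3_hits, queries, calibration, config)

  fp_chr <- function(x) if (is.character(x)) x else as.character(x)
  # a table with no detected negative has no boundaries: any hit then beats
  # every observed negative, i.e. "FP<1"
  safe_assign <- function(e, table, grid) {
    if (all(is.na(table$fp_grid_boundaries[as.character(grid)])))
      return(list(fp = "FP<1", fpr = 0))
    assign_fpr(e, table, grid)
  }
  recs <- list()
  # H3-detected models: local E-value + glocal re-alignment
  h3 <- s1$h3_hits
  if (nrow(h3)) {
    per_pair <- stats::aggregate(evalue ~ query_id + model_id, h3, min)
    re <- s2$realignments
    for (i in seq_len(nrow(per_pair))) {
      qid <- per_pair$query_id[i]; mid <- per_pair$model_id[i]
      r <- re[re$query_id == qid & re$model_id == mid, , drop = FALSE]
      t3 <- calibration$models[[mid]]$table_h3
      t2 <- calibration$models[[mid]]$table_h2
      a3 <- safe_assign(per_pair$evalue[i], t3, config$fp_grid)
      a2 <- safe_assign(r$evalue[1], t2, config$fp_grid)
      recs[[length(recs) + 1L]] <- data.frame(
        query_id = qid, model_id = mid,
        hmm_from = r$hmm_from[1], hmm_to = r$hmm_to[1],
        seq_from = r$seq_from[1], seq_to = r$seq_to[1],
        evalue_h2 = r$evalue[1], evalue_h3 = per_pair$evalue[i],
        fp = fp_chr(a3$fp), fpr = a3$fpr,
        fp_h2 = fp_chr(a2$fp), fp_h3 = fp_chr(a3$fp),
        source_build = "H3", stringsAsFactors = FALSE)
    }
  }
  # H2-native models: glocal hit only
  h2 <- s1$h2_hits
  if (nrow(h2)) for (i in seq_len(nrow(h2))) {
    mid <- h2$model_id[i]
    t2 <- calibration$models[[mid]]$table_h2
    a2 <- safe_assign(h2$evalue[i], t2, config$fp_grid)
    recs[[length(recs) + 1L]] <- data.frame(
      query_id = h2$query_id[i], model_id = mid,
      hmm_from = h2$hmm_from[i], hmm_to = h2$hmm_to[i],
      seq_from = h2$seq_from[i], seq_to = h2$seq_to[i],
      evalue_h2 = h2$evalue[i], evalue_h3 = NA_real_,
      fp = fp_chr(a2$fp), fpr = a2$fpr,
      fp_h2 = fp_chr(a2$fp), fp_h3 = NA_character_,
      source_build = "H2", stringsAsFactors = FALSE)
  }
  ann <- if (length(recs)) do.call(rbind, recs) else
    data.frame(query_id = character(0), model_id = character(0),
               hmm_from = integer(0), hmm_to = integer(0),
               seq_from = integer(0), seq_to = integer(0),
               evalue_h2 = numeric(0), evalue_h3 = numeric(0),
               fp = character(0), fpr = numeric(0),
               fp_h2 = character(0), fp_h3 = character(0),
               source_build = character(0), stringsAsFactors = FALSE)
  ann <- ann[order(ann$query_id, ann$model_id), , drop = FALSE]
  rownames(ann) <- NULL

  summary <- list(
    N = s1$N, M = s1$M,
    K = length(s1$K_models), L = s1$L_hits,
    n_queries = length(queries), n_records = nrow(ann),
    t_h3 = s1$t_h3, t_h2_native = s1$t_h2_native,
    t_h2_realign = s2$t_h2_realign, t_h2_reference = s1$t_h2_reference)
  list(annotations = ann, summary = summary)
}

#' Concordance screen over paired FP assignments
#'
#' Compares the standardized FP values assigned to the same hit by the two
#' builds. Pairs where either value is a sentinel (`"FP<1"`,
#' `"beyond-grid"`) are excluded from the histogram and reported separately.
#' A numeric pair is concordant iff `|FP_H2 - FP_H3| <= tolerance` and
#' flagged for scrutiny iff `FP_H2 - FP_H3 < -tolerance` (the local build's
#' FPR exceeds the glocal build's).
#'
#' @param fp_h2,fp_h3 vectors of assigned FP values (numeric or the
#'   character sentinels).
#' @param tolerance concordance half-width (default 4).
#' @return list with `diff_table` (data.frame: `fp_h2`, `fp_h3`, `diff`,
#'   `concordant`, `flagged`), `n_pairs`, `n_sentinel`, `n_concordant`,
#'   `n_flagged`, `histogram` (table of diffs).
#' @export
concordance_screen <- function(fp_h2, fp_h3, tolerance = 4) {
  if (length(fp_h2) != length(fp_h3)) stop("inputs must have equal length")
  n2 <- suppressWarnings(as.numeric(fp_h2))
  n3 <- suppressWarnings(as.numeric(fp_h3))
  num <- !is.na(n2) & !is.na(n3)
  d <- n2[num] - n3[num]
  dt <- data.frame(fp_h2 = n2[num], fp_h3 = n3[num], diff = d,
                   concordant = abs(d) <= tolerance,
                   flagged = d < -tolerance)
  list(diff_table = dt,
       n_pairs = sum(num), n_sentinel = sum(!num),
       n_concordant = sum(dt$concordant), n_flagged = sum(dt$flagged),
       histogram = table(dt$diff))
}
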