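# Build selection: per-model comparison of the two builds by normalized
# partial-AUC differences over a set A of false-positive counts.

#' Partial area under the ROC staircase up to a false-positive count
#'
#' Right-continuous step integration of TPR over FPR in
#' `[0, fp_limit / n_neg]`: the staircase holds the TPR attained with exactly
#' r false positives on the interval between the r-th and (r+1)-th negative
#' boundary, so the area is `sum_{r=0}^{fp_limit-1} TPR_r / n_neg` with
#' `TPR_r = #(pos E < (r+1)-th negative E) / alpha`. When fewer negatives
#' than `fp_limit` are detected the TPR extends flat to the limit. A perfect
#' model (all positives before the first negative) yields exactly
#' `fp_limit / n_neg`.
#'
#' @param table a `calibration_table`.
#' @param fp_limit FP count bounding the integration (>= 1).
#' @return the partial AUC (area, not normalized).
#' @export
partial_auc <- function(table, fp_limit) {
  stopifnot(inherits(table, "calibration_table"), fp_limit >= 1)
  pos <- table$pos_evalues
  neg <- table$neg_evalues  # sorted ascending, +Inf for undetected
  alpha <- table$alpha
  tpr <- vapply(seq_len(fp_limit), function(r) {
    b <- if (r <= length(neg)) neg[r] else Inf
    sum(pos < b) / alpha
  }, numeric(1))
  sum(tpr) / table$n_neg
}

#' Normalized partial-AUC difference between the two builds
#'
#' `(partial_auc_H2 - partial_auc_H3) / (x / norm_n)`: the raw partial-AUC
#' difference at FP = x, normalized by the area of the evaluation rectangle.
#' The convention normalizes by `x / n_total` (library size), while the FPR
#' axis uses `n_neg = n_total - 1`; the sign is invariant to `norm_n`.
#'
#' @param table_h2,table_h3 calibration tables of the same model.
#' @param x FP count (> 0).
#' @param norm_n normalization denominator (default `n_neg + 1`, the library
#'   size).
#' @return the normalized difference (positive: glocal more sensitive).
#' @export
normalized_auc_diff <- function(table_h2, table_h3, x,
                                norm_n = table_h2$n_neg + 1L) {
  if (x <= 0) stop("x must be positive")
  (partial_auc(table_h2, x) - partial_auc(table_h3, x)) / (x / norm_n)
}

#' Count criterion and build choice for one model
#'
#' `count_y` is the number of FP-set elements at which the glocal build's
#' normalized partial-AUC strictly exceeds the local build's. The glocal
#' build (H2) is chosen only when the advantage holds over the whole set
#' (`count_y = |A|`); a zero count selects the local build (H3); anything in
#' between is undetermined (the model fluctuates between builds). Ties
#' (difference exactly 0) favor H3, the faster default. Setting
#' `literal_eq_mapping = TRUE` restores the alternative printed pairing in
#' which a zero count is labelled undetermined and intermediate counts H3.
#'
#' @param auc_diff_by_x named numeric, normalized AUC difference at every
#'   x in `A` (names = x values).
#' @param A the FP set (ascending distinct positive counts).
#' @param literal_eq_mapping swap the H3/undetermined labels (see above).
#' @return a `selection_result`: list with `count_y`, `chosen_build`
#'   (`"H2"`, `"H3"` or `"undetermined"`), `auc_diff_by_x`.
#' @export
count_and_select <- function(auc_diff_by_x, A = as.integer(names(auc_diff_by_x)),
                             literal_eq_mapping = FALSE) {
  if (any(is.na(match(as.character(A), names(auc_diff_by_x)))))
    stop("auc_diff_by_x must cover every x in A")
  d <- auc_diff_by_x[as.character(A)]
  count_y <- sum(d > 0)
  chosen <- if (count_y == length(A)) "H2"
            else if (!literal_eq_mapping) {
              if (count_y == 0) "H3" else "undetermined"
            } else {
              if (count_y == 0) "undetermined" else "H3"
            }
  structure(list(count_y = count_y, n_A = length(A),
                 chosen_build = chosen, auc_diff_by_x = d),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: count = %d / %d -> %s\n",
              x$count_y, x$n_A, x$chosen_build))
  invisible(x)
}

#' Select the more sensitive build for every model of a library
#'
#' Computes, per model, the normalized partial-AUC difference at each FP
#' count in `A`, applies the count criterion, and tallies library totals.
#' The totals partition the library
#' (`total_H2 + total_H3 + total_undetermined = n_total`). A suffix sweep is
#' also reported: dropping the smaller x values from A one at a time, the
#' per-suffix totals (the count criterion becomes easier to satisfy at both
#' ends, so H2 and H3 totals can only grow along the sweep).
#'
#' @param calibration a `library_calibration`.
#' @param A the FP set (default [default_fp_set()]).
#' @param norm_n normalization denominator for [normalized_auc_diff()]
#'   (default the library size).
#' @param literal_eq_mapping see [count_and_select()].
#' @return a `library_selection`: list with `per_model` (data.frame:
#'   `model_id`, `count_y`, `chosen_build`, `mean_auc_diff`, one column per
#'   x), `totals` (named counts), `A`, `sweep` (data.frame of totals per
#'   suffix FP set).
#' @export
select_library <- function(calibration, A = default_fp_set(),
                           norm_n = calibration$n_neg + 1L,
                           literal_eq_mapping = FALSE) {
  stopifnot(inherits(calibration, "library_calibration"))
  A <- sort(unique(as.integer(A)))
  if (any(A <= 0)) stop("FP set A must contain positive counts")
  ids <- names(calibration$models)
  diffs <- matrix(NA_real_, length(ids), length(A),
                  dimnames = list(ids, as.character(A)))
  for (id in ids) {
    cm <- calibration$models[[id]]
    diffs[id, ] <- vapply(A, function(x)
      normalized_auc_diff(cm$table_h2, cm$table_h3, x, norm_n), numeric(1))
  }

  res <- lapply(ids, function(id)
    count_and_select(setNames(diffs[id, ], colnames(diffs)), A,
                     literal_eq_mapping))
  per_model <- data.frame(model_id = ids,
                          count_y = vapply(res, `[[`, numeric(1), "count_y"),
                          chosen_build = vapply(res, `[[`, character(1), "chosen_build"),
                          mean_auc_diff = rowMeans(diffs),
                          stringsAsFactors = FALSE)
  per_model <- cbind(per_model, as.data.frame(diffs, check.names = FALSE))
  totals <- c(H2 = sum(per_model$chosen_build == "H2"),
              H3 = sum(per_model$chosen_build == "H3"),
              undetermined = sum(per_model$chosen_build == "undetermined"))

  sweep <- do.call(rbind, lapply(seq_along(A), function(i) {
    Ai <- A[i:length(A)]
    ch <- vapply(ids, function(id)
      count_and_select(setNames(diffs[id, as.character(Ai)], as.character(Ai)),
                       Ai, literal_eq_mapping)$chosen_build, character(1))
    data.frame(first_x = A[i], n_x = length(Ai),
               H2 = sum(ch == "H2"), H3 = sum(ch == "H3"),
               undetermined = sum(ch == "undetermined"))
  }))

  structure(list(per_model = per_model, totals = totals, A = A,
                 norm_n = norm_n, sweep = sweep),
            class = "library_selection")
}

#' @export
print.library_selection <- function(x, ...) {
  cat("library_selection over A = {", paste(x$A, collapse = ", "), "}:\n")
  print(x$totals)
  invisible(x)
}

#' Selected build per model, as used by the workflow
#'
#' Undetermined models are assigned the local (H3) build, which the
#' selection deems to perform closest to; `top_n` optionally keeps only the
#' n highest-ranked H2-selected models (ranked by `count_y`, then mean
#' normalized AUC difference, descending) as H2 and demotes the rest to H3.
#'
#' @param selection a `library_selection`.
#' @param top_n optional cap on the number of H2 models.
#' @return named character vector `model_id -> "H2"/"H3"`.
#' @export
selected_builds <- function(selection, top_n = NULL) {
  pm <- selection$per_model
  b <- ifelse(pm$chosen_build == "H2", "H2", "H3")
  names(b) <- pm$model_id
  if (!is.null(top_n)) {
    h2 <- pm[pm$chosen_build == "H2", , drop = FALSE]
    h2 <- h2[order(-h2$count_y, -h2$mean_auc_diff), , drop = FALSE]
    demote <- if (nrow(h2) > top_n) h2$model_id[-seq_len(top_n)] else character(0)
    b[demote] <- "H3"
  }
  b
}
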