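# Analytical speed model for the mixed workflow versus a pure glocal search.

#' Predicted speed improvement over a pure glocal search
#'
#' `f = M_h2 / (M_h3 + K_h2)`: the glocal scan time over the M local-selected
#' models, divided by the local scan time over the same M models plus the
#' glocal re-alignment time over the K detected models. `f` is bounded above
#' by `M_h2 / M_h3` (attained at `K_h2 = 0`) and strictly decreasing in
#' `K_h2`.
#'
#' @param M_h2 total glocal search time over the M models.
#' @param M_h3 total local search time over the same M models.
#' @param K_h2 glocal re-alignment time over the K detected models.
#' @return the speedup factor f.
#' @export
predicted_speedup <- function(M_h2, M_h3, K_h2) {
  if (any(c(M_h2, M_h3, K_h2) < 0)) stop("times must be non-negative")
  if (M_h3 + K_h2 <= 0) stop("zero denominator: M_h3 + K_h2 must be positive")
  M_h2 / (M_h3 + K_h2)
}

#' Extract speed-model inputs from a pipeline run summary
#'
#' Aggregates the per-stage wall-clock timings of a [run_pipeline()] summary
#' into the terms of the speed model: `M_h3` (stage-1 local scan over the M
#' models), `K_h2` (stage-2 glocal re-alignment) and `M_h2` (glocal scan
#' over the same M models, available only when the run was configured with
#' `time_h2_reference = TRUE`). Timings are hardware-dependent: they are
#' reported, never asserted.
#'
#' @param summary the `summary` element of a [run_pipeline()] result.
#' @return list with `M_h3`, `K_h2`, `M_h2` (NA if not measured), per-model
#'   vectors `t_h3_i`, `t_h2_k`, and `f` (NA if `M_h2` unavailable).
#' @export
measure_run_times <- function(summary) {
  M_h3 <- sum(summary$t_h3)
  K_h2 <- sum(summary$t_h2_realign)
  M_h2 <- if (!is.null(summary$t_h2_reference)) sum(summary$t_h2_reference)
          else NA_real_
  f <- if (!is.na(M_h2) && M_h3 + K_h2 > 0)
    predicted_speedup(M_h2, M_h3, K_h2) else NA_real_
  list(M_h3 = M_h3, K_h2 = K_h2, M_h2 = M_h2,
       t_h3_i = summary$t_h3, t_h2_k = summary$t_h2_realign,
       f = f, f_upper_bound = if (!is.na(M_h2) && M_h3 > 0) M_h2 / M_h3
                             else NA_real_)
}
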