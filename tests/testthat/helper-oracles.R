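# Independent brute-force oracles: exhaustive enumeration of all legal state
# paths, kept deliberately separate from the package's dynamic programming.

# Max score over all glocal paths: traverse columns 1..L once via M or D,
# entry only at column 1, optional insert runs between consecutive columns,
# flanking residues free.
enumerate_glocal_score <- function(hmm, seq) {
  sc <- xcal:::.profile_scores(hmm)
  x <- xcal:::encode_seq(seq)
  n <- length(x); L <- nrow(sc$mat)
  best <- -Inf
  # extend from state (M or D) at column k having consumed j residues
  extend <- function(k, j, state, score) {
    if (k == L) { best <<- max(best, score); return(invisible()) }
    tM <- if (state == "M") sc$tr$mm[k] else sc$tr$dm[k]
    tI <- if (state == "M") sc$tr$mi[k] else -Inf  # no D->I
    tD <- if (state == "M") sc$tr$md[k] else sc$tr$dd[k]
    if (j < n) extend(k + 1, j + 1, "M", score + tM + sc$mat[k + 1, x[j + 1]])
    extend(k + 1, j, "D", score + tD)
    if (is.finite(tI)) {
      # insert runs of m >= 1 residues at I_k, then M_{k+1}
      s <- score + tI
      jj <- j
      while (jj < n) {
        jj <- jj + 1
        s <- s + sc$ins[k, x[jj]]
        if (jj < n)
          extend(k + 1, jj + 1, "M", s + sc$tr$im[k] + sc$mat[k + 1, x[jj + 1]])
        s <- s + sc$tr$ii[k]
      }
    }
  }
  for (j0 in 0:n) {
    if (j0 < n) extend(1, j0 + 1, "M", sc$log_bm + sc$mat[1, x[j0 + 1]])
    extend(1, j0, "D", sc$log_bd)
  }
  best
}

# All single local domains (entry at M_a, exit after M_b, internal I/D) as
# (seq_from, seq_to, score); score includes the per-domain entry term.
enumerate_local_domains <- function(hmm, seq) {
  sc <- xcal:::.profile_scores(hmm)
  x <- xcal:::encode_seq(seq)
  n <- length(x); L <- nrow(sc$mat)
  doms <- list()
  emit <- function(i1, i2, score)
    doms[[length(doms) + 1L]] <<- c(i1, i2, score)
  # at M or D of column k, consumed up to residue j, domain started at i1
  extend <- function(k, j, state, score, i1) {
    if (state == "M") emit(i1, j, score)  # free exit after any match
    if (k == L) return(invisible())
    tM <- if (state == "M") sc$tr$mm[k] else sc$tr$dm[k]
    tI <- if (state == "M") sc$tr$mi[k] else -Inf
    tD <- if (state == "M") sc$tr$md[k] else sc$tr$dd[k]
    if (j < n) extend(k + 1, j + 1, "M", score + tM + sc$mat[k + 1, x[j + 1]], i1)
    extend(k + 1, j, "D", score + tD, i1)
    if (is.finite(tI)) {
      s <- score + tI
      jj <- j
      while (jj < n) {
        jj <- jj + 1
        s <- s + sc$ins[k, x[jj]]
        if (jj < n)
          extend(k + 1, jj + 1, "M", s + sc$tr$im[k] + sc$mat[k + 1, x[jj + 1]], i1)
        s <- s + sc$tr$ii[k]
      }
    }
  }
  for (i1 in seq_len(n))
    for (a in seq_len(L))
      extend(a, i1, "M", sc$log_entry + sc$mat[a, x[i1]], i1)
  doms
}

# Max total score over all ordered sets of non-overlapping domains, with a
# log_loop restart penalty between consecutive domains; empty set scores 0.
enumerate_local_score <- function(hmm, seq) {
  sc <- xcal:::.profile_scores(hmm)
  doms <- enumerate_local_domains(hmm, seq)
  # max over paths with the same sequence span: combining spans afterwards is
  # exhaustive because the total is additive over spans
  if (length(doms)) {
    key <- vapply(doms, function(d) paste(d[1], d[2]), character(1))
    doms <- lapply(split(doms, key), function(g)
      g[[which.max(vapply(g, `[`, numeric(1), 3))]])
  }
  best <- 0
  combine <- function(min_start, acc, d_count) {
    best <<- max(best, acc)
    for (d in doms) {
      if (d[1] >= min_start) {
        pen <- if (d_count > 0) sc$log_loop else 0
        combine(d[2] + 1, acc + pen + d[3], d_count + 1)
      }
    }
  }
  combine(1, 0, 0)
  best
}

# all sequences over an alphabet up to a maximum length (includes "")
all_seqs_upto <- function(alphabet, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# inversion sampler for Gumbel(mu, lambda) maxima — independent of the fitter
rgumbel_inv <- function(n, mu, lambda) mu - log(-log(runif(n))) / lambda
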