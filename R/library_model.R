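#' Read a seed multiple sequence alignment
#'
#' Reads the curated seed alignment that defines a domain family, either in
#' Stockholm format (annotation lines `#=GF`, `#=GC`, `#=GS`, `#=GR` and
#' comments are skipped; wrapped blocks are concatenated per sequence name)
#' or as aligned FASTA. Residues are upper-cased and the gap characters
#' `-` and `.` are both normalized to `-`.
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (sniff the first non-blank line), `"stockholm"` or
#'   `"fasta"`.
#' @param model_id identifier for the family; defaults to the file base name.
#' @return a `seed_alignment` object: list with `model_id`, `rows`
#'   (character vector of equal-length aligned rows), `row_ids` and
#'   `n_columns`.
#' @export
read_seed_alignment <- function(path, format = c("auto", "stockholm", "fasta"),
                                model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  model_id <- model_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "stockholm"
  }
  if (format == "stockholm") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines, which = "right")
    keep <- nzchar(lines) & !startsWith(lines, "#") & lines != "//"
    lines <- lines[keep]
    if (!length(lines)) stop("empty alignment file: ", path)
    parts <- regmatches(lines, regexpr("\\S+", lines))
    seqs <- sub("^\\S+\\s+", "", lines)
    if (any(seqs == lines)) stop("malformed Stockholm row (no sequence field) in ", path)
    ids <- unique(parts)
    rows <- vapply(ids, function(id)
      paste(seqs[parts == id], collapse = ""), character(1))
  } else {
    set <- Biostrings::readBStringSet(path)
    if (!length(set)) stop("empty alignment file: ", path)
    rows <- as.character(set)
    ids <- names(set)
  }
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  seed_alignment(model_id, rows, row_ids = ids)
}

#' Construct and validate a seed alignment
#'
#' @param model_id family identifier.
#' @param rows character vector of aligned residue strings (gap `-`).
#' @param row_ids optional sequence names.
#' @return a `seed_alignment` object.
#' @export
seed_alignment <- function(model_id, rows, row_ids = NULL) {
  if (!length(rows)) stop("alignment must have at least one row")
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment rows: widths ", paste(unique(widths), collapse = ", "))
  if (widths[1] == 0L) stop("alignment has zero columns")
  bad <- grepl(paste0("[^", paste(AA, collapse = ""), "X-]"), rows)
  if (any(bad))
    stop("alignment rows contain characters outside the amino-acid alphabet")
  structure(list(model_id = model_id, rows = unname(rows),
                 row_ids = row_ids %||% paste0(model_id, "_seed", seq_along(rows)),
                 n_columns = unname(widths[1])),
            class = "seed_alignment")
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat("seed_alignment", x$model_id, ":", length(x$rows), "rows x",
      x$n_columns, "columns\n")
  invisible(x)
}

# residues-per-column count matrix (L x 20); gaps and ambiguity codes excluded
.column_counts <- function(seed) {
  L <- seed$n_columns
  m <- matrix(0L, L, 20L, dimnames = list(NULL, AA))
  for (row in seed$rows) {
    code <- encode_seq(row)
    gap <- strsplit(row, "", fixed = TRUE)[[1]] == "-"
    idx <- which(!gap & code <= 20L)
    if (length(idx)) {
      tab <- cbind(idx, code[idx])
      for (i in seq_len(nrow(tab))) m[tab[i, 1], tab[i, 2]] <- m[tab[i, 1], tab[i, 2]] + 1L
    }
  }
  m
}

#' Build a profile HMM from a seed alignment
#'
#' Every alignment column becomes a match position, so the model length L
#' equals the number of alignment columns. Match emissions are add-pseudocount
#' estimates over the 20-letter alphabet: (column counts + pseudocount) /
#' (column residue depth + 20 * pseudocount); ambiguity codes ('X' etc.) are
#' excluded from the counts and score as background when aligned. Gaps place
#' the row in the delete path, and match/delete transition counts between
#' consecutive columns are turned into probabilities with the same
#' pseudocount. Insert states (between consecutive match positions) receive
#' pure-pseudocount transitions and background emissions, since with
#' all-columns-as-match there are no insert observations in the seed.
#'
#' The `mode` fixes the entry/exit topology: `"glocal"` enters only at
#' position 1 (through match or delete, with probabilities estimated from
#' column-1 occupancy) and exits only after position L; `"local"` enters any
#' match position with uniform probability 1/L, exits freely after any match
#' position, and restarts (multihit) with probability `loop_prob`.
#'
#' @param seed a `seed_alignment`.
#' @param mode `"glocal"` or `"local"`.
#' @param pseudocount positive pseudocount added to every emission and
#'   transition count (default 1, add-one).
#' @param background length-20 residue background distribution
#'   (default uniform 1/20).
#' @param loop_prob multihit restart probability for local mode.
#' @return a `profile_hmm` object.
#' @export
build_profile <- function(seed, mode = c("glocal", "local"), pseudocount = 1,
                          background = rep(1 / 20, 20), loop_prob = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(seed, "seed_alignment"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-9)
    stop("background must be a length-20 probability vector")
  L <- seed$n_columns
  if (L < 1L) stop("alignment has zero columns")

  counts <- .column_counts(seed)
  depth <- rowSums(counts)
  match_em <- (counts + pseudocount) / (depth + 20 * pseudocount)
  insert_em <- matrix(background, L, 20L, byrow = TRUE,
                      dimnames = list(NULL, AA))

  # transition counts along the match/delete paths of the seed rows
  nrows <- length(seed$rows)
  is_gap <- do.call(rbind, lapply(seed$rows, function(r)
    strsplit(r, "", fixed = TRUE)[[1]] == "-"))
  nM <- colSums(!is_gap)            # rows in match at each column
  nD <- colSums(is_gap)
  # from column k to k+1 (k = 1..L-1)
  pc <- pseudocount
  if (L > 1) {
    fromM <- !is_gap[, -L, drop = FALSE]
    toM   <- !is_gap[, -1L, drop = FALSE]
    nMM <- colSums(fromM & toM); nMD <- colSums(fromM & !toM)
    nDM <- colSums(!fromM & toM); nDD <- colSums(!fromM & !toM)
  } else {
    nMM <- nMD <- nDM <- nDD <- numeric(0)
  }
  pad <- function(v) c(v, NA_real_)  # position L: exit handled by topology
  mm <- pad((nMM + pc) / (nMM + nMD + 3 * pc))   # M -> {M, I, D}
  mi <- pad(rep(pc, max(L - 1, 0)) / (nMM + nMD + 3 * pc))
  md <- pad((nMD + pc) / (nMM + nMD + 3 * pc))
  im <- pad(rep(0.5, max(L - 1, 0)))             # I -> {M, I}: pseudocounts only
  ii <- pad(rep(0.5, max(L - 1, 0)))
  dm <- pad((nDM + pc) / (nDM + nDD + 2 * pc))   # D -> {M, D}
  dd <- pad((nDD + pc) / (nDM + nDD + 2 * pc))

  entry <- switch(mode,
    glocal = c(bm = (nM[1] + pc) / (nrows + 2 * pc),
               bd = (nD[1] + pc) / (nrows + 2 * pc)),
    local = rep(1 / L, L))

  structure(list(
    model_id = seed$model_id, L = L, mode = mode,
    match_emissions = match_em, insert_emissions = insert_em,
    transitions = list(mm = mm, mi = mi, md = md, im = im, ii = ii,
                       dm = dm, dd = dd),
    entry = entry, loop_prob = if (mode == "local") loop_prob else NA_real_,
    background = background, pseudocount = pseudocount),
    class = "profile_hmm")
}

#' Validate profile-HMM normalization invariants
#'
#' Checks that every probability vector (match and insert emissions per
#' position, transition triples/pairs per source state, entry distribution)
#' sums to one within `tol`.
#'
#' @param hmm a `profile_hmm`.
#' @param tol tolerance on each probability-vector sum (default 1e-9).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_profile <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  chk <- function(x, what) if (any(abs(x - 1) > tol))
    stop("probability vectors of ", what, " do not sum to 1")
  chk(rowSums(hmm$match_emissions), "match emissions")
  chk(rowSums(hmm$insert_emissions), "insert emissions")
  L <- hmm$L
  if (L > 1) {
    k <- seq_len(L - 1)
    tr <- hmm$transitions
    chk(tr$mm[k] + tr$mi[k] + tr$md[k], "match transitions")
    chk(tr$im[k] + tr$ii[k], "insert transitions")
    chk(tr$dm[k] + tr$dd[k], "delete transitions")
  }
  if (hmm$mode == "glocal") chk(sum(hmm$entry), "glocal entry") else
    chk(sum(hmm$entry), "local entry")
  invisible(TRUE)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm", x$model_id, ":", x$L, "match positions,",
      x$mode, "mode\n")
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' Position k emits the residue with maximal match-emission probability;
#' ties are broken alphabetically by one-letter code.
#'
#' @param hmm a `profile_hmm`.
#' @return a residue string of length L.
#' @export
consensus_sequence <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  idx <- apply(hmm$match_emissions, 1L, which.max)  # first max = alphabetical
  paste(AA[idx], collapse = "")
}

#' Assemble a domain model (both builds) from a seed alignment
#'
#' Builds the glocal-style and local-style profile from the same seed and
#' derives the consensus sequence. Gumbel null parameters (`evd_glocal`,
#' `evd_local`) are unset until [calibrate_evd()] is run.
#'
#' @param seed a `seed_alignment`.
#' @param pseudocount,background,loop_prob passed to [build_profile()].
#' @param local_seed optional alternative seed used only for the local build
#'   (the synthetic-fixture generator uses this to weaken one build).
#' @return a `domain_model` object.
#' @export
domain_model <- function(seed, pseudocount = 1, background = rep(1 / 20, 20),
                         loop_prob = 0.5, local_seed = NULL) {
  glocal <- build_profile(seed, "glocal", pseudocount, background, loop_prob)
  local <- build_profile(local_seed %||% seed, "local", pseudocount,
                         background, loop_prob)
  if (local$L != glocal$L) stop("both builds must share the model length")
  structure(list(model_id = seed$model_id, seed = seed,
                 glocal_build = glocal, local_build = local,
                 consensus = consensus_sequence(glocal),
                 evd_glocal = NULL, evd_local = NULL,
                 L = glocal$L),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat("domain_model", x$model_id, ": L =", x$L, ", alpha =",
      length(x$seed$rows), if (!is.null(x$evd_glocal)) "(calibrated)" else "",
      "\n")
  invisible(x)
}

#' Assemble a domain library
#'
#' @param models list of `domain_model` objects with unique ids; at least two
#'   models are required (otherwise no negative set exists).
#' @return a `domain_library`: named list of models with `n_total` and
#'   `n_neg = n_total - 1` attributes.
#' @export
domain_library <- function(models) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) stop("model ids must be unique")
  if (length(models) < 2L) stop("a library needs at least 2 models")
  structure(list(models = setNames(models, ids),
                 n_total = length(models), n_neg = length(models) - 1L),
            class = "domain_library")
}

#' @export
print.domain_library <- function(x, ...) {
  cat("domain_library:", x$n_total, "models (", x$n_neg, "negatives per calibration )\n")
  invisible(x)
}

#' Read a domain library from a manifest file
#'
#' The manifest is tab-separated with one model per line:
#' `model_id <TAB> path-to-seed-alignment` (paths relative to the manifest's
#' directory are resolved).
#'
#' @param manifest path to the manifest file.
#' @param pseudocount,background passed to [domain_model()].
#' @return a `domain_library`.
#' @export
read_library <- function(manifest, pseudocount = 1,
                         background = rep(1 / 20, 20)) {
  tab <- read.delim(manifest, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("manifest needs two tab-separated columns")
  base <- dirname(manifest)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab[i, 2]
    if (!file.exists(p)) p <- file.path(base, p)
    domain_model(read_seed_alignment(p, model_id = tab[i, 1]),
                 pseudocount = pseudocount, background = background)
  })
  domain_library(models)
}
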