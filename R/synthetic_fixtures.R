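# Deterministic generators for miniature domain libraries and query sets,
# emulating curated seed alignments (alpha rows per family around a
# consensus) and query proteins with implanted domains plus decoys.

#' Specification for a synthetic domain library and query set
#'
#' @param n_models number of domain families.
#' @param length_range integer range of model lengths (sampled uniformly).
#' @param alpha seed rows per family.
#' @param conservation per-column probability that a seed row copies the
#'   consensus (otherwise a uniform residue is substituted), in (0, 1].
#' @param implant_conservation per-column consensus-copy probability for
#'   implanted domain instances (default: `conservation`).
#' @param n_queries number of implant-carrying query sequences.
#' @param implants_per_query domain instances implanted per query.
#' @param linker_range integer range of background linker/flank lengths.
#' @param decoy_fraction decoy (implant-free) sequences as a fraction of
#'   `n_queries`, appended after the implant queries.
#' @param weakened_local model ids (or indices) whose local build is built
#'   from a noise-degraded copy of the seed, forcing the glocal build to be
#'   the more sensitive one.
#' @param weakened_noise per-column substitution probability applied to the
#'   degraded seed copy. The default 1 redraws every column (an uninformative
#'   local build): over the domain lengths generated here, anything short of
#'   full randomization still leaves enough per-column signal for the local
#'   build to separate positives from negatives perfectly.
#' @param rng_seed integer seed; all generation is deterministic given it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_models = 30, length_range = c(60, 90), alpha = 8,
                         conservation = 0.95, implant_conservation = NULL,
                         n_queries = n_models, implants_per_query = 1,
                         linker_range = c(15, 40), decoy_fraction = 0.2,
                         weakened_local = character(0), weakened_noise = 1,
                         rng_seed = 1L) {
  if (conservation <= 0 || conservation > 1)
    stop("conservation must be in (0, 1]")
  if (n_models < 2 || alpha < 1) stop("need n_models >= 2 and alpha >= 1")
  structure(list(n_models = n_models, length_range = length_range,
                 alpha = alpha, conservation = conservation,
                 implant_conservation = implant_conservation %||% conservation,
                 n_queries = n_queries, implants_per_query = implants_per_query,
                 linker_range = linker_range, decoy_fraction = decoy_fraction,
                 weakened_local = weakened_local,
                 weakened_noise = weakened_noise, rng_seed = rng_seed),
            class = "fixture_spec")
}

# mutate a residue string: per position, with probability `rate` replace by
# a uniform residue (which may coincide with the original)
.mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(AA, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate one synthetic domain family
#'
#' The consensus is drawn uniformly over the 20 residues; each of the
#' `alpha` seed rows copies the consensus per column with probability
#' `conservation` and substitutes a uniform residue otherwise (so the
#' expected per-column identity is `p + (1 - p)/20`). Deterministic given
#' `rng_seed`.
#'
#' @param length model length (>= 1).
#' @param alpha number of seed rows (>= 1).
#' @param conservation consensus-copy probability, in (0, 1].
#' @param rng_seed integer seed.
#' @param model_id family identifier.
#' @return list with `seed` (a `seed_alignment`) and `consensus`.
#' @export
generate_domain_family <- function(length, alpha, conservation, rng_seed,
                                   model_id = "fam1") {
  if (conservation <= 0 || conservation > 1)
    stop("conservation must be in (0, 1]")
  if (length < 1 || alpha < 1) stop("length and alpha must be >= 1")
  withr::with_seed(rng_seed, {
    consensus <- paste(sample(AA, length, replace = TRUE), collapse = "")
    rows <- vapply(seq_len(alpha), function(i)
      .mutate_seq(consensus, 1 - conservation), character(1))
    list(seed = seed_alignment(model_id, rows), consensus = consensus)
  })
}

#' Generate a miniature domain library
#'
#' Families are generated per [generate_domain_family()]; true consensus
#' sequences are required to be mutually distinct (error after 100 redraws).
#' For models flagged `weakened_local`, the local build is constructed from a
#' noise-degraded copy of the seed (`weakened_noise` substitution rate per
#' column), leaving the glocal build untouched — a fixture device that forces
#' glocal selection for those models. If `dir` is given, Stockholm seed files
#' and a tab-separated manifest are written there.
#'
#' @param spec a `fixture_spec`.
#' @param dir optional output directory for seed files + manifest.
#' @return a `domain_library`; the generating consensus of each family is
#'   attached as attribute `"true_consensus"` (named character vector).
#' @export
generate_mini_library <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  weakened <- spec$weakened_local
  if (is.numeric(weakened)) weakened <- sprintf("fam%02d", weakened)
  models <- vector("list", spec$n_models)
  consensi <- character(spec$n_models)
  withr::with_seed(spec$rng_seed, {
    for (i in seq_len(spec$n_models)) {
      mid <- sprintf("fam%02d", i)
      L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
      fam <- NULL
      for (try in 1:100) {
        cand <- generate_domain_family(L, spec$alpha, spec$conservation,
                                       rng_seed = sample.int(2^30, 1L),
                                       model_id = mid)
        if (!cand$consensus %in% consensi[seq_len(i - 1)]) { fam <- cand; break }
      }
      if (is.null(fam)) stop("duplicate consensus after 100 redraws")
      local_seed <- NULL
      if (mid %in% weakened) {
        noisy <- vapply(fam$seed$rows, .mutate_seq, character(1),
                        rate = spec$weakened_noise)
        local_seed <- seed_alignment(mid, unname(noisy))
      }
      models[[i]] <- domain_model(fam$seed, local_seed = local_seed)
      consensi[i] <- fam$consensus
    }
  })
  lib <- domain_library(models)
  attr(lib, "true_consensus") <- setNames(consensi, names(lib$models))
  if (!is.null(dir)) write_library(lib, dir)
  lib
}

#' Write a library's seed alignments and manifest to disk
#'
#' One Stockholm file per model plus `manifest.tsv`
#' (`model_id <TAB> file`).
#'
#' @param library a `domain_library`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(library$models), function(mid) {
    seed <- library$models[[mid]]$seed
    path <- file.path(dir, paste0(mid, ".sto"))
    con <- file(path, "w")
    writeLines("# STOCKHOLM 1.0", con)
    writeLines(sprintf("#=GF ID %s", mid), con)
    writeLines(sprintf("%-20s %s", seed$row_ids, seed$rows), con)
    writeLines("//", con)
    close(con)
    c(mid, paste0(mid, ".sto"))
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(manifest)
}

#' Generate a query set with implanted domains and decoys
#'
#' Each of the `n_queries` implant queries consists of background residues
#' (uniform, matching the engine's default null) with `implants_per_query`
#' noisy domain copies (consensus mutated at rate
#' `1 - implant_conservation`) implanted at recorded positions, separated by
#' background linkers; implanted models cycle through the library. Decoy
#' sequences contain no implant. The truth table records 1-based inclusive
#' coordinates.
#'
#' @param library a `domain_library` from [generate_mini_library()].
#' @param spec the `fixture_spec`.
#' @param fasta optional path: write the queries as FASTA.
#' @return list with `queries` (named character vector) and `truth`
#'   (data.frame: `query_id`, `model_id`, `seq_from`, `seq_to`).
#' @export
generate_query_set <- function(library, spec, fasta = NULL) {
  stopifnot(inherits(library, "domain_library"), inherits(spec, "fixture_spec"))
  cons <- attr(library, "true_consensus") %||%
    vapply(library$models, function(m) m$consensus, character(1))
  mids <- names(library$models)
  rand_bg <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
  linker <- function() sample(seq(spec$linker_range[1], spec$linker_range[2]), 1L)
  withr::with_seed(spec$rng_seed + 104729L, {
    queries <- character(0); truth <- list()
    k <- 0L
    for (q in seq_len(spec$n_queries)) {
      qid <- sprintf("query%03d", q)
      parts <- rand_bg(linker()); pos <- nchar(parts)
      for (d in seq_len(spec$implants_per_query)) {
        k <- k + 1L
        mid <- mids[((k - 1L) %% length(mids)) + 1L]
        implant <- .mutate_seq(cons[[mid]], 1 - spec$implant_conservation)
        truth[[k]] <- data.frame(query_id = qid, model_id = mid,
                                 seq_from = pos + 1L,
                                 seq_to = pos + nchar(implant),
                                 stringsAsFactors = FALSE)
        tail <- rand_bg(linker())
        parts <- paste0(parts, implant, tail)
        pos <- nchar(parts)
      }
      queries[qid] <- parts
    }
    n_decoys <- ceiling(spec$decoy_fraction * spec$n_queries)
    med_len <- if (length(queries)) round(median(nchar(queries))) else 100L
    for (d in seq_len(n_decoys)) {
      qid <- sprintf("decoy%03d", d)
      queries[qid] <- rand_bg(med_len)
    }
    truth <- do.call(rbind, truth)
  })
  if (!is.null(fasta)) write_fasta(queries, fasta)
  list(queries = queries, truth = truth)
}
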