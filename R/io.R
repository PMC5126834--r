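# Text I/O: FASTA query sets, tab-separated hit/annotation tables,
# calibration serialization, and an adapter for external domain-table output.
# All coordinates in written tables are 1-based inclusive.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a hit table
#'
#' Tab-separated with header `query_id, model_id, build, seq_from, seq_to,
#' hmm_from, hmm_to, bit_score, evalue`; coordinates 1-based inclusive.
#'
#' @param hits a hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_id", "model_id", "build", "seq_from", "seq_to",
            "hmm_from", "hmm_to", "bit_score", "evalue")
  write.table(hits[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a hit table written by [write_hit_table()]
#' @param path input path.
#' @return a hit table data.frame.
#' @export
read_hit_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Adapt an external per-domain table to the hit-table layout
#'
#' Ingests a table shaped like HMMER3's `--domtblout` (whitespace-separated,
#' `#` comments; columns: target name, accession, tlen, query name,
#' accession, qlen, full E-value/score/bias, domain #, of, c-E-value,
#' i-E-value, domain score, bias, hmm from/to, ali from/to, ...). This is an
#' I/O convenience only: scores from external engines are not comparable to
#' this package's bit scores and no downstream step requires them.
#'
#' @param path domain-table file.
#' @param build label recorded in the `build` column (default `"H3"`).
#' @return a hit table data.frame.
#' @export
read_domtblout <- function(path, build = "H3") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_hits())
  f <- strsplit(trimws(lines), "\\s+")
  rows <- lapply(f, function(x) data.frame(
    query_id = x[4], model_id = x[1], build = build,
    seq_from = as.integer(x[18]), seq_to = as.integer(x[19]),
    hmm_from = as.integer(x[16]), hmm_to = as.integer(x[17]),
    bit_score = as.numeric(x[14]), evalue = as.numeric(x[13]),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write an annotation table
#'
#' Tab-separated with header `query_id, model_id, hmm_from, hmm_to,
#' seq_from, seq_to, evalue_h2, evalue_h3, fp, fpr`; FP sentinels are
#' rendered `FP<1` and `>grid`. When the table carries per-build FP columns
#' (`fp_h2`, `fp_h3`, as [run_pipeline()] produces), they are appended so the
#' written file feeds the concordance screen directly.
#'
#' @param annotations the `annotations` element of a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("query_id", "model_id", "hmm_from", "hmm_to",
            "seq_from", "seq_to", "evalue_h2", "evalue_h3", "fp", "fpr")
  extra <- intersect(c("fp_h2", "fp_h3"), names(annotations))
  out <- annotations[, c(cols, extra)]
  out$fp[out$fp == "beyond-grid"] <- ">grid"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a library calibration to a directory
#'
#' One tab-separated table per model and build (columns `kind` =
#' pos/neg/boundary, `id`, `evalue`) plus `summary.json` holding the grid
#' boundaries and metadata per model.
#'
#' @param calibration a `library_calibration`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(calibration, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(Z = calibration$Z, n_neg = calibration$n_neg,
               fp_grid = calibration$fp_grid, models = list())
  for (mid in names(calibration$models)) {
    cm <- calibration$models[[mid]]
    for (b in c("h2", "h3")) {
      t <- cm[[paste0("table_", b)]]
      df <- rbind(
        data.frame(kind = "pos", id = seq_along(t$pos_evalues),
                   evalue = t$pos_evalues),
        data.frame(kind = "neg", id = seq_along(t$neg_evalues),
                   evalue = t$neg_evalues),
        data.frame(kind = "boundary", id = t$fp_grid,
                   evalue = unname(t$fp_grid_boundaries)))
      write.table(df, file.path(dir, sprintf("%s_%s.tsv", mid, b)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ$models[[mid]] <- list(
      alpha = cm$table_h2$alpha,
      evd_glocal = unclass(calibration$library$models[[mid]]$evd_glocal),
      evd_local = unclass(calibration$library$models[[mid]]$evd_local),
      boundaries_h2 = as.list(cm$table_h2$fp_grid_boundaries),
      boundaries_h3 = as.list(cm$table_h3$fp_grid_boundaries))
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
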