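#' Read and write log2 expression matrices as TSV
#'
#' Expression tables are tab-separated with a `gene_id` first column and one
#' column per sample, values on the log2 scale. Annotation tables carry
#' `sample_id`, `class` and `species` columns.
#'
#' @param path File path.
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @return `read_expression_tsv()` returns a tibble; the writers return the
#'   path invisibly.
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expr_to_matrix(expr) # validation side-effect
  expr
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  expr_to_matrix(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) abort(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")))
  ann
}

#' @rdname read_expression_tsv
#' @param annot Annotation tibble (`sample_id`, `class`, optionally `species`).
#' @export
write_annotation_tsv <- function(annot, path) {
  readr::write_tsv(annot, path, progress = FALSE)
  invisible(path)
}

#' Read and write AIRR rearrangement tables
#'
#' The AIRR Rearrangement TSV schema is used with columns `sequence_id`,
#' `v_call`, `j_call`, `junction`, `duplicate_count` plus the extension
#' columns `sample_id`, `chain` and `isoform` used by the clonality stage.
#'
#' @param path File path.
#' @param airr AIRR tibble.
#' @return A tibble, or the path invisibly for the writer.
#' @export
read_airr_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_airr_tsv
#' @export
write_airr_tsv <- function(airr, path) {
  readr::write_tsv(airr, path, progress = FALSE)
  invisible(path)
}

#' Write FASTQ records
#'
#' Standard 4-line FASTQ records with Phred+33 quality strings.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("sequence and quality lengths differ")
  }
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$sequence, "+", reads$quality
  ))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) abort("malformed FASTQ: line count not a multiple of 4")
  idx <- seq(1, length(lines), by = 4)
  tibble::tibble(
    read_id = sub("^@", "", sub(" .*$", "", lines[idx])),
    sequence = toupper(lines[idx + 1]),
    quality = lines[idx + 3]
  )
}

#' Write ground-truth sidecar JSON
#'
#' @param truth A list of ground-truth fields from a simulator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
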