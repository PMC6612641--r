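## Plain-text readers/writers for the pipeline's external formats: FASTA via
## Biostrings, TSV matrices and tables, GMT-style query signatures, and a
## ranked compound library TSV.

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a numeric matrix as TSV with a leading id column
#' @param mat matrix with rownames.
#' @param path output file.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "transcript_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path TSV file.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path TSV file.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a bidirectional query signature as a two-line GMT file
#' @param query list with `up_genes` and `down_genes`.
#' @param path output file.
#' @export
write_query_gmt <- function(query, path) {
  lines <- c(paste(c("query_up", "direction=+1", query$up_genes), collapse = "\t"),
             paste(c("query_down", "direction=-1", query$down_genes), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-line GMT query signature
#' @param path GMT file with `query_up` and `query_down` rows.
#' @export
read_query_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                          vapply(lines, `[[`, character(1), 1L))
  if (!all(c("query_up", "query_down") %in% names(sets)))
    abort_input("GMT query must contain query_up and query_down sets")
  list(up_genes = sets$query_up, down_genes = sets$query_down)
}

#' Write a compound library as TSV (compound_id, class, ranked gene list)
#' @param library list with `rankings` and `truth`.
#' @param path output file.
#' @export
write_library_tsv <- function(library, path) {
  cls <- library$truth$compound_class[match(names(library$rankings),
                                            library$truth$compound_id)]
  lines <- vapply(seq_along(library$rankings), function(i) {
    paste(c(names(library$rankings)[i], cls[i],
            paste(library$rankings[[i]], collapse = ",")), collapse = "\t")
  }, character(1))
  writeLines(c("compound_id\tcompound_class\tranking", lines), path)
  invisible(path)
}

#' Read a compound library TSV written by [write_library_tsv()]
#' @param path TSV file.
#' @export
read_library_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rankings <- stats::setNames(strsplit(df$ranking, ",", fixed = TRUE),
                              df$compound_id)
  list(rankings = rankings,
       truth = data.frame(compound_id = df$compound_id,
                          class_label = NA_character_,
                          compound_class = df$compound_class,
                          stringsAsFactors = FALSE))
}
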