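#' Write a count matrix as TSV
#'
#' Genes x samples, header row of sample ids, first column `gene_id`.
#'
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_counts_tsv()].
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as MatrixMarket with id sidecars
#'
#' Writes `<stem>.mtx` plus `<stem>.genes.txt` and `<stem>.samples.txt`.
#'
#' @param counts Gene x sample matrix.
#' @param stem Path stem (no extension).
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".samples.txt"))
}

#' Read a MatrixMarket count matrix with id sidecars
#'
#' @param stem Path stem used by [write_counts_mtx()].
#' @return Integer matrix with dimnames.
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  storage.mode(m) <- "integer"
  m
}

#' Write an annotation as GMT
#'
#' One line per term: term_id, description, then tab-separated gene ids.
#'
#' @param annotation A [term_annotation()].
#' @param path Output path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$terms), function(id)
    paste(c(id, annotation$term_names[[id]], annotation$terms[[id]]),
          collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a GMT annotation
#'
#' @param path GMT file path.
#' @param universe Background gene ids; defaults to the union of all term
#'   genes.
#' @return A [term_annotation()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  nms <- vapply(parts, `[`, "", 2)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- ids
  if (is.null(universe)) universe <- unique(unlist(terms))
  term_annotation(terms, stats::setNames(nms, ids), universe)
}

#' Write a gene signature as JSON
#'
#' @param signature A `gene_signature`.
#' @param path Output path.
#' @export
write_signature_json <- function(signature, path) {
  jsonlite::write_json(unclass(signature), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Read a gene signature from JSON
#'
#' @param path Path written by [write_signature_json()].
#' @return A `gene_signature`.
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(class_name = x$class_name, genes = x$genes,
                 frequencies = x$frequencies, mean_rank = x$mean_rank,
                 provenance = x$provenance),
            class = "gene_signature")
}

#' Published participant characteristics reference table
#'
#' The printed group summary of the study cohort (means and SDs by
#' weight-loss group and timepoint), shipped as package data. Used as the
#' reference input for worked-value checks such as the difference in 2-month
#' group mean weight-loss percentages.
#'
#' @return Data frame: variable, group, timepoint, mean, sd.
#' @export
participant_reference_table <- function() {
  path <- system.file("extdata", "table1_participants.tsv", package = "wlsig",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
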