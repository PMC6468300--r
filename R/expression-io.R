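#' Read a gene-by-sample expression matrix from delimited text
#'
#' First column holds gene ids; remaining columns are samples. Values may be
#' any finite numbers (log2 expression) — use [read_count_matrix()] for
#' integer count experiments with annotation/design validation.
#'
#' @param path Path to the matrix file.
#' @param delim Field delimiter; tab by default.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, delim = "\t") {
  raw <- read_table_checked(path, delim)
  if (ncol(raw) < 2L) abort("Expression file needs a gene-id column plus >= 1 sample column.")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated gene ids: %s",
                  id_list(unique(ids[duplicated(ids)]))))
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("Expression values must all be finite numbers.")
  }
  rownames(m) <- ids
  m
}

#' Write a gene-by-sample expression matrix to delimited text
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param delim Field delimiter; tab by default.
#' @param id_column Name of the first (gene id) column.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path, delim = "\t",
                                    id_column = "gene_id") {
  df <- tibble::as_tibble(x, rownames = id_column)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}
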