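# Plain-text readers/writers for the matrix and table formats the pipeline
# exchanges between stages. All identifiers are opaque, case-sensitive
# strings.

#' Write a numeric matrix as a wide TSV
#'
#' First column holds the row axis (label given by `row_label`), the header
#' row the column axis.
#' @param m Numeric matrix with dimnames.
#' @param path Output file.
#' @param row_label Name of the first column.
#' @return `path`, invisibly.
#' @export
write_wide_matrix <- function(m, path, row_label = "cell_line") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide TSV into a numeric matrix
#'
#' @param path File whose first column is the row axis and whose header row
#'   is the other axis.
#' @return Numeric matrix with dimnames.
#' @export
read_wide_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a two-column edge table (TSV with header)
#'
#' Used for GRN (tf, target) and PIN (gene_a, gene_b, optional confidence)
#' inputs; the first two columns are taken as endpoints whatever their
#' header names.
#' @param path File path.
#' @return data.frame with columns `from`, `to` and any extra columns kept.
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("edge table needs at least two columns: ", path)
  out <- data.frame(from = as.character(tab[[1]]), to = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) > 2) out <- cbind(out, tab[, -(1:2), drop = FALSE])
  out
}

#' Read a literature relevance score table
#'
#' Two-column TSV (gene, score), e.g. an export from a biomedical entity
#' search engine ranking genes by relevance to a drug.
#' @param path File path.
#' @return Named numeric vector of scores.
#' @export
read_literature_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("literature score table needs two columns (gene, score)")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
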