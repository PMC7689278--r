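# Gene-centric (cell line x gene) matrix construction for the four omics
# layers: min-max scaling of continuous values, mutation binarization, and
# promoter-window averaging of methylation probes.

#' Min-max normalize a matrix to [0, 1]
#'
#' Each unit (a gene column with `axis = "per_gene"`, or the whole matrix
#' with `axis = "global"`) is mapped through (x - min) / (max - min).
#' Constant units map to all zeros. The transform is invariant to affine
#' rescaling a*x + b (a > 0) of the input. Missing entries are ignored when
#' computing the range and preserved in the output; a unit that is entirely
#' missing is an error.
#'
#' @param m Numeric matrix (cell lines x genes).
#' @param axis `"per_gene"` (default: each column scaled on its own range
#'   across cell lines) or `"global"`.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(m, axis = c("per_gene", "global")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (any(is.infinite(m))) stop("matrix must be finite")
  scale_unit <- function(x) {
    if (all(is.na(x))) stop("cannot min-max normalize an all-missing unit")
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (hi == lo) return(ifelse(is.na(x), NA_real_, 0))
    (x - lo) / (hi - lo)
  }
  if (axis == "global") {
    out <- matrix(scale_unit(as.vector(m)), nrow(m), ncol(m),
                  dimnames = dimnames(m))
  } else {
    out <- apply(m, 2, scale_unit)
    if (nrow(m) == 1L) out <- matrix(out, 1L, ncol(m), dimnames = dimnames(m))
    dimnames(out) <- dimnames(m)
  }
  out
}

#' Binarize a mutation call table into a cell line x gene 0/1 matrix
#'
#' Entry (c, g) is 1 iff at least one mutation record exists for that pair;
#' repeated records do not accumulate. Records for genes (or cell lines)
#' outside the requested axes are dropped with a logged warning.
#'
#' @param table data.frame with columns `cell_line` and `gene` (extra
#'   columns, e.g. the mutation description, are ignored).
#' @param cell_lines,genes Character vectors fixing the output axes.
#' @return 0/1 matrix of dimension length(cell_lines) x length(genes).
#' @export
binarize_mutation <- function(table, cell_lines, genes) {
  m <- matrix(0, length(cell_lines), length(genes),
              dimnames = list(cell_lines, genes))
  if (NROW(table) > 0) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (!all(c("cell_line", "gene") %in% names(table))) {
      names(table)[1:2] <- c("cell_line", "gene")
    }
    bad_gene <- setdiff(unique(table$gene), genes)
    if (length(bad_gene)) {
      log_msg("warn", "binarize_mutation: ignoring ", length(bad_gene),
              " gene(s) absent from the gene axis: ",
              paste(utils::head(bad_gene, 5), collapse = ", "))
    }
    bad_cell <- setdiff(unique(table$cell_line), cell_lines)
    if (length(bad_cell)) {
      log_msg("warn", "binarize_mutation: ignoring ", length(bad_cell),
              " unknown cell line(s)")
    }
    keep <- table$gene %in% genes & table$cell_line %in% cell_lines
    tab <- table[keep, , drop = FALSE]
    m[cbind(match(tab$cell_line, cell_lines), match(tab$gene, genes))] <- 1
  }
  m
}

#' Average promoter-window methylation probes per gene
#'
#' Probes are kept when their genomic offset relative to the transcription
#' start site (TSS at 0, negative = upstream) lies in
#' \[-window_upstream, 0\]; per (cell line, gene) the beta values of the
#' qualifying probes are averaged. Genes with no qualifying probe in a cell
#' line are imputed with the gene's mean across the cell lines where it was
#' observed, and with 0 when never observed anywhere.
#'
#' @param probes data.frame with columns `cell_line`, `gene`, `offset`
#'   (bases, signed) and `beta` (in \[0, 1\]); a `probe` id column may be
#'   present and is ignored.
#' @param cell_lines,genes Character vectors fixing the output axes.
#' @param window_upstream Window size in bases upstream of the TSS
#'   (default 1000).
#' @return Matrix of mean beta values in \[0, 1\].
#' @export
promoter_average_methylation <- function(probes, cell_lines, genes,
                                         window_upstream = 1000) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  need <- c("cell_line", "gene", "offset", "beta")
  if (!all(need %in% names(probes))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(probes$beta < 0 | probes$beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  keep <- probes$offset >= -window_upstream & probes$offset <= 0 &
    probes$gene %in% genes & probes$cell_line %in% cell_lines
  tab <- probes[keep, , drop = FALSE]
  m <- matrix(NA_real_, length(cell_lines), length(genes),
              dimnames = list(cell_lines, genes))
  if (nrow(tab) > 0) {
    agg <- stats::aggregate(beta ~ cell_line + gene, data = tab, FUN = mean)
    m[cbind(match(agg$cell_line, cell_lines), match(agg$gene, genes))] <- agg$beta
  }
  # impute: gene mean across observed cell lines, 0 if never observed
  gene_mean <- colMeans(m, na.rm = TRUE)
  gene_mean[is.nan(gene_mean)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- gene_mean[idx[, 2]]
  m
}

#' Assemble the four aligned gene-centric omics matrices
#'
#' Aligns expression, copy number, methylation and mutation to a shared
#' (cell line, gene) grid, then applies the per-omics normalizations:
#' min-max for expression and copy number (copy-number input is assumed
#' already gene-summarized), nothing further for methylation (already beta
#' values in \[0,1\]) and mutation (already 0/1). The returned matrices
#' share identical axis orderings by construction.
#'
#' @param expression,copy_number Cell line x gene numeric matrices.
#' @param methylation Either a cell line x gene matrix of beta values or a
#'   probe table for [promoter_average_methylation()].
#' @param mutation Either a 0/1 cell line x gene matrix or a mutation call
#'   table for [binarize_mutation()].
#' @param cell_lines,genes Optional axis orderings; default to the
#'   intersection of the matrix inputs' axes.
#' @param axis Min-max axis, see [minmax_normalize()].
#' @param window_upstream Promoter window passed through when `methylation`
#'   is a probe table.
#' @return Named list (expression, copy_number, methylation, mutation) of
#'   aligned matrices, with an attribute `normalization` recording the
#'   transform applied per omics.
#' @export
build_gene_centric <- function(expression, copy_number, methylation, mutation,
                               cell_lines = NULL, genes = NULL,
                               axis = "per_gene", window_upstream = 1000) {
  mats <- list(expression = expression, copy_number = copy_number)
  if (is.matrix(methylation)) mats$methylation <- methylation
  if (is.matrix(mutation)) mats$mutation <- mutation
  if (is.null(cell_lines)) {
    cell_lines <- Reduce(intersect, lapply(mats, rownames))
  }
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(mats, colnames))
  }
  if (length(cell_lines) == 0 || length(genes) == 0) {
    stop("no shared cell lines / genes across the omics inputs")
  }
  align <- function(m) m[cell_lines, genes, drop = FALSE]
  out <- list(
    expression = minmax_normalize(align(expression), axis = axis),
    copy_number = minmax_normalize(align(copy_number), axis = axis),
    methylation = if (is.matrix(methylation)) align(methylation) else
      promoter_average_methylation(methylation, cell_lines, genes,
                                   window_upstream = window_upstream),
    mutation = if (is.matrix(mutation)) align(mutation) else
      binarize_mutation(mutation, cell_lines, genes)
  )
  if (any(out$methylation < 0 | out$methylation > 1)) {
    stop("methylation betas must lie in [0, 1]")
  }
  if (!all(out$mutation %in% c(0, 1))) stop("mutation matrix must be 0/1")
  attr(out, "normalization") <- list(expression = paste0("minmax:", axis),
                                     copy_number = paste0("minmax:", axis),
                                     methylation = "promoter-window mean beta",
                                     mutation = "presence/absence")
  out
}
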