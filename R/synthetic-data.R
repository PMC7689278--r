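# Synthetic inputs with planted, recoverable ground truth.
#
# Two generators cover the pipeline's two data worlds: (i) control/treated
# time-series expression in which a differential-expression perturbation is
# planted at source genes and propagated along pathway edges with a fixed
# lag, and (ii) a low-rank multi-omics block (cell line x gene x 4 omics)
# whose cell-line factors drive a simulated IC50 phenotype.

#' Simulate control/treated time-series expression with planted propagation
#'
#' The control arm is a per-gene constant baseline plus Gaussian noise. The
#' treated arm additionally carries an additive perturbation of size
#' `amplitude` that switches on at the source genes at time 1 and propagates
#' along every directed pathway edge with a lag of `delay_per_edge` time
#' points, persisting once it arrives (expression values are understood on a
#' log-like scale, so the perturbation is a log-fold-change). The planted
#' truth — the set of propagating edges whose two endpoints both change
#' inside the observation window, with their lags — is recorded alongside.
#'
#' @param pathway A [pathway_graph()].
#' @param source_genes Character vector of perturbation sources (must be
#'   pathway nodes).
#' @param delay_per_edge Integer lag (time points) per edge, >= 0.
#' @param amplitude Additive perturbation size (log-scale units).
#' @param noise_sd Gaussian noise standard deviation applied to both arms.
#' @param n_time Number of time points, >= 2.
#' @param n_rep Replicates per arm per time point.
#' @param seed Integer seed; the fixture is deterministic given it.
#' @return A `timeseries_fixture`: list with `control` and `treated`
#'   (gene x time x replicate arrays), `truth_subpathway` (data.frame
#'   source/target), `truth_delays` (data.frame source/target/delay),
#'   `onset` (named per-gene first perturbed time, NA if never), and `seed`.
#' @examples
#' pw <- pathway_graph(data.frame(source = c("A", "B"), target = c("B", "C")))
#' fx <- generate_timeseries(pw, "A", delay_per_edge = 1, amplitude = 10,
#'                           noise_sd = 0, n_time = 3, n_rep = 2, seed = 1)
#' fx$treated["C", , 1] - fx$control["C", , 1]  # 0, 0, 10
#' @export
generate_timeseries <- function(pathway, source_genes, delay_per_edge = 1L,
                                amplitude = 2, noise_sd = 0.1,
                                n_time = 4L, n_rep = 3L, seed = 1L) {
  stopifnot(inherits(pathway, "pathway_graph"))
  if (delay_per_edge < 0) stop("delay_per_edge must be >= 0")
  if (n_time < 2) stop("n_time must be >= 2")
  unknown <- setdiff(source_genes, pathway$nodes)
  if (length(unknown)) {
    stop("unknown source gene(s): ", paste(unknown, collapse = ", "))
  }
  genes <- pathway$nodes
  g <- igraph::graph_from_data_frame(pathway$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = genes))
  dmat <- igraph::distances(g, v = source_genes, to = genes, mode = "out")
  hops <- apply(dmat, 2, min)[genes]
  onset <- ifelse(is.finite(hops), 1 + hops * delay_per_edge, NA_real_)
  names(onset) <- genes

  with_seed(seed, {
    baseline <- stats::rnorm(length(genes), mean = 8, sd = 1)
    dims <- c(length(genes), n_time, n_rep)
    dn <- list(genes, paste0("t", seq_len(n_time)), paste0("rep", seq_len(n_rep)))
    control <- array(baseline, dim = dims, dimnames = dn) +
      array(stats::rnorm(prod(dims), sd = noise_sd), dim = dims)
    perturb <- matrix(0, length(genes), n_time)
    for (i in seq_along(genes)) {
      if (!is.na(onset[i]) && onset[i] <= n_time) {
        perturb[i, seq(onset[i], n_time)] <- amplitude
      }
    }
    treated <- array(baseline, dim = dims, dimnames = dn) +
      array(perturb, dim = dims) +
      array(stats::rnorm(prod(dims), sd = noise_sd), dim = dims)

    e <- pathway$edges
    on_s <- onset[e$source]; on_t <- onset[e$target]
    planted <- !is.na(on_s) & !is.na(on_t) & on_s <= n_time & on_t <= n_time &
      (on_t - on_s) == delay_per_edge
    truth <- e[planted, c("source", "target"), drop = FALSE]
    rownames(truth) <- NULL
    structure(list(control = control, treated = treated,
                   truth_subpathway = truth,
                   truth_delays = cbind(truth,
                                        delay = rep(as.integer(delay_per_edge),
                                                    nrow(truth))),
                   onset = onset, seed = seed),
              class = "timeseries_fixture")
  })
}

#' @export
print.timeseries_fixture <- function(x, ...) {
  d <- dim(x$control)
  cat(sprintf("Time-series fixture: %d genes x %d time points x %d replicates; %d planted edges (seed %d)\n",
              d[1], d[2], d[3], nrow(x$truth_subpathway), x$seed))
  invisible(x)
}

#' Simulate a low-rank multi-omics block with an IC50 phenotype
#'
#' Draws rank-`rank` CP factors (cell-line and gene factors standard normal,
#' omics factors uniform on \[0.5, 1.5\]) and builds the cell x gene x 4
#' tensor as their CP product plus Gaussian noise. The expression and
#' copy-number slices keep the raw values; the methylation slice is squashed
#' into \[0,1\] with a logistic transform of its standardized values; the
#' mutation slice is binarized at its 80th percentile, giving a sparse
#' binary matrix as in real mutation calls. IC50 (on a log scale) is
#' `effect_size` times the sum of the causal cell-line factor columns plus
#' noise.
#'
#' @param n_cell,n_gene Dimensions; `n_cell >= rank`.
#' @param rank CP rank of the planted structure, >= 1.
#' @param causal_factors Integer indices in `1:rank` of the factors that
#'   drive IC50.
#' @param effect_size Coefficient of the causal factors in the IC50 model.
#' @param noise_sd Gaussian noise sd (tensor entries and IC50).
#' @param seed Integer seed.
#' @return A `multiomics_fixture`: list with `omics` (named list of four
#'   cell x gene matrices: expression, copy_number, methylation, mutation),
#'   `ic50` (named vector, log-scale), `ic50_scale = "log"`, `truth`
#'   (factor matrices `C_c`, `C_g`, `C_o` and `causal_factors`), and `seed`.
#' @export
generate_multiomics <- function(n_cell = 60L, n_gene = 200L, rank = 3L,
                                causal_factors = 1L, effect_size = 2,
                                noise_sd = 0.1, seed = 1L) {
  if (rank < 1) stop("rank must be >= 1")
  if (n_cell < rank) stop("n_cell must be >= rank")
  causal_factors <- as.integer(causal_factors)
  if (length(causal_factors) == 0 || any(causal_factors < 1 | causal_factors > rank)) {
    stop("causal_factors must be a non-empty subset of 1:", rank)
  }
  cells <- sprintf("CL%03d", seq_len(n_cell))
  genes <- sprintf("G%04d", seq_len(n_gene))
  omics <- c("expression", "copy_number", "methylation", "mutation")

  with_seed(seed, {
    C_c <- matrix(stats::rnorm(n_cell * rank), n_cell, rank,
                  dimnames = list(cells, NULL))
    C_g <- matrix(stats::rnorm(n_gene * rank), n_gene, rank,
                  dimnames = list(genes, NULL))
    C_o <- matrix(stats::runif(4 * rank, 0.5, 1.5), 4, rank,
                  dimnames = list(omics, NULL))
    slice <- function(k) {
      base <- tcrossprod(C_c %*% diag(C_o[k, ], nrow = rank), C_g)
      if (noise_sd > 0) base <- base + matrix(stats::rnorm(n_cell * n_gene,
                                                           sd = noise_sd),
                                              n_cell, n_gene)
      dimnames(base) <- list(cells, genes)
      base
    }
    expr <- slice(1)
    cn <- slice(2)
    meth_raw <- slice(3)
    s <- stats::sd(meth_raw)
    meth <- stats::plogis((meth_raw - mean(meth_raw)) / if (s > 0) s else 1)
    mut_raw <- slice(4)
    mut <- (mut_raw > stats::quantile(mut_raw, 0.8)) * 1
    ic50 <- effect_size * rowSums(C_c[, causal_factors, drop = FALSE]) +
      stats::rnorm(n_cell, sd = noise_sd)
    names(ic50) <- cells
    structure(list(omics = list(expression = expr, copy_number = cn,
                                methylation = meth, mutation = mut),
                   ic50 = ic50, ic50_scale = "log",
                   truth = list(C_c = C_c, C_g = C_g, C_o = C_o,
                                causal_factors = causal_factors),
                   seed = seed),
              class = "multiomics_fixture")
  })
}

#' @export
print.multiomics_fixture <- function(x, ...) {
  cat(sprintf("Multi-omics fixture: %d cell lines x %d genes x 4 omics, planted rank %d (causal factor(s) %s, seed %d)\n",
              nrow(x$omics$expression), ncol(x$omics$expression),
              ncol(x$truth$C_c), paste(x$truth$causal_factors, collapse = ","),
              x$seed))
  invisible(x)
}

#' Write a time-series fixture as a long TSV plus a JSON truth sidecar
#'
#' The long table has columns gene, time, replicate, arm, value — the same
#' format [read_timeseries_long()] consumes, so the generator doubles as
#' format documentation.
#'
#' @param fixture A `timeseries_fixture`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_timeseries_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long_one <- function(arr, arm) {
    d <- dim(arr); dn <- dimnames(arr)
    data.frame(gene = rep(dn[[1]], times = d[2] * d[3]),
               time = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
               arm = arm, value = as.vector(arr), stringsAsFactors = FALSE)
  }
  tab <- rbind(long_one(fixture$control, "control"),
               long_one(fixture$treated, "treated"))
  utils::write.table(tab, file.path(dir, "timeseries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(subpathway = fixture$truth_delays,
                onset = as.list(fixture$onset[!is.na(fixture$onset)]),
                seed = fixture$seed)
  jsonlite::write_json(truth, file.path(dir, "truth_timeseries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read control/treated time series from a long TSV
#'
#' @param path TSV with columns gene, time, replicate, arm, value.
#' @return List with `control` and `treated` gene x time x replicate arrays
#'   (either may be NULL if absent from the file).
#' @export
read_timeseries_long <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "time", "replicate", "arm", "value")
  if (!all(need %in% names(tab))) {
    stop("long time-series TSV must have columns: ", paste(need, collapse = ", "))
  }
  to_array <- function(sub) {
    genes <- unique(sub$gene)
    times <- sort(unique(sub$time))
    reps <- sort(unique(sub$replicate))
    arr <- array(NA_real_, dim = c(length(genes), length(times), length(reps)),
                 dimnames = list(genes, paste0("t", times), paste0("rep", reps)))
    arr[cbind(match(sub$gene, genes), match(sub$time, times),
              match(sub$replicate, reps))] <- sub$value
    arr
  }
  out <- list(control = NULL, treated = NULL)
  for (arm in intersect(c("control", "treated"), unique(tab$arm))) {
    out[[arm]] <- to_array(tab[tab$arm == arm, , drop = FALSE])
  }
  out
}

#' Write a multi-omics fixture as four wide TSVs, an IC50 TSV and truth JSON
#'
#' @param fixture A `multiomics_fixture`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_multiomics_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(fixture$omics)) {
    write_wide_matrix(fixture$omics[[k]], file.path(dir, paste0(k, ".tsv")),
                      row_label = "cell_line")
  }
  utils::write.table(data.frame(cell_line = names(fixture$ic50),
                                ic50 = unname(fixture$ic50)),
                     file.path(dir, "ic50.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(C_c = fixture$truth$C_c, C_g = fixture$truth$C_g,
                C_o = fixture$truth$C_o,
                causal_factors = fixture$truth$causal_factors,
                ic50_scale = fixture$ic50_scale, seed = fixture$seed)
  jsonlite::write_json(truth, file.path(dir, "truth_multiomics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the four omics matrices and the IC50 vector from a directory
#'
#' Expects expression.tsv, copy_number.tsv, methylation.tsv, mutation.tsv
#' (wide, first column `cell_line`) and ic50.tsv (cell_line, ic50).
#'
#' @param dir Directory written by [write_multiomics_fixture()] or of the
#'   same layout.
#' @return List with `omics` (named list of four matrices) and `ic50`.
#' @export
read_omics_matrices <- function(dir) {
  kinds <- c("expression", "copy_number", "methylation", "mutation")
  omics <- lapply(kinds, function(k) {
    read_wide_matrix(file.path(dir, paste0(k, ".tsv")))
  })
  names(omics) <- kinds
  ic <- utils::read.delim(file.path(dir, "ic50.tsv"), stringsAsFactors = FALSE)
  ic50 <- stats::setNames(ic$ic50, ic$cell_line)
  list(omics = omics, ic50 = ic50)
}
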