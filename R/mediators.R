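# IC50-associated feature selection and potential-mediator gene ranking.
#
# The cell-line embedding (CP cell factors C_c or autoencoder codes z) is
# regressed on IC50 with an L1 penalty; features with non-zero coefficients
# are the IC50-associated features. Genes are mapped back to features
# either through the CP gene factor matrix (row-wise argmax) or by
# propagating one-hot latent activations through the trained decoder, and
# the resulting omics scores are optionally blended with a literature
# relevance score by a weighted rank-normalized sum.

#' L1-regularized selection of IC50-associated embedding features
#'
#' Features are standardized internally (zero mean, unit variance;
#' constant columns become zeros) and an L1-penalized least-squares model
#' of IC50 on the features is fit, with the penalty chosen by
#' cross-validation (leave-one-out when the number of cell lines is below
#' twice `cv_folds`). When `lambda_grid` has a single value, the model is
#' fit directly at that penalty without cross-validation. Coefficients are
#' reported on the standardized scale.
#'
#' @param features Cell line x F numeric matrix (C_c or z).
#' @param ic50 Per-cell-line response vector; transform (e.g. log) before
#'   calling if desired and record it via `target_transform`.
#' @param lambda_grid Optional penalty grid (decreasing); default lets the
#'   fitting path choose.
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @param target_transform Free-text record of any transform already
#'   applied to `ic50` (e.g. "log", "none").
#' @return Object of class `feature_selection`: list with `coef` (named,
#'   standardized scale, intercept dropped), `selected` (integer indices of
#'   non-zero coefficients), `lambda`, `target`, `target_transform`.
#' @export
lasso_select <- function(features, ic50, lambda_grid = NULL, cv_folds = 10L,
                         seed = 1L, target_transform = "none") {
  X <- as.matrix(features)
  y <- as.numeric(ic50)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 cell lines")
  if (length(y) != n) stop("ic50 length must match the number of cell lines")
  if (stats::sd(y) == 0) stop("ic50 is constant; nothing to select")
  # standardize features; constant columns -> 0 (never selected)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu)
  keep <- sdv > 0
  Xs[, keep] <- sweep(Xs[, keep, drop = FALSE], 2, sdv[keep], "/")
  Xs[, !keep] <- 0
  if (is.null(colnames(Xs))) colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
  # the elastic-net fitter needs >= 2 columns; pad a zero dummy for F = 1
  n_feat <- ncol(Xs)
  if (n_feat == 1L) Xs <- cbind(Xs, .dummy = 0)

  with_seed(seed, {
    if (!is.null(lambda_grid) && length(lambda_grid) == 1) {
      fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = lambda_grid,
                            standardize = FALSE)
      lambda_use <- lambda_grid
      beta <- as.numeric(stats::coef(fit, s = lambda_use))[-1]
    } else {
      nfolds <- if (n < 2 * cv_folds) n else cv_folds
      foldid <- sample(rep_len(seq_len(nfolds), n))
      cv <- glmnet::cv.glmnet(Xs, y, alpha = 1, lambda = lambda_grid,
                              foldid = foldid, standardize = FALSE,
                              grouped = n >= 3 * nfolds)
      lambda_use <- cv$lambda.min
      beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    }
    beta <- beta[seq_len(n_feat)]
    names(beta) <- colnames(Xs)[seq_len(n_feat)]
    structure(list(coef = beta, selected = which(beta != 0),
                   lambda = lambda_use, target = y,
                   target_transform = target_transform),
              class = "feature_selection")
  })
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("L1 feature selection: %d/%d features non-zero at lambda %.4g (target transform: %s)\n",
              length(x$selected), length(x$coef), x$lambda,
              x$target_transform))
  invisible(x)
}

#' Map selected CP features back to genes (tensor route)
#'
#' For each gene the feature most related to it is the row-wise argmax of
#' the absolute gene factor loadings |C_g(g, f)| (relatedness magnitude;
#' ties broken toward the lowest feature index). The gene is emitted iff
#' that feature was selected, with omics score the signed product
#' C_g(g, f*) * coef(f*); since CP components carry an arbitrary
#' orientation, genes are ranked by the score's magnitude, the sign being
#' the direction of association under the decomposition's fixed sign
#' convention.
#'
#' @param C_g Gene x R factor matrix (columns aligned with the selection's
#'   feature indices).
#' @param selection A `feature_selection` fitted on the matching cell-line
#'   factors.
#' @return data.frame (gene, omics_score, best_feature, route) sorted by
#'   decreasing omics score.
#' @export
tensor_gene_scores <- function(C_g, selection) {
  stopifnot(inherits(selection, "feature_selection"))
  if (ncol(C_g) != length(selection$coef)) {
    stop("C_g columns must align with the selection's features")
  }
  f_star <- apply(abs(C_g), 1, which.max)   # ties -> lowest index
  keep <- f_star %in% selection$selected
  genes <- rownames(C_g) %||% as.character(seq_len(nrow(C_g)))
  out <- data.frame(gene = genes[keep],
                    omics_score = C_g[cbind(which(keep), f_star[keep])] *
                      selection$coef[f_star[keep]],
                    best_feature = f_star[keep],
                    route = "tensor", stringsAsFactors = FALSE)
  out <- out[order(-abs(out$omics_score), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map selected autoencoder features back to genes (decoder activation)
#'
#' Each selected latent feature f is activated as a one-hot latent vector
#' and propagated through the trained decoder to the omics data layer; the
#' per-gene activation a_g(f) sums the absolute outputs over the gene's
#' four omics slots. The omics score aggregates over the selected features
#' weighted by coefficient magnitude:
#' score(g) = sum_f a_g(f) * |coef(f)|. The top `top_fraction` of genes by
#' score is emitted.
#'
#' @param model A trained `omics_autoencoder`.
#' @param selection A `feature_selection` fitted on the model's z codes.
#' @param top_fraction Fraction of genes to emit (default 0.05).
#' @return data.frame (gene, omics_score, best_feature, route) sorted by
#'   decreasing score; empty when nothing was selected.
#' @export
autoencoder_gene_scores <- function(model, selection, top_fraction = 0.05) {
  stopifnot(inherits(model, "omics_autoencoder"),
            inherits(selection, "feature_selection"))
  if (is.null(model$params)) stop("model has no trained decoder")
  latent <- model$arch$integration[2]
  if (length(selection$coef) != latent) {
    stop("selection features must align with the bottleneck dimension")
  }
  n_gene <- model$arch$n_genes
  genes <- model$genes %||% paste0("g", seq_len(n_gene))
  empty <- data.frame(gene = character(), omics_score = numeric(),
                      best_feature = integer(), route = character(),
                      stringsAsFactors = FALSE)
  if (length(selection$selected) == 0) return(empty)
  contrib <- matrix(0, n_gene, length(selection$selected))
  for (j in seq_along(selection$selected)) {
    f <- selection$selected[j]
    one_hot <- matrix(0, 1, latent)
    one_hot[1, f] <- 1
    out <- abs(decode_latent(model, one_hot))
    a_g <- rowSums(matrix(out, n_gene, 4))   # gene-wise sum over omics slots
    contrib[, j] <- a_g * abs(selection$coef[f])
  }
  score <- rowSums(contrib)
  best <- selection$selected[apply(contrib, 1, which.max)]
  n_keep <- max(1L, ceiling(top_fraction * n_gene))
  ord <- order(-score, genes)[seq_len(n_keep)]
  out <- data.frame(gene = genes[ord], omics_score = score[ord],
                    best_feature = best[ord], route = "autoencoder",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Combine omics scores with a literature relevance score
#'
#' Both score sets are rank-normalized to \[0, 1\] (so the combination is
#' invariant to strictly monotone transforms of either raw score) and
#' blended as w * omics + (1 - w) * literature. The omics component ranks
#' score magnitudes (tensor-route scores are signed with an arbitrary
#' global orientation; autoencoder-route scores are already non-negative). Genes absent from the
#' literature table get a literature component of 0; when no literature
#' table is given the combined ranking equals the omics ranking.
#'
#' @param mediators data.frame from [tensor_gene_scores()] or
#'   [autoencoder_gene_scores()].
#' @param literature Named numeric vector of per-gene relevance scores
#'   (e.g. from [read_literature_scores()]), or NULL.
#' @param w Weight of the omics score in \[0, 1\] (default 0.5).
#' @return The mediator data.frame with columns `literature_score` (NA when
#'   absent), `omics_norm`, `literature_norm` and `combined_score`, sorted
#'   by decreasing combined score.
#' @export
combine_scores <- function(mediators, literature = NULL, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  out <- mediators
  n <- nrow(out)
  out$omics_norm <- rank_normalize(abs(out$omics_score))
  if (is.null(literature)) {
    out$literature_score <- NA_real_
    out$literature_norm <- 0
    out$combined_score <- out$omics_norm
  } else {
    lit <- literature[match(out$gene, names(literature))]
    out$literature_score <- as.numeric(lit)
    has <- !is.na(out$literature_score)
    out$literature_norm <- 0
    out$literature_norm[has] <- rank_normalize(out$literature_score[has])
    out$combined_score <- w * out$omics_norm + (1 - w) * out$literature_norm
  }
  out <- out[order(-out$combined_score, -out$omics_norm, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
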