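# CP/PARAFAC decomposition of the cell line x gene x omics tensor.
#
# The three-way array x_ijk is modelled as sum_f c_if g_jf o_kf + e_ijk
# with R components; the cell-line factor matrix C_c is the embedding used
# downstream for IC50 regression, the gene factor matrix C_g for mapping
# selected features back to genes. Fitting is alternating least squares
# with seeded random initialization; no non-negativity constraint is
# imposed.

#' Stack the four gene-centric matrices into an omics tensor
#'
#' Always stacks in the fixed order expression, copy_number, methylation,
#' mutation regardless of input list order, and requires identical cell and
#' gene axes across the four.
#'
#' @param matrices Named list of the four cell line x gene matrices.
#' @return 3-way array (cell line x gene x omics) with dimnames.
#' @export
assemble_tensor <- function(matrices) {
  kinds <- c("expression", "copy_number", "methylation", "mutation")
  if (!all(kinds %in% names(matrices))) {
    stop("need the four omics matrices: ", paste(kinds, collapse = ", "))
  }
  ref <- matrices[[kinds[1]]]
  for (k in kinds[-1]) {
    m <- matrices[[k]]
    if (!identical(dim(m), dim(ref)) ||
        !identical(dimnames(m), dimnames(ref))) {
      stop("omics matrix '", k, "' does not share the cell/gene axes")
    }
  }
  arr <- array(NA_real_, dim = c(nrow(ref), ncol(ref), 4L),
               dimnames = list(rownames(ref), colnames(ref), kinds))
  for (i in seq_along(kinds)) arr[, , i] <- matrices[[kinds[i]]]
  arr
}

#' Column-wise Khatri-Rao product
#' @noRd
khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' CP/PARAFAC decomposition by alternating least squares
#'
#' Fits x_ijk ~ sum_f c_if g_jf o_kf. After convergence the gene and omics
#' factor columns are rescaled to unit norm with all scale absorbed into
#' the cell-line factors, so that row-wise comparisons across the columns
#' of `C_g` (the argmax used in mediator selection) are on a common scale.
#'
#' @param tensor Cell line x gene x omics array from [assemble_tensor()].
#' @param R Number of components (rank), >= 1.
#' @param seed Integer seed for the random initialization.
#' @param tol Stop when the relative reconstruction error improves by less
#'   than this between sweeps (default 1e-8).
#' @param max_iter Maximum ALS sweeps (default 500; non-convergence yields
#'   a warning and the current factors).
#' @param n_init Number of seeded random restarts; the fit with the lowest
#'   reconstruction error is kept (ALS can land in local optima).
#' @return Object of class `cp_factors`: list with `C_c` (cell x R), `C_g`
#'   (gene x R), `C_o` (omics x R), `R`, `rel_error`
#'   (||X - Xhat||_F / ||X||_F, 0 for a zero tensor), `iterations`,
#'   `converged`.
#' @export
cp_decompose <- function(tensor, R, seed = 1L, tol = 1e-8, max_iter = 500L,
                         n_init = 3L) {
  if (any(!is.finite(tensor))) stop("tensor has non-finite entries")
  if (R < 1) stop("R must be >= 1")
  dims <- dim(tensor)
  I <- dims[1]; J <- dims[2]; K <- dims[3]
  X1 <- matrix(tensor, I, J * K)                       # mode-1 unfolding
  X2 <- matrix(aperm(tensor, c(2, 1, 3)), J, I * K)    # mode-2
  X3 <- matrix(aperm(tensor, c(3, 1, 2)), K, I * J)    # mode-3
  normX <- sqrt(sum(tensor^2))
  if (normX == 0) {
    zero <- function(n) matrix(0, n, R)
    return(structure(list(C_c = zero(I), C_g = zero(J), C_o = zero(K),
                          R = R, rel_error = 0, iterations = 0L,
                          converged = TRUE),
                     class = "cp_factors"))
  }
  solve_ls <- function(Xn, U1, U2) {
    # rows of factor = Xn %*% khatri_rao(U1, U2) %*% pinv((U1'U1)*(U2'U2))
    G <- crossprod(U1) * crossprod(U2)
    Xn %*% khatri_rao(U1, U2) %*% chol2inv(chol(G + diag(1e-12, R)))
  }
  run_als <- function(init_seed) {
    with_seed(init_seed, {
      A <- matrix(stats::rnorm(I * R), I, R)
      B <- matrix(stats::rnorm(J * R), J, R)
      C <- matrix(stats::rnorm(K * R), K, R)
      prev_err <- Inf; err <- Inf; converged <- FALSE; it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        A <- solve_ls(X1, C, B)
        B <- solve_ls(X2, C, A)
        C <- solve_ls(X3, B, A)
        Xhat1 <- A %*% t(khatri_rao(C, B))
        err <- sqrt(sum((X1 - Xhat1)^2)) / normX
        if (is.finite(prev_err) && abs(prev_err - err) < tol) {
          converged <- TRUE
          break
        }
        prev_err <- err
      }
      list(A = A, B = B, C = C, err = err, it = it, converged = converged)
    })
  }
  # multi-start: ALS is prone to local optima; keep the best of n_init
  # seeded random initializations
  best <- NULL
  for (i in seq_len(max(1L, n_init))) {
    fit <- run_als(derive_seed(seed, i - 1L))
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  if (!best$converged) {
    log_msg("warn", "cp_decompose: ALS did not converge in ", max_iter,
            " sweeps (rel error ", format(best$err, digits = 4), ")")
    warning("CP-ALS did not converge in ", max_iter, " sweeps")
  }
  A <- best$A; B <- best$B; C <- best$C
  # absorb all scale into the cell-line mode and fix a deterministic sign:
  # the largest-magnitude entry of each gene factor column is made positive
  # (CP components are otherwise sign-indeterminate)
  for (r in seq_len(R)) {
    nb <- sqrt(sum(B[, r]^2)); nc <- sqrt(sum(C[, r]^2))
    if (nb > 0) B[, r] <- B[, r] / nb
    if (nc > 0) C[, r] <- C[, r] / nc
    A[, r] <- A[, r] * nb * nc
    if (any(B[, r] != 0)) {
      s <- sign(B[which.max(abs(B[, r])), r])
      B[, r] <- s * B[, r]
      A[, r] <- s * A[, r]
    }
  }
  rownames(A) <- dimnames(tensor)[[1]]
  rownames(B) <- dimnames(tensor)[[2]]
  rownames(C) <- dimnames(tensor)[[3]]
  structure(list(C_c = A, C_g = B, C_o = C, R = R, rel_error = best$err,
                 iterations = best$it, converged = best$converged),
            class = "cp_factors")
}

#' Reconstruct the tensor from CP factors
#' @param factors A `cp_factors` object.
#' @return 3-way array of the same shape as the decomposed tensor.
#' @export
cp_reconstruct <- function(factors) {
  I <- nrow(factors$C_c); J <- nrow(factors$C_g); K <- nrow(factors$C_o)
  X1 <- factors$C_c %*% t(khatri_rao(factors$C_o, factors$C_g))
  array(X1, dim = c(I, J, K),
        dimnames = list(rownames(factors$C_c), rownames(factors$C_g),
                        rownames(factors$C_o)))
}

#' @export
print.cp_factors <- function(x, ...) {
  cat(sprintf("CP factors: rank %d over %d cell lines x %d genes x %d omics; rel. reconstruction error %.4g (%d sweeps%s)\n",
              x$R, nrow(x$C_c), nrow(x$C_g), nrow(x$C_o), x$rel_error,
              x$iterations, if (x$converged) "" else ", not converged"))
  invisible(x)
}
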