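# Late-integration autoencoder for gene-centric multi-omics embedding.
#
# Each cell line is the concatenation x = (x_1, ..., x_4n) of its four
# omics vectors (n genes each). Four omics-specific encoder stacks map each
# block through two ReLU layers; the concatenated codes h = (h_1..h_4) pass
# through a two-layer integration encoder to the bottleneck embedding z;
# the decoder mirrors the encoder (integration decoder, then four
# omics-specific decoders). Hidden layers are ReLU; the bottleneck and the
# final reconstruction layer are linear (a ReLU bottleneck can die
# irrecoverably under gradient descent, and reconstructions must be
# sign-unconstrained). Training minimizes mean squared
# reconstruction error plus a lambda-weighted penalty on the weights
# (squared-norm by default, absolute-value optionally), with full-batch
# Adam. Everything is seeded and deterministic.

.relu <- function(z) pmax(z, 0)

.new_dense <- function(n_in, n_out, act) {
  # He-style scaled Gaussian init; ReLU biases slightly positive so units
  # start alive
  list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
       b = rep(if (act == "relu") 0.01 else 0, n_out), act = act)
}

.stack_forward <- function(stack, A) {
  cache <- vector("list", length(stack))
  for (l in seq_along(stack)) {
    lay <- stack[[l]]
    Z <- A %*% t(lay$W) + matrix(lay$b, nrow(A), length(lay$b), byrow = TRUE)
    A_out <- if (lay$act == "relu") .relu(Z) else Z
    cache[[l]] <- list(A_in = A, Z = Z)
    A <- A_out
  }
  list(out = A, cache = cache)
}

.stack_backward <- function(stack, cache, dOut) {
  grads <- vector("list", length(stack))
  dA <- dOut
  for (l in rev(seq_along(stack))) {
    lay <- stack[[l]]
    dZ <- if (lay$act == "relu") dA * (cache[[l]]$Z > 0) else dA
    grads[[l]] <- list(W = crossprod(dZ, cache[[l]]$A_in), b = colSums(dZ))
    dA <- dZ %*% lay$W
  }
  list(grads = grads, dIn = dA)
}

.concat_input <- function(matrices) {
  kinds <- c("expression", "copy_number", "methylation", "mutation")
  if (is.matrix(matrices)) return(matrices)
  if (!all(kinds %in% names(matrices))) {
    stop("need the four omics matrices: ", paste(kinds, collapse = ", "))
  }
  do.call(cbind, matrices[kinds])
}

#' Train the late-integration multi-omics autoencoder
#'
#' @param matrices Named list of the four cell line x gene matrices
#'   (expression, copy_number, methylation, mutation), identical axes.
#' @param arch List with `specific` (two hidden sizes of each omics-specific
#'   stack) and `integration` (two sizes of the integration stack, the
#'   second being the bottleneck dimension of z). The defaults are the full
#'   production sizes; scale them down for small gene counts.
#' @param lambda Weight-penalty coefficient (>= 0).
#' @param epochs Full-batch Adam steps.
#' @param lr Learning rate (default 1e-3).
#' @param seed Integer seed (weight initialization).
#' @param penalty `"l2"` (squared-norm, default) or `"l1"` (absolute-value)
#'   weight penalty; biases are never penalized.
#' @param early_stop_tol If positive, stop once the loss improves by less
#'   than this for `patience` consecutive epochs.
#' @param patience Consecutive low-improvement epochs tolerated before
#'   early stop (default 20; irrelevant when `early_stop_tol = 0`).
#' @return Object of class `omics_autoencoder` with elements `z` (cell x
#'   latent embedding), `params` (all layer weights), `arch`,
#'   `loss_history`, `final_loss`, `lambda`, `penalty`, `epochs_run`,
#'   `seed`, `cells`, `genes`.
#' @export
train_autoencoder <- function(matrices,
                              arch = list(specific = c(2048L, 1024L),
                                          integration = c(1024L, 256L)),
                              lambda = 0, epochs = 500L, lr = 1e-3,
                              seed = 1L, penalty = c("l2", "l1"),
                              early_stop_tol = 0, patience = 20L) {
  penalty <- match.arg(penalty)
  X <- .concat_input(matrices)
  n_cell <- nrow(X)
  n_gene <- ncol(X) / 4L
  if (n_gene != floor(n_gene)) stop("input width must be 4 x n_genes")
  s <- arch$specific; g <- arch$integration
  if (length(s) != 2 || length(g) != 2) {
    stop("arch$specific and arch$integration must each give two layer sizes")
  }

  with_seed(seed, {
    params <- list(
      enc_spec = lapply(1:4, function(i) list(.new_dense(n_gene, s[1], "relu"),
                                              .new_dense(s[1], s[2], "relu"))),
      enc_int = list(.new_dense(4 * s[2], g[1], "relu"),
                     .new_dense(g[1], g[2], "linear")),
      dec_int = list(.new_dense(g[2], g[1], "relu"),
                     .new_dense(g[1], 4 * s[2], "relu")),
      dec_spec = lapply(1:4, function(i) list(.new_dense(s[2], s[1], "relu"),
                                              .new_dense(s[1], n_gene, "linear")))
    )
    # flat views for the optimizer
    flat_paths <- list()
    for (i in 1:4) for (l in 1:2) flat_paths[[length(flat_paths) + 1]] <- c("enc_spec", i, l)
    for (l in 1:2) flat_paths[[length(flat_paths) + 1]] <- c("enc_int", l)
    for (l in 1:2) flat_paths[[length(flat_paths) + 1]] <- c("dec_int", l)
    for (i in 1:4) for (l in 1:2) flat_paths[[length(flat_paths) + 1]] <- c("dec_spec", i, l)
    get_layer <- function(p, path) {
      if (length(path) == 3) p[[path[1]]][[as.integer(path[2])]][[as.integer(path[3])]]
      else p[[path[1]]][[as.integer(path[2])]]
    }
    set_layer <- function(p, path, lay) {
      if (length(path) == 3) p[[path[1]]][[as.integer(path[2])]][[as.integer(path[3])]] <- lay
      else p[[path[1]]][[as.integer(path[2])]] <- lay
      p
    }
    adam <- lapply(flat_paths, function(path) {
      lay <- get_layer(params, path)
      list(mW = lay$W * 0, vW = lay$W * 0, mb = lay$b * 0, vb = lay$b * 0)
    })
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

    block <- function(M, i) M[, ((i - 1) * n_gene + 1):(i * n_gene), drop = FALSE]
    blockH <- function(M, i) M[, ((i - 1) * s[2] + 1):(i * s[2]), drop = FALSE]

    forward <- function(p, X) {
      cs <- lapply(1:4, function(i) .stack_forward(p$enc_spec[[i]], block(X, i)))
      H <- do.call(cbind, lapply(cs, `[[`, "out"))
      ce <- .stack_forward(p$enc_int, H)
      cdi <- .stack_forward(p$dec_int, ce$out)
      cds <- lapply(1:4, function(i) .stack_forward(p$dec_spec[[i]],
                                                    blockH(cdi$out, i)))
      Xp <- do.call(cbind, lapply(cds, `[[`, "out"))
      list(z = ce$out, Xp = Xp, cs = cs, ce = ce, cdi = cdi, cds = cds)
    }

    loss_history <- numeric(0)
    low_improve <- 0L
    fw <- NULL
    for (epoch in seq_len(epochs)) {
      fw <- forward(params, X)
      mse <- mean((X - fw$Xp)^2)
      pen <- 0
      for (path in flat_paths) {
        W <- get_layer(params, path)$W
        pen <- pen + if (penalty == "l2") sum(W^2) else sum(abs(W))
      }
      loss <- mse + lambda * pen
      if (!is.finite(loss)) {
        stop("autoencoder training diverged (non-finite loss at epoch ",
             epoch, "; last finite loss ",
             if (length(loss_history)) format(utils::tail(loss_history, 1))
             else "none", "; try a smaller lr)")
      }
      loss_history <- c(loss_history, loss)

      # backward
      dXp <- 2 * (fw$Xp - X) / length(X)
      grads <- list(enc_spec = vector("list", 4), enc_int = NULL,
                    dec_int = NULL, dec_spec = vector("list", 4))
      dH_dec <- matrix(0, n_cell, 4 * s[2])
      for (i in 1:4) {
        bk <- .stack_backward(params$dec_spec[[i]], fw$cds[[i]]$cache,
                              block(dXp, i))
        grads$dec_spec[[i]] <- bk$grads
        dH_dec[, ((i - 1) * s[2] + 1):(i * s[2])] <- bk$dIn
      }
      bk <- .stack_backward(params$dec_int, fw$cdi$cache, dH_dec)
      grads$dec_int <- bk$grads
      dz <- bk$dIn
      bk <- .stack_backward(params$enc_int, fw$ce$cache, dz)
      grads$enc_int <- bk$grads
      dH_enc <- bk$dIn
      for (i in 1:4) {
        bk <- .stack_backward(params$enc_spec[[i]], fw$cs[[i]]$cache,
                              blockH(dH_enc, i))
        grads$enc_spec[[i]] <- bk$grads
      }

      # Adam update with weight penalty gradient
      corr1 <- 1 - b1^epoch; corr2 <- 1 - b2^epoch
      for (j in seq_along(flat_paths)) {
        path <- flat_paths[[j]]
        lay <- get_layer(params, path)
        gr <- get_layer(grads, path)
        gW <- gr$W + if (penalty == "l2") 2 * lambda * lay$W else
          lambda * sign(lay$W)
        st <- adam[[j]]
        st$mW <- b1 * st$mW + (1 - b1) * gW
        st$vW <- b2 * st$vW + (1 - b2) * gW^2
        st$mb <- b1 * st$mb + (1 - b1) * gr$b
        st$vb <- b2 * st$vb + (1 - b2) * gr$b^2
        lay$W <- lay$W - lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
        lay$b <- lay$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
        adam[[j]] <- st
        params <- set_layer(params, path, lay)
      }

      if (early_stop_tol > 0 && epoch > 1) {
        improve <- loss_history[epoch - 1] - loss
        low_improve <- if (improve < early_stop_tol) low_improve + 1L else 0L
        if (low_improve >= patience) break
      }
    }
    fw <- forward(params, X)
    final_mse <- mean((X - fw$Xp)^2)
    pen <- 0
    for (path in flat_paths) {
      W <- get_layer(params, path)$W
      pen <- pen + if (penalty == "l2") sum(W^2) else sum(abs(W))
    }
    z <- fw$z
    rownames(z) <- rownames(X)
    colnames(z) <- paste0("z", seq_len(ncol(z)))
    structure(list(z = z, params = params,
                   arch = list(n_genes = n_gene, specific = s, integration = g),
                   loss_history = loss_history,
                   final_loss = final_mse + lambda * pen,
                   final_mse = final_mse, lambda = lambda, penalty = penalty,
                   epochs_run = length(loss_history), lr = lr, seed = seed,
                   cells = rownames(X),
                   genes = colnames(if (is.matrix(matrices)) NULL else
                     matrices$expression)),
              class = "omics_autoencoder")
  })
}

#' @export
print.omics_autoencoder <- function(x, ...) {
  cat(sprintf("Late-integration autoencoder: %d genes x 4 omics -> z dim %d; specific %s, integration %s\n",
              x$arch$n_genes, x$arch$integration[2],
              paste(x$arch$specific, collapse = "/"),
              paste(x$arch$integration, collapse = "/")))
  cat(sprintf("  trained %d epochs (lambda %g, %s penalty), final loss %.6g (MSE %.6g)\n",
              x$epochs_run, x$lambda, x$penalty, x$final_loss, x$final_mse))
  invisible(x)
}

#' Encode cell lines with a trained autoencoder
#'
#' Forward pass through the encoder only; encoding the training set
#' reproduces the stored `z` exactly.
#'
#' @param model An `omics_autoencoder`.
#' @param matrices Named list of the four omics matrices, or an already
#'   concatenated cell x 4n matrix (gene axis must match training).
#' @return Cell x latent embedding matrix.
#' @export
encode <- function(model, matrices) {
  X <- .concat_input(matrices)
  n_gene <- model$arch$n_genes
  if (ncol(X) != 4 * n_gene) {
    stop("input width ", ncol(X), " does not match the trained gene axis (",
         4 * n_gene, ")")
  }
  block <- function(M, i) M[, ((i - 1) * n_gene + 1):(i * n_gene), drop = FALSE]
  H <- do.call(cbind, lapply(1:4, function(i)
    .stack_forward(model$params$enc_spec[[i]], block(X, i))$out))
  z <- .stack_forward(model$params$enc_int, H)$out
  rownames(z) <- rownames(X)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  z
}

#' Decode latent vectors with a trained autoencoder
#'
#' Forward pass through the decoder only (integration decoder, then the
#' four omics-specific decoders), returning the reconstructed concatenated
#' omics vector per row.
#'
#' @param model An `omics_autoencoder`.
#' @param Z Matrix of latent row vectors (columns = bottleneck dimension).
#' @return Matrix of reconstructed cell x 4n outputs.
#' @export
decode_latent <- function(model, Z) {
  if (is.null(model$params)) stop("model has no trained decoder")
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1)
  if (ncol(Z) != model$arch$integration[2]) {
    stop("latent width ", ncol(Z), " does not match the bottleneck (",
         model$arch$integration[2], ")")
  }
  s2 <- model$arch$specific[2]
  Hp <- .stack_forward(model$params$dec_int, Z)$out
  blockH <- function(M, i) M[, ((i - 1) * s2 + 1):(i * s2), drop = FALSE]
  do.call(cbind, lapply(1:4, function(i)
    .stack_forward(model$params$dec_spec[[i]], blockH(Hp, i))$out))
}

#' Total weight norm of a trained autoencoder
#'
#' Sum over all layers of the penalized norm (squared Frobenius norm for
#' the L2 penalty, absolute sum for L1); biases excluded. Used to check
#' that stronger regularization shrinks the weights.
#'
#' @param model An `omics_autoencoder`.
#' @return A single number.
#' @export
autoencoder_weight_norm <- function(model) {
  tot <- 0
  walk <- function(stack) {
    for (lay in stack) {
      tot <<- tot + if (model$penalty == "l2") sum(lay$W^2) else sum(abs(lay$W))
    }
  }
  for (i in 1:4) walk(model$params$enc_spec[[i]])
  walk(model$params$enc_int)
  walk(model$params$dec_int)
  for (i in 1:4) walk(model$params$dec_spec[[i]])
  tot
}
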