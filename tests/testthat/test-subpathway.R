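# Differential time vectors, cross-correlation, edge validation,
# sub-pathway extraction and the permutation null.

test_that("moderated t calls separated means and stays silent on null data", {
  set.seed(1)
  genes <- paste0("g", 1:50)
  ctrl <- matrix(rnorm(150, 8, 0.01), 50, 3, dimnames = list(genes, NULL))
  expect_true(all(moderated_t_deg(ctrl, ctrl) == 0))
  trt <- ctrl
  trt["g7", ] <- trt["g7", ] + 10
  trt["g9", ] <- trt["g9", ] - 10
  call <- moderated_t_deg(ctrl, trt)
  expect_equal(unname(call["g7"]), 1L)
  expect_equal(unname(call["g9"]), -1L)
  expect_equal(sum(call != 0), 2)
  expect_error(moderated_t_deg(ctrl, trt[rev(genes), ]), "same genes")
})

test_that("single-replicate arms fall back to fold-change-only calling", {
  genes <- c("a", "b", "c")
  ctrl <- matrix(c(5, 5, 5), 3, 1, dimnames = list(genes, NULL))
  trt <- matrix(c(7, 5, 3.5), 3, 1, dimnames = list(genes, NULL))
  expect_equal(unname(moderated_t_deg(ctrl, trt, lfc_cutoff = 1)),
               c(1L, 0L, -1L))
})

test_that("variance squeezing matches limma's empirical-Bayes posterior", {
  set.seed(42)
  n_gene <- 300; n <- 4
  sd_true <- sqrt(1 / rgamma(n_gene, shape = 3, rate = 3))
  y <- matrix(rnorm(n_gene * 2 * n, sd = rep(sd_true, 2 * n)), n_gene, 2 * n)
  design <- cbind(1, rep(0:1, each = n))
  fit <- limma::eBayes(limma::lmFit(y, design))
  s2 <- fit$sigma^2
  sq <- squeeze_var(s2, df = 2 * n - 2)
  expect_equal(sq$var_post, unname(fit$s2.post), tolerance = 1e-6)
  expect_equal(sq$var_prior, unname(fit$s2.prior), tolerance = 1e-6)
  expect_equal(sq$df_prior, unname(fit$df.prior), tolerance = 1e-4)
})

test_that("moderated variances shrink toward the pooled prior under common variance", {
  set.seed(7)
  s2 <- rchisq(500, df = 4) / 4          # unit-variance genes, 4 df
  sq <- squeeze_var(s2, df = 4)
  # posterior spread strictly smaller than raw spread, centred near 1
  expect_lt(sd(sq$var_post), sd(s2) / 2)
  expect_equal(mean(sq$var_post), 1, tolerance = 0.15)
})

test_that("time vectors reproduce the planted step pattern in all three modes", {
  pw <- chain_pathway(c("A", "B", "C"))
  fx <- generate_timeseries(pw, "A", 1, amplitude = 10, noise_sd = 0,
                            n_time = 3, n_rep = 2, seed = 1)
  v <- build_time_vectors(fx$control, fx$treated, mode = "vs_control")
  expect_equal(unname(v["A", ]), c(1L, 1L, 1L))
  expect_equal(unname(v["B", ]), c(0L, 1L, 1L))
  expect_equal(unname(v["C", ]), c(0L, 0L, 1L))
  # constant series: vs_initial all zero
  const <- fx$control
  expect_true(all(build_time_vectors(treated_series = const,
                                     mode = "vs_initial") == 0))
  # monotone increase beyond cutoff: vs_previous flags every step after t=1
  inc <- fx$control
  for (t in seq_len(dim(inc)[2])) inc[, t, ] <- 10 + 3 * t
  vp <- build_time_vectors(treated_series = inc, mode = "vs_previous")
  expect_true(all(vp[, 1] == 0))
  expect_true(all(vp[, -1] == 1))
  expect_error(build_time_vectors(fx$control[, 1, , drop = FALSE],
                                  fx$treated[, 1, , drop = FALSE]),
               "2 time points")
})

test_that("cross-correlation matches the direct lagged inner product", {
  expect_equal(cross_correlation(c(1, 1, 0), c(1, 1, 0), 0), 2L)
  expect_equal(cross_correlation(c(1, 0, 0), c(0, 1, 0), 1), 1L)
  expect_equal(cross_correlation(c(1, 0, 0), c(0, 1, 0), 0), 0L)
  # lag antisymmetry (v1*v2)(n) = (v2*v1)(-n) on random vectors
  set.seed(11)
  for (i in 1:200) {
    T <- sample(2:8, 1)
    v1 <- random_vector(T); v2 <- random_vector(T)
    n <- sample(-(T - 1):(T - 1), 1)
    expect_identical(cross_correlation(v1, v2, n),
                     cross_correlation(v2, v1, -n))
  }
})

test_that("propagation delay resolves ties toward the causal forward lag", {
  expect_equal(propagation_delay(c(1, 0, 0), c(0, 1, 0)), list(d = 1L, peak = 1L))
  # peak 2 attained at n = -1 and n = +1; forward lag wins
  pd <- propagation_delay(c(1, -1, 1), c(-1, 1, -1))
  expect_equal(pd$d, 1L)
  expect_equal(pd$peak, 2L)
  expect_equal(propagation_delay(c(0, 1, 0), c(1, 0, 0))$d, -1L)
  # sustained responses: delay equals the onset difference, reversed edges negative
  v <- step_vectors(c(A = 1, B = 2, C = 3, D = 4), 4)
  expect_equal(propagation_delay(v["A", ], v["B", ])$d, 1L)
  expect_equal(propagation_delay(v["A", ], v["C", ])$d, 2L)
  expect_lt(propagation_delay(v["C", ], v["A", ])$d, 0L)
})

test_that("edge validation applies direction, threshold and positivity rules", {
  pw <- chain_pathway(c("A", "B", "C"))
  v <- step_vectors(c(A = 1, B = 2, C = 3), 3)
  val <- validate_edges(pw, v, delay_threshold = 2)
  expect_true(all(val$valid))
  expect_equal(val$d, c(1L, 1L))
  expect_true(all(!validate_edges(pw, v, delay_threshold = 0)$valid))
  rev_pw <- pathway_graph(data.frame(source = "C", target = "A"))
  rv <- validate_edges(rev_pw, v, delay_threshold = 2)
  expect_false(rv$valid)
  expect_lt(rv$d, 0)
  # missing gene: edge skipped with a warning message
  pw2 <- pathway_graph(data.frame(source = c("A", "A"), target = c("B", "Z")))
  expect_message(val2 <- validate_edges(pw2, v, 2), "skipping")
  expect_equal(nrow(val2), 1)
})

test_that("sub-pathway extraction respects the component and min-edge rules", {
  # 4-node chain: one component of 3 valid edges
  pw <- chain_pathway(c("A", "B", "C", "D"))
  v <- step_vectors(c(A = 1, B = 2, C = 3, D = 4), 4)
  val <- validate_edges(pw, v, delay_threshold = 2)
  subs <- extract_subpathways(pw, val, min_edges = 3)
  expect_length(subs, 1)
  expect_equal(subs[[1]]$statistic, sum(val$peak))
  expect_equal(nrow(subs[[1]]$edges), 3)
  # only 2 valid edges -> nothing at the default threshold
  pw2 <- chain_pathway(c("A", "B", "C"))
  val2 <- validate_edges(pw2, step_vectors(c(A = 1, B = 2, C = 3), 4), 2)
  expect_length(extract_subpathways(pw2, val2, min_edges = 3), 0)
  expect_length(extract_subpathways(pw2, val2, min_edges = 2), 1)
  # two disjoint valid triples -> two sub-pathways
  pw3 <- pathway_graph(data.frame(
    source = c("A", "B", "C", "P", "Q", "R"),
    target = c("B", "C", "D", "Q", "R", "S")), name = "two")
  v3 <- rbind(step_vectors(c(A = 1, B = 2, C = 3, D = 4), 4),
              step_vectors(c(P = 1, Q = 2, R = 3, S = 4), 4, sign = -1))
  subs3 <- extract_subpathways(pw3, validate_edges(pw3, v3, 2), 3)
  expect_length(subs3, 2)
})

test_that("permutation p-value obeys its bounds and plus-one correction", {
  v <- step_vectors(c(A = 1, B = 2, C = 3, D = 4), 4)
  pw <- chain_pathway(c("A", "B", "C", "D"))
  sp <- extract_subpathways(pw, validate_edges(pw, v, 2), 3)[[1]]
  # pool of inert genes: no permutation can reach the observed statistic
  pool <- matrix(0L, 30, 4, dimnames = list(paste0("n", 1:30), NULL))
  expect_equal(permutation_pvalue(sp, pool, B = 999, seed = 1), 1 / 1000)
  # an all-zero sub-pathway can never beat any permutation: p = 1
  sp0 <- sp; sp0$statistic <- 0
  expect_equal(permutation_pvalue(sp0, pool, B = 99, seed = 1), 1)
  expect_error(permutation_pvalue(sp, pool[1:3, ], B = 9, seed = 1), "smaller")
  expect_identical(permutation_pvalue(sp, rbind(pool, v), B = 199, seed = 5),
                   permutation_pvalue(sp, rbind(pool, v), B = 199, seed = 5))
})

test_that("permutation p-values are valid (super-uniform) under a random pool", {
  set.seed(31)
  pvals <- replicate(60, {
    pool <- matrix(sample(c(-1L, 0L, 1L), 40 * 4, replace = TRUE), 40, 4,
                   dimnames = list(paste0("g", 1:40), NULL))
    genes <- paste0("g", 1:4)
    edges <- data.frame(source = genes[1:3], target = genes[2:4],
                        stringsAsFactors = FALSE)
    peaks <- vapply(1:3, function(e)
      propagation_delay(pool[edges$source[e], ],
                        pool[edges$target[e], ])$peak, integer(1))
    sp <- make_subpathway(cbind(edges, d = 0L, peak = peaks, valid = TRUE))
    permutation_pvalue(sp, pool, B = 99, seed = sample.int(1e6, 1))
  })
  expect_true(all(pvals >= 1 / 100 & pvals <= 1))
  # validity at the conventional level, with Monte-Carlo slack
  expect_lte(mean(pvals <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("whole-genome pools give small p for planted signal, BH column present", {
  pw <- chain_pathway(paste0("G", 1:4))
  fx <- generate_timeseries(pw, "G1", 1, amplitude = 8, noise_sd = 0.2,
                            n_time = 4, n_rep = 3, seed = 3)
  v <- build_time_vectors(fx$control, fx$treated)
  nulls <- matrix(0L, 60, 4, dimnames = list(paste0("null", 1:60), NULL))
  res <- find_perturbed_subpathways(pw, rbind(v, nulls), B = 199, seed = 2)
  expect_equal(nrow(res$table), 1)
  expect_lte(res$table$p, 0.05)
  expect_true("fdr" %in% names(res$table))
})
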