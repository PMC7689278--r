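# Shared fixture builders. Everything is generated in code at test time.

# linear chain pathway A -> B -> ... over `labels`
chain_pathway <- function(labels, name = "chain") {
  n <- length(labels)
  pathway_graph(data.frame(source = labels[-n], target = labels[-1]),
                name = name)
}

# matrix of step-like differential time vectors: gene i switches on at
# onsets[i] (NA = never) and stays on with the given sign
step_vectors <- function(onsets, n_time, sign = 1L) {
  genes <- names(onsets) %||% paste0("g", seq_along(onsets))
  v <- matrix(0L, length(onsets), n_time,
              dimnames = list(genes, paste0("t", seq_len(n_time))))
  for (i in seq_along(onsets)) {
    if (!is.na(onsets[i]) && onsets[i] <= n_time) {
      v[i, seq(onsets[i], n_time)] <- as.integer(sign)
    }
  }
  v
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-built perturbed sub-pathway over an explicit edge table
make_subpathway <- function(edges, name = "pw", id = 1L) {
  structure(list(pathway = name, component_id = id,
                 genes = sort(unique(c(edges$source, edges$target))),
                 edges = edges, statistic = sum(edges$peak),
                 p_value = NA_real_),
            class = "perturbed_subpathway")
}

# small deterministic time-bounded network straight from explicit pieces
make_network <- function(edges, n_time, labels = NULL) {
  genes <- unique(c(edges$from, edges$to))
  # vectors only needed for export; a dummy all-zero matrix suffices here
  vecs <- matrix(0L, length(genes), n_time,
                 dimnames = list(genes, paste0("t", seq_len(n_time))))
  nodes <- data.frame(name = genes,
                      label = if (is.null(labels)) "other"
                              else labels[genes],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges, T = n_time,
                 delay_threshold = n_time - 1L, vectors = vecs),
            class = "time_bounded_network")
}

# brute-force spec of Eq. 1 + argmax used as the independent oracle:
# slow direct summation over t, enumeration over all lags
oracle_xcorr <- function(v1, v2, n) {
  s <- 0L
  for (t in seq_along(v1)) {
    u <- t + n
    if (u >= 1 && u <= length(v2)) s <- s + v1[t] * v2[u]
  }
  s
}
oracle_delay <- function(v1, v2) {
  T <- length(v1)
  lags <- -(T - 1):(T - 1)
  vals <- sapply(lags, function(n) oracle_xcorr(v1, v2, n))
  peak <- max(vals)
  cand <- lags[vals == peak]
  cand <- cand[order(-abs(cand), cand < 0)]
  list(d = cand[1], peak = peak)
}

random_vector <- function(T) sample(c(-1L, 0L, 1L), T, replace = TRUE)

# independent-cascade expectation on a two-edge chain head -> m -> g with
# probabilities p1, p2 (delays within budget): closed form
chain_expectation <- function(p1, p2) p1 + p1 * p2

# deterministic reachability spread used by brute-force IM oracles
reach_spread <- function(edges, seeds, targets, budget) {
  genes <- unique(c(edges$from, edges$to, seeds, targets))
  dist <- stats::setNames(rep(Inf, length(genes)), genes)
  dist[seeds] <- 0
  live <- edges[edges$p >= 1, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(live))) {
      nd <- dist[live$from[e]] + live$d[e]
      if (nd < dist[live$to[e]]) {
        dist[live$to[e]] <- nd
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sum(dist[targets] <= budget)
}

# pipeline input bundle shared by the pipeline and acceptance suites
write_pipeline_inputs <- function(td, seed = 11) {
  sim_pw <- pathway_graph(data.frame(
    source = c("TF1", "G0001", "G0002", "G0003"),
    target = c("G0001", "G0002", "G0003", "G0004")))
  # null genes pad the permutation donor pool
  nulls <- paste0("N", sprintf("%02d", 1:40))
  sim_pw <- pathway_graph(sim_pw$edges, nodes = c(sim_pw$nodes, nulls))
  fx <- generate_timeseries(sim_pw, "TF1", 1, amplitude = 8, noise_sd = 0.2,
                            n_time = 5, n_rep = 3, seed = seed)
  write_timeseries_fixture(fx, td)
  mfx <- generate_multiomics(40, 60, 3, causal_factors = 1, effect_size = 2,
                             noise_sd = 0.1, seed = seed + 1)
  write_multiomics_fixture(mfx, td)
  write_pathway_tsv(chain_pathway(paste0("G000", 1:4), name = "chain"),
                    file.path(td, "pathway_chain.tsv"))
  utils::write.table(data.frame(tf = "TF1", target = "G0001"),
                     file.path(td, "grn.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_a = "G0002", gene_b = "G0003",
                                confidence = 0.9),
                     file.path(td, "pin.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(inputs = list(timeseries = file.path(td, "timeseries.tsv"),
                     pathways = list(file.path(td, "pathway_chain.tsv")),
                     multiomics = td, grn = file.path(td, "grn.tsv"),
                     pin = file.path(td, "pin.tsv")),
       subpathway = list(B = 199),
       embedding = list(route = "both", rank = 3, epochs = 120,
                        arch = list(specific = c(24L, 12L),
                                    integration = c(12L, 4L))),
       mediators = list(log_ic50 = FALSE, top_fraction = 0.1),
       network = list(n_sim = 200, k = 1),
       seed = 42)
}
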