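# TF-regulatory time-bounded network and labeled influence maximization.
#
# GRN (TF -> target) edges, PIN (gene-gene, instantiated in both
# directions) edges and the perturbed sub-pathway edges are merged into one
# directed network in which every edge must satisfy the same propagation
# rule as pathway edges: delay d in [0, delay_threshold] and positive peak
# cross-correlation between the endpoint differential time vectors. Each
# edge carries a propagation probability p = peak / T (the normalized
# maximal concordance, floored at epsilon), optionally scaled by a PIN
# confidence. Influence spreads under the independent-cascade model where
# traversing an edge consumes its delay and activation beyond the
# observation window T-1 is discarded; seed TFs are chosen greedily by
# marginal spread counted over target-labeled (sub-pathway) nodes only.

#' Build the TF-regulatory time-bounded network
#'
#' @param grn data.frame of directed TF -> target edges (columns `from`,
#'   `to`, see [read_edge_table()]).
#' @param pin data.frame of undirected gene-gene edges (`from`, `to`,
#'   optional `confidence` in \[0, 1\]); both directions are instantiated
#'   and validated independently.
#' @param subpathways List of `perturbed_subpathway` objects (must be
#'   non-empty: the network exists to explain them).
#' @param vectors Differential time vector matrix; nodes without a vector
#'   are dropped with a logged warning.
#' @param mediators Character vector of mediator gene names, or a mediator
#'   data.frame with a `gene` column; may be NULL.
#' @param delay_threshold Maximum admissible edge delay (default
#'   `ceiling(T/2)`).
#' @param epsilon Floor for the edge probability (default 0.01).
#' @param const_p If non-NULL, overrides the evidence-based probability
#'   with a constant for every edge.
#' @return Object of class `time_bounded_network`: list with `graph`
#'   (igraph), `nodes` (data.frame name/label), `edges` (data.frame
#'   from/to/provenance/d/peak/p), `T`, `delay_threshold`, `vectors`.
#' @export
build_time_bounded_network <- function(grn, pin, subpathways, vectors,
                                       mediators = NULL,
                                       delay_threshold = NULL,
                                       epsilon = 0.01, const_p = NULL) {
  if (length(subpathways) == 0) {
    stop("no perturbed sub-pathways given: nothing for the network to explain")
  }
  T <- ncol(vectors)
  if (is.null(delay_threshold)) delay_threshold <- ceiling(T / 2)
  med_genes <- if (is.data.frame(mediators)) mediators$gene else mediators
  sp_genes <- unique(unlist(lapply(subpathways, `[[`, "genes")))
  tf_genes <- unique(as.character(grn$from))

  validate_cand <- function(tab, provenance) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    have <- tab$from %in% rownames(vectors) & tab$to %in% rownames(vectors)
    if (any(!have)) {
      log_msg("warn", "time-bounded network: dropping ", sum(!have), " ",
              provenance, " edge(s) whose genes lack time vectors")
    }
    tab <- tab[have, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    d <- integer(nrow(tab)); peak <- integer(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      pd <- propagation_delay(vectors[tab$from[i], ], vectors[tab$to[i], ])
      d[i] <- pd$d; peak[i] <- pd$peak
    }
    keep <- d >= 0 & d <= delay_threshold & peak > 0
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    data.frame(from = tab$from, to = tab$to, provenance = provenance,
               d = d[keep], peak = peak[keep],
               confidence = if ("confidence" %in% names(tab))
                 as.numeric(tab$confidence) else NA_real_,
               stringsAsFactors = FALSE)
  }

  grn_edges <- validate_cand(grn[, c("from", "to"), drop = FALSE], "GRN")
  pin_both <- if (!is.null(pin) && nrow(pin) > 0) {
    rbind(pin, stats::setNames(pin[, c(2, 1, seq_len(ncol(pin))[-(1:2)]),
                                   drop = FALSE], names(pin)))
  } else {
    NULL
  }
  pin_edges <- validate_cand(pin_both, "PIN")
  sp_edges <- do.call(rbind, lapply(subpathways, function(sp) {
    data.frame(from = sp$edges$source, to = sp$edges$target,
               provenance = "subpathway", d = sp$edges$d,
               peak = sp$edges$peak, confidence = NA_real_,
               stringsAsFactors = FALSE)
  }))
  all_edges <- rbind(sp_edges, grn_edges, pin_edges)
  if (is.null(all_edges) || nrow(all_edges) == 0) stop("no valid edges survive")

  p <- if (is.null(const_p)) pmin(pmax(all_edges$peak / T, epsilon), 1)
       else rep(const_p, nrow(all_edges))
  conf <- all_edges$confidence
  p <- ifelse(is.na(conf), p, pmin(pmax(p * conf, 0), 1))
  all_edges$p <- p
  all_edges$confidence <- NULL
  # dedupe parallel edges: keep the most propagative copy (highest p);
  # rbind order gives sub-pathway > GRN > PIN priority on ties
  ord <- order(all_edges$from, all_edges$to, -all_edges$p)
  all_edges <- all_edges[ord, , drop = FALSE]
  all_edges <- all_edges[!duplicated(all_edges[, c("from", "to")]), ,
                         drop = FALSE]
  rownames(all_edges) <- NULL

  node_names <- unique(c(all_edges$from, all_edges$to))
  label <- ifelse(node_names %in% tf_genes, "TF",
                  ifelse(node_names %in% med_genes, "mediator",
                         ifelse(node_names %in% sp_genes, "pathway_gene",
                                "other")))
  nodes <- data.frame(name = node_names, label = label,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(all_edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = all_edges, T = T,
                 delay_threshold = delay_threshold,
                 vectors = vectors[intersect(rownames(vectors), node_names), ,
                                   drop = FALSE]),
            class = "time_bounded_network")
}

#' @export
print.time_bounded_network <- function(x, ...) {
  tab <- table(x$nodes$label)
  cat(sprintf("Time-bounded network: %d nodes (%s), %d edges; T = %d, delay threshold %d\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$edges), x$T, x$delay_threshold))
  invisible(x)
}

# earliest-activation distances on one live-edge draw (small graphs:
# Bellman-Ford style relaxation)
.spread_once <- function(from_idx, to_idx, d, live, seed_idx, target_mask,
                         budget, n_nodes) {
  dist <- rep(Inf, n_nodes)
  dist[seed_idx] <- 0
  es <- which(live)
  if (length(es)) {
    repeat {
      changed <- FALSE
      for (e in es) {
        nd <- dist[from_idx[e]] + d[e]
        if (nd < dist[to_idx[e]]) {
          dist[to_idx[e]] <- nd
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  sum(target_mask & dist <= budget)
}

.network_arrays <- function(network) {
  nn <- network$nodes$name
  list(nn = nn,
       from_idx = match(network$edges$from, nn),
       to_idx = match(network$edges$to, nn),
       d = network$edges$d, p = network$edges$p,
       budget = network$T - 1)
}

#' Monte-Carlo influence spread over target-labeled nodes
#'
#' Estimates, under the independent-cascade model on the time-bounded
#' network (each edge fires independently with its probability p; firing
#' consumes the edge delay; activations arriving after time T-1 are
#' discarded), the expected number of target nodes activated from the seed
#' set. Seeds are active at time 0, so seeds that are themselves targets
#' count.
#'
#' @param network A `time_bounded_network`.
#' @param seeds,targets Character vectors of node names.
#' @param n_sim Number of cascade simulations (>= 1, default 10000).
#' @param seed Integer RNG seed.
#' @return Expected activated-target count (a single number).
#' @export
influence_spread <- function(network, seeds, targets, n_sim = 10000L,
                             seed = 1L) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  ar <- .network_arrays(network)
  bad <- setdiff(c(seeds, targets), ar$nn)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  seed_idx <- match(seeds, ar$nn)
  target_mask <- ar$nn %in% targets
  E <- length(ar$p)
  with_seed(seed, {
    tot <- 0
    for (s in seq_len(n_sim)) {
      live <- stats::runif(E) < ar$p
      tot <- tot + .spread_once(ar$from_idx, ar$to_idx, ar$d, live, seed_idx,
                                target_mask, ar$budget, length(ar$nn))
    }
    tot / n_sim
  })
}

#' Greedy labeled influence maximization over TF seeds
#'
#' Standard greedy seed selection: iteratively adds the candidate TF with
#' the largest marginal expected spread, where spread counts only
#' target-labeled nodes (the "labeled" restriction). Cascade draws are
#' shared across iterations and candidates (common random numbers) for
#' variance reduction.
#'
#' @param network A `time_bounded_network`.
#' @param candidate_seeds Character vector of TF node names; defaults to
#'   all TF-labeled nodes.
#' @param targets Character vector of target nodes; defaults to all
#'   pathway_gene-labeled nodes.
#' @param k Number of seeds to select (>= 1).
#' @param n_sim Cascade simulations per spread estimate.
#' @param seed Integer RNG seed.
#' @return data.frame (tf, marginal_spread, cumulative_spread) in selection
#'   order; zero rows (with a warning) when no TF reaches any target.
#' @export
greedy_labeled_im <- function(network, candidate_seeds = NULL, targets = NULL,
                              k = 3L, n_sim = 10000L, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(candidate_seeds)) {
    candidate_seeds <- network$nodes$name[network$nodes$label == "TF"]
  }
  if (is.null(targets)) {
    targets <- network$nodes$name[network$nodes$label == "pathway_gene"]
  }
  if (length(candidate_seeds) == 0) stop("no candidate TF seeds")
  ar <- .network_arrays(network)
  target_mask <- ar$nn %in% targets
  E <- length(ar$p)
  live_mat <- with_seed(seed, {
    matrix(stats::runif(n_sim * E), n_sim, E) < rep(ar$p, each = n_sim)
  })
  est <- function(seed_names) {
    idx <- match(seed_names, ar$nn)
    tot <- 0
    for (s in seq_len(n_sim)) {
      tot <- tot + .spread_once(ar$from_idx, ar$to_idx, ar$d, live_mat[s, ],
                                idx, target_mask, ar$budget, length(ar$nn))
    }
    tot / n_sim
  }
  chosen <- character(0)
  rows <- list()
  base_spread <- 0
  remaining <- sort(candidate_seeds)
  for (step in seq_len(min(k, length(candidate_seeds)))) {
    gains <- vapply(remaining, function(tf) est(c(chosen, tf)) - base_spread,
                    numeric(1))
    best <- which.max(gains)
    if (step == 1 && gains[best] <= 0) {
      log_msg("warn", "greedy_labeled_im: no TF reaches any target")
      warning("no TF reaches any target; empty selection")
      return(data.frame(tf = character(), marginal_spread = numeric(),
                        cumulative_spread = numeric()))
    }
    chosen <- c(chosen, remaining[best])
    base_spread <- base_spread + gains[best]
    rows[[step]] <- data.frame(tf = remaining[best],
                               marginal_spread = gains[best],
                               cumulative_spread = base_spread,
                               stringsAsFactors = FALSE)
    remaining <- remaining[-best]
    if (length(remaining) == 0) break
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the most influential TF-to-sub-pathway regulatory paths
#'
#' Enumerates simple paths from the TF that end on their first entry into
#' the sub-pathway's node set, subject to the time budget (cumulative edge
#' delay <= T-1). Paths are scored by the product of edge probabilities
#' (equivalently, minimal additive -log p cost) and the top `max_paths`
#' are returned; ties break toward shorter paths, then lexicographic node
#' order. With `require_mediator = TRUE`, paths lacking a mediator-labeled
#' interior node are filtered out.
#'
#' @param network A `time_bounded_network`.
#' @param tf Name of a TF-labeled node.
#' @param subpathway A `perturbed_subpathway` (or character vector of
#'   target gene names).
#' @param require_mediator Require a mediator on the path interior
#'   (default FALSE).
#' @param max_paths Maximum number of paths returned (default 10).
#' @return List of `regulatory_path` objects (nodes, score,
#'   cumulative_delay, tf, subpathway_id), best first; empty when the
#'   sub-pathway is unreachable.
#' @export
extract_regulatory_paths <- function(network, tf, subpathway,
                                     require_mediator = FALSE,
                                     max_paths = 10L) {
  lab <- network$nodes$label[match(tf, network$nodes$name)]
  if (is.na(lab) || lab != "TF") stop("'", tf, "' is not a TF-labeled node")
  targets <- if (inherits(subpathway, "perturbed_subpathway"))
    subpathway$genes else as.character(subpathway)
  sp_id <- if (inherits(subpathway, "perturbed_subpathway"))
    paste0(subpathway$pathway, "#", subpathway$component_id) else "targets"
  ar <- .network_arrays(network)
  # adjacency lists
  adj <- split(seq_along(ar$from_idx), ar$from_idx)
  target_set <- ar$nn %in% targets
  tf_idx <- match(tf, ar$nn)
  found <- list()
  dfs <- function(node, visited, delay_used, logp, path_idx) {
    out_edges <- adj[[as.character(node)]]
    if (is.null(out_edges)) return(invisible(NULL))
    for (e in out_edges) {
      nxt <- ar$to_idx[e]
      if (visited[nxt]) next
      nd <- delay_used + ar$d[e]
      if (nd > ar$budget) next
      nlogp <- logp + log(ar$p[e])
      if (target_set[nxt]) {
        found[[length(found) + 1]] <<- list(idx = c(path_idx, nxt),
                                            delay = nd, logp = nlogp)
      } else {
        visited[nxt] <- TRUE
        dfs(nxt, visited, nd, nlogp, c(path_idx, nxt))
        visited[nxt] <- FALSE
      }
    }
    invisible(NULL)
  }
  visited <- rep(FALSE, length(ar$nn))
  visited[tf_idx] <- TRUE
  dfs(tf_idx, visited, 0, 0, tf_idx)
  if (length(found) == 0) return(list())
  if (require_mediator) {
    is_med <- network$nodes$label == "mediator"
    keep <- vapply(found, function(f) {
      interior <- f$idx[-c(1, length(f$idx))]
      length(interior) > 0 && any(is_med[interior])
    }, logical(1))
    if (!any(keep)) {
      log_msg("warn", "extract_regulatory_paths: all paths filtered by the ",
              "mediator requirement")
      warning("all paths lack a mediator interior node")
      return(list())
    }
    found <- found[keep]
  }
  key <- vapply(found, function(f) paste(ar$nn[f$idx], collapse = ";"), "")
  ord <- order(-vapply(found, `[[`, 0, "logp"),
               vapply(found, function(f) length(f$idx), 0L), key)
  found <- found[ord][seq_len(min(max_paths, length(found)))]
  lapply(found, function(f) {
    path <- structure(list(nodes = ar$nn[f$idx], score = exp(f$logp),
                           cumulative_delay = f$delay, tf = tf,
                           subpathway_id = sp_id),
                      class = "regulatory_path")
    stopifnot(path$nodes[1] == tf, f$delay <= ar$budget)
    path
  })
}

#' @export
print.regulatory_path <- function(x, ...) {
  cat(sprintf("Regulatory path [%s]: %s (score %.4g, cumulative delay %d)\n",
              x$subpathway_id, paste(x$nodes, collapse = " -> "), x$score,
              x$cumulative_delay))
  invisible(x)
}

#' Terminator proteins: nodes with no outgoing edges
#'
#' @param network A `time_bounded_network`.
#' @return Character vector of node names with out-degree 0 (isolated
#'   nodes included).
#' @export
terminator_proteins <- function(network) {
  deg <- igraph::degree(network$graph, mode = "out")
  names(deg)[deg == 0]
}

#' Flatten regulatory paths into a table
#' @param paths List of `regulatory_path` objects.
#' @return data.frame (tf, subpathway_id, path, score, cumulative_delay).
#' @export
paths_table <- function(paths) {
  if (length(paths) == 0) {
    return(data.frame(tf = character(), subpathway_id = character(),
                      path = character(), score = numeric(),
                      cumulative_delay = integer()))
  }
  data.frame(tf = vapply(paths, `[[`, "", "tf"),
             subpathway_id = vapply(paths, `[[`, "", "subpathway_id"),
             path = vapply(paths, function(p) paste(p$nodes, collapse = ";"), ""),
             score = vapply(paths, `[[`, 0, "score"),
             cumulative_delay = vapply(paths, function(p)
               as.integer(p$cumulative_delay), 0L),
             stringsAsFactors = FALSE)
}

#' Export a time-bounded network as GraphML, TSV tables and a time-state JSON
#'
#' Writes `network.graphml`, `nodes.tsv`, `edges.tsv` and
#' `node_states.json` (per time point, the nodes called over/under
#' expressed — a static stand-in for an interactive per-time-point view).
#'
#' @param network A `time_bounded_network`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  igraph::write_graph(network$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  utils::write.table(network$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  v <- network$vectors
  states <- lapply(seq_len(ncol(v)), function(t) {
    list(time = t,
         over = rownames(v)[v[, t] > 0],
         under = rownames(v)[v[, t] < 0])
  })
  jsonlite::write_json(states, file.path(dir, "node_states.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
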