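# Time-bounded network construction, independent-cascade spread, greedy
# labeled influence maximization and regulatory path extraction.

# one valid sub-pathway used throughout
toy_subpathway <- function() {
  make_subpathway(data.frame(source = c("P1", "P2"), target = c("P2", "P3"),
                             d = c(1L, 1L), peak = c(2L, 1L), valid = TRUE,
                             stringsAsFactors = FALSE))
}

test_that("network assembly validates GRN/PIN edges by the propagation rule", {
  v <- step_vectors(c(X = 1, M = 2, G = 3, P1 = 1, P2 = 2, P3 = 3), 3)
  net <- build_time_bounded_network(
    grn = data.frame(from = "X", to = "M"),
    pin = data.frame(from = "M", to = "G"),
    subpathways = list(toy_subpathway()),
    vectors = v)
  e <- net$edges
  expect_true(all(c("GRN", "PIN", "subpathway") %in% e$provenance))
  expect_equal(e$d[e$from == "X" & e$to == "M"], 1L)
  expect_equal(e$d[e$from == "M" & e$to == "G"], 1L)
  # the reverse PIN direction G -> M has negative delay and is dropped
  expect_false(any(e$from == "G" & e$to == "M"))
  # labels: TF > mediator > pathway_gene > other
  expect_equal(net$nodes$label[net$nodes$name == "X"], "TF")
  expect_equal(net$nodes$label[net$nodes$name == "P1"], "pathway_gene")
  expect_error(build_time_bounded_network(
    data.frame(from = "X", to = "M"), NULL, list(), v), "sub-pathways")
})

test_that("a mediator vector preceding its TF removes the GRN edge", {
  v <- step_vectors(c(X = 2, M = 1, P1 = 1, P2 = 2, P3 = 3), 3)
  net <- suppressWarnings(build_time_bounded_network(
    grn = data.frame(from = "X", to = "M"), pin = NULL,
    subpathways = list(toy_subpathway()), vectors = v))
  expect_false(any(net$edges$from == "X" & net$edges$to == "M"))
})

test_that("simultaneous concordant PIN partners keep both directions at d = 0", {
  v <- step_vectors(c(A = 2, B = 2, P1 = 1, P2 = 2, P3 = 3), 3)
  net <- build_time_bounded_network(
    grn = data.frame(from = character(), to = character()),
    pin = data.frame(from = "A", to = "B"),
    subpathways = list(toy_subpathway()), vectors = v)
  expect_true(any(net$edges$from == "A" & net$edges$to == "B" &
                    net$edges$d == 0))
  expect_true(any(net$edges$from == "B" & net$edges$to == "A" &
                    net$edges$d == 0))
})

test_that("edge probabilities are normalized peaks with floor and confidence", {
  v <- step_vectors(c(X = 1, M = 2, P1 = 1, P2 = 2, P3 = 3), 4)
  net <- build_time_bounded_network(
    grn = data.frame(from = "X", to = "M"),
    pin = data.frame(from = "X", to = "P1", confidence = 0.5),
    subpathways = list(toy_subpathway()), vectors = v,
    delay_threshold = 2)
  e <- net$edges
  xm <- e[e$from == "X" & e$to == "M", ]
  expect_equal(xm$p, xm$peak / 4)
  xp <- e[e$from == "X" & e$to == "P1", ]
  expect_equal(xp$p, (xp$peak / 4) * 0.5)
  expect_true(all(e$p >= 0 & e$p <= 1))
})

test_that("deterministic cascades activate exactly the reachable targets", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                      provenance = "GRN", d = 1L, peak = 1L, p = 1,
                      stringsAsFactors = FALSE)
  net <- make_network(edges, n_time = 4)
  expect_equal(influence_spread(net, "a", c("b", "c", "d"), 50, seed = 1), 3)
  # p = 0 everywhere: only seeds that are targets count
  net0 <- make_network(transform(edges, p = 0), n_time = 4)
  expect_equal(influence_spread(net0, "a", c("a", "b"), 50, seed = 1), 1)
  # delay budget: with T = 3 the 3-hop node d is out of reach
  net3 <- make_network(edges, n_time = 3)
  expect_equal(influence_spread(net3, "a", c("b", "c", "d"), 50, seed = 1), 2)
  expect_error(influence_spread(net, "a", "b", n_sim = 0), "n_sim")
  expect_error(influence_spread(net, "zz", "b", 10), "unknown")
})

test_that("Monte-Carlo spread matches the closed-form chain expectation", {
  edges <- data.frame(from = c("x", "m"), to = c("m", "g"),
                      provenance = "GRN", d = 1L, peak = 1L, p = 0.5,
                      stringsAsFactors = FALSE)
  net <- make_network(edges, n_time = 4)
  est <- influence_spread(net, "x", c("m", "g"), n_sim = 20000, seed = 2)
  expect_equal(est, chain_expectation(0.5, 0.5), tolerance = 0.02)
  # asymmetric probabilities
  edges$p <- c(0.9, 0.3)
  net2 <- make_network(edges, n_time = 4)
  est2 <- influence_spread(net2, "x", c("m", "g"), n_sim = 20000, seed = 3)
  expect_equal(est2, chain_expectation(0.9, 0.3), tolerance = 0.02)
})

test_that("spread is monotone in the seed set", {
  set.seed(4)
  edges <- data.frame(from = c("a", "a", "b", "c", "d"),
                      to = c("b", "c", "d", "d", "e"),
                      provenance = "GRN", d = 1L, peak = 1L,
                      p = runif(5, 0.2, 0.8), stringsAsFactors = FALSE)
  net <- make_network(edges, n_time = 5)
  targets <- c("d", "e")
  s1 <- influence_spread(net, "a", targets, 4000, seed = 5)
  s2 <- influence_spread(net, c("a", "c"), targets, 4000, seed = 5)
  expect_gte(s2 + 0.03, s1)
})

test_that("greedy selection orders TFs by marginal spread on disjoint targets", {
  # TF_a reaches 3 targets, TF_b reaches 2, all p = 1
  edges <- data.frame(
    from = c("TF_a", "TF_a", "TF_a", "TF_b", "TF_b"),
    to = c("t1", "t2", "t3", "u1", "u2"),
    provenance = "GRN", d = 1L, peak = 1L, p = 1, stringsAsFactors = FALSE)
  labels <- c(TF_a = "TF", TF_b = "TF", t1 = "pathway_gene",
              t2 = "pathway_gene", t3 = "pathway_gene",
              u1 = "pathway_gene", u2 = "pathway_gene")
  net <- make_network(edges, n_time = 3, labels = labels)
  out <- greedy_labeled_im(net, k = 2, n_sim = 50, seed = 1)
  expect_equal(out$tf, c("TF_a", "TF_b"))
  expect_equal(out$marginal_spread, c(3, 2))
  expect_equal(out$cumulative_spread, c(3, 5))
  # single TF with a sure path to every target
  out1 <- greedy_labeled_im(net, candidate_seeds = "TF_a",
                            targets = c("t1", "t2", "t3"), k = 1,
                            n_sim = 20, seed = 2)
  expect_equal(out1$marginal_spread, 3)
  # nothing reachable -> empty with warning
  net0 <- make_network(transform(edges, p = 0), n_time = 3, labels = labels)
  expect_warning(out0 <- greedy_labeled_im(net0, k = 1, n_sim = 20, seed = 3),
                 "no TF")
  expect_equal(nrow(out0), 0)
})

test_that("greedy reaches (1 - 1/e) of the brute-force optimum on deterministic graphs", {
  set.seed(6)
  for (trial in 1:25) {
    n <- sample(4:8, 1)
    genes <- paste0("n", seq_len(n))
    # random sparse deterministic graph (p in {0, 1} realized as kept edges)
    pairs <- expand.grid(from = genes, to = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
    if (nrow(pairs) == 0) next
    edges <- data.frame(pairs, provenance = "GRN", d = 1L, peak = 1L, p = 1,
                        stringsAsFactors = FALSE)
    tfs <- sample(genes, min(3, n))
    targets <- sample(genes, min(4, n))
    labels <- stats::setNames(rep("other", n), genes)
    labels[targets] <- "pathway_gene"; labels[tfs] <- "TF"
    net <- make_network(edges, n_time = n + 1, labels = labels)
    k <- 2
    got <- tryCatch(suppressWarnings(
      greedy_labeled_im(net, candidate_seeds = tfs, targets = targets,
                        k = k, n_sim = 1, seed = trial)),
      error = function(e) NULL)
    greedy_spread <- if (is.null(got) || nrow(got) == 0) 0 else
      max(got$cumulative_spread)
    # brute force over all seed subsets of size <= k
    combos <- c(lapply(tfs, identity), if (length(tfs) >= 2)
      utils::combn(tfs, 2, simplify = FALSE))
    opt <- max(vapply(combos, function(ss)
      reach_spread(edges, ss, targets, n), numeric(1)))
    expect_gte(greedy_spread + 1e-9, (1 - exp(-1)) * opt)
  }
})

test_that("regulatory paths are scored, filtered and bounded correctly", {
  # two routes to the target: 0.9*0.9 = 0.81 beats 0.95*0.5 = 0.475
  edges <- data.frame(
    from = c("TF", "a", "TF", "b"), to = c("a", "t", "b", "t"),
    provenance = "GRN", d = 1L, peak = 1L, p = c(0.9, 0.9, 0.95, 0.5),
    stringsAsFactors = FALSE)
  labels <- c(TF = "TF", a = "mediator", b = "other", t = "pathway_gene")
  net <- make_network(edges, n_time = 4, labels = labels)
  paths <- extract_regulatory_paths(net, "TF", "t")
  expect_length(paths, 2)
  expect_equal(paths[[1]]$nodes, c("TF", "a", "t"))
  expect_equal(paths[[1]]$score, 0.81, tolerance = 1e-12)
  expect_equal(paths[[2]]$score, 0.475, tolerance = 1e-12)
  expect_equal(paths[[1]]$cumulative_delay, 2)
  # mediator requirement keeps only the path through the mediator "a"
  med_paths <- extract_regulatory_paths(net, "TF", "t", require_mediator = TRUE)
  expect_length(med_paths, 1)
  expect_equal(med_paths[[1]]$nodes, c("TF", "a", "t"))
  # if the only path lacks a mediator the result is empty with a warning
  labels2 <- labels; labels2["a"] <- "other"
  net2 <- make_network(edges[1:2, ], n_time = 4, labels = labels2)
  expect_warning(p2 <- extract_regulatory_paths(net2, "TF", "t",
                                                require_mediator = TRUE),
                 "mediator")
  expect_length(p2, 0)
  # unreachable target -> empty list; non-TF start rejected
  expect_length(extract_regulatory_paths(net, "TF", "zz"), 0)
  expect_error(extract_regulatory_paths(net, "a", "t"), "TF-labeled")
  # delay budget: with T = 2 the two-edge paths exceed the window
  net3 <- make_network(edges, n_time = 2, labels = labels)
  expect_length(extract_regulatory_paths(net3, "TF", "t"), 0)
})

test_that("path extraction agrees with brute-force simple-path enumeration", {
  set.seed(8)
  for (trial in 1:30) {
    n <- sample(5:10, 1)
    genes <- paste0("n", seq_len(n))
    pairs <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    if (nrow(pairs) == 0) next
    edges <- data.frame(pairs, provenance = "GRN",
                        d = sample(0:2, nrow(pairs), replace = TRUE),
                        peak = 1L, p = round(runif(nrow(pairs), 0.1, 1), 3),
                        stringsAsFactors = FALSE)
    tf <- genes[1]; target <- genes[n]
    if (!all(c(tf, target) %in% c(edges$from, edges$to))) next
    labels <- stats::setNames(rep("other", n), genes)
    labels[tf] <- "TF"; labels[target] <- "pathway_gene"
    n_time <- 5L
    net <- make_network(edges, n_time = n_time, labels = labels)
    got <- extract_regulatory_paths(net, tf, target, max_paths = 1000)
    # oracle: enumerate all simple paths with igraph, drop those entering
    # the target early or exceeding the delay budget, score by product
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = genes)
    asp <- igraph::all_simple_paths(g, from = tf, to = target, mode = "out")
    want <- list()
    for (pth in asp) {
      nm <- names(pth)
      if (target %in% nm[-length(nm)]) next
      idx <- match(paste(nm[-length(nm)], nm[-1]),
                   paste(edges$from, edges$to))
      delay <- sum(edges$d[idx])
      if (delay > n_time - 1) next
      want[[length(want) + 1]] <- list(nodes = nm,
                                       score = prod(edges$p[idx]),
                                       delay = delay)
    }
    expect_equal(length(got), length(want))
    if (length(want)) {
      expect_equal(sort(vapply(got, `[[`, 0, "score")),
                   sort(vapply(want, `[[`, 0, "score")), tolerance = 1e-12)
      # the winner is a genuine maximum
      expect_equal(got[[1]]$score, max(vapply(want, `[[`, 0, "score")),
                   tolerance = 1e-12)
    }
  }
})

test_that("terminator proteins are exactly the out-degree-zero nodes", {
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"),
                      provenance = "GRN", d = 1L, peak = 1L, p = 1,
                      stringsAsFactors = FALSE)
  expect_equal(terminator_proteins(make_network(edges, 3)), "c")
  cyc <- data.frame(from = c("a", "b"), to = c("b", "a"),
                    provenance = "GRN", d = 1L, peak = 1L, p = 1,
                    stringsAsFactors = FALSE)
  expect_length(terminator_proteins(make_network(cyc, 3)), 0)
  # isolated node counts
  net <- make_network(edges, 3)
  g2 <- igraph::add_vertices(net$graph, 1, name = "iso", label = "other")
  net$graph <- g2
  expect_setequal(terminator_proteins(net), c("c", "iso"))
})

test_that("network export writes GraphML, tables and per-time node states", {
  td <- withr::local_tempdir()
  v <- step_vectors(c(X = 1, M = 2, P1 = 1, P2 = 2, P3 = 3), 3)
  net <- build_time_bounded_network(
    grn = data.frame(from = "X", to = "M"), pin = NULL,
    subpathways = list(toy_subpathway()), vectors = v)
  export_network(net, td)
  expect_true(all(file.exists(file.path(td, c("network.graphml", "nodes.tsv",
                                              "edges.tsv",
                                              "node_states.json")))))
  st <- jsonlite::read_json(file.path(td, "node_states.json"))
  expect_length(st, 3)
  g <- igraph::read_graph(file.path(td, "network.graphml"),
                          format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
})
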