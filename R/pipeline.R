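# End-to-end orchestration: configuration, per-stage drivers that consume
# and produce only files (so any stage can be re-run standalone), and the
# full pipeline runner. A single master seed deterministically derives the
# per-stage seeds; re-running with the same config and seed reproduces all
# outputs byte for byte.

.default_config <- function() {
  list(
    inputs = list(timeseries = NULL, pathways = NULL, multiomics = NULL,
                  grn = NULL, pin = NULL, literature = NULL),
    deg = list(mode = "vs_control", lfc_cutoff = 1, p_cutoff = 0.05),
    subpathway = list(min_edges = 3L, delay_threshold = NULL, B = 999L),
    embedding = list(route = "tensor", rank = 8L,
                     arch = list(specific = c(64L, 32L),
                                 integration = c(32L, 8L)),
                     lambda = 0, epochs = 300L, lr = 1e-3),
    mediators = list(w = 0.5, top_fraction = 0.05, log_ic50 = TRUE,
                     cv_folds = 10L),
    network = list(k = 3L, n_sim = 1000L, epsilon = 0.01, max_paths = 10L,
                   require_mediator = FALSE),
    seed = 1L
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' sections `inputs`, `deg`, `subpathway`, `embedding`, `mediators`,
#' `network` and a master `seed`; unspecified values fall back to package
#' defaults. Referenced input paths must exist and flags must lie in their
#' documented ranges.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return Validated config list (class `run_config`), with a
#'   `config_path` attribute when read from a file.
#' @export
read_run_config <- function(config) {
  path <- NULL
  if (is.character(config) && length(config) == 1) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
  }
  cfg <- .merge_config(.default_config(), config)
  for (nm in c("timeseries", "multiomics", "grn", "pin", "literature")) {
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input '", nm, "' does not exist: ", p)
    }
  }
  for (p in cfg$inputs$pathways) {
    if (!file.exists(p)) stop("pathway file does not exist: ", p)
  }
  if (!cfg$deg$mode %in% c("vs_control", "vs_previous", "vs_initial")) {
    stop("deg$mode must be vs_control, vs_previous or vs_initial")
  }
  if (!cfg$embedding$route %in% c("tensor", "autoencoder", "both")) {
    stop("embedding$route must be tensor, autoencoder or both")
  }
  stopifnot(cfg$subpathway$min_edges >= 1, cfg$subpathway$B >= 1,
            cfg$mediators$w >= 0, cfg$mediators$w <= 1,
            cfg$network$k >= 1, cfg$network$n_sim >= 1)
  attr(cfg, "config_path") <- path
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Stage 1: perturbed sub-pathway identification
#'
#' Reads the long time-series TSV and the pathway edge lists named in the
#' config, builds differential time vectors, and writes `vectors.tsv`,
#' `subpathways.tsv` (with BH FDR) and `subpathway_edges.tsv` into
#' `out_dir`.
#'
#' @param config A validated `run_config` (or something [read_run_config()]
#'   accepts).
#' @param out_dir Run directory.
#' @return The [find_perturbed_subpathways()] result, invisibly.
#' @export
stage_subpathway <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_timeseries_long(cfg$inputs$timeseries)
  vectors <- build_time_vectors(series$control, series$treated,
                                mode = cfg$deg$mode,
                                lfc_cutoff = cfg$deg$lfc_cutoff,
                                p_cutoff = cfg$deg$p_cutoff)
  pathways <- lapply(cfg$inputs$pathways, read_pathway_tsv)
  res <- find_perturbed_subpathways(pathways, vectors,
                                    delay_threshold = cfg$subpathway$delay_threshold,
                                    min_edges = cfg$subpathway$min_edges,
                                    B = cfg$subpathway$B,
                                    seed = derive_seed(cfg$seed, 1))
  write_wide_matrix(vectors, file.path(out_dir, "vectors.tsv"),
                    row_label = "gene")
  .write_tsv(res$table, file.path(out_dir, "subpathways.tsv"))
  .write_tsv(res$edges, file.path(out_dir, "subpathway_edges.tsv"))
  log_msg("info", "subpathway stage: ", nrow(res$table),
          " perturbed sub-pathway(s)")
  invisible(res)
}

#' Stage 2: multi-omics embedding
#'
#' Reads the four omics matrices (and IC50) from the multiomics input
#' directory and fits the configured embedding route(s). Writes `C_c.tsv`,
#' `C_g.tsv`, `C_o.tsv` and `embedding_tensor.json` for the tensor route;
#' `z.tsv`, `autoencoder_model.rds` and `embedding_autoencoder.json` for
#' the autoencoder route.
#'
#' @inheritParams stage_subpathway
#' @return List with `cp` and/or `ae` fits, invisibly.
#' @export
stage_embedding <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_omics_matrices(cfg$inputs$multiomics)
  out <- list()
  route <- cfg$embedding$route
  if (route %in% c("tensor", "both")) {
    tensor <- assemble_tensor(dat$omics)
    cp <- cp_decompose(tensor, R = cfg$embedding$rank,
                       seed = derive_seed(cfg$seed, 2))
    write_wide_matrix(cp$C_c, file.path(out_dir, "C_c.tsv"), "cell_line")
    write_wide_matrix(cp$C_g, file.path(out_dir, "C_g.tsv"), "gene")
    write_wide_matrix(cp$C_o, file.path(out_dir, "C_o.tsv"), "omics")
    jsonlite::write_json(list(rank = cp$R, rel_error = cp$rel_error,
                              iterations = cp$iterations,
                              converged = cp$converged,
                              seed = derive_seed(cfg$seed, 2)),
                         file.path(out_dir, "embedding_tensor.json"),
                         auto_unbox = TRUE, digits = NA)
    out$cp <- cp
  }
  if (route %in% c("autoencoder", "both")) {
    ae <- train_autoencoder(dat$omics, arch = cfg$embedding$arch,
                            lambda = cfg$embedding$lambda,
                            epochs = cfg$embedding$epochs,
                            lr = cfg$embedding$lr,
                            seed = derive_seed(cfg$seed, 3))
    write_wide_matrix(ae$z, file.path(out_dir, "z.tsv"), "cell_line")
    saveRDS(ae, file.path(out_dir, "autoencoder_model.rds"))
    jsonlite::write_json(list(arch = ae$arch, lambda = ae$lambda,
                              penalty = ae$penalty,
                              final_loss = ae$final_loss,
                              epochs_run = ae$epochs_run,
                              seed = derive_seed(cfg$seed, 3)),
                         file.path(out_dir, "embedding_autoencoder.json"),
                         auto_unbox = TRUE, digits = NA)
    out$ae <- ae
  }
  invisible(out)
}

.prepare_ic50 <- function(ic50, log_ic50) {
  if (isTRUE(log_ic50)) {
    if (any(ic50 <= 0)) {
      stop("log transform of IC50 requested but values are not all positive; ",
           "set mediators$log_ic50: false for responses already on a log scale")
    }
    list(y = log(ic50), transform = "log")
  } else {
    list(y = ic50, transform = "none")
  }
}

#' Stage 3: mediator gene selection
#'
#' Consumes the embedding outputs in `out_dir` plus the IC50 table, runs
#' the L1 feature selection and the route-specific gene scoring, combines
#' with the optional literature score table, and writes
#' `mediators_<route>.tsv` (and `route_comparison.tsv` when both routes
#' ran).
#'
#' @inheritParams stage_subpathway
#' @return Named list of mediator tables, invisibly.
#' @export
stage_mediators <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dat <- read_omics_matrices(cfg$inputs$multiomics)
  prep <- .prepare_ic50(dat$ic50, cfg$mediators$log_ic50)
  literature <- if (!is.null(cfg$inputs$literature)) {
    read_literature_scores(cfg$inputs$literature)
  } else {
    NULL
  }
  route <- cfg$embedding$route
  out <- list()
  if (route %in% c("tensor", "both")) {
    C_c <- read_wide_matrix(file.path(out_dir, "C_c.tsv"))
    C_g <- read_wide_matrix(file.path(out_dir, "C_g.tsv"))
    sel <- lasso_select(C_c, prep$y[rownames(C_c)],
                        cv_folds = cfg$mediators$cv_folds,
                        seed = derive_seed(cfg$seed, 4),
                        target_transform = prep$transform)
    med <- combine_scores(tensor_gene_scores(C_g, sel), literature,
                          w = cfg$mediators$w)
    .write_tsv(med, file.path(out_dir, "mediators_tensor.tsv"))
    out$tensor <- med
  }
  if (route %in% c("autoencoder", "both")) {
    ae <- readRDS(file.path(out_dir, "autoencoder_model.rds"))
    sel <- lasso_select(ae$z, prep$y[rownames(ae$z)],
                        cv_folds = cfg$mediators$cv_folds,
                        seed = derive_seed(cfg$seed, 5),
                        target_transform = prep$transform)
    med <- combine_scores(autoencoder_gene_scores(ae, sel,
                                                  cfg$mediators$top_fraction),
                          literature, w = cfg$mediators$w)
    .write_tsv(med, file.path(out_dir, "mediators_autoencoder.tsv"))
    out$autoencoder <- med
  }
  if (length(out) == 2) {
    common <- intersect(out$tensor$gene, out$autoencoder$gene)
    comp <- data.frame(
      n_tensor = nrow(out$tensor), n_autoencoder = nrow(out$autoencoder),
      n_common = length(common),
      rank_spearman = if (length(common) >= 3) {
        stats::cor(match(common, out$tensor$gene),
                   match(common, out$autoencoder$gene), method = "spearman")
      } else {
        NA_real_
      })
    .write_tsv(comp, file.path(out_dir, "route_comparison.tsv"))
  }
  invisible(out)
}

#' Stage 4: time-bounded network and regulatory paths
#'
#' Consumes the sub-pathway and mediator outputs in `out_dir` plus the GRN
#' and PIN edge tables, rebuilds the perturbed sub-pathways from the stored
#' edge table, runs greedy labeled influence maximization over TF seeds and
#' extracts regulatory paths from each selected TF to each sub-pathway.
#' Writes the network exports, `im_seeds.tsv` and `paths.tsv`.
#'
#' @inheritParams stage_subpathway
#' @return List with the network, IM seed table and paths, invisibly.
#' @export
stage_network <- function(config, out_dir) {
  cfg <- read_run_config(config)
  vectors <- read_wide_matrix(file.path(out_dir, "vectors.tsv"))
  storage.mode(vectors) <- "integer"
  sp_edges <- utils::read.delim(file.path(out_dir, "subpathway_edges.tsv"),
                                stringsAsFactors = FALSE)
  sp_tab <- utils::read.delim(file.path(out_dir, "subpathways.tsv"),
                              stringsAsFactors = FALSE)
  # rebuild sub-pathway objects from the stage-1 tables
  subpathways <- list()
  for (i in seq_len(nrow(sp_tab))) {
    pw <- sp_tab$pathway[i]
    val <- sp_edges[sp_edges$pathway == pw, c("source", "target", "d", "peak",
                                              "valid")]
    pg <- pathway_graph(val[, c("source", "target")], name = pw)
    subs <- extract_subpathways(pg, val, min_edges = cfg$subpathway$min_edges)
    for (s in subs) {
      if (s$component_id == sp_tab$component_id[i]) {
        s$p_value <- sp_tab$p[i]
        subpathways[[length(subpathways) + 1]] <- s
      }
    }
  }
  med_file <- file.path(out_dir,
                        if (cfg$embedding$route == "autoencoder")
                          "mediators_autoencoder.tsv" else "mediators_tensor.tsv")
  mediators <- if (file.exists(med_file)) {
    utils::read.delim(med_file, stringsAsFactors = FALSE)$gene
  } else {
    NULL
  }
  grn <- read_edge_table(cfg$inputs$grn)
  pin <- read_edge_table(cfg$inputs$pin)
  net <- build_time_bounded_network(grn, pin, subpathways, vectors,
                                    mediators = mediators,
                                    delay_threshold = cfg$subpathway$delay_threshold,
                                    epsilon = cfg$network$epsilon)
  # targets are the sub-pathway nodes themselves (label priority may mark
  # some of them as mediators)
  sp_nodes <- intersect(unique(unlist(lapply(subpathways, `[[`, "genes"))),
                        net$nodes$name)
  seeds <- greedy_labeled_im(net, targets = sp_nodes, k = cfg$network$k,
                             n_sim = cfg$network$n_sim,
                             seed = derive_seed(cfg$seed, 6))
  paths <- list()
  for (tf in seeds$tf) {
    for (sp in subpathways) {
      paths <- c(paths,
                 extract_regulatory_paths(net, tf, sp,
                                          require_mediator = cfg$network$require_mediator,
                                          max_paths = cfg$network$max_paths))
    }
  }
  export_network(net, out_dir)
  .write_tsv(seeds, file.path(out_dir, "im_seeds.tsv"))
  .write_tsv(paths_table(paths), file.path(out_dir, "paths.tsv"))
  invisible(list(network = net, seeds = seeds, paths = paths))
}

#' Run the full pipeline
#'
#' Chains the four analysis stages (sub-pathway identification, multi-omics
#' embedding, mediator selection, regulatory network) on the inputs named
#' in the config, writing every intermediate table plus a `manifest.json`
#' (package version, config, derived seeds, config-file MD5). A stage
#' failure halts the run with the stage name in the error. Re-running with
#' an identical config and seed reproduces all outputs byte for byte.
#'
#' @param config Path to a YAML config or a nested list
#'   ([read_run_config()]).
#' @param out_dir Run directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  for (nm in c("timeseries", "multiomics", "grn", "pin")) {
    if (is.null(cfg$inputs[[nm]])) stop("config is missing input '", nm, "'")
  }
  if (length(cfg$inputs$pathways) == 0) stop("config names no pathway files")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log_msg("info", "run: stage subpathway")
  run_stage("subpathway", function() stage_subpathway(cfg, out_dir))
  log_msg("info", "run: stage embedding")
  run_stage("embedding", function() stage_embedding(cfg, out_dir))
  log_msg("info", "run: stage mediators")
  run_stage("mediators", function() stage_mediators(cfg, out_dir))
  log_msg("info", "run: stage network")
  run_stage("network", function() stage_network(cfg, out_dir))
  manifest <- list(
    package = "tempomics",
    version = as.character(utils::packageVersion("tempomics")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(as.list(vapply(1:6, function(i)
      derive_seed(cfg$seed, i), integer(1))),
      c("subpathway", "tensor", "autoencoder", "lasso_tensor",
        "lasso_autoencoder", "influence")),
    config = unclass(cfg),
    config_md5 = if (!is.null(attr(cfg, "config_path")))
      unname(tools::md5sum(attr(cfg, "config_path"))) else NA
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("info", "run complete: ", out_dir)
  invisible(out_dir)
}
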