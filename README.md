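# tempomics

Drug perturbations do not hit a cell all at once: a treatment switches genes
on and off in waves that travel along signalling pathways, and whether a
cell line responds to the drug at all is shaped by its multi-omics state
before treatment. **tempomics** implements both halves of that picture for
pharmacogenomic screens:

1. **Perturbed sub-pathway detection.** From control vs. drug-treated
   time-series expression (genes × time points × replicates), each gene
   gets a *differential time vector* v ∈ {−1, 0, +1}^T (under/unchanged/over
   at each time point, called with an empirical-Bayes moderated t-test).
   For a directed pathway edge N1 → N2 the lagged cross-correlation

       (v1 ⋆ v2)(n) = Σ_t v1(t) · v2(t + n),    v(t) = 0 outside 1..T

   is maximized over n; the argmax d = argmax_n (v1 ⋆ v2)(n) is the edge's
   propagation delay. Edges with d ≥ 0, d ≤ a delay threshold and a
   positive peak are *valid*; connected components with ≥ 3 valid edges are
   perturbed sub-pathways, scored by the summed peaks and tested with a
   permutation null that reassigns gene vectors from the whole-experiment
   pool.

2. **Multi-omics mediator genes.** Four gene-centric (cell line × gene)
   matrices — expression, copy number, promoter methylation, mutation —
   are embedded into a low-dimensional cell-line feature space either by
   CP/PARAFAC decomposition of the (cell × gene × omics) tensor,
   x_ijk ≈ Σ_f c_if g_jf o_kf, or by a late-integration autoencoder
   (per-omics encoders → shared bottleneck z → mirrored decoder). LASSO
   regression of IC50 on the embedding picks the drug-sensitivity-associated
   features; genes are mapped back through the gene factor matrix (tensor
   route) or by decoder activation of the selected latent units
   (autoencoder route), optionally blended with a literature relevance
   score.

3. **Regulatory paths.** GRN (TF → target) and PIN (gene–gene) edges that
   satisfy the same delayed-propagation rule are merged with the
   sub-pathway edges into a *time-bounded network*; each edge carries a
   propagation probability p = peak/T. Greedy labeled influence
   maximization under the independent-cascade model (cascades consume edge
   delays; activations beyond T−1 are discarded) ranks the TFs that best
   explain the perturbed sub-pathways, and the highest-probability simple
   paths TF → … → sub-pathway are reported.

A synthetic-data module plants recoverable ground truth for every stage
(propagating perturbations with known delays; low-rank multi-omics whose
factors drive IC50), so the whole pipeline is testable without any
external download.

## Worked example

```r
library(tempomics)

# a five-gene cascade TF1 -> G1 -> G2 -> G3 -> G4 with 40 inert bystanders
pw  <- pathway_graph(data.frame(source = c("TF1", "G1", "G2", "G3"),
                                target = c("G1",  "G2", "G3", "G4")))
sim <- pathway_graph(pw$edges, nodes = c(pw$nodes, sprintf("N%02d", 1:40)))
fx  <- generate_timeseries(sim, "TF1", delay_per_edge = 1, amplitude = 8,
                           noise_sd = 0.2, n_time = 5, n_rep = 3, seed = 1)

v     <- build_time_vectors(fx$control, fx$treated)
chain <- pathway_graph(data.frame(source = c("G1", "G2", "G3"),
                                  target = c("G2", "G3", "G4")), name = "chain")
res   <- find_perturbed_subpathways(chain, v, B = 999, seed = 2)
res$table
#>   pathway component_id n_edges statistic     p   fdr
#> 1   chain            1       3         6 0.001 0.001
```

The planted chain is recovered as one sub-pathway with three valid edges
(each with delay 1), a statistic of 6 (summed peak cross-correlations) and
the smallest p-value attainable at B = 999.

```r
mo  <- generate_multiomics(n_cell = 60, n_gene = 200, rank = 3,
                           causal_factors = 2, effect_size = 2,
                           noise_sd = 0.1, seed = 3)
cp  <- cp_decompose(assemble_tensor(mo$omics), R = 3, seed = 4, max_iter = 400)
cp
#> CP factors: rank 3 over 60 cell lines x 200 genes x 4 omics;
#>   rel. reconstruction error 0.2721 (206 sweeps)
sel <- lasso_select(cp$C_c, mo$ic50, seed = 5)
sel
#> L1 feature selection: 2/3 features non-zero at lambda 0.01692
head(combine_scores(tensor_gene_scores(cp$C_g, sel)), 3)
#>    gene omics_score best_feature  route omics_norm ... combined_score
#> 1 G0079  -0.3339819            3 tensor  1.0000000 ...      1.0000000
#> 2 G0068   0.2775820            3 tensor  0.9927007 ...      0.9927007
#> 3 G0112   0.2669248            3 tensor  0.9854015 ...      0.9854015
```

The LASSO keeps the embedding feature that carries the planted
IC50-driving factor (largest |coefficient|), and the top-ranked mediator
genes are the ones loaded most heavily on that factor (signed scores; the
global sign of a CP component is arbitrary, so ranking uses magnitude).

```r
net <- build_time_bounded_network(grn = data.frame(from = "TF1", to = "G1"),
                                  pin = data.frame(from = "G2", to = "G3"),
                                  subpathways = res$subpathways, vectors = v)
greedy_labeled_im(net, k = 1, n_sim = 2000, seed = 6)
#>    tf marginal_spread cumulative_spread
#> 1 TF1           1.518             1.518
extract_regulatory_paths(net, "TF1", res$subpathways[[1]])[[1]]
#> Regulatory path [chain#1]: TF1 -> G1 (score 0.8, cumulative delay 1)
```

TF1 is selected as the seed best spreading influence into the sub-pathway
(expected ≈1.5 of the 4 pathway genes activated within the observation
window), entering through G1 with edge probability 0.8 (= peak 4 / T 5).

The full pipeline — all four stages from TSV inputs to output tables plus a
reproducibility manifest — runs from a YAML config via `run_pipeline()`,
or from the shell through the thin CLI in `inst/cli/tempomics.R`
(subcommands `simulate`, `subpathway`, `embed`, `mediators`, `network`,
`run`).

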