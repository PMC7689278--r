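---
title: "Methods: time-resolved sub-pathway detection and multi-omics mediator discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved sub-pathway detection and multi-omics mediator discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Differential time vectors and the moderated t-test

The unit of evidence is the per-gene *differential time vector*
v ∈ {−1, 0, +1}^T: at each time point a gene is called over-, under- or
un-changed, treated vs. control, so downstream analysis works on the
direction of change rather than on expression magnitudes. Calls come from a
two-sample moderated t-test per time point: gene-wise residual variances
s²_g (df = n₁ + n₂ − 2) are squeezed toward a common prior under the scaled
inverse-chi-square model, with the prior degrees of freedom d₀ and scale
s₀² estimated by method of moments on log s² (digamma/trigamma matching;
the trigamma inverse is solved by Newton iteration). The statistic uses the
posterior variance (d·s² + d₀·s₀²)/(d + d₀) with d + d₀ degrees of
freedom. A gene is called ±1 when p < `p_cutoff` (default 0.05) **and**
|log-fold-change| > `lfc_cutoff` (default 1); expression is assumed already
log-scale and normalized. Degenerate inputs are handled explicitly: with a
single replicate per arm no variance is estimable and calling falls back to
the fold-change rule alone; when every variance is zero (noise-free
fixtures) a nonzero mean difference gets p = 0 and a zero difference p = 1.
Control-free designs are supported by comparing each time point to the
previous one (`vs_previous`, t = 1 stays 0) or to the first (`vs_initial`).

## 2. Cross-correlation, delays and the argmax tie-break

For an edge N1 → N2 the lagged cross-correlation
(v1 ⋆ v2)(n) = Σ_t v1(t)·v2(t+n) (zero outside 1..T) is scanned over
n ∈ [−(T−1), T−1]; the maximizing lag is the propagation delay d, and the
maximum itself the edge's peak. An edge is valid iff d ≥ 0 (simultaneous
change, d = 0, counts: only propagation *against* the edge direction is
disqualifying), d ≤ `delay_threshold`, and peak > 0 (a non-positive
maximum means there is no concordant overlap at all).

**Tie-breaking matters more than it looks.** The differential responses
this pipeline produces are typically *sustained*: a gene switches on and
stays on, giving step-like vectors. For a step pair whose onsets differ by
δ, the maximizing lags form the contiguous run between 0 and δ — the
overlap count is the same anywhere in that run. We therefore break ties
toward the **largest |n|, preferring the non-negative lag when magnitudes
tie**: this recovers δ (the quantity of interest) for sustained responses,
assigns a *negative* delay to reversed edges (whose run is {−δ, …, 0}), and
resolves the symmetric ±n case in the causal, forward direction. A
smallest-|n| rule would collapse every sustained pair to d = 0 and validate
reversed edges. For pulse-like vectors the maximum is generically unique
and the tie-break never fires.

`delay_threshold` defaults to ⌈T/2⌉: delays beyond half the observation
window cannot be distinguished from coincidence with so few time points.
Sub-pathways are weakly connected components of the valid-edge subgraph
with at least `min_edges = 3` edges ("more than two"); the bound is a flag
because a ≥ 2 reading is also defensible.

## 3. The permutation null

The pathway-level statistic is the sum of per-edge peaks. The null
reassigns to the sub-pathway's genes vectors drawn **without replacement
from the whole-experiment vector pool** — using the genome-wide pool
preserves the marginal sparsity of DEG calls, which a within-sub-pathway
shuffle would not. The statistic is recomputed on the fixed observed edge
set without re-applying the validity filter (the filter defines the edge
set; the null asks how surprising the observed concordance is on that
set), and p = (1 + #{perm ≥ obs})/(B + 1).

Because the statistic is integer-valued, its permutation distribution has
substantial tie mass, and a "≥"-counting p-value is **super-uniform by
construction**: P(p ≤ α) ≤ α, with a visible gap at conventional B. The
package's calibration test measures the p-value ECDF against the uniform
diagonal and documents this conservatism honestly; a mid-p correction
would remove it but would sacrifice the finite-sample validity guarantee,
so it is not applied. Benjamini–Hochberg FDR across sub-pathways is
reported alongside raw p.

## 4. CP/PARAFAC embedding

The four gene-centric matrices are stacked (fixed omics order: expression,
copy number, methylation, mutation) into a cell × gene × 4 tensor and
fitted as x_ijk ≈ Σ_f c_if g_jf o_kf by alternating least squares: each
mode is solved in closed form via the Khatri–Rao product and the Hadamard
product of Gram matrices (ridge 1e−12 for rank-deficient corners).
Numerical choices:

* **Multi-start.** ALS is prone to local optima; `n_init = 3` seeded
  random restarts are run and the fit with the lowest relative
  reconstruction error ‖X − X̂‖_F/‖X‖_F is kept.
* **Convergence.** Stop when the error improves by < `tol` (1e−8) between
  sweeps, warn at `max_iter`. A zero tensor returns zero factors with
  error defined as 0.
* **Scale and sign conventions.** All column scale is absorbed into the
  cell-line mode and the gene/omics columns are unit-normalized, so
  row-wise comparisons across the columns of C_g are on a common scale;
  each component is oriented so the largest-|entry| of its gene column is
  positive (CP components are otherwise sign-indeterminate).

No non-negativity constraint is imposed. The default rank (8 in the
pipeline config; 32 is a reasonable production value for genome-scale
matrices) is a capacity knob, not an estimate; the relative-error report
serves as a scree diagnostic, and tests use the planted rank.

## 5. The late-integration autoencoder

Each cell line is the concatenation x = (x₁…x_{4n}) of its four omics
vectors. Four omics-specific two-layer encoders produce h = (h₁…h₄), a
two-layer integration encoder maps h to the bottleneck z, and the decoder
mirrors the encoder. Hidden layers are ReLU. Two deliberate deviations
from an all-ReLU stack: the **bottleneck and the final reconstruction
layer are linear**. A ReLU bottleneck can die irrecoverably under gradient
descent (once z ≡ 0 for every sample no gradient reaches the encoder),
which we observed on small fixtures; a linear code removes that failure
mode without changing what z represents, and a linear output is required
for sign-unconstrained reconstructions. ReLU biases are initialized at
0.01 (He-scaled weights) so units start alive.

The loss is the mean squared reconstruction error plus λ·Σ‖W‖² — the
squared-norm (L2) reading of the regularizer, with an `penalty = "l1"`
flag preserving the absolute-value alternative; biases are never
penalized. Optimization is full-batch Adam (lr 1e−3, β = 0.9/0.999),
seeded and deterministic; optional plateau-based early stopping. The
production architecture (2048/1024 specific, 1024/256 integration) is the
default; tests use scaled-down stacks (e.g. 16/8 and 8/3) matched to
synthetic gene counts. Training aborts with diagnostics on a non-finite
loss.

## 6. Feature selection and mediator scoring

IC50 (log-transformed by default for concentration-scale inputs; the flag
`log_ic50: false` serves responses already on a log scale, including the
synthetic fixtures) is regressed on the embedding (C_c or z) with an L1
penalty. Features are standardized internally and coefficients reported on
that scale; the penalty is chosen by cross-validation (leave-one-out below
2×folds cell lines), and a single-value `lambda_grid` bypasses CV for
direct fits. Non-zero coefficients define the selected features.

*Tensor route.* For each gene the most related feature is the row-wise
argmax of |C_g(g, f)| — relatedness magnitude, not signed loading: CP
orientation is arbitrary, and a signed argmax would make genes with
negative loadings on the causal factor invisible. A gene is emitted iff
its argmax feature is selected, scored by the signed product
C_g(g, f*)·coef(f*) and ranked by its magnitude.

*Autoencoder route.* Each selected latent unit is activated as a one-hot
code, decoded, and the absolute output summed over a gene's four omics
slots; scores aggregate over selected features weighted by |coef| (the
magnitude-weighted analogue of the tensor route's product), and the top
5% of genes are emitted by default.

*Combination.* Omics and literature scores are rank-normalized to [0, 1]
(ties averaged; invariant to monotone transforms of either raw score) and
blended as w·omics + (1−w)·literature, w = 0.5 by default; genes missing
from the literature table contribute 0 and an absent table reduces to the
omics ranking. This transparent weighted-rank scheme stands in for
proprietary literature-mining scores, which are accepted as a plain
two-column table.

## 7. The time-bounded network and influence maximization

GRN edges stay directed; PIN edges are instantiated in both directions and
each direction validated independently by the same delay rule as pathway
edges (d ∈ [0, threshold], peak > 0); sub-pathway edges import their
existing validations. Edge probability is p = peak/T — the normalized
maximal concordance, floored at ε = 0.01 and multiplied by a PIN
confidence when present (clipped to [0, 1]); a constant-p override exists
for diagnostics. Parallel edges from several sources keep the most
propagative copy. Node labels are exclusive with priority
TF > mediator > pathway_gene > other.

Influence spreads under the independent cascade: each edge fires once with
probability p, firing consumes the edge's delay, and activations arriving
after T−1 (the observable window — the operational meaning of
"time-bounded") are discarded. Spread is estimated by Monte-Carlo
live-edge sampling with delay-weighted shortest paths; the greedy seed
selector shares one set of cascade draws across iterations and candidates
(common random numbers), counting only target-labeled nodes — the
"labeled" restriction. The greedy routine inherits the usual (1 − 1/e)
guarantee on monotone submodular spreads, checked against brute force on
small deterministic instances. Regulatory paths are enumerated by
depth-first search from a TF, ending at the *first* entry into the
sub-pathway's node set, pruned by the delay budget; scores are products of
edge probabilities (minimal −log p cost), ties break to shorter, then
lexicographically earlier paths. Exhaustive enumeration is exponential in
the worst case but the delay budget and first-entry truncation keep it
small at the network sizes this pipeline produces; `terminator_proteins()`
(out-degree-0 nodes) supports comparing where cascades end.

## 8. What the synthetic data does and does not emulate

`generate_timeseries()` plants an additive, persistent (step-like)
perturbation that starts at source genes and moves one edge per
`delay_per_edge` time points, over a per-gene constant baseline with
i.i.d. Gaussian noise — the cleanest realization of the propagation model
above. `generate_multiomics()` draws CP factors (Gaussian cell/gene
factors, positive omics weights), adds Gaussian noise, squashes the
methylation slice to [0, 1] logistically and thresholds the mutation slice
at its 80th percentile (sparse binary, like real mutation calls), and
makes log-IC50 linear in the causal cell-line factor columns.

Real data differ in ways these fixtures deliberately omit: transient
(pulse) rather than sustained responses, heteroskedastic and correlated
noise, batch structure, feedback loops violating the acyclic propagation
picture, non-linear genotype–phenotype links, missing values, and
measurement platforms' mean–variance relationships. Passing the planted
recovery suites therefore demonstrates correctness of the algorithms under
their own assumptions, not performance on any real screen.

Generator defaults are study conditions, not dials: recovery tests use
noise-free or low-noise settings (noise_sd ≤ 0.2 on amplitude-8 signals;
multi-omics noise_sd 0.1 with effect size 2 over 60 cell lines × 200
genes) and were fixed together with the test design.

## 9. Problem sizes and reproducibility

The shipped suites run at deliberately small scale: 1,000 random vector
pairs for the delay oracle; 50 noise-free planted fixtures; 200
calibration trials at B = 499; CP fits up to 60 × 200 × 4; autoencoder
training on 5–12 cell lines with 16/8–8/3 stacks for ≤ 2,500 full-batch
epochs; 20,000 cascade simulations on closed-form chains; brute-force IM
and path oracles on ≤ 8–10-node graphs; and an end-to-end run on a
5-gene cascade with 40 bystanders plus a 40 × 60 multi-omics block. Every
stochastic step takes an explicit seed, derives child seeds
deterministically, and restores the caller's RNG state; two pipeline runs
with the same config and seed produce byte-identical outputs, which the
determinism suite verifies file by file.

## 10. Known limitations

* Edge relation labels (activation/inhibition) are carried through but do
  not enter validity; signed semantics would refine both the
  cross-correlation (expected anti-correlation under inhibition) and the
  cascade model.
* The permutation p-value's discreteness makes it conservative (see §3).
* The autoencoder is a small dense implementation intended for the
  moderate dimensionalities of gene-centric matrices; it is full-batch and
  CPU-bound by design, with no minibatching or GPU path.
* CP rank and the latent dimension are user choices; no automatic rank
  selection is attempted.
* KGML parsing is minimal (gene-type entries and their relations only),
  meant for locally stored files rather than as a full KGML implementation.
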