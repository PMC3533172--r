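---
title: "Methods: stress-series scoring, ordination and network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-series scoring, ordination and network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

## Scope and model of the data

`stressnet` analyses multi-condition abiotic-stress time courses of the kind
produced by large *Arabidopsis* expression atlases: several stress treatments
(heat, cold, salt, osmotic, drought, UV-B, wounding, genotoxic, oxidative)
sampled at a handful of time points between 0.5 and 24 h in shoot and root
tissue, each with control arrays at the same tissue and time point. All
expression values are assumed normalized and on log2 scale, so a fold change
is a difference of values and never a ratio. The pipeline runs per tissue:

1. **Scoring** — rank genes by the strength of their stress response,
2. **Ordination** — summarize which conditions reprogram the transcriptome most,
3. **Network inference** — reconstruct gene–gene dependence among the
   top-scoring genes,
4. **Interpretation** — hub genes, ego subnetworks, set overlap, enrichment.

## The stress score

For one tissue and one stress, the log fold change of gene $g$ at time $t$ is
the difference of replicate means,
$\mathrm{LFC}(g,t) = \overline{\log_2 x}_{\text{stress},t} -
\overline{\log_2 x}_{\text{control},t}$, and the per-stress score is

$$S_{\text{stress}}(g) \;=\; \sum_{t} \bigl|\mathrm{LFC}(g,t)\bigr|.$$

Summing *absolute* fold changes is deliberate: a gene induced early and
repressed late responds strongly, and a signed sum would cancel the two
phases. (A signed-sum variant is available via `stress_score(absolute =
FALSE)` for comparison; with it, transient biphasic responders score near
zero.) The per-gene **global score** is the median of $S$ across stresses, so
a gene must respond to at least half of the stress panel to rank highly —
this is what makes the top set a set of *ubiquitous* stress responders rather
than condition specialists. Ranks are dense (rank 1 = largest score) and all
selection ties break lexicographically by gene id, so every output is
reproducible byte for byte.

A second ranking, `median_fold_change_ranks()`, summarizes each arm by its
median expression over the whole time course before taking differences, then
ranks per stress by $|\mathrm{LFC}_{\mathrm{med}}|$ and reports the median of
the per-stress ranks as a consensus. It compresses sustained responses and
transient responses differently from the summed score, which is why both are
reported rather than one replacing the other.

## Between-group analysis

`between_group_analysis()` is an ordination of *group means*: genes are
centered across all samples, the group-mean matrix is formed, each group row
is weighted by $\sqrt{n_g/N}$ (so unbalanced groups do not dominate), and the
weighted matrix is decomposed by SVD. Samples and genes are projected onto
the resulting axes. Two consequences worth stating plainly:

* the per-axis `variance_fraction` is the fraction of **between-group
  inertia** — the quantity this ordination actually decomposes — not of the
  total sample variance;
* with every sample its own group the method reduces exactly to PCA of the
  centered matrix, which the test suite verifies to $10^{-8}$.

Axis signs are fixed by making the largest-magnitude gene loading of each
axis positive. The default grouping is condition within one tissue;
`group_separation_summary()` then reports the Euclidean distance from each
stress centroid to the control centroid on the leading axes — the larger the
displacement, the stronger the transcriptome reprogramming under that
stress.

## Mutual information estimation

Expression profiles are discretized per gene (equal-frequency bins by
default, `ceiling(sqrt(n_samples))` bins) and MI is estimated in bits as
$I(X;Y) = H(X) + H(Y) - H(X,Y)$ with the empirical, Miller–Madow or
James–Stein-shrinkage entropy estimator, clamped at zero.

The empirical estimator's bias under independence is approximately
$(b_x-1)(b_y-1) / (2 n \ln 2)$ bits for $b$ bins and $n$ samples. This grows
quickly with the bin count: at $n = 120$ samples and the default 11 bins it
is on the order of half a bit, so *every* gene pair shows substantially
positive MI. Two design choices deal with this:

* methods that compare MI values within the matrix (MRNET's redundancy
  penalty, CLR's per-gene z-scoring, ARACNE's triangle rule) are unaffected
  by a uniform bias shift and are run on the raw matrix;
* wherever an *absolute* significance statement is needed,
  `permutation_null()` estimates the null MI distribution by permuting one
  gene of a random pair (destroying dependence, preserving both marginals),
  and the $(1-\alpha)$ empirical quantile of that sample is the critical
  value. `infer_network()` applies this filter before MRNET and ARACNE
  (`mi_alpha = 0.05`, disable with `NULL`); C3NET's first step is the same
  idea by construction.

Tests that assert numeric bias bounds pin `n_bins = 8`, where the bound
above is 0.018 bits at $n = 2000$; at the $\lceil\sqrt n\rceil$ default
those absolute bounds do not hold and only rank-based properties are
meaningful.

## Inference algorithms

All methods return symmetric, self-loop-free networks with nonnegative
weights and lexicographic tie-breaking throughout.

* **MRNET** — for each target, greedy maximum-relevance/minimum-redundancy
  forward selection over all candidates; a candidate's score when selected is
  $\mathrm{MI}(i,j) - \frac{1}{|S|}\sum_{k \in S}\mathrm{MI}(j,k)$. The edge
  weight is the larger of the two directional scores and only positive
  weights are kept.
* **CLR** — MI z-scored against each gene's background (population-variance
  convention), negative z clamped; edge weight
  $\sqrt{z_i(j)^2 + z_j(i)^2}$.
* **ARACNE** — all positive-MI edges, then simultaneous removal of every
  edge that is the strict minimum of a triangle beyond tolerance `eps`
  (default 0; ties survive). The scan-then-remove order makes the result
  independent of traversal order.
* **C3NET** — zero all MI at or below the permutation-null critical value,
  then keep an edge only if it is the row maximum of one of its endpoints:
  at most one nominated edge per gene, hence never more edges than genes.
* **Relevance network** — plain strict thresholding of the MI matrix.
* **Correlation / partial correlation** — Pearson or Spearman thresholding;
  the partial-correlation filter proposes edges above a high threshold and
  removes edge $(i,j)$ if some common neighbour $k$ drives the first-order
  partial correlation
  $r_{ij\cdot k} = (r_{ij} - r_{ik} r_{jk})/\sqrt{(1-r_{ik}^2)(1-r_{jk}^2)}$
  below a low threshold — the classic indirect-edge signature.

MRNET, ARACNE and the enrichment tail probabilities are cross-checked in the
test suite against independent brute-force re-implementations (full greedy
trace, exhaustive triple enumeration, binomial-coefficient sums) on
exhaustive small grids.

### Hubs on dense weighted networks

MRNET's "keep any positive score" rule emits a halo of near-zero-weight
edges around the real structure (a score is positive whenever relevance
exceeds average redundancy by any amount, which for null pairs happens about
half the time). Raw degree on such a network is mostly noise. The pipeline
therefore detects hubs on the **nominated-edge backbone**
(`network_backbone()`): an edge survives iff it is the strongest incident
edge of at least one endpoint — C3NET's maximal-edge principle applied to
the inferred weights. Degree on the backbone counts how many partners
*nominate* a gene as their strongest association, which is exactly the
notion of a coordinating regulator that hub analysis is after. Hub ranking
is by degree, then weighted degree, then gene id.

## The synthetic stress study

`simulate_experiment()` emulates the study design, not array physics. With
defaults: 100 genes, 9 stresses × 6 time points (0.5–24 h) × 2 tissues × 2
replicates = 240 arrays plus an embedded ground-truth network of 5 hub
regulators with 5 targets each.

* **Baselines** are drawn once per gene from $N(8, 1)$ log2 units.
* **Drivers** (all hubs plus free genes up to `responsive_fraction`, default
  0.1) respond to every stress with a transient pulse
  $e_g\,(t/t_p)e^{1-t/t_p}$, peak time drawn from the time grid and signed
  amplitude $\pm 2$ log2 units redrawn per stress. Drawing the driver set
  once per tissue (rather than per stress) makes the responsive genes
  ubiquitous responders, which is the population the global median score is
  designed to find.
* **Propagation**: in each stress sample a target receives
  `sign * strength` times its regulator's *realized* response — pulse plus
  the regulator's stochastic deviation in that sample — plus its own noise,
  with strengths uniform on [0.5, 1]. Propagating the realized value rather
  than the noiseless pulse matters: it makes the regulator an observed
  parent in the Markov sense, so two targets of one hub are conditionally
  independent given the hub, and the data-processing inequality that ARACNE
  and MRNET exploit actually holds in the generated data. (With noiseless
  propagation, a strength-1 target is statistically indistinguishable from
  its regulator and no method can identify the hub.)
* **Tissues** re-use hubs and targets but re-draw free drivers with 10%
  overlap by default; measurement noise is $N(0, 0.5)$ log2 units per array,
  optionally with exchangeable across-gene correlation (`background_corr`).

All randomness flows from a single seeded stream consumed in a fixed loop
order, so one integer seed reproduces every array byte for byte.

What the generator does *not* emulate — probe-level artifacts, normalization
residue, batch structure, non-linear regulation, feedback, autocorrelated
kinetics beyond one pulse — bounds what green tests mean: they demonstrate
the algorithms' correctness and their recovery behaviour under the declared
dependence structure, not performance on real arrays.

## Numerical conventions and degenerate inputs

* Constant genes: correlation defined as 0 with a warning; discretization
  puts all samples in bin 0; CLR rows with zero spread get z = 0.
* A conditioning gene perfectly correlated with an endpoint is skipped (with
  a warning) in the partial-correlation filter rather than dividing by zero.
* Medians over an even number of stresses are midpoint means.
* Quantiles of permutation nulls use the inverse-ECDF convention
  (`type = 1`).
* All argmax ties anywhere in the package break lexicographically by gene
  id.

## Problem sizes

The shipped tests and the acceptance script use 20 simulation replicates of
the 100-gene, 240-array design, 2000-sample Gaussian chains for the
indirect-edge properties, and exhaustive oracle comparisons on 3–6-gene
matrices; the full suite completes in well under a minute on one core. The
same code paths scale to atlas-sized inputs (the MI matrix is $O(G^2 n)$,
MRNET $O(G^3)$); for genome-wide work one runs scoring first and infers
networks on the top set, exactly as the pipeline does.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
truth <- generate_ground_truth(cfg)
sim <- simulate_experiment(cfg, truth)

asm <- abiotic_stress_matrix(sim$experiment, "shoot")
responsive <- rownames(sim$labels$shoot)[rowSums(sim$labels$shoot) > 0]
top <- select_top_bottom(asm, length(responsive))$top

shoot <- subset_samples(sim$experiment, tissue = "shoot")
net <- infer_network(shoot$values[top, ], "mrnet", seed = 1)
hub_genes(network_backbone(net), 5)
recovery_metrics(net, truth)
```
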