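---
title: "Topological clustering with graph-based stochastic SOMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological clustering with graph-based stochastic SOMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsomata)
```

## The problem

Dissociated single-cell (and laser-microdissected mini-bulk) transcriptomes
lose the spatial or temporal arrangement of the cells. Often, however, a
*coarse* picture of that arrangement is known: which tissue layers touch,
which developmental stages succeed each other, which cell types derive from
which. `gsomata` exploits exactly this level of prior knowledge. The user
supplies a **topology graph** whose vertices are cell domains and whose
edges mark physical adjacency or developmental succession, and the package
searches for the gene subset whose expression best reproduces that topology
when cells are clustered onto the graph. The genes in the winning subsets —
*topology discriminator genes* — are the scientific output: genes whose
expression gradients carry the tissue architecture, which need not coincide
with the top differentially expressed marker genes.

## Clustering model

The clustering engine is a batch-learning self-organizing map whose mapping
layer is the topology graph itself: one centroid vector $m_i$ per vertex,
over the currently selected genes. Per learning step every cell $x_j$ is
assigned to its best matching unit $c_j = \arg\min_i \lVert x_j - m_i
\rVert$, and all centroids are replaced by neighborhood-weighted means

$$m_i \leftarrow \frac{\sum_j h_{c_j i}\, x_j}{\sum_j h_{c_j i}}, \qquad
h_{ci} = \exp\!\left(-\,\frac{u \cdot d_G(v_c, v_i)^2}{2\sigma^2(t)}\right),$$

where $d_G$ is the shortest-path edge count between vertices and $u \sim
\mathrm{Uniform}[0.5, 1)$ is drawn fresh for every (cell, vertex) weight in
every step. The random factor keeps the map from freezing into local minima
late in learning, when $\sigma(t)$ is small — the map retains a Gibbs-like
ability to rearrange. The batch form makes the result independent of cell
order; an online (per-sample) variant is deliberately not implemented.

Numerical choices, all exposed as arguments:

* $\sigma(t)$ decays exponentially from $\sigma_0$ = the largest finite
  graph distance (a radius proxy, so learning starts with global smoothing)
  to $\sigma_T = 0.3$ (near-indicator weights) over `som_steps` (default
  200 for a standalone fit; search-internal fits use smaller values, see
  below).
* Unreachable vertex pairs on disconnected mapping layers get the sentinel
  distance $|V|$ — one more than any achievable path length — so weights
  stay finite and positive and the batch denominator can never vanish.
* BMU ties break to the lowest vertex index; centroids are initialized
  uniformly inside each gene's observed range.

With the stochastic factor pinned and $\sigma$ near-indicator, one batch
step reduces exactly to a Lloyd k-means step; the test suite asserts this
equivalence to $10^{-10}$ against `stats::kmeans`.

## Scoring a clustering

Two complementary criteria are combined as $\mathrm{Score} =
\mathrm{Accuracy} + a\cdot\mathrm{ARI}$ with $a = 1$ by default.

* **Pairwise adjacency accuracy**: over all $\binom{n}{2}$ cell pairs, the
  fraction whose predicted domain pair has the same adjacency-matrix state
  as its true domain pair. Same-domain pairs read the zero diagonal, so
  large domains make this term generous; it is the only term that sees the
  graph, and it is invariant under graph automorphisms.
* **Adjusted Rand index** between the predicted and true partitions,
  ignoring the graph. The degenerate $0/0$ case (e.g. both partitions a
  single cluster) is defined as 1 when the partitions are identical up to
  relabeling and 0 otherwise — the conventional choice.

Accuracy is computed from the domain-by-vertex contingency table rather
than by pair enumeration, which makes it $O((mk)^2)$ instead of $O(n^2)$;
brute-force pair counting serves as the oracle in the tests.

## Allocation optimization

On unstructured topologies the map often gets the *memberships* right but
parks clusters on the wrong vertices: high ARI, low accuracy. A
simulated-annealing pass therefore swaps whole clusters between vertices,
leaving memberships — and hence the ARI — untouched. Per step the post-swap
accuracy of every vertex pair is computed; a pair is drawn with probability
$\propto \exp(z)^c$ where $z$ standardizes the post-swap accuracies and $c
= \sqrt{m/2}$; the swap is adopted with probability 1 if it does not hurt,
else $\exp(-\Delta f / T_t)$, with $T_t$ decaying exponentially from 1 to
0.001. Standardization uses the population (divide-by-$m'$) SD; a flat
accuracy profile falls back to uniform selection. The best allocation seen
is returned; accepted centroids are swapped alongside. The pass runs once
after SOM learning (default 100 steps standalone, 20 inside searches); for
up to five clusters the tests compare its result against the exhaustive
optimum over all cluster-to-vertex permutations.

## Gene-set search

The search objective is the clustering score of a full fit (SOM learning +
allocation + scoring) on the candidate gene subset.

1. **Prefilter**: keep genes with (log-scale) expression above 1.0 in at
   least two cells and across-cell SD above 0.05.
2. **Shadow-feature preselection**: iteratively grow a random forest
   (via `ranger`) on the genes plus per-gene permuted "shadow" copies;
   genes whose importance beats the best shadow significantly more often
   than chance (binomial test, $p < 0.01$) are confirmed, significantly
   less often rejected. Confirmed plus still-tentative genes form the
   candidate pool.
3. **Replica-exchange MCMC**: each replica starts from a uniform random
   subset of `n_init` = 10 genes. Per step, all unseen single-gene
   additions and removals are scored by full fits; one candidate is chosen
   by the standardized softmax with $c = \sqrt{N/2}$ and adopted or
   rejected by the annealing rule with $\Delta f = -(s_x - s_{best})$.
   Every evaluated subset is registered and never re-evaluated within a
   run; if the whole neighborhood is exhausted, one random one-gene swap
   replacement is proposed instead. Every `exchange_interval` = 10 steps,
   adjacent replicas on a geometric temperature ladder (0.005 cold to 0.5
   hot across 8 replicas) attempt to exchange their current sets with
   probability $\min(1, \exp((E_i - E_j)(1/T_i - 1/T_j)))$, using the
   negated score as energy so good sets migrate to cold replicas.

Choices the method description leaves open, fixed here as package defaults:
the initial subset size (10), the ladder and exchange interval (above,
alternating even/odd adjacent pairing), the annealing schedule inside each
replica (the same exponential 1 to 0.001 used by the allocation pass), and
the per-evaluation fit seeds (derived deterministically from the run seed,
step and candidate index, so a search is exactly reproducible). The best
set is updated whenever any evaluated candidate strictly improves the best
score. A `max_candidates` cap (off by default) uniformly subsamples the
neighborhood when the pool is large; the full-fit evaluation of every
candidate is the dominant cost, so the cap trades thoroughness for time
transparently.

## Multi-run protocol and downstream analyses

A production run repeats the search ten times, each on a fresh random
downsample of at most ten cells per domain, and calls genes appearing in at
least three of the ten best sets **consensus** discriminator genes. A final
full-data fit on the consensus set yields the reported assignment.
Downstream utilities:

* **Virtual knockout**: remove knockout sets from the consensus genes and
  re-cluster 100 times with the same seeds for every set (rows are paired);
  rank by ascending mean score. The search is not re-run per knockout —
  rankings measure how much the *fixed* consensus set depends on each gene.
* **Hypergeometric enrichment**: upper-tail `phyper` p-values per annotation
  term, raw (as the primary output) plus a Benjamini–Hochberg column.

## Synthetic benchmark generator

Because the real datasets behind the method are external downloads, the
package ships a seeded generator that emulates their structure: cells spread
evenly over the modules of a backbone graph (`linear`, `cycle`,
`bifurcating`, `branching`, `disconnected`), with three gene classes —
per-module markers whose mean decays geometrically (factor 0.4 per edge)
with graph distance, gradient genes whose log-mean falls linearly with
distance from a root module (roots cycling over modules so the whole graph
is covered), and module-independent noise genes. Counts are negative
binomial (dispersion 0.2) around these means with ±20% library-size jitter
and 10% log-normal biological noise. Defaults (500 cells, 3 markers per
module, 40 gradient + 40 noise genes, peak mean 150 versus baseline 3
counts) were chosen so that standard preprocessing separates the modules
cleanly and adjacent-module centroid correlations fall inside the 0.70–0.85
band used for graph derivation — i.e., a *benchmark of topology recovery*,
not of transcription kinetics. The generator deliberately omits regulatory
dynamics, doublets, batch effects and ambient contamination; passing the
recovery tests therefore demonstrates correctness of the machinery on
well-behaved data, not robustness to every artifact of real scRNA-seq.

The **topology derivation** mirrors a standard workflow: top-variance gene
selection, per-gene scaling, PCA (10 components), a k-nearest-neighbor
graph (k = 15), Louvain communities with the resolution tuned until the
cluster count lies within a requested range, then edges between clusters
whose all-gene log-space centroid Pearson correlation reaches the threshold
(default 0.75). A consistency check requires the derived graph to be
connected for single-component backbones and disconnected otherwise; if the
requested threshold fails, the band 0.70–0.85 is scanned (nearest to the
default first), and failure reports the full correlation spectrum. One
known limit: for the cycle backbone a single sub-threshold ring edge leaves
a connected path that passes the consistency check, so exact ring recovery
is seed-dependent even though the derived graph remains a valid input for
the recovery benchmark.

**Misspecification experiments** flip each unordered vertex pair of the
derived graph independently with probability $p$ (resampling up to 1000
times to respect the backbone's connectivity class), then re-run the search
against the corrupted graph and summarize per-graph score maxima with 95%
confidence intervals.

## Problem sizes and budgets

Standalone fits default to 200 SOM steps and 100 allocation steps; a
production search to 1000 MCMC steps and 8 replicas. The test suite and the
bundled acceptance script run the same code paths at benchmark scale —
500-cell datasets, searches of 150 steps × 3 replicas (recovery) and 30
steps × 2 replicas (misspecification), search-internal fits of 30 SOM and
20 allocation steps, and a 12–16 candidate cap per step — sizes chosen so a
complete benchmark finishes on a single desktop core while leaving the
search enough budget to reach perfect scores on the clean synthetic data.

## Limitations

* The method is not unsupervised: it needs domain labels and a topology
  guess, and its accuracy term rewards reproducing that guess.
* Scores across topologies of different density are not directly
  comparable (denser graphs make adjacency agreement easier).
* The Boruta-style preselection inherits random-forest blind spots: genes
  informative only through interactions across distant domains may be
  rejected before the search sees them.
* Stochastic scores: two fits of the same subset with different seeds can
  differ, so reported "best" values are maxima over seeded repetitions —
  the multi-run consensus protocol exists precisely to stabilize the gene
  lists.
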