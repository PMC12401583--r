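---
title: "Methods: network proximity, separation and module significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network proximity, separation and module significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprox)
```

## The model

netprox treats the interactome as an undirected simple graph with optional
positive edge weights. Disease genes and drug targets are node sets on this
graph, and every question the package answers has the same shape: *is the
observed configuration of a set (or pair of sets) more extreme than that of
random sets matched on size and degree structure?*

Three raw statistics are supported.

**Module localization.** The size of the largest connected component (LCC)
of the subgraph induced by a set $A$. Disease genes that participate in a
common process tend to form a connected neighbourhood, so an LCC much larger
than degree-matched chance is evidence of a disease module.

**Proximity.** The average minimum shortest path length (AMSPL)
$$P(A,B) = \frac{1}{|A|}\sum_{a \in A}\min_{b \in B} d(a,b),$$
with $A$ the *source* set averaged over. This is asymmetric:
$P(A,B) \ne P(B,A)$ in general. The package fixes the orientation so that
the first argument is the source set — for drug–disease questions, pass the
drug-target set first. A symmetric variant
$$P_s(A,B) = \frac{\sum_{a}\min_b d(a,b) + \sum_{b}\min_a d(b,a)}{|A|+|B|}$$
is available wherever the asymmetry is unwanted; it is invariant under
swapping $A$ and $B$ for any symmetric metric.

**Separation.**
$$s_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2},$$
where $d_{AB} = P_s(A,B)$ and $d_{AA}$ is the mean within-set
nearest-neighbour distance (0 for singletons by convention). Negative
$s_{AB}$ means the two sets' neighbourhoods interpenetrate; $s(A,A) =
-d_{AA}$ exactly, which the tests assert as an identity.

Each raw statistic is reported with the null mean $\mu$, the null standard
deviation $\sigma$ (population form, $n$ in the denominator — the null
samples *are* the ensemble being described, not an estimate of a larger
one), $z = (\text{raw}-\mu)/\sigma$, and an add-one empirical p-value
$p = (1 + \#\{\text{as-or-more extreme}\})/(n+1)$, which can never be 0 and
is uniform on $\{1/(n+1), \dots, 1\}$ when the observation is itself a null
draw — a property the acceptance tests verify by simulation. Proximity and
separation use the lower tail by default (closer/more overlapping than
random); LCC uses the upper tail.

## Distance metrics

All statistics read from a precomputed all-pairs `distance_matrix`, computed
once and cached to disk, because a screen of hundreds of set pairs re-reads
the same distances millions of times. Four metrics are built in:

- **Shortest path** — hop counts on unweighted graphs, minimal weight sums
  (Dijkstra) on weighted ones. Unreachable pairs are `Inf`, never a sentinel.
- **Random walk with restart (RWR)** — a walker restarts at the seed $p$
  with probability $r$, otherwise steps with probability proportional to the
  edge weight. With row-stochastic transition matrix $W$ the visiting
  distribution is $\pi(p) = r\,(I - (1-r)W^\top)^{-1} e_p$ and
  $d(p,q) = -\ln \pi(p)_q$ for $p \ne q$; the diagonal is forced to 0. The
  matrix is asymmetric and finite within a connected component. Default
  $r = 0.15$, the conventional restart used in network-biology diffusion.
- **Degree-biased random walk** — identical machinery with
  $W_{i \to j} \propto w_{ij}\,k_j^{\beta}$ row-normalized. $\beta = 0$
  reduces exactly (to $10^{-12}$, tested) to the unbiased walk; $\beta > 0$
  attracts the walker to hubs. Default $\beta = 1$. On a regular graph the
  bias cancels and the output is independent of $\beta$.
- **Communicability** — $\xi(p,q) = \sqrt{G_{pp} + G_{qq} - 2G_{pq}}$ with
  $G = e^{A}$ the matrix exponential of the (weighted) adjacency matrix.
  This is a true Euclidean metric with zero diagonal. Weighted adjacencies
  are exponentiated without normalization, so very large weights can
  overflow; rescale weights first if your network carries unbounded scores.

Both closed-form anchors — $d(a,b) = \ln 3$ for RWR at $r = 1/2$ on a single
edge, and $\xi(a,b) = \sqrt{2/e}$ for communicability on the same graph —
were derived by hand from the $2\times 2$ systems and are asserted to
$10^{-9}$.

Custom metrics plug in as a function `g -> distance_matrix`; the result is
validated against the container invariants (square, nonnegative, zero
diagonal, symmetry flag consistent), so a broken plug-in fails at
construction rather than corrupting downstream z-scores.

The disk cache is a small versioned binary format (magic `NMDM1`, metric
name, JSON-encoded parameters, node-id table, row-major 64-bit floats). The
round trip is bit-identical, including infinities; truncated or
wrong-magic files error without partial results.

## Null models

Z-scores are only as meaningful as the ensemble behind them. The package
draws random node sets matched to the observed set under:

- **Perfect degree match** — each member replaced by a uniform draw from the
  nodes of identical degree.
- **Logarithmic (degree) binning** — nodes are sorted by degree and
  consecutive distinct degree values accumulate greedily into a bin until it
  holds at least `min_bin_size` nodes; a trailing undersized bin merges
  backward. Members are replaced by draws from their bin. The default
  `min_bin_size = 100` suits interactome-scale heavy-tailed degree
  distributions, where exact matching is impossible for high-degree hubs
  that are unique in their degree class; tests use small values.
- **Strength binning** — the same greedy rule on the sum of incident edge
  weights; identical to degree binning on unweighted graphs (asserted
  bin-for-bin and draw-for-draw).
- **Uniform** — any node.
- **Custom** — a user sampler `(g, size) -> ids`, validated for size,
  distinctness and membership.

Within one sample all draws are without replacement (a node used once
leaves every candidate pool) and the original node is admissible — excluding
originals would bias small degree classes. With `min_bin_size = 1` every
bin is a single degree class, making log-binning coincide with perfect
degree match; this reduction is an acceptance test. Note that a demand can
never exceed a degree class for a harmonized set (the members belong to the
class), so the pool-exhaustion error exists as a guard for custom samplers
and malformed inputs.

Two-set scores resample **both** sets each iteration, matching the practice
of randomizing drug targets and disease genes jointly; a `freeze` flag pins
either set when a conditional null is wanted.

## Determinism and parallelism

Every (iteration, set) draw derives its seed from
`(master seed, iteration index, set name)` and every screened pair from
`(master seed, source name, target name)` via a small multiplicative string
hash modulo $2^{31}-1$. Consequences, all tested: a run is reproducible from
its seed; a shorter run is a prefix of a longer one; adding a disease to a
screen does not change other pairs' rows; and serial and 4-worker parallel
screens write byte-identical CSVs. Failures (e.g. a set unreachable from
every source) are recorded per row and never abort a screen.

## The synthetic world

`generate_graph()` provides Erdős–Rényi and Barabási–Albert graphs with
optional uniform weights; `plant_connected_module()` grows a connected
induced subgraph by seeded breadth-first expansion (a positive control for
LCC significance); `perturb_node_set()` removes and adds member fractions
(rounding half away from zero, for platform determinism) to emulate
incomplete or noisy annotations. These fixtures exercise every code path —
planted modules of size 20 in ER(500, 0.01) reach LCC $z > 2$ in at least
18 of 20 seeds, and module-adjacent target sets score proximity $z < 0$ in
at least 19 of 20 seeds — but they do not reproduce the degree
heterogeneity, clustering or annotation bias of a real interactome. A green
test establishes the statistical machinery, not the biology: conclusions on
real data still depend on interactome completeness and curation quality,
which are out of scope here (no identifier mapping or curation is
performed; node ids are opaque case-sensitive strings).

## Numerical and design choices

- Duplicate edges collapse to the **maximum** weight (order-independent);
  self-loops are dropped with a warning count. Self-distances are fixed at 0
  by convention, so loops carry no information for these scores.
- Members of a source set with no finite distance to the target set are
  excluded from the AMSPL average with a warning; if all are excluded the
  score errors. This keeps scores finite on fragmented graphs while making
  the data loss visible, rather than propagating `Inf` silently.
- A zero-variance null sets a `degenerate` flag and reports `z` as missing;
  the empirical p-value is still computed (it is 1 when all null samples
  equal the observation).
- `perturb_node_set()` with `remove_frac = 1` errors immediately rather than
  returning an empty set: node sets are non-empty by contract, and the
  failure surfaces with a clearer message than a downstream harmonization
  error would give.
- Screening kind `"separation"` reports raw-only rows (no null, `n_iter` 0);
  `"separation_z"` adds the resampled significance. Raw separation is often
  screened at scale where nulls are prohibitive, so both are exposed.
- The config key for the null model is `null_model` (CLI flag `--null` is an
  alias): a literal `null` key is indistinguishable from YAML's null scalar.
- Edge-list headers are auto-detected: the first line is a header when its
  third field is non-numeric and its tokens never reappear as node ids.

## Limitations

- Random-walk and communicability matrices are dense $O(n^2)$ objects built
  through dense solves/exponentials; they are practical to a few thousand
  nodes per component. Shortest paths scale much further.
- No analytic null approximations and no multiple-testing correction across
  screened pairs: p-values are per-pair and downstream correction is the
  caller's responsibility.
- Edge randomization (degree-preserving rewiring) is deliberately absent;
  the nulls randomize node identity, preserving the network topology.
- Directed graphs, GPU linear algebra and landmark-approximate shortest
  paths are out of scope.
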