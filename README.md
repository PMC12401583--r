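# netprox

Network-medicine screening on interactomes in R: disease-module
localization, drug–disease proximity and disease–disease separation, with
degree-aware null models, multiple graph distance metrics, and a
deterministic parallel screening engine.

## The problem

Proteins associated with one disease tend to occupy a coherent neighbourhood
of the protein–protein interaction network (the *disease module*), and drugs
tend to act on diseases whose genes sit close to the drug's protein targets.
Quantifying this requires three statistics, each benchmarked against random
node sets matched on size and degree:

- **LCC significance.** For a gene set *A*, the size of the largest connected
  component of the subgraph induced by *A*, compared with the LCC sizes of
  matched random sets: `z = (|LCC(A)| − μ_null) / σ_null`. Large positive *z*
  means *A* is more module-like than chance.
- **Proximity.** The average minimum shortest path length (AMSPL) from drug
  targets *A* to disease genes *B*,
  `P(A,B) = (1/|A|) Σ_{a∈A} min_{b∈B} d(a,b)`,
  which is asymmetric (`P(A,B) ≠ P(B,A)`); a symmetric variant
  `P_s(A,B) = (Σ_a min_b d(a,b) + Σ_b min_a d(b,a)) / (|A|+|B|)` is also
  provided. Negative *z* means closer than matched random sets.
- **Separation.** `s_AB = d_AB − (d_AA + d_BB)/2`, where `d_AB` is the
  symmetric AMSPL and `d_AA`, `d_BB` are mean within-set nearest-neighbour
  distances. Negative `s_AB` indicates overlapping network neighbourhoods.

Because biological signals do not only travel along geodesics, `d(·,·)` can
be taken from four metrics: shortest paths, random walk with restart
(`d(p,q) = −ln π(p)_q` with visiting distribution
`π(p) = r (I − (1−r)Wᵀ)⁻¹ e_p`), degree-biased random walks
(`W[i→j] ∝ w_ij · k_j^β`), or communicability
(`ξ(p,q) = sqrt(G_pp + G_qq − 2G_pq)`, `G = expm(A)`), plus user-defined
metrics. Null sets are drawn by perfect degree match, degree log-binning,
strength binning, uniform sampling, or a user-provided sampler.

All-pairs distances are computed once, cached to disk in a versioned binary
format, and reused across an entire drug × disease screen, which runs in
parallel yet is bit-reproducible for any worker count.

## Worked example

Using the committed quickstart fixture (a 59-node synthetic interactome with
a planted 8-node module; regenerate with `Rscript tools/make_quickstart.R`):

```r
library(netprox)
net  <- system.file("extdata", "quickstart_network.tsv", package = "netprox")
sf   <- system.file("extdata", "quickstart_sets.json",   package = "netprox")
g    <- load_network(net)
sets <- lapply(load_node_sets(sf), function(s) harmonize(s, g)$set)
D    <- all_pairs_shortest_path(g)
spec <- null_model_spec("log_binning", min_bin_size = 10)

lcc_significance(g, sets$module, spec, n_iter = 1000, seed = 1)
#> <lcc: raw=8 mu=2.516 sigma=1.023 z=5.363 p=0.000999 (upper, n_iter=1000)>

proximity(g, sets$targetsA, sets$diseaseX, D, spec, n_iter = 1000, seed = 1)
#> <proximity: raw=0.6 mu=1.481 sigma=0.3398 z=-2.592 p=0.01299 (lower, n_iter=1000)>

separation(sets$diseaseX, sets$diseaseY, D)
#> <separation s_ab=-0.6932 (d_ab=1.462 d_aa=2.143 d_bb=2.167)>
```

The planted module's LCC covers all 8 of its nodes while degree-matched
random sets average 2.5 (z = 5.36, p ≈ 0.001): the set is strongly
localized. `targetsA` sits 0.6 steps (AMSPL) from `diseaseX` against a null
mean of 1.48 (z = −2.59): significantly closer than matched random target
sets. The negative separation says the two disease sets' neighbourhoods
overlap.

Screening every source against every target reuses the same matrix:

```r
tab <- screen(sets[c("targetsA", "targetsB")], sets[c("diseaseX", "diseaseY")],
              g, D, "proximity", spec, n_iter = 1000, workers = 2, seed = 1)
tab[, c("source", "target", "raw", "mu", "z", "p_empirical")]
#>     source   target raw     mu          z p_empirical
#> 1 targetsA diseaseX 0.6 1.4706 -2.5437483  0.00999001
#> 2 targetsA diseaseY 1.6 1.4378  0.5095412  0.80319680
#> 3 targetsB diseaseX 1.0 1.4958 -1.3386202  0.14485514
#> 4 targetsB diseaseY 1.4 1.4874 -0.2505530  0.51248751
```

Only `targetsA`–`diseaseX` is significantly proximal; the table is written
with `write_table()` as round-trippable CSV and is byte-identical for any
`workers` value at a fixed seed.

## Command line

```sh
Rscript inst/cli/netprox.R synth --n 500 --p 0.01 --seed 7 --out net.tsv \
    --module-size 20 --module-out sets.json
Rscript inst/cli/netprox.R distances --network net.tsv --metric shortest_path --out net.nmd
Rscript inst/cli/netprox.R screen --network net.tsv --distances net.nmd \
    --sources drugs.json --targets diseases.json --score proximity \
    --null log_binning --iters 1000 --seed 7 --workers 4 --out screen.csv
```

Subcommands: `synth`, `distances`, `lcc`, `proximity`, `separation`,
`screen`. Options may also come from a YAML or `key=value` config file via
`--config` (flags win). Exit codes: 0 success, 2 usage, 3 data, 4 compute.

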