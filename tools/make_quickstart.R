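#!/usr/bin/env Rscript
# Regenerates the committed quickstart fixtures under inst/extdata/.
# Run from the repository root with the package installed.
suppressPackageStartupMessages(library(netprox))

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

g <- generate_graph("erdos_renyi", n = 60, p = 0.08, seed = 42)
g <- largest_connected_component(g)
write_network(g, "inst/extdata/quickstart_network.tsv")

mod <- plant_connected_module(g, 8, seed = 42)
ids <- sort(igraph::V(g)$name)
set.seed(42)
write_node_sets(list(
  module    = mod$members,
  targetsA  = sample(ids, 5),
  targetsB  = sample(ids, 5),
  diseaseX  = sample(ids, 7),
  diseaseY  = sample(ids, 6)
), "inst/extdata/quickstart_sets.json")

cat("wrote inst/extdata/quickstart_{network.tsv,sets.json}\n")
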