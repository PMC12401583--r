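# Synthetic benchmark graphs with planted structure: the whole pipeline is
# testable without downloading an interactome. Generators are pure functions
# of their seed.

#' Generate a synthetic benchmark graph
#'
#' Erdos-Renyi G(n, p) or Barabasi-Albert preferential attachment, with
#' optional uniform edge weights. Node ids are `"v1" ... "vn"`. Reproducible:
#' the same spec and seed always give the same graph.
#'
#' @param kind `"erdos_renyi"` or `"barabasi_albert"`.
#' @param n Number of nodes.
#' @param p Edge probability (Erdos-Renyi).
#' @param m Edges added per step (Barabasi-Albert).
#' @param weighted Draw edge weights uniformly from `weight_range`.
#' @param weight_range Length-2 positive range for weights.
#' @param seed Integer seed.
#' @return A validated interactome.
#' @export
generate_graph <- function(kind = c("erdos_renyi", "barabasi_albert"),
                           n = 100L, p = 0.05, m = 2L,
                           weighted = FALSE, weight_range = c(0.5, 2),
                           seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  set.seed(as.integer(seed))
  g <- if (kind == "erdos_renyi") {
    if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
    igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  } else {
    if (m < 1L) stop("m must be >= 1", call. = FALSE)
    igraph::sample_pa(n, m = m, directed = FALSE)
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g <- igraph::simplify(g)
  w <- if (weighted) {
    if (length(weight_range) != 2 || any(weight_range <= 0)) {
      stop("weight_range must be two positive numbers", call. = FALSE)
    }
    runif(igraph::ecount(g), weight_range[1], weight_range[2])
  } else {
    rep(1.0, igraph::ecount(g))
  }
  igraph::E(g)$weight <- w
  g <- igraph::set_graph_attr(g, "name", sprintf("%s(n=%d,seed=%d)", kind, n, seed))
  validate_interactome(g)
  g
}

#' Plant a connected module in a graph
#'
#' Grows a k-node connected induced subgraph by seeded breadth-first
#' expansion from a random start node, with uniformly shuffled frontiers.
#' Useful as a positive control for LCC significance: the returned set is
#' connected by construction.
#'
#' @param g Interactome.
#' @param k Module size (at most the largest component size).
#' @param seed Integer seed.
#' @return A `node_set` of `k` nodes whose induced subgraph is connected.
#' @export
plant_connected_module <- function(g, k, seed = 1L) {
  comp <- igraph::components(g)
  if (k > max(comp$csize)) {
    stop(sprintf("k = %d exceeds the largest component size (%d)",
                 k, max(comp$csize)), call. = FALSE)
  }
  set.seed(as.integer(seed))
  big <- which(comp$csize >= k)
  start_comp <- if (length(big) == 1L) big else sample(big, 1L)
  candidates <- igraph::V(g)$name[comp$membership == start_comp]
  start <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
  chosen <- character(0)
  frontier <- start
  while (length(chosen) < k) {
    pick <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    chosen <- c(chosen, pick)
    nbrs <- igraph::V(g)$name[igraph::neighbors(g, pick)]
    frontier <- setdiff(unique(c(frontier, nbrs)), c(chosen, pick))
  }
  node_set(chosen, name = sprintf("module_k%d_seed%d", k, seed))
}

# round-half-away-from-zero, platform-stable
.round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Perturb a node set (robustness analyses)
#'
#' Removes `round(remove_frac * |s|)` members uniformly at random, then adds
#' `round(add_frac * |s|)` nodes drawn uniformly from `pool` minus the
#' current set. Counts round half away from zero. Models incomplete or noisy
#' annotations; the degradation of a score under increasing perturbation is
#' a robustness curve.
#'
#' @param s A `node_set`.
#' @param remove_frac,add_frac Fractions in `[0, 1]` of the original size.
#' @param pool Character vector of candidate nodes for additions.
#' @param seed Integer seed.
#' @return The perturbed `node_set` (possibly empty -> error, surfacing the
#'   same failure a fully unannotated set would).
#' @export
perturb_node_set <- function(s, remove_frac, add_frac, pool, seed = 1L) {
  stopifnot(inherits(s, "node_set"))
  if (remove_frac < 0 || remove_frac > 1 || add_frac < 0 || add_frac > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- length(s$members)
  n_rm <- as.integer(.round_away(remove_frac * n))
  n_add <- as.integer(.round_away(add_frac * n))
  kept <- s$members
  if (n_rm > 0) {
    drop <- if (length(kept) == 1L) kept else sample(kept, n_rm)
    kept <- setdiff(kept, drop)
  }
  if (n_add > 0) {
    cands <- setdiff(pool, kept)
    if (length(cands) < n_add) {
      stop(sprintf("candidate pool too small: need %d, have %d", n_add,
                   length(cands)), call. = FALSE)
    }
    add <- if (length(cands) == 1L) cands else sample(cands, n_add)
    kept <- c(kept, add)
  }
  if (length(kept) == 0) {
    stop(sprintf("perturbation removed every member of '%s'", s$name), call. = FALSE)
  }
  node_set(kept, name = paste0(s$name, "_perturbed"))
}
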