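# Deterministic seed derivation: every (iteration, set-name) draw gets its
# own stream derived from the master seed, so results never depend on the
# order in which pairs or iterations are scheduled.
.MOD31 <- 2147483647

.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% .MOD31
  h
}

.derive_seed <- function(master, ...) {
  h <- (as.numeric(master) %% .MOD31) + 1
  for (part in list(...)) {
    ph <- if (is.character(part)) .hash_string(part) else as.numeric(part) %% .MOD31
    h <- (h * 48271 + ph + 1) %% .MOD31
  }
  as.integer(h)
}

#' Null-model specification
#'
#' Chooses how random node sets matched to an observed set are drawn, the
#' benchmark for every Z-score in the package.
#'
#' @param kind `"degree_match"` (each member replaced by a node of identical
#'   degree), `"log_binning"` / `"strength_binning"` (drawn from the member's
#'   degree/strength bin), `"uniform"` (any node), or `"custom"`.
#' @param min_bin_size Minimum nodes per bin for the binning kinds; default
#'   100, sized for interactome-scale heavy-tailed degree distributions
#'   (tests use small values).
#' @param custom_sampler For `kind = "custom"`: function
#'   `(g, size) -> character vector` of `size` distinct node ids, drawing from
#'   the current RNG state.
#' @return A `null_model_spec` object.
#' @export
null_model_spec <- function(kind = c("degree_match", "log_binning",
                                     "strength_binning", "uniform", "custom"),
                            min_bin_size = 100L, custom_sampler = NULL) {
  kind <- match.arg(kind)
  min_bin_size <- as.integer(min_bin_size)
  if (is.na(min_bin_size) || min_bin_size < 1L) {
    stop("min_bin_size must be a positive integer", call. = FALSE)
  }
  if (kind == "custom" && !is.function(custom_sampler)) {
    stop("kind 'custom' requires custom_sampler", call. = FALSE)
  }
  structure(list(kind = kind, min_bin_size = min_bin_size,
                 custom_sampler = custom_sampler),
            class = "null_model_spec")
}

.node_property <- function(g, property) {
  if (property == "degree") {
    setNames(igraph::degree(g), igraph::V(g)$name)
  } else {
    w <- igraph::E(g)$weight
    setNames(igraph::strength(g, weights = w), igraph::V(g)$name)
  }
}

#' Partition nodes into property bins
#'
#' Nodes are sorted by the property (degree or strength); consecutive
#' distinct property values accumulate greedily into a bin until it holds at
#' least `min_bin_size` nodes, then a new bin starts. A trailing undersized
#' bin merges backward into its predecessor. On unweighted graphs strength
#' equals degree, so the two partitions coincide.
#'
#' @param g Interactome.
#' @param property `"degree"` or `"strength"`.
#' @param min_bin_size Minimum members per bin (must not exceed the node
#'   count).
#' @return A `bin_partition`: list with `bins` (each with `lower`, `upper`,
#'   `members`) and `property`.
#' @export
build_bins <- function(g, property = c("degree", "strength"), min_bin_size = 100L) {
  property <- match.arg(property)
  min_bin_size <- as.integer(min_bin_size)
  n <- igraph::vcount(g)
  if (min_bin_size > n) {
    stop(sprintf("min_bin_size (%d) exceeds node count (%d)", min_bin_size, n),
         call. = FALSE)
  }
  prop <- .node_property(g, property)
  vals <- sort(unique(prop))
  bins <- list()
  cur_members <- character(0)
  cur_lower <- NA_real_
  for (v in vals) {
    members_v <- names(prop)[prop == v]
    if (length(cur_members) == 0) cur_lower <- v
    cur_members <- c(cur_members, members_v)
    if (length(cur_members) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- list(lower = cur_lower, upper = v,
                                        members = cur_members)
      cur_members <- character(0)
    }
  }
  if (length(cur_members) > 0) {
    if (length(bins) == 0) {
      bins[[1L]] <- list(lower = cur_lower, upper = max(vals), members = cur_members)
    } else {
      last <- bins[[length(bins)]]
      bins[[length(bins)]] <- list(lower = last$lower, upper = max(vals),
                                   members = c(last$members, cur_members))
    }
  }
  structure(list(bins = bins, property = property), class = "bin_partition")
}

# bin index for each queried node
.bin_of <- function(partition, ids) {
  idx <- integer(length(ids))
  for (bi in seq_along(partition$bins)) {
    idx[ids %in% partition$bins[[bi]]$members] <- bi
  }
  if (any(idx == 0L)) stop("node not covered by bin partition", call. = FALSE)
  idx
}

# draw one matched set; `pools` maps each member to its candidate pool key,
# `pool_members` maps key -> candidate node ids. Draws are without
# replacement across the whole sample; the original node is admissible.
.sample_matched <- function(member_keys, pool_members, size_label) {
  used <- character(0)
  out <- character(length(member_keys))
  # process scarcer pools first so feasible samples are found when they exist
  counts <- table(member_keys)
  order_keys <- names(sort(vapply(names(counts), function(k)
    length(pool_members[[k]]) - counts[[k]], 0)))
  pos <- 1L
  for (k in order_keys) {
    need <- counts[[k]]
    pool <- setdiff(pool_members[[k]], used)
    if (length(pool) < need) {
      stop(sprintf("null-model pool exhausted for %s %s: need %d, have %d",
                   size_label, k, need, length(pool)), call. = FALSE)
    }
    draw <- if (length(pool) == 1L) pool else sample(pool, need)
    out[pos:(pos + need - 1L)] <- draw
    used <- c(used, draw)
    pos <- pos + need
  }
  out
}

#' Draw one random node set matched to an observed set
#'
#' Returns exactly `|s|` distinct nodes. Under `degree_match` each member is
#' replaced by a uniformly drawn node of identical degree; under the binning
#' kinds, by a node from the member's degree/strength bin; under `uniform`,
#' by any node. All draws within one sample are without replacement, and the
#' original node is an admissible draw. Consumes the current RNG state unless
#' `seed` is given.
#'
#' @param g Interactome.
#' @param s Harmonized `node_set`.
#' @param spec A `null_model_spec`.
#' @param seed Optional integer seed for this single draw.
#' @param bins Optional precomputed `bin_partition` (binning kinds only);
#'   avoids rebuilding inside loops.
#' @return A `node_set` of the same size as `s`.
#' @export
sample_null_set <- function(g, s, spec, seed = NULL, bins = NULL) {
  stopifnot(inherits(s, "node_set"), inherits(spec, "null_model_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- igraph::V(g)$name
  k <- length(s$members)
  if (k > length(nodes)) stop("set larger than the network", call. = FALSE)
  members <- switch(spec$kind,
    uniform = if (length(nodes) == 1L) nodes else sample(nodes, k),
    degree_match = {
      deg <- setNames(igraph::degree(g), nodes)
      keys <- as.character(deg[s$members])
      pools <- split(nodes, as.character(deg))
      .sample_matched(keys, pools, "degree")
    },
    log_binning = ,
    strength_binning = {
      property <- if (spec$kind == "log_binning") "degree" else "strength"
      if (is.null(bins)) bins <- build_bins(g, property, spec$min_bin_size)
      if (!identical(bins$property, property)) {
        stop("bin partition property does not match null-model kind", call. = FALSE)
      }
      keys <- as.character(.bin_of(bins, s$members))
      pools <- setNames(lapply(bins$bins, `[[`, "members"),
                        as.character(seq_along(bins$bins)))
      .sample_matched(keys, pools, "bin")
    },
    custom = {
      out <- spec$custom_sampler(g, k)
      out <- as.character(out)
      if (length(out) != k || anyDuplicated(out) || !all(out %in% nodes)) {
        stop("custom sampler returned an invalid node set", call. = FALSE)
      }
      out
    })
  node_set(members, name = paste0(s$name, "_null"))
}

#' Null distribution of a score under set randomization
#'
#' Draws `n_iter` independent randomizations of the input set(s) and applies
#' `score_fn` to each. For two-set scores both sets are resampled each
#' iteration by default; `freeze` pins either one. Each (iteration, set) draw
#' derives its RNG stream from `(seed, iteration, set name)`, so the output
#' is reproducible and independent of scheduling order.
#'
#' @param score_fn Function of one or two `node_set`s returning a scalar.
#' @param g Interactome.
#' @param sets List of one or two harmonized `node_set`s.
#' @param spec A `null_model_spec`.
#' @param n_iter Number of null samples (>= 1).
#' @param seed Master seed (integer).
#' @param freeze Logical vector along `sets`: `TRUE` keeps that set fixed.
#' @return Numeric vector of length `n_iter`, in iteration order.
#' @export
null_distribution <- function(score_fn, g, sets, spec, n_iter, seed = 0L,
                              freeze = rep(FALSE, length(sets))) {
  stopifnot(is.list(sets), length(sets) >= 1, n_iter >= 1)
  bins <- NULL
  if (spec$kind %in% c("log_binning", "strength_binning")) {
    property <- if (spec$kind == "log_binning") "degree" else "strength"
    bins <- build_bins(g, property, spec$min_bin_size)
  }
  vapply(seq_len(n_iter), function(i) {
    drawn <- lapply(seq_along(sets), function(j) {
      if (freeze[j]) return(sets[[j]])
      sample_null_set(g, sets[[j]], spec,
                      seed = .derive_seed(seed, i, sets[[j]]$name),
                      bins = bins)
    })
    as.numeric(do.call(score_fn, drawn))
  }, numeric(1))
}
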