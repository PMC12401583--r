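# Score layer: AMSPL-based proximity (asymmetric and symmetric), separation,
# and LCC size, each judged against a null ensemble via Z-score and an
# add-one empirical p-value. Everything reads from a precomputed
# distance_matrix; no graph traversal happens here.

.check_in_matrix <- function(D, s) {
  missing <- setdiff(s$members, rownames(D$values))
  if (length(missing)) {
    stop(sprintf("set '%s' has members absent from the distance matrix: %s",
                 s$name, paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
}

# per-source minimum distance to the target set; Inf-only sources are
# dropped with a warning (keeps scores finite on fragmented graphs while
# making the data loss visible)
.min_dists <- function(D, from, to) {
  sub <- D$values[from, to, drop = FALSE]
  m <- apply(sub, 1L, min)
  inf <- !is.finite(m)
  if (any(inf)) {
    warning(sprintf("%d source node(s) unreachable from the target set; excluded",
                    sum(inf)), call. = FALSE)
    m <- m[!inf]
  }
  if (length(m) == 0) stop("no source node can reach the target set", call. = FALSE)
  m
}

#' Average minimum shortest path length (asymmetric proximity raw score)
#'
#' `(1/|A|) * sum_{a in A} min_{b in B} D[a, b]` with `A` the source set
#' (rows of `D`). The orientation matters: for drug-disease proximity, pass
#' the drug-target set as `A`. Source nodes with no finite distance to any
#' target are excluded with a warning; if all are excluded this errors.
#'
#' @param A Source `node_set` (averaged over).
#' @param B Target `node_set`.
#' @param D A `distance_matrix` covering both sets.
#' @return The AMSPL, a nonnegative scalar in the metric's units.
#' @export
amspl <- function(A, B, D) {
  .check_in_matrix(D, A); .check_in_matrix(D, B)
  mean(.min_dists(D, A$members, B$members))
}

#' Symmetric AMSPL
#'
#' `(sum_{a} min_b D[a,b] + sum_{b} min_a D[b,a]) / (|A| + |B|)` — invariant
#' under swapping `A` and `B` when `D` is symmetric.
#'
#' @inheritParams amspl
#' @return Symmetric proximity raw score.
#' @export
symmetric_amspl <- function(A, B, D) {
  .check_in_matrix(D, A); .check_in_matrix(D, B)
  fwd <- .min_dists(D, A$members, B$members)
  rev <- .min_dists(D, B$members, A$members)
  (sum(fwd) + sum(rev)) / (length(fwd) + length(rev))
}

#' Mean within-set nearest-neighbour distance
#'
#' `(1/|A|) * sum_{a} min_{a' != a} D[a, a']`; a singleton set returns 0 by
#' convention.
#'
#' @param A `node_set` with at least one member.
#' @param D A `distance_matrix` covering `A`.
#' @return Internal distance `d_AA`.
#' @export
internal_distance <- function(A, D) {
  .check_in_matrix(D, A)
  if (length(A$members) == 1L) return(0)
  sub <- D$values[A$members, A$members, drop = FALSE]
  diag(sub) <- Inf
  mean(.min_dists(structure(list(values = sub), class = "distance_matrix"),
                  A$members, A$members))
}

#' Separation between two node sets
#'
#' `s_AB = d_AB - (d_AA + d_BB) / 2`, where `d_AB` is the symmetric AMSPL
#' and `d_AA`, `d_BB` are within-set nearest-neighbour means. Negative values
#' indicate overlapping network neighbourhoods; `s(A, A) = -d_AA`.
#'
#' @inheritParams amspl
#' @return A `separation_value` with fields `s_ab`, `d_ab`, `d_aa`, `d_bb`.
#' @export
separation <- function(A, B, D) {
  d_ab <- symmetric_amspl(A, B, D)
  d_aa <- internal_distance(A, D)
  d_bb <- internal_distance(B, D)
  structure(list(s_ab = d_ab - (d_aa + d_bb) / 2,
                 d_ab = d_ab, d_aa = d_aa, d_bb = d_bb),
            class = "separation_value")
}

#' @export
print.separation_value <- function(x, ...) {
  cat(sprintf("<separation s_ab=%.4g (d_ab=%.4g d_aa=%.4g d_bb=%.4g)>\n",
              x$s_ab, x$d_ab, x$d_aa, x$d_bb))
  invisible(x)
}

#' Z-score and empirical p-value against a null sample
#'
#' `z = (raw - mean) / sd` with the population (n-denominator) standard
#' deviation, since the null samples are the full ensemble being described.
#' The empirical p uses the add-one convention
#' `p = (1 + #extreme) / (n + 1)` and never returns 0: lower tail counts
#' `x <= raw`, upper `x >= raw`, two-sided doubles the smaller tail (capped
#' at 1). A zero-sd null sets the `degenerate` flag and leaves `z` as `NA`;
#' p is still computed.
#'
#' @param raw Observed score.
#' @param null_samples Numeric vector of null scores (length >= 2).
#' @param side `"lower"`, `"upper"`, or `"two_sided"`.
#' @return List with `mu`, `sigma`, `z`, `p_empirical`, `degenerate`.
#' @export
z_and_p <- function(raw, null_samples, side = c("lower", "upper", "two_sided")) {
  side <- match.arg(side)
  n <- length(null_samples)
  stopifnot(n >= 2)
  mu <- mean(null_samples)
  sigma <- sqrt(mean((null_samples - mu)^2))
  degenerate <- sigma == 0
  z <- if (degenerate) NA_real_ else (raw - mu) / sigma
  p_lower <- (1 + sum(null_samples <= raw)) / (n + 1)
  p_upper <- (1 + sum(null_samples >= raw)) / (n + 1)
  p <- switch(side, lower = p_lower, upper = p_upper,
              two_sided = min(1, 2 * min(p_lower, p_upper)))
  list(mu = mu, sigma = sigma, z = z, p_empirical = p, degenerate = degenerate)
}

.score_result <- function(kind, raw, null_samples, side, n_iter, seed) {
  zp <- z_and_p(raw, null_samples, side)
  structure(list(score_kind = kind, raw = raw, null_samples = null_samples,
                 mu = zp$mu, sigma = zp$sigma, z = zp$z,
                 p_empirical = zp$p_empirical, side = side,
                 degenerate = zp$degenerate, n_iter = n_iter, seed = seed),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s: raw=%.4g mu=%.4g sigma=%.4g z=%s p=%.4g (%s, n_iter=%d)>\n",
              x$score_kind, x$raw, x$mu, x$sigma,
              if (is.na(x$z)) "NA (degenerate)" else sprintf("%.3f", x$z),
              x$p_empirical, x$side, x$n_iter))
  invisible(x)
}

#' Proximity between two node sets with null-model significance
#'
#' Raw score is the (a)symmetric AMSPL from `A` (e.g. drug targets) to `B`
#' (e.g. disease genes); the null resamples both sets under the chosen model.
#' Default side is `"lower"`: a large negative z means the sets are closer on
#' the network than matched random sets.
#'
#' @param g Interactome (needed for null sampling).
#' @param A Source `node_set`.
#' @param B Target `node_set`.
#' @param D Precomputed `distance_matrix` on `g`.
#' @param spec A `null_model_spec`.
#' @param n_iter Null-sample count (default 1000).
#' @param symmetric Use the symmetric AMSPL.
#' @param seed Master seed.
#' @param side Tail for the empirical p-value.
#' @param freeze Length-2 logical: pin `A` and/or `B` during resampling.
#' @return A `score_result`.
#' @export
proximity <- function(g, A, B, D, spec, n_iter = 1000L, symmetric = FALSE,
                      seed = 0L, side = "lower", freeze = c(FALSE, FALSE)) {
  stopifnot(n_iter >= 2)
  fn <- if (symmetric) symmetric_amspl else amspl
  raw <- fn(A, B, D)
  nulls <- null_distribution(function(a, b) fn(a, b, D), g, list(A, B),
                             spec, n_iter, seed = seed, freeze = freeze)
  .score_result(if (symmetric) "proximity_symmetric" else "proximity",
                raw, nulls, side, n_iter, seed)
}

#' Separation significance between two node sets
#'
#' Raw score is `s_AB`; the null resamples both sets. Default side is
#' `"lower"` (more overlapping than random).
#'
#' @inheritParams proximity
#' @return A `score_result` (the raw value is `s_AB`).
#' @export
separation_significance <- function(g, A, B, D, spec, n_iter = 1000L,
                                    seed = 0L, side = "lower",
                                    freeze = c(FALSE, FALSE)) {
  stopifnot(n_iter >= 2)
  raw <- separation(A, B, D)$s_ab
  nulls <- null_distribution(function(a, b) separation(a, b, D)$s_ab, g,
                             list(A, B), spec, n_iter, seed = seed,
                             freeze = freeze)
  .score_result("separation", raw, nulls, side, n_iter, seed)
}

#' Largest-connected-component significance of a node set
#'
#' Raw score is the LCC size of the subgraph induced by `A`; the null is the
#' LCC size of matched random sets. Side is `"upper"`: a large positive z
#' means the set is more topologically cohesive (module-like) than random.
#'
#' @inheritParams proximity
#' @param A Harmonized `node_set`.
#' @return A `score_result`.
#' @export
lcc_significance <- function(g, A, spec, n_iter = 1000L, seed = 0L,
                             side = "upper") {
  stopifnot(n_iter >= 2)
  lcc_size <- function(s) {
    sub <- induced_subgraph_set(g, s)
    if (igraph::vcount(sub) == 0) return(0)
    max(igraph::components(sub)$csize)
  }
  raw <- lcc_size(A)
  nulls <- null_distribution(lcc_size, g, list(A), spec, n_iter, seed = seed)
  .score_result("lcc", raw, nulls, side, n_iter, seed)
}
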