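# All scores work off a precomputed all-pairs distance matrix so that an
# entire screen performs no graph traversal. The traversal counter below
# exists only so tests can assert that contract.
.traversal <- new.env(parent = emptyenv())
.traversal$count <- 0L

.count_traversal <- function() .traversal$count <- .traversal$count + 1L

#' Number of graph traversals performed so far
#'
#' Internal instrumentation: incremented once per all-pairs matrix
#' computation. Screens must not change it.
#' @return Integer count.
#' @export
traversal_count <- function() .traversal$count

#' Construct a distance matrix object
#'
#' @param values Square numeric matrix with node ids as both dimnames.
#'   Entries are nonnegative; `Inf` marks unreachable pairs; the diagonal is 0.
#' @param metric Metric label.
#' @param symmetric Whether `values` equals its transpose by construction.
#' @param params Named list of metric parameters (e.g. restart probability).
#' @return A `distance_matrix` object.
#' @export
distance_matrix <- function(values, metric, symmetric, params = list()) {
  d <- structure(list(values = values, metric = metric,
                      symmetric = isTRUE(symmetric), params = params),
                 class = "distance_matrix")
  validate_distance_matrix(d)
  d
}

#' Validate a distance matrix object
#'
#' Used on every constructed matrix, including ones returned by user-supplied
#' custom metric functions.
#' @param d A `distance_matrix`.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d) {
  if (!inherits(d, "distance_matrix")) stop("not a distance_matrix", call. = FALSE)
  v <- d$values
  if (!is.matrix(v) || nrow(v) != ncol(v)) stop("values must be a square matrix", call. = FALSE)
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    stop("values needs identical row/column node ids", call. = FALSE)
  }
  if (anyNA(v)) stop("distance matrix contains NA", call. = FALSE)
  if (any(v < 0)) stop("distance matrix contains negative entries", call. = FALSE)
  if (any(diag(v) != 0)) stop("distance matrix diagonal must be 0", call. = FALSE)
  if (isTRUE(d$symmetric) && !identical(v, t(v))) {
    stop("matrix flagged symmetric but is not", call. = FALSE)
  }
  invisible(d)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix '%s': %d nodes, %s>\n", x$metric, nrow(x$values),
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' All-pairs shortest-path distances
#'
#' Hop counts on unweighted graphs; minimal edge-weight sums on weighted
#' graphs (Dijkstra per source). Unreachable pairs are `Inf`.
#'
#' @param g Interactome.
#' @return A symmetric `distance_matrix`.
#' @export
all_pairs_shortest_path <- function(g) {
  validate_interactome(g)
  .count_traversal()
  w <- igraph::E(g)$weight
  v <- igraph::distances(g, weights = w, algorithm = if (is.null(w)) "unweighted" else "dijkstra")
  v <- (v + t(v)) / 2  # igraph is already symmetric; guard against fp asymmetry
  ids <- igraph::V(g)$name
  dimnames(v) <- list(ids, ids)
  distance_matrix(v, "shortest_path", symmetric = TRUE)
}

.adj <- function(g) {
  attr <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  as.matrix(igraph::as_adjacency_matrix(g, attr = attr, sparse = TRUE))
}

# strength-normalized transition matrix of one connected component
.transition_matrix <- function(A, beta = NULL, deg = NULL) {
  if (!is.null(beta) && beta != 0) A <- sweep(A, 2L, deg^beta, `*`)
  rs <- rowSums(A)
  A / rs
}

.rwr_component <- function(A, r, beta = NULL, deg = NULL) {
  n <- nrow(A)
  if (n == 1L) return(matrix(0, 1, 1))
  W <- .transition_matrix(A, beta, deg)
  # visiting distribution from seed p: pi(p) = r (I - (1-r) W^T)^{-1} e_p
  M <- r * solve(diag(n) - (1 - r) * t(W))
  d <- -log(t(M))          # d[p, q] = -ln pi(p)_q
  diag(d) <- 0
  d
}

.per_component <- function(g, fun) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  v <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(v) <- 0
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, idx)
    v[idx, idx] <- fun(.adj(sub), igraph::degree(sub))
  }
  v
}

#' Random-walk-with-restart distance
#'
#' A walker restarts at the seed node `p` with probability `r` and otherwise
#' steps to a neighbour with probability proportional to the edge weight. The
#' stationary visiting distribution `pi(p)` gives the distance
#' `d(p, q) = -ln pi(p)_q` for `p != q`; the diagonal is 0 by convention. The
#' result is asymmetric. Cross-component pairs are `Inf`.
#'
#' @param g Interactome.
#' @param r Restart probability in (0, 1); default 0.15.
#' @return An asymmetric `distance_matrix`.
#' @export
random_walk_distance <- function(g, r = 0.15) {
  validate_interactome(g)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1) {
    stop("restart probability r must lie in (0, 1)", call. = FALSE)
  }
  .count_traversal()
  v <- .per_component(g, function(A, deg) .rwr_component(A, r))
  distance_matrix(v, "random_walk", symmetric = FALSE, params = list(r = r))
}

#' Degree-biased random-walk distance
#'
#' Same restart machinery as [random_walk_distance()], but the step from `i`
#' to `j` has probability proportional to `w_ij * degree(j)^beta`
#' (row-normalized). `beta = 0` reduces exactly to the unbiased walk;
#' `beta > 0` attracts the walker to hubs, `beta < 0` repels it.
#'
#' @param g Interactome.
#' @param r Restart probability in (0, 1).
#' @param beta Bias exponent on the target node's degree; default 1.
#' @return An asymmetric `distance_matrix`.
#' @export
biased_random_walk_distance <- function(g, r = 0.15, beta = 1.0) {
  validate_interactome(g)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1) {
    stop("restart probability r must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta)) {
    stop("beta must be a finite number", call. = FALSE)
  }
  .count_traversal()
  v <- .per_component(g, function(A, deg) .rwr_component(A, r, beta, deg))
  distance_matrix(v, "biased_random_walk", symmetric = FALSE,
                  params = list(r = r, beta = beta))
}

#' Communicability distance
#'
#' With `G = expm(A)` the (weighted) adjacency matrix exponential, the
#' distance is `xi(p, q) = sqrt(G_pp + G_qq - 2 G_pq)` — a Euclidean metric
#' counting walks of all lengths, shorter walks weighted more. Weighted graphs
#' exponentiate the weighted adjacency directly: very large weights can
#' overflow `expm`; rescale weights beforehand if needed.
#'
#' @param g Interactome.
#' @return A symmetric `distance_matrix`.
#' @export
communicability_distance <- function(g) {
  validate_interactome(g)
  .count_traversal()
  G <- as.matrix(Matrix::expm(Matrix::Matrix(.adj(g), sparse = TRUE)))
  d2 <- outer(diag(G), diag(G), `+`) - 2 * G
  d2[d2 < 0] <- 0  # fp noise on near-identical rows
  v <- sqrt(d2)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  ids <- igraph::V(g)$name
  dimnames(v) <- list(ids, ids)
  distance_matrix(v, "communicability", symmetric = TRUE)
}

#' Compute a distance matrix under a chosen metric
#'
#' Dispatcher over the built-in metrics plus user-defined functions. A custom
#' function receives the graph and must return a valid `distance_matrix`
#' (checked).
#'
#' @param g Interactome.
#' @param metric One of `"shortest_path"`, `"random_walk"`,
#'   `"biased_random_walk"`, `"communicability"`, `"custom"`.
#' @param r Restart probability for the walk metrics.
#' @param beta Bias exponent for the biased walk.
#' @param custom_fn Function `g -> distance_matrix`, required when
#'   `metric = "custom"`.
#' @return A `distance_matrix`.
#' @export
compute_distance_matrix <- function(g,
                                    metric = c("shortest_path", "random_walk",
                                               "biased_random_walk",
                                               "communicability", "custom"),
                                    r = 0.15, beta = 1.0, custom_fn = NULL) {
  metric <- match.arg(metric)
  switch(metric,
    shortest_path = all_pairs_shortest_path(g),
    random_walk = random_walk_distance(g, r = r),
    biased_random_walk = biased_random_walk_distance(g, r = r, beta = beta),
    communicability = communicability_distance(g),
    custom = {
      if (!is.function(custom_fn)) stop("metric 'custom' requires custom_fn", call. = FALSE)
      d <- custom_fn(g)
      validate_distance_matrix(d)
      d
    })
}

# Cache file layout (version NMDM1), all integers little-endian int32,
# strings length-prefixed UTF-8, floats little-endian float64 row-major:
#   magic "NMDM1" | metric | params JSON | symmetric int | n | n ids | n*n values
.write_lpstr <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  writeBin(length(b), con, size = 4L, endian = "little")
  writeBin(b, con)
}

.read_lpstr <- function(con) {
  len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(len) != 1L || is.na(len) || len < 0) stop("truncated distance cache", call. = FALSE)
  b <- readBin(con, "raw", len)
  if (length(b) != len) stop("truncated distance cache", call. = FALSE)
  rawToChar(b)
}

#' Save a distance matrix to a binary cache file
#'
#' The cache round-trips bit-identically (64-bit floats, including `Inf`), so
#' screens can reuse one expensive computation across many runs.
#'
#' @param d A `distance_matrix`.
#' @param path Output path (conventionally `.nmd`).
#' @return `path`, invisibly.
#' @export
save_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("NMDM1"), con)
  .write_lpstr(con, d$metric)
  .write_lpstr(con, as.character(jsonlite::toJSON(d$params, auto_unbox = TRUE, digits = NA)))
  writeBin(as.integer(isTRUE(d$symmetric)), con, size = 4L, endian = "little")
  n <- nrow(d$values)
  writeBin(n, con, size = 4L, endian = "little")
  for (id in rownames(d$values)) .write_lpstr(con, id)
  writeBin(as.vector(t(d$values)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a distance matrix from a binary cache file
#'
#' @param path Cache file written by [save_distance_matrix()].
#' @return The reconstructed `distance_matrix`.
#' @export
load_distance_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("cache file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 5L)
  if (length(magic) != 5L || !identical(rawToChar(magic), "NMDM1")) {
    stop("not a distance cache file (bad magic/version)", call. = FALSE)
  }
  metric <- .read_lpstr(con)
  params <- jsonlite::fromJSON(.read_lpstr(con), simplifyVector = TRUE)
  symmetric <- readBin(con, "integer", 1L, size = 4L, endian = "little") == 1L
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n < 0) stop("truncated distance cache", call. = FALSE)
  ids <- vapply(seq_len(n), function(i) .read_lpstr(con), "")
  vals <- readBin(con, "double", n * n, size = 8L, endian = "little")
  if (length(vals) != n * n) stop("truncated distance cache", call. = FALSE)
  v <- matrix(vals, nrow = n, byrow = TRUE, dimnames = list(ids, ids))
  distance_matrix(v, metric, symmetric = symmetric, params = as.list(params))
}
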