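# Fixtures are built in code; nothing is read from disk except temp files
# the tests themselves write.

path_graph <- function(n, weights = NULL) {
  ids <- paste0("v", seq_len(n) - 1L)
  ed <- data.frame(from = ids[-n], to = ids[-1], stringsAsFactors = FALSE)
  if (!is.null(weights)) ed$weight <- weights
  make_interactome(ed, name = sprintf("P%d", n))
}

star_graph <- function(k) {
  ed <- data.frame(from = rep("c", k), to = paste0("l", seq_len(k)),
                   stringsAsFactors = FALSE)
  make_interactome(ed, name = sprintf("S%d", k))
}

# Floyd-Warshall oracle, independent of igraph
fw_oracle <- function(g) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  ed <- igraph::as_data_frame(g, what = "edges")
  w <- if (is.null(ed$weight)) rep(1, nrow(ed)) else ed$weight
  for (i in seq_len(nrow(ed))) {
    d[ed$from[i], ed$to[i]] <- min(d[ed$from[i], ed$to[i]], w[i])
    d[ed$to[i], ed$from[i]] <- min(d[ed$to[i], ed$from[i]], w[i])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# brute-force AMSPL straight off the definition
amspl_oracle <- function(A, B, D) {
  vals <- numeric(0)
  for (a in A$members) {
    m <- Inf
    for (b in B$members) m <- min(m, D$values[a, b])
    if (is.finite(m)) vals <- c(vals, m)
  }
  mean(vals)
}

random_er <- function(n, p, seed, weighted = FALSE) {
  g <- generate_graph("erdos_renyi", n = n, p = p, seed = seed,
                      weighted = weighted)
  g
}

tsv_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
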