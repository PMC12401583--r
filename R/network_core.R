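#' @importFrom stats sd setNames rbinom runif
#' @importFrom utils write.csv read.csv head
NULL

# Interactomes are undirected simple igraph objects with a vertex attribute
# "name" holding the (case-sensitive, opaque) node ids and an optional
# positive edge attribute "weight". All public functions validate through
# validate_interactome() so downstream code can assume the invariants.

#' Validate an interactome graph
#'
#' Checks the invariants every score in this package relies on: the graph is
#' undirected and simple (no self-loops, no parallel edges), every node has a
#' unique non-empty id, and all edge weights (if present) are positive and
#' finite.
#'
#' @param g An `igraph` object.
#' @return `g`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_interactome <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("interactome must be undirected", call. = FALSE)
  if (any(igraph::which_loop(g))) stop("interactome must not contain self-loops", call. = FALSE)
  if (any(igraph::which_multiple(g))) stop("interactome must not contain parallel edges", call. = FALSE)
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("every node needs a non-empty id ('name' attribute)", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicate node ids", call. = FALSE)
  w <- igraph::E(g)$weight
  if (!is.null(w) && (anyNA(w) || any(!is.finite(w)) || any(w <= 0))) {
    stop("edge weights must be positive and finite", call. = FALSE)
  }
  invisible(g)
}

#' Construct an interactome from an edge table
#'
#' @param edges Two- or three-column data frame (source, target, optional
#'   weight) or a character matrix of endpoints.
#' @param directed Ignored; graphs are always undirected.
#' @param name Optional graph label.
#' @return A validated interactome (`igraph` object). Parallel edges collapse
#'   to the maximum weight; self-loops are dropped with a warning giving their
#'   count.
#' @export
make_interactome <- function(edges, name = "interactome", directed = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("need at least source and target columns", call. = FALSE)
  src <- as.character(edges[[1]])
  dst <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1.0, length(src))
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("edge weights must be positive finite numbers", call. = FALSE)
  }
  loops <- src == dst
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    src <- src[!loops]; dst <- dst[!loops]; w <- w[!loops]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = src, to = dst, weight = w, stringsAsFactors = FALSE),
    directed = FALSE
  )
  # duplicate edges (in either orientation) keep the maximum weight
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "max"))
  g <- igraph::set_graph_attr(g, "name", name)
  validate_interactome(g)
  g
}

# Header detection for edge-list TSVs: the first line is a header when its
# third field (if any) does not parse as a number AND none of its tokens
# reappear as node ids later in the file. Interactome dumps in the wild vary.
.detect_header <- function(lines) {
  if (length(lines) < 2) return(FALSE)
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(first) < 2) return(FALSE)  # malformed, not a header
  third_numeric <- length(first) >= 3 && !is.na(suppressWarnings(as.numeric(first[3])))
  if (third_numeric) return(FALSE)
  rest <- unlist(strsplit(lines[-1], "\t", fixed = TRUE), use.names = FALSE)
  !any(first[1:2] %in% rest)
}

#' Load an interactome from disk
#'
#' Reads either a tab-separated edge list (`source<TAB>target[<TAB>weight]`,
#' header auto-detected) or a GraphML file. Self-loops are dropped (with a
#' warning counting them) and duplicate edges collapse to the maximum weight.
#'
#' @param path Path to the network file.
#' @param format `"edge_list"` (TSV) or `"graphml"`.
#' @param weighted If `FALSE`, any weight column/attribute is ignored and all
#'   edges get weight 1.
#' @return A validated interactome.
#' @export
load_network <- function(path, format = c("edge_list", "graphml"), weighted = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path), call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      idat <- igraph::vertex_attr(g, "id")
      igraph::V(g)$name <- if (!is.null(idat)) as.character(idat) else as.character(seq_len(igraph::vcount(g)))
    }
    ed <- igraph::as_data_frame(g, what = "edges")
    if (!weighted || is.null(ed$weight)) ed$weight <- rep(1.0, nrow(ed))
    return(make_interactome(ed[, c("from", "to", "weight")],
                            name = basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file", call. = FALSE)
  if (.detect_header(lines)) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2)
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d: fewer than 2 fields", bad[1]), call. = FALSE)
  }
  src <- vapply(parts, `[[`, "", 1L)
  dst <- vapply(parts, `[[`, "", 2L)
  w <- rep(1.0, length(parts))
  has_w <- nfield >= 3
  if (weighted && any(has_w)) {
    wraw <- vapply(parts[has_w], `[[`, "", 3L)
    wnum <- suppressWarnings(as.numeric(wraw))
    if (anyNA(wnum)) {
      stop(sprintf("malformed edge-list line %d: weight '%s' is not a number",
                   which(has_w)[which(is.na(wnum))[1]],
                   wraw[which(is.na(wnum))[1]]), call. = FALSE)
    }
    if (any(wnum <= 0 | !is.finite(wnum))) {
      stop(sprintf("non-positive weight on line %d", which(has_w)[which(wnum <= 0 | !is.finite(wnum))[1]]),
           call. = FALSE)
    }
    w[has_w] <- wnum
  }
  make_interactome(data.frame(src, dst, w, stringsAsFactors = FALSE),
                   name = basename(path))
}

#' Write an interactome as a TSV edge list
#'
#' @param g Interactome.
#' @param path Output path.
#' @param header Write a `source	target	weight` header line.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, header = TRUE) {
  validate_interactome(g)
  ed <- igraph::as_data_frame(g, what = "edges")
  if (is.null(ed$weight)) ed$weight <- rep(1.0, nrow(ed))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("source\ttarget\tweight", con)
  if (nrow(ed)) {
    writeLines(sprintf("%s\t%s\t%.17g", ed$from, ed$to, ed$weight), con)
  }
  invisible(path)
}

#' Create a named node set
#'
#' @param members Character vector of node ids; duplicates are removed.
#' @param name Set label.
#' @return A `node_set` object.
#' @export
node_set <- function(members, name = "set") {
  members <- unique(as.character(members))
  if (length(members) == 0) stop(sprintf("node set '%s' is empty", name), call. = FALSE)
  structure(list(name = name, members = members), class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set '%s': %d members>\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.node_set <- function(x) length(x$members)

#' Load node sets from a JSON file
#'
#' The file must be a JSON object mapping a set name (e.g. a disease) to an
#' array of node ids (its associated genes). Duplicate ids within a list are
#' dropped; an empty list is an error naming the offending key.
#'
#' @param path Path to the JSON file.
#' @return Named list of `node_set` objects.
#' @export
load_node_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("node-set file not found: %s", path), call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("node-set JSON must be an object of name -> array of ids", call. = FALSE)
  }
  out <- lapply(names(raw), function(k) {
    ids <- unlist(raw[[k]], use.names = FALSE)
    if (length(ids) == 0) stop(sprintf("node set '%s' is empty", k), call. = FALSE)
    if (!is.character(ids)) ids <- as.character(ids)
    node_set(ids, name = k)
  })
  setNames(out, names(raw))
}

#' Write node sets to JSON
#'
#' @param sets Named list of `node_set` objects (or character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_sets <- function(sets, path) {
  payload <- lapply(sets, function(s) {
    if (inherits(s, "node_set")) s$members else as.character(s)
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' Restrict a node set to the network
#'
#' Drops members absent from the interactome and reports them. Scores in this
#' package require harmonized sets. Harmonization is idempotent.
#'
#' @param s A `node_set`.
#' @param g Interactome.
#' @return List with elements `set` (the restricted `node_set`) and `report`
#'   (list with `set_name`, `kept`, `dropped`).
#' @export
harmonize <- function(s, g) {
  stopifnot(inherits(s, "node_set"))
  nodes <- igraph::V(g)$name
  keep <- s$members %in% nodes
  dropped <- s$members[!keep]
  if (!any(keep)) {
    stop(sprintf("node set '%s': no members present in the network", s$name), call. = FALSE)
  }
  list(
    set = node_set(s$members[keep], name = s$name),
    report = list(set_name = s$name, kept = sum(keep), dropped = dropped)
  )
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest component; ties are broken by
#' the lexicographically smallest node id contained in a component.
#'
#' @param g Interactome (non-empty).
#' @return Interactome restricted to the largest component.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest id over each tied component decides
    minid <- vapply(best, function(ci) min(igraph::V(g)$name[comp$membership == ci]), "")
    best <- best[order(minid)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Induced subgraph on a node set
#'
#' @param g Interactome.
#' @param s Harmonized `node_set` (or character vector of ids present in `g`).
#' @return The subgraph with nodes `s` and the edges of `g` internal to `s`.
#' @export
induced_subgraph_set <- function(g, s) {
  ids <- if (inherits(s, "node_set")) s$members else as.character(s)
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing)) {
    stop(sprintf("node set contains ids absent from the network (harmonize first): %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  igraph::induced_subgraph(g, ids)
}
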