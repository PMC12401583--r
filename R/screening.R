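# All-pairs screening: many source sets x many target sets against one
# precomputed distance matrix. Each pair's RNG stream is keyed by
# (master seed, source name, target name) -- not by enumeration index -- so
# adding a set never changes other pairs' results, and serial and parallel
# execution agree exactly.

.screen_one <- function(src_name, tgt_name, sources, targets, g, D,
                        score_kind, spec, n_iter, master_seed) {
  pair_seed <- .derive_seed(master_seed, src_name, tgt_name)
  row <- data.frame(source = src_name, target = tgt_name,
                    score_kind = score_kind, raw = NA_real_, mu = NA_real_,
                    sigma = NA_real_, z = NA_real_, p_empirical = NA_real_,
                    n_iter = as.integer(n_iter), degenerate = FALSE,
                    error = "", stringsAsFactors = FALSE)
  res <- tryCatch({
    A <- sources[[src_name]]; B <- targets[[tgt_name]]
    if (score_kind == "separation") {
      sep <- separation(A, B, D)
      row$raw <- sep$s_ab
      row$n_iter <- 0L
      row
    } else {
      sr <- switch(score_kind,
        proximity = proximity(g, A, B, D, spec, n_iter, symmetric = FALSE,
                              seed = pair_seed),
        proximity_symmetric = proximity(g, A, B, D, spec, n_iter,
                                        symmetric = TRUE, seed = pair_seed),
        separation_z = separation_significance(g, A, B, D, spec, n_iter,
                                               seed = pair_seed))
      row$raw <- sr$raw; row$mu <- sr$mu; row$sigma <- sr$sigma
      row$z <- sr$z; row$p_empirical <- sr$p_empirical
      row$degenerate <- sr$degenerate
      row
    }
  }, error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
  res
}

#' Screen every source set against every target set
#'
#' Produces exactly `|sources| x |targets|` rows ordered lexicographically by
#' (source, target). Per-pair failures are recorded in the row's `error`
#' column and never abort the screen. The distance matrix is computed once
#' beforehand and only read here.
#'
#' @param sources,targets Named lists of harmonized `node_set`s.
#' @param g Interactome.
#' @param D Precomputed `distance_matrix` on `g`.
#' @param score_kind `"proximity"`, `"proximity_symmetric"`,
#'   `"separation"` (raw values only, no null), or `"separation_z"`.
#' @param spec A `null_model_spec`.
#' @param n_iter Null iterations per pair.
#' @param workers Number of parallel workers (forked; results are identical
#'   for any worker count).
#' @param seed Master seed.
#' @return A `screening_table` (data frame).
#' @export
screen <- function(sources, targets, g, D,
                   score_kind = c("proximity", "proximity_symmetric",
                                  "separation", "separation_z"),
                   spec = null_model_spec("degree_match"),
                   n_iter = 1000L, workers = 1L, seed = 0L) {
  score_kind <- match.arg(score_kind)
  stopifnot(length(names(sources)) == length(sources),
            length(names(targets)) == length(targets))
  src_names <- sort(names(sources))
  tgt_names <- sort(names(targets))
  if (length(src_names) == 0L || length(tgt_names) == 0L) {
    pairs <- data.frame(source = character(0), target = character(0))
  } else {
    pairs <- expand.grid(target = tgt_names, source = src_names,
                         stringsAsFactors = FALSE)[, c("source", "target")]
  }
  run <- function(i) .screen_one(pairs$source[i], pairs$target[i], sources,
                                 targets, g, D, score_kind, spec, n_iter, seed)
  if (nrow(pairs) == 0L) {
    out <- data.frame(source = character(0), target = character(0),
                      score_kind = character(0), raw = numeric(0),
                      mu = numeric(0), sigma = numeric(0), z = numeric(0),
                      p_empirical = numeric(0), n_iter = integer(0),
                      degenerate = logical(0), error = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("screening_table", "data.frame")
    return(out)
  }
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(pairs)), run, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(pairs)), run)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_table", "data.frame")
  out
}

#' Write a screening table as CSV
#'
#' RFC-4180 CSV with a header; numeric columns are rendered with 17
#' significant digits so every double round-trips exactly, and names
#' containing commas or quotes are quoted.
#'
#' @param t A `screening_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(t, path) {
  out <- as.data.frame(t)
  for (col in c("raw", "mu", "sigma", "z", "p_empirical")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  write.csv(out, path, row.names = FALSE, quote = which(vapply(out, is.character, TRUE)))
  invisible(path)
}

#' Read back a screening table CSV
#'
#' @param path CSV written by [write_table()].
#' @return A `screening_table`.
#' @export
read_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source = "character", target = "character",
                                 score_kind = "character", error = "character"))
  for (col in c("raw", "mu", "sigma", "z", "p_empirical")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  class(out) <- c("screening_table", "data.frame")
  out
}
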