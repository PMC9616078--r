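#' Graph construction configuration
#'
#' @param n Maximum number of nodes kept per slide (the top-n most abnormal
#'   patches).
#' @param gamma Edge distance threshold: a non-negative number, `Inf` (fully
#'   connected graph) or `"auto"` to use the `auto_q`-th percentile of the
#'   slide's pairwise node distances. `gamma = 0` yields no off-diagonal
#'   edges.
#' @param add_self_loops Put 1 on the adjacency diagonal (default `TRUE`) so
#'   isolated nodes still propagate their own features.
#' @param auto_q Percentile (0--100) used when `gamma = "auto"`.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(n = 64, gamma = "auto", add_self_loops = TRUE,
                         auto_q = 20) {
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  if (!(identical(gamma, "auto") ||
        (is.numeric(gamma) && length(gamma) == 1 && gamma >= 0)))
    stop("gamma must be 'auto' or a single number >= 0 (Inf allowed)")
  structure(list(n = as.integer(n), gamma = gamma,
                 add_self_loops = isTRUE(add_self_loops), auto_q = auto_q),
            class = "graph_config")
}

#' Abnormality grade of a patch
#'
#' The mean of the patch's probability-map values: the fraction of the patch
#' predicted abnormal, used to rank patches for discriminative node
#' selection.
#'
#' @param map Numeric probability raster in `[0, 1]`.
#' @return A real in `[0, 1]`.
#' @export
abnormality_grade <- function(map) {
  if (length(map) == 0) stop("empty probability map")
  stopifnot_prob(map, "map")
  mean(map)
}

#' Select the top-n discriminative patches by abnormality grade
#'
#' Keeps the `n` highest-grade patches (all of them when fewer than `n`),
#' removing interference from purely negative regions. Ties are broken by
#' row-major patch order, and the output is sorted by descending grade then
#' row-major order.
#'
#' @param grades Numeric vector of abnormality grades, one per patch, in
#'   row-major patch order.
#' @param n Maximum number of patches to keep.
#' @return Integer indices into `grades` of the selected patches, in
#'   descending-grade order.
#' @export
select_discriminative_nodes <- function(grades, n) {
  if (length(grades) < 1) stop("need at least one patch")
  ord <- order(-grades, seq_along(grades))
  ord[seq_len(min(n, length(grades)))]
}

#' Chebyshev (L-infinity) distance between two feature vectors
#'
#' @param x,y Equal-length finite numeric vectors.
#' @return `max(abs(x - y))`.
#' @export
chebyshev_distance <- function(x, y) {
  if (length(x) != length(y)) stop("feature vectors differ in length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("feature vectors must be finite")
  max(abs(x - y))
}

# Pairwise Chebyshev distance matrix for the rows of X.
chebyshev_distance_matrix <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    d <- apply(abs(sweep(X[(i + 1):n, , drop = FALSE], 2, X[i, ])), 1, max)
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  D
}

#' Build the slide graph from selected patches
#'
#' Nodes are the selected discriminative patches with their feature vectors
#' and grades; an (undirected, unweighted) edge connects nodes m and n
#' exactly when the Chebyshev distance of their features is strictly below
#' the threshold gamma. `gamma = 0` therefore yields no edges and
#' `gamma = Inf` the complete graph. With `gamma = "auto"` the threshold is
#' the configured percentile of this slide's pairwise node distances.
#'
#' @param features Numeric matrix, one row per selected node (in selection
#'   order).
#' @param grades Numeric vector of the nodes' abnormality grades.
#' @param cfg A [graph_config()]; `cfg$n` caps the node count (the first
#'   `n` rows are kept, matching [select_discriminative_nodes()] order).
#' @param coords Optional data.frame with the nodes' patch positions
#'   (`row`, `col`), carried along for serialization.
#' @param slide_id Identifier.
#' @return An object of class `slide_graph`: `features`, `grades`,
#'   `coords`, symmetric binary `adjacency` (diagonal 1 iff self-loops),
#'   resolved numeric `gamma` and `slide_id`.
#' @export
build_graph <- function(features, grades, cfg = graph_config(),
                        coords = NULL, slide_id = "slide") {
  stopifnot(inherits(cfg, "graph_config"))
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (nrow(features) < 1) stop("need at least one node")
  keep <- seq_len(min(cfg$n, nrow(features)))
  features <- features[keep, , drop = FALSE]
  grades <- grades[keep]
  if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
  n <- nrow(features)
  D <- chebyshev_distance_matrix(features)
  gamma <- cfg$gamma
  if (identical(gamma, "auto")) {
    off <- D[upper.tri(D)]
    gamma <- if (length(off)) unname(quantile(off, cfg$auto_q / 100)) else 0
  }
  A <- (D < gamma) * 1
  diag(A) <- if (cfg$add_self_loops) 1 else 0
  structure(list(slide_id = slide_id, features = features, grades = grades,
                 coords = coords, adjacency = A, gamma = gamma,
                 n_config = cfg$n),
            class = "slide_graph")
}

#' Build the slide graph straight from segmenter output
#'
#' Applies [select_discriminative_nodes()] to the per-patch grades and then
#' [build_graph()] to the selected features.
#'
#' @param inference Output of [infer_slide()].
#' @param cfg A [graph_config()].
#' @param slide_id Identifier.
#' @return A `slide_graph`.
#' @export
slide_graph_from_inference <- function(inference, cfg = graph_config(),
                                       slide_id = "slide") {
  sel <- select_discriminative_nodes(inference$grades, cfg$n)
  build_graph(inference$features[sel, , drop = FALSE],
              inference$grades[sel], cfg,
              coords = inference$index[sel, c("row", "col")],
              slide_id = slide_id)
}

#' @export
print.slide_graph <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf("<slide_graph> %s: %d nodes, %d edges, gamma = %.4g\n",
              x$slide_id, n,
              (sum(x$adjacency) - sum(diag(x$adjacency))) / 2, x$gamma))
  invisible(x)
}

#' Serialize / restore a slide graph
#'
#' Writes a JSON header (slide id, node count, gamma, feature dimension), a
#' TSV edge list, a node CSV (index, row, col, grade) and the feature
#' matrix as CSV, under a common path prefix.
#'
#' @param graph A `slide_graph`.
#' @param prefix Path prefix; four files are written with suffixes
#'   `.json`, `_edges.tsv`, `_nodes.csv` and `_features.csv`.
#' @export
write_slide_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "slide_graph"))
  n <- nrow(graph$features)
  jsonlite::write_json(list(slide_id = graph$slide_id, n = n,
                            gamma = graph$gamma, d = ncol(graph$features),
                            n_config = graph$n_config),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  ut <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
  write.table(data.frame(m = ut[, 1], n = ut[, 2]),
              paste0(prefix, "_edges.tsv"), sep = "\t", row.names = FALSE)
  coords <- graph$coords
  if (is.null(coords)) coords <- data.frame(row = rep(NA, n), col = rep(NA, n))
  write.csv(data.frame(node = seq_len(n), row = coords$row, col = coords$col,
                       grade = graph$grades),
            paste0(prefix, "_nodes.csv"), row.names = FALSE)
  write.csv(as.data.frame(graph$features), paste0(prefix, "_features.csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_slide_graph
#' @return `read_slide_graph()` returns the restored `slide_graph` (the
#'   adjacency is rebuilt from the edge list plus self-loops inferred from
#'   the stored diagonal convention).
#' @param self_loops Whether the restored adjacency carries self-loops.
#' @export
read_slide_graph <- function(prefix, self_loops = TRUE) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  feats <- as.matrix(read.csv(paste0(prefix, "_features.csv")))
  nodes <- read.csv(paste0(prefix, "_nodes.csv"))
  edges <- read.table(paste0(prefix, "_edges.tsv"), header = TRUE, sep = "\t")
  n <- meta$n
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[cbind(edges$m, edges$n)] <- 1
    A[cbind(edges$n, edges$m)] <- 1
  }
  diag(A) <- if (self_loops) 1 else 0
  structure(list(slide_id = meta$slide_id, features = unname(feats),
                 grades = nodes$grade,
                 coords = nodes[, c("row", "col")], adjacency = A,
                 gamma = meta$gamma, n_config = meta$n_config),
            class = "slide_graph")
}
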