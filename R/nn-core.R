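# Numerical core for the graph network: batch assembly, segment
# operations, activations, parameter initialization and flattening.
# Everything is dense base-R linear algebra over a block-diagonal batch
# graph (nodes of all molecules concatenated; edges offset per graph).

# sum rows of x by integer group idx into an n-row matrix (missing groups
# stay zero)
seg_sum <- function(x, idx, n) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) == 0) return(matrix(0, n, ncol(x)))
  s <- rowsum(x, idx)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(s)), ] <- s
  out
}

seg_count <- function(idx, n) {
  tab <- tabulate(idx, nbins = n)
  as.numeric(tab)
}

ACTIVATIONS <- list(
  relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
  leaky_relu = list(f = function(x) ifelse(x > 0, x, 0.2 * x),
                    df = function(x) ifelse(x > 0, 1, 0.2)),
  identity = list(f = function(x) x, df = function(x) x * 0 + 1),
  tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2)
)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
d_leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# Glorot-uniform matrix
glorot <- function(d_in, d_out) {
  r <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out)
}

#' Assemble a batch from molecular graphs
#'
#' Concatenates graphs into one block-diagonal graph: a node feature
#' matrix, a directed edge list with per-graph index offsets, and node ->
#' graph membership. Coordinates, when used, enter as three extra feature
#' columns.
#'
#' @param graphs list of `molecular_graph` objects.
#' @param use_coords append centered 3D coordinates to the features.
#' @param onehot_elements optional integer vector of atomic numbers; when
#'   given, the atomic-number column is replaced by a one-hot encoding
#'   over this vocabulary (plus an "other" slot).
#' @return a `graph_batch` list.
#' @export
make_batch <- function(graphs, use_coords = FALSE, onehot_elements = NULL) {
  stopifnot(length(graphs) > 0)
  n_nodes <- vapply(graphs, function(g) nrow(g$node_features), 1L)
  if (any(n_nodes == 0)) stop("batch contains an empty graph")
  offsets <- cumsum(c(0L, utils::head(n_nodes, -1)))
  feats <- lapply(seq_along(graphs), function(k) {
    g <- graphs[[k]]
    x <- g$node_features
    if (!is.null(colnames(x)) && all(ATOM_FEATURE_NAMES %in% colnames(x))) {
      x <- x[, ATOM_FEATURE_NAMES, drop = FALSE]
    }
    if (!is.null(onehot_elements)) {
      z <- x[, "atomic_number"]
      oh <- matrix(0, nrow(x), length(onehot_elements) + 1L)
      pos <- match(z, onehot_elements, nomatch = length(onehot_elements) + 1L)
      oh[cbind(seq_len(nrow(x)), pos)] <- 1
      colnames(oh) <- c(paste0("elem_", onehot_elements), "elem_other")
      x <- cbind(oh, x[, setdiff(colnames(x), "atomic_number"), drop = FALSE])
    }
    if (use_coords) {
      if (is.null(g$coords)) {
        stop(sprintf("graph '%s' has no 3D coordinates but the model requires them",
                     g$mol_id))
      }
      x <- cbind(x, g$coords)
    }
    x
  })
  X <- do.call(rbind, feats)
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    ei <- graphs[[k]]$edge_index
    if (nrow(ei) == 0) return(matrix(integer(0), 0, 2))
    ei + offsets[k]
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- matrix(integer(0), 0, 2)
  }
  labels <- do.call(rbind, lapply(graphs, function(g) matrix(g$labels, 1)))
  mask <- do.call(rbind, lapply(graphs, function(g) matrix(g$label_mask, 1)))
  structure(list(
    X = X, src = edges[, 1], dst = edges[, 2],
    graph_id = rep(seq_along(graphs), n_nodes),
    n_nodes = sum(n_nodes), n_graphs = length(graphs),
    nodes_per_graph = as.numeric(n_nodes),
    node_offset = offsets,
    labels = labels, mask = mask,
    mol_ids = vapply(graphs, function(g) g$mol_id, character(1))
  ), class = "graph_batch")
}

# flatten nested parameter lists into a single numeric vector and back;
# used by the optimizer and by numerical gradient checks
#' Flatten a parameter tree into a numeric vector
#' @param params nested list of parameter matrices/vectors.
#' @return numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Rebuild a parameter tree from a flattened vector
#' @param template parameter tree giving shapes.
#' @param vec numeric vector from [flatten_params()].
#' @return parameter tree shaped like `template`.
#' @export
unflatten_params <- function(template, vec) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  walk(template)
}

# elementwise combination of two parameter trees
map2_params <- function(a, b, f) {
  if (is.list(a)) return(Map(function(x, y) map2_params(x, y, f), a, b))
  f(a, b)
}

zero_like <- function(params) {
  if (is.list(params)) return(lapply(params, zero_like))
  params * 0
}
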