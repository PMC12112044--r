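# Brute-force oracles: literal per-node / per-edge evaluations of the
# layer equations, kept deliberately independent of the vectorized
# implementation (plain loops, no segment operations).

# neighbors of node i (sources of edges into i)
.nbrs <- function(graph_edges, i) graph_edges[graph_edges[, 2] == i, 1]

oracle_mpnn <- function(params, H, edges, act = identity) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(params$W))
  mlp <- function(hi, hj) {
    z <- c(hi, hj)
    h1 <- pmax(as.numeric(z %*% params$M1) + params$bm1, 0)
    as.numeric(h1 %*% params$M2) + params$bm2
  }
  for (i in seq_len(n)) {
    acc <- as.numeric(H[i, ] %*% params$W) + params$b
    for (j in .nbrs(edges, i)) acc <- acc + mlp(H[i, ], H[j, ])
    out[i, ] <- act(acc)
  }
  out
}

oracle_gat <- function(params, H, edges, n_heads, combine = "concat",
                       act = identity, slope = 0.2) {
  n <- nrow(H)
  dh <- nrow(params$a_dst)
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  heads_out <- vector("list", n_heads)
  alphas <- list()
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    W <- params$W[, cols, drop = FALSE]
    hout <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      js <- c(.nbrs(edges, i), i)                    # self-loop included
      e <- vapply(js, function(j) {
        lrelu(sum(params$a_dst[, h] * as.numeric(H[i, ] %*% W)) +
                sum(params$a_src[, h] * as.numeric(H[j, ] %*% W)))
      }, numeric(1))
      al <- exp(e - max(e)); al <- al / sum(al)
      alphas[[length(alphas) + 1]] <- data.frame(head = h, i = i, j = js,
                                                 weight = al)
      for (k in seq_along(js)) {
        hout[i, ] <- hout[i, ] + al[k] * as.numeric(H[js[k], ] %*% W)
      }
    }
    heads_out[[h]] <- hout
  }
  comb <- if (combine == "concat") do.call(cbind, heads_out) else
    Reduce(`+`, heads_out) / n_heads
  list(out = act(sweep(comb, 2, params$b, `+`)),
       alpha = do.call(rbind, alphas))
}

oracle_sage <- function(params, H, edges, act = identity) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(params$W))
  for (i in seq_len(n)) {
    js <- .nbrs(edges, i)
    acc <- as.numeric(H[i, ] %*% params$W)
    if (length(js) > 0) {
      for (j in js) acc <- acc + as.numeric(H[j, ] %*% params$W) / length(js)
    }
    out[i, ] <- act(acc + params$b)
  }
  out
}

oracle_gcn <- function(params, H, edges, act = identity) {
  n <- nrow(H)
  deg <- vapply(seq_len(n), function(i) length(.nbrs(edges, i)) + 1, 1)
  out <- matrix(0, n, ncol(params$W))
  for (i in seq_len(n)) {
    js <- c(.nbrs(edges, i), i)
    acc <- numeric(ncol(params$W))
    for (j in js) {
      acc <- acc + as.numeric(H[j, ] %*% params$W) / sqrt(deg[i] * deg[j])
    }
    out[i, ] <- act(acc + params$b)
  }
  out
}

# single-graph batch wrapper around a raw feature matrix + edge list
batch_from_matrix <- function(H, edges, n_graphs_split = NULL) {
  g <- structure(list(node_features = H, edge_index = edges, coords = NULL,
                      labels = 0, label_mask = 1, mol_id = "g1",
                      smiles = NA_character_, mol = NULL),
                 class = "molecular_graph")
  make_batch(list(g))
}

# permute a molecular_graph's nodes consistently
permute_graph <- function(g, perm) {
  inv <- order(perm)
  g$node_features <- g$node_features[perm, , drop = FALSE]
  if (!is.null(g$coords)) g$coords <- g$coords[perm, , drop = FALSE]
  if (nrow(g$edge_index) > 0) {
    ei <- g$edge_index
    g$edge_index <- cbind(src = inv[ei[, 1]], dst = inv[ei[, 2]])
  }
  g
}

skip_slow <- function() invisible(TRUE)  # all tests run everywhere

# independent metric reimplementations used as oracles (rank / identity
# formulations, deliberately different algorithms from the package code)
oracle_auc_rank <- function(scores, labels) {
  # Mann-Whitney with midranks
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
oracle_ap <- function(scores, labels) {
  # average precision by literal loop over distinct thresholds
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0; n_pos <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

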