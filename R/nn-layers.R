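#' Graph network layers
#'
#' Low-level layer API: each layer exposes a seeded initializer
#' (`*_init`), a forward pass returning the new node embeddings plus a
#' cache, and a backward pass returning parameter gradients and the
#' gradient w.r.t. the input embeddings. `mpnn_forward` implements the
#' message-passing update, `gat_forward` the multi-head attention update
#' (returning every attention coefficient), `sage_forward` the
#' neighborhood mean aggregation, `gcn_forward` the symmetric-normalized
#' graph convolution used by the five-layer baseline, and
#' `readout_forward` global average pooling with a linear head.
#'
#' @param params layer parameter list from the matching `*_init`.
#' @param H node embedding matrix (nodes x features).
#' @param batch a [make_batch()] batch providing the edge lists.
#' @param activation activation name (`"relu"`, `"identity"`, ...).
#' @param d_in,d_out,d_msg,n_tasks layer dimensions.
#' @param n_heads number of attention heads.
#' @param combine head combination: `"concat"` or `"mean"`.
#' @param leaky_slope negative slope of the attention LeakyReLU.
#' @param cache forward cache.
#' @param dout,dlogits upstream gradient.
#' @name layers
NULL

# Graph network layers: forward passes with caches and hand-derived
# backward passes. Every layer follows the same contract:
#   <layer>_forward(params, H, batch, ...)  -> list(out, cache)
#   <layer>_backward(params, cache, dout)   -> list(dparams, dH)
# Gradients are validated against numerical differentiation in the tests.

# ---- message passing layer -------------------------------------------------
# h_i' = act( W h_i + sum_{j in N(i)} M(h_i, h_j) + b )
# with M(h_i, h_j) = relu([h_i || h_j] M1 + bm1) M2 + bm2 (one hidden layer)

#' @rdname layers
#' @export
mpnn_init <- function(d_in, d_out, d_msg = d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out),
       M1 = glorot(2 * d_in, d_msg), bm1 = numeric(d_msg),
       M2 = glorot(d_msg, d_out), bm2 = numeric(d_out))
}

#' @rdname layers
#' @export
mpnn_forward <- function(params, H, batch, activation = "relu") {
  act <- ACTIVATIONS[[activation]]
  n <- nrow(H)
  self_term <- H %*% params$W
  if (length(batch$src) > 0) {
    # edge (src=j, dst=i): message into i is M(h_i, h_j)
    msg_in <- cbind(H[batch$dst, , drop = FALSE], H[batch$src, , drop = FALSE])
    A1 <- sweep(msg_in %*% params$M1, 2, params$bm1, `+`)
    R1 <- pmax(A1, 0)
    msg <- sweep(R1 %*% params$M2, 2, params$bm2, `+`)
    agg <- seg_sum(msg, batch$dst, n)
  } else {
    msg_in <- NULL; A1 <- NULL; R1 <- NULL
    agg <- matrix(0, n, ncol(self_term))
  }
  Z <- sweep(self_term + agg, 2, params$b, `+`)
  list(out = act$f(Z),
       cache = list(H = H, Z = Z, msg_in = msg_in, A1 = A1, R1 = R1,
                    activation = activation))
}

#' @rdname layers
#' @export
mpnn_backward <- function(params, cache, dout, batch) {
  act <- ACTIVATIONS[[cache$activation]]
  dZ <- dout * act$df(cache$Z)
  H <- cache$H
  d_in <- ncol(H)
  dH <- dZ %*% t(params$W)
  if (!is.null(cache$msg_in)) {
    dmsg <- dZ[batch$dst, , drop = FALSE]           # d agg routed to edges
    dM2 <- crossprod(cache$R1, dmsg)
    dbm2 <- colSums(dmsg)
    dR1 <- dmsg %*% t(params$M2)
    dA1 <- dR1 * (cache$A1 > 0)
    dM1 <- crossprod(cache$msg_in, dA1)
    dbm1 <- colSums(dA1)
    dmsg_in <- dA1 %*% t(params$M1)
    dH <- dH + seg_sum(dmsg_in[, seq_len(d_in), drop = FALSE], batch$dst, nrow(H))
    dH <- dH + seg_sum(dmsg_in[, d_in + seq_len(d_in), drop = FALSE], batch$src, nrow(H))
  } else {
    dM1 <- params$M1 * 0; dbm1 <- params$bm1 * 0
    dM2 <- params$M2 * 0; dbm2 <- params$bm2 * 0
  }
  # field order must mirror mpnn_init for parameter flattening
  dparams <- list(W = crossprod(H, dZ), b = colSums(dZ),
                  M1 = dM1, bm1 = dbm1, M2 = dM2, bm2 = dbm2)
  list(dparams = dparams, dH = dH)
}

# ---- multi-head graph attention layer --------------------------------------
# per head: e_ij = LeakyReLU(a^T [W h_i || W h_j]), alpha = softmax_j,
# h_i' = act( sum_j alpha_ij W h_j ); self-loops are added transiently so
# every node has nonempty softmax support. Heads are concatenated
# (combine = "concat") or averaged (combine = "mean").

#' @rdname layers
#' @export
gat_init <- function(d_in, d_out, n_heads = 8, combine = "concat") {
  dh <- if (combine == "concat") {
    stopifnot(d_out %% n_heads == 0)
    d_out %/% n_heads
  } else d_out
  list(W = glorot(d_in, dh * n_heads),
       a_dst = matrix(stats::runif(dh * n_heads, -0.3, 0.3), dh, n_heads),
       a_src = matrix(stats::runif(dh * n_heads, -0.3, 0.3), dh, n_heads),
       b = numeric(d_out))
}

# self-loop-augmented edge list shared by the GAT forward/backward
#' @rdname layers
#' @export
gat_edges <- function(batch) {
  n <- batch$n_nodes
  list(src = c(batch$src, seq_len(n)), dst = c(batch$dst, seq_len(n)))
}

#' @rdname layers
#' @export
gat_forward <- function(params, H, batch, n_heads = 8, combine = "concat",
                        activation = "relu", leaky_slope = 0.2) {
  act <- ACTIVATIONS[[activation]]
  n <- nrow(H)
  ed <- gat_edges(batch)
  dh <- nrow(params$a_dst)
  Z <- H %*% params$W                                  # n x (dh * heads)
  d_out <- if (combine == "concat") dh * n_heads else dh
  comb <- matrix(0, n, d_out)
  alpha <- matrix(0, length(ed$src), n_heads)
  Elog <- matrix(0, length(ed$src), n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Zh <- Z[, cols, drop = FALSE]
    s <- Zh[ed$dst, , drop = FALSE] %*% params$a_dst[, h] +
      Zh[ed$src, , drop = FALSE] %*% params$a_src[, h]
    e <- leaky_relu(s, leaky_slope)
    Elog[, h] <- s
    ex <- exp(e - max(e))
    denom <- seg_sum(ex, ed$dst, n)[ed$dst]
    al <- as.numeric(ex / denom)
    alpha[, h] <- al
    hh <- seg_sum(al * Zh[ed$src, , drop = FALSE], ed$dst, n)
    if (combine == "concat") comb[, cols] <- hh else comb <- comb + hh / n_heads
  }
  Zpre <- sweep(comb, 2, params$b, `+`)
  list(out = act$f(Zpre),
       cache = list(H = H, Z = Z, Zpre = Zpre, alpha = alpha, Elog = Elog,
                    ed = ed, n_heads = n_heads, dh = dh, combine = combine,
                    activation = activation, leaky_slope = leaky_slope))
}

#' @rdname layers
#' @export
gat_backward <- function(params, cache, dout, batch) {
  act <- ACTIVATIONS[[cache$activation]]
  H <- cache$H; Z <- cache$Z; ed <- cache$ed
  n <- nrow(H); dh <- cache$dh; n_heads <- cache$n_heads
  dZpre <- dout * act$df(cache$Zpre)
  db <- colSums(dZpre)
  dZ <- matrix(0, nrow(Z), ncol(Z))
  da_dst <- params$a_dst * 0
  da_src <- params$a_src * 0
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Zh <- Z[, cols, drop = FALSE]
    Zsrc <- Zh[ed$src, , drop = FALSE]
    al <- cache$alpha[, h]
    dhh <- if (cache$combine == "concat") {
      dZpre[, cols, drop = FALSE]
    } else dZpre / n_heads
    # hh_i = sum_e alpha_e Zsrc_e  (grouped by dst)
    dhh_e <- dhh[ed$dst, , drop = FALSE]
    dal <- rowSums(dhh_e * Zsrc)
    dZ_src_part <- al * dhh_e
    # softmax backward per dst group: de = al * (dal - sum_group(al * dal))
    gsum <- seg_sum(al * dal, ed$dst, n)[ed$dst]
    de <- al * (dal - gsum)
    ds <- de * d_leaky_relu(cache$Elog[, h], cache$leaky_slope)
    # s = Zdst a_dst + Zsrc a_src
    Zdst <- Zh[ed$dst, , drop = FALSE]
    da_dst[, h] <- crossprod(Zdst, ds)
    da_src[, h] <- crossprod(Zsrc, ds)
    dZh <- seg_sum(ds %*% t(params$a_dst[, h, drop = FALSE]), ed$dst, n) +
      seg_sum(ds %*% t(params$a_src[, h, drop = FALSE]), ed$src, n) +
      seg_sum(dZ_src_part, ed$src, n)
    dZ[, cols] <- dZ[, cols] + dZh
  }
  dparams <- list(W = crossprod(H, dZ), a_dst = da_dst, a_src = da_src, b = db)
  dH <- dZ %*% t(params$W)
  list(dparams = dparams, dH = dH)
}

# ---- neighborhood mean-aggregation (GraphSAGE-style) layer -----------------
# h_i' = act( W h_i + (1/|N(i)|) sum_j W h_j + b ); empty neighborhoods
# contribute a zero mean.

#' @rdname layers
#' @export
sage_init <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

#' @rdname layers
#' @export
sage_forward <- function(params, H, batch, activation = "relu") {
  act <- ACTIVATIONS[[activation]]
  n <- nrow(H)
  deg <- seg_count(batch$dst, n)
  if (length(batch$src) > 0) {
    nb_sum <- seg_sum(H[batch$src, , drop = FALSE], batch$dst, n)
    nb_mean <- nb_sum / pmax(deg, 1)
  } else {
    nb_mean <- matrix(0, n, ncol(H))
  }
  Hin <- H + nb_mean
  Z <- sweep(Hin %*% params$W, 2, params$b, `+`)
  list(out = act$f(Z),
       cache = list(H = H, Hin = Hin, Z = Z, deg = deg, activation = activation))
}

#' @rdname layers
#' @export
sage_backward <- function(params, cache, dout, batch) {
  act <- ACTIVATIONS[[cache$activation]]
  dZ <- dout * act$df(cache$Z)
  dparams <- list(W = crossprod(cache$Hin, dZ), b = colSums(dZ))
  dHin <- dZ %*% t(params$W)
  dH <- dHin
  if (length(batch$src) > 0) {
    scaled <- dHin / pmax(cache$deg, 1)
    dH <- dH + seg_sum(scaled[batch$dst, , drop = FALSE], batch$src, nrow(cache$H))
  }
  list(dparams = dparams, dH = dH)
}

# ---- graph convolution baseline layer --------------------------------------
# h' = act( D^-1/2 (A + I) D^-1/2 H W + b )

#' @rdname layers
#' @export
gcn_init <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

#' @rdname layers
#' @export
gcn_forward <- function(params, H, batch, activation = "relu") {
  act <- ACTIVATIONS[[activation]]
  n <- nrow(H)
  ed <- gat_edges(batch)           # edges + self loops
  deg <- seg_count(ed$dst, n)
  w <- 1 / sqrt(deg[ed$src] * deg[ed$dst])
  AH <- seg_sum(w * H[ed$src, , drop = FALSE], ed$dst, n)
  Z <- sweep(AH %*% params$W, 2, params$b, `+`)
  list(out = act$f(Z),
       cache = list(H = H, AH = AH, Z = Z, ed = ed, w = w, activation = activation))
}

#' @rdname layers
#' @export
gcn_backward <- function(params, cache, dout, batch) {
  act <- ACTIVATIONS[[cache$activation]]
  dZ <- dout * act$df(cache$Z)
  dparams <- list(W = crossprod(cache$AH, dZ), b = colSums(dZ))
  dAH <- dZ %*% t(params$W)
  dH <- seg_sum(cache$w * dAH[cache$ed$dst, , drop = FALSE], cache$ed$src,
                nrow(cache$H))
  list(dparams = dparams, dH = dH)
}

# ---- readout: global average pooling + linear head -------------------------

#' @rdname layers
#' @export
readout_init <- function(d_in, n_tasks) {
  list(W = glorot(d_in, n_tasks), b = numeric(n_tasks))
}

#' @rdname layers
#' @export
readout_forward <- function(params, H, batch) {
  pooled <- seg_sum(H, batch$graph_id, batch$n_graphs) / batch$nodes_per_graph
  logits <- sweep(pooled %*% params$W, 2, params$b, `+`)
  list(out = logits, cache = list(H = H, pooled = pooled))
}

#' @rdname layers
#' @export
readout_backward <- function(params, cache, dlogits, batch) {
  dparams <- list(W = crossprod(cache$pooled, dlogits), b = colSums(dlogits))
  dpooled <- dlogits %*% t(params$W)
  dH <- (dpooled / batch$nodes_per_graph)[batch$graph_id, , drop = FALSE]
  list(dparams = dparams, dH = dH)
}
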