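# Model assembly: configuration, the hybrid architecture
# (MPNN -> GAT x3 -> SAGE -> mean-pool readout), ablation variants and
# five-layer single-architecture baselines.

MODEL_VARIANTS <- c("full", "smiles_only", "no_mpnn", "no_gat", "no_sage",
                    "baseline_mpnn5", "baseline_gat5", "baseline_sage5",
                    "baseline_gcn5")

#' Model configuration
#'
#' @param variant one of `"full"` (MPNN -> 3 x 8-head GAT -> SAGE),
#'   `"smiles_only"` (same architecture, 2D features only),
#'   `"no_mpnn"` / `"no_gat"` / `"no_sage"` (component ablations), or the
#'   five-layer single-architecture baselines `"baseline_mpnn5"`,
#'   `"baseline_gat5"`, `"baseline_sage5"`, `"baseline_gcn5"`.
#' @param hidden_dim hidden width (default 64; must be divisible by
#'   `n_heads` where attention heads are concatenated).
#' @param n_gat_layers number of attention layers in the hybrid stack
#'   (default 3).
#' @param n_heads attention heads per GAT layer (default 8).
#' @param n_tasks number of binary tasks (default 1).
#' @param dropout dropout probability on hidden node embeddings during
#'   training (default 0 for exact reproducibility).
#' @param activation hidden nonlinearity (default `"relu"`; the attention
#'   logits always use LeakyReLU).
#' @param use_coords whether 3D coordinates join the node features;
#'   defaults to TRUE for every variant except `smiles_only`.
#' @param onehot_elements optional atomic-number vocabulary for one-hot
#'   element encoding (NULL = raw integer features).
#' @param seed seed for parameter initialization.
#' @return a `model_config`.
#' @export
model_config <- function(variant = "full", hidden_dim = 64L,
                         n_gat_layers = 3L, n_heads = 8L, n_tasks = 1L,
                         dropout = 0, activation = "relu",
                         use_coords = NULL, onehot_elements = NULL,
                         seed = 1L) {
  if (!variant %in% MODEL_VARIANTS) {
    stop(sprintf("unknown variant '%s' (expected one of: %s)", variant,
                 paste(MODEL_VARIANTS, collapse = ", ")))
  }
  stopifnot(n_heads >= 1, hidden_dim >= 1, n_tasks >= 1,
            dropout >= 0, dropout < 1)
  if (hidden_dim %% n_heads != 0) {
    stop("hidden_dim must be divisible by n_heads for concatenated heads")
  }
  if (is.null(use_coords)) use_coords <- variant != "smiles_only"
  if (variant == "smiles_only" && use_coords) {
    stop("the smiles_only variant cannot use coordinates")
  }
  structure(list(
    variant = variant, hidden_dim = as.integer(hidden_dim),
    n_gat_layers = as.integer(n_gat_layers), n_heads = as.integer(n_heads),
    n_tasks = as.integer(n_tasks), dropout = dropout,
    activation = activation, use_coords = use_coords,
    onehot_elements = onehot_elements, seed = as.integer(seed)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config %s: hidden %d, %d heads, %d task(s)%s>\n",
              x$variant, x$hidden_dim, x$n_heads, x$n_tasks,
              if (x$use_coords) ", 3D" else ""))
  invisible(x)
}

# input feature width implied by a config
config_input_dim <- function(config) {
  d <- length(ATOM_FEATURE_NAMES)
  if (!is.null(config$onehot_elements)) {
    d <- d - 1L + length(config$onehot_elements) + 1L
  }
  if (config$use_coords) d <- d + 3L
  d
}

# layer stack (types only) implied by a variant
variant_layers <- function(config) {
  h <- config$hidden_dim
  gat_stack <- function(n) {
    lapply(seq_len(n), function(k) {
      list(type = "gat", combine = if (k == n) "mean" else "concat")
    })
  }
  core <- switch(config$variant,
    full = , smiles_only = c(list(list(type = "mpnn")),
                             gat_stack(config$n_gat_layers),
                             list(list(type = "sage"))),
    no_mpnn = c(gat_stack(config$n_gat_layers), list(list(type = "sage"))),
    no_gat = list(list(type = "mpnn"), list(type = "sage")),
    no_sage = c(list(list(type = "mpnn")), gat_stack(config$n_gat_layers)),
    baseline_mpnn5 = rep(list(list(type = "mpnn")), 5),
    baseline_gat5 = c(rep(list(list(type = "gat", combine = "concat")), 4),
                      list(list(type = "gat", combine = "mean"))),
    baseline_sage5 = rep(list(list(type = "sage")), 5),
    baseline_gcn5 = rep(list(list(type = "gcn")), 5)
  )
  core
}

#' Initialize model parameters for a variant
#'
#' Builds the layer stack implied by the configured variant and draws all
#' weights (Glorot-uniform) under the configuration seed, so the same seed
#' always yields identical parameters.
#'
#' @param config a [model_config()].
#' @return an `adcgnn_model`: list with `config` and per-layer parameter
#'   list `layers`.
#' @export
make_variant <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d_in <- config_input_dim(config)
  specs <- variant_layers(config)
  h <- config$hidden_dim
  params <- with_seed(config$seed, {
    d <- d_in
    lapply(specs, function(sp) {
      p <- switch(sp$type,
        mpnn = mpnn_init(d, h),
        gat = gat_init(d, h, config$n_heads, sp$combine),
        sage = sage_init(d, h),
        gcn = gcn_init(d, h)
      )
      d <<- h
      c(sp, list(params = p))
    })
  })
  head_p <- with_seed(config$seed + 1L, readout_init(h, config$n_tasks))
  structure(list(config = config, layers = params, head = head_p),
            class = "adcgnn_model")
}

#' @export
print.adcgnn_model <- function(x, ...) {
  types <- vapply(x$layers, function(l) l$type, character(1))
  np <- length(flatten_params(model_params(x)))
  cat(sprintf("<adcgnn_model %s: %s -> readout; %d parameters>\n",
              x$config$variant, paste(types, collapse = " -> "), np))
  invisible(x)
}

# parameter tree of a model (layers + head)
#' Extract or replace a model's parameter tree
#' @param model an `adcgnn_model`.
#' @param params parameter tree (as returned by `model_params`).
#' @name model_params
#' @export
model_params <- function(model) {
  c(lapply(model$layers, function(l) l$params), list(head = model$head))
}

# write a parameter tree back into a model
#' @rdname model_params
#' @export
set_model_params <- function(model, params) {
  nl <- length(model$layers)
  for (k in seq_len(nl)) model$layers[[k]]$params <- params[[k]]
  model$head <- params$head
  model
}

#' Forward pass of the network
#'
#' Runs the configured layer stack over a batch and returns per-graph
#' logits; optionally keeps per-layer caches (for backprop) and the
#' attention coefficients of every GAT layer and head.
#'
#' @param model an [make_variant()] model.
#' @param batch a [make_batch()] batch (feature columns must match the
#'   model configuration).
#' @param keep_cache retain layer caches for a backward pass.
#' @param dropout_mask optional list of precomputed dropout masks (used
#'   internally by the training loop).
#' @return list with `logits` (`n_graphs x n_tasks`), `attention` (list of
#'   GAT caches: alpha matrix, self-loop-augmented edge list, layer index)
#'   and, when requested, `caches`.
#' @export
model_forward <- function(model, batch, keep_cache = FALSE,
                          dropout_mask = NULL) {
  config <- model$config
  if (ncol(batch$X) != config_input_dim(config)) {
    stop(sprintf("batch has %d feature columns but the %s variant expects %d",
                 ncol(batch$X), config$variant, config_input_dim(config)))
  }
  H <- batch$X
  caches <- list()
  attention <- list()
  gat_idx <- 0L
  for (k in seq_along(model$layers)) {
    lay <- model$layers[[k]]
    res <- switch(lay$type,
      mpnn = mpnn_forward(lay$params, H, batch, config$activation),
      gat = gat_forward(lay$params, H, batch, config$n_heads, lay$combine,
                        config$activation),
      sage = sage_forward(lay$params, H, batch, config$activation),
      gcn = gcn_forward(lay$params, H, batch, config$activation)
    )
    H <- res$out
    if (!is.null(dropout_mask) && !is.null(dropout_mask[[k]])) {
      H <- H * dropout_mask[[k]]
      res$cache$drop <- dropout_mask[[k]]
    }
    if (lay$type == "gat") {
      gat_idx <- gat_idx + 1L
      attention[[gat_idx]] <- list(layer_index = gat_idx,
                                   alpha = res$cache$alpha,
                                   src = res$cache$ed$src,
                                   dst = res$cache$ed$dst)
    }
    if (keep_cache) caches[[k]] <- res$cache
  }
  head_res <- readout_forward(model$head, H, batch)
  if (keep_cache) caches$head <- head_res$cache
  list(logits = head_res$out, attention = attention,
       caches = if (keep_cache) caches else NULL, H_final = H)
}

# backward pass: gradient of a scalar loss wrt all parameters, given
# d loss / d logits
#' Backward pass: gradients of a loss w.r.t. all model parameters
#' @param model an `adcgnn_model`.
#' @param batch the batch used in the forward pass.
#' @param caches caches from `model_forward(..., keep_cache = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits.
#' @return parameter-tree-shaped gradient list.
#' @export
model_backward <- function(model, batch, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  hb <- readout_backward(model$head, caches$head, dlogits, batch)
  dH <- hb$dH
  for (k in rev(seq_along(model$layers))) {
    lay <- model$layers[[k]]
    cache <- caches[[k]]
    if (!is.null(cache$drop)) dH <- dH * cache$drop
    res <- switch(lay$type,
      mpnn = mpnn_backward(lay$params, cache, dH, batch),
      gat = gat_backward(lay$params, cache, dH, batch),
      sage = sage_backward(lay$params, cache, dH, batch),
      gcn = gcn_backward(lay$params, cache, dH, batch)
    )
    grads[[k]] <- res$dparams
    dH <- res$dH
  }
  c(grads, list(head = hb$dparams))
}

#' Predict activity scores
#'
#' @param model an `adcgnn_model`.
#' @param graphs list of `molecular_graph` objects.
#' @param aggregate average scores over records sharing a `mol_id`
#'   (multiple conformers of one molecule).
#' @return data.frame with `mol_id` and one score column per task
#'   (sigmoid of the logits).
#' @export
predict_scores <- function(model, graphs, aggregate = TRUE) {
  batch <- make_batch(graphs, use_coords = model$config$use_coords,
                      onehot_elements = model$config$onehot_elements)
  logits <- model_forward(model, batch)$logits
  scores <- 1 / (1 + exp(-logits))
  df <- data.frame(mol_id = batch$mol_ids, check.names = FALSE)
  for (t in seq_len(ncol(scores))) df[[paste0("score", t)]] <- scores[, t]
  if (aggregate && anyDuplicated(df$mol_id)) {
    df <- stats::aggregate(df[-1], by = list(mol_id = df$mol_id), FUN = mean)
  }
  df
}
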