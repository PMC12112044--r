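# Training: masked binary cross-entropy, AdamW with decoupled weight
# decay, node-budget dynamic batching, early stopping on a monitored
# validation metric, and the evaluation entry point.

#' Training configuration
#'
#' @param learning_rate initial AdamW learning rate (default 1e-4).
#' @param max_epochs maximum number of epochs (default 1000).
#' @param patience early-stopping patience in epochs without improvement
#'   of the monitored metric (default 50; must be < `max_epochs`).
#' @param batch_nodes dynamic batch sizing: target number of atoms per
#'   mini-batch (default 2000).
#' @param monitor_metric validation metric driving early stopping
#'   (default `"auc_roc"`; any `metrics_report` field).
#' @param weight_decay decoupled weight decay coefficient (default 0.01).
#' @param seed seed for shuffling and dropout.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 1000L,
                         patience = 50L, batch_nodes = 2000L,
                         monitor_metric = "auc_roc", weight_decay = 0.01,
                         seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1)
  if (patience >= max_epochs) {
    stop("patience must be smaller than max_epochs")
  }
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_nodes = as.integer(batch_nodes),
                 monitor_metric = monitor_metric,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Masked binary cross-entropy over logits
#'
#' Mean BCE over entries whose mask is 1; masked entries contribute
#' exactly zero to the value and the gradient. Computed in the
#' numerically stable logit form.
#'
#' @param logits numeric matrix (graphs x tasks) of raw logits.
#' @param labels 0/1 matrix of the same shape.
#' @param label_mask 0/1 matrix; 1 = label observed.
#' @return scalar loss with attribute `"grad"` (d loss / d logits).
#' @export
masked_loss <- function(logits, labels, label_mask = NULL) {
  logits <- as.matrix(logits); labels <- as.matrix(labels)
  if (is.null(label_mask)) label_mask <- labels * 0 + 1
  label_mask <- as.matrix(label_mask)
  stopifnot(all(dim(logits) == dim(labels)), all(dim(logits) == dim(label_mask)))
  m <- sum(label_mask)
  if (m == 0) stop("all labels are masked; loss undefined")
  # bce = max(x,0) - x*y + log(1 + exp(-|x|))
  per <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  loss <- sum(per * label_mask) / m
  grad <- (1 / (1 + exp(-logits)) - labels) * label_mask / m
  attr(loss, "grad") <- grad
  loss
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(theta) {
  list(m = theta * 0, v = theta * 0, t = 0L)
}

adamw_step <- function(theta, grad, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

# greedy node-budget batching: fill each mini-batch until adding another
# graph would exceed the atom budget
.node_budget_batches <- function(sizes, order_idx, budget) {
  batches <- list()
  cur <- integer(0); cur_n <- 0
  for (k in order_idx) {
    if (length(cur) > 0 && cur_n + sizes[k] > budget) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_n <- 0
    }
    cur <- c(cur, k); cur_n <- cur_n + sizes[k]
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  batches
}

#' Train a model with early stopping
#'
#' AdamW optimization of the masked BCE over node-budget mini-batches,
#' monitoring a validation metric each epoch. Returns the parameters of
#' the best epoch; training halts after `patience` epochs without strict
#' improvement or at `max_epochs`. Fully reproducible given the seeds in
#' the model and training configurations.
#'
#' @param model an [make_variant()] model (its parameters are the
#'   starting point).
#' @param train_graphs,valid_graphs lists of `molecular_graph` objects;
#'   multi-conformer molecules are scored per record and averaged per
#'   `mol_id` when the validation metric is computed.
#' @param config a [train_config()].
#' @param monitor_fn optional override: `function(model, epoch)` returning
#'   the monitored scalar (used by tests to inject a metric sequence).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best parameters), `history` (per-epoch
#'   data.frame: epoch, train_loss, monitor), `best_epoch` and
#'   `best_metric`.
#' @export
train_model <- function(model, train_graphs, valid_graphs, config,
                        monitor_fn = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "adcgnn_model"), inherits(config, "train_config"))
  if (length(train_graphs) == 0) stop("empty training partition")
  if (length(valid_graphs) == 0 && is.null(monitor_fn)) {
    stop("empty validation partition")
  }
  use_coords <- model$config$use_coords
  onehot <- model$config$onehot_elements
  sizes <- vapply(train_graphs, function(g) nrow(g$node_features), 1L)

  valid_eval <- function(mdl) {
    sc <- predict_scores(mdl, valid_graphs, aggregate = TRUE)
    lab <- .labels_by_mol(valid_graphs)
    rep_ <- metrics_report(sc$score1, lab[sc$mol_id])
    p <- pmin(pmax(sc$score1, 1e-12), 1 - 1e-12)
    y <- lab[sc$mol_id]
    list(metric = rep_[[config$monitor_metric]],
         loss = -mean(y * log(p) + (1 - y) * log(1 - p)))
  }

  template <- model_params(model)
  theta <- flatten_params(template)
  opt <- adamw_init(theta)
  best <- list(metric = -Inf, loss = Inf, epoch = 0L, theta = theta)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        monitor = numeric(0))

  for (epoch in seq_len(config$max_epochs)) {
    perm <- with_seed(config$seed * 10000L + epoch, sample.int(length(train_graphs)))
    batches <- .node_budget_batches(sizes, perm, config$batch_nodes)
    epoch_loss <- 0; n_obs <- 0
    for (bidx in batches) {
      batch <- make_batch(train_graphs[bidx], use_coords = use_coords,
                          onehot_elements = onehot)
      model <- set_model_params(model, unflatten_params(template, theta))
      drop_mask <- NULL
      if (model$config$dropout > 0) {
        drop_mask <- with_seed(config$seed * 100000L + opt$t + 1L, {
          lapply(seq_along(model$layers), function(k) {
            keep <- stats::rbinom(batch$n_nodes * model$config$hidden_dim, 1,
                                  1 - model$config$dropout)
            matrix(keep / (1 - model$config$dropout), batch$n_nodes)
          })
        })
      }
      fw <- model_forward(model, batch, keep_cache = TRUE,
                          dropout_mask = drop_mask)
      loss <- masked_loss(fw$logits, batch$labels, batch$mask)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d (lr %.3g); aborting",
                     epoch, config$learning_rate))
      }
      grads <- model_backward(model, batch, fw$caches, attr(loss, "grad"))
      gvec <- flatten_params(grads)
      st <- adamw_step(theta, gvec, opt, config$learning_rate,
                       config$weight_decay)
      theta <- st$theta; opt <- st$state
      nb <- sum(batch$mask)
      epoch_loss <- epoch_loss + as.numeric(loss) * nb
      n_obs <- n_obs + nb
    }
    model <- set_model_params(model, unflatten_params(template, theta))
    if (is.null(monitor_fn)) {
      ev <- valid_eval(model)
      metric <- ev$metric; vloss <- ev$loss
    } else {
      metric <- monitor_fn(model, epoch); vloss <- NA_real_
    }
    if (is.na(metric)) metric <- -Inf
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_obs,
                                         monitor = metric))
    # best epoch: highest monitored metric; exact ties resolved by lower
    # validation loss (keeps calibrating once a ranking metric saturates)
    improved <- metric > best$metric ||
      (!is.na(vloss) && metric == best$metric && vloss < best$loss)
    if (improved) {
      best <- list(metric = metric, loss = vloss, epoch = epoch, theta = theta)
    }
    if (verbose) {
      message(sprintf("epoch %3d loss %.4f monitor %.4f (best %.4f @ %d)",
                      epoch, epoch_loss / n_obs, metric, best$metric, best$epoch))
    }
    if (epoch - best$epoch >= config$patience) break
  }
  model <- set_model_params(model, unflatten_params(template, best$theta))
  list(model = model, history = history, best_epoch = best$epoch,
       best_metric = best$metric)
}

# per-molecule labels (first record wins; records of one molecule share
# their label vector)
.labels_by_mol <- function(graphs) {
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  lab <- vapply(graphs, function(g) g$labels[1], numeric(1))
  lab[match(unique(ids), ids)] -> out
  names(out) <- unique(ids)
  out
}

#' Evaluate a model on a partition
#'
#' Scores every record, averages scores of records sharing a `mol_id`,
#' and computes the eight-metric report at threshold 0.5.
#'
#' @param model an `adcgnn_model`.
#' @param graphs list of `molecular_graph` objects with labels.
#' @param task task index for multi-task models (default 1).
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, graphs, task = 1L) {
  if (length(graphs) == 0) stop("empty partition")
  sc <- predict_scores(model, graphs, aggregate = TRUE)
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  lab <- vapply(graphs, function(g) g$labels[task], numeric(1))
  lab <- lab[match(sc$mol_id, ids)]
  metrics_report(sc[[paste0("score", task)]], lab)
}
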