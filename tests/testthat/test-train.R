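test_that("masked BCE has the right closed forms and masking behavior", {
  # logits 0 on balanced labels: loss = ln 2
  l <- masked_loss(matrix(0, 4, 1), matrix(c(1, 0, 1, 0), 4, 1))
  expect_equal(as.numeric(l), log(2), tolerance = 1e-12)
  # near-perfect logits: loss ~ 0
  big <- matrix(c(20, -20), 2, 1)
  lp <- masked_loss(big, matrix(c(1, 0), 2, 1))
  expect_lt(as.numeric(lp), 1e-6)
  # a fully masked task contributes nothing
  logits <- matrix(rnorm(6), 3, 2)
  labels <- matrix(rbinom(6, 1, 0.5), 3, 2)
  mask <- cbind(rep(0, 3), rep(1, 3))
  l2 <- masked_loss(logits, labels, mask)
  l_single <- masked_loss(logits[, 2, drop = FALSE],
                          labels[, 2, drop = FALSE])
  expect_equal(as.numeric(l2), as.numeric(l_single), tolerance = 1e-12)
  g <- attr(l2, "grad")
  expect_true(all(g[, 1] == 0))
  expect_error(masked_loss(logits, labels, labels * 0), "masked")
})

test_that("masked loss gradient matches numerical differentiation", {
  set.seed(31)
  logits <- matrix(rnorm(8), 4, 2)
  labels <- matrix(rbinom(8, 1, 0.5), 4, 2)
  mask <- matrix(rbinom(8, 1, 0.7), 4, 2)
  if (sum(mask) == 0) mask[1, 1] <- 1
  l <- masked_loss(logits, labels, mask)
  g <- attr(l, "grad")
  eps <- 1e-6
  for (i in seq_along(logits)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (as.numeric(masked_loss(lp, labels, mask)) -
              as.numeric(masked_loss(lm, labels, mask))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("config validation rejects degenerate settings", {
  expect_error(train_config(patience = 100, max_epochs = 100), "patience")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_silent(train_config(patience = 5, max_epochs = 6))
})

test_that("early stopping halts patience epochs after the peak and returns peak parameters", {
  graphs <- generate_random_graphs(12, c(3, 6), seed = 71)
  cfg <- model_config("no_gat", hidden_dim = 8, use_coords = FALSE, seed = 5)
  model <- make_variant(cfg)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 50, patience = 5,
                     seed = 5)
  seq_metric <- c(0.5, 0.6, 0.9)           # peaks at epoch 3, then plateau
  captured <- new.env()
  monitor <- function(mdl, epoch) {
    if (epoch == 3) captured$theta3 <- flatten_params(model_params(mdl))
    if (epoch <= 3) seq_metric[epoch] else 0.9
  }
  fit <- train_model(model, graphs, list(), tc, monitor_fn = monitor)
  expect_equal(nrow(fit$history), 3 + 5)
  expect_equal(fit$best_epoch, 3)
  expect_identical(flatten_params(model_params(fit$model)), captured$theta3)
})

test_that("node-budget batching respects the budget and covers every graph", {
  sizes <- c(5, 30, 12, 8, 25, 3, 3, 3)
  b <- adcgnn:::.node_budget_batches(sizes, seq_along(sizes), 30)
  expect_setequal(unlist(b), seq_along(sizes))
  for (idx in b) {
    expect_true(sum(sizes[idx]) <= 30 || length(idx) == 1)
  }
})

test_that("seeded training is reproducible and learns a learnable task", {
  task <- generate_motif_task(motif_task_spec(n_molecules = 120, seed = 19))
  graphs <- graphs_from_table(task[, c("smiles", "mol_id", "label")],
                              deduplicate = FALSE)
  split <- scaffold_split(graphs, seed = 19)
  parts <- apply_split(graphs, split)
  cfg <- model_config("no_gat", hidden_dim = 16, use_coords = FALSE, seed = 19)
  tc <- train_config(learning_rate = 2e-3, max_epochs = 12, patience = 10,
                     seed = 19)
  fit1 <- train_model(make_variant(cfg), parts$train, parts$valid, tc)
  fit2 <- train_model(make_variant(cfg), parts$train, parts$valid, tc)
  expect_identical(flatten_params(model_params(fit1$model)),
                   flatten_params(model_params(fit2$model)))
  expect_identical(fit1$history, fit2$history)
  # validation ranking improves over the first epochs on this easy task
  expect_gt(max(fit1$history$monitor), fit1$history$monitor[1])
  # best parameters never come from an epoch after the best-metric epoch
  expect_lte(fit1$best_epoch, which.max(fit1$history$monitor) +
               sum(fit1$history$monitor == max(fit1$history$monitor)))
})

test_that("evaluation aggregates multi-conformer records per molecule", {
  g <- build_graph("CCO", labels = 1, mol_id = "m1")
  g2 <- build_graph("CCO", labels = 1, mol_id = "m1")   # second record
  g3 <- build_graph("CCCC", labels = 0, mol_id = "m2")
  cfg <- model_config("no_gat", hidden_dim = 8, use_coords = FALSE, seed = 2)
  model <- make_variant(cfg)
  sc <- predict_scores(model, list(g, g2, g3))
  expect_equal(nrow(sc), 2)                 # m1 aggregated
  r <- evaluate_model(model, list(g, g2, g3))
  expect_equal(r$n_pos + r$n_neg, 2)
})
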