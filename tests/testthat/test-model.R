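test_that("message-passing layer handles isolated nodes and hand-set weights", {
  # single node, identity activation, W = I, zero bias: output = input
  H <- matrix(c(1, -2, 3), 1, 3)
  p <- mpnn_init(3, 3)
  p$W <- diag(3); p$b <- rep(0, 3)
  batch <- batch_from_matrix(H, matrix(integer(0), 0, 2))
  out <- mpnn_forward(p, H, batch, activation = "identity")$out
  expect_equal(out, H)

  # 3-node path graph with small random weights matches the literal sum
  set.seed(21)
  H3 <- matrix(rnorm(9, sd = 0.5), 3, 3)
  edges <- cbind(src = c(1, 2, 2, 3), dst = c(2, 1, 3, 2))
  p3 <- with_seed(4, mpnn_init(3, 4))
  b3 <- batch_from_matrix(H3, edges)
  got <- mpnn_forward(p3, H3, b3, activation = "identity")$out
  want <- oracle_mpnn(p3, H3, edges, identity)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("attention weights are uniform over identical neighbors", {
  # star graph, identical leaf features: equal attention on every leaf
  n <- 5
  H <- rbind(c(1, 0, 0.5), matrix(rep(c(0.2, -1, 0.3), n - 1), n - 1, 3,
                                  byrow = TRUE))
  edges <- cbind(src = c(2:n, rep(1, n - 1)), dst = c(rep(1, n - 1), 2:n))
  p <- with_seed(8, gat_init(3, 4, n_heads = 2, combine = "concat"))
  batch <- batch_from_matrix(H, edges)
  fw <- gat_forward(p, H, batch, n_heads = 2, combine = "concat")
  ed <- gat_edges(batch)
  for (h in 1:2) {
    # weights of hub -> each identical leaf must be equal
    leaf_w <- fw$cache$alpha[ed$dst == 1 & ed$src != 1, h]
    expect_equal(max(leaf_w) - min(leaf_w), 0, tolerance = 1e-12)
  }
  # a node with two identical-feature neighbors gets alpha 0.5/0.5 after
  # removing the self edge contribution
  H2 <- matrix(rep(1, 3 * 3), 3, 3)
  edges2 <- cbind(src = c(1, 3, 2, 2), dst = c(2, 2, 1, 3))
  b2 <- batch_from_matrix(H2, edges2)
  fw2 <- gat_forward(p, H2, b2, n_heads = 2)
  ed2 <- gat_edges(b2)
  w <- fw2$cache$alpha[ed2$dst == 2, 1]
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-10)  # all features equal
})

test_that("attention weights normalize to one per node, head and layer", {
  graphs <- generate_random_graphs(25, c(2, 9), seed = 31)
  batch <- make_batch(graphs)
  cfg <- model_config("full", hidden_dim = 16, n_heads = 8,
                      use_coords = FALSE, seed = 6)
  model <- make_variant(cfg)
  fw <- model_forward(model, batch)
  for (att in fw$attention) {
    for (h in seq_len(ncol(att$alpha))) {
      sums <- rowsum(att$alpha[, h], att$dst)
      expect_lt(max(abs(sums - 1)), 1e-6)
    }
  }
})

test_that("mean-aggregation layer follows its update rule exactly", {
  # identical features, W = I, identity act: h' = 2v for connected nodes
  v <- c(0.5, -1, 2)
  H <- matrix(rep(v, 4), 4, 3, byrow = TRUE)
  edges <- cbind(src = c(1, 2, 2, 3), dst = c(2, 1, 3, 2))  # node 4 isolated
  p <- sage_init(3, 3); p$W <- diag(3); p$b <- rep(0, 3)
  batch <- batch_from_matrix(H, edges)
  out <- sage_forward(p, H, batch, activation = "identity")$out
  expect_equal(out[1, ], 2 * v)
  expect_equal(out[2, ], 2 * v)
  expect_equal(out[4, ], v)            # isolated: empty mean is zero
})

test_that("readout pools means per graph and applies the linear head", {
  g1 <- generate_random_graphs(1, c(3, 3), seed = 1)[[1]]
  g2 <- generate_random_graphs(1, c(1, 1), seed = 2)[[1]]
  u <- c(1, 2, 3, 4, 5)
  g1$node_features <- matrix(rep(u, 3), 3, 5, byrow = TRUE,
                             dimnames = dimnames(g1$node_features))
  batch <- make_batch(list(g1, g2))
  p <- readout_init(5, 2)
  res <- readout_forward(p, batch$X, batch)
  expect_equal(res$cache$pooled[1, ], u)
  # zero weights: logits equal the bias for every graph
  p0 <- list(W = matrix(0, 5, 2), b = c(0.3, -0.7))
  res0 <- readout_forward(p0, batch$X, batch)
  expect_equal(res0$out, matrix(rep(c(0.3, -0.7), each = 2), 2, 2))
})

test_that("variant factory is seeded, structured and validated", {
  cfg <- model_config("full", hidden_dim = 16, use_coords = FALSE, seed = 9)
  m1 <- make_variant(cfg)
  m2 <- make_variant(cfg)
  expect_identical(flatten_params(model_params(m1)),
                   flatten_params(model_params(m2)))
  n_full <- length(flatten_params(model_params(m1)))
  m_nogat <- make_variant(model_config("no_gat", hidden_dim = 16,
                                       use_coords = FALSE, seed = 9))
  expect_gt(n_full, length(flatten_params(model_params(m_nogat))))
  m_gcn <- make_variant(model_config("baseline_gcn5", hidden_dim = 16,
                                     use_coords = FALSE, seed = 9))
  types <- vapply(m_gcn$layers, function(l) l$type, character(1))
  expect_equal(types, rep("gcn", 5))
  dims <- vapply(m_gcn$layers, function(l) ncol(l$params$W), 1L)
  expect_true(all(dims == 16))
  expect_error(model_config("bogus"), "unknown variant")
  expect_error(model_config("full", hidden_dim = 30, n_heads = 8),
               "divisible")
})

test_that("graph-level logits are invariant to node relabeling for every variant", {
  graphs <- generate_random_graphs(4, c(3, 8), seed = 41, with_coords = TRUE)
  for (variant in c("full", "smiles_only", "no_mpnn", "no_gat", "no_sage",
                    "baseline_mpnn5", "baseline_gat5", "baseline_sage5",
                    "baseline_gcn5")) {
    cfg <- model_config(variant, hidden_dim = 16, n_heads = 4,
                        use_coords = variant != "smiles_only", seed = 13)
    model <- make_variant(cfg)
    base <- model_forward(model, make_batch(graphs, cfg$use_coords))$logits
    for (rep_ in 1:3) {
      perm_graphs <- lapply(graphs, function(g) {
        permute_graph(g, sample(nrow(g$node_features)))
      })
      got <- model_forward(model, make_batch(perm_graphs, cfg$use_coords))$logits
      expect_lt(max(abs(got - base)), 1e-5)
    }
  }
})

test_that("coordinate use is variant-consistent", {
  graphs <- generate_random_graphs(6, c(3, 8), seed = 51, with_coords = TRUE)
  # smiles_only never reads coordinates: bit-identical logits
  cfg2d <- model_config("smiles_only", hidden_dim = 16, seed = 3)
  m2d <- make_variant(cfg2d)
  l1 <- model_forward(m2d, make_batch(graphs, use_coords = FALSE))$logits
  moved <- lapply(graphs, function(g) {
    g$coords <- g$coords + matrix(rnorm(length(g$coords)), nrow(g$coords))
    g
  })
  l2 <- model_forward(m2d, make_batch(moved, use_coords = FALSE))$logits
  expect_identical(l1, l2)
  # the full variant demands coordinates
  cfg3d <- model_config("full", hidden_dim = 16, seed = 3)
  m3d <- make_variant(cfg3d)
  no3d <- generate_random_graphs(2, c(3, 5), seed = 52)
  expect_error(model_forward(m3d, make_batch(no3d, use_coords = TRUE)),
               "coordinates")
})

test_that("every layer backward matches numerical gradients", {
  graphs <- generate_random_graphs(3, c(2, 6), seed = 61)
  batch <- make_batch(graphs)
  for (variant in c("full", "baseline_gcn5")) {
    cfg <- model_config(variant, hidden_dim = 8, n_heads = 2,
                        use_coords = FALSE, seed = 17)
    model <- make_variant(cfg)
    template <- model_params(model)
    theta <- flatten_params(template)
    lossfn <- function(th) {
      m <- set_model_params(model, unflatten_params(template, th))
      fw <- model_forward(m, batch)
      as.numeric(masked_loss(fw$logits, batch$labels, batch$mask))
    }
    fw <- model_forward(model, batch, keep_cache = TRUE)
    loss <- masked_loss(fw$logits, batch$labels, batch$mask)
    gvec <- flatten_params(model_backward(model, batch, fw$caches,
                                          attr(loss, "grad")))
    idx <- with_seed(1, sample(length(theta), 60))
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps; f1 <- lossfn(tp)
      tp[i] <- theta[i] - eps; f0 <- lossfn(tp)
      (f1 - f0) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gvec[idx])), 1e-6)
  }
})

test_that("checkpoints round-trip through JSON", {
  cfg <- model_config("no_sage", hidden_dim = 8, n_heads = 2,
                      use_coords = FALSE, seed = 23)
  model <- make_variant(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  # checkpoints store parameters as decimal text (15 significant digits)
  expect_equal(flatten_params(model_params(back)),
               flatten_params(model_params(model)), tolerance = 1e-12)
  expect_equal(back$config$variant, "no_sage")
  graphs <- generate_random_graphs(3, c(2, 5), seed = 3)
  b <- make_batch(graphs)
  expect_equal(model_forward(back, b)$logits, model_forward(model, b)$logits,
               tolerance = 1e-12)
})
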