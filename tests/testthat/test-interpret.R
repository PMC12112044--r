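# small fixed model + molecule set shared by the attribution tests
interp_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    graphs <- graphs_from_table(data.frame(
      smiles = c("COC(C)=O", "CCOC(C)=O", "CCO", "c1ccccc1", "Cc1ccccc1",
                 "C1CCCC1", "CCCCC"),
      mol_id = paste0("m", 1:7)), deduplicate = FALSE)
    cfg <- model_config("no_sage", hidden_dim = 16, n_heads = 4,
                        use_coords = FALSE, seed = 27)
    model <- make_variant(cfg)
    records <- collect_attention(model, graphs)
    cache <<- list(graphs = graphs, model = model, records = records)
    cache
  }
})

test_that("attention collection emits normalized, deterministic records", {
  fx <- interp_fixture()
  records <- fx$records
  expect_setequal(unique(records$layer), 1:3)
  expect_setequal(unique(records$head), 1:4)
  # per (mol, layer, head, target atom) weights sum to one
  sums <- aggregate(weight ~ mol_id + layer + head + i, data = records, sum)
  expect_lt(max(abs(sums$weight - 1)), 1e-6)
  # deterministic across repeated calls
  again <- collect_attention(fx$model, fx$graphs)
  expect_equal(records, again)
  # a model without attention layers cannot provide records
  m2 <- make_variant(model_config("no_gat", hidden_dim = 8,
                                  use_coords = FALSE, seed = 1))
  expect_error(collect_attention(m2, fx$graphs), "no attention layers")
})

test_that("single-node graphs carry all attention on the self edge", {
  g <- build_graph("C", mol_id = "meth")
  model <- make_variant(model_config("no_mpnn", hidden_dim = 8, n_heads = 2,
                                     use_coords = FALSE, seed = 3))
  rec <- collect_attention(model, list(g))
  expect_true(all(rec$i == 1 & rec$j == 1))
  expect_true(all(abs(rec$weight - 1) < 1e-12))
})

test_that("attention summary has the right closed forms and bounds", {
  # uniform pooled distribution over K outcomes: entropy = ln K
  for (K in c(2, 8, 128)) {
    rec <- data.frame(mol_id = "m", layer = 1,
                      head = rep(1:2, each = K / 2),
                      i = seq_len(K), j = seq_len(K), weight = 1 / 3)
    s <- summarize_attention(rec)
    expect_equal(s$entropy, log(K), tolerance = 1e-9)
  }
  # uniform head importance over 8 heads: effective heads = 8
  rec8 <- data.frame(mol_id = "m", layer = 1, head = rep(1:8, each = 4),
                     i = rep(1:4, 8), j = rep(1:4, 8), weight = 0.25)
  s8 <- summarize_attention(rec8)
  expect_equal(s8$effective_heads, 8, tolerance = 1e-9)
  # one-hot head importance: effective heads = 1
  rec1 <- rec8
  rec1$weight <- ifelse(rec1$head == 3, 0.25, 0)
  s1 <- summarize_attention(rec1)
  expect_equal(s1$effective_heads, 1, tolerance = 1e-9)
  # bounds on real records; pooled renormalization sums to one
  fx <- interp_fixture()
  s <- summarize_attention(fx$records)
  expect_true(all(s$effective_heads >= 1 - 1e-9))
  expect_true(all(s$effective_heads <= 4 + 1e-9))
  expect_true(all(s$entropy >= 0))
  hi <- attr(s, "head_importance")
  expect_equal(unname(rowSums(hi)), rep(1, nrow(hi)), tolerance = 1e-9)
  expect_error(summarize_attention(fx$records[0, ]), "no attention")
})

test_that("SMARTS attribution counts matches and pools matched-atom scores", {
  fx <- interp_fixture()
  atts <- attribute_smarts(fx$graphs, fx$records, c("COC(=O)", "C[OH]"))
  ester <- atts[[1]]; hydroxyl <- atts[[2]]
  expect_equal(ester$n_molecules_matched, 2)     # both acetate esters
  expect_equal(hydroxyl$n_molecules_matched, 1)  # ethanol only
  expect_true(is.finite(ester$mean_attention))
  none <- attribute_smarts(fx$graphs[4], fx$records, "C[OH]")[[1]]
  expect_equal(none$n_molecules_matched, 0)
  expect_true(is.na(none$mean_attention))
  expect_error(attribute_smarts(fx$graphs, fx$records, "[[bad"),
               class = "adcgnn_smarts_error")
})

test_that("scaffold, fragment and ring attributions group molecules correctly", {
  fx <- interp_fixture()
  mk <- attribute_murcko(fx$graphs, fx$records)
  keys <- vapply(mk, function(a) a$pattern, character(1))
  benzene <- mk[[which(keys == canonical_smiles("c1ccccc1"))]]
  expect_equal(benzene$n_molecules_matched, 2)   # benzene + toluene
  empty <- mk[[which(keys == "")]]
  expect_equal(empty$n_molecules_matched, 0)     # acyclic group
  expect_equal(length(empty$matches[["m3"]]), 0)

  br <- attribute_brics(fx$graphs, fx$records)
  expect_gt(length(br), 1)
  tab <- attributions_table(c(mk, br))
  expect_true(all(c("kind", "pattern", "mean_attention") %in% names(tab)))

  ring5 <- ring_system_attribution(fx$graphs, fx$records, ring_size = 5)
  expect_equal(ring5$n_molecules_matched, 1)     # cyclopentane only
  expect_length(ring5$matches[["m6"]], 5)
  ring6 <- ring_system_attribution(fx$graphs, fx$records, ring_size = 6)
  expect_equal(ring6$n_molecules_matched, 2)
})

test_that("uniform attention makes every attribution identical", {
  fx <- interp_fixture()
  # force uniform weights: every edge of every head gets equal mass
  rec <- fx$records
  rec$weight <- 0.125
  atts <- c(attribute_smarts(fx$graphs, rec, c("COC(=O)", "C[OH]", "[#6]")),
            attribute_murcko(fx$graphs, rec),
            attribute_brics(fx$graphs, rec),
            list(ring_system_attribution(fx$graphs, rec, 5)))
  means <- vapply(atts, function(a) a$mean_attention, numeric(1))
  means <- means[!is.na(means)]
  expect_lt(max(means) - min(means), 1e-9)
})
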