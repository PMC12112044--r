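test_that("atom featurization matches known chemistry on small molecules", {
  eth <- parse_smiles("CCO")[[1]]
  f1 <- featurize_atom(eth, 1)
  expect_equal(unname(f1[c("atomic_number", "degree", "num_hydrogens",
                           "is_aromatic")]), c(6, 1, 3, 0))
  f3 <- featurize_atom(eth, 3)
  expect_equal(unname(f3[c("atomic_number", "degree", "num_hydrogens",
                           "is_aromatic")]), c(8, 1, 1, 0))
  benz <- parse_smiles("c1ccccc1")[[1]]
  for (a in 1:6) {
    f <- featurize_atom(benz, a)
    expect_equal(unname(f["is_aromatic"]), 1)
    expect_equal(unname(f["degree"]), 2)
  }
  expect_error(featurize_atom(eth, 4), "out of range")
})

test_that("featurization agrees atom-by-atom with the frozen toolkit panel", {
  panel <- readLines(test_path("fixtures", "featurization_panel.smi"))
  expected <- read.csv(test_path("fixtures", "featurization_panel_expected.csv"))
  mols <- parse_smiles(panel)
  got <- do.call(rbind, lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    do.call(rbind, lapply(seq_len(m$n_atoms), function(a) {
      f <- featurize_atom(m, a)
      data.frame(smiles = panel[k], atom = a,
                 atomic_number = f[["atomic_number"]],
                 degree = f[["degree"]],
                 num_hydrogens = f[["num_hydrogens"]],
                 implicit_valence = f[["implicit_valence"]],
                 is_aromatic = f[["is_aromatic"]])
    }))
  }))
  m <- merge(got, expected, by = c("smiles", "atom"),
             suffixes = c(".got", ".exp"))
  expect_equal(nrow(m), nrow(expected))
  for (f in c("atomic_number", "degree", "num_hydrogens",
              "implicit_valence", "is_aromatic")) {
    expect_identical(as.integer(m[[paste0(f, ".got")]]),
                     as.integer(m[[paste0(f, ".exp")]]),
                     label = f)
  }
})

test_that("build_graph produces the directed edge index and handles edge cases", {
  g <- build_graph("CCO")
  expect_equal(nrow(g$node_features), 3)
  expect_equal(nrow(g$edge_index), 4)
  pairs <- paste(g$edge_index[, 1], g$edge_index[, 2])
  expect_setequal(pairs, c("1 2", "2 1", "2 3", "3 2"))

  g1 <- build_graph("C")
  expect_equal(nrow(g1$node_features), 1)
  expect_equal(nrow(g1$edge_index), 0)

  hexagon <- 1.4 * cbind(cos(2 * pi * (0:5) / 6 + 1), sin(2 * pi * (0:5) / 6 + 1), 0)
  gb <- build_graph("c1ccccc1", coords = hexagon + 5)  # offset gets centered
  expect_equal(nrow(gb$edge_index), 12)
  expect_equal(colMeans(gb$coords), c(x = 0, y = 0, z = 0), tolerance = 1e-6)

  expect_error(build_graph("not-a-smiles[["), class = "adcgnn_parse_error")
  expect_error(build_graph("CCO", coords = matrix(0, 2, 3)), "coords")
})

test_that("edge symmetry holds across many generated molecules", {
  task <- generate_motif_task(motif_task_spec(n_molecules = 60, seed = 11))
  graphs <- graphs_from_table(task[, c("smiles", "mol_id", "label")],
                              deduplicate = FALSE)
  rnd <- generate_random_graphs(60, seed = 12)
  for (g in c(graphs, rnd)) {
    ei <- g$edge_index
    if (nrow(ei) == 0) next
    expect_true(all(ei[, 1] != ei[, 2]))  # no self loops
    expect_true(all(ei >= 1 & ei <= nrow(g$node_features)))
    key <- paste(ei[, 1], ei[, 2])
    rev <- paste(ei[, 2], ei[, 1])
    expect_setequal(key, rev)
  }
})

test_that("IC50 binarization is strict at the cutoff and rejects bad input", {
  expect_equal(label_from_ic50(50), 1L)
  expect_equal(label_from_ic50(250), 0L)
  expect_equal(label_from_ic50(100), 0L)   # boundary is negative
  expect_equal(label_from_ic50(c(0.5, 99.99, 100.01), cutoff_uM = 100),
               c(1L, 1L, 0L))
  expect_error(label_from_ic50(-1), "positive")
  expect_error(label_from_ic50(0), "positive")
})

test_that("conformer pruning keeps RMSD-distinct conformers, greedily in order", {
  set.seed(5)
  a <- matrix(rnorm(15), 5, 3)
  # identical coordinate sets collapse to one
  cs <- conformer_set("m1", list(a, a))
  expect_length(prune_conformers(cs)$conformers, 1)
  # a rigidly rotated + translated copy has RMSD 0 after superposition
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cs2 <- conformer_set("m2", list(a, a %*% rot + 2))
  expect_length(prune_conformers(cs2)$conformers, 1)
  # single conformer returned unchanged
  one <- prune_conformers(conformer_set("m3", list(a)))
  expect_equal(one$conformers[[1]]$coords, a)
  # distinct conformer above the cutoff is kept; idempotence
  b <- a + matrix(rnorm(15, sd = 3), 5, 3)
  r <- kabsch_rmsd(a, b)
  expect_gt(r, 1.5)
  cs3 <- conformer_set("m4", list(a, b, a))
  pruned <- prune_conformers(cs3)
  expect_length(pruned$conformers, 2)
  expect_equal(prune_conformers(pruned), pruned)
  expect_error(conformer_set("m", list()), "conformer")
})

test_that("Kabsch RMSD agrees with an independent superposition routine", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    b <- matrix(rnorm(3 * n), n, 3)
    ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
    expect_equal(kabsch_rmsd(a, b), ref, tolerance = 1e-3)
  }
})

test_that("graphs round-trip through the JSON-lines interchange format", {
  hexagon <- 1.4 * cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  graphs <- list(
    build_graph("CCO", labels = 1, mol_id = "a"),
    build_graph("C", labels = 0, mol_id = "b"),
    build_graph("c1ccccc1", coords = hexagon, labels = c(1, NA), mol_id = "c")
  )
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_graphs_jsonl(graphs, f)
  back <- read_graphs_jsonl(f)
  for (k in seq_along(graphs)) {
    expect_identical(back[[k]]$node_features, graphs[[k]]$node_features)
    expect_identical(back[[k]]$edge_index, graphs[[k]]$edge_index)
    expect_equal(back[[k]]$coords, graphs[[k]]$coords)
    expect_equal(back[[k]]$labels, graphs[[k]]$labels)
    expect_equal(back[[k]]$label_mask, graphs[[k]]$label_mask)
    expect_identical(back[[k]]$mol_id, graphs[[k]]$mol_id)
  }
})

test_that("table readers parse labels and masks; duplicates collapse on ingestion", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("smiles,act,tox\nCCO,1,\nOCC,0,1\nc1ccccc1,0,0", csv)
  df <- read_molecule_csv(csv)
  expect_true(is.na(df$tox[1]))
  graphs <- graphs_from_table(df)
  expect_length(graphs, 2)            # CCO and OCC are the same molecule
  expect_equal(graphs[[1]]$labels, c(1, 0))
  expect_equal(graphs[[1]]$label_mask, c(1, 0))

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO\t1", "CCN\t0"), smi)
  df2 <- read_smi(smi)
  expect_equal(df2$smiles, c("CCO", "CCN"))
  expect_equal(df2$task1, c(1, 0))
})
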