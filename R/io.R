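# Dataset readers and the JSON-lines interchange format.

#' Read a SMILES list file
#'
#' One record per line: a SMILES string optionally followed by
#' tab-separated label columns. Lines starting with `#` are skipped.
#'
#' @param file path to a `.smi` file.
#' @return data.frame with a `smiles` column and numeric task columns.
#' @export
read_smi <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1)
  ncol_lab <- max(lengths(parts)) - 1L
  out <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
  if (ncol_lab > 0) {
    for (k in seq_len(ncol_lab)) {
      out[[paste0("task", k)]] <- suppressWarnings(as.numeric(
        vapply(parts, function(p) if (length(p) > k) p[k + 1] else NA_character_,
               character(1))))
    }
  }
  out
}

#' Read a molecule CSV
#'
#' Requires a `smiles` column; every other column is treated as a binary
#' task label. Empty cells become masked labels (NA).
#'
#' @param file path to a CSV file.
#' @return data.frame with `smiles` plus numeric task columns.
#' @export
read_molecule_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"smiles" %in% names(df)) stop("CSV must contain a 'smiles' column")
  task_cols <- setdiff(names(df), c("smiles", "mol_id"))
  for (cc in task_cols) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Build molecular graphs for a labeled molecule table
#'
#' Canonicalizes all SMILES, collapses duplicates (same canonical SMILES;
#' the first label row wins) and builds one [build_graph()] per unique
#' molecule. NA labels become masked entries.
#'
#' @param df data.frame with `smiles`, optional `mol_id`, and task columns.
#' @param deduplicate collapse duplicate canonical SMILES (default TRUE).
#' @return list of `molecular_graph` objects.
#' @export
graphs_from_table <- function(df, deduplicate = TRUE) {
  stopifnot("smiles" %in% names(df))
  task_cols <- setdiff(names(df), c("smiles", "mol_id"))
  can <- canonical_smiles(df$smiles)
  bad <- which(is.na(can))
  if (length(bad)) adcgnn_parse_error(df$smiles[bad[1]])
  if (deduplicate) {
    keep <- !duplicated(can)
    df <- df[keep, , drop = FALSE]
    can <- can[keep]
  }
  ids <- if ("mol_id" %in% names(df)) as.character(df$mol_id) else
    sprintf("mol%04d", seq_along(can))
  mols <- parse_smiles(can, mol_id = ids)
  lapply(seq_along(mols), function(k) {
    labels <- if (length(task_cols)) as.numeric(df[k, task_cols]) else 0
    build_graph(can[k], labels = labels, mol_id = ids[k], mol = mols[[k]])
  })
}

#' Write molecular graphs as JSON lines
#'
#' One JSON object per line with fields `mol_id`, `smiles`,
#' `node_features` (row-major array of arrays), `edge_index` (0-based
#' `[src, dst]` pairs), `coords` (or null), `labels` and `label_mask`.
#'
#' @param graphs list of `molecular_graph` objects.
#' @param file output path.
#' @export
write_graphs_jsonl <- function(graphs, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (g in graphs) {
    rec <- list(
      mol_id = g$mol_id, smiles = g$smiles,
      node_features = unname(apply(g$node_features, 1, as.numeric, simplify = FALSE)),
      edge_index = if (nrow(g$edge_index)) {
        unname(apply(g$edge_index - 1L, 1, as.integer, simplify = FALSE))
      } else list(),
      coords = if (!is.null(g$coords)) {
        unname(apply(g$coords, 1, as.numeric, simplify = FALSE))
      } else NULL,
      labels = as.numeric(g$labels), label_mask = as.numeric(g$label_mask)
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(file)
}

#' Read molecular graphs from JSON lines
#'
#' Inverse of [write_graphs_jsonl()]. The parsed chemistry (`mol`) is not
#' stored in the interchange format; it is re-derived lazily from the
#' SMILES when a downstream operation needs it.
#'
#' @param file path written by [write_graphs_jsonl()].
#' @param parse_mols re-parse SMILES into `adc_mol` objects (default FALSE).
#' @return list of `molecular_graph` objects.
#' @export
read_graphs_jsonl <- function(file, parse_mols = FALSE) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    nf <- rec$node_features
    if (!is.matrix(nf)) nf <- matrix(nf, nrow = 1)
    storage.mode(nf) <- "double"
    dimnames(nf) <- list(NULL, ATOM_FEATURE_NAMES[seq_len(ncol(nf))])
    ei <- if (length(rec$edge_index)) {
      m <- matrix(as.integer(rec$edge_index), ncol = 2) + 1L
      colnames(m) <- c("src", "dst"); m
    } else matrix(integer(0), 0, 2, dimnames = list(NULL, c("src", "dst")))
    coords <- if (!is.null(rec$coords)) {
      m <- matrix(as.numeric(rec$coords), ncol = 3)
      colnames(m) <- c("x", "y", "z"); m
    } else NULL
    mol <- if (parse_mols) parse_smiles(rec$smiles, mol_id = rec$mol_id)[[1]] else NULL
    structure(list(
      node_features = nf, edge_index = ei, coords = coords,
      labels = as.numeric(rec$labels), label_mask = as.numeric(rec$label_mask),
      mol_id = rec$mol_id, smiles = rec$smiles, mol = mol
    ), class = "molecular_graph")
  })
}

#' Parsed molecule of a graph
#'
#' Returns the graph's `adc_mol`, re-parsing the stored canonical SMILES
#' lazily when the chemistry was dropped (e.g. after a JSONL round trip).
#'
#' @param g a `molecular_graph`.
#' @return an `adc_mol`.
#' @export
graph_mol <- function(g) {
  if (is.null(g$mol)) parse_smiles(g$smiles, mol_id = g$mol_id)[[1]] else g$mol
}
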