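# Attention-based interpretability: layer-wise attention collection,
# entropy / effective-head summaries, and substructure attribution via
# SMARTS patterns, Murcko scaffolds, BRICS fragments and ring systems.

#' Collect per-edge attention weights
#'
#' Runs the model over the graphs and emits one record per (molecule,
#' attention layer, head, directed attention edge) including the
#' transient self-loop edges. Weights over the neighbors of a fixed
#' target atom sum to 1 per layer and head.
#'
#' @param model an `adcgnn_model` whose variant contains GAT layers.
#' @param graphs list of `molecular_graph` objects.
#' @return data.frame with columns `mol_id`, `layer`, `head`, `i` (target
#'   atom), `j` (source atom; 1-based within the molecule) and `weight`.
#' @export
collect_attention <- function(model, graphs) {
  has_gat <- any(vapply(model$layers, function(l) l$type == "gat", logical(1)))
  if (!has_gat) {
    stop(sprintf("variant '%s' has no attention layers; attention collection unavailable",
                 model$config$variant))
  }
  batch <- make_batch(graphs, use_coords = model$config$use_coords,
                      onehot_elements = model$config$onehot_elements)
  fw <- model_forward(model, batch)
  recs <- lapply(fw$attention, function(att) {
    gid <- batch$graph_id[att$dst]
    off <- batch$node_offset[gid]
    n_heads <- ncol(att$alpha)
    data.frame(
      mol_id = rep(batch$mol_ids[gid], n_heads),
      layer = att$layer_index,
      head = rep(seq_len(n_heads), each = length(att$dst)),
      i = rep(att$dst - off, n_heads),
      j = rep(att$src - off, n_heads),
      weight = as.numeric(att$alpha)
    )
  })
  do.call(rbind, recs)
}

#' Layer-wise attention summary
#'
#' For each attention layer: the Shannon entropy (nats) of the pooled
#' attention-weight distribution (weights pooled over molecules, heads
#' and edges, renormalized to sum to 1), the mean and standard deviation
#' of the raw weights, the head-importance distribution (each head's
#' share of total attention mass), its variance (`diversity`), and the
#' effective number of heads, exp(entropy of head importance), which
#' ranges from 1 (one dominant head) to `n_heads` (uniform use).
#'
#' @param records attention records from [collect_attention()].
#' @return an `attention_summary`: data.frame with one row per layer and
#'   columns `layer`, `entropy`, `mean`, `std`, `effective_heads`,
#'   `diversity`, plus a `head_importance` matrix attribute
#'   (layers x heads).
#' @export
summarize_attention <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no attention records")
  layers <- sort(unique(records$layer))
  heads <- sort(unique(records$head))
  hi_mat <- matrix(0, length(layers), length(heads),
                   dimnames = list(paste0("layer", layers),
                                   paste0("head", heads)))
  out <- do.call(rbind, lapply(seq_along(layers), function(li) {
    r <- records[records$layer == layers[li], ]
    w <- r$weight
    p <- w / sum(w)
    entropy <- -sum(ifelse(p > 0, p * log(p), 0))
    mass <- vapply(heads, function(h) sum(r$weight[r$head == h]), numeric(1))
    hi <- mass / sum(mass)
    hi_mat[li, ] <<- hi
    h_ent <- -sum(ifelse(hi > 0, hi * log(hi), 0))
    data.frame(layer = layers[li], entropy = entropy,
               mean = mean(w), std = stats::sd(w),
               effective_heads = exp(h_ent),
               diversity = stats::var(hi))
  }))
  structure(out, head_importance = hi_mat,
            class = c("attention_summary", "data.frame"))
}

#' Per-atom attention scores
#'
#' The attention score of an atom is the mean weight it attracts from
#' its attending neighbors (edges where the atom is the message source,
#' self-edges included), averaged over the heads of the chosen layer
#' (default: the final attention layer). The weights an atom pays out
#' sum to one by construction and carry only degree information, so the
#' attracted direction is the informative one.
#'
#' @param records attention records from [collect_attention()].
#' @param layer layer index (default: last).
#' @return data.frame with `mol_id`, `atom`, `score`.
#' @export
atom_attention_scores <- function(records, layer = NULL) {
  if (is.null(layer)) layer <- max(records$layer)
  r <- records[records$layer == layer, ]
  agg <- stats::aggregate(weight ~ mol_id + j, data = r, FUN = mean)
  names(agg) <- c("mol_id", "atom", "score")
  agg
}

# shared aggregation: given per-molecule matched atom sets, pool the
# atom scores and build one attribution entry
.make_attribution <- function(kind, pattern, matched_atoms, scores_df) {
  mol_ids <- names(matched_atoms)
  vals <- numeric(0)
  n_matched <- 0L
  for (id in mol_ids) {
    atoms <- matched_atoms[[id]]
    if (length(atoms) == 0) next
    n_matched <- n_matched + 1L
    sc <- scores_df$score[scores_df$mol_id == id & scores_df$atom %in% atoms]
    vals <- c(vals, sc)
  }
  structure(list(
    kind = kind, pattern = pattern, matches = matched_atoms,
    n_molecules_matched = n_matched,
    n_atoms = length(vals),
    mean_attention = if (length(vals)) mean(vals) else NA_real_,
    std_attention = if (length(vals) > 1) stats::sd(vals) else
      if (length(vals) == 1) 0 else NA_real_
  ), class = "substructure_attribution")
}

#' @export
print.substructure_attribution <- function(x, ...) {
  cat(sprintf("<%s '%s': %d molecule(s), %d atom(s), attention %.4f +/- %.4f>\n",
              x$kind, x$pattern, x$n_molecules_matched, x$n_atoms,
              ifelse(is.na(x$mean_attention), NaN, x$mean_attention),
              ifelse(is.na(x$std_attention), NaN, x$std_attention)))
  invisible(x)
}

#' Flatten attributions into a table
#'
#' @param attributions list of attribution entries.
#' @return data.frame with kind, pattern, n_molecules_matched, n_atoms,
#'   mean_attention, std_attention.
#' @export
attributions_table <- function(attributions) {
  do.call(rbind, lapply(attributions, function(a) {
    data.frame(kind = a$kind, pattern = a$pattern,
               n_molecules_matched = a$n_molecules_matched,
               n_atoms = a$n_atoms, mean_attention = a$mean_attention,
               std_attention = a$std_attention)
  }))
}

#' SMARTS-pattern attention attribution
#'
#' Matches each pattern against every molecule and pools the per-atom
#' attention scores of the matched atoms.
#'
#' @param graphs list of `molecular_graph` objects.
#' @param records attention records from [collect_attention()].
#' @param smarts_patterns character vector of SMARTS patterns.
#' @param layer attention layer for the atom scores (default: last).
#' @return list of `substructure_attribution` entries, one per pattern.
#' @export
attribute_smarts <- function(graphs, records, smarts_patterns, layer = NULL) {
  scores <- atom_attention_scores(records, layer)
  queries <- lapply(smarts_patterns, parse_smarts)
  lapply(seq_along(queries), function(qi) {
    matched <- lapply(graphs, function(g) {
      hits <- smarts_match(graph_mol(g), queries[[qi]])
      sort(unique(unlist(hits)))
    })
    names(matched) <- vapply(graphs, function(g) g$mol_id, character(1))
    .make_attribution("smarts", smarts_patterns[qi], matched, scores)
  })
}

#' Murcko-scaffold attention attribution
#'
#' Computes the Bemis-Murcko scaffold of every molecule and aggregates
#' the attention over scaffold atoms, one entry per distinct scaffold.
#' Acyclic molecules fall into the empty-scaffold entry with no matched
#' atoms.
#'
#' @inheritParams attribute_smarts
#' @return list of `substructure_attribution` entries (kind
#'   `"murcko_scaffold"`).
#' @export
attribute_murcko <- function(graphs, records, layer = NULL) {
  scores <- atom_attention_scores(records, layer)
  scafs <- lapply(graphs, function(g) murcko_scaffold(graph_mol(g)))
  keys <- vapply(scafs, function(s) s$smiles, character(1))
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  lapply(unique(keys), function(key) {
    sel <- which(keys == key)
    matched <- lapply(sel, function(k) scafs[[k]]$atoms)
    names(matched) <- ids[sel]
    a <- .make_attribution("murcko_scaffold", key, matched, scores)
    if (key == "") a$n_molecules_matched <- 0L
    a
  })
}

#' BRICS-fragment attention attribution
#'
#' Decomposes every molecule at its BRICS bonds and aggregates attention
#' per fragment, keyed by the canonical fragment SMILES.
#'
#' @inheritParams attribute_smarts
#' @return list of `substructure_attribution` entries (kind
#'   `"brics_fragment"`).
#' @export
attribute_brics <- function(graphs, records, layer = NULL) {
  scores <- atom_attention_scores(records, layer)
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  per_mol <- lapply(graphs, function(g) brics_decompose(graph_mol(g)))
  keys <- unique(unlist(lapply(per_mol, function(d) d$smiles)))
  lapply(keys, function(key) {
    matched <- list()
    for (k in seq_along(per_mol)) {
      sel <- which(per_mol[[k]]$smiles == key)
      if (length(sel)) {
        matched[[ids[k]]] <- sort(unique(unlist(per_mol[[k]]$fragments[sel])))
      }
    }
    .make_attribution("brics_fragment", key, matched, scores)
  })
}

#' Ring-system attention attribution
#'
#' Detects rings of the requested size and aggregates attention over the
#' member atoms.
#'
#' @inheritParams attribute_smarts
#' @param ring_size ring size to match (default 5).
#' @return a single `substructure_attribution` (kind `"ring_system"`).
#' @export
ring_system_attribution <- function(graphs, records, ring_size = 5L,
                                    layer = NULL) {
  stopifnot(ring_size >= 3)
  scores <- atom_attention_scores(records, layer)
  matched <- lapply(graphs, function(g) {
    mol <- graph_mol(g)
    hits <- mol$rings[lengths(mol$rings) == ring_size]
    sort(unique(unlist(hits)))
  })
  names(matched) <- vapply(graphs, function(g) g$mol_id, character(1))
  .make_attribution("ring_system", sprintf("%d-membered ring", ring_size),
                    matched, scores)
}
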