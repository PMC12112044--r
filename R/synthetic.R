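# Synthetic test inputs: planted-motif molecular classification tasks,
# abstract random graphs for layer-level tests, and 3D conformer
# embedding for generated molecules. Everything is deterministic per
# seed, so the whole pipeline is testable without any external dataset.

# default backbone pool: simple alkyl chains, carbocycles and (hetero)
# aromatic rings, giving a spread of Murcko scaffolds for scaffold splits
DEFAULT_SCAFFOLD_POOL <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)C", "CC(C)(C)C",
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1",
  "C1CCCCC1", "C1CCCC1", "C1CCOC1", "C1CCNC1", "c1ccsc1", "c1ccoc1"
)

# substituents that cannot create an ester linkage (negatives)
NEGATIVE_TAILS <- c("", "C", "CC", "CCC", "O", "CO", "N", "CC(C)=O", "C#N",
                    "F", "Cl")
# substituents that plant the motif (methylene + ester variants)
POSITIVE_TAILS <- c("COC(C)=O", "CCOC(C)=O", "COC(CC)=O")
PREFIXES <- c("", "C", "CC", "CCC")

#' Specification of a planted-motif classification task
#'
#' @param motif_smarts SMARTS pattern planted in positives (default the
#'   ester linkage `"COC(=O)"`).
#' @param n_molecules number of molecules to generate.
#' @param positive_fraction fraction of positives (default 0.5).
#' @param scaffold_pool backbone SMILES fragments used for composition.
#' @param seed RNG seed.
#' @param label_noise probability in \[0, 0.5) of flipping a label.
#' @return a `motif_task_spec`.
#' @export
motif_task_spec <- function(motif_smarts = "COC(=O)", n_molecules = 600L,
                            positive_fraction = 0.5,
                            scaffold_pool = DEFAULT_SCAFFOLD_POOL,
                            seed = 1L, label_noise = 0) {
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            label_noise >= 0, label_noise < 0.5, length(scaffold_pool) > 0)
  structure(list(motif_smarts = motif_smarts,
                 n_molecules = as.integer(n_molecules),
                 positive_fraction = positive_fraction,
                 scaffold_pool = scaffold_pool, seed = as.integer(seed),
                 label_noise = label_noise),
            class = "motif_task_spec")
}

#' Generate a planted-motif classification task
#'
#' Composes molecules as prefix + backbone + substituent strings.
#' Positives receive an ester-containing substituent and are verified to
#' contain at least one motif match; negatives are verified to contain
#' none (both checked with the package's SMARTS matcher before label
#' noise is applied). Labels equal motif presence XOR a Bernoulli noise
#' flip.
#'
#' @param spec a [motif_task_spec()].
#' @return data.frame with `mol_id`, `smiles` (canonical), `motif`
#'   (ground-truth presence) and `label`.
#' @export
generate_motif_task <- function(spec) {
  stopifnot(inherits(spec, "motif_task_spec"))
  query <- parse_smarts(spec$motif_smarts)
  n_pos <- round(spec$n_molecules * spec$positive_fraction)
  want <- c(rep(1L, n_pos), rep(0L, spec$n_molecules - n_pos))
  with_seed(spec$seed, {
    smiles <- character(length(want))
    for (k in seq_along(want)) {
      ok <- FALSE
      for (try in 1:20) {
        backbone <- sample(spec$scaffold_pool, 1)
        prefix <- sample(PREFIXES, 1)
        tail_ <- if (want[k] == 1) sample(POSITIVE_TAILS, 1) else
          sample(NEGATIVE_TAILS, 1)
        smi <- paste0(prefix, backbone, tail_)
        can <- canonical_smiles(smi)
        if (is.na(can)) next
        nhit <- length(smarts_match(can, query))
        if ((want[k] == 1 && nhit >= 1) || (want[k] == 0 && nhit == 0)) {
          smiles[k] <- can; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop(sprintf("could not compose a %s molecule after 20 attempts",
                     if (want[k] == 1) "motif-bearing" else "motif-free"))
      }
    }
    flip <- if (spec$label_noise > 0) {
      stats::rbinom(length(want), 1, spec$label_noise)
    } else rep(0L, length(want))
    perm <- sample.int(length(want))
    data.frame(
      mol_id = sprintf("synth%04d", seq_along(want)),
      smiles = smiles[perm],
      motif = want[perm],
      label = as.integer(xor(want[perm] == 1, flip[perm] == 1))
    )
  })
}

#' Generate abstract random graphs
#'
#' Connected undirected graphs (spanning tree plus random extra edges)
#' with both directed entries per edge, random finite node features and
#' optionally random centered 3D coordinates. These are not molecules;
#' they exercise the layer contracts directly.
#'
#' @param n_graphs number of graphs.
#' @param node_range integer length-2 vector: min/max nodes per graph.
#' @param feature_dim number of node feature columns (default: the 2D
#'   atom feature width).
#' @param seed RNG seed.
#' @param with_coords attach random centered coordinates.
#' @return list of `molecular_graph` objects (abstract, no chemistry).
#' @export
generate_random_graphs <- function(n_graphs, node_range = c(2L, 10L),
                                   feature_dim = length(ATOM_FEATURE_NAMES),
                                   seed = 1L, with_coords = FALSE) {
  stopifnot(node_range[1] >= 1, node_range[2] >= node_range[1])
  with_seed(seed, {
    lapply(seq_len(n_graphs), function(k) {
      n <- sample(node_range[1]:node_range[2], 1)
      und <- NULL
      if (n > 1) {
        for (v in 2:n) und <- rbind(und, c(sample(v - 1L, 1), v))
        n_extra <- stats::rbinom(1, n, 0.3)
        if (n_extra > 0) {
          extra <- cbind(sample(n, n_extra, replace = TRUE),
                         sample(n, n_extra, replace = TRUE))
          extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
          if (nrow(extra)) {
            extra <- t(apply(extra, 1, sort))
            und <- unique(rbind(und, extra))
          }
        }
      }
      ei <- if (is.null(und)) {
        matrix(integer(0), 0, 2, dimnames = list(NULL, c("src", "dst")))
      } else {
        cbind(src = c(und[, 1], und[, 2]), dst = c(und[, 2], und[, 1]))
      }
      nf <- matrix(stats::rnorm(n * feature_dim), n, feature_dim)
      colnames(nf) <- if (feature_dim == length(ATOM_FEATURE_NAMES)) {
        ATOM_FEATURE_NAMES
      } else paste0("f", seq_len(feature_dim))
      coords <- NULL
      if (with_coords) {
        coords <- matrix(stats::rnorm(n * 3, sd = 2), n, 3)
        coords <- sweep(coords, 2, colMeans(coords))
        colnames(coords) <- c("x", "y", "z")
      }
      structure(list(node_features = nf, edge_index = ei, coords = coords,
                     labels = stats::rbinom(1, 1, 0.5), label_mask = 1,
                     mol_id = sprintf("rnd%04d", k), smiles = NA_character_,
                     mol = NULL),
                class = "molecular_graph")
    })
  })
}

# canonical orientation: rotate centered coordinates onto their
# principal axes (proper rotation only, so chirality is preserved), with
# a deterministic sign convention per axis
.canonical_orientation <- function(coords) {
  if (nrow(coords) < 2) return(coords)
  v <- eigen(crossprod(coords), symmetric = TRUE)$vectors   # always 3 x 3
  if (det(v) < 0) v[, 3] <- -v[, 3]
  rot <- coords %*% v
  for (ax in 1:2) {
    if (rot[which.max(abs(rot[, ax])), ax] < 0) {
      rot[, ax] <- -rot[, ax]
      rot[, 3] <- -rot[, 3]          # keep the rotation proper
    }
  }
  rot
}

#' Embed 3D conformers for SMILES
#'
#' Generates one force-field-optimized 3D conformer per molecule with
#' OpenBabel (MMFF94 where parameterized) and returns centered heavy-atom
#' coordinates aligned with the canonical-SMILES atom order used by
#' [parse_smiles()]. Coordinates are rotated to a canonical
#' principal-axes orientation. The underlying conformer search draws its
#' own random numbers internally, so repeated embeddings agree up to
#' small numerical differences rather than bitwise. Failures are
#' reported per molecule, never silently dropped.
#'
#' @param smiles character vector of SMILES.
#' @param seed accepted for interface symmetry (the conformer search
#'   cannot be seeded through the toolkit API).
#' @return list (one per input) of [conformer_set()] objects, `NULL`
#'   where embedding failed; failed indices are given in the
#'   `"failures"` attribute.
#' @export
embed_coords <- function(smiles, seed = 1L) {
  can <- canonical_smiles(smiles)
  out <- vector("list", length(smiles))
  failures <- which(is.na(can))
  idx_ok <- setdiff(seq_along(smiles), failures)
  if (length(idx_ok)) {
    src <- paste0(paste(can[idx_ok], collapse = "\n"), "\n")
    sdf_text <- tryCatch(suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", source = src,
      options = data.frame(names = "gen3d", args = ""))),
      error = function(e) "")
    records <- .split_sdf_records(strsplit(sdf_text, "\n", fixed = TRUE)[[1]])
    if (length(records) == length(idx_ok)) {
      for (r in seq_along(records)) {
        rec <- .parse_v2000(records[[r]])
        k <- idx_ok[r]
        if (is.null(rec)) { failures <- c(failures, k); next }
        heavy <- rec$symbol != "H"
        coords <- rec$coords[heavy, , drop = FALSE]
        coords <- sweep(coords, 2, colMeans(coords))
        coords <- .canonical_orientation(coords)
        colnames(coords) <- c("x", "y", "z")
        out[[k]] <- conformer_set(sprintf("mol%04d", k), list(coords))
      }
    } else {
      failures <- c(failures, idx_ok)
    }
  }
  if (length(failures)) {
    warning(sprintf("3D embedding failed for %d molecule(s): %s",
                    length(failures),
                    paste(utils::head(sort(failures), 10), collapse = ", ")))
  }
  attr(out, "failures") <- sort(unique(failures))
  out
}

#' Attach embedded 3D coordinates to graphs
#'
#' Convenience wrapper: embeds one conformer per graph (via
#' [embed_coords()] on the graph SMILES) and returns graphs with centered
#' coordinates. Graphs whose embedding failed are dropped with a warning
#' naming them.
#'
#' @param graphs list of `molecular_graph` objects.
#' @param seed passed to [embed_coords()].
#' @return list of graphs with `coords` set.
#' @export
embed_graph_coords <- function(graphs, seed = 1L) {
  smiles <- vapply(graphs, function(g) g$smiles, character(1))
  confs <- embed_coords(smiles, seed = seed)
  keep <- logical(length(graphs))
  out <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    cs <- confs[[k]]
    if (is.null(cs)) next
    coords <- cs$conformers[[1]]$coords
    if (nrow(coords) != nrow(graphs[[k]]$node_features)) next
    g <- graphs[[k]]
    g$coords <- coords
    if (!is.null(g$mol)) g$mol$coords <- coords
    out[[k]] <- g
    keep[k] <- TRUE
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d graph(s) without a 3D embedding: %s",
                    sum(!keep),
                    paste(utils::head(vapply(graphs[!keep], function(g) g$mol_id,
                                             character(1)), 10), collapse = ", ")))
  }
  out[keep]
}
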