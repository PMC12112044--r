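# Molecular graph construction: atom featurization, directed edge index,
# activity binarization and conformer deduplication.

ATOM_FEATURE_NAMES <- c("atomic_number", "degree", "num_hydrogens",
                        "implicit_valence", "is_aromatic")

#' Atomic feature vector
#'
#' Extracts the five 2D atomic features used by the model: atomic number,
#' heavy-atom degree, attached hydrogen count, implicit valence (implicit
#' hydrogen count) and an aromaticity flag. When the molecule carries 3D
#' coordinates these are appended as `x`, `y`, `z` (Angstrom, centered).
#'
#' @param mol an `adc_mol` (see [parse_smiles()]) or a single SMILES string.
#' @param atom_index 1-based heavy-atom index.
#' @return named numeric vector of length 5 (or 8 with coordinates).
#' @examples
#' \donttest{
#' m <- parse_smiles("CCO")[[1]]
#' featurize_atom(m, 1)  # methyl carbon: Z=6, degree 1, 3 H
#' }
#' @export
featurize_atom <- function(mol, atom_index) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  stopifnot(inherits(mol, "adc_mol"))
  if (!(atom_index %in% seq_len(mol$n_atoms))) {
    stop(sprintf("atom index %s out of range [1, %d]", atom_index, mol$n_atoms))
  }
  v <- c(
    atomic_number    = as.numeric(mol$atomic_number[atom_index]),
    degree           = as.numeric(mol$degree[atom_index]),
    num_hydrogens    = as.numeric(mol$num_h[atom_index]),
    implicit_valence = as.numeric(mol$implicit_h[atom_index]),
    is_aromatic      = as.numeric(mol$is_aromatic[atom_index])
  )
  if (!is.null(mol$coords)) {
    v <- c(v, x = mol$coords[atom_index, 1], y = mol$coords[atom_index, 2],
           z = mol$coords[atom_index, 3])
  }
  v
}

#' Build a molecular graph from SMILES
#'
#' Constructs the attributed heavy-atom graph the network consumes: a node
#' feature matrix (one row per atom, [featurize_atom()] features), a
#' directed edge index with both orientations of every bond, optional
#' centered 3D coordinates, and the activity label vector with its
#' missing-label mask.
#'
#' @param smiles SMILES string (canonicalized on ingestion).
#' @param coords optional `n_atoms x 3` coordinate matrix (Angstrom), rows
#'   aligned with the atoms of the canonicalized molecule. Coordinates are
#'   centered at the molecular centroid before storage.
#' @param labels numeric vector of 0/1 task labels (NA allowed when masked).
#' @param label_mask 0/1 vector, 1 = label observed. Defaults to all-ones
#'   with NA labels masked out.
#' @param mol_id molecule identifier.
#' @param mol optional pre-parsed `adc_mol` (skips re-parsing).
#' @return a `molecular_graph`: list with `node_features`, `edge_index`
#'   (E x 2 matrix, 1-based, both directions of every bond), `coords`,
#'   `labels`, `label_mask`, `mol_id`, `smiles` and the parsed molecule.
#' @export
build_graph <- function(smiles, coords = NULL, labels = 0,
                        label_mask = NULL, mol_id = "mol", mol = NULL) {
  if (is.null(mol)) mol <- parse_smiles(smiles, mol_id = mol_id)[[1]]
  n <- mol$n_atoms
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop(sprintf("coords must be %d x 3 for '%s' (got %d x %d)",
                   n, mol$smiles, nrow(coords), ncol(coords)))
    }
    coords <- sweep(coords, 2, colMeans(coords))
    colnames(coords) <- c("x", "y", "z")
    mol$coords <- coords
  } else if (!is.null(mol$coords)) {
    coords <- mol$coords
  }

  nf <- matrix(0, n, length(ATOM_FEATURE_NAMES),
               dimnames = list(NULL, ATOM_FEATURE_NAMES))
  nf[, "atomic_number"] <- mol$atomic_number
  nf[, "degree"] <- mol$degree
  nf[, "num_hydrogens"] <- mol$num_h
  nf[, "implicit_valence"] <- mol$implicit_h
  nf[, "is_aromatic"] <- as.numeric(mol$is_aromatic)

  b <- mol$bonds
  edge_index <- if (nrow(b) > 0) {
    cbind(src = c(b[, "i"], b[, "j"]), dst = c(b[, "j"], b[, "i"]))
  } else matrix(integer(0), 0, 2, dimnames = list(NULL, c("src", "dst")))

  labels <- as.numeric(labels)
  if (is.null(label_mask)) label_mask <- as.numeric(!is.na(labels))
  stopifnot(length(label_mask) == length(labels))
  labels[is.na(labels)] <- 0

  structure(list(
    node_features = nf, edge_index = edge_index, coords = coords,
    labels = labels, label_mask = as.numeric(label_mask),
    mol_id = mol$mol_id, smiles = mol$smiles, mol = mol
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph %s: %d atoms, %d directed edges%s, %d task(s)> %s\n",
              x$mol_id, nrow(x$node_features), nrow(x$edge_index),
              if (!is.null(x$coords)) ", 3D" else "", length(x$labels), x$smiles))
  invisible(x)
}

#' Binarize an IC50 measurement
#'
#' Applies the activity threshold used to label Topoisomerase I inhibitors:
#' IC50 values strictly below the cutoff (default 100 uM) are labeled
#' positive (1), values at or above it negative (0).
#'
#' @param ic50_uM positive IC50 in micromolar.
#' @param cutoff_uM activity cutoff in micromolar (default 100).
#' @return integer 0/1 vector.
#' @export
label_from_ic50 <- function(ic50_uM, cutoff_uM = 100) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  as.integer(ic50_uM < cutoff_uM)
}

#' Optimal-superposition RMSD between two conformers
#'
#' Kabsch alignment: both coordinate sets are centered, the optimal
#' rotation is obtained from the SVD of the covariance matrix (with the
#' usual reflection correction), and the RMSD of the superposed sets is
#' returned.
#'
#' @param a,b `n x 3` coordinate matrices over the same atom ordering.
#' @return RMSD in the units of the input coordinates.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, all(dim(a) == dim(b)))
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- a - b %*% rot
  sqrt(sum(diff^2) / nrow(a))
}

#' Conformer set container
#'
#' @param mol_id molecule identifier.
#' @param conformers list of conformers; each either an `n x 3` coordinate
#'   matrix or a list with elements `coords` and optional `energy`
#'   (kcal/mol).
#' @return a `conformer_set`.
#' @export
conformer_set <- function(mol_id, conformers) {
  stopifnot(length(conformers) >= 1)
  confs <- lapply(conformers, function(cf) {
    if (is.matrix(cf)) cf <- list(coords = cf, energy = NA_real_)
    stopifnot(is.matrix(cf$coords), ncol(cf$coords) == 3)
    if (is.null(cf$energy)) cf$energy <- NA_real_
    cf
  })
  n <- nrow(confs[[1]]$coords)
  if (!all(vapply(confs, function(cf) nrow(cf$coords), 1L) == n)) {
    stop("all conformers must share the parent molecule's atom count")
  }
  structure(list(mol_id = mol_id, conformers = confs), class = "conformer_set")
}

#' Deduplicate conformers by RMSD
#'
#' Greedy selection in input order: a conformer is kept iff its
#' best-superposition RMSD to every already-kept conformer exceeds the
#' cutoff (default 1.5 Angstrom). Idempotent; preserves input order.
#'
#' @param conf_set a [conformer_set()].
#' @param rmsd_cutoff_A RMSD cutoff in Angstrom.
#' @return the pruned `conformer_set`.
#' @export
prune_conformers <- function(conf_set, rmsd_cutoff_A = 1.5) {
  stopifnot(inherits(conf_set, "conformer_set"))
  confs <- conf_set$conformers
  if (length(confs) == 0) stop("empty conformer set")
  keep <- 1L
  if (length(confs) > 1) {
    for (k in 2:length(confs)) {
      d <- vapply(keep, function(i) {
        kabsch_rmsd(confs[[i]]$coords, confs[[k]]$coords)
      }, numeric(1))
      if (all(d > rmsd_cutoff_A)) keep <- c(keep, k)
    }
  }
  conformer_set(conf_set$mol_id, confs[keep])
}
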