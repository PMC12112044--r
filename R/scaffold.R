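# Bemis-Murcko scaffolds and dataset splitting (random / scaffold /
# predefined). The scaffold of a molecule is its ring systems plus the
# linker atoms connecting them, with side chains stripped; atoms attached
# to the retained core by a double or triple bond are kept (so exocyclic
# carbonyls stay part of the scaffold).

# canonical SMILES of the induced heavy-atom subgraph; hydrogens are left
# implicit, so cutting substituent bonds refills valences
subgraph_smiles <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (length(atoms) == 0) return("")
  idx_map <- match(seq_len(mol$n_atoms), atoms)
  b <- mol$bonds
  keep <- b[, "i"] %in% atoms & b[, "j"] %in% atoms
  bonds <- b[keep, , drop = FALSE]
  n <- length(atoms)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, mol$symbol[atoms])
  bond_lines <- if (nrow(bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0", idx_map[bonds[, "i"]],
            idx_map[bonds[, "j"]], bonds[, "order"])
  } else character(0)
  chg <- which(mol$charge[atoms] != 0)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, mol$charge[atoms][chg]), collapse = ""))
  } else character(0)
  sdf <- c("", " adcgnn", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
           atom_lines, bond_lines, chg_lines, "M  END", "$$$$")
  out <- tryCatch(suppressWarnings(ChemmineOB::convertFormat(
    "SDF", "CAN", source = paste(c(sdf, ""), collapse = "\n"))),
    error = function(e) "")
  smi <- strsplit(out, "[ \t\n]")[[1]][1]
  if (is.na(smi)) "" else smi
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal atoms until only ring systems and their
#' linkers remain, then re-attaches atoms joined to the retained core by a
#' double or triple bond. Acyclic molecules have an empty scaffold.
#'
#' @param mol an `adc_mol` or SMILES string.
#' @return list with `atoms` (1-based heavy-atom indices, empty for
#'   acyclic molecules) and `smiles` (canonical scaffold SMILES, `""` when
#'   empty).
#' @export
murcko_scaffold <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  stopifnot(inherits(mol, "adc_mol"))
  n <- mol$n_atoms
  b <- mol$bonds
  if (n == 0 || nrow(b) == 0 || !any(mol$atom_in_ring)) {
    return(list(atoms = integer(0), smiles = ""))
  }
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    keep <- alive[b[, "i"]] & alive[b[, "j"]]
    if (any(keep)) {
      tab <- table(factor(c(b[keep, "i"], b[keep, "j"]), levels = seq_len(n)))
      deg <- as.integer(tab)
    }
    terminal <- alive & deg <= 1
    if (!any(terminal)) break
    alive[terminal] <- FALSE
    if (!any(alive)) break
  }
  core <- which(alive)
  if (!length(core)) return(list(atoms = integer(0), smiles = ""))
  # re-attach multiple-bonded substituent atoms (e.g. exocyclic C=O)
  multi <- b[, "order"] >= 2
  extra <- unique(c(
    b[multi & alive[b[, "i"]] & !alive[b[, "j"]], "j"],
    b[multi & alive[b[, "j"]] & !alive[b[, "i"]], "i"]
  ))
  atoms <- sort(unique(c(core, extra)))
  list(atoms = atoms, smiles = subgraph_smiles(mol, atoms))
}

#' Split molecules into train / validation / test partitions
#'
#' @description
#' `scaffold_split()` groups molecules by Murcko scaffold, sorts the groups
#' by size (descending, ties broken by scaffold string) and assigns each
#' group to the partition with the largest remaining deficit relative to
#' the target fractions, so no scaffold straddles partitions.
#' `random_split()` shuffles molecules with the given seed. Both operate on
#' `mol_id`s, so multiple conformer records of one molecule always share a
#' partition.
#'
#' @param graphs list of `molecular_graph` objects.
#' @param fractions numeric length-3 vector (train, valid, test) summing
#'   to 1; default `c(0.8, 0.1, 0.1)`.
#' @param seed integer seed (recorded; used by the random strategy).
#' @return a `split_spec`: list with `strategy`, `fractions`, `seed` and
#'   `assignment`, a named character vector mapping `mol_id` to
#'   `"train"`, `"valid"` or `"test"`.
#' @export
scaffold_split <- function(graphs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  uid <- unique(ids)
  first <- match(uid, ids)
  scaffolds <- vapply(first, function(k) {
    murcko_scaffold(graph_mol(graphs[[k]]))$smiles
  }, character(1))
  groups <- split(uid, scaffolds)
  if (length(groups) == 1L) {
    warning("all molecules share one scaffold; entire set assigned to train")
    assignment <- stats::setNames(rep("train", length(uid)), uid)
    return(structure(list(strategy = "scaffold", fractions = fractions,
                          seed = as.integer(seed), assignment = assignment),
                     class = "split_spec"))
  }
  if (length(groups) < 3L) {
    stop("fewer scaffold groups than partitions; cannot scaffold-split")
  }
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  target <- fractions * length(uid)
  count <- c(train = 0, valid = 0, test = 0)
  assignment <- character(0)
  for (grp in groups) {
    deficit <- target - count
    part <- names(count)[which.max(deficit)]   # ties: train > valid > test
    assignment[grp] <- part
    count[part] <- count[part] + length(grp)
  }
  structure(list(strategy = "scaffold", fractions = fractions,
                 seed = as.integer(seed), assignment = assignment),
            class = "split_spec")
}

#' @rdname scaffold_split
#' @export
random_split <- function(graphs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  ids <- unique(vapply(graphs, function(g) g$mol_id, character(1)))
  n <- length(ids)
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_valid <- round(fractions[2] * n)
  part <- rep("test", n)
  part[perm <= n_train] <- "train"
  part[perm > n_train & perm <= n_train + n_valid] <- "valid"
  structure(list(strategy = "random", fractions = fractions,
                 seed = as.integer(seed),
                 assignment = stats::setNames(part, ids)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c("train", "valid", "test")))
  cat(sprintf("<split_spec %s: train %d / valid %d / test %d (seed %d)>\n",
              x$strategy, tab["train"], tab["valid"], tab["test"], x$seed))
  invisible(x)
}

#' Partition graphs according to a split
#'
#' @param graphs list of `molecular_graph` objects.
#' @param split a `split_spec`.
#' @return named list of graph lists: `train`, `valid`, `test`.
#' @export
apply_split <- function(graphs, split) {
  stopifnot(inherits(split, "split_spec"))
  ids <- vapply(graphs, function(g) g$mol_id, character(1))
  part <- split$assignment[ids]
  if (anyNA(part)) stop("split assignment is missing some mol_ids")
  list(train = graphs[part == "train"],
       valid = graphs[part == "valid"],
       test = graphs[part == "test"])
}

#' Evaluate code under a temporary RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`; the caller's RNG state is restored.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
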