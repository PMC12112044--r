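# BRICS decomposition: retrosynthetic bond cleavage over 16 link-atom
# environment classes with an allowed-pair table. Environments are
# implemented as predicates over the perceived molecule (element,
# aromaticity, degree, ring membership, bond orders), matching the
# standard rule set used across cheminformatics toolkits.

# adjacency cache: per atom, matrix with columns nbr / order / aromatic /
# in_ring
.mol_adjacency <- function(mol) {
  n <- mol$n_atoms
  empty <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("nbr", "order", "aromatic", "in_ring")))
  if (nrow(mol$bonds) == 0) return(rep(list(empty), n))
  b <- mol$bonds
  src <- c(b[, "i"], b[, "j"]); dst <- c(b[, "j"], b[, "i"])
  ord <- c(b[, "order"], b[, "order"])
  aro <- as.numeric(c(mol$aromatic_bond, mol$aromatic_bond))
  rng <- as.numeric(c(mol$bond_in_ring, mol$bond_in_ring))
  out <- rep(list(empty), n)
  sp <- split(seq_along(src), src)
  for (nm in names(sp)) {
    k <- sp[[nm]]
    out[[as.integer(nm)]] <- cbind(nbr = dst[k], order = ord[k],
                                   aromatic = aro[k], in_ring = rng[k])
  }
  out
}

# environment predicates; `a` is an atom index, `adj` the adjacency cache
.brics_env <- function(mol, adj) {
  Z <- mol$atomic_number; arom <- mol$is_aromatic; deg <- mol$degree
  inring <- mol$atom_in_ring; chg <- mol$charge
  nb <- function(a) adj[[a]]
  has_carbonyl <- function(a) {
    m <- nb(a)
    any(m[, "order"] == 2 & Z[m[, "nbr"]] == 8 & m[, "aromatic"] == 0)
  }
  list(
    L1 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && deg[a] == 3 && has_carbonyl(a))) return(FALSE)
      m <- nb(a)
      other <- m[, "nbr"][!(m[, "order"] == 2 & Z[m[, "nbr"]] == 8)]
      any(Z[other] %in% c(6L, 7L, 8L))
    },
    L3 = function(a) {
      if (!(Z[a] == 8 && !arom[a] && deg[a] == 2)) return(FALSE)
      m <- nb(a)
      any(m[, "order"] == 1 & m[, "aromatic"] == 0 & m[, "in_ring"] == 0 &
            Z[m[, "nbr"]] == 6)
    },
    L4 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && deg[a] >= 2)) return(FALSE)
      m <- nb(a)
      if (any(m[, "order"] == 2 & m[, "aromatic"] == 0)) return(FALSE)  # C=*
      any(m[, "order"] == 1 & m[, "aromatic"] == 0 & m[, "in_ring"] == 0 &
            Z[m[, "nbr"]] == 6)
    },
    L5 = function(a) {
      if (!(Z[a] == 7 && !arom[a] && deg[a] >= 2)) return(FALSE)
      m <- nb(a)
      if (any(m[, "order"] >= 2)) return(FALSE)                         # N=*
      if (!all(Z[m[, "nbr"]] %in% c(6L, 16L))) return(FALSE)
      # exclude lactam nitrogens: ring N bonded in-ring to a ring C(=O)
      if (inring[a]) {
        ringC <- m[, "nbr"][m[, "in_ring"] == 1 & Z[m[, "nbr"]] == 6]
        if (any(vapply(ringC, has_carbonyl, logical(1)))) return(FALSE)
      }
      TRUE
    },
    L6 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && !inring[a] && deg[a] == 3 &&
              has_carbonyl(a))) return(FALSE)
      m <- nb(a)
      any(m[, "order"] == 1 & m[, "aromatic"] == 0 & m[, "in_ring"] == 0 &
            Z[m[, "nbr"]] %in% c(6L, 7L, 8L))
    },
    L7 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && deg[a] %in% c(2L, 3L))) return(FALSE)
      m <- nb(a)
      any(m[, "order"] == 1 & m[, "aromatic"] == 0 & Z[m[, "nbr"]] == 6)
    },
    L8 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && !inring[a] && deg[a] >= 2)) return(FALSE)
      m <- nb(a)
      all(m[, "order"] == 1 & m[, "aromatic"] == 0)
    },
    L9 = function(a) Z[a] == 7 && arom[a] && chg[a] == 0,
    L10 = function(a) {
      if (!(Z[a] == 7 && !arom[a] && inring[a])) return(FALSE)
      m <- nb(a)
      ringC <- m[, "nbr"][m[, "in_ring"] == 1 & Z[m[, "nbr"]] == 6]
      any(vapply(ringC, has_carbonyl, logical(1)))
    },
    L11 = function(a) {
      if (!(Z[a] == 16 && !arom[a] && deg[a] == 2)) return(FALSE)
      m <- nb(a)
      any(m[, "order"] == 1 & m[, "aromatic"] == 0 & m[, "in_ring"] == 0 &
            Z[m[, "nbr"]] == 6)
    },
    L12 = function(a) {
      if (!(Z[a] == 16 && deg[a] == 4)) return(FALSE)
      m <- nb(a)
      sum(m[, "order"] == 2 & Z[m[, "nbr"]] == 8) == 2 &&
        any(Z[m[, "nbr"]] == 6)
    },
    L13 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && inring[a])) return(FALSE)
      m <- nb(a)
      ringb <- m[, "in_ring"] == 1 & m[, "order"] == 1 & m[, "aromatic"] == 0 &
        !arom[m[, "nbr"]]
      zr <- Z[m[, "nbr"]][ringb]
      sum(zr %in% c(6L, 7L, 8L, 16L)) >= 2 && any(zr %in% c(7L, 8L, 16L))
    },
    L14 = function(a) {
      if (!(Z[a] == 6 && arom[a])) return(FALSE)
      m <- nb(a)
      any(m[, "aromatic"] == 1 & arom[m[, "nbr"]] &
            Z[m[, "nbr"]] %in% c(7L, 8L, 16L))
    },
    L15 = function(a) {
      if (!(Z[a] == 6 && !arom[a] && inring[a])) return(FALSE)
      m <- nb(a)
      sum(m[, "in_ring"] == 1 & m[, "order"] == 1 & m[, "aromatic"] == 0 &
            Z[m[, "nbr"]] == 6 & !arom[m[, "nbr"]]) >= 2
    },
    L16 = function(a) {
      if (!(Z[a] == 6 && arom[a])) return(FALSE)
      m <- nb(a)
      sum(m[, "aromatic"] == 1 & arom[m[, "nbr"]] & Z[m[, "nbr"]] == 6) >= 2
    }
  )
}

# allowed environment pairs, in rule order; all cleave acyclic single
# bonds except the L7-L7 double-bond rule
BRICS_PAIRS <- rbind(
  c("L1", "L3", 1), c("L1", "L5", 1), c("L1", "L10", 1),
  c("L3", "L4", 1), c("L3", "L13", 1), c("L3", "L14", 1),
  c("L3", "L15", 1), c("L3", "L16", 1),
  c("L4", "L5", 1), c("L4", "L11", 1),
  c("L5", "L12", 1), c("L5", "L14", 1), c("L5", "L16", 1),
  c("L5", "L13", 1), c("L5", "L15", 1),
  c("L6", "L13", 1), c("L6", "L14", 1), c("L6", "L15", 1), c("L6", "L16", 1),
  c("L7", "L7", 2),
  c("L8", "L9", 1), c("L8", "L10", 1), c("L8", "L13", 1),
  c("L8", "L14", 1), c("L8", "L15", 1), c("L8", "L16", 1),
  c("L9", "L13", 1), c("L9", "L14", 1), c("L9", "L15", 1), c("L9", "L16", 1),
  c("L10", "L13", 1), c("L10", "L14", 1), c("L10", "L15", 1), c("L10", "L16", 1),
  c("L11", "L13", 1), c("L11", "L14", 1), c("L11", "L15", 1), c("L11", "L16", 1),
  c("L13", "L14", 1), c("L13", "L15", 1), c("L13", "L16", 1),
  c("L14", "L14", 1), c("L14", "L15", 1), c("L14", "L16", 1),
  c("L15", "L16", 1),
  c("L16", "L16", 1)
)

#' Find BRICS cleavage bonds
#'
#' Scans every acyclic bond for the first matching environment pair of the
#' BRICS rule set.
#'
#' @param mol an `adc_mol` or SMILES string.
#' @return data.frame with columns `i`, `j` (atom indices), `label_i`,
#'   `label_j` (environment classes); zero rows when nothing is cleavable.
#' @export
find_brics_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  adj <- .mol_adjacency(mol)
  env <- .brics_env(mol, adj)
  memo <- new.env(parent = emptyenv())
  pred <- function(lab, a) {
    key <- paste0(lab, ".", a)
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- env[[lab]](a)
    memo[[key]]
  }
  out <- data.frame(i = integer(0), j = integer(0),
                    label_i = character(0), label_j = character(0))
  b <- mol$bonds
  if (nrow(b) == 0) return(out)
  for (k in seq_len(nrow(b))) {
    if (mol$bond_in_ring[k] || mol$aromatic_bond[k]) next
    i <- b[k, "i"]; j <- b[k, "j"]; ord <- b[k, "order"]
    for (p in seq_len(nrow(BRICS_PAIRS))) {
      la <- BRICS_PAIRS[p, 1]; lb <- BRICS_PAIRS[p, 2]
      if (ord != as.integer(BRICS_PAIRS[p, 3])) next
      if (pred(la, i) && pred(lb, j)) {
        out <- rbind(out, data.frame(i = i, j = j, label_i = la, label_j = lb))
        break
      }
      if (pred(la, j) && pred(lb, i)) {
        out <- rbind(out, data.frame(i = j, j = i, label_i = la, label_j = lb))
        break
      }
    }
  }
  out
}

#' BRICS decomposition into fragments
#'
#' Cleaves all [find_brics_bonds()] bonds and returns the connected
#' components. A molecule with no cleavable bond yields itself as the
#' single fragment.
#'
#' @param mol an `adc_mol` or SMILES string.
#' @return list with `fragments` (list of atom-index vectors), `smiles`
#'   (canonical SMILES of each fragment subgraph, open valences hydrogen
#'   filled) and `bonds` (the cleaved-bond table).
#' @export
brics_decompose <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  cuts <- find_brics_bonds(mol)
  n <- mol$n_atoms
  b <- mol$bonds
  cut_key <- paste(pmin(cuts$i, cuts$j), pmax(cuts$i, cuts$j))
  keep <- if (nrow(b)) {
    !(paste(pmin(b[, "i"], b[, "j"]), pmax(b[, "i"], b[, "j"])) %in% cut_key)
  } else logical(0)
  # connected components of the cut graph
  comp <- seq_len(n)
  if (any(keep)) {
    for (k in which(keep)) {
      ci <- comp[b[k, "i"]]; cj <- comp[b[k, "j"]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  frags <- unname(split(seq_len(n), comp))
  frags <- frags[order(vapply(frags, min, 1L))]
  list(
    fragments = frags,
    smiles = vapply(frags, function(at) subgraph_smiles(mol, at), character(1)),
    bonds = cuts
  )
}
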