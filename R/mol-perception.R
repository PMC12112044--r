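# Molecule perception layer: SMILES/SDF ingestion via ChemmineOB
# (OpenBabel), ring/aromaticity perception via ChemmineR. Produces the
# internal `adc_mol` representation every other module consumes: a
# heavy-atom graph with kekulized bond orders, perceived aromaticity,
# implicit hydrogen counts and optional 3D coordinates.
#
# The V2000 connection table OpenBabel emits is read with a minimal
# fixed-column reader because ChemmineR::read.SDFset rejects bond-free
# records (single-atom molecules such as methane must round-trip).

PERIODIC_TABLE <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Zn = 30L, Se = 34L, Br = 35L,
  I = 53L
)

# default valence candidates used for implicit-hydrogen perception
# (organic subset; elements absent from this table get no implicit H)
DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES for each input. Unparseable inputs
#' yield `NA_character_`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  # titles carry the input index so that molecules OpenBabel drops can be
  # identified (OpenBabel silently skips unparseable records)
  src <- paste0(smiles, " idx", seq_along(smiles), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                    source = paste0(src, "\n")))
  res <- rep(NA_character_, length(smiles))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) >= 2L && grepl("^idx[0-9]+$", parts[2])) {
      i <- as.integer(sub("idx", "", parts[2]))
      res[i] <- parts[1]
    }
  }
  res
}

adcgnn_parse_error <- function(smiles) {
  stop(structure(
    class = c("adcgnn_parse_error", "error", "condition"),
    list(message = sprintf("unparseable SMILES: '%s'", smiles), call = NULL,
         smiles = smiles)
  ))
}

.sdf_charge_from_code <- function(code) {
  # SDF atom-block charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1,
  # 6 -2, 7 -3
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# minimal fixed-column V2000 reader for one record (without the $$$$ line)
.parse_v2000 <- function(lines) {
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1) return(NULL)
  if (is.na(nbonds)) nbonds <- 0L
  atom_lines <- lines[5:(4 + natoms)]
  coords <- cbind(
    as.numeric(substr(atom_lines, 1, 10)),
    as.numeric(substr(atom_lines, 11, 20)),
    as.numeric(substr(atom_lines, 21, 30))
  )
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge <- .sdf_charge_from_code(suppressWarnings(
    as.integer(substr(atom_lines, 37, 39))))
  bonds <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order")))
  if (nbonds > 0) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- cbind(i = as.integer(substr(bond_lines, 1, 3)),
                   j = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  }
  # property block charges (M  CHG) override atom-block codes
  mchg <- grep("^M  CHG", lines, value = TRUE)
  if (length(mchg)) {
    charge[] <- 0L
    for (ln in mchg) {
      toks <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)),
                                  "[ ]+")[[1]])
      if (length(toks) >= 2) {
        idx <- toks[seq(1, length(toks), by = 2)]
        val <- toks[seq(2, length(toks), by = 2)]
        charge[idx] <- val
      }
    }
  }
  list(natoms = natoms, symbol = symbol, coords = coords, charge = charge,
       bonds = bonds)
}

.implicit_h <- function(symbol, charge, bond_order_sum) {
  cand <- DEFAULT_VALENCES[[symbol]]
  if (is.null(cand)) return(0L)
  cand <- cand + charge
  cand <- cand[cand >= bond_order_sum]
  if (length(cand) == 0L) return(0L)
  as.integer(min(cand) - bond_order_sum)
}

# ring perception on an original-indexing SDF record (ChemmineR cycle
# search); aromaticity is decided separately by .ring_is_aromatic
.perceive_rings <- function(sdf) {
  if (is.null(sdf)) return(list(rings = list()))
  rr <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = FALSE),
                 error = function(e) NULL)
  if (is.null(rr) || length(rr) == 0) return(list(rings = list()))
  list(rings = lapply(rr, function(r) as.integer(sub("^.*_", "", r))))
}

# Hueckel-style aromaticity for one ring over the kekulized heavy-atom
# graph: every ring atom must be sp2 (a double bond, or a lone-pair
# heteroatom N/O/S); pi electrons are counted as 1 for an atom whose
# double-bond partner is itself a ring member (of any ring), 0 for an
# exocyclic double bond (e.g. quinone C=O), 2 for a lone-pair
# heteroatom; the ring is aromatic iff the count satisfies 4n + 2.
.ring_is_aromatic <- function(ring, Z, dbl_partner, atom_in_ring) {
  if (length(ring) < 5) return(FALSE)
  pi_total <- 0L
  for (a in ring) {
    if (!Z[a] %in% c(6L, 7L, 8L, 16L)) return(FALSE)
    p <- dbl_partner[[a]]
    if (length(p) > 0) {
      pi_total <- pi_total + if (any(atom_in_ring[p])) 1L else 0L
    } else if (Z[a] %in% c(7L, 8L, 16L)) {
      pi_total <- pi_total + 2L          # lone pair enters the pi system
    } else {
      return(FALSE)                      # sp3 carbon breaks conjugation
    }
  }
  pi_total %% 4 == 2
}

# Build an adc_mol from a parsed V2000 record. Explicit hydrogens are
# folded into per-atom counts; indices refer to heavy atoms only.
.build_mol <- function(rec, ring_info, smiles = NA_character_,
                       mol_id = NA_character_, keep_coords = FALSE) {
  symbol_all <- rec$symbol
  n_all <- rec$natoms
  heavy <- symbol_all != "H"
  idx_map <- cumsum(heavy)           # old index -> new heavy index
  n <- sum(heavy)
  if (n == 0L) adcgnn_parse_error(smiles)

  bb <- rec$bonds
  bi <- bb[, 1]; bj <- bb[, 2]; bo <- bb[, 3]

  n_explicit_h <- integer(n)
  keep_bond <- heavy[bi] & heavy[bj]
  h_bond <- xor(heavy[bi], heavy[bj])
  if (any(h_bond)) {
    heavy_end <- ifelse(heavy[bi[h_bond]], bi[h_bond], bj[h_bond])
    tab <- table(idx_map[heavy_end])
    n_explicit_h[as.integer(names(tab))] <- as.integer(tab)
  }
  bonds <- cbind(i = idx_map[bi[keep_bond]], j = idx_map[bj[keep_bond]],
                 order = bo[keep_bond])
  if (nrow(bonds) == 0L) {
    bonds <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order")))
  } else colnames(bonds) <- c("i", "j", "order")

  symbol <- symbol_all[heavy]
  charge <- as.integer(rec$charge[heavy])
  atomic_number <- PERIODIC_TABLE[symbol]
  if (anyNA(atomic_number)) {
    stop(sprintf("unsupported element(s): %s",
                 paste(unique(symbol[is.na(atomic_number)]), collapse = ", ")))
  }

  degree <- integer(n)
  if (nrow(bonds) > 0) {
    tab <- table(factor(c(bonds[, "i"], bonds[, "j"]), levels = seq_len(n)))
    degree <- as.integer(tab)
  }
  bond_order_sum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bond_order_sum[bonds[k, "i"]] <- bond_order_sum[bonds[k, "i"]] + bonds[k, "order"]
      bond_order_sum[bonds[k, "j"]] <- bond_order_sum[bonds[k, "j"]] + bonds[k, "order"]
    }
  }

  implicit_h <- vapply(seq_len(n), function(a) {
    .implicit_h(symbol[a], charge[a], bond_order_sum[a] + n_explicit_h[a])
  }, integer(1))

  is_aromatic <- rep(FALSE, n)
  atom_in_ring <- rep(FALSE, n)
  aromatic_bond <- rep(FALSE, nrow(bonds))
  bond_in_ring <- rep(FALSE, nrow(bonds))
  ring_atoms <- list()
  if (length(ring_info$rings) > 0) {
    ring_atoms <- lapply(ring_info$rings, function(r) unname(idx_map[r]))
    for (k in seq_along(ring_atoms)) atom_in_ring[ring_atoms[[k]]] <- TRUE
    # double-bond partners per atom, for the aromaticity rule
    dbl_partner <- rep(list(integer(0)), n)
    if (nrow(bonds) > 0) {
      for (k in which(bonds[, "order"] == 2)) {
        i <- bonds[k, "i"]; j <- bonds[k, "j"]
        dbl_partner[[i]] <- c(dbl_partner[[i]], j)
        dbl_partner[[j]] <- c(dbl_partner[[j]], i)
      }
    }
    ring_aromatic <- vapply(ring_atoms, .ring_is_aromatic, logical(1),
                            Z = atomic_number, dbl_partner = dbl_partner,
                            atom_in_ring = atom_in_ring)
    for (k in which(ring_aromatic)) is_aromatic[ring_atoms[[k]]] <- TRUE
    if (nrow(bonds) > 0) {
      ring_key <- function(ks) unlist(lapply(ks, function(k) {
        r <- ring_atoms[[k]]
        m <- cbind(r, c(r[-1], r[1]))
        paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      }))
      key <- paste(pmin(bonds[, "i"], bonds[, "j"]), pmax(bonds[, "i"], bonds[, "j"]))
      bond_in_ring <- key %in% ring_key(seq_along(ring_atoms))
      aromatic_bond <- key %in% ring_key(which(ring_aromatic))
    }
  }

  coords <- NULL
  if (keep_coords) {
    coords <- rec$coords[heavy, , drop = FALSE]
    coords <- sweep(coords, 2, colMeans(coords))
    colnames(coords) <- c("x", "y", "z")
  }

  structure(list(
    smiles = smiles, mol_id = mol_id, n_atoms = n,
    symbol = unname(symbol), atomic_number = unname(atomic_number),
    charge = charge, degree = degree,
    n_explicit_h = n_explicit_h, implicit_h = implicit_h,
    num_h = n_explicit_h + implicit_h,
    is_aromatic = is_aromatic, atom_in_ring = atom_in_ring,
    rings = ring_atoms, bonds = bonds,
    bond_in_ring = bond_in_ring, aromatic_bond = aromatic_bond,
    coords = coords
  ), class = "adc_mol")
}

# split multi-record SDF text into per-record line vectors
.split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(if (length(lines)) list(lines) else list())
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

# ChemmineR SDFset aligned with records (NULL where ChemmineR rejects a
# record, e.g. bond-free molecules); used only for ring perception
.sdfset_for_rings <- function(sdf_text_lines, n_records) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text_lines, tf)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e) NULL)
  out <- vector("list", n_records)
  if (is.null(sdfset) || length(sdfset) != n_records) return(out)
  valid <- tryCatch(ChemmineR::validSDF(sdfset), error = function(e) rep(FALSE, n_records))
  for (k in seq_len(n_records)) if (valid[k]) out[[k]] <- sdfset[[k]]
  out
}

#' Parse SMILES strings into perceived molecules
#'
#' Canonicalizes each SMILES with OpenBabel and perceives the heavy-atom
#' graph: elements, formal charges, kekulized bond orders, rings,
#' aromaticity and implicit hydrogen counts. Atom indices follow the order
#' of appearance in the canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @param mol_id optional character vector of molecule identifiers.
#' @return a list of `adc_mol` objects.
#' @export
parse_smiles <- function(smiles, mol_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  if (is.null(mol_id)) mol_id <- sprintf("mol%04d", seq_along(smiles))
  can <- canonical_smiles(smiles)
  bad <- which(is.na(can))
  if (length(bad) > 0) adcgnn_parse_error(smiles[bad[1]])
  sdf_text <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", source = paste0(paste(can, collapse = "\n"), "\n")))
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  records <- .split_sdf_records(lines)
  if (length(records) != length(smiles)) {
    stop("SMILES to SDF conversion dropped molecules")
  }
  ring_sdfs <- .sdfset_for_rings(lines, length(records))
  lapply(seq_along(records), function(k) {
    rec <- .parse_v2000(records[[k]])
    if (is.null(rec)) adcgnn_parse_error(smiles[k])
    needs_rings <- nrow(rec$bonds) >= 3
    ri <- if (needs_rings) .perceive_rings(ring_sdfs[[k]]) else
      list(rings = list(), aromatic = logical(0))
    .build_mol(rec, ri, smiles = can[k], mol_id = mol_id[k])
  })
}

#' Read molecules with 3D coordinates from an SDF file
#'
#' Explicit hydrogens are folded into per-atom hydrogen counts; coordinates
#' of the heavy atoms are retained and centered at the molecular centroid.
#'
#' @param file path to an SDF (V2000) file.
#' @return list of `adc_mol` objects with a `coords` matrix.
#' @export
read_sdf_molecules <- function(file) {
  lines <- readLines(file, warn = FALSE)
  records <- .split_sdf_records(lines)
  records <- records[vapply(records, length, 1L) >= 4]
  if (!length(records)) stop("no SDF records in ", file)
  ring_sdfs <- .sdfset_for_rings(lines, length(records))
  lapply(seq_along(records), function(k) {
    rec <- .parse_v2000(records[[k]])
    if (is.null(rec)) stop("malformed SDF record ", k, " in ", file)
    title <- trimws(records[[k]][1])
    id <- if (nzchar(title)) title else sprintf("sdf%04d", k)
    smi <- tryCatch({
      out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN",
        source = paste(c(records[[k]], "$$$$"), collapse = "\n")))
      strsplit(out, "[ \t\n]")[[1]][1]
    }, error = function(e) NA_character_)
    ri <- if (nrow(rec$bonds) >= 3) .perceive_rings(ring_sdfs[[k]]) else
      list(rings = list(), aromatic = logical(0))
    .build_mol(rec, ri, smiles = smi, mol_id = id, keep_coords = TRUE)
  })
}

#' @export
print.adc_mol <- function(x, ...) {
  cat(sprintf("<adc_mol %s: %d heavy atoms, %d bonds%s> %s\n",
              x$mol_id, x$n_atoms, nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D" else "", x$smiles))
  invisible(x)
}
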