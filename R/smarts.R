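# Restricted SMARTS parser and substructure matcher.
#
# Supported subset (sufficient for functional-group attribution):
#   * organic-subset atoms: C N O S P F Cl Br I B (aliphatic),
#     c n o s p (aromatic), * (any), A (aliphatic any), a (aromatic any)
#   * bracket atoms [ ... ] with ',' alternatives, ';'/'&'/juxtaposition
#     conjunction and '!' negation of single primitives; primitives:
#     #<n> (atomic number, any aromaticity), element symbols, H<n> (total
#     hydrogen count, bare H = 1), D<n> (heavy-atom degree), R (ring
#     membership), +/-/+<n>/-<n> formal charge, * A a
#   * bonds: - = # : ~ and the SMARTS default (single-or-aromatic)
#   * branches ( ) and ring-closure digits 1-9
# Unsupported constructs (recursive $(...), stereo, X, v, %nn, maps) raise
# a parse error naming the pattern.

SMARTS_TWO_CHAR <- c("Cl", "Br")
SMARTS_ALIPHATIC <- c("B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
SMARTS_AROMATIC <- c("b", "c", "n", "o", "s", "p")

smarts_parse_error <- function(pattern, why) {
  stop(structure(
    class = c("adcgnn_smarts_error", "error", "condition"),
    list(message = sprintf("invalid SMARTS '%s': %s", pattern, why),
         call = NULL, pattern = pattern)
  ))
}

# parse the contents of a bracket atom into a list of alternatives,
# each a list of primitives list(type=, value=, negate=)
.parse_bracket <- function(body, pattern) {
  alts <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (length(alts) == 0) smarts_parse_error(pattern, "empty bracket atom")
  lapply(alts, function(alt) {
    prims <- list()
    s <- gsub("[;&]", "", alt)
    i <- 1L
    negate <- FALSE
    while (i <= nchar(s)) {
      ch <- substr(s, i, i)
      rest <- substr(s, i, nchar(s))
      if (ch == "!") { negate <- TRUE; i <- i + 1L; next }
      prim <- NULL
      if (ch == "#") {
        m <- regmatches(rest, regexpr("^#[0-9]+", rest))
        if (!length(m)) smarts_parse_error(pattern, "bad atomic number primitive")
        prim <- list(type = "anum", value = as.integer(sub("#", "", m)))
        i <- i + nchar(m)
      } else if (grepl("^(Cl|Br)", rest)) {
        sym <- substr(rest, 1, 2)
        prim <- list(type = "element", value = sym, aromatic = FALSE)
        i <- i + 2L
      } else if (ch %in% SMARTS_ALIPHATIC) {
        prim <- list(type = "element", value = ch, aromatic = FALSE)
        i <- i + 1L
      } else if (ch %in% SMARTS_AROMATIC) {
        prim <- list(type = "element", value = toupper(ch), aromatic = TRUE)
        i <- i + 1L
      } else if (ch == "*") {
        prim <- list(type = "any"); i <- i + 1L
      } else if (ch == "A") {
        prim <- list(type = "aliphatic_any"); i <- i + 1L
      } else if (ch == "a") {
        prim <- list(type = "aromatic_any"); i <- i + 1L
      } else if (ch == "H") {
        m <- regmatches(rest, regexpr("^H[0-9]*", rest))
        nh <- sub("H", "", m)
        prim <- list(type = "hcount", value = if (nzchar(nh)) as.integer(nh) else 1L)
        i <- i + nchar(m)
      } else if (ch == "D") {
        m <- regmatches(rest, regexpr("^D[0-9]*", rest))
        nd <- sub("D", "", m)
        prim <- list(type = "degree", value = if (nzchar(nd)) as.integer(nd) else 1L)
        i <- i + nchar(m)
      } else if (ch == "R") {
        prim <- list(type = "ring"); i <- i + 1L
      } else if (ch %in% c("+", "-")) {
        m <- regmatches(rest, regexpr("^[+-][0-9]*", rest))
        q <- sub("^([+-]).*", "\\1", m)
        num <- sub("^[+-]", "", m)
        val <- if (nzchar(num)) as.integer(num) else 1L
        prim <- list(type = "charge", value = if (q == "+") val else -val)
        i <- i + nchar(m)
      } else {
        smarts_parse_error(pattern, sprintf("unsupported primitive at '%s'", rest))
      }
      prim$negate <- negate
      negate <- FALSE
      prims[[length(prims) + 1L]] <- prim
    }
    if (negate) smarts_parse_error(pattern, "dangling '!'")
    if (!length(prims)) smarts_parse_error(pattern, "empty bracket alternative")
    prims
  })
}

#' Parse a SMARTS pattern (restricted subset)
#'
#' @param pattern SMARTS string.
#' @return a `smarts_query` with query atoms and bonds.
#' @export
parse_smarts <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (grepl("\\$\\(", pattern)) {
    smarts_parse_error(pattern, "recursive SMARTS are not supported")
  }
  atoms <- list()       # each: list of alternatives (list of primitive lists)
  bonds <- list()       # each: c(a, b), type
  stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list()
  i <- 1L
  np <- nchar(pattern)
  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    a <- length(atoms)
    if (prev > 0L) {
      bt <- if (is.na(pending_bond)) "default" else pending_bond
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = a, type = bt)
    }
    pending_bond <<- NA_character_
    prev <<- a
  }
  while (i <= np) {
    ch <- substr(pattern, i, i)
    rest <- substr(pattern, i, np)
    if (ch == "[") {
      j <- regexpr("]", rest, fixed = TRUE)
      if (j < 0) smarts_parse_error(pattern, "unclosed bracket")
      add_atom(.parse_bracket(substr(pattern, i + 1L, i + j - 2L), pattern))
      i <- i + j
    } else if (grepl("^(Cl|Br)", rest)) {
      add_atom(list(list(list(type = "element", value = substr(rest, 1, 2),
                              aromatic = FALSE, negate = FALSE))))
      i <- i + 2L
    } else if (ch %in% SMARTS_ALIPHATIC) {
      add_atom(list(list(list(type = "element", value = ch, aromatic = FALSE,
                              negate = FALSE))))
      i <- i + 1L
    } else if (ch %in% SMARTS_AROMATIC) {
      add_atom(list(list(list(type = "element", value = toupper(ch),
                              aromatic = TRUE, negate = FALSE))))
      i <- i + 1L
    } else if (ch == "*") {
      add_atom(list(list(list(type = "any", negate = FALSE)))); i <- i + 1L
    } else if (ch == "A") {
      add_atom(list(list(list(type = "aliphatic_any", negate = FALSE)))); i <- i + 1L
    } else if (ch == "a") {
      add_atom(list(list(list(type = "aromatic_any", negate = FALSE)))); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- c(`-` = "single", `=` = "double", `#` = "triple",
                        `:` = "aromatic", `~` = "any")[[ch]]
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) smarts_parse_error(pattern, "unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[1-9]$", ch)) {
      if (!is.null(ring_open[[ch]])) {
        op <- ring_open[[ch]]
        bt <- if (!is.na(pending_bond)) pending_bond else op$type
        if (is.na(bt)) bt <- "default"
        bonds[[length(bonds) + 1L]] <- list(a = op$atom, b = prev, type = bt)
        ring_open[[ch]] <- NULL
      } else {
        ring_open[[ch]] <- list(atom = prev, type = pending_bond)
      }
      pending_bond <- NA_character_
      i <- i + 1L
    } else {
      smarts_parse_error(pattern, sprintf("unsupported token '%s'", ch))
    }
  }
  if (length(Filter(Negate(is.null), ring_open))) {
    smarts_parse_error(pattern, "unclosed ring bond")
  }
  if (length(stack)) smarts_parse_error(pattern, "unbalanced '('")
  if (!length(atoms)) smarts_parse_error(pattern, "no atoms")
  structure(list(pattern = pattern, atoms = atoms, bonds = bonds),
            class = "smarts_query")
}

.smarts_atom_ok <- function(mol, a, expr) {
  for (alt in expr) {
    ok <- TRUE
    for (p in alt) {
      val <- switch(p$type,
        any = TRUE,
        aliphatic_any = !mol$is_aromatic[a],
        aromatic_any = mol$is_aromatic[a],
        anum = mol$atomic_number[a] == p$value,
        element = mol$symbol[a] == p$value && mol$is_aromatic[a] == p$aromatic,
        hcount = mol$num_h[a] == p$value,
        degree = mol$degree[a] == p$value,
        ring = mol$atom_in_ring[a],
        charge = mol$charge[a] == p$value,
        FALSE)
      if (isTRUE(p$negate)) val <- !val
      if (!val) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.smarts_bond_ok <- function(order, aromatic, type) {
  switch(type,
    single = order == 1 && !aromatic,
    double = order == 2 && !aromatic,
    triple = order == 3 && !aromatic,
    aromatic = aromatic,
    any = TRUE,
    default = (order == 1 && !aromatic) || aromatic,
    FALSE)
}

#' Match a SMARTS pattern against a molecule
#'
#' Backtracking subgraph matcher over the heavy-atom graph. Matches are
#' returned as integer vectors of molecule atom indices in query-atom
#' order; by default symmetric duplicates (same atom set) are collapsed.
#'
#' @param mol an `adc_mol` or SMILES string.
#' @param query a [parse_smarts()] query or SMARTS string.
#' @param uniquify drop matches covering an already-matched atom set.
#' @return list of integer vectors (possibly empty).
#' @export
smarts_match <- function(mol, query, uniquify = TRUE) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  if (is.character(query)) query <- parse_smarts(query)
  nq <- length(query$atoms)
  n <- mol$n_atoms

  # molecule adjacency with bond annotation
  badj <- vector("list", n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, "i"]; j <- b[k, "j"]
      badj[[i]] <- rbind(badj[[i]], c(j, b[k, "order"], mol$aromatic_bond[k]))
      badj[[j]] <- rbind(badj[[j]], c(i, b[k, "order"], mol$aromatic_bond[k]))
    }
  }
  bond_info <- function(i, j) {
    m <- badj[[i]]
    if (is.null(m)) return(NULL)
    r <- which(m[, 1] == j)
    if (!length(r)) return(NULL)
    m[r[1], ]
  }

  # query adjacency; order atoms so each after the first touches an earlier
  qadj <- lapply(seq_len(nq), function(a) list())
  for (qb in query$bonds) {
    qadj[[qb$a]][[length(qadj[[qb$a]]) + 1L]] <- list(nbr = qb$b, type = qb$type)
    qadj[[qb$b]][[length(qadj[[qb$b]]) + 1L]] <- list(nbr = qb$a, type = qb$type)
  }
  order_q <- 1L
  seen <- rep(FALSE, nq); seen[1] <- TRUE
  while (length(order_q) < nq) {
    nxt <- NA_integer_
    for (q in order_q) {
      for (e in qadj[[q]]) if (!seen[e$nbr]) { nxt <- e$nbr; break }
      if (!is.na(nxt)) break
    }
    if (is.na(nxt)) nxt <- which(!seen)[1]  # disconnected query component
    seen[nxt] <- TRUE
    order_q <- c(order_q, nxt)
  }

  cand <- lapply(seq_len(nq), function(q) {
    which(vapply(seq_len(n), function(a) .smarts_atom_ok(mol, a, query$atoms[[q]]),
                 logical(1)))
  })
  if (any(lengths(cand) == 0)) return(list())

  matches <- list()
  assign_vec <- rep(NA_integer_, nq)
  recurse <- function(pos) {
    if (pos > nq) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    q <- order_q[pos]
    for (a in cand[[q]]) {
      if (a %in% assign_vec) next
      ok <- TRUE
      for (e in qadj[[q]]) {
        other <- assign_vec[e$nbr]
        if (is.na(other)) next
        bi <- bond_info(a, other)
        if (is.null(bi) || !.smarts_bond_ok(bi[2], as.logical(bi[3]), e$type)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[q] <<- a
      recurse(pos + 1L)
      assign_vec[q] <<- NA_integer_
    }
    invisible(NULL)
  }
  recurse(1L)
  if (uniquify && length(matches) > 1) {
    keys <- vapply(matches, function(m) paste(sort(m), collapse = ","), character(1))
    matches <- matches[!duplicated(keys)]
  }
  matches
}
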