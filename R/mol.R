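# Molecular graph layer.
#
# Molecules are held as lightweight graphs ("rvmol"): typed heavy atoms with
# implicit hydrogen counts, plus a bond matrix. OpenBabel (via ChemmineOB)
# is the sanitizer and canonicalizer: every molecule enters the package
# through its canonical SMILES, and canonical identifiers are OpenBabel
# canonical SMILES of the stereo-stripped graph. Aromaticity is kept as its
# own bond order so descriptors never depend on a Kekulé assignment.
# Stereochemistry is ignored throughout: atom-pair descriptors and the
# structure generator are purely topological.

BOND_SINGLE <- 1
BOND_DOUBLE <- 2
BOND_TRIPLE <- 3
BOND_AROMATIC <- 4

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_subset <- c("b", "c", "n", "o", "p", "s", "se", "as")

# Standard valence lists used for implicit-hydrogen completion of neutral
# organic-subset atoms (bracket atoms always carry an explicit H count).
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

parse_error <- function(msg, smiles = NULL) {
  stop(structure(
    class = c("rvdesign_parse_error", "error", "condition"),
    list(message = if (is.null(smiles)) msg else sprintf("%s [in %s]", msg, smiles),
         call = NULL)
  ))
}

new_rvmol <- function(elem, arom, charge, nH, iso, bonds) {
  structure(list(
    elem = as.character(elem), arom = as.logical(arom),
    charge = as.integer(charge), nH = as.integer(nH), iso = as.integer(iso),
    bonds = matrix(as.numeric(bonds), ncol = 3,
                   dimnames = list(NULL, c("a1", "a2", "order")))
  ), class = "rvmol")
}

n_atoms <- function(mol) length(mol$elem)

#' Heavy-atom count of a molecule
#'
#' Counts non-hydrogen, non-dummy atoms. Attachment-point dummies (`*`) are
#' excluded, matching the fragment bookkeeping used by the fragmentation and
#' design modules.
#'
#' @param mol An `rvmol` molecular graph.
#' @return Integer heavy-atom count.
#' @export
heavy_atom_count <- function(mol) sum(mol$elem != "*")

is_dummy <- function(mol) mol$elem == "*"

# ---- SMILES reading ---------------------------------------------------------

# Syntax-level validation. OpenBabel silently repairs malformed SMILES, so the
# package refuses anything its own tokenizer cannot account for.
.smiles_syntax_ok <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  rest <- s
  depth <- 0L
  token <- paste0(
    "^(\\[[^\\]]+\\]|Cl|Br|[BCNOPSFI*]|[bcnops]|",
    "%[0-9]{2}|[0-9]|[().=#:/\\\\~-])"
  )
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr(token, rest, perl = TRUE))
    if (length(m) == 0) return(FALSE)
    if (m == "(") depth <- depth + 1L
    if (m == ")") { depth <- depth - 1L; if (depth < 0) return(FALSE) }
    rest <- substring(rest, nchar(m) + 1)
  }
  depth == 0L
}

.parse_bracket_atom <- function(tok, smiles) {
  body <- substring(tok, 2, nchar(tok) - 1)
  m <- regmatches(body, regexec(
    "^([0-9]*)(\\*|[A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+\\+|--)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0) parse_error(paste0("bad bracket atom ", tok), smiles)
  iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  sym <- m[3]
  arom <- sym %in% .aromatic_subset
  elem <- if (sym == "*") "*" else paste0(toupper(substring(sym, 1, 1)), substring(sym, 2))
  htok <- m[5]
  nH <- if (!nzchar(htok)) 0L else if (htok == "H") 1L else as.integer(substring(htok, 2))
  ctok <- m[6]
  charge <- 0L
  if (nzchar(ctok)) {
    charge <- if (ctok == "+") 1L else if (ctok == "-") -1L
    else if (ctok == "++") 2L else if (ctok == "--") -2L
    else as.integer(paste0(substring(ctok, 1, 1), substring(ctok, 2)))
  }
  list(elem = elem, arom = arom, charge = charge, nH = nH, iso = iso)
}

# Implicit hydrogens for bare (organic subset, neutral) atoms. `deg` counts
# explicit connections, `bondsum` sums bond orders with aromatic as 1.
.implied_h <- function(elem, arom, bondsum, deg) {
  if (arom) {
    return(if (elem == "C") max(0L, 3L - as.integer(deg)) else 0L)
  }
  vals <- .default_valences[[elem]]
  if (is.null(vals)) return(0L)
  need <- as.integer(ceiling(bondsum))
  ok <- vals[vals >= need]
  if (length(ok) == 0) return(0L)
  as.integer(ok[1] - bondsum)
}

# Parse a SMILES string into an rvmol. Expects aromaticity to be expressed in
# lowercase form (the package always reads OpenBabel-canonical strings or its
# own writer output). Stereo markers are accepted and discarded.
parse_smiles_graph <- function(s) {
  if (!.smiles_syntax_ok(s)) parse_error("malformed SMILES", s)
  elem <- character(); arom <- logical(); charge <- integer()
  nH <- integer(); iso <- integer(); hset <- logical()
  bonds <- matrix(numeric(0), ncol = 3)
  prev <- NA_integer_
  stack <- integer()
  pending <- NA_real_
  ring <- list()
  i <- 1L; n <- nchar(s)

  add_bond <- function(a, b, ord) {
    if (is.na(ord)) ord <- if (arom[a] && arom[b]) BOND_AROMATIC else BOND_SINGLE
    if (a == b) parse_error("self bond", s)
    bonds <<- rbind(bonds, c(a, b, ord))
  }
  add_atom <- function(at) {
    elem <<- c(elem, at$elem); arom <<- c(arom, at$arom)
    charge <<- c(charge, at$charge); nH <<- c(nH, at$nH); iso <<- c(iso, at$iso)
    hset <<- c(hset, isTRUE(at$hset))
    idx <- length(elem)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_real_
    prev <<- idx
  }
  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- c(prev, pending)
      pending <<- NA_real_
    } else {
      open <- ring[[key]]
      ord <- pending
      if (is.na(ord)) ord <- open[2]
      add_bond(open[1], prev, ord)
      ring[[key]] <<- NULL
      pending <<- NA_real_
    }
  }

  while (i <= n) {
    ch <- substring(s, i, i)
    two <- substring(s, i, i + 1)
    if (ch == "[") {
      j <- regexpr("\\]", substring(s, i))
      if (j < 0) parse_error("unclosed bracket", s)
      tok <- substring(s, i, i + j - 1)
      at <- .parse_bracket_atom(tok, s)
      at$hset <- TRUE
      add_atom(at)
      i <- i + j
    } else if (two %in% c("Cl", "Br")) {
      add_atom(list(elem = two, arom = FALSE, charge = 0L, nH = 0L, iso = 0L))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(list(elem = ch, arom = FALSE, charge = 0L, nH = 0L, iso = 0L))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(list(elem = toupper(ch), arom = TRUE, charge = 0L, nH = 0L, iso = 0L))
      i <- i + 1L
    } else if (ch == "*") {
      add_atom(list(elem = "*", arom = FALSE, charge = 0L, nH = 0L, iso = 0L))
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) parse_error("branch before any atom", s)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) parse_error("unbalanced parentheses", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") { pending <- BOND_SINGLE; i <- i + 1L
    } else if (ch == "=") { pending <- BOND_DOUBLE; i <- i + 1L
    } else if (ch == "#") { pending <- BOND_TRIPLE; i <- i + 1L
    } else if (ch == ":") { pending <- BOND_AROMATIC; i <- i + 1L
    } else if (ch %in% c("/", "\\", "~")) { pending <- BOND_SINGLE; i <- i + 1L
    } else if (ch == ".") { prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else if (ch == "%") {
      num <- as.integer(substring(s, i + 1, i + 2))
      if (is.na(num) || is.na(prev)) parse_error("bad ring closure", s)
      close_ring(num); i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) parse_error("ring closure before any atom", s)
      close_ring(as.integer(ch)); i <- i + 1L
    } else parse_error(paste0("unexpected character '", ch, "'"), s)
  }
  if (length(ring) > 0) parse_error("unclosed ring bond", s)
  if (length(stack) > 0) parse_error("unbalanced parentheses", s)
  if (length(elem) == 0) parse_error("empty SMILES", s)

  mol <- new_rvmol(elem, arom, charge, nH, iso, bonds)
  # An unmarked bond between two aromatic atoms is aromatic only inside a
  # ring; acyclic such bonds (biaryl links) are single.
  if (nrow(mol$bonds) > 0) {
    ar <- mol$bonds[, "order"] == BOND_AROMATIC
    if (any(ar)) {
      rb <- ring_bond_flags(mol)
      demote <- ar & !rb
      mol$bonds[demote, "order"] <- BOND_SINGLE
    }
  }
  # Implicit hydrogens for atoms whose H count was not set by a bracket.
  bs <- bond_order_sums(mol)
  dg <- atom_degrees(mol)
  for (a in seq_len(n_atoms(mol))) {
    if (!hset[a] && mol$elem[a] != "*") {
      mol$nH[a] <- .implied_h(mol$elem[a], mol$arom[a], bs[a], dg[a])
    }
  }
  mol
}

bond_order_sums <- function(mol) {
  out <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(out)
  ord <- ifelse(mol$bonds[, "order"] == BOND_AROMATIC, 1.5, mol$bonds[, "order"])
  for (k in seq_len(nrow(mol$bonds))) {
    out[mol$bonds[k, "a1"]] <- out[mol$bonds[k, "a1"]] + ord[k]
    out[mol$bonds[k, "a2"]] <- out[mol$bonds[k, "a2"]] + ord[k]
  }
  out
}

atom_degrees <- function(mol) {
  out <- integer(n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(out)
  t1 <- tabulate(mol$bonds[, "a1"], nbins = n_atoms(mol))
  t2 <- tabulate(mol$bonds[, "a2"], nbins = n_atoms(mol))
  out + t1 + t2
}

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
      adj[[a]] <- c(adj[[a]], k)
      adj[[b]] <- c(adj[[b]], k)
    }
  }
  adj
}

bond_other <- function(mol, k, a) {
  b <- mol$bonds[k, c("a1", "a2")]
  if (b[1] == a) b[2] else b[1]
}

# Ring-membership flags per bond: a bond is in a ring iff it is not a bridge
# (iterative DFS low-link bridge finding).
ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  disc <- rep(NA_integer_, n); low <- integer(n)
  bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (!is.na(disc[root])) next
    stack <- list(list(a = root, pe = 0L, ci = 1L))
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      a <- fr$a
      if (fr$ci == 1L) {
        if (!is.na(disc[a])) {  # duplicate frame from multiple pushes
          stack[[length(stack)]] <- NULL
          next
        }
        timer <- timer + 1L
        disc[a] <- timer; low[a] <- timer
      }
      edges <- adj[[a]]
      if (fr$ci <= length(edges)) {
        k <- edges[fr$ci]
        stack[[length(stack)]]$ci <- fr$ci + 1L
        if (k == fr$pe) next
        b <- bond_other(mol, k, a)
        if (is.na(disc[b])) {
          stack[[length(stack) + 1L]] <- list(a = b, pe = k, ci = 1L)
        } else {
          low[a] <- min(low[a], disc[b])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0) {
          p <- stack[[length(stack)]]$a
          low[p] <- min(low[p], low[a])
          if (low[a] > disc[p]) bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !bridge
}

# ---- SMILES writing ---------------------------------------------------------

.atom_token <- function(mol, a, deg) {
  elem <- mol$elem[a]
  if (elem == "*") {
    return(if (mol$iso[a] > 0) sprintf("[%d*]", mol$iso[a]) else "*")
  }
  arom <- mol$arom[a]
  sym <- if (arom) tolower(elem) else elem
  bs <- 0
  adj <- which(mol$bonds[, "a1"] == a | mol$bonds[, "a2"] == a)
  if (length(adj) > 0) {
    ords <- mol$bonds[adj, "order"]
    bs <- sum(ifelse(ords == BOND_AROMATIC, 1.5, ords))
  }
  bare_ok <- elem %in% .organic_subset && mol$charge[a] == 0L &&
    (!arom || tolower(elem) %in% .aromatic_subset) &&
    mol$nH[a] == .implied_h(elem, arom, bs, deg)
  if (bare_ok) return(sym)
  h <- if (mol$nH[a] == 0L) "" else if (mol$nH[a] == 1L) "H" else paste0("H", mol$nH[a])
  ch <- mol$charge[a]
  cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
  else sprintf("%+d", ch)
  sprintf("[%s%s%s]", sym, h, cs)
}

.bond_token <- function(mol, k) {
  ord <- mol$bonds[k, "order"]
  a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
  if (ord == BOND_SINGLE) {
    if (mol$arom[a] && mol$arom[b]) "-" else ""
  } else if (ord == BOND_DOUBLE) "="
  else if (ord == BOND_TRIPLE) "#"
  else ""  # aromatic between aromatic atoms
}

#' Write a molecular graph as SMILES
#'
#' Produces a (non-canonical) SMILES string; use [canonical_smiles()] for a
#' canonical identifier. Aromatic atoms are written in lowercase with
#' aromatic ring bonds left implicit; atoms whose hydrogen count differs from
#' the organic-subset default are bracketed.
#'
#' @param mol An `rvmol`.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return("")
  adj <- adjacency_list(mol)
  deg <- atom_degrees(mol)
  visited <- logical(n)
  used_bond <- logical(nrow(mol$bonds))
  # ring-closure bookkeeping
  closure_of_bond <- vector("list", nrow(mol$bonds))
  open_digits <- logical(100)

  digits_tok <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)

  pieces <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    if (length(pieces) > 0) pieces <- c(pieces, ".")
    # First pass: find ring-closure bonds via DFS spanning tree.
    tree_bond <- logical(nrow(mol$bonds))
    order_visit <- integer(0)
    st <- c(root); seen <- logical(n)
    parent_edge <- rep(0L, n)
    while (length(st) > 0) {
      a <- st[length(st)]; st <- st[-length(st)]
      if (seen[a]) next
      seen[a] <- TRUE
      order_visit <- c(order_visit, a)
      for (k in rev(adj[[a]])) {
        b <- bond_other(mol, k, a)
        if (!seen[b] && k != parent_edge[a]) {
          tree_bond[k] <- TRUE  # provisional; duplicates resolved below
          parent_edge[b] <- k
          st <- c(st, b)
        }
      }
    }
    # tree bonds = parent_edge values actually used
    tree_bond[] <- FALSE
    tree_bond[setdiff(unique(parent_edge[seen]), 0L)] <- TRUE
    comp_bonds <- if (nrow(mol$bonds) == 0) integer(0)
    else which(seen[mol$bonds[, "a1"]] & seen[mol$bonds[, "a2"]])
    closure_bonds <- setdiff(comp_bonds, which(tree_bond))

    # assign closure digits per atom
    closures_at <- vector("list", n)
    for (k in closure_bonds) {
      a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
      closures_at[[a]] <- c(closures_at[[a]], k)
      closures_at[[b]] <- c(closures_at[[b]], k)
    }
    closure_digit <- new.env(parent = emptyenv())
    closure_open <- new.env(parent = emptyenv())

    # Recursive emit via explicit stack.
    emit <- character(0)
    emit_atom <- function(a) {
      tok <- .atom_token(mol, a, deg[a])
      for (k in closures_at[[a]]) {
        key <- as.character(k)
        if (is.null(closure_digit[[key]])) {
          d <- which(!open_digits)[1]
          open_digits[d] <<- TRUE
          closure_digit[[key]] <- d
          closure_open[[key]] <- a
          tok <- paste0(tok, .bond_token(mol, k), digits_tok(d))
        } else {
          d <- closure_digit[[key]]
          open_digits[d] <<- FALSE
          tok <- paste0(tok, digits_tok(d))
        }
      }
      tok
    }
    walk <- function(a, from_bond) {
      visited[a] <<- TRUE
      out <- if (from_bond > 0) paste0(.bond_token(mol, from_bond), emit_atom(a))
      else emit_atom(a)
      kids <- Filter(function(k) tree_bond[k] && !visited[bond_other(mol, k, a)],
                     adj[[a]])
      if (length(kids) > 0) {
        for (i in seq_along(kids)) {
          sub <- walk(bond_other(mol, kids[i], a), kids[i])
          out <- if (i < length(kids)) paste0(out, "(", sub, ")")
          else paste0(out, sub)
        }
      }
      out
    }
    pieces <- c(pieces, walk(root, 0L))
  }
  paste0(pieces, collapse = "")
}

# ---- OpenBabel bridge -------------------------------------------------------

ob_convert <- function(from, to, source) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  out <- sub("[\t ]*\n?$", "", out)
  out <- sub("\t.*$", "", out)
  out
}

#' Canonical SMILES identifier
#'
#' OpenBabel canonical SMILES of the (stereo-stripped) molecular graph. This
#' is the identity used for structure deduplication throughout the package.
#'
#' @param x An `rvmol` or a SMILES string.
#' @return A canonical SMILES string.
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "rvmol")) {
    if (!is.null(attr(x, "cansmi"))) return(attr(x, "cansmi"))
    x <- write_smiles(x)
  }
  out <- ob_convert("SMI", "CAN", x)
  if (!nzchar(out)) parse_error("OpenBabel could not canonicalize", x)
  out
}

#' InChI identifier
#'
#' @param x An `rvmol` or SMILES string.
#' @return InChI string.
#' @export
inchi <- function(x) {
  if (inherits(x, "rvmol")) x <- write_smiles(x)
  out <- ob_convert("SMI", "INCHI", x)
  if (!nzchar(out)) parse_error("OpenBabel could not derive InChI", x)
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' The string is syntax-checked, canonicalized through OpenBabel (which
#' perceives aromaticity and normalizes the form), and parsed into an
#' `rvmol` graph with implicit hydrogen counts resolved. Stereochemistry is
#' discarded. Malformed input raises a condition of class
#' `rvdesign_parse_error`.
#'
#' @param smiles A single SMILES string.
#' @param canonicalize Pass the string through OpenBabel first (default).
#'   Set to `FALSE` only for strings already in canonical aromatic form.
#' @return An `rvmol`.
#' @export
#' @examples
#' m <- mol_from_smiles("c1ccccc1O")
#' heavy_atom_count(m)
mol_from_smiles <- function(smiles, canonicalize = TRUE) {
  if (!.smiles_syntax_ok(smiles)) parse_error("malformed SMILES", smiles)
  s <- if (canonicalize) canonical_smiles(smiles) else smiles
  mol <- parse_smiles_graph(s)
  attr(mol, "cansmi") <- if (canonicalize) canonical_smiles(write_smiles(mol)) else NULL
  mol
}

#' @export
print.rvmol <- function(x, ...) {
  cat(sprintf("rvmol: %d heavy atoms, %d bonds | %s\n",
              heavy_atom_count(x), nrow(x$bonds), write_smiles(x)))
  invisible(x)
}

# ---- graph surgery ----------------------------------------------------------

# Connected components as a membership vector.
component_membership <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- adjacency_list(mol)
  cid <- 0L
  for (root in seq_len(n)) {
    if (comp[root] > 0) next
    cid <- cid + 1L
    st <- root
    while (length(st) > 0) {
      a <- st[length(st)]; st <- st[-length(st)]
      if (comp[a] > 0) next
      comp[a] <- cid
      for (k in adj[[a]]) st <- c(st, bond_other(mol, k, a))
    }
  }
  comp
}

# Extract the sub-molecule induced by an atom index set.
subset_mol <- function(mol, atoms) {
  atoms <- sort(atoms)
  map <- integer(n_atoms(mol)); map[atoms] <- seq_along(atoms)
  keep <- nrow(mol$bonds) > 0 &
    (mol$bonds[, "a1"] %in% atoms & mol$bonds[, "a2"] %in% atoms)
  b <- mol$bonds[keep, , drop = FALSE]
  if (nrow(b) > 0) {
    b[, "a1"] <- map[b[, "a1"]]; b[, "a2"] <- map[b[, "a2"]]
  }
  new_rvmol(mol$elem[atoms], mol$arom[atoms], mol$charge[atoms],
            mol$nH[atoms], mol$iso[atoms], b)
}

#' Split a molecular graph into connected components
#'
#' @param mol An `rvmol`.
#' @return A list of `rvmol`, one per component, in order of first atom.
#' @export
mol_components <- function(mol) {
  comp <- component_membership(mol)
  lapply(seq_len(max(comp, 0L)), function(ci) subset_mol(mol, which(comp == ci)))
}

# Concatenate two molecular graphs (disconnected union).
combine_mols <- function(a, b) {
  off <- n_atoms(a)
  bb <- b$bonds
  if (nrow(bb) > 0) {
    bb[, "a1"] <- bb[, "a1"] + off; bb[, "a2"] <- bb[, "a2"] + off
  }
  new_rvmol(c(a$elem, b$elem), c(a$arom, b$arom), c(a$charge, b$charge),
            c(a$nH, b$nH), c(a$iso, b$iso), rbind(a$bonds, bb))
}

# Remove attachment-point dummies, capping the neighbours with hydrogens.
strip_dummies <- function(mol) {
  d <- which(is_dummy(mol))
  if (length(d) == 0) return(mol)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
      ord <- mol$bonds[k, "order"]
      ordv <- if (ord == BOND_AROMATIC) 1 else ord
      if (a %in% d && !(b %in% d)) mol$nH[b] <- mol$nH[b] + as.integer(ordv)
      if (b %in% d && !(a %in% d)) mol$nH[a] <- mol$nH[a] + as.integer(ordv)
    }
  }
  subset_mol(mol, setdiff(seq_len(n_atoms(mol)), d))
}

# Delete bond k, returning hydrogens to both endpoints.
delete_bond <- function(mol, k) {
  a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
  ord <- mol$bonds[k, "order"]
  ordv <- if (ord == BOND_AROMATIC) 1L else as.integer(ord)
  mol$nH[a] <- mol$nH[a] + ordv
  mol$nH[b] <- mol$nH[b] + ordv
  mol$bonds <- mol$bonds[-k, , drop = FALSE]
  attr(mol, "cansmi") <- NULL
  mol
}

# Add a bond of the given order, consuming hydrogens; NULL if infeasible.
add_bond <- function(mol, a, b, ord) {
  ordv <- if (ord == BOND_AROMATIC) 1L else as.integer(ord)
  if (mol$nH[a] < ordv || mol$nH[b] < ordv) return(NULL)
  if (a == b) return(NULL)
  if (nrow(mol$bonds) > 0 &&
      any((mol$bonds[, "a1"] == a & mol$bonds[, "a2"] == b) |
          (mol$bonds[, "a1"] == b & mol$bonds[, "a2"] == a))) return(NULL)
  mol$nH[a] <- mol$nH[a] - ordv
  mol$nH[b] <- mol$nH[b] - ordv
  mol$bonds <- rbind(mol$bonds, c(a, b, ord))
  attr(mol, "cansmi") <- NULL
  mol
}
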