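# Atom typing, atom-pair (AP2/AP3) descriptor vectors, and the fingerprint /
# similarity primitives used by every other module.
#
# An atom type is (element, formal charge, aromatic flag, attached-H count).
# AP2 is a bonded heavy-atom pair with its bond order; AP3 is a linear path
# of three heavy atoms with both bond orders. Keeping the hydrogen count in
# the atom type lets hydrogen-losing transformations (amide coupling,
# esterification, ...) register in a reaction vector without hydrogens ever
# being descriptor endpoints. Descriptor vectors are sparse named integer
# vectors: names are canonical atom-pair keys, values are signed counts, and
# zero entries are never stored. Molecule-derived vectors are all-positive;
# reaction vectors are mixed-sign.

.bond_symbol <- c("1", "2", "3", "a")

#' Atom type of an atom in a molecule
#'
#' @param mol An `rvmol`.
#' @param idx Atom index.
#' @return A string `"<element><charge><a|.><H-count>"`, e.g. `"C0.3"` for a
#'   methyl carbon or `"N+1.3"` for an ammonium nitrogen; the per-atom unit
#'   from which atom-pair keys are assembled.
#' @export
atom_type <- function(mol, idx) {
  atom_type_strings(mol)[idx]
}

atom_type_strings <- function(mol) {
  ch <- ifelse(mol$charge == 0L, "0", sprintf("%+d", mol$charge))
  paste0(mol$elem, ch, ifelse(mol$arom, "a", "."), mol$nH)
}

ap2_key <- function(t1, b, t2) {
  f <- paste0(t1, "|", b, "|", t2)
  r <- paste0(t2, "|", b, "|", t1)
  ifelse(f <= r, f, r)
}

ap3_key <- function(t1, b1, t2, b2, t3) {
  f <- paste0(t1, "|", b1, "|", t2, "|", b2, "|", t3)
  r <- paste0(t3, "|", b2, "|", t2, "|", b1, "|", t1)
  ifelse(f <= r, f, r)
}

# Collapse a character vector of keys into a sparse count vector.
.tally <- function(keys) {
  if (length(keys) == 0) return(structure(integer(0), names = character(0)))
  tb <- table(keys)
  structure(as.integer(tb), names = names(tb))
}

#' Atom-pair descriptor vector of a molecule
#'
#' Counts every bonded heavy-atom pair (AP2) and every linear three-atom
#' heavy path (AP3), each undirected path once. Hydrogens are never
#' endpoints; they enter through the H count inside the atom type.
#'
#' @param mol An `rvmol`.
#' @param orders Which descriptor orders to include (default both 2 and 3;
#'   the generator uses the AP2-only form as a cheap pre-screen).
#' @return Named integer vector (a sparse descriptor vector), all counts
#'   positive; empty for a molecule with no bonds.
#' @export
#' @examples
#' compute_atom_pairs(mol_from_smiles("CCC"))
compute_atom_pairs <- function(mol, orders = c(2L, 3L)) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(.tally(character(0)))
  ty <- atom_type_strings(mol)
  b1 <- mol$bonds[, "a1"]; b2 <- mol$bonds[, "a2"]
  bs <- .bond_symbol[mol$bonds[, "order"]]
  keys <- character(0)
  if (2L %in% orders) keys <- ap2_key(ty[b1], bs, ty[b2])
  if (3L %in% orders) {
    adj <- adjacency_list(mol)
    k3 <- character(0)
    for (c in seq_len(n_atoms(mol))) {
      ks <- adj[[c]]
      if (length(ks) < 2) next
      for (i in seq_len(length(ks) - 1)) {
        for (j in seq(i + 1, length(ks))) {
          e1 <- ks[i]; e2 <- ks[j]
          a <- bond_other(mol, e1, c); b <- bond_other(mol, e2, c)
          k3 <- c(k3, ap3_key(ty[a], .bond_symbol[mol$bonds[e1, "order"]],
                              ty[c], .bond_symbol[mol$bonds[e2, "order"]],
                              ty[b]))
        }
      }
    }
    keys <- c(keys, k3)
  }
  .tally(keys)
}

#' Signed addition of sparse descriptor vectors
#'
#' @param a,b Named integer vectors (sparse descriptor vectors).
#' @return The per-key signed sum with zero entries removed, names sorted.
#' @export
vector_add <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(structure(integer(0), names = character(0)))
  keys <- c(names(a), names(b))
  vals <- c(as.integer(a), as.integer(b))
  s <- vapply(split(vals, keys), sum, integer(1))
  s <- s[s != 0L]
  s[order(names(s))]
}

vector_negate <- function(a) {
  out <- -a
  out
}

vector_subtract <- function(a, b) vector_add(a, vector_negate(b))

# Canonical single-line serialization of a sparse descriptor vector:
# "key=count" joined by spaces, keys sorted. Used as RV identity.
serialize_vector <- function(v) {
  if (length(v) == 0) return("")
  v <- v[order(names(v))]
  paste0(names(v), "=", as.integer(v), collapse = " ")
}

deserialize_vector <- function(s) {
  if (!nzchar(s)) return(structure(integer(0), names = character(0)))
  parts <- strsplit(s, " ", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^(.*)=(-?[0-9]+)$", parts))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed descriptor vector serialization")
  structure(as.integer(vapply(kv, `[`, "", 3)),
            names = vapply(kv, `[`, "", 2))
}

# ---- fingerprints -----------------------------------------------------------

#' Fingerprint specification
#'
#' @param kind `"binary"` or `"count"`.
#' @param radius Circular (Morgan) radius; default 2.
#' @param n_bits Folded length; default 1024.
#' @return A `fingerprint_spec` object.
#' @export
fingerprint_spec <- function(kind = c("binary", "count"), radius = 2L, n_bits = 1024L) {
  kind <- match.arg(kind)
  stopifnot(n_bits > 0, radius >= 0)
  structure(list(kind = kind, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "fingerprint_spec")
}

# Deterministic 31-bit FNV-1a style hash of an integer vector; plain doubles
# with exact modular arithmetic (all intermediates stay below 2^53).
.hash_ints <- function(xs) {
  h <- 216613626
  for (x in xs) {
    x <- as.numeric(x) %% 2147483647
    h <- (h + x) %% 2147483647
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 2147483647 * 65536 + lo * 16777619) %% 2147483647
  }
  h
}

#' Morgan-style circular fingerprint
#'
#' Iterative neighbourhood hashing over the heavy-atom graph: atom
#' invariants seeded from (element, charge, aromaticity, H count, degree),
#' refined over `radius` rounds with sorted (bond order, neighbour
#' invariant) pairs, all (atom, radius) features folded into `n_bits`
#' positions. Attachment-point dummies are removed (hydrogen-capped) first.
#' `kind = "binary"` gives a 0/1 vector, `kind = "count"` a count vector.
#'
#' @param mol An `rvmol`.
#' @param spec A [fingerprint_spec()].
#' @return Numeric vector of length `spec$n_bits`.
#' @export
fingerprint <- function(mol, spec = fingerprint_spec()) {
  mol <- strip_dummies(mol)
  n <- n_atoms(mol)
  fp <- numeric(spec$n_bits)
  if (n == 0) return(fp)
  deg <- atom_degrees(mol)
  elemnum <- vapply(mol$elem, function(e) {
    i <- match(e, c("*", "H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
                    "Si", "Se", "As", "Li", "Na", "K", "Mg", "Ca", "Zn", "Fe"))
    if (is.na(i)) 99L else i
  }, integer(1))
  inv <- vapply(seq_len(n), function(a) {
    .hash_ints(c(elemnum[a], mol$charge[a] + 10L, as.integer(mol$arom[a]),
                 mol$nH[a], deg[a]))
  }, numeric(1))
  adj <- adjacency_list(mol)
  feats <- inv
  if (spec$radius > 0) {
    for (r in seq_len(spec$radius)) {
      newinv <- numeric(n)
      for (a in seq_len(n)) {
        ks <- adj[[a]]
        if (length(ks) == 0) {
          newinv[a] <- .hash_ints(c(r, inv[a]))
          next
        }
        pairs <- vapply(ks, function(k) {
          nb <- bond_other(mol, k, a)
          mol$bonds[k, "order"] * 2147483647 + inv[nb]
        }, numeric(1))
        pairs <- sort(pairs)
        xs <- c(r, inv[a])
        for (p in pairs) xs <- c(xs, p %/% 2147483647, p %% 2147483647)
        newinv[a] <- .hash_ints(xs)
      }
      inv <- newinv
      feats <- c(feats, inv)
    }
  }
  idx <- (feats %% spec$n_bits) + 1
  for (i in idx) fp[i] <- fp[i] + 1
  if (spec$kind == "binary") fp <- as.numeric(fp > 0)
  fp
}

#' Tanimoto similarity of two binary fingerprints
#'
#' Defined as 1 when both vectors are all-zero, so degenerate tiny fragments
#' match each other instead of failing.
#'
#' @param a,b Equal-length binary vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Euclidean distance between two count fingerprints
#'
#' @param a,b Equal-length numeric vectors.
#' @return Non-negative L2 distance.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  sqrt(sum((a - b)^2))
}
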