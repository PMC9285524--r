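# BRICS retrosynthetic fragmentation and key-fragment role assignment.
#
# The 16-environment BRICS cleavage table is implemented as graph predicates
# over the rvmol layer: a bond is cleavable when its two atoms match a
# compatible environment pair, the bond is acyclic, and the bond order is
# single (double for the olefin rule). Cleaving replaces the bond with two
# labelled attachment-point dummies, the label being the environment number
# of the atom each dummy caps. Fragmentation is a single decomposition pass:
# all eligible bonds are cut simultaneously and fragments are not
# re-fragmented.

fragmentation_failure <- function(msg) {
  stop(structure(
    class = c("rvdesign_fragmentation_failure", "error", "condition"),
    list(message = msg, call = NULL)))
}

# ---- BRICS environments -----------------------------------------------------

.brics_env_table <- function(mol) {
  n <- n_atoms(mol)
  rb <- ring_bond_flags(mol)
  adj <- adjacency_list(mol)
  deg <- atom_degrees(mol)
  in_ring <- vapply(seq_len(n), function(a) any(rb[adj[[a]]]), logical(1))
  ords <- if (nrow(mol$bonds) > 0) mol$bonds[, "order"] else numeric(0)

  nb_info <- function(a) {
    ks <- adj[[a]]
    data.frame(k = ks,
               other = vapply(ks, function(k) bond_other(mol, k, a), numeric(1)),
               ord = ords[ks], ring = rb[ks])
  }
  el <- mol$elem; ar <- mol$arom; ch <- mol$charge

  has_nb <- function(a, f) {
    ni <- nb_info(a)
    if (nrow(ni) == 0) return(FALSE)
    any(vapply(seq_len(nrow(ni)), function(i)
      f(ni$other[i], ni$ord[i], ni$ring[i]), logical(1)))
  }
  all_nb <- function(a, f) {
    ni <- nb_info(a)
    if (nrow(ni) == 0) return(TRUE)
    all(vapply(seq_len(nrow(ni)), function(i)
      f(ni$other[i], ni$ord[i], ni$ring[i]), logical(1)))
  }

  aliC <- el == "C" & !ar
  aroC <- el == "C" & ar

  env <- list()
  env[["1"]] <- vapply(seq_len(n), function(a) {
    aliC[a] && deg[a] == 3 &&
      has_nb(a, function(o, d, r) el[o] == "O" && d == BOND_DOUBLE) &&
      has_nb(a, function(o, d, r) el[o] %in% c("C", "N", "O", "*") &&
               d %in% c(BOND_SINGLE, BOND_AROMATIC))
  }, logical(1))
  env[["3"]] <- vapply(seq_len(n), function(a) {
    el[a] == "O" && !ar[a] && deg[a] == 2 &&
      has_nb(a, function(o, d, r) el[o] %in% c("C", "*") && d == BOND_SINGLE && !r)
  }, logical(1))
  env[["4"]] <- vapply(seq_len(n), function(a) {
    aliC[a] && deg[a] >= 2 &&
      !has_nb(a, function(o, d, r) d == BOND_DOUBLE) &&
      has_nb(a, function(o, d, r) el[o] == "C" && d == BOND_SINGLE && !r)
  }, logical(1))
  env[["5"]] <- vapply(seq_len(n), function(a) {
    if (!(el[a] == "N" && !ar[a] && deg[a] != 1)) return(FALSE)
    if (has_nb(a, function(o, d, r) d == BOND_DOUBLE)) return(FALSE)
    ok_nbrs <- all_nb(a, function(o, d, r)
      !(d == BOND_SINGLE && !(el[o] %in% c("C", "S", "*"))))
    if (!ok_nbrs) return(FALSE)
    # exclude lactam-type N: ring bond to a ring carbon bearing =O
    if (in_ring[a] && has_nb(a, function(o, d, r) {
      r && el[o] == "C" && in_ring[o] &&
        has_nb(o, function(o2, d2, r2) el[o2] == "O" && d2 == BOND_DOUBLE)
    })) return(FALSE)
    TRUE
  }, logical(1))
  env[["6"]] <- vapply(seq_len(n), function(a) {
    aliC[a] && deg[a] == 3 && !in_ring[a] &&
      has_nb(a, function(o, d, r) el[o] == "O" && d == BOND_DOUBLE) &&
      has_nb(a, function(o, d, r) el[o] %in% c("C", "N", "O", "*") &&
               d == BOND_SINGLE && !r)
  }, logical(1))
  env[["7"]] <- vapply(seq_len(n), function(a) {
    aliC[a] && deg[a] %in% c(2, 3) &&
      has_nb(a, function(o, d, r) el[o] == "C" && d == BOND_SINGLE)
  }, logical(1))
  env[["8"]] <- vapply(seq_len(n), function(a) {
    aliC[a] && !in_ring[a] && deg[a] >= 2 &&
      all_nb(a, function(o, d, r) d == BOND_SINGLE)
  }, logical(1))
  env[["9"]] <- vapply(seq_len(n), function(a) {
    if (!(el[a] == "N" && ar[a] && ch[a] == 0L)) return(FALSE)
    ni <- nb_info(a)
    if (nrow(ni) == 0) return(FALSE)
    sum(ni$ord == BOND_AROMATIC & ar[ni$other] &
          el[ni$other] %in% c("C", "N", "O", "S")) >= 2
  }, logical(1))
  env[["10"]] <- vapply(seq_len(n), function(a) {
    if (!(el[a] == "N" && !ar[a] && in_ring[a])) return(FALSE)
    has_acyl <- has_nb(a, function(o, d, r) {
      r && el[o] == "C" && !ar[o] &&
        has_nb(o, function(o2, d2, r2) el[o2] == "O" && d2 == BOND_DOUBLE)
    })
    other_ring <- has_nb(a, function(o, d, r) {
      r && el[o] %in% c("C", "N", "O", "S") && !ar[o] &&
        !has_nb(o, function(o2, d2, r2) el[o2] == "O" && d2 == BOND_DOUBLE)
    })
    # need both a ring acyl neighbour and a second ring neighbour
    ni <- nb_info(a)
    ring_nbrs <- sum(ni$ring)
    has_acyl && ring_nbrs >= 2
  }, logical(1))
  env[["11"]] <- vapply(seq_len(n), function(a) {
    el[a] == "S" && !ar[a] && deg[a] == 2 &&
      has_nb(a, function(o, d, r) el[o] %in% c("C", "*") && d == BOND_SINGLE && !r)
  }, logical(1))
  env[["12"]] <- vapply(seq_len(n), function(a) {
    el[a] == "S" && !ar[a] && deg[a] == 4 &&
      sum(vapply(seq_len(nrow(nb_info(a))), function(i) {
        ni <- nb_info(a); el[ni$other[i]] == "O" && ni$ord[i] == BOND_DOUBLE
      }, logical(1))) >= 2 &&
      has_nb(a, function(o, d, r) el[o] %in% c("C", "*"))
  }, logical(1))
  # the two-branch environments need two DISTINCT neighbours
  env[["13"]] <- vapply(seq_len(n), function(a) {
    if (!aliC[a]) return(FALSE)
    ni <- nb_info(a)
    ok <- ni$ring & ni$ord == BOND_SINGLE & !ar[ni$other]
    n_all <- sum(ok & el[ni$other] %in% c("C", "N", "O", "S"))
    n_het <- sum(ok & el[ni$other] %in% c("N", "O", "S"))
    n_all >= 2 && n_het >= 1
  }, logical(1))
  env[["14"]] <- vapply(seq_len(n), function(a) {
    if (!aroC[a]) return(FALSE)
    ni <- nb_info(a)
    ok <- ni$ord == BOND_AROMATIC & ar[ni$other]
    n_all <- sum(ok & el[ni$other] %in% c("C", "N", "O", "S"))
    n_het <- sum(ok & el[ni$other] %in% c("N", "O", "S"))
    n_all >= 2 && n_het >= 1
  }, logical(1))
  env[["15"]] <- vapply(seq_len(n), function(a) {
    ni <- nb_info(a)
    aliC[a] && nrow(ni) > 0 &&
      sum(ni$ring & ni$ord == BOND_SINGLE & !ar[ni$other] & el[ni$other] == "C") >= 2
  }, logical(1))
  env[["16"]] <- vapply(seq_len(n), function(a) {
    ni <- nb_info(a)
    aroC[a] && nrow(ni) > 0 &&
      sum(ni$ord == BOND_AROMATIC & ar[ni$other] & el[ni$other] == "C") >= 2
  }, logical(1))
  env
}

# Compatible environment pairs, in rule-group order; first match claims a bond.
.brics_rules <- list(
  list(c("1", "3"), c("1", "5"), c("1", "10")),
  list(c("3", "4"), c("3", "13"), c("3", "14"), c("3", "15"), c("3", "16")),
  list(c("4", "5"), c("4", "11")),
  list(c("5", "12"), c("5", "14"), c("5", "16"), c("5", "13"), c("5", "15")),
  list(c("6", "13"), c("6", "14"), c("6", "15"), c("6", "16")),
  list(c("7", "7")),   # the one double-bond rule
  list(c("8", "9"), c("8", "10"), c("8", "13"), c("8", "14"), c("8", "15"), c("8", "16")),
  list(c("9", "13"), c("9", "14"), c("9", "15"), c("9", "16")),
  list(c("10", "13"), c("10", "14"), c("10", "15"), c("10", "16")),
  list(c("11", "13"), c("11", "14"), c("11", "15"), c("11", "16")),
  list(c("13", "14"), c("13", "15"), c("13", "16")),
  list(c("14", "14"), c("14", "15"), c("14", "16")),
  list(c("15", "16")),
  list(c("16", "16"))
)

#' Find BRICS-cleavable bonds
#'
#' @param mol An `rvmol` (a sanitized query molecule, no dummies).
#' @return A data.frame with one row per cleavable bond: bond index, the two
#'   atoms, and the environment labels each side receives on cleavage.
#' @export
brics_bonds <- function(mol) {
  out <- data.frame(bond = integer(0), a1 = integer(0), a2 = integer(0),
                    l1 = character(0), l2 = character(0))
  if (nrow(mol$bonds) == 0) return(out)
  env <- .brics_env_table(mol)
  rb <- ring_bond_flags(mol)
  claimed <- logical(nrow(mol$bonds))
  for (grp in .brics_rules) {
    for (rule in grp) {
      i1 <- rule[1]; i2 <- rule[2]
      want_ord <- if (i1 == "7") BOND_DOUBLE else BOND_SINGLE
      for (k in seq_len(nrow(mol$bonds))) {
        if (claimed[k] || rb[k] || mol$bonds[k, "order"] != want_ord) next
        a <- mol$bonds[k, "a1"]; b <- mol$bonds[k, "a2"]
        if (env[[i1]][a] && env[[i2]][b]) {
          claimed[k] <- TRUE
          out <- rbind(out, data.frame(bond = k, a1 = a, a2 = b, l1 = i1, l2 = i2))
        } else if (env[[i1]][b] && env[[i2]][a]) {
          claimed[k] <- TRUE
          out <- rbind(out, data.frame(bond = k, a1 = b, a2 = a, l1 = i1, l2 = i2))
        }
      }
    }
  }
  out
}

# Wrap an rvmol as a fragment record.
new_fragment <- function(mol) {
  structure(list(
    structure = mol,
    smiles = canonical_smiles(mol),
    n_connections = sum(is_dummy(mol)),
    n_heavy = heavy_atom_count(mol)
  ), class = "rv_fragment")
}

#' @export
print.rv_fragment <- function(x, ...) {
  cat(sprintf("fragment: %s (%d heavy, %d connection%s)\n", x$smiles,
              x$n_heavy, x$n_connections, if (x$n_connections == 1) "" else "s"))
  invisible(x)
}

# Replace bond k of mol by two labelled dummy caps (l1 on the a1 side; a1/a2
# are passed explicitly because the environment orientation may be flipped
# relative to the bond-matrix row).
.cut_bond <- function(mol, k, a1, a2, l1, l2) {
  cut_ord <- mol$bonds[k, "order"]
  mol$bonds <- mol$bonds[-k, , drop = FALSE]
  if (cut_ord == BOND_DOUBLE) {
    # the dummy cap is a single bond; the freed valence becomes a hydrogen
    mol$nH[a1] <- mol$nH[a1] + 1L
    mol$nH[a2] <- mol$nH[a2] + 1L
  }
  for (side in 1:2) {
    at <- if (side == 1) a1 else a2
    lab <- as.integer(if (side == 1) l1 else l2)
    mol$elem <- c(mol$elem, "*"); mol$arom <- c(mol$arom, FALSE)
    mol$charge <- c(mol$charge, 0L); mol$nH <- c(mol$nH, 0L)
    mol$iso <- c(mol$iso, lab)
    mol$bonds <- rbind(mol$bonds, c(at, length(mol$elem), BOND_SINGLE))
  }
  attr(mol, "cansmi") <- NULL
  mol
}

#' BRICS fragmentation of a query molecule
#'
#' Recursive decomposition: in each fragment the first BRICS-cleavable bond
#' whose cleavage leaves at least `min_fragment_size` heavy atoms (dummies
#' excluded) on both sides is cut and capped with labelled dummies, and both
#' pieces are decomposed further; fragments with no allowed cut are the
#' returned leaves. With `min_fragment_size = 1` this cuts every cleavable
#' bond; larger values keep small linkers (carbonyls, single heteroatoms)
#' attached to their neighbours, which is what makes leaf fragments resemble
#' purchasable building blocks. Raises a condition of class
#' `rvdesign_fragmentation_failure` when no bond is cleavable — the observed
#' failure mode for queries whose only breakable bonds (e.g. single bonds
#' between aromatic and aliphatic rings) have no BRICS rule.
#'
#' @param query An `rvmol`.
#' @param min_fragment_size Minimum heavy-atom count per cleavage side
#'   (default 3).
#' @return List of `rv_fragment`.
#' @export
brics_fragment <- function(query, min_fragment_size = 3L) {
  queue <- list(query)
  leaves <- list()
  any_cut <- FALSE
  while (length(queue) > 0) {
    mol <- queue[[1]]; queue <- queue[-1]
    bb <- brics_bonds(mol)
    cut_done <- FALSE
    for (i in seq_len(nrow(bb))) {
      m2 <- mol
      m2$bonds <- m2$bonds[-bb$bond[i], , drop = FALSE]
      comp <- component_membership(m2)
      sizes <- c(sum(comp == comp[bb$a1[i]] & m2$elem != "*"),
                 sum(comp == comp[bb$a2[i]] & m2$elem != "*"))
      if (min(sizes) < min_fragment_size) next
      pieces <- mol_components(.cut_bond(mol, bb$bond[i], bb$a1[i], bb$a2[i],
                                         bb$l1[i], bb$l2[i]))
      queue <- c(queue, pieces)
      cut_done <- TRUE
      any_cut <- TRUE
      break
    }
    if (!cut_done) leaves[[length(leaves) + 1L]] <- mol
  }
  if (!any_cut) fragmentation_failure("no BRICS-cleavable bond")
  lapply(leaves, new_fragment)
}

#' Filter key fragments by size
#'
#' Retains fragments whose heavy-atom count plus connection count reaches
#' `min_key_frag_size`; fragments below the threshold are too small to drive
#' a design iteration. Raises a fragmentation failure if nothing survives.
#'
#' @param fragments List of `rv_fragment`.
#' @param min_key_frag_size Integer threshold on `n_heavy + n_connections`.
#' @return Filtered list.
#' @export
filter_key_fragments <- function(fragments, min_key_frag_size = 4L) {
  keep <- vapply(fragments, function(f)
    f$n_heavy + f$n_connections >= min_key_frag_size, logical(1))
  out <- fragments[keep]
  if (length(out) == 0) fragmentation_failure("all fragments below minKeyFragSize")
  out
}

#' Assign scaffold and substituent roles
#'
#' Fragments are sorted by descending connection count, then descending
#' heavy-atom count, then canonical SMILES; the head of the ranking is the
#' scaffold that seeds the inside-out design, the rest are substituents in
#' ranked order.
#'
#' @param fragments Non-empty list of `rv_fragment`.
#' @return A `fragment_set` with elements `scaffold`, `substituents`.
#' @export
assign_roles <- function(fragments) {
  if (length(fragments) == 0) stop("no fragments to rank")
  conn <- vapply(fragments, `[[`, numeric(1), "n_connections")
  heavy <- vapply(fragments, `[[`, numeric(1), "n_heavy")
  smi <- vapply(fragments, `[[`, character(1), "smiles")
  ord <- order(-conn, -heavy, smi)
  fragments <- fragments[ord]
  structure(list(scaffold = fragments[[1]],
                 substituents = fragments[-1]),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set\n  scaffold:    ", x$scaffold$smiles, "\n")
  for (s in x$substituents) cat("  substituent: ", s$smiles, "\n")
  invisible(x)
}
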