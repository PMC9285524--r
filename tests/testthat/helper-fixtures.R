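# Shared fixture universe, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_universe <- function() {
  if (is.null(.fixture_env$u)) {
    fx <- generate_fixture(fixture_spec())
    corpus <- lapply(fx$reactions, parse_reaction)
    db <- build_rv_database(corpus)
    mols <- lapply(fx$catalogue$smiles, curate_molecule)
    names(mols) <- fx$catalogue$id
    cat_ <- catalogue_from_molecules(mols)
    .fixture_env$u <- list(fx = fx, corpus = corpus, db = db, catalogue = cat_,
                           config = design_config())
  }
  .fixture_env$u
}

# Independent brute-force atom-pair counter: enumerates bonds and all
# 3-atom simple paths directly over an adjacency matrix, assembling keys
# with its own (reversed-orientation) canonicalization.
brute_force_atom_pairs <- function(mol) {
  n <- length(mol$elem)
  ty <- vapply(seq_len(n), function(a) rvdesign::atom_type(mol, a), character(1))
  bsym <- c("1", "2", "3", "a")
  keys <- character(0)
  nb <- nrow(mol$bonds)
  if (nb == 0) return(table(character(0)))
  adj <- matrix(0, n, n)
  for (k in seq_len(nb)) {
    i <- mol$bonds[k, "a1"]; j <- mol$bonds[k, "a2"]
    adj[i, j] <- mol$bonds[k, "order"]; adj[j, i] <- mol$bonds[k, "order"]
    f <- paste(ty[i], bsym[mol$bonds[k, "order"]], ty[j], sep = "|")
    r <- paste(ty[j], bsym[mol$bonds[k, "order"]], ty[i], sep = "|")
    keys <- c(keys, min(f, r))
  }
  for (c in seq_len(n)) {
    nbrs <- which(adj[c, ] > 0)
    if (length(nbrs) < 2) next
    cmb <- utils::combn(nbrs, 2)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1, q]; k <- cmb[2, q]
      f <- paste(ty[i], bsym[adj[i, c]], ty[c], bsym[adj[c, k]], ty[k], sep = "|")
      r <- paste(ty[k], bsym[adj[c, k]], ty[c], bsym[adj[i, c]], ty[i], sep = "|")
      keys <- c(keys, min(f, r))
    }
  }
  table(keys)
}

expect_same_vector <- function(dv, tab) {
  got <- dv[order(names(dv))]
  want <- as.integer(tab)[order(names(tab))]
  names(want) <- sort(names(tab))
  expect_identical(unname(got), unname(want))
  expect_identical(names(got), names(want))
}

# a pool of diverse fragmentable molecules for property tests
property_molecules <- function(n = 50) {
  u <- fixture_universe()
  smis <- unique(c(u$fx$queries$smiles, u$fx$catalogue$smiles))
  smis[seq_len(min(n, length(smis)))]
}

drug_file <- function() {
  system.file("extdata", "validation_drugs_synthetic.smi", package = "rvdesign")
}
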