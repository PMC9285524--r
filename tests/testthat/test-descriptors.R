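test_that("atom typing is forced by element, charge, aromaticity and H count", {
  m <- mol_from_smiles("C")            # methane
  expect_equal(atom_type(m, 1), "C0.4")
  b <- mol_from_smiles("c1ccccc1")
  expect_equal(atom_type(b, 1), "C0a1")
  amm <- mol_from_smiles("C[NH3+]")
  expect_equal(atom_type(amm, which(amm$elem == "N")), "N+1.3")
})

test_that("atom pair counts match hand enumeration on tiny molecules", {
  expect_length(compute_atom_pairs(mol_from_smiles("C")), 0)
  eth <- compute_atom_pairs(mol_from_smiles("CC"))
  expect_identical(eth, structure(1L, names = "C0.3|1|C0.3"))
  pro <- compute_atom_pairs(mol_from_smiles("CCC"))
  # 2 bonds (AP2 total 2) and exactly one 3-atom path
  expect_equal(sum(pro[rvdesign:::.is_ap2_key(names(pro))]), 2)
  expect_equal(sum(pro[!rvdesign:::.is_ap2_key(names(pro))]), 1)
  expect_equal(unname(pro["C0.3|1|C0.2|1|C0.3"]), 1L)
})

test_that("atom pair vectors equal brute-force path enumeration", {
  for (smi in property_molecules(50)) {
    mol <- mol_from_smiles(smi)
    expect_same_vector(compute_atom_pairs(mol), brute_force_atom_pairs(mol))
  }
})

test_that("path-count conservation holds", {
  for (smi in property_molecules(25)) {
    mol <- mol_from_smiles(smi)
    dv <- compute_atom_pairs(mol)
    ap2 <- rvdesign:::.is_ap2_key(names(dv))
    deg <- rvdesign:::atom_degrees(mol)
    expect_equal(sum(dv[ap2]), nrow(mol$bonds))
    expect_equal(sum(dv[!ap2]), sum(deg * (deg - 1) / 2))
  }
})

test_that("atom pair keys canonicalize: path and reverse give one key", {
  expect_identical(rvdesign:::ap2_key("C0.3", "1", "O0.1"),
                   rvdesign:::ap2_key("O0.1", "1", "C0.3"))
  expect_identical(rvdesign:::ap3_key("C0.3", "1", "C0.2", "2", "O0.0"),
                   rvdesign:::ap3_key("O0.0", "2", "C0.2", "1", "C0.3"))
})

test_that("sparse vector arithmetic forms an abelian group", {
  set.seed(7)
  mols <- lapply(property_molecules(10), mol_from_smiles)
  vs <- lapply(mols, compute_atom_pairs)
  zero <- integer(0)
  for (i in seq_along(vs)) {
    v <- vs[[i]]
    expect_identical(vector_add(v, zero), v[order(names(v))])
    expect_length(vector_add(v, rvdesign:::vector_negate(v)), 0)
    j <- (i %% length(vs)) + 1
    ab <- vector_add(v, vs[[j]])
    ba <- vector_add(vs[[j]], v)
    expect_identical(ab, ba)
  }
  expect_identical(vector_add(c(k = 2L), c(k = -1L)), c(k = 1L))
})

test_that("vector serialization round trips", {
  v <- vector_add(compute_atom_pairs(mol_from_smiles("CC(=O)OCC")),
                  rvdesign:::vector_negate(compute_atom_pairs(mol_from_smiles("CCO"))))
  s <- rvdesign:::serialize_vector(v)
  expect_identical(rvdesign:::deserialize_vector(s), v[order(names(v))])
})

test_that("fingerprints are deterministic with self-similarity one", {
  spec_b <- fingerprint_spec("binary")
  spec_c <- fingerprint_spec("count")
  m <- mol_from_smiles("Cc1ccc(cc1)S(N)(=O)=O")
  expect_identical(fingerprint(m, spec_b), fingerprint(m, spec_b))
  expect_equal(tanimoto(fingerprint(m, spec_b), fingerprint(m, spec_b)), 1)
  expect_equal(euclidean_distance(fingerprint(m, spec_c), fingerprint(m, spec_c)), 0)
  expect_length(fingerprint(m, spec_b), 1024)
})

test_that("tanimoto and euclidean obey their contracts", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 1), c(1, 1)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)   # degenerate: defined as match
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)))
  expect_equal(euclidean_distance(c(0, 3), c(4, 0)), 5)
  expect_error(euclidean_distance(1, c(1, 2)))
  # symmetry and triangle inequality on random count fingerprints
  spec <- fingerprint_spec("count", n_bits = 64)
  mols <- lapply(property_molecules(9), mol_from_smiles)
  fps <- lapply(mols, fingerprint, spec = spec)
  for (i in 1:3) {
    a <- fps[[i]]; b <- fps[[i + 3]]; c <- fps[[i + 6]]
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(euclidean_distance(a, c),
               euclidean_distance(a, b) + euclidean_distance(b, c) + 1e-12)
  }
})
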