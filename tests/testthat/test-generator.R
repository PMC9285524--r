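ester_rv <- function() {
  compute_reaction_vector(parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O\tFIX\tester"))
}

test_that("null transform returns the starting material unchanged", {
  m <- mol_from_smiles("CCO")
  rv0 <- compute_reaction_vector(parse_reaction("CCO>>CCO"))
  res <- apply_rv(m, NULL, rv0)
  expect_length(res$products, 1)
  expect_identical(res$products[[1]]$smiles, canonical_smiles(m))
})

test_that("inapplicable reaction vectors yield an empty result", {
  rv <- ester_rv()
  res <- apply_rv(mol_from_smiles("c1ccccc1"), mol_from_smiles("CC"), rv)
  expect_length(res$products, 0)
})

test_that("esterification closes on its own reactants", {
  rv <- ester_rv()
  res <- apply_rv(mol_from_smiles("CC(=O)O"), mol_from_smiles("CCO"), rv)
  smis <- vapply(res$products, `[[`, "", "smiles")
  expect_true(canonical_smiles("CC(=O)OCC") %in% smis)
  # byproduct water is tracked
  hit <- res$products[[match(canonical_smiles("CC(=O)OCC"), smis)]]
  expect_equal(vapply(hit$byproducts, canonical_smiles, character(1)), "O")
})

test_that("verify_product accepts the recorded outcome and rejects perturbations", {
  rec <- parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O")
  rv <- compute_reaction_vector(rec)
  expect_true(verify_product(rec$products[[1]], rec$products[2],
                             rec$reactants, rv))
  # water has no heavy-atom bond, so it is invisible in atom-pair space:
  # strict conservation cannot (and does not) flag its absence
  expect_true(verify_product(rec$products[[1]], list(), rec$reactants, rv))
  # a bonded byproduct, in contrast, is required: dropping the boron residue
  # of a biaryl coupling breaks conservation
  suz <- parse_reaction("Brc1ccccc1.OB(O)c1ccccc1>>c1ccccc1c1ccccc1.Br.OBO")
  rv_s <- compute_reaction_vector(suz)
  expect_true(verify_product(suz$products[[1]], suz$products[2:3],
                             suz$reactants, rv_s))
  expect_false(verify_product(suz$products[[1]], suz$products[2],
                              suz$reactants, rv_s))
  # a product with one extra bond is rejected
  p <- rec$products[[1]]
  mutated <- NULL
  for (i in seq_along(p$elem)) {
    for (j in seq_along(p$elem)) {
      if (i < j) mutated <- rvdesign:::add_bond(p, i, j, 1)
      if (!is.null(mutated)) break
    }
    if (!is.null(mutated)) break
  }
  expect_false(is.null(mutated))
  expect_false(verify_product(mutated, rec$products[2], rec$reactants, rv))
})

test_that("every corpus reaction self-reproduces through the generator", {
  u <- fixture_universe()
  n_ok <- 0
  for (rec in u$corpus) {
    rv <- compute_reaction_vector(rec)
    res <- apply_rv(rec$reactants[[1]], rec$reactants[[2]], rv)
    smis <- vapply(res$products, `[[`, "", "smiles")
    want <- canonical_smiles(rec$products[[1]])
    if (want %in% smis) n_ok <- n_ok + 1
    # conservation re-asserted on every emitted product
    for (p in res$products) {
      expect_true(verify_product(p$product, p$byproducts, rec$reactants, rv))
    }
  }
  expect_equal(n_ok, length(u$corpus))
})

test_that("generation is deterministic and bounded", {
  rv <- ester_rv()
  sm <- mol_from_smiles("CC(=O)O"); rg <- mol_from_smiles("CCO")
  r1 <- apply_rv(sm, rg, rv)
  r2 <- apply_rv(sm, rg, rv)
  expect_identical(vapply(r1$products, `[[`, "", "smiles"),
                   vapply(r2$products, `[[`, "", "smiles"))

  lim <- generator_limits(max_bond_edits = 4, max_candidates_per_rv = 1)
  suppressWarnings(r3 <- apply_rv(sm, rg, rv, lim))
  expect_lte(length(r3$products), 1)
})

test_that("a supplied reagent must end up in the product", {
  # the null transform leaves the SM untouched; with a reagent present that
  # outcome contains no reagent atom and must be culled
  rv0 <- compute_reaction_vector(parse_reaction("CCO>>CCO"))
  res <- apply_rv(mol_from_smiles("CCO"), mol_from_smiles("CC"), rv0)
  expect_length(res$products, 0)
})
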