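test_that("fixture generation is deterministic for a fixed seed", {
  a <- generate_fixture(fixture_spec(seed = 5))
  b <- generate_fixture(fixture_spec(seed = 5))
  expect_identical(a, b)
  d <- generate_fixture(fixture_spec(seed = 6))
  expect_false(identical(a$reactions, d$reactions))   # order differs
  expect_setequal(a$reactions, d$reactions)           # content does not
})

test_that("fixture files are written in pipeline-readable formats", {
  dir <- tempfile(); dir.create(dir)
  fx <- generate_fixture(fixture_spec(), dir)
  expect_true(all(file.exists(file.path(dir, c("reactions.rsmi", "catalogue.smi",
                                               "queries.smi", "ground_truth.csv")))))
  cat_ <- load_catalogue(file.path(dir, "catalogue.smi"))
  expect_equal(length(cat_), nrow(fx$catalogue))
  corpus <- read_reaction_corpus(file.path(dir, "reactions.rsmi"))
  expect_length(corpus, length(fx$reactions))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_identical(gt$id, fx$queries$id)
})

test_that("every query records a ground-truth route of the stated length", {
  u <- fixture_universe()
  for (i in seq_len(nrow(u$fx$queries))) {
    steps <- strsplit(u$fx$queries$steps[i], " | ", fixed = TRUE)[[1]]
    expect_length(steps, u$fx$queries$route_length[i])
    # each step parses as a reaction and the last step's product is the query
    recs <- lapply(steps, parse_reaction)
    last <- recs[[length(recs)]]
    expect_identical(canonical_smiles(last$products[[1]]),
                     canonical_smiles(u$fx$queries$smiles[i]))
  }
})

test_that("ring counting matches hand-checked values", {
  cases <- list(
    list("c1ccccc1", 1, 1), list("Cc1ccccc1", 1, 1),
    list("c1ccc2ccccc2c1", 2, 2),                 # naphthalene: 2 fused
    list("c1ccc2cc3ccccc3cc2c1", 3, 3),           # anthracene
    list("c1ccccc1c1ccccc1", 2, 1),               # biphenyl: no fusion
    list("C1CCC2CCCCC2C1", 2, 2),                 # decalin
    list("C1CCC2(CC1)CCCCC2", 2, 2),              # spiro counts as one system
    list("C1CC12CC2", 2, 2),
    list("CC12CC3CC(C)(C1)CC(N)(C3)C2", 3, 3),    # adamantane cage
    list("c1ccc2[nH]ccc2c1", 2, 2),               # indole
    list("C1CCNC1", 1, 1), list("C1COCCN1", 1, 1),
    list("Cn1c(=O)c2[nH]cnc2n(C)c1=O", 2, 2),     # theophylline
    list("c1ccc2ncccc2c1", 2, 2),                 # quinoline
    list("C1CC2CCC1C2", 2, 2),                    # norbornane
    list("CCO", 0, 0), list("CC(=O)O", 0, 0),
    list("C1CCCCC1C1CCCCC1", 2, 1),
    list("c1ccc(cc1)Cc1ccccc1", 2, 1),
    list("c1ccc2c(c1)ccc1ccccc12", 3, 3)          # phenanthrene
  )
  for (cs in cases) {
    mol <- mol_from_smiles(cs[[1]])
    expect_equal(count_rings(mol), cs[[2]], info = cs[[1]])
    expect_equal(count_fused_rings(mol), cs[[3]], info = cs[[1]])
  }
})

test_that("Lipinski violations match hand-checked values", {
  # triacontane: logP far above 5, everything else fine
  expect_equal(lipinski_violations(mol_from_smiles(
    paste(rep("C", 30), collapse = ""))), 1)
  # sorbitol: six H-bond donors, tiny and hydrophilic
  expect_equal(lipinski_violations(mol_from_smiles("OCC(O)C(O)C(O)C(O)CO")), 1)
  expect_equal(lipinski_violations(mol_from_smiles("CC(=O)Oc1ccccc1C(=O)O")), 0)
  expect_equal(lipinski_violations(mol_from_smiles("CCO")), 0)
  # donor/acceptor counts are recomputed independently here
  m <- mol_from_smiles("NC(=O)c1ccc(O)cc1")
  hbd <- sum(m$nH[m$elem %in% c("N", "O")])
  hba <- sum(m$elem %in% c("N", "O"))
  expect_equal(hbd, 3); expect_equal(hba, 3)
  expect_equal(lipinski_violations(m), 0)
})

test_that("validation-set preparation applies filters then greedy diversity", {
  mols <- list(
    small = curate_molecule("CCO"),                       # < 20 atoms
    acyclic = curate_molecule("CCCCCCCCCCCCCCCCCCCC"),    # 0 rings
    steroidish = curate_molecule("C1CCC2(C1)CCC1C2CCC2(C)C1CCC2"), # 4 fused
    keep1 = curate_molecule("Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1"),
    dup_of_keep1 = curate_molecule("Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1"),
    keep2 = curate_molecule("COc1ccc2cc(C(C)C(=O)O)ccc2c1CCCC")
  )
  kept <- prepare_validation_set(mols)
  expect_identical(names(kept), c("keep1", "keep2"))
  # identical pair: similarity 1 >= 0.6, first wins
  expect_false("dup_of_keep1" %in% names(kept))
})

test_that("every corpus reaction passes the generator closure property", {
  # (the full corpus sweep lives in the generator tests; spot-check here that
  # fixture reactions parse into two reactants and a main product)
  u <- fixture_universe()
  expect_gte(length(u$corpus), 25)
  for (rec in u$corpus[1:10]) {
    expect_length(rec$reactants, 2)
    expect_gte(length(rec$products), 1)
  }
})
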