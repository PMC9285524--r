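test_that("size filter treats the boundary as kept", {
  q20 <- mol_from_smiles(paste(rep("C", 20), collapse = ""))
  p25 <- mol_from_smiles(paste(rep("C", 25), collapse = ""))
  p26 <- mol_from_smiles(paste(rep("C", 26), collapse = ""))
  expect_true(size_filter(p25, q20, 0.25))    # 25 = 20 * 1.25: not exceeding
  expect_false(size_filter(p26, q20, 0.25))
  expect_true(size_filter(q20, q20, 0))
})

make_cands <- function(smis) {
  lapply(smis, function(s) {
    m <- curate_molecule(s)
    rvdesign:::new_candidate(m, canonical_smiles(m), NA_real_, list(list()), 1L)
  })
}

test_that("active selection equals a brute-force sort with size filtering", {
  u <- fixture_universe()
  query <- curate_molecule(u$fx$queries$smiles[1])
  pool <- make_cands(c(u$fx$catalogue$smiles[1:15], u$fx$queries$smiles[1]))
  cfg <- u$config
  sel <- active_select(pool, query, 5, cfg)
  expect_lte(length(sel), 5)
  # the query itself ranks first at distance zero
  expect_identical(sel[[1]]$smiles, canonical_smiles(query))
  expect_equal(sel[[1]]$score, 0)
  # oracle: euclidean distance of count fingerprints, ascending, smiles ties
  qfp <- fingerprint(query, cfg$scoring_fp)
  keep <- Filter(function(p)
    size_filter(p$mol, query, cfg$query_heavy_atoms_add_threshold), pool)
  d <- vapply(keep, function(p)
    euclidean_distance(fingerprint(p$mol, cfg$scoring_fp), qfp), numeric(1))
  smi <- vapply(keep, `[[`, "", "smiles")
  oracle <- smi[order(d, smi)][1:5]
  expect_identical(vapply(sel, `[[`, "", "smiles"), oracle)
  # n larger than the pool returns all survivors
  expect_length(active_select(pool, query, 999, cfg), length(keep))
  # everything filtered -> empty selection
  big <- make_cands(paste(rep("C", 60), collapse = ""))
  expect_length(active_select(big, query, 3, cfg), 0)
})

test_that("passive ranking deduplicates and is monotone in score", {
  u <- fixture_universe()
  query <- curate_molecule(u$fx$queries$smiles[1])
  pool <- make_cands(c(u$fx$catalogue$smiles[1:10],
                       u$fx$catalogue$smiles[1:5],   # duplicates via second route
                       u$fx$queries$smiles[1]))
  ranked <- passive_rank(pool, query, 100, u$config)
  smis <- vapply(ranked, `[[`, "", "smiles")
  expect_identical(smis, unique(smis))
  expect_identical(ranked[[1]]$smiles, canonical_smiles(query))
  scores <- vapply(ranked, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) >= 0))
  expect_length(passive_rank(list(), query, 10, u$config), 0)
  expect_length(passive_rank(pool, query, 3, u$config), 3)
})

test_that("a one-step query with its true precursors is recovered exactly", {
  # minimal universe: the two real precursors and the one true reaction
  rec <- "Cc1ccc(cc1)C(=O)O.NCc1ccccc1>>Cc1ccc(cc1)C(=O)NCc1ccccc1.O"
  db <- build_rv_database(list(parse_reaction(rec)))
  mols <- list(acid = curate_molecule("Cc1ccc(cc1)C(=O)O"),
               amine = curate_molecule("NCc1ccccc1"))
  cat_ <- catalogue_from_molecules(mols)
  query <- "Cc1ccc(cc1)C(=O)NCc1ccccc1"
  res <- suppressWarnings(run_design(query, cat_, db, design_config()))
  expect_gt(length(res), 0)
  expect_identical(res[[1]]$smiles, canonical_smiles(query))
  expect_equal(res[[1]]$score, 0)
  expect_length(res[[1]]$route, 1)
  expect_true(replay_route(res[[1]], db))
})

test_that("an empty reaction-vector database yields no candidates", {
  u <- fixture_universe()
  empty_db <- structure(list(entries = list()), class = "rv_database")
  res <- suppressWarnings(run_design(u$fx$queries$smiles[1], u$catalogue,
                                     empty_db, u$config))
  expect_length(res, 0)
})

test_that("cycle count equals the number of substituents", {
  u <- fixture_universe()
  query <- curate_molecule(u$fx$queries$smiles[1])
  roles <- assign_roles(filter_key_fragments(
    brics_fragment(query, u$config$min_fragment_size), u$config$min_key_frag_size))
  res <- suppressWarnings(run_design(query, u$catalogue, u$db, u$config))
  rep <- attr(res, "run_report")
  expect_equal(nrow(rep), length(roles$substituents))
  expect_true(all(vapply(res, function(x) x$cycle, integer(1)) <=
                    length(roles$substituents)))
})

test_that("fragmentation failure propagates from the design entry point", {
  u <- fixture_universe()
  expect_error(run_design("C1CCCCC1", u$catalogue, u$db, u$config),
               class = "rvdesign_fragmentation_failure")
})
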