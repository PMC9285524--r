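test_that("reaction SMILES parsing follows the curation contract", {
  r <- parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O")
  expect_length(r$reactants, 2)
  expect_length(r$products, 2)

  r2 <- parse_reaction("CCO>[H+]>CCO")
  expect_length(r2$reactants, 1)
  expect_length(r2$products, 1)

  expect_error(parse_reaction(">>CCO"), class = "rvdesign_parse_error")
  expect_error(parse_reaction("CCO>>"), class = "rvdesign_parse_error")
  expect_error(parse_reaction("CC(.CC>>C"), class = "rvdesign_parse_error")

  r3 <- parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O\tUSPD-1\tUS123")
  expect_equal(r3$source_id, "USPD-1")
  expect_equal(r3$reference, "US123")
})

test_that("corpus reading skips malformed lines with a warning", {
  f <- tempfile(fileext = ".rsmi")
  writeLines(c("CCO.CC(=O)O>>CC(=O)OCC.O", "not_a_reaction", ">>C"), f)
  warns <- capture_warnings(corpus <- read_reaction_corpus(f))
  expect_length(warns, 2)
  expect_match(warns, "skipping", all = TRUE)
  expect_length(corpus, 1)
})

test_that("reaction vector is product-minus-reactant, order-free", {
  rv <- compute_reaction_vector(parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O"))
  # identity reaction gives the null transform
  rv0 <- compute_reaction_vector(parse_reaction("CCO>>CCO"))
  expect_true(rvdesign:::is_null_transform(rv0))
  expect_false(rvdesign:::is_null_transform(rv))
  # permuting reactant/product order changes nothing
  rv_perm <- compute_reaction_vector(parse_reaction("CC(=O)O.CCO>>O.CC(=O)OCC"))
  expect_identical(rv$vector, rv_perm$vector)
  # hand-enumerated esterification entries: the acid C-OH and the ethanol
  # C-OH pairs are consumed; the ester C-O pairs are created
  expect_equal(unname(rv$vector["C0.2|1|O0.1"]), -1L)
  expect_equal(unname(rv$vector["C0.0|1|O0.1"]), -1L)
  expect_equal(unname(rv$vector["C0.2|1|O0.0"]), 1L)
  expect_equal(unname(rv$vector["C0.0|1|O0.0"]), 1L)
  expect_true(any(rv$vector < 0) && any(rv$vector > 0))
})

test_that("per-record sign balance holds on the whole fixture corpus", {
  u <- fixture_universe()
  for (rec in u$corpus) {
    rv <- compute_reaction_vector(rec)
    lhs <- rvdesign:::sum_vectors(rec$products)
    rhs <- vector_add(rvdesign:::sum_vectors(rec$reactants), rv$vector)
    expect_identical(rvdesign:::serialize_vector(lhs),
                     rvdesign:::serialize_vector(rhs))
  }
})

test_that("database construction deduplicates and discards null transforms", {
  twice <- lapply(c("CCO.CC(=O)O>>CC(=O)OCC.O\tA\tr1",
                    "CCO.CC(=O)O>>CC(=O)OCC.O\tB\tr2"), parse_reaction)
  db <- build_rv_database(twice)
  expect_length(db, 1)
  expect_length(db$entries[[1]]$sources, 2)

  expect_warning(db0 <- build_rv_database(list(parse_reaction("CCO>>CCO"))),
                 "empty")
  expect_length(db0, 0)

  u <- fixture_universe()
  expect_gt(length(u$db), 4)
  # determinism: a shuffled corpus yields a serialization-identical database
  f1 <- tempfile(); f2 <- tempfile()
  write_rv_database(u$db, f1)
  set.seed(42)
  write_rv_database(build_rv_database(sample(u$corpus)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("RV database text format round trips losslessly", {
  u <- fixture_universe()
  f <- tempfile()
  write_rv_database(u$db, f)
  db2 <- read_rv_database(f)
  expect_identical(names(db2$entries), names(u$db$entries))
  for (k in names(u$db$entries)) {
    expect_identical(db2$entries[[k]]$vector, u$db$entries[[k]]$vector)
    expect_equal(db2$entries[[k]]$n_reactants, u$db$entries[[k]]$n_reactants)
    expect_identical(db2$entries[[k]]$sources, u$db$entries[[k]]$sources)
  }
})

test_that("applicability respects negative-pair multiplicity", {
  rv_pos <- structure(list(vector = c(k = 2L), n_reactants = 1L,
                           sources = list(c(source_id = "x", reference = ""))),
                      class = "reaction_vector")
  expect_true(is_applicable(rv_pos, structure(integer(0), names = character(0))))

  rv_need2 <- rv_pos; rv_need2$vector <- c(k = -2L)
  expect_false(is_applicable(rv_need2, c(k = 1L)))
  expect_true(is_applicable(rv_need2, c(k = 2L)))

  # self-consistency across the corpus: every RV applies to its own reactants
  u <- fixture_universe()
  for (rec in u$corpus) {
    rv <- compute_reaction_vector(rec)
    ens <- rvdesign:::sum_vectors(rec$reactants)
    expect_true(is_applicable(rv, ens))
  }
})
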