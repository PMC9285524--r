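# Synthetic test universe: toy reaction corpora, matched building-block
# catalogues, and constructible queries with known ground-truth routes, plus
# the validation-set preparation filters used to curate drug reference sets.
#
# Product SMILES are composed from string templates (never through the
# package's own generator) so the emitted corpus is independent ground truth
# for generator tests. Reaction vectors carry AP3 context, so they only
# transfer between reactant pairs with matching local environments; each
# reagent pool below is therefore a single context class (para-substituted
# aryl electrophiles, benzylic primary amines, cyclic secondary amines,
# primary alcohols with a beta-CH2, aryl boronic acids), and corpus
# reactions and query precursors are drawn from the same classes.

.aryl_subs <- c("", "C", "F", "OC", "CC", "Cl")
.aryl_prefix_map <- c("", "C", "F", "CO", "CC", "Cl")

# para-substituted phenyl written before an attached group: "<sub>c1ccc(cc1)X"
.ar_pre <- function(sub, digit = 1) {
  i <- match(sub, .aryl_subs)
  p <- .aryl_prefix_map[i]
  if (sub == "") sprintf("c%dccccc%d", digit, digit)
  else sprintf("%sc%dccc(cc%d)", p, digit, digit)
}
# para-substituted phenyl written after an attachment: "Xc2ccc(<sub>)cc2"
.ar_suf <- function(sub, digit = 2) {
  if (sub == "") sprintf("c%dccccc%d", digit, digit)
  else sprintf("c%dccc(%s)cc%d", digit, sub, digit)
}

# nucleophile pools: full molecule + splice rendering at a given ring digit
.benzylic_amines <- function(subs) {
  lapply(subs, function(t) list(
    name = paste0("bnz_amine_", if (t == "") "H" else t),
    full = paste0("NC", .ar_suf(t, 1)),
    splice = function(d) paste0("NC", .ar_suf(t, d))))
}
.cyclic_amines <- function(n) {
  pool <- list(
    list(name = "piperidine", full = "C1CCNCC1",
         splice = function(d) sprintf("N%dCCCCC%d", d, d)),
    list(name = "pyrrolidine", full = "C1CCNC1",
         splice = function(d) sprintf("N%dCCCC%d", d, d)),
    list(name = "morpholine", full = "C1COCCN1",
         splice = function(d) sprintf("N%dCCOCC%d", d, d)),
    list(name = "4-Me-piperidine", full = "CC1CCNCC1",
         splice = function(d) sprintf("N%dCCC(C)CC%d", d, d)),
    list(name = "N-Me-piperazine", full = "CN1CCNCC1",
         splice = function(d) sprintf("N%dCCN(C)CC%d", d, d)),
    list(name = "azepane", full = "C1CCCNCC1",
         splice = function(d) sprintf("N%dCCCCCC%d", d, d)))
  pool[seq_len(min(n, length(pool)))]
}
.alcohols <- function(n) {
  tails <- list(
    list(name = "propan-1-ol", t = function(d) "C"),
    list(name = "butan-1-ol", t = function(d) "CC"),
    list(name = "pentan-1-ol", t = function(d) "CCC"),
    list(name = "2-phenylethanol", t = function(d) .ar_suf("", d)),
    list(name = "3-Me-butan-1-ol", t = function(d) "C(C)C"),
    list(name = "2-(4-tolyl)ethanol", t = function(d) .ar_suf("C", d)))
  lapply(tails[seq_len(min(n, length(tails)))], function(x) list(
    name = x$name,
    full = paste0("OCC", x$t(1)),
    splice = function(d) paste0("OCC", x$t(d))))
}
.boronics <- function(subs) {
  lapply(subs, function(t) list(
    name = paste0("boronic_", if (t == "") "H" else t),
    full = paste0("OB(O)", .ar_suf(t, 1)),
    aryl = function(d) .ar_suf(t, d)))
}

#' Fixture specification
#'
#' @param families Which reaction families to generate. The default set
#'   covers condensations (amide, ester, sulfonamide), substitution (ether),
#'   a reduction (reductive amination) and a coupling (Suzuki biaryl).
#' @param n_reagents_per_family Pool size per reagent class (>= 2).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(families = c("amide", "ester", "sulfonamide",
                                      "ether", "reductive_amination", "suzuki"),
                         n_reagents_per_family = 6L, seed = 1L) {
  stopifnot(n_reagents_per_family >= 2)
  families <- match.arg(families, several.ok = TRUE)
  structure(list(families = families,
                 n_reagents_per_family = as.integer(n_reagents_per_family),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# one family-class block: electrophile pool, nucleophile pool, product and
# byproduct composers
.fixture_blocks <- function(spec) {
  n <- spec$n_reagents_per_family
  subs <- .aryl_subs[seq_len(min(n, length(.aryl_subs)))]
  bnz <- .benzylic_amines(subs)[seq_len(min(n, length(subs)))]
  cyc <- .cyclic_amines(n)
  alc <- .alcohols(n)
  bor <- .boronics(subs)
  acid <- lapply(subs, function(s) list(
    name = paste0("acid_", if (s == "") "H" else s),
    pre = .ar_pre(s), full = paste0(.ar_pre(s), "C(=O)O")))
  sulf <- lapply(subs, function(s) list(
    name = paste0("sulfonyl_", if (s == "") "H" else s),
    pre = .ar_pre(s), full = paste0(.ar_pre(s), "S(=O)(=O)Cl")))
  bzbr <- lapply(subs, function(s) list(
    name = paste0("benzylbromide_", if (s == "") "H" else s),
    pre = .ar_pre(s), full = paste0(.ar_pre(s), "CBr")))
  ald <- lapply(subs, function(s) list(
    name = paste0("aldehyde_", if (s == "") "H" else s),
    pre = .ar_pre(s), full = paste0(.ar_pre(s), "C=O")))
  arbr <- lapply(subs, function(s) list(
    name = paste0("arylbromide_", if (s == "") "H" else s),
    pre = .ar_pre(s), full = paste0(.ar_pre(s), "Br")))

  blocks <- list()
  addb <- function(family, e_pool, nu_pool, product, byproducts) {
    blocks[[length(blocks) + 1L]] <<- list(family = family, e = e_pool,
                                           nu = nu_pool, product = product,
                                           byproducts = byproducts)
  }
  if ("amide" %in% spec$families) {
    pf <- function(e, nu) paste0(e$pre, "C(=O)", nu$splice(2))
    addb("amide", acid, bnz, pf, "O")
    addb("amide", acid, cyc, pf, "O")
  }
  if ("ester" %in% spec$families) {
    addb("ester", acid, alc, function(e, nu) paste0(e$pre, "C(=O)", nu$splice(2)), "O")
  }
  if ("sulfonamide" %in% spec$families) {
    pf <- function(e, nu) paste0(e$pre, "S(=O)(=O)", nu$splice(2))
    addb("sulfonamide", sulf, bnz, pf, "Cl")
    addb("sulfonamide", sulf, cyc, pf, "Cl")
  }
  if ("ether" %in% spec$families) {
    addb("ether", bzbr, alc, function(e, nu) paste0(e$pre, "C", nu$splice(2)), "Br")
  }
  if ("reductive_amination" %in% spec$families) {
    pf <- function(e, nu) paste0(e$pre, "C", nu$splice(2))
    addb("reductive_amination", ald, bnz, pf, "O")
    addb("reductive_amination", ald, cyc, pf, "O")
  }
  if ("suzuki" %in% spec$families) {
    addb("suzuki", arbr, bor, function(e, nu) paste0(e$pre, nu$aryl(2)),
         c("Br", "OBO"))
  }
  blocks
}

#' Generate the synthetic fixture universe
#'
#' Emits a reaction corpus (reaction SMILES with provenance columns), a
#' matched building-block catalogue, and queries that are by construction
#' the products of 1-2 chained template reactions over catalogue members,
#' together with their ground-truth routes. Corpus reactions use shifted
#' reagent pairings and queries use aligned pairings from the same context
#' classes, so every query's true reaction vector is in the corpus but the
#' query's own reaction is not.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory: writes `reactions.rsmi`, `catalogue.smi`,
#'   `queries.smi` and `ground_truth.csv` there.
#' @return List with `reactions` (character lines), `catalogue` (data.frame
#'   id/smiles), `queries` (data.frame id/smiles/route_length/steps).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  blocks <- .fixture_blocks(spec)

  corpus <- character(0)
  cat_ids <- character(0); cat_smis <- character(0)
  note_block <- function(pool) {
    for (b in pool) {
      if (!(b$name %in% cat_ids)) {
        cat_ids <<- c(cat_ids, b$name); cat_smis <<- c(cat_smis, b$full)
      }
    }
  }
  qid <- character(0); qsmi <- character(0); qlen <- integer(0); qsteps <- character(0)

  bi <- 0L
  for (blk in blocks) {
    bi <- bi + 1L
    note_block(blk$e); note_block(blk$nu)
    ne <- length(blk$e); nn <- length(blk$nu)
    npairs <- min(ne, nn)
    # corpus: shifted pairings (i, i+1); queries: aligned pairings (i, i)
    for (i in seq_len(npairs)) {
      j <- (i %% nn) + 1L
      e <- blk$e[[i]]; nu <- blk$nu[[j]]
      prod <- blk$product(e, nu)
      rsmi <- paste0(e$full, ".", nu$full, ">>",
                     paste(c(prod, blk$byproducts), collapse = "."))
      corpus <- c(corpus, paste(rsmi, sprintf("FIX%02d-%02d", bi, i),
                                paste0(blk$family, " template"), sep = "\t"))
    }
    for (i in seq_len(min(2L, npairs))) {
      e <- blk$e[[i]]; nu <- blk$nu[[i]]
      prod <- blk$product(e, nu)
      rsmi <- paste0(e$full, ".", nu$full, ">>",
                     paste(c(prod, blk$byproducts), collapse = "."))
      qid <- c(qid, sprintf("Q_%s_%d_%s", blk$family, i,
                            sub("^.*_", "", e$name)))
      qsmi <- c(qsmi, prod)
      qlen <- c(qlen, 1L)
      qsteps <- c(qsteps, rsmi)
    }
  }

  # two-step queries: Suzuki coupling on 4-bromobenzoic acid, then amide
  if (all(c("suzuki", "amide") %in% vapply(blocks, `[[`, "", "family")) ||
      all(c("suzuki", "amide") %in% spec$families)) {
    bracid <- "Brc1ccc(cc1)C(=O)O"
    if (!("acid_Br" %in% cat_ids)) {
      cat_ids <- c(cat_ids, "acid_Br"); cat_smis <- c(cat_smis, bracid)
    }
    subs2 <- .aryl_subs[seq_len(min(spec$n_reagents_per_family, length(.aryl_subs)))]
    bor <- .boronics(subs2); bnz <- .benzylic_amines(subs2)
    for (i in 1:2) {
      t <- bor[[i]]; u <- bnz[[i + 1]]
      p1 <- paste0(.ar_pre(subs2[i], 2), "c1ccc(cc1)C(=O)O")
      p2 <- paste0(.ar_pre(subs2[i], 2), "c1ccc(cc1)C(=O)", u$splice(3))
      s1 <- paste0(bracid, ".", t$full, ">>", p1, ".Br.OBO")
      s2 <- paste0(p1, ".", u$full, ">>", p2, ".O")
      qid <- c(qid, sprintf("Q_twostep_%d", i))
      qsmi <- c(qsmi, p2)
      qlen <- c(qlen, 2L)
      qsteps <- c(qsteps, paste(s1, s2, sep = " | "))
    }
  }

  # deterministic shuffle of corpus order under the fixture seed (the RV
  # database must not depend on it)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  corpus <- corpus[sample.int(length(corpus))]
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  # sanity: everything must sanitize
  for (s in cat_smis) mol_from_smiles(s)
  for (s in qsmi) mol_from_smiles(s)

  out <- list(
    reactions = corpus,
    catalogue = data.frame(id = cat_ids, smiles = cat_smis),
    queries = data.frame(id = qid, smiles = qsmi, route_length = qlen,
                         steps = qsteps))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(out$reactions, file.path(dir, "reactions.rsmi"))
    writeLines(paste(out$catalogue$smiles, out$catalogue$id),
               file.path(dir, "catalogue.smi"))
    writeLines(paste(out$queries$smiles, out$queries$id),
               file.path(dir, "queries.smi"))
    utils::write.csv(out$queries, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  out
}

# ---- validation-set preparation ---------------------------------------------

#' Ring count (SSSR size) of a molecule
#'
#' Cyclomatic number: bonds - atoms + components.
#'
#' @param mol An `rvmol`.
#' @return Integer ring count.
#' @export
count_rings <- function(mol) {
  comp <- component_membership(mol)
  nrow(mol$bonds) - n_atoms(mol) + max(comp, 0L)
}

#' Size of the largest fused ring system
#'
#' Ring systems are connected components of the subgraph of ring bonds; the
#' size of a system is its SSSR ring count (cyclomatic number). A system of
#' isolated rings joined by linkers counts each ring separately; ortho-fused
#' and bridged rings accumulate.
#'
#' @param mol An `rvmol`.
#' @return Integer: rings in the largest ring system (0 if acyclic).
#' @export
count_fused_rings <- function(mol) {
  rb <- ring_bond_flags(mol)
  if (!any(rb)) return(0L)
  sub <- mol
  sub$bonds <- mol$bonds[rb, , drop = FALSE]
  comp <- component_membership(sub)
  ring_atoms <- unique(as.integer(sub$bonds[, c("a1", "a2")]))
  best <- 0L
  for (ci in unique(comp[ring_atoms])) {
    atoms <- intersect(which(comp == ci), ring_atoms)
    nb <- sum(comp[sub$bonds[, "a1"]] == ci)
    best <- max(best, nb - length(atoms) + 1L)
  }
  best
}

#' Lipinski rule-of-five violation count
#'
#' MW > 500, logP > 5 (both from OpenBabel), H-bond donors (N/O-attached
#' hydrogens) > 5, H-bond acceptors (N + O atoms) > 10.
#'
#' @param mol An `rvmol`.
#' @return Integer 0-4.
#' @export
lipinski_violations <- function(mol) {
  smi <- write_smiles(mol)
  sdf <- ChemmineR::smiles2sdf(smi)
  pr <- ChemmineR::propOB(sdf)
  hbd <- sum(mol$nH[mol$elem %in% c("N", "O")])
  hba <- sum(mol$elem %in% c("N", "O"))
  sum(pr$MW[1] > 500, pr$logP[1] > 5, hbd > 5, hba > 10)
}

#' Total atom count including hydrogens
#'
#' @param mol An `rvmol`.
#' @return Heavy atoms plus implicit hydrogens.
#' @export
total_atom_count <- function(mol) heavy_atom_count(mol) + sum(mol$nH)

#' Prepare a validation set of reference structures
#'
#' Applies, in order: a minimum total atom count (heavy atoms plus
#' hydrogens), a maximum on the largest fused ring system, a minimum ring
#' count, a maximum Lipinski-violation count, then a greedy diversity pass
#' over the input order that keeps the earlier molecule of any pair with
#' binary Morgan (radius 2, 1024-bit) Tanimoto at or above the cutoff.
#'
#' @param mols Named list of `rvmol`.
#' @param min_atoms Minimum total atoms (default 20).
#' @param max_fused_rings Maximum rings in one fused system (default 3).
#' @param min_rings Minimum ring count (default 2).
#' @param max_lipinski_violations Maximum violations (default 1).
#' @param diversity_cutoff Tanimoto cutoff (default 0.6).
#' @return Named list of `rvmol`, the retained subset in input order.
#' @export
prepare_validation_set <- function(mols, min_atoms = 20L, max_fused_rings = 3L,
                                   min_rings = 2L, max_lipinski_violations = 1L,
                                   diversity_cutoff = 0.6) {
  keep <- vapply(mols, function(m) {
    total_atom_count(m) >= min_atoms &&
      count_fused_rings(m) <= max_fused_rings &&
      count_rings(m) >= min_rings &&
      lipinski_violations(m) <= max_lipinski_violations
  }, logical(1))
  mols <- mols[keep]
  if (length(mols) <= 1) return(mols)
  spec <- fingerprint_spec("binary")
  fps <- lapply(mols, fingerprint, spec = spec)
  retained <- logical(length(mols))
  for (i in seq_along(mols)) {
    ok <- TRUE
    for (j in which(retained)) {
      if (tanimoto(fps[[i]], fps[[j]]) >= diversity_cutoff) { ok <- FALSE; break }
    }
    retained[i] <- ok
  }
  mols[retained]
}
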