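# The inside-out design loop: scaffold-derived starting materials are
# combined with successive substituent-derived reagent sets through the
# reaction-vector generator; each cycle the best products are carried
# forward (active scoring), and at the end the whole accumulated population
# of intermediates and final products is ranked (passive scoring).

#' Design configuration
#'
#' The seven named design parameters plus fingerprint and generator
#' settings. `query_heavy_atoms_add_threshold` bounds product size: with
#' threshold t, products whose heavy-atom count exceeds (1 + t) times the
#' query's are filtered out each cycle. Active scoring defaults to Euclidean
#' distance on 1024-count Morgan (radius 2) fingerprints, the combination
#' chosen for reproduction-driven scoring; binary Tanimoto is available via
#' `active_scoring = "tanimoto-binary"`.
#'
#' @param min_fragment_size Minimum heavy atoms on both sides of a BRICS cut.
#' @param min_key_frag_size Threshold on heavy atoms + connections for a
#'   fragment to drive a design cycle.
#' @param max_starting_materials Catalogue hits retrieved for the scaffold.
#' @param max_reagents Catalogue hits retrieved per substituent.
#' @param query_heavy_atoms_add_threshold Size-filter fraction (>= 0).
#' @param num_products_cycle Products carried into the next cycle.
#' @param num_final_products Candidates returned by passive ranking.
#' @param active_scoring `"euclidean-count"` or `"tanimoto-binary"`.
#' @param search_fp Fingerprint spec for the building-block search.
#' @param scoring_fp Fingerprint spec for scoring (count Morgan by default).
#' @param limits [generator_limits()].
#' @return A `design_config`.
#' @export
design_config <- function(min_fragment_size = 3L,
                          min_key_frag_size = 4L,
                          max_starting_materials = 10L,
                          max_reagents = 10L,
                          query_heavy_atoms_add_threshold = 0.25,
                          num_products_cycle = 10L,
                          num_final_products = 25L,
                          active_scoring = c("euclidean-count", "tanimoto-binary"),
                          search_fp = fingerprint_spec("binary"),
                          scoring_fp = fingerprint_spec("count"),
                          limits = generator_limits()) {
  active_scoring <- match.arg(active_scoring)
  stopifnot(min_fragment_size >= 1, min_key_frag_size >= 1,
            max_starting_materials >= 1, max_reagents >= 1,
            query_heavy_atoms_add_threshold >= 0,
            num_products_cycle >= 1, num_final_products >= 1)
  structure(list(
    min_fragment_size = as.integer(min_fragment_size),
    min_key_frag_size = as.integer(min_key_frag_size),
    max_starting_materials = as.integer(max_starting_materials),
    max_reagents = as.integer(max_reagents),
    query_heavy_atoms_add_threshold = query_heavy_atoms_add_threshold,
    num_products_cycle = as.integer(num_products_cycle),
    num_final_products = as.integer(num_final_products),
    active_scoring = active_scoring,
    search_fp = search_fp, scoring_fp = scoring_fp,
    limits = limits), class = "design_config")
}

#' Size filter against the query ligand
#'
#' Keeps a product iff its heavy-atom count does not exceed the query's by
#' more than the threshold fraction ("exceeding" is strict: the boundary
#' product is kept).
#'
#' @param product,query `rvmol`s.
#' @param threshold Non-negative fraction.
#' @return Logical flag.
#' @export
size_filter <- function(product, query, threshold = 0.25) {
  heavy_atom_count(product) <= heavy_atom_count(query) * (1 + threshold)
}

new_candidate <- function(mol, smiles, score, route, cycle) {
  structure(list(mol = mol, smiles = smiles, score = score,
                 route = route, cycle = cycle),
            class = "design_candidate")
}

#' @export
print.design_candidate <- function(x, ...) {
  cat(sprintf("design_candidate: %s (score %.4g, cycle %d, %d-step route)\n",
              x$smiles, x$score, x$cycle, length(x$route)))
  invisible(x)
}

# Score = distance to query: Euclidean on count fingerprints, or
# 1 - Tanimoto on binary fingerprints. Lower is better in both modes.
score_against_query <- function(mol, query_fp, config) {
  fp <- fingerprint(mol, .scoring_spec(config))
  if (config$active_scoring == "euclidean-count") euclidean_distance(fp, query_fp)
  else 1 - tanimoto(fp, query_fp)
}

.scoring_spec <- function(config) {
  if (config$active_scoring == "euclidean-count") config$scoring_fp
  else config$search_fp
}

#' Active selection at the end of a design cycle
#'
#' Applies the size filter, scores survivors against the query (lower =
#' closer), and keeps the best `n` with deterministic canonical-SMILES
#' tie-breaks.
#'
#' @param products List of `design_candidate`.
#' @param query Query `rvmol`.
#' @param n Number to retain.
#' @param config A [design_config()].
#' @return List of scored `design_candidate`, best first.
#' @export
active_select <- function(products, query, n, config = design_config()) {
  stopifnot(n >= 1)
  keep <- vapply(products, function(p)
    size_filter(p$mol, query, config$query_heavy_atoms_add_threshold), logical(1))
  products <- products[keep]
  if (length(products) == 0) return(list())
  qfp <- fingerprint(query, .scoring_spec(config))
  scored <- lapply(products, function(p) {
    p$score <- score_against_query(p$mol, qfp, config)
    p
  })
  ord <- order(vapply(scored, `[[`, numeric(1), "score"),
               vapply(scored, `[[`, character(1), "smiles"))
  scored[ord[seq_len(min(n, length(ord)))]]
}

#' Passive ranking of the accumulated population
#'
#' Deduplicates the union of all intermediates and final products by
#' structure (keeping the better-scoring route, then the shorter one), ranks
#' by score ascending, and returns the top `n_final`.
#'
#' @param population List of `design_candidate`.
#' @param query Query `rvmol`.
#' @param n_final Number of final candidates.
#' @param config A [design_config()].
#' @return List of `design_candidate`, best first, scores non-decreasing.
#' @export
passive_rank <- function(population, query, n_final, config = design_config()) {
  if (length(population) == 0) return(list())
  qfp <- fingerprint(query, .scoring_spec(config))
  scored <- lapply(population, function(p) {
    p$score <- score_against_query(p$mol, qfp, config)
    p
  })
  key <- vapply(scored, `[[`, character(1), "smiles")
  sc <- vapply(scored, `[[`, numeric(1), "score")
  steps <- vapply(scored, function(p) length(p$route), integer(1))
  ord <- order(sc, steps, key)
  scored <- scored[ord]
  scored <- scored[!duplicated(vapply(scored, `[[`, character(1), "smiles"))]
  scored[seq_len(min(n_final, length(scored)))]
}

#' Run the inside-out design loop
#'
#' Fragment the query, retrieve scaffold-similar starting materials and
#' substituent-similar reagent sets, then iterate: every (starting material,
#' reagent) pair is tried against every reaction vector in the database,
#' verified products are size-filtered and scored, the best
#' `num_products_cycle` feed the next cycle, and all intermediates enter the
#' final passive ranking. A cycle that generates nothing carries its
#' starting materials forward with a warning. Fragmentation failure
#' propagates as a `rvdesign_fragmentation_failure` condition.
#'
#' @param query An `rvmol` (or SMILES string).
#' @param catalogue A `catalogue`.
#' @param rvdb An `rv_database`.
#' @param config A [design_config()].
#' @return List of `design_candidate` (possibly empty), best first, with a
#'   `run_report` attribute of per-cycle counts.
#' @export
run_design <- function(query, catalogue, rvdb, config = design_config()) {
  if (is.character(query)) query <- curate_molecule(query)
  frags <- brics_fragment(query, config$min_fragment_size)
  frags <- filter_key_fragments(frags, config$min_key_frag_size)
  roles <- assign_roles(frags)

  sm_hits <- search_catalogue(roles$scaffold, catalogue, config$max_starting_materials)
  sms <- lapply(seq_len(nrow(sm_hits)), function(i) {
    mol <- catalogue$mols[[match(sm_hits$id[i], catalogue$ids)]]
    new_candidate(mol, sm_hits$smiles[i], NA_real_, list(), 0L)
  })

  rv_list <- rvdb$entries
  ap_cache <- new.env(parent = emptyenv())
  ap_of <- function(smiles, mol) {
    v <- ap_cache[[smiles]]
    if (is.null(v)) {
      v <- compute_atom_pairs(mol)
      ap_cache[[smiles]] <- v
    }
    v
  }

  population <- list()
  report <- data.frame()
  n_cycles <- length(roles$substituents)
  for (ci in seq_len(max(n_cycles, 0L))) {
    sub <- roles$substituents[[ci]]
    rg_hits <- search_catalogue(sub, catalogue, config$max_reagents)
    produced <- list()
    seen <- character(0)
    n_applicable <- 0L
    for (sm in sms) {
      sm_vec <- ap_of(sm$smiles, sm$mol)
      for (ri in seq_len(nrow(rg_hits))) {
        rg_mol <- catalogue$mols[[match(rg_hits$id[ri], catalogue$ids)]]
        ens_vec <- vector_add(sm_vec, ap_of(rg_hits$smiles[ri], rg_mol))
        for (rv in rv_list) {
          if (!is_applicable(rv, ens_vec)) next
          n_applicable <- n_applicable + 1L
          res <- apply_rv(sm$mol, rg_mol, rv, config$limits)
          for (p in res$products) {
            if (p$smiles %in% seen) next
            seen <- c(seen, p$smiles)
            step <- list(
              sm_id = if (sm$cycle == 0L) sm_hits$id[match(sm$smiles, sm_hits$smiles)]
              else sprintf("cycle%d_product", sm$cycle),
              sm_smiles = sm$smiles,
              reagent_id = rg_hits$id[ri],
              reagent_smiles = rg_hits$smiles[ri],
              rv_key = rv_key(rv),
              rv_sources = vapply(rv$sources, function(s)
                paste0(s[["source_id"]],
                       if (nzchar(s[["reference"]])) paste0(":", s[["reference"]]) else ""),
                character(1)),
              product_smiles = p$smiles)
            produced[[length(produced) + 1L]] <-
              new_candidate(p$product, p$smiles, NA_real_, c(sm$route, list(step)), ci)
          }
        }
      }
    }
    kept <- active_select(produced, query, config$num_products_cycle, config)
    sized <- if (length(produced) > 0) {
      szk <- vapply(produced, function(p)
        size_filter(p$mol, query, config$query_heavy_atoms_add_threshold), logical(1))
      produced[szk]
    } else list()
    population <- c(population, sized)
    report <- rbind(report, data.frame(
      cycle = ci, n_starting_materials = length(sms),
      n_reagents = nrow(rg_hits), n_applicable_rv = n_applicable,
      n_generated = length(produced), n_kept = length(kept)))
    if (length(kept) == 0) {
      warning(sprintf("design cycle %d produced no products; carrying starting materials forward", ci))
    } else {
      sms <- kept
    }
  }

  out <- passive_rank(population, query, config$num_final_products, config)
  attr(out, "run_report") <- report
  attr(out, "fragment_set") <- roles
  out
}

#' Replay a candidate's synthetic route
#'
#' Re-applies each step's reaction vector to its recorded reactants through
#' the generator and checks that the recorded step product is regenerated —
#' the audit trail behind every returned candidate.
#'
#' @param candidate A `design_candidate`.
#' @param rvdb The `rv_database` used in the design.
#' @param limits [generator_limits()].
#' @return TRUE if every step reproduces its product, else FALSE.
#' @export
replay_route <- function(candidate, rvdb, limits = generator_limits()) {
  for (step in candidate$route) {
    rv <- rvdb$entries[[step$rv_key]]
    if (is.null(rv)) return(FALSE)
    sm <- mol_from_smiles(step$sm_smiles)
    rg <- if (!is.null(step$reagent_smiles) && nzchar(step$reagent_smiles))
      mol_from_smiles(step$reagent_smiles) else NULL
    res <- apply_rv(sm, rg, rv, limits)
    if (!(step$product_smiles %in% vapply(res$products, `[[`, "", "smiles")))
      return(FALSE)
  }
  length(candidate$route) >= 1
}
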