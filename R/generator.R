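# The structure generator: apply a reaction vector to a starting material
# (plus optional reagent) by graph editing, verifying every candidate by
# exact descriptor-vector conservation.
#
# The reaction vector specifies the outcome, not the edit script, so the
# generator enumerates small edit sets guided by the vector's AP2 entries:
# bonds whose atom-pair key is consumed (negative AP2) are deletion
# candidates, and new bonds realizing created atom-pair keys (positive AP2)
# are addition candidates. Hydrogen counts adjust locally (a deleted bond
# returns hydrogens, a formed bond consumes them), and a candidate product
# is kept only if the descriptor vector of the whole edited ensemble equals
# the reactant ensemble vector plus the reaction vector, key for key — the
# definitional conservation property of a reaction vector. AP3 entries thus
# act as the environment check even though edits are AP2-guided.

.is_ap2_key <- function(keys) {
  lengths(regmatches(keys, gregexpr("|", keys, fixed = TRUE))) == 2L
}

#' Generator limits
#'
#' Combinatorial safety valve for [apply_rv()]: `max_bond_edits` bounds the
#' total number of bond deletions plus formations tried per candidate
#' (default 4 covers common one-step transforms, including biaryl couplings
#' with a leaving group on each side), and `max_candidates_per_rv` bounds
#' the number of distinct verified products returned.
#'
#' @param max_bond_edits Positive integer.
#' @param max_candidates_per_rv Positive integer.
#' @return A `generator_limits` object.
#' @export
generator_limits <- function(max_bond_edits = 4L, max_candidates_per_rv = 64L) {
  stopifnot(max_bond_edits > 0, max_candidates_per_rv > 0)
  structure(list(max_bond_edits = as.integer(max_bond_edits),
                 max_candidates_per_rv = as.integer(max_candidates_per_rv)),
            class = "generator_limits")
}

#' Verify a candidate product against a reaction vector
#'
#' True iff `vector(product) + sum(vector(byproducts))` equals
#' `sum(vector(ensemble)) + rv$vector` exactly, key for key. This is the
#' conservation check every emitted product must pass.
#'
#' @param product An `rvmol`.
#' @param byproducts List of `rvmol` (may be empty).
#' @param ensemble List of reactant `rvmol`s.
#' @param rv A `reaction_vector`.
#' @return Logical flag.
#' @export
verify_product <- function(product, byproducts, ensemble, rv) {
  lhs <- vector_add(compute_atom_pairs(product), sum_vectors(byproducts))
  rhs <- vector_add(sum_vectors(ensemble), rv$vector)
  identical(serialize_vector(lhs), serialize_vector(rhs))
}

# Subsets of v of size k as a list (deterministic order).
.subsets_of_size <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  if (k > n) return(list())
  asplit(utils::combn(n, k), 2)
}

#' Apply a reaction vector to a starting material and optional reagent
#'
#' Enumerates bounded bond-edit sets guided by the reaction vector's AP2
#' entries and returns every distinct, verified product. Each product is a
#' single connected component that contains at least one starting-material
#' atom and — when a reagent is supplied — at least one reagent atom (a step
#' that ignores its reagent is a wasted design iteration); the remaining
#' components are tracked as byproducts. If the reaction vector is not
#' applicable to the combined descriptor vector, the result is empty.
#'
#' @param starting_material An `rvmol`.
#' @param reagent An `rvmol` or `NULL`.
#' @param rv A `reaction_vector`.
#' @param limits A [generator_limits()].
#' @return An `application_result`: list with `products` (list of entries,
#'   each `product`, `smiles`, `byproducts`), `rv_used`, `truncated` flag.
#' @export
apply_rv <- function(starting_material, reagent = NULL, rv,
                     limits = generator_limits()) {
  ensemble_mols <- if (is.null(reagent)) list(starting_material)
  else list(starting_material, reagent)
  ens <- if (is.null(reagent)) starting_material
  else combine_mols(starting_material, reagent)
  sm_atoms <- seq_len(n_atoms(starting_material))
  rg_atoms <- if (is.null(reagent)) integer(0)
  else n_atoms(starting_material) + seq_len(n_atoms(reagent))

  empty <- structure(list(products = list(), rv_used = rv, truncated = FALSE),
                     class = "application_result")
  ens_vec <- compute_atom_pairs(ens)
  if (!is_applicable(rv, ens_vec)) return(empty)
  target <- vector_add(ens_vec, rv$vector)
  if (any(target < 0)) return(empty)
  ap2 <- .is_ap2_key(names(rv$vector))
  target_ap2 <- target[.is_ap2_key(names(target))]
  neg_ap2 <- rv$vector[ap2 & rv$vector < 0]
  pos_ap2 <- rv$vector[ap2 & rv$vector > 0]
  n_add_minus_del <- sum(rv$vector[ap2])

  # deletion candidates: bonds whose current AP2 key is consumed by the RV
  ty <- atom_type_strings(ens)
  del_cand <- integer(0)
  if (nrow(ens$bonds) > 0 && length(neg_ap2) > 0) {
    keys <- ap2_key(ty[ens$bonds[, "a1"]], .bond_symbol[ens$bonds[, "order"]],
                    ty[ens$bonds[, "a2"]])
    del_cand <- which(keys %in% names(neg_ap2))
  }

  seen <- character(0)
  out <- list()
  truncated <- FALSE
  budget <- 20000L  # hard cap on candidate evaluations

  consider <- function(edited) {
    # cheap AP2 screen before the full conservation check
    got2 <- compute_atom_pairs(edited, orders = 2L)
    if (!identical(serialize_vector(got2), serialize_vector(target_ap2))) return(FALSE)
    got <- compute_atom_pairs(edited)
    if (!identical(serialize_vector(got), serialize_vector(target))) return(FALSE)
    comp <- component_membership(edited)
    with_sm <- unique(comp[sm_atoms])
    if (length(with_sm) == 0) return(FALSE)
    # main product: the SM-bearing component, largest first, canonical tie-break
    cand_comp <- sort(with_sm)
    sizes <- vapply(cand_comp, function(ci) sum(comp == ci & edited$elem != "*"),
                    numeric(1))
    if (length(cand_comp) > 1 && sum(sizes == max(sizes)) > 1) {
      smi_all <- vapply(cand_comp, function(ci)
        tryCatch(canonical_smiles(subset_mol(edited, which(comp == ci))),
                 rvdesign_parse_error = function(e) "~"), character(1))
      cand_comp <- cand_comp[order(-sizes, smi_all)]
    } else {
      cand_comp <- cand_comp[order(-sizes)]
    }
    main_ci <- cand_comp[1]
    main_atoms <- which(comp == main_ci)
    if (length(rg_atoms) > 0 && !any(rg_atoms %in% main_atoms)) return(FALSE)
    product <- subset_mol(edited, main_atoms)
    smi <- tryCatch(canonical_smiles(product), rvdesign_parse_error = function(e) NA_character_)
    if (is.na(smi) || smi %in% seen) return(FALSE)
    byp <- lapply(setdiff(unique(comp), main_ci), function(ci)
      subset_mol(edited, which(comp == ci)))
    seen <<- c(seen, smi)
    out[[length(out) + 1L]] <<- list(product = product, smiles = smi, byproducts = byp)
    TRUE
  }

  max_d <- min(limits$max_bond_edits, length(del_cand))
  for (d in 0:max_d) {
    a_needed <- d + n_add_minus_del
    if (a_needed < 0 || d + a_needed > limits$max_bond_edits) next
    for (D in .subsets_of_size(length(del_cand), d)) {
      molD <- ens
      for (k in sort(del_cand[D], decreasing = TRUE)) molD <- delete_bond(molD, k)
      if (a_needed == 0) {
        if (budget <= 0) { truncated <- TRUE; break }
        budget <- budget - 1L
        consider(molD)
        if (length(out) >= limits$max_candidates_per_rv) { truncated <- TRUE; break }
        next
      }
      # addition candidates realizing positive AP2 keys under post-deletion types
      tyD <- atom_type_strings(molD)
      adds <- list()
      if (length(pos_ap2) > 0) {
        nat <- n_atoms(molD)
        for (x in seq_len(nat - 1)) {
          for (y in seq(x + 1, nat)) {
            for (os in seq_along(.bond_symbol)) {
              ordv <- if (os == 4L) 1L else os
              if (molD$nH[x] < ordv || molD$nH[y] < ordv) next
              tx <- sub("[0-9]+$", as.character(molD$nH[x] - ordv), tyD[x])
              tyy <- sub("[0-9]+$", as.character(molD$nH[y] - ordv), tyD[y])
              key <- ap2_key(tx, .bond_symbol[os], tyy)
              if (key %in% names(pos_ap2)) {
                adds[[length(adds) + 1L]] <- c(x, y, os)
              }
            }
          }
        }
      }
      for (A in .subsets_of_size(length(adds), a_needed)) {
        if (budget <= 0) { truncated <- TRUE; break }
        budget <- budget - 1L
        molA <- molD
        ok <- TRUE
        for (ai in A) {
          molA <- add_bond(molA, adds[[ai]][1], adds[[ai]][2], adds[[ai]][3])
          if (is.null(molA)) { ok <- FALSE; break }
        }
        if (!ok) next
        consider(molA)
        if (length(out) >= limits$max_candidates_per_rv) { truncated <- TRUE; break }
      }
      if (truncated) break
    }
    if (truncated) break
  }
  if (truncated) warning("apply_rv: enumeration bound reached; result truncated")

  ordx <- order(vapply(out, `[[`, "", "smiles"))
  structure(list(products = out[ordx], rv_used = rv, truncated = truncated,
                 reactant_ensemble = ensemble_mols),
            class = "application_result")
}

#' @export
print.application_result <- function(x, ...) {
  cat(sprintf("application_result: %d verified product(s)%s\n",
              length(x$products), if (x$truncated) " [truncated]" else ""))
  for (p in x$products) cat(" ", p$smiles, "\n")
  invisible(x)
}
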