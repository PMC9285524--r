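# Building-block catalogue: curated reagent collection with a precomputed
# fingerprint index, and similarity search for scaffold / substituent
# queries.

#' Build a catalogue from molecules
#'
#' @param mols Named list of `rvmol` (names are ids), e.g. from
#'   [read_molecules()].
#' @param spec Fingerprint specification for the similarity index.
#' @param exclusions Optional list/vector of structures (SMILES or `rvmol`)
#'   to remove, matched at InChI level — used to keep reference query
#'   molecules out of their own building-block pool.
#' @return A `catalogue`.
#' @export
catalogue_from_molecules <- function(mols, spec = fingerprint_spec("binary"),
                                     exclusions = list()) {
  if (length(mols) == 0) {
    warning("empty catalogue")
    return(structure(list(ids = character(0), smiles = character(0),
                          inchi = character(0), mols = list(),
                          fps = matrix(numeric(0), nrow = 0, ncol = spec$n_bits),
                          spec = spec),
                     class = "catalogue"))
  }
  ids <- names(mols)
  smiles <- vapply(mols, canonical_smiles, character(1))
  keys <- vapply(smiles, inchi, character(1))
  keep <- !duplicated(keys)
  excl <- vapply(exclusions, function(x) {
    inchi(if (inherits(x, "rvmol")) x else curate_molecule(x))
  }, character(1))
  keep <- keep & !(keys %in% excl)
  mols <- mols[keep]; ids <- ids[keep]; smiles <- smiles[keep]; keys <- keys[keep]
  fps <- t(vapply(mols, function(m) fingerprint(m, spec), numeric(spec$n_bits)))
  structure(list(ids = unname(ids), smiles = unname(smiles),
                 inchi = unname(keys), mols = unname(mols),
                 fps = fps, spec = spec),
            class = "catalogue")
}

#' Load a building-block catalogue from a file
#'
#' Reads SMILES or SDF, curates each record (sanitize, strip salts,
#' neutralize), deduplicates by InChI, removes exclusions, and precomputes
#' the fingerprint index.
#'
#' @param path SMILES/SDF file.
#' @param spec Fingerprint specification (binary Morgan radius 2, 1024 bits
#'   by default).
#' @param exclusions Structures to remove (SMILES strings or `rvmol`s).
#' @return A `catalogue`.
#' @export
load_catalogue <- function(path, spec = fingerprint_spec("binary"),
                           exclusions = list()) {
  catalogue_from_molecules(read_molecules(path), spec, exclusions)
}

#' @export
print.catalogue <- function(x, ...) {
  cat(sprintf("catalogue: %d building blocks (%s %d-bit Morgan r%d index)\n",
              length(x$ids), x$spec$kind, x$spec$n_bits, x$spec$radius))
  invisible(x)
}

#' @export
length.catalogue <- function(x) length(x$ids)

#' Similarity search against a catalogue
#'
#' Fingerprints the query fragment with its attachment-point dummies removed
#' (catalogue reagents carry no dummies) and ranks the catalogue by Tanimoto
#' similarity, descending, ties broken by id.
#'
#' @param fragment An `rv_fragment` or `rvmol`.
#' @param catalogue A `catalogue`.
#' @param top_n Maximum number of hits.
#' @return data.frame with columns `id`, `smiles`, `similarity`.
#' @export
search_catalogue <- function(fragment, catalogue, top_n) {
  stopifnot(top_n >= 1)
  if (length(catalogue$ids) == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      similarity = numeric(0)))
  }
  mol <- if (inherits(fragment, "rv_fragment")) fragment$structure else fragment
  qfp <- fingerprint(mol, catalogue$spec)
  sims <- vapply(seq_len(nrow(catalogue$fps)), function(i)
    tanimoto(qfp, catalogue$fps[i, ]), numeric(1))
  ord <- order(-sims, catalogue$ids)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(id = catalogue$ids[ord], smiles = catalogue$smiles[ord],
             similarity = sims[ord])
}
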