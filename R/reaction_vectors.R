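# Reaction corpus parsing, reaction vectors, the RV database, and the
# applicability test.
#
# A reaction vector is the descriptor vector of the products minus that of
# the reactants: negative entries are atom-pair context consumed by the
# transformation, positive entries are context created. No atom mapping is
# involved anywhere — the vector is a multiset difference. Agents (the middle
# reaction-SMILES field) are discarded as non-structural context. Records
# with any unparseable component are skipped whole: a partial reaction
# vector silently corrupts the chemistry it encodes.

#' Parse one reaction SMILES line
#'
#' Accepts `reactants>agents>products`, optionally followed by tab-separated
#' `source_id` and `reference` columns. Agents are discarded. Every component
#' is sanitized; a component that fails to parse fails the whole record.
#'
#' @param rsmi_line One line of reaction SMILES text.
#' @return A `reaction_record`: lists of reactant/product `rvmol`s plus
#'   provenance strings.
#' @export
#' @examples
#' r <- parse_reaction("CCO.CC(=O)O>>CC(=O)OCC.O")
#' length(r$reactants)
parse_reaction <- function(rsmi_line) {
  parts <- strsplit(rsmi_line, "\t", fixed = TRUE)[[1]]
  rsmi <- parts[1]
  source_id <- if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else "unknown"
  reference <- if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else ""
  fields <- strsplit(rsmi, ">", fixed = TRUE)[[1]]
  if (length(fields) == 2 && grepl(">>", rsmi, fixed = TRUE)) fields <- c(fields[1], "", fields[2])
  if (length(fields) != 3) parse_error("reaction SMILES must have two '>' separators", rsmi)
  split_side <- function(side) {
    if (!nzchar(side)) return(list())
    lapply(strsplit(side, ".", fixed = TRUE)[[1]], mol_from_smiles)
  }
  reactants <- split_side(fields[1])
  products <- split_side(fields[3])
  if (length(reactants) == 0) parse_error("reaction has no reactants", rsmi)
  if (length(products) == 0) parse_error("reaction has no products", rsmi)
  structure(list(reactants = reactants, products = products,
                 source_id = source_id, reference = reference, rsmi = rsmi),
            class = "reaction_record")
}

#' Read a reaction corpus file
#'
#' One reaction SMILES per line (optional tab-separated source id and
#' reference columns); malformed lines are skipped with a warning, matching
#' the curation contract used for the patent and journal corpora.
#'
#' @param path Path to an RSMI text file.
#' @return List of `reaction_record`.
#' @export
read_reaction_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(parse_reaction(lines[i]),
                    rvdesign_parse_error = function(e) {
                      warning(sprintf("skipping reaction line %d: %s", i, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

sum_vectors <- function(mols) {
  out <- structure(integer(0), names = character(0))
  for (m in mols) out <- vector_add(out, compute_atom_pairs(m))
  out
}

#' Compute the reaction vector of a reaction record
#'
#' Product descriptor sum minus reactant descriptor sum. An all-zero result
#' (identity transformation) is flagged as a null transform via the
#' `null_transform` attribute; callers building a database discard such
#' records.
#'
#' @param rec A `reaction_record` from [parse_reaction()].
#' @return A `reaction_vector`: sparse signed vector, reactant count, and
#'   source provenance.
#' @export
compute_reaction_vector <- function(rec) {
  v <- vector_subtract(sum_vectors(rec$products), sum_vectors(rec$reactants))
  structure(list(vector = v,
                 n_reactants = length(rec$reactants),
                 sources = list(c(source_id = rec$source_id, reference = rec$reference))),
            class = "reaction_vector",
            null_transform = length(v) == 0)
}

is_null_transform <- function(rv) isTRUE(attr(rv, "null_transform")) || length(rv$vector) == 0

rv_key <- function(rv) serialize_vector(rv$vector)

#' Build a reaction-vector database from a corpus
#'
#' Null transforms are discarded; duplicate vectors (exact signed-count
#' equality) are merged with the union of their sources. The result is
#' independent of corpus order: entries are keyed and sorted by the
#' canonical vector serialization.
#'
#' @param corpus List of `reaction_record`.
#' @return An `rv_database`.
#' @export
build_rv_database <- function(corpus) {
  entries <- list()
  for (rec in corpus) {
    rv <- compute_reaction_vector(rec)
    if (is_null_transform(rv)) next
    key <- rv_key(rv)
    if (is.null(entries[[key]])) {
      entries[[key]] <- rv
    } else {
      entries[[key]]$sources <- unique(c(entries[[key]]$sources, rv$sources))
      entries[[key]]$n_reactants <- max(entries[[key]]$n_reactants, rv$n_reactants)
    }
  }
  if (length(entries) == 0) {
    warning("reaction corpus yielded an empty RV database")
    return(structure(list(entries = list()), class = "rv_database"))
  }
  # canonical source order, so the database is corpus-order independent
  entries <- lapply(entries, function(rv) {
    key <- vapply(rv$sources, function(s)
      paste0(s[["source_id"]], "\r", s[["reference"]]), character(1))
    rv$sources <- rv$sources[order(key)]
    rv
  })
  entries <- entries[order(names(entries))]
  structure(list(entries = entries), class = "rv_database")
}

#' @export
print.rv_database <- function(x, ...) {
  cat(sprintf("rv_database: %d unique reaction vectors\n", length(x$entries)))
  invisible(x)
}

#' @export
length.rv_database <- function(x) length(x$entries)

#' Applicability of a reaction vector to a reactant ensemble
#'
#' A reaction vector may be applied only if every negatively counted atom
#' pair is present in the combined descriptor vector of the starting
#' material and reagent, with multiplicity respected.
#'
#' @param rv A `reaction_vector`.
#' @param reactant_ensemble Molecule-derived (all-positive) descriptor
#'   vector, typically `vector_add(compute_atom_pairs(sm), compute_atom_pairs(reagent))`.
#' @return Logical flag.
#' @export
is_applicable <- function(rv, reactant_ensemble) {
  neg <- rv$vector[rv$vector < 0]
  if (length(neg) == 0) return(TRUE)
  have <- reactant_ensemble[names(neg)]
  have[is.na(have)] <- 0L
  all(have >= -neg)
}

# ---- RV database text format ------------------------------------------------
# One entry per line: serialized vector <TAB> n_reactants <TAB>
# semicolon-joined "source_id|reference" pairs. Diffable and order-canonical.

#' Write an RV database to its line-oriented text format
#'
#' @param db An `rv_database`.
#' @param path Output file path.
#' @export
write_rv_database <- function(db, path) {
  lines <- vapply(db$entries, function(rv) {
    src <- paste(vapply(rv$sources, function(s) paste0(s[["source_id"]], "|", s[["reference"]]),
                        character(1)), collapse = ";")
    paste(serialize_vector(rv$vector), rv$n_reactants, src, sep = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an RV database written by [write_rv_database()]
#'
#' @param path Input file path.
#' @return An `rv_database`; the round trip through the text format is
#'   lossless.
#' @export
read_rv_database <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed RV database line: ", ln)
    v <- deserialize_vector(parts[1])
    sources <- lapply(strsplit(parts[3], ";", fixed = TRUE)[[1]], function(s) {
      kv <- strsplit(s, "|", fixed = TRUE)[[1]]
      c(source_id = kv[1], reference = if (length(kv) > 1) kv[2] else "")
    })
    rv <- structure(list(vector = v, n_reactants = as.integer(parts[2]),
                         sources = sources),
                    class = "reaction_vector", null_transform = length(v) == 0)
    entries[[rv_key(rv)]] <- rv
  }
  entries <- entries[order(names(entries))]
  structure(list(entries = entries), class = "rv_database")
}
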