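# Molecule file I/O, design-candidate output, and configuration files.

.read_smi_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  lines
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files (`.smi`, one `SMILES [whitespace] id` per line) are read
#' directly; SDF files are converted through OpenBabel. Each record is
#' sanitized, salts and ions are stripped to the largest component, and
#' simple protonation charges are neutralized (one molecule per entry).
#' Unreadable records are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param path Path to a `.smi`/`.txt` SMILES file or an `.sdf` file.
#' @return Named list of `rvmol` (names are record ids).
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    tmp <- tempfile(fileext = ".smi")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile("SDF", "SMI", path, tmp)
    lines <- .read_smi_lines(tmp)
  } else {
    lines <- .read_smi_lines(path)
  }
  out <- list()
  skipped <- 0L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    id <- if (length(parts) >= 2) paste(parts[-1], collapse = "_")
    else sprintf("MOL%05d", i)
    mol <- tryCatch(curate_molecule(parts[1]),
                    rvdesign_parse_error = function(e) {
                      warning(sprintf("skipping record %d (%s): %s", i, id,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(mol)) { skipped <- skipped + 1L; next }
    out[[id]] <- mol
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Curate a single structure
#'
#' Sanitize, keep the largest component (salt/ion stripping), neutralize
#' protonation-type charges where a hydrogen can be added or removed.
#'
#' @param smiles SMILES string.
#' @return An `rvmol`.
#' @export
curate_molecule <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  comps <- mol_components(mol)
  if (length(comps) > 1) {
    sizes <- vapply(comps, heavy_atom_count, numeric(1))
    smis <- vapply(comps, function(m) canonical_smiles(m), character(1))
    mol <- comps[[order(-sizes, smis)[1]]]
  }
  mol <- neutralize(mol)
  attr(mol, "cansmi") <- NULL
  attr(mol, "cansmi") <- canonical_smiles(mol)
  mol
}

# Neutralize +N-H / -O type charges; quaternary or non-protic charges stay.
neutralize <- function(mol) {
  for (a in seq_len(n_atoms(mol))) {
    while (mol$charge[a] > 0L && mol$nH[a] > 0L) {
      mol$charge[a] <- mol$charge[a] - 1L
      mol$nH[a] <- mol$nH[a] - 1L
    }
    while (mol$charge[a] < 0L) {
      mol$charge[a] <- mol$charge[a] + 1L
      mol$nH[a] <- mol$nH[a] + 1L
    }
  }
  attr(mol, "cansmi") <- NULL
  mol
}

# ---- candidates output ------------------------------------------------------

route_step_rsmi <- function(step) {
  lhs <- paste(c(step$sm_smiles, step$reagent_smiles), collapse = ".")
  paste0(lhs, ">>", step$product_smiles)
}

#' Write design candidates to SDF and CSV
#'
#' The SDF carries one record per candidate with data fields `score`,
#' `generation_cycle`, one `route_step_<i>` reaction-SMILES field per step,
#' and the reaction-vector provenance references. The CSV is a flat summary.
#' Both re-read losslessly (see [read_candidates()]).
#'
#' @param candidates List of `design_candidate` from [run_design()].
#' @param sdf_path,csv_path Output paths (either may be `NULL` to skip).
#' @export
write_candidates <- function(candidates, sdf_path = NULL, csv_path = NULL) {
  df <- candidates_table(candidates)
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(sdf_path)) {
    if (length(candidates) == 0) {
      writeLines(character(0), sdf_path)
    } else {
      blocks <- vapply(seq_along(candidates), function(i) {
        cand <- candidates[[i]]
        sdf <- ChemmineR::smiles2sdf(cand$smiles)
        lns <- unlist(ChemmineR::sdf2str(sdf[[1]]))
        # deterministic header: the OpenBabel program line embeds a timestamp
        lns[1] <- df$id[i]
        lns[2] <- " rvdesign          2D"
        txt <- paste(lns, collapse = "\n")
        # drop the default terminator, append data fields
        txt <- sub("\\$\\$\\$\\$\\s*$", "", txt)
        fields <- c(
          sprintf(">  <id>\n%s\n", df$id[i]),
          sprintf(">  <score>\n%.10g\n", cand$score),
          sprintf(">  <generation_cycle>\n%d\n", cand$cycle),
          vapply(seq_along(cand$route), function(s)
            sprintf(">  <route_step_%d>\n%s\n", s, route_step_rsmi(cand$route[[s]])),
            character(1)),
          sprintf(">  <rv_references>\n%s\n", df$rv_references[i])
        )
        paste0(txt, paste(fields, collapse = "\n"), "\n$$$$")
      }, character(1))
      writeLines(blocks, sdf_path)
    }
  }
  invisible(df)
}

#' Summary table of design candidates
#'
#' @param candidates List of `design_candidate`.
#' @return data.frame with id, smiles, score, cycle, route and provenance.
#' @export
candidates_table <- function(candidates) {
  if (length(candidates) == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      score = numeric(0), generation_cycle = integer(0),
                      n_steps = integer(0), route = character(0),
                      rv_references = character(0)))
  }
  data.frame(
    id = sprintf("CAND%04d", seq_along(candidates)),
    smiles = vapply(candidates, `[[`, "", "smiles"),
    score = vapply(candidates, `[[`, numeric(1), "score"),
    generation_cycle = vapply(candidates, function(x) as.integer(x$cycle), integer(1)),
    n_steps = vapply(candidates, function(x) length(x$route), integer(1)),
    route = vapply(candidates, function(x)
      paste(vapply(x$route, route_step_rsmi, character(1)), collapse = " | "), character(1)),
    rv_references = vapply(candidates, function(x)
      paste(unique(unlist(lapply(x$route, `[[`, "rv_sources"))), collapse = ";"),
      character(1))
  )
}

#' Read back a candidate SDF written by [write_candidates()]
#'
#' @param path SDF path.
#' @return data.frame with id, smiles (re-canonicalized), score, cycle and
#'   route strings.
#' @export
read_candidates <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || !any(grepl("\\$\\$\\$\\$", txt))) {
    return(candidates_table(list()))
  }
  recs <- split(txt, cumsum(c(1, head(grepl("^\\$\\$\\$\\$", txt), -1))))
  rows <- lapply(recs, function(block) {
    getf <- function(name) {
      i <- grep(sprintf("^>  <%s>$", name), block)
      if (length(i) == 0) return(NA_character_)
      block[i[1] + 1]
    }
    steps <- grep("^>  <route_step_", block)
    route <- vapply(sort(steps), function(i) block[i + 1], character(1))
    data.frame(id = getf("id"), score = as.numeric(getf("score")),
               generation_cycle = as.integer(getf("generation_cycle")),
               route = paste(route, collapse = " | "),
               rv_references = getf("rv_references"))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# ---- configuration ----------------------------------------------------------

.config_yaml_names <- c(
  minFragmentSize = "min_fragment_size",
  minKeyFragSize = "min_key_frag_size",
  maxStartingMaterials = "max_starting_materials",
  maxReagents = "max_reagents",
  queryHeavyAtomsAddThreshold = "query_heavy_atoms_add_threshold",
  numProductsCycle = "num_products_cycle",
  numFinalProducts = "num_final_products",
  activeScoring = "active_scoring",
  maxBondEdits = "max_bond_edits",
  maxCandidatesPerRV = "max_candidates_per_rv"
)

#' Write a design configuration file
#'
#' Flat YAML using the seven canonical parameter names
#' (`minFragmentSize`, `minKeyFragSize`, `maxStartingMaterials`,
#' `maxReagents`, `queryHeavyAtomsAddThreshold`, `numProductsCycle`,
#' `numFinalProducts`) plus scoring and generator settings.
#'
#' @param config A [design_config()].
#' @param path Output path.
#' @export
write_design_config <- function(config, path) {
  vals <- list(
    minFragmentSize = config$min_fragment_size,
    minKeyFragSize = config$min_key_frag_size,
    maxStartingMaterials = config$max_starting_materials,
    maxReagents = config$max_reagents,
    queryHeavyAtomsAddThreshold = config$query_heavy_atoms_add_threshold,
    numProductsCycle = config$num_products_cycle,
    numFinalProducts = config$num_final_products,
    activeScoring = config$active_scoring,
    maxBondEdits = config$limits$max_bond_edits,
    maxCandidatesPerRV = config$limits$max_candidates_per_rv
  )
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read a design configuration file written by [write_design_config()]
#'
#' @param path YAML path.
#' @return A [design_config()]; the round trip is exact.
#' @export
read_design_config <- function(path) {
  vals <- yaml::read_yaml(path)
  args <- list()
  for (nm in names(vals)) {
    tgt <- .config_yaml_names[[nm]]
    if (is.null(tgt)) next
    args[[tgt]] <- vals[[nm]]
  }
  lim <- generator_limits(
    max_bond_edits = args$max_bond_edits %||% 4L,
    max_candidates_per_rv = args$max_candidates_per_rv %||% 64L)
  args$max_bond_edits <- NULL
  args$max_candidates_per_rv <- NULL
  args$limits <- lim
  do.call(design_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
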