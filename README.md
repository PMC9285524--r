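# rvdesign

Reaction-vector driven, pseudo-retrosynthetic *de novo* molecular design in R.

Medicinal chemists exploring the neighbourhood of a known ligand want
candidate molecules that are not just similar but *makeable*: each suggestion
should come with real purchasable building blocks and a literature-backed
reaction for every bond the design forms. `rvdesign` implements that
workflow end to end:

1. **Ligand fragmentation** — the query is decomposed with the 16 BRICS
   bond-cleavage rules into key fragments; fragments are ranked by
   attachment-point count, then size, and the top fragment becomes the
   *scaffold*, the rest *substituents*.
2. **Building-block search** — each fragment retrieves its most similar
   catalogue reagents by Tanimoto similarity over 1024-bit binary Morgan
   (radius 2) fingerprints.
3. **Structure generation with reaction vectors** — a reaction vector (RV)
   is the signed difference of atom-pair descriptor counts between the
   products and reactants of a known reaction,

   `RV = Σ AP(products) − Σ AP(reactants)`,

   where AP counts typed bonded pairs (AP2) and typed linear three-atom
   paths (AP3); atom types are (element, charge, aromaticity, H count). An
   RV is *applicable* to a starting-material + reagent pair when every
   negatively counted atom pair is present with sufficient multiplicity, and
   applying it is a bounded graph-edit search whose products must conserve
   descriptors exactly: `AP(products) = AP(reactants) + RV`.
4. **Scoring** — designs grow "inside out": each cycle combines the current
   starting materials with the next substituent's reagents over all
   applicable RVs, keeps the `numProductsCycle` products closest to the
   query (active scoring, Euclidean distance on 1024-count Morgan
   fingerprints), and finally ranks the whole accumulated population
   (passive scoring). Every candidate carries a replayable synthetic route.

The package also ships the curation utilities used to build validation sets
(salt stripping, neutralization, fused-ring / ring-count / Lipinski filters,
greedy diversity selection) and a fixture generator that emits a toy
reaction corpus, a matched catalogue, and queries with known ground-truth
routes, so the entire pipeline is testable offline.

## Worked example

Recover a one-step amide from its true precursors:

```r
library(rvdesign)

rxn <- "Cc1ccc(cc1)C(=O)O.NCc1ccccc1>>Cc1ccc(cc1)C(=O)NCc1ccccc1.O"
db  <- build_rv_database(list(parse_reaction(rxn)))
cat <- catalogue_from_molecules(list(
  acid  = curate_molecule("Cc1ccc(cc1)C(=O)O"),
  amine = curate_molecule("NCc1ccccc1")))

res <- run_design("Cc1ccc(cc1)C(=O)NCc1ccccc1", cat, db, design_config())
res[[1]]
#> design_candidate: Cc1ccc(cc1)C(=O)NCc1ccccc1 (score 0, cycle 1, 1-step route)
replay_route(res[[1]], db)
#> [1] TRUE
```

The score is the Euclidean distance between count-Morgan fingerprints of
candidate and query — 0 means the query itself was regenerated — and
`replay_route()` re-runs every step of the suggested route through the
generator as an audit.

The same pipeline is available from the shell:

```sh
rvdesign extract-rv --reactions reactions.rsmi --out rv.tsv
rvdesign fragment   --query "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1"
rvdesign design     --query query.smi --catalogue catalogue.smi --rvdb rv.tsv \
                    --out-sdf cand.sdf --out-csv cand.csv --maxReagents 10
rvdesign validate   --queries drugs.smi --out report.csv
```

`fragment` prints the scaffold/substituent assignment (for celecoxib the
pyrazole core, with three attachment points, is the scaffold);
`validate` tabulates per-query outcomes — `ok`, `fragmentation_failure`
(no BRICS-cleavable bond, e.g. molecules held together by
aromatic–aliphatic ring bonds), or `no_candidates`.

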