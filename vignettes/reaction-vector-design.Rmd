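---
title: "Reaction-vector driven pseudo-retrosynthetic design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-vector driven pseudo-retrosynthetic design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvdesign)
```

## The problem and the model

Reaction-based *de novo* design generates candidate molecules by applying
transformations extracted from known reactions, so that every suggested
structure arrives with an explicit, literature-anchored synthetic route.
`rvdesign` couples this with pseudo-retrosynthesis: instead of growing a
molecule outward from one starting material (which explodes combinatorially
over multiple steps), a reference ligand is first *fragmented*, each
fragment retrieves similar purchasable building blocks, and the building
blocks are recombined inside-out. "Pseudo" means fragmentation uses only
bond-cleavage rules — no functional-group interconversion, eliminations or
ring transforms — so a ring-closing step in the true synthesis can never be
recovered by fragmentation.

### Atom-pair descriptors and reaction vectors

A molecule is described by a sparse multiset of typed atom pairs over its
heavy-atom graph:

* **AP2** — a bonded pair: `(type_i, bond order, type_j)`;
* **AP3** — a linear three-atom path: `(type_i, bond, type_center, bond,
  type_k)`;

with atom type = (element, formal charge, aromatic flag, attached-H count)
and bond order in {single, double, triple, aromatic}. The **reaction
vector** of a reaction is the signed difference

$$\mathrm{RV} = \sum_{\text{products}} \mathrm{AP}(m) \;-\;
               \sum_{\text{reactants}} \mathrm{AP}(m).$$

Negative entries are the atom-pair context the reaction consumes, positive
entries the context it creates. No atom mapping is involved. AP2 entries
register the actual bond changes; AP3 entries encode the one-bond
environment around them, which is what makes an RV *context-specific*: an
amide coupling extracted from an aryl acid + benzylic amine pair transfers
to other aryl acid + benzylic amine pairs, but not to an aliphatic acid,
because the AP3 paths through the reacting carbonyl differ.

Keeping the hydrogen count inside the atom type is what lets
hydrogen-losing condensations register without hydrogens ever being
descriptor endpoints: esterification consumes `(C,0,·,2)–O(h1)` pairs and
creates `(C,0,·,2)–O(h0)` pairs even though the O–H bond itself is never a
descriptor.

### Applicability and structure generation

An RV may be applied to a starting material (SM) plus optional reagent when
every negatively counted atom pair is present in their combined descriptor
vector with at least the required multiplicity. Generation is a bounded
graph-edit search guided by the RV's AP2 entries:

1. bonds whose current AP2 key is negatively counted are deletion
   candidates;
2. atom pairs whose post-edit AP2 key is positively counted are bond-formation
   candidates;
3. hydrogen counts adjust locally (a deleted bond returns hydrogens to its
   endpoints, a formed bond consumes them; negative hydrogen counts reject a
   candidate);
4. the number of formations minus deletions is fixed by the RV's net AP2
   sum, and the total edit count is bounded by `max_bond_edits` (default 4,
   enough for condensations, substitutions, reductive aminations and biaryl
   couplings with a leaving group on each side);
5. a candidate is kept only if the descriptor vector of the edited ensemble
   equals `AP(reactants) + RV` **exactly**, key for key. The AP3 entries act
   here as the environment verification even though edits are AP2-guided.

The edited graph is split into components: the component containing SM atoms
(largest, canonical-SMILES tie-break) is the main product; the rest are
byproducts. When a reagent is supplied, products that contain no reagent
atom are discarded — a design step that ignores its reagent is a wasted
iteration. One verification blind spot is inherent to the descriptor space:
a byproduct with a single heavy atom (water, HCl, HBr) has no atom pairs, so
its presence or absence cannot be checked; bonded byproducts (e.g. the boron
residue of a biaryl coupling) are fully constrained.

Aromaticity is kept as its own bond order (never Kekulé alternation) and all
molecules enter through one canonicalization path (OpenBabel canonical
SMILES), so descriptor comparison never depends on perception drift.
Stereochemistry is ignored throughout: the descriptors and the generator are
topological, and enantiomeric inputs collapse to one canonical identifier.

### Fragmentation

Cleavage follows the published 16-environment BRICS rule table, implemented
as graph predicates. `minFragmentSize` (default **3** heavy atoms, dummies
excluded) is enforced *recursively*: in each fragment the first rule-ordered
cleavable bond whose two sides both meet the threshold is cut and both
pieces are decomposed further. This keeps small linkers — a lone carbonyl,
an ether oxygen, an amide nitrogen — attached to a neighbour, so leaf
fragments resemble purchasable building blocks; with the threshold at 1
every cleavable bond is cut. The leaves always partition the query (their
heavy atoms sum to the query's), which a union over alternative cut orders
would not. `minKeyFragSize` (default **4**, on heavy atoms + attachment
points) then drops fragments too small to drive a design cycle. A query
with no allowed cut raises a `fragmentation_failure`; drug sets typically
show a ~10–15 % failure rate, dominated by molecules whose only breakable
bonds are single bonds between aromatic and aliphatic rings, for which
BRICS has no rule (benzodiazepines, cage amines, tetralin-like cores in the
bundled set).

Key fragments are sorted by descending attachment-point count, then
descending heavy-atom count, then canonical SMILES (the third key is ours;
determinism requires one). The head is the scaffold. For celecoxib the
pyrazole core carries three attachment points and wins over both aryl rings.

### The design loop and scoring

Scaffold hits (≤ `maxStartingMaterials`, default 10) seed cycle 1, which
combines them with the first substituent's reagent hits (≤ `maxReagents`,
default 10) over every applicable RV. Products exceeding the query's
heavy-atom count by more than `queryHeavyAtomsAddThreshold` (default 0.25,
the boundary itself is kept) are filtered, survivors are scored, and the
best `numProductsCycle` (default 10) become the next cycle's starting
materials; a cycle that produces nothing carries its starting materials
forward with a warning rather than aborting. All size-filtered products of
every cycle accumulate into the population that the final passive ranking
deduplicates (better score, then shorter route, then canonical SMILES) and
truncates to `numFinalProducts` (default 25).

Scoring is distance to the query, lower better: Euclidean distance over
1024-count Morgan (radius 2) fingerprints by default, which is the natural
choice when the goal is reproducing a reference structure; binary
Tanimoto is available (`active_scoring = "tanimoto-binary"`). Catalogue
search always uses binary Tanimoto. The Morgan-style fingerprints are
computed in-package (deterministic 31-bit FNV-style hashing of iterated
neighbourhood invariants); they are used only for internal comparisons, so
bit-compatibility with any other toolkit is not required and not claimed.
Where defaults are not forced by the method description they were fixed
once, at design time, at the values above.

There is no randomness anywhere in the pipeline: identical inputs and
configuration give byte-identical candidate SDF/CSV outputs.

## The synthetic fixture universe

`generate_fixture()` emits a reaction corpus, a matched building-block
catalogue (~55 blocks) and 20 queries with ground-truth routes, spanning six
reaction families: amide coupling, Fischer esterification, sulfonamide
formation, Williamson ether synthesis, reductive amination and Suzuki biaryl
coupling. Because RVs carry AP3 context, reagent pools are built as context
classes (para-substituted aryl electrophiles; benzylic primary amines;
cyclic secondary amines; primary alcohols with a β-CH~2~; aryl boronic
acids): corpus reactions use shifted reagent pairings and queries use
aligned pairings from the same classes, so each query's true RV is in the
database while its own reaction is not. Products are composed from string
templates and canonicalized — never produced by the package's generator — so
the corpus is independent ground truth for the generator's closure tests.
Eighteen queries are one-step; two chain a Suzuki coupling on
4-bromobenzoic acid into an amide (ground-truth length 2).

What the fixtures emulate: transferable single-step medicinal-chemistry
transformations over drug-like building blocks, with leaving groups and
byproducts. What they do not emulate: reaction corpora with inconsistent
curation, protection chemistry, ring-forming steps, stereochemistry, or
catalogue scale (tens of blocks, not 10^5^–10^6^ reagents). Passing the
fixture suite therefore demonstrates the mechanism — fragmentation, search,
applicability, generation, scoring and route replay — not retrieval quality
at production scale, where ranking is harder and RV coverage sparser. The
measured behaviour on the fixtures: 100 % corpus closure, and exact
top-candidate recovery of 17/20 queries (85 %). The three misses are
informative rather than accidental: in two, the true two-step starting
material (4-bromobenzoic acid) is not similar enough to the scaffold to
enter the top-10 starting materials, and in one the true benzylic amine
falls just below the top-10 reagent cutoff — the same near-miss behaviour
that full-scale validations of this design strategy report for multi-step
reproductions.

## The bundled validation drug set

`inst/extdata/validation_drugs_synthetic.smi` contains 73 approved drugs
hand-curated from the public top-200 US prescription universe. It is a
**synthetic stand-in** assembled for this package (stereo-free, drawn from
public knowledge), not any publication's supplementary file; counts measured
on it (currently 65 fragmentable, 8 failures, 11 %) characterize this set,
not any published one. It exercises the full curation path: salt stripping,
neutralization and the validation filters (≥ 20 atoms counting hydrogens,
≤ 3 fused rings — ring systems are connected components of the ring-bond
subgraph, so spiro pairs count as one system — ≥ 2 rings, ≤ 1 Lipinski
violation with MW and logP from OpenBabel, then greedy first-kept diversity
dedup at Tanimoto 0.6 over input order; ties and order rules are this
package's deterministic choices).

## Numerical and degenerate-case choices

* Tanimoto of two all-zero fingerprints is defined as 1: degenerate tiny
  fragments should match each other rather than error.
* Empty molecules give empty descriptor vectors; the null transform applied
  to a lone starting material returns it unchanged.
* Sparse vectors never store zeros; serialization sorts keys, making the RV
  database file diffable and its construction independent of corpus order
  (duplicate RVs merge with sources sorted canonically).
* OpenBabel silently repairs malformed SMILES, so the package runs its own
  syntax check first and refuses what it cannot tokenize; unreadable corpus
  or catalogue records are skipped whole, with warnings — a partially parsed
  reaction would corrupt its RV.
* Enumeration in the generator is capped (`max_candidates_per_rv`, plus a
  hard evaluation budget); hitting a cap truncates with a warning rather
  than failing.

## Known limitations

* Linear AP3 paths are the largest environment encoded; sphere-based
  environments beyond one bond, 3D descriptors and stereochemistry are out
  of scope.
* Ring-forming/ring-opening transforms whose edit sets exceed
  `max_bond_edits`, and aromaticity changes during a reaction, are not
  generated.
* Single-heavy-atom byproducts are invisible to descriptor conservation
  (see above).
* Similarity search is exhaustive (no index); adequate for fixture-scale
  catalogues, linear in catalogue size.
* Problem sizes in the test suite and acceptance script (a ~54-reaction
  corpus, ~55-block catalogue, 20 queries, 73 validation drugs) are chosen
  so the whole pipeline, including every end-to-end design run, executes in
  a few minutes; they are the package's testing conditions, and scale-up is
  a matter of inputs, not code paths.
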