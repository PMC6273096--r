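---
title: "Extended functional groups: registry design, matching semantics and enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended functional groups: registry design, matching semantics and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efgtools)
```

## Why functional-group descriptors

Classical functional groups — hydroxyls, nitro groups, amides, heterocyclic
ring systems — are the vocabulary chemists use to reason about reactivity,
toxicity and physicochemical behavior. Counting well-defined groups in each
molecule yields a small, dense, directly interpretable descriptor vector:
when a model or a set comparison flags "aromatic nitro group", a medicinal
chemist knows immediately what that means structurally, which is not true of
hashed fingerprint bits. `efgtools` implements an *extended functional
group* (EFG) system: a registry of 583 SMARTS-encoded group definitions, a
matcher that converts compound collections into per-molecule group-count
profiles, and an exact-test enrichment analyzer for comparing two labeled
compound sets.

## The registry

The registry is a flat, user-editable TSV
(`system.file("extdata", "efg_registry.tsv", package = "efgtools")`) with
one row per group: `group_id`, `name`, `smarts`, `category`, `specificity`,
`ls_parent`, `notes`. Four categories partition the 583 entries:

* **`checkmol_base` (200 entries).** The classical functional-group
  families: carbonyl chemistry, alcohols/phenols/ethers, the full amine
  hierarchy, halides, carboxylic-acid and carbonic-acid derivatives and
  their thio analogues, sulfur and phosphorus acid families, boron groups,
  and generic flags (alkene, aromatic compound, heterocyclic compound).
* **`reactivity_extension` (15 entries).** Groups associated with chemical
  reactivity or metabolic liability: the vinyl/alkynyl/allyl × halide/
  alcohol/thiol series, 2-amino(thio)phenols, ortho- and para-quinones, and
  the aromatic/aliphatic refinement of the nitro group (below).
* **`heterocycle` (353 entries).** A systematic taxonomy described in the
  next section.
* **`periodic_group` (15 entries).** Element-category patterns: the eight
  main-group columns (alkali metals through noble gases), transition
  metals, lanthanides, actinides, post-transition metals, metalloids,
  reactive nonmetals, and "any metal". These are disjunctions of
  atomic-number primitives (`[#7,#15,...]`), so they match regardless of
  charge, valence or aromaticity state; `build_periodic_group_pattern()`
  constructs additional categories from any element list.

The registry loader enforces structural invariants (unique ids and names,
compiling SMARTS, resolvable `ls_parent` references); `validate_registry()`
reports the same checks without throwing, for auditing edited files.

### The nitro refinement

The general nitro pattern is an alternation over the two common input
conventions, hypervalent `N(=O)=O` and charge-separated `[N+](=O)[O-]`,
anchored on the nitrogen so each nitro group counts once. Two extension
entries qualify the attachment atom: *aromatic nitro* (`...[a]`) and
*aliphatic nitro* (`...[A;!$([OX1])]`; the exclusion keeps the pattern off
the nitro group's own oxygens). On carbon-attached nitro compounds the two
refinements partition the general count exactly, which the test suite
asserts.

## The heterocycle taxonomy

Heterocycles are enumerated systematically rather than hand-listed, over
ring sizes 3–7, aromaticity, and ring heteroatom count and identity
(N, O, S). Two specificity levels are generated for every class:

* **LS (low specificity)** patterns are element-generic and
  fusion-tolerant: heteroatom positions are written "any (aromatic) atom
  except carbon" (`[a;!#6]` in aromatic rings, `[!#6;!#1;!a]` in
  non-aromatic ones), carbons are plain. Indole therefore matches the LS
  class "aromatic 5-membered heterocycle, 1 ring heteroatom".
* **HS (high specificity)** patterns fix the heteroatom elements and
  positions and forbid ring fusion: every ring atom carries the SMARTS
  ring-bond-count primitive `x2` (exactly two ring bonds), which excludes
  fused and spiro atoms. Indole does not match the HS pyrrole pattern.

Each HS entry records its LS generalization in `ls_parent`, giving a
one-level forest that `hs_entries_of()` traverses.

Positional isomers are equivalence classes of heteroatom placements under
the ring's dihedral symmetry: the three diazines (1,2-, 1,3-, 1,4-) are
distinct HS classes, as are pyrazole/imidazole or morpholine/piperazine.
Names are generated by replacement nomenclature ("1-oxa-4-azacyclohexane"),
with trivial names for the familiar parents (pyrrole, furan, thiophene,
morpholine, ...).

Enumeration is bounded by composition rules chosen once, on the grounds of
which parent ring systems are experimentally established classes:

* aromatic rings carry at most one O and at most one S; six-membered
  aromatics are nitrogen-only (neutral pyrylium/thiopyrylium analogues are
  charged species); azoles run up to five heteroatoms but the fully
  heteroatomic 5-ring is restricted to the all-nitrogen pentazole; azines
  run up to the tetrazines;
* saturated rings of sizes 3–7 carry one to three heteroatoms
  (never a fully heteroatomic ring), with at most two sulfurs among three
  heteroatoms.

These rules yield 353 heterocycle entries — 43 LS positional classes and
310 HS element-specific isomers — and, with the other three blocks, a
registry of exactly 583 patterns.

## Normalization: one aromaticity model

SMARTS matching outcomes depend on aromaticity perception, and the same
molecule may arrive written aromatic (`c1ccccc1`), Kekulé (`C1=CC=CC=C1`),
or as an SDF MOL block. To make profiles representation-independent, every
structure is normalized before matching: it is first written to a MOL block
— which by definition carries explicit Kekulé bond orders — and then
re-read and re-aromatized under a single aromaticity model, OpenBabel's
perception, producing a canonical aromatic SMILES. Matching runs only on
this normalized form.

Properties of this normalization, all asserted by the test suite:

* **Idempotence**: normalizing a normalized structure is a no-op.
* **Representation invariance**: aromatic SMILES, Kekulé SMILES and SDF
  spellings of the same molecule give bit-identical 583-long profiles.
* **Content preservation**: atom counts and multi-fragment (salt) inputs
  are preserved; no standardization beyond aromaticity is performed — no
  tautomer canonicalization, no charge neutralization, no counterion
  stripping (discarding counterions would silently change element-category
  profiles).

Inputs whose aromatic flags admit no valid Kekulé assignment are resolved
deterministically by the engine's perception model (demoted to explicit
single/double bonds) rather than rejected; genuinely unreadable structures
are reported as failures, never passed through silently. Explicit-hydrogen
inputs are collapsed to implicit hydrogens by the engine, so SMARTS H-count
primitives behave uniformly.

## Occurrence semantics

An occurrence is a *distinct matched atom set*: symmetry-equivalent
mappings of a pattern onto the same atoms count once (benzene contains one
aromatic ring, not twelve), while matches on different atom sets all count
(1,3-dinitrobenzene contains two nitro groups). This makes counts
chemically meaningful and keeps the descriptor additive. The matcher's
counts are cross-checked in the test suite against an independent
subgraph-enumeration engine (RDKit, driven through Python) over the entire
registry on every fixture molecule — two implementations, one semantics.

`profile_collection()` assembles the molecules × groups matrix in input ×
registry order, as raw counts or presence/absence indicators. Which mode
serves better as a machine-learning descriptor is application-dependent,
so both are first-class.

## Two-set enrichment

`compare_sets()` reproduces the "overrepresented groups" analysis style
for two labeled sets A and B (e.g. assay-active vs. inactive):

* *k* counts **molecules containing** the group, not total occurrences —
  prevalences are fractions of compounds.
* The p-value is the exact hypergeometric upper tail: with `N = n_A + n_B`
  pooled molecules of which `K = k_A + k_B` contain the group,
  `p = P(X >= k_A)` for a sample of size `n_A` drawn without replacement
  (and symmetrically for overrepresentation in B). One-sided tests in each
  direction separately mirror the two ranked report columns of the
  analysis style this reproduces; each group is reported with the
  direction of its higher prevalence, ties defaulting to A.
* `hypergeom_tail()` sums the probability mass function in log space
  (`lchoose` + log-sum-exp); no normal approximation is involved, so the
  tail is exact to floating-point accuracy for populations well beyond
  1e5. A randomized sweep against exact rational arithmetic holds the
  relative error below 1e-12.
* Raw p-values are always retained; Benjamini–Hochberg adjustment is
  applied within each reported direction (Bonferroni available).
* The enrichment factor is the prevalence ratio oriented to be >= 1;
  reports round it to one decimal (23% vs. 5.5% prints 4.2), machine
  output keeps full precision. A zero denominator reports `Inf` with the
  counts alongside; both prevalences zero is "not computable" and such
  groups are excluded from output anyway.

Under a null in which group membership is assigned independently of the
set label, the directional test's false-positive fraction at
`alpha = 0.05` stays at or below the nominal level (the discrete
hypergeometric tail is conservative); the acceptance checks run 1,000
simulated 50-vs-50 comparisons with 20 independent pseudo-groups at
prevalence 0.5 and assert the rate is within three binomial standard
errors of alpha.

## The fixture generator

`generate_fixtures()` produces toy molecules whose group content is known
by construction: nitrobenzene, nitromethane, 1,3-dinitrobenzene, the
pyrrole/furan/thiophene triple, indole as the fused control, aziridine,
oxetane, an organophosphorus ester, plus seeded para-substituted
nitrobenzenes (labeled `setA`) against a linear-alkane background
(`setB`). Every case carries at least two equivalent spellings (aromatic
and Kekulé dialects or different atom orderings) and a curated map of
expected nonzero counts and expected-absent groups.

What the fixtures emulate: known planted group content, representation
variety, a clean two-set enrichment signal. What they do not emulate:
realistic molecular size and diversity, tautomeric ambiguity,
stereochemistry, noisy labels, or correlated group co-occurrence. Passing
tests therefore demonstrate the correctness of the machinery — pattern
semantics, normalization invariance, exact statistics — not predictive
performance on real assay data, which depends on datasets outside this
package's scope.

## Numerical and design choices

* Direction ties (equal prevalences) report `over_in_A`; the p-value is
  then the same under set exchange whenever set sizes are equal.
* Empty (atom-free) molecules profile to the zero vector.
* Duplicate molecule identifiers are suffixed (`id_2`, ...) with a
  message, never silently merged.
* Validation problem sizes: the matcher/oracle cross-check runs the full
  583-pattern registry on all fixture molecules up to 12 heavy atoms; the
  hypergeometric sweep uses 1e4 random parameter sets with populations up
  to 60 (where exact rational arithmetic is cheap); the null calibration
  uses 1,000 replicate comparisons.

## Known limitations

* The registry is a faithful reconstruction of a published taxonomy's
  *rules* (category sizes, HS/LS semantics, enumeration strata), not a
  character-level copy of any published pattern listing; individual SMARTS
  are this package's own encodings.
* Aromaticity follows one engine's model; patterns relying on another
  vendor's aromaticity conventions may need adjustment — which is why the
  registry ships as an editable file.
* Matching is constitution-level: stereochemistry is ignored.
* Group co-occurrence (interaction) analysis is out of scope; each group
  is tested marginally.
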