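# efgtools

Extended functional group (EFG) profiling and enrichment analysis for small
molecules, in R.

Functional groups — nitro groups, amines, heterocyclic ring systems,
element categories — are the vocabulary chemists use to reason about
reactivity and biological activity. `efgtools` ships a curated registry of
**583 SMARTS-encoded group definitions** spanning four blocks:

| category               | entries | content                                              |
|------------------------|--------:|------------------------------------------------------|
| `checkmol_base`        |     200 | classical functional-group families                  |
| `reactivity_extension` |      15 | vinyl/alkynyl/allyl halides, alcohols and thiols; amino(thio)phenols; quinones; aromatic/aliphatic nitro |
| `heterocycle`          |     353 | systematic HS/LS taxonomy, ring sizes 3–7, N/O/S     |
| `periodic_group`       |      15 | periodic-table element categories                    |

and three layers of machinery on top of it:

1. **Normalization** — every input structure (SMILES or SDF) is converted
   to a Kekulé representation and re-aromatized under a single aromaticity
   model, so group counts never depend on the input dialect.
2. **Matching** — each group's occurrence count is the number of *distinct
   matched atom sets* of its SMARTS pattern in the normalized structure;
   `profile_collection()` builds the molecules × 583 count (or binary)
   descriptor matrix.
3. **Set comparison** — `compare_sets()` ranks groups by
   overrepresentation between two labeled compound sets using the exact
   hypergeometric tail `P(X >= k)` computed in log space, with
   Benjamini–Hochberg adjustment per direction and prevalence-ratio
   enrichment factors.

Heterocycles come in two specificity levels: **HS** (high specificity)
patterns pin down the exact ring — elements, positions, and *no ring
fusion*, enforced with the SMARTS ring-bond-count primitive `x2` — while
**LS** (low specificity) patterns are element-generic and fusion-tolerant.
Pyrrole matches both its HS pattern and the LS class "aromatic 5-ring, one
heteroatom"; indole, being fused, matches only the LS class.

## Worked example

```r
library(efgtools)

reg <- efg_registry()
validate_registry(reg)
#> EFG registry: 583 patterns
#>   checkmol_base          200
#>   reactivity_extension   15
#>   heterocycle            353
#>   periodic_group         15
#> specificity: HS=310, LS=43, not_applicable=230
#> all SMARTS compile

# profile one molecule: 4-chloronitrobenzene
m <- normalize_molecules("O=[N+]([O-])c1ccc(Cl)cc1")
profile(m, reg)
#> EFG profile for mol1 - 11 group(s) present
#>     halogen_deriv       aryl_halide     aryl_chloride             nitro
#>                 1                 1                 1                 1
#> aromatic_compound    nitro_aromatic   pt_carbon_group     pt_pnictogens
#>                 6                 1                 6                 1
#>     pt_chalcogens       pt_halogens      pt_nonmetals
#>                 2                 1                10
```

The profile reads directly: one aryl chloride, one aromatic-attached nitro
group, six aromatic atoms, one pnictogen (the nitro N), two chalcogens
(the nitro oxygens). Comparing a nitroaromatic set against an alkane
background recovers the planted enrichment with exact p-values:

```r
fx   <- generate_fixtures(seed = 1, n_per_class = 5)
setA <- normalize_molecules(fixture_molecules(fx, label = "setA"))
setB <- normalize_molecules(fixture_molecules(fx, label = "setB"))
compare_sets(setA, setB, reg)
#> EFG set comparison: 14 group(s) tested
#>
#> over_in_A(top 4):
#>               group k_A k_B  EF        p    p_adj
#> 1             nitro   8   0 Inf 0.000155 0.000725
#> 2     pt_chalcogens   8   0 Inf 0.000155 0.000725
#> 3     pt_pnictogens   8   0 Inf 0.000155 0.000725
#> 4 aromatic_compound   7   0 Inf 0.001240 0.003480
```

All eight set-A molecules and none of the seven set-B molecules carry a
nitro group; `p = 0.000155` is the exact tail `1/choose(15, 8) = 1/6435`,
not an approximation. Enrichment factors are prevalence ratios: a group present
in 23% of actives and 5.5% of inactives reports
`round(enrichment_factor(0.23, 0.055), 1)` = **4.2**.

## Command line

```sh
Rscript inst/cli/efg.R registry stats inst/extdata/efg_registry.tsv
Rscript inst/cli/efg.R profile compounds.smi --mode counts --out profiles.csv
Rscript inst/cli/efg.R setcompare actives.smi inactives.smi --top 6 --out report.tsv
```

Diagnostics go to stderr, data to files/stdout; exit codes are 0 on
success, 2 on usage errors, 1 otherwise.

## Registry customization

The registry is a plain TSV (`inst/extdata/efg_registry.tsv`) with columns
`group_id`, `name`, `smarts`, `category`, `specificity`, `ls_parent`,
`notes`. Edit it (or build project-specific variants with
`build_periodic_group_pattern()` / `write_registry()`) and validate with
`efg registry validate <file>`; `load_registry()` enforces unique ids,
compiling SMARTS and resolvable HS→LS references.
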