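#' @title Toy molecules with analytically known group content
#' @description
#' The fixture generator produces a deterministic collection of small
#' molecules whose functional-group content is known by construction: every
#' case carries at least two equivalent SMILES spellings (aromatic and
#' Kekulé dialects, or two different atom orderings) plus a curated map of
#' expected nonzero group counts and groups expected absent. Labels plant a
#' nitro-family enrichment in `setA` against an alkane background in
#' `setB`, so the whole profile -> set-comparison pipeline has a known
#' ground truth.
#' @name efg-fixtures
NULL

.fixture_case <- function(mol_id, smiles_variants, expected_nonzero = integer(0),
                          expected_zero = character(0), label = "neutral") {
  stopifnot(length(smiles_variants) >= 2L, label %in% c("setA", "setB", "neutral"))
  list(mol_id = mol_id, smiles_variants = smiles_variants,
       expected_nonzero = expected_nonzero, expected_zero = expected_zero,
       label = label)
}

.core_fixture_cases <- function() list(
  .fixture_case("nitrobenzene",
    c("O=[N+]([O-])c1ccccc1", "O=[N+]([O-])C1=CC=CC=C1"),
    c(nitro = 1L, nitro_aromatic = 1L, aromatic_compound = 6L,
      pt_pnictogens = 1L, pt_chalcogens = 2L),
    expected_zero = c("nitro_aliphatic", "halogen_deriv", "hydroxy"),
    label = "setA"),
  .fixture_case("nitromethane",
    c("C[N+](=O)[O-]", "[O-][N+](=O)C"),
    c(nitro = 1L, nitro_aliphatic = 1L, pt_pnictogens = 1L),
    expected_zero = c("nitro_aromatic", "aromatic_compound"),
    label = "setA"),
  .fixture_case("dinitrobenzene_13",
    c("O=[N+]([O-])c1cccc([N+](=O)[O-])c1",
      "O=[N+]([O-])C1=CC=CC(=C1)[N+](=O)[O-]"),
    c(nitro = 2L, nitro_aromatic = 2L, pt_pnictogens = 2L),
    expected_zero = "nitro_aliphatic",
    label = "setA"),
  .fixture_case("pyrrole",
    c("c1cc[nH]c1", "C1=CC=CN1"),
    c(hs_ar5_1n = 1L, ls_ar5_h1 = 1L, heterocyclic_compound = 1L,
      aromatic_compound = 5L, pt_pnictogens = 1L),
    expected_zero = c("hs_ar5_1o", "hs_ar5_1s", "nitro")),
  .fixture_case("furan",
    c("c1ccoc1", "C1=CC=CO1"),
    c(hs_ar5_1o = 1L, ls_ar5_h1 = 1L, heterocyclic_compound = 1L),
    expected_zero = c("hs_ar5_1n", "pt_pnictogens")),
  .fixture_case("thiophene",
    c("c1ccsc1", "C1=CC=CS1"),
    c(hs_ar5_1s = 1L, ls_ar5_h1 = 1L, pt_chalcogens = 1L),
    expected_zero = c("hs_ar5_1n", "hs_ar5_1o")),
  .fixture_case("indole",   # fused control: LS matches, HS must not
    c("c1ccc2c(c1)cc[nH]2", "C1=CC=C2C(=C1)C=CN2"),
    c(ls_ar5_h1 = 1L, heterocyclic_compound = 1L, aromatic_compound = 9L),
    expected_zero = c("hs_ar5_1n", "hs_ar5_1o", "hs_ar6_1n")),
  .fixture_case("aziridine",
    c("C1CN1", "N1CC1"),
    c(hs_st3_1n = 1L, ls_na3_h1 = 1L, sec_aliph_amine = 1L,
      heterocyclic_compound = 1L),
    expected_zero = c("hs_st3_1o", "aromatic_compound")),
  .fixture_case("oxetane",  # saturated 4-ring heterocycle
    c("C1COC1", "O1CCC1"),
    c(hs_st4_1o = 1L, ls_na4_h1 = 1L, dialkyl_ether = 1L),
    expected_zero = c("hs_st4_1n", "hs_st3_1o")),
  .fixture_case("trimethyl_phosphate",  # organophosphorus example
    c("COP(=O)(OC)OC", "P(=O)(OC)(OC)OC"),
    c(phosphoric_deriv = 1L, pt_pnictogens = 1L),
    expected_zero = c("nitro", "heterocyclic_compound")),
  .fixture_case("butane",
    c("CCCC", "C(C)CC"),
    expected_zero = c("nitro", "pt_pnictogens", "heterocyclic_compound",
                      "aromatic_compound", "alkene"),
    label = "setB"),
  .fixture_case("isobutane",
    c("CC(C)C", "C(C)(C)C"),
    expected_zero = c("nitro", "pt_pnictogens"),
    label = "setB"))

# substituents used to decorate extra nitroaromatic setA members
.nitroaryl_substituents <- c("C", "CC", "CCC", "C(C)C", "F", "Cl", "Br", "OC")

#' Generate the fixture collection
#'
#' Returns the core hand-curated cases plus `n_per_class` seeded variations
#' per label class: para-substituted nitrobenzenes for `setA` and linear
#' alkanes of varying length for `setB`. Deterministic for a given seed.
#'
#' @param seed integer seed controlling the sampled decorations.
#' @param n_per_class number of extra molecules per labeled class (>= 1).
#' @return an object of class `efg_fixtures`: a list of fixture cases, each
#'   with `mol_id`, `smiles_variants` (>= 2 equivalent spellings),
#'   `expected_nonzero`, `expected_zero`, `label`.
#' @export
generate_fixtures <- function(seed = 1L, n_per_class = 3L) {
  stopifnot(n_per_class >= 1L)
  cases <- .core_fixture_cases()
  rng <- local({ set.seed(seed); list(
    subs = sample(.nitroaryl_substituents, n_per_class, replace = n_per_class > length(.nitroaryl_substituents)),
    lens = sample(4:11, n_per_class, replace = n_per_class > 8L)) })
  for (i in seq_len(n_per_class)) {
    r <- rng$subs[i]
    cases[[length(cases) + 1L]] <- .fixture_case(
      paste0("nitroaryl_", i, "_", r),
      c(paste0("O=[N+]([O-])c1ccc(", r, ")cc1"),
        paste0("O=[N+]([O-])C1=CC=C(", r, ")C=C1")),
      c(nitro = 1L, nitro_aromatic = 1L),
      expected_zero = "nitro_aliphatic",
      label = "setA")
    len <- rng$lens[i]
    cases[[length(cases) + 1L]] <- .fixture_case(
      paste0("alkane_C", len, "_", i),
      c(strrep("C", len), paste0("C(C)", strrep("C", len - 2L))),
      expected_zero = c("nitro", "pt_pnictogens", "aromatic_compound"),
      label = "setB")
  }
  structure(cases, class = "efg_fixtures", seed = seed)
}

#' Molecule collection from fixtures
#'
#' @param fixtures an `efg_fixtures` object.
#' @param variant which SMILES spelling to use (1 = primary aromatic form,
#'   2 = alternate Kekulé/reordered form).
#' @param label optional filter: `"setA"`, `"setB"` or `"neutral"`.
#' @return an `efg_molecules` collection (not yet normalized); fixture
#'   labels are attached as `attr(, "label")`.
#' @export
fixture_molecules <- function(fixtures, variant = 1L, label = NULL) {
  stopifnot(inherits(fixtures, "efg_fixtures"))
  if (!is.null(label)) {
    fixtures <- Filter(function(cs) cs$label %in% label, fixtures)
    if (!length(fixtures)) stop("no fixture case carries label ", label)
  }
  smi <- vapply(fixtures, function(cs) {
    v <- min(variant, length(cs$smiles_variants))
    cs$smiles_variants[[v]]
  }, character(1))
  mols <- efg_molecules(smi, mol_id = vapply(fixtures, `[[`, character(1), "mol_id"))
  attr(mols, "label") <- vapply(fixtures, `[[`, character(1), "label")
  mols
}

#' @export
print.efg_fixtures <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat("efg_fixtures:", length(x), "cases (seed ", attr(x, "seed"), "); ",
      paste(names(table(labs)), table(labs), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
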