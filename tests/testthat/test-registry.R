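# Registry loading, validation, taxonomy structure and periodic-table
# pattern construction.

test_that("shipped registry has the documented composition and all patterns compile", {
  reg <- efg_registry()
  st <- validate_registry(reg)
  expect_equal(st$total_count, 583L)
  expect_equal(unname(st$per_category[["checkmol_base"]]), 200L)
  expect_equal(nrow(st$invalid_entries), 0L)
  expect_equal(st$total_count, sum(st$per_category))
  expect_equal(st$total_count, sum(st$per_specificity))
  expect_false(anyDuplicated(reg$group_id) > 0)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("shipped registry file matches the programmatic build", {
  expect_identical(as.data.frame(efg_registry()),
                   as.data.frame(build_default_registry()))
})

test_that("validate_registry on an empty collection returns zeroed stats", {
  st <- validate_registry(efg_registry()[0, ])
  expect_equal(st$total_count, 0L)
  expect_equal(nrow(st$invalid_entries), 0L)
})

test_that("validate_registry reports uncompilable SMARTS without throwing", {
  reg <- efg_registry()[1:3, ]
  reg$smarts[2] <- "C("
  st <- validate_registry(reg)
  expect_equal(st$total_count, 3L)
  expect_equal(st$invalid_entries$group_id, reg$group_id[2])
})

test_that("load_registry round-trips a registry file in order", {
  reg <- efg_registry()[c(5, 1, 9), ]
  path <- tempfile(fileext = ".tsv")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_equal(back$group_id, reg$group_id)  # file order preserved
  expect_equal(back$smarts, reg$smarts)
})

test_that("load_registry rejects malformed registries, naming the offender", {
  expect_error(load_registry(tempfile()), "not found")

  write_bad <- function(rows) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("group_id", "name", "smarts", "category",
                         "specificity", "ls_parent", "notes"), collapse = "\t"),
                 rows), path)
    path
  }
  bad_smarts <- write_bad("grpX\tGroup X\tC(\tcheckmol_base\tnot_applicable\t\t")
  expect_error(load_registry(bad_smarts), "grpX")

  dup <- write_bad(c("a\tA\tC\tcheckmol_base\tnot_applicable\t\t",
                     "a\tA2\tN\tcheckmol_base\tnot_applicable\t\t"))
  expect_error(load_registry(dup), "duplicate group_id")

  dangling <- write_bad("pyr\tPyrrole (HS)\t[nX3]1cccc1\theterocycle\tHS\tnowhere\t")
  expect_error(load_registry(dangling), "dangling")

  # HS entry whose parent exists and is LS loads fine
  ok <- write_bad(c("arom5\tLS 5-ring\t[a;!#6]1cccc1\theterocycle\tLS\t\t",
                    "pyr\tPyrrole (HS)\t[nx2]1cccc1\theterocycle\tHS\tarom5\t"))
  expect_silent(reg <- load_registry(ok))
  expect_equal(nrow(reg), 2L)
})

test_that("HS->LS references form a one-level forest over the shipped registry", {
  reg <- efg_registry()
  hs <- reg[reg$specificity == "HS", ]
  expect_true(all(hs$ls_parent %in% reg$group_id))
  parents <- reg[match(hs$ls_parent, reg$group_id), ]
  expect_true(all(parents$specificity == "LS"))
  expect_true(all(is.na(parents$ls_parent)))  # no chains, hence no cycles
  expect_true(all(reg$specificity[reg$category == "periodic_group"] ==
                    "not_applicable"))
})

test_that("hs_entries_of returns the HS children of an LS class", {
  reg <- efg_registry()
  kids <- hs_entries_of("ls_ar5_h1", reg)
  expect_setequal(kids$name, c("Pyrrole (HS)", "Furan (HS)", "Thiophene (HS)"))
  # an LS class with no children
  lonely <- reg[reg$specificity == "LS", ]
  childless <- setdiff(lonely$group_id, reg$ls_parent[!is.na(reg$ls_parent)])
  if (length(childless))
    expect_equal(nrow(hs_entries_of(childless[1], reg)), 0L)
  expect_error(hs_entries_of("hs_ar5_1n", reg), "not a low-specificity")
  expect_error(hs_entries_of("no_such_group", reg), "not found")
})

test_that("periodic-group patterns match element containment, any state", {
  pn <- build_periodic_group_pattern(c("N", "P", "As", "Sb", "Bi"), "Pnictogens")
  mols <- normalize_molecules(efg_molecules(
    c("c1ccncc1", "c1ccc(cc1)P(c1ccccc1)c1ccccc1", "c1ccccc1", "C[Si](C)(C)C", "C"),
    mol_id = c("pyridine", "tpp", "benzene", "tms", "methane")))
  counts <- profile_collection(mols, pn)[, 1]
  expect_true(counts[["pyridine"]] > 0)
  expect_true(counts[["tpp"]] > 0)
  expect_equal(counts[["benzene"]], 0L)

  si <- build_periodic_group_pattern("Si", "Silicon compounds")
  si_counts <- profile_collection(mols, si)[, 1]
  expect_equal(si_counts[["tms"]], 1L)
  expect_equal(si_counts[["methane"]], 0L)

  expect_error(build_periodic_group_pattern(c("N", "Xx"), "bad"), "Xx")
  expect_error(build_periodic_group_pattern(character(0), "none"), "non-empty")
})

test_that("metalloid containment agrees with a lexical scan of the atom list", {
  met_elements <- c("B", "Si", "Ge", "As", "Sb", "Te")
  met <- build_periodic_group_pattern(met_elements, "Metalloids")
  smis <- c(boric_acid = "OB(O)O", ethanol = "CCO", tms = "C[Si](C)(C)C",
            arsine = "[AsH3]", toluene = "Cc1ccccc1")
  mols <- normalize_molecules(efg_molecules(smis, mol_id = names(smis)))
  got <- profile_collection(mols, met)[, 1] > 0
  # independent check: scan element tokens lexically in the input SMILES
  expected <- vapply(smis, function(s) {
    x <- gsub("\\[|\\]", "", s)
    toks <- regmatches(x, gregexpr("[A-Z][a-z]?", x))[[1]]
    any(toks %in% met_elements)
  }, logical(1))
  expect_equal(unname(got), unname(expected))
})

test_that("periodic patterns are aromaticity-invariant", {
  pn <- build_periodic_group_pattern(c("N", "P", "As", "Sb", "Bi"), "Pnictogens")
  arom <- normalize_molecules(efg_molecules("c1cc[nH]c1", "m"))
  kek <- normalize_molecules(efg_molecules("C1=CC=CN1", "m"))
  expect_equal(profile_collection(arom, pn), profile_collection(kek, pn))
})
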