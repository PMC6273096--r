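# Occurrence counting semantics, profiles and descriptor matrices.

reg_slice <- function(reg, ids) reg[match(ids, reg$group_id), ]

test_that("nitro occurrences split correctly by attachment environment", {
  b <- test_fixture_bundle()
  p <- b$prof1
  expect_equal(unname(p["nitrobenzene", c("nitro", "nitro_aromatic", "nitro_aliphatic")]),
               c(1L, 1L, 0L))
  expect_equal(unname(p["nitromethane", c("nitro", "nitro_aromatic", "nitro_aliphatic")]),
               c(1L, 0L, 1L))
  expect_equal(unname(p["dinitrobenzene_13", "nitro"]), 2L)
})

test_that("the nitro partition is exact on carbon-attached nitro molecules", {
  b <- test_fixture_bundle()
  p <- b$prof1
  expect_equal(p[, "nitro_aromatic"] + p[, "nitro_aliphatic"], p[, "nitro"])
})

test_that("HS patterns reject ring fusion while LS parents tolerate it", {
  b <- test_fixture_bundle()
  p <- b$prof1
  for (m in c("pyrrole", "furan", "thiophene")) {
    hs <- c(pyrrole = "hs_ar5_1n", furan = "hs_ar5_1o", thiophene = "hs_ar5_1s")[[m]]
    expect_equal(unname(p[m, hs]), 1L)
    expect_equal(unname(p[m, "ls_ar5_h1"]), 1L)
  }
  expect_equal(unname(p["indole", "hs_ar5_1n"]), 0L)
  expect_equal(unname(p["indole", "ls_ar5_h1"]), 1L)
})

test_that("HS occurrence implies LS-parent occurrence across all fixtures", {
  b <- test_fixture_bundle()
  hs <- b$reg[b$reg$specificity == "HS", ]
  present_hs <- b$prof1[, hs$group_id, drop = FALSE] > 0
  present_parent <- b$prof1[, hs$ls_parent, drop = FALSE] > 0
  expect_true(all(!present_hs | present_parent))
})

test_that("an ethanol profile is nonzero exactly on the expected families", {
  b <- test_fixture_bundle()
  eth <- normalize_molecules(efg_molecules("CCO", "ethanol"))
  p <- profile(eth, b$reg)
  expect_true(all(p[c("hydroxy", "alcohol", "prim_alcohol", "pt_chalcogens")] > 0))
  ngroups <- c("nitro", "amine", "pt_pnictogens", "nitrile", "carboxamide")
  expect_true(all(p[ngroups] == 0))
  # and nothing nitrogenous anywhere: groups containing N cannot match
  expect_equal(unname(p["heterocyclic_compound"]), 0L)
})

test_that("an atom-free molecule yields the all-zero profile", {
  b <- test_fixture_bundle()
  empty <- normalize_molecules("")
  p <- profile(empty, b$reg)
  expect_equal(sum(p), 0L)
  expect_length(p, nrow(b$reg))
})

test_that("profiles are invariant to input atom ordering", {
  b <- test_fixture_bundle()
  # variant 2 uses different atom orders / ring writings throughout
  expect_identical(b$prof1, b$prof2)
  # and an explicit scramble of one molecule
  v1 <- normalize_molecules(efg_molecules("O=[N+]([O-])c1ccc(Cl)cc1", "m"))
  v2 <- normalize_molecules(efg_molecules("Clc1ccc(cc1)[N+](=O)[O-]", "m"))
  expect_equal(profile(v1, b$reg), profile(v2, b$reg))
})

test_that("descriptor matrices have registry shape, order and modes", {
  b <- test_fixture_bundle()
  three <- b$mols1[1:3, ]
  mat <- profile_collection(three, b$reg)
  expect_equal(dim(mat), c(3L, 583L))
  expect_equal(rownames(mat), three$mol_id)
  expect_equal(colnames(mat), b$reg$group_id)
  expect_true(all(mat >= 0L))

  bin <- profile_collection(three, b$reg, mode = "binary")
  expect_equal(unname(bin), unname((mat > 0L) + 0L), ignore_attr = TRUE)

  one <- profile_collection(b$mols1[1, ], b$reg)
  expect_equal(one[1, ], unclass(profile(b$mols1[1, ], b$reg)),
               ignore_attr = TRUE)
})

test_that("count_occurrences requires normalized records", {
  raw <- efg_molecules("c1ccccc1", "benzene")
  expect_error(count_occurrences(raw, "[a]"), "normalized")
  expect_error(profile_collection(raw, efg_registry()[1:2, ]), "normalized")
})

test_that("counts equal RDKit subgraph enumeration on small fixture molecules", {
  b <- test_fixture_bundle()
  heavy <- vapply(b$mols1$smiles, lexical_heavy_atoms, integer(1))
  small <- b$mols1[heavy <= 12L, ]
  got <- b$prof1[small$mol_id, , drop = FALSE]
  oracle <- rdkit_count_matrix(small$smiles, small$mol_id,
                               b$reg$smarts, b$reg$group_id)
  expect_false(anyNA(oracle))
  expect_equal(unname(got), unname(oracle[rownames(got), colnames(got)]))
})

test_that("profile matrices write to CSV with mol_id first", {
  b <- test_fixture_bundle()
  path <- tempfile(fileext = ".csv")
  write_profile_matrix(b$prof1[1:2, 1:5], path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(back)[1], "mol_id")
  expect_equal(back$mol_id, rownames(b$prof1)[1:2])
  expect_equal(as.integer(as.matrix(back[, -1])), as.integer(b$prof1[1:2, 1:5]))
})
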