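# Hypergeometric statistics, enrichment factors and two-set comparison.

test_that("hypergeometric tail handles the boundary cases exactly", {
  expect_equal(hypergeom_tail(5, 20, 5, 20), 1)    # k = n, K = N: certain
  expect_equal(hypergeom_tail(0, 7, 4, 20), 1)     # P(X >= 0) = 1
  # frozen exact value: P(X >= 3), N=20, K=5, n=5 = 1126/15504
  expect_equal(hypergeom_tail(3, 5, 5, 20), 1126 / 15504, tolerance = 1e-14)
  expect_error(hypergeom_tail(-1, 5, 5, 20), "non-negative")
  expect_error(hypergeom_tail(3, 25, 5, 20), "population")
  expect_error(hypergeom_tail(6, 5, 5, 20), "min")
})

test_that("hypergeometric tail matches exact rational summation on a random sweep", {
  set.seed(7)
  n_cases <- 2000L
  N <- sample(1:60, n_cases, replace = TRUE)
  K <- vapply(N, function(x) sample.int(x + 1L, 1L) - 1L, integer(1))
  n <- vapply(N, function(x) sample.int(x + 1L, 1L) - 1L, integer(1))
  k <- vapply(pmin(n, K), function(x) sample.int(x + 1L, 1L) - 1L, integer(1))
  exact <- exact_hypergeom_oracle(k, K, n, N)
  mine <- hypergeom_tail(k, K, n, N)
  rel <- abs(mine - exact) / pmax(exact, .Machine$double.xmin)
  expect_lt(max(rel), 1e-12)
  # and the base-R implementation agrees too (independent second route)
  expect_equal(mine, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("increasing k weakly decreases the upper tail", {
  for (K in c(3L, 10L, 25L)) {
    p <- hypergeom_tail(0:min(12L, K), K, 12L, 40L)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("enrichment factors reproduce the worked prevalence example", {
  ef <- enrichment_factor(0.23, 0.055)
  expect_equal(round(ef, 1), 4.2)       # 23% vs 5.5% -> 4.2 at one decimal
  expect_equal(enrichment_factor(0.37, 0.37), 1)
  expect_equal(enrichment_factor(0.10, 0), Inf)
  expect_message(na_ef <- enrichment_factor(0, 0), "not computable")
  expect_true(is.na(na_ef))
  expect_error(enrichment_factor(1.2, 0.5), "\\[0, 1\\]")
})

test_that("p-value adjustment follows the BH step-up rule", {
  expect_equal(adjust_pvalues(0.02), 0.02)                  # single p unchanged
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))  # hand-derived
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_error(adjust_pvalues(c(0.5, 1.4)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(adjust_pvalues(p) >= p))
})

make_sets <- function() {
  subs <- c("C", "CC", "CCC", "F", "Cl", "Br", "OC", "O", "N", "C(C)C")
  a <- normalize_molecules(efg_molecules(
    paste0("O=[N+]([O-])c1ccc(", subs, ")cc1"),
    mol_id = paste0("nitroaryl", seq_along(subs))))
  b <- normalize_molecules(efg_molecules(
    vapply(4:13, function(n) strrep("C", n), character(1)),
    mol_id = paste0("alkane", 4:13)))
  list(a = a, b = b)
}

test_that("a planted nitro enrichment is recovered with the exact p-value", {
  sets <- make_sets()
  res <- compare_sets(sets$a, sets$b, efg_registry())
  top <- res[1, ]
  # nitro present in all 10 of A, none of B: p = 1/choose(20,10)
  nitro <- res[res$group_id == "nitro", ]
  expect_equal(nitro$direction, "over_in_A")
  expect_equal(nitro$k_A, 10L)
  expect_equal(nitro$k_B, 0L)
  expect_equal(nitro$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(nitro$p_value, min(res$p_value))   # nothing ranks above it
  expect_true(top$p_value <= res$p_value[nrow(res)])
  # groups absent from every molecule are excluded
  expect_false("hs_ar5_1o" %in% res$group_id)  # no furans anywhere
  expect_true(all(res$k_A + res$k_B > 0L))
})

test_that("comparing a set against itself finds nothing", {
  sets <- make_sets()
  res <- compare_sets(sets$a, sets$a, efg_registry())
  expect_true(all(res$enrichment_factor == 1))
  expect_true(all(res$p_adjusted > 0.05))
  expect_true(all(res$p_value > 0.5))  # tail at equal prevalence is >= 1/2-ish
})

test_that("swapping the sets mirrors directions and keeps p-values", {
  sets <- make_sets()
  ab <- compare_sets(sets$a, sets$b, efg_registry())
  ba <- compare_sets(sets$b, sets$a, efg_registry())
  m <- match(ab$group_id, ba$group_id)
  expect_false(anyNA(m))
  expect_equal(ab$p_value, ba$p_value[m])
  # equal-prevalence groups keep the over_in_A convention in both orderings
  tied <- ab$prevalence_A == ab$prevalence_B
  flipped <- ifelse(ab$direction == "over_in_A", "over_in_B", "over_in_A")
  expect_equal(ba$direction[m][!tied], flipped[!tied])
  expect_equal(ba$direction[m][tied], ab$direction[tied])
  expect_equal(ab$k_A, ba$k_B[m])
  expect_equal(ab$enrichment_factor, ba$enrichment_factor[m])
})

test_that("profile matrices are accepted directly and misalignment is caught", {
  sets <- make_sets()
  reg <- efg_registry()
  binA <- profile_collection(sets$a, reg, mode = "binary")
  binB <- profile_collection(sets$b, reg, mode = "binary")
  res_mat <- compare_sets(binA, binB, reg)
  res_mol <- compare_sets(sets$a, sets$b, reg)
  expect_equal(res_mat, res_mol)
  expect_error(compare_sets(binA, binB[, 1:10], reg), "misalignment")
  expect_error(compare_sets(binA[0, , drop = FALSE], binB, reg), "empty set")
})

test_that("reports carry the documented columns with one-decimal factors", {
  sets <- make_sets()
  res <- compare_sets(sets$a, sets$b, efg_registry())
  path <- tempfile(fileext = ".tsv")
  write_enrichment_report(res, path, top = 6)
  rep <- utils::read.delim(path)
  expect_equal(names(rep),
               c("group_id", "name", "direction", "k_A", "n_A", "k_B", "n_B",
                 "prevalence_A", "prevalence_B", "enrichment_factor",
                 "p_value", "p_adjusted"))
  expect_lte(sum(rep$direction == "over_in_A"), 6L)
  finite_ef <- rep$enrichment_factor[is.finite(rep$enrichment_factor)]
  expect_equal(finite_ef, round(finite_ef, 1))
})

test_that("null-distributed group assignments stay at the nominal error rate", {
  # 200 replicate comparisons x 20 independent pseudo-groups, presence
  # Bernoulli(0.5) regardless of the set label; direction A tested per group
  set.seed(11)
  n_rep <- 200L; n_groups <- 20L; n_side <- 50L
  kA <- rbinom(n_rep * n_groups, n_side, 0.5)
  kB <- rbinom(n_rep * n_groups, n_side, 0.5)
  p <- hypergeom_tail(kA, kA + kB, n_side, 2L * n_side)
  fpr <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lte(fpr, 0.05 + 3 * se)
})
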