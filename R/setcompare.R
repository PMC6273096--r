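#' @title Two-set enrichment analysis
#' @description
#' Given two labeled compound sets (e.g. assay-active vs. inactive), every
#' registry group is ranked by overrepresentation. For a group present in
#' `k_A` of `n_A` set-A molecules and `k_B` of `n_B` set-B molecules, the
#' p-value is the exact hypergeometric upper-tail probability of drawing at
#' least `k_A` group-containing molecules in a sample of `n_A` from the
#' pooled population of `N = n_A + n_B` molecules of which `K = k_A + k_B`
#' contain the group (and symmetrically for overrepresentation in B).
#' Presence, not occurrence count, defines `k`: prevalences are fractions of
#' compounds. The enrichment factor is the ratio of the two prevalences,
#' oriented so that it is >= 1.
#' @name efg-setcompare
NULL

#' Exact hypergeometric upper-tail probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (population `N`,
#' `K` marked, sample size `n`) by direct log-space summation of the
#' probability mass function (log-factorials via `lchoose`, accumulated with
#' log-sum-exp). No normal approximation is involved, so the tail is exact
#' to floating-point accuracy for populations well beyond 1e5.
#'
#' @param k observed successes in the sample (vectorized).
#' @param K successes in the population.
#' @param n sample size.
#' @param N population size.
#' @return `P(X >= k)`, in `[0, 1]`.
#' @examples
#' hypergeom_tail(3, 5, 5, 20)   # 1126/15504
#' @export
hypergeom_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)  # recycles
  k <- args[, "k"]; K <- args[, "K"]; n <- args[, "n"]; N <- args[, "N"]
  if (any(args < 0L) || any(args != floor(args)))
    stop("all arguments must be non-negative integers")
  if (any(n > N) || any(K > N))
    stop("sample size and marked count cannot exceed the population size")
  if (any(k > pmin(n, K)))
    stop("k cannot exceed min(n, K)")
  vapply(seq_along(k), function(i) {
    if (k[i] <= max(0L, n[i] + K[i] - N[i])) return(1)  # certain event
    x <- k[i]:min(n[i], K[i])
    lt <- lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) - lchoose(N[i], n[i])
    m <- max(lt)
    min(1, exp(m + log(sum(exp(lt - m)))))
  }, numeric(1))
}

#' Prevalence ratio between two sets
#'
#' @param prevalence_a,prevalence_b group prevalences (fractions of
#'   compounds containing the group) in the two sets.
#' @return `prevalence_a / prevalence_b`; `Inf` when only `prevalence_b` is
#'   zero; `NA` (not computable) when both are zero.
#' @examples
#' enrichment_factor(0.23, 0.055)          # 4.18...; reported as 4.2
#' round(enrichment_factor(0.23, 0.055), 1)
#' @export
enrichment_factor <- function(prevalence_a, prevalence_b) {
  if (any(c(prevalence_a, prevalence_b) < 0, na.rm = TRUE) ||
      any(c(prevalence_a, prevalence_b) > 1, na.rm = TRUE))
    stop("prevalences must lie in [0, 1]")
  out <- ifelse(prevalence_a == 0 & prevalence_b == 0, NA_real_,
                prevalence_a / prevalence_b)
  if (anyNA(out)) message("enrichment factor not computable where both prevalences are zero")
  out
}

#' Multiplicity adjustment for p-values
#'
#' Benjamini-Hochberg step-up adjustment by default; Bonferroni available.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

# presence counts per group from either a molecule collection or a
# precomputed profile/indicator matrix with group_id columns
.presence_counts <- function(x, groups) {
  if (inherits(x, "efg_molecules")) {
    mat <- profile_collection(x, groups, mode = "binary")
  } else if (is.matrix(x)) {
    if (is.null(colnames(x)))
      stop("profile matrices must carry group_id column names")
    mat <- (x > 0) + 0L
  } else stop("sets must be efg_molecules collections or profile matrices")
  list(k = colSums(mat), n = nrow(mat))
}

#' Compare two compound sets by group overrepresentation
#'
#' Ranks registry groups by their one-sided exact hypergeometric p-value for
#' overrepresentation, tested in each direction separately; each group is
#' reported with the direction of its higher prevalence. Groups absent from
#' both sets are excluded. Benjamini-Hochberg adjustment is applied within
#' each reported direction (raw p-values are always retained).
#'
#' @param set_a,set_b normalized `efg_molecules` collections (or profile
#'   matrices with `group_id` columns, e.g. from [profile_collection()]).
#' @param groups an `efg_registry`.
#' @param adjust multiplicity-adjustment method passed to [adjust_pvalues()].
#' @return a data.frame of class `efg_enrichment`, sorted by ascending
#'   adjusted then raw p-value, with columns `group_id`, `name`,
#'   `direction`, `k_A`, `n_A`, `k_B`, `n_B`, `prevalence_A`,
#'   `prevalence_B`, `enrichment_factor`, `p_value`, `p_adjusted`.
#' @export
compare_sets <- function(set_a, set_b, groups = efg_registry(),
                         adjust = "BH") {
  a <- .presence_counts(set_a, groups)
  b <- .presence_counts(set_b, groups)
  if (a$n == 0L || b$n == 0L) stop("empty set: both sets must be non-empty")
  if (!identical(names(a$k), names(b$k)))
    stop("registry/profile misalignment between the two sets")
  keep <- which(a$k + b$k > 0L)
  if (!length(keep))
    return(.empty_enrichment())
  k_A <- a$k[keep]; k_B <- b$k[keep]
  n_A <- a$n; n_B <- b$n
  N <- n_A + n_B; K <- k_A + k_B
  prev_A <- k_A / n_A; prev_B <- k_B / n_B
  over_A <- prev_A >= prev_B
  p <- ifelse(over_A,
              hypergeom_tail(k_A, K, n_A, N),
              hypergeom_tail(k_B, K, n_B, N))
  direction <- ifelse(over_A, "over_in_A", "over_in_B")
  ef <- ifelse(over_A,
               suppressMessages(enrichment_factor(prev_A, prev_B)),
               suppressMessages(enrichment_factor(prev_B, prev_A)))
  p_adj <- p
  for (d in unique(direction))
    p_adj[direction == d] <- adjust_pvalues(p[direction == d], method = adjust)
  idx <- match(names(k_A), groups$group_id)
  out <- data.frame(group_id = groups$group_id[idx], name = groups$name[idx],
                    direction = direction, k_A = as.integer(k_A), n_A = n_A,
                    k_B = as.integer(k_B), n_B = n_B,
                    prevalence_A = prev_A, prevalence_B = prev_B,
                    enrichment_factor = ef, p_value = p, p_adjusted = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$p_value, out$group_id), ]
  rownames(out) <- NULL
  class(out) <- c("efg_enrichment", "data.frame")
  out
}

.empty_enrichment <- function() {
  out <- data.frame(group_id = character(0), name = character(0),
                    direction = character(0), k_A = integer(0), n_A = integer(0),
                    k_B = integer(0), n_B = integer(0),
                    prevalence_A = numeric(0), prevalence_B = numeric(0),
                    enrichment_factor = numeric(0), p_value = numeric(0),
                    p_adjusted = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("efg_enrichment", "data.frame")
  out
}

#' Write an enrichment report
#'
#' Tab-separated report with the standard column set; enrichment factors are
#' rounded to one decimal place in the report (the returned object keeps full
#' precision). By default the six most significant groups per direction are
#' written.
#'
#' @param res an `efg_enrichment` result.
#' @param path output TSV path.
#' @param top number of top-ranked groups to keep per direction
#'   (`Inf` for all).
#' @param alpha if non-`NULL`, additionally restrict to `p_adjusted <= alpha`.
#' @return the written subset, invisibly.
#' @export
write_enrichment_report <- function(res, path, top = 6L, alpha = NULL) {
  parts <- lapply(split(res, res$direction), function(d)
    utils::head(d[order(d$p_adjusted, d$p_value), ], top))
  rep <- do.call(rbind, parts)
  if (!is.null(alpha)) rep <- rep[rep$p_adjusted <= alpha, , drop = FALSE]
  rep <- rep[order(rep$p_adjusted, rep$p_value), ]
  rep$enrichment_factor <- round(rep$enrichment_factor, 1)
  rep$prevalence_A <- signif(rep$prevalence_A, 4)
  rep$prevalence_B <- signif(rep$prevalence_B, 4)
  rep$p_value <- signif(rep$p_value, 4)
  rep$p_adjusted <- signif(rep$p_adjusted, 4)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rep)
}

#' @export
print.efg_enrichment <- function(x, top = 6L, ...) {
  cat("EFG set comparison:", nrow(x), "group(s) tested\n")
  for (d in c("over_in_A", "over_in_B")) {
    sub <- x[x$direction == d, ]
    if (!nrow(sub)) next
    cat("\n", d, "(top ", min(top, nrow(sub)), "):\n", sep = "")
    sub <- utils::head(sub, top)
    print(data.frame(group = sub$group_id,
                     k_A = sub$k_A, k_B = sub$k_B,
                     EF = round(sub$enrichment_factor, 1),
                     p = signif(sub$p_value, 3),
                     p_adj = signif(sub$p_adjusted, 3)))
  }
  invisible(x)
}
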