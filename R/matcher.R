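#' @title Occurrence counting and descriptor matrices
#' @description
#' A group's occurrence count in a molecule is the number of *distinct
#' matched atom sets* of its SMARTS pattern: symmetry-equivalent mappings
#' onto the same atoms count once (benzene contains one aromatic ring, not
#' twelve), while overlapping matches on different atom sets all count
#' (1,3-dinitrobenzene contains two nitro groups). Counts are computed on
#' the normalized structure only and are invariant to input atom order and
#' aromaticity dialect.
#' @name efg-matcher
NULL

# OBMol references for a vector of (normalized) SMILES; empty molecules are
# NA and handled by the callers
.obmols <- function(smiles) {
  lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    ChemmineOB::forEachMol("SMI", paste0(s, " m\n"), identity)[[1]]
  })
}

.check_normalized <- function(mols) {
  if (!inherits(mols, "efg_molecules"))
    stop("expected an efg_molecules collection")
  if (!all(mols$normalized))
    stop("records must be normalized first (see normalize_molecules): ",
         paste(utils::head(mols$mol_id[!mols$normalized], 5L), collapse = ", "))
  invisible(mols)
}

#' Count occurrences of one group in one molecule
#'
#' @param record a one-row normalized `efg_molecules` collection.
#' @param group a one-row `efg_registry` slice (or a bare SMARTS string).
#' @return non-negative integer: the number of distinct matched atom sets.
#' @examples
#' \donttest{
#' m <- normalize_molecules("O=[N+]([O-])c1ccccc1")
#' count_occurrences(m, efg_registry()[efg_registry()$group_id == "nitro", ])
#' }
#' @export
count_occurrences <- function(record, group) {
  .check_normalized(record)
  stopifnot(nrow(record) == 1L)
  smarts <- if (is.character(group)) group else group$smarts
  stopifnot(length(smarts) == 1L)
  ob <- .obmols(record$smiles)[[1]]
  if (is.null(ob)) return(0L)
  as.integer(ChemmineOB::smartsSearch_OB(list(ob), smarts, uniqueMatches = TRUE))
}

#' Group-count profile of a single molecule
#'
#' @param record a one-row normalized `efg_molecules` collection.
#' @param groups an `efg_registry`.
#' @return named integer vector of occurrence counts in registry order, with
#'   attributes `mol_id` and class `efg_profile`.
#' @export
profile <- function(record, groups = efg_registry()) {
  .check_normalized(record)
  stopifnot(nrow(record) == 1L)
  mat <- profile_collection(record, groups, mode = "counts")
  out <- mat[1L, ]
  attr(out, "mol_id") <- record$mol_id
  class(out) <- "efg_profile"
  out
}

#' @export
print.efg_profile <- function(x, ...) {
  cat("EFG profile for", attr(x, "mol_id"), "-", sum(x > 0), "group(s) present\n")
  nz <- unclass(x)[x > 0]
  print(nz)
  invisible(x)
}

#' Descriptor matrix for a molecule collection
#'
#' Computes the full molecules x groups occurrence-count matrix (or its
#' presence/absence indicator). Row order follows the input collection,
#' column order the registry.
#'
#' @param records a normalized `efg_molecules` collection.
#' @param groups an `efg_registry`.
#' @param mode `"counts"` or `"binary"` (counts thresholded at > 0).
#' @return integer matrix with `mol_id` rownames, `group_id` colnames and a
#'   `mode` attribute.
#' @export
profile_collection <- function(records, groups = efg_registry(),
                               mode = c("counts", "binary")) {
  mode <- match.arg(mode)
  .check_normalized(records)
  obs <- .obmols(records$smiles)
  live <- !vapply(obs, is.null, logical(1))
  mat <- matrix(0L, nrow = nrow(records), ncol = nrow(groups),
                dimnames = list(records$mol_id, groups$group_id))
  if (any(live)) {
    obs_live <- obs[live]
    for (j in seq_len(nrow(groups))) {
      cnt <- try(ChemmineOB::smartsSearch_OB(obs_live, groups$smarts[j],
                                             uniqueMatches = TRUE),
                 silent = TRUE)
      if (inherits(cnt, "try-error"))
        stop("matching failed for group '", groups$group_id[j], "': ",
             attr(cnt, "condition")$message)
      mat[live, j] <- as.integer(cnt)
    }
  }
  if (mode == "binary") mat[] <- as.integer(mat > 0L)
  attr(mat, "mode") <- mode
  mat
}

#' Write a descriptor matrix as CSV
#'
#' Header row of group ids, first column `mol_id`.
#'
#' @param mat matrix from [profile_collection()].
#' @param path output file.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(mat, path, sep = ",") {
  df <- data.frame(mol_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
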