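#' @title EFG pattern registry
#' @description
#' The registry is an ordered table of functional-group definitions. Each row
#' is one group: a stable `group_id`, a human-readable `name`, a SMARTS
#' pattern, a `category` (`checkmol_base`, `reactivity_extension`,
#' `heterocycle`, or `periodic_group`), a `specificity` flag (`HS`, `LS`, or
#' `not_applicable`) and, for HS entries, the `ls_parent` group_id of the
#' low-specificity generalization.
#' @name efg-registry
NULL

.efg_categories    <- c("checkmol_base", "reactivity_extension", "heterocycle", "periodic_group")
.efg_specificities <- c("HS", "LS", "not_applicable")
.registry_columns  <- c("group_id", "name", "smarts", "category", "specificity", "ls_parent", "notes")

#' Construct a functional-group record
#'
#' @param group_id stable short identifier, unique within a registry.
#' @param name human-readable group name, unique within a registry.
#' @param smarts SMARTS pattern string.
#' @param category one of `"checkmol_base"`, `"reactivity_extension"`,
#'   `"heterocycle"`, `"periodic_group"`.
#' @param specificity `"HS"`, `"LS"` or `"not_applicable"`.
#' @param ls_parent for HS entries, the `group_id` of the LS generalization;
#'   `NA` otherwise.
#' @param notes free-text annotation.
#' @return a one-row `data.frame` with class `efg_registry`.
#' @examples
#' functional_group("nitro_general", "Nitro group",
#'   "[$([NX3](=[OX1])=[OX1]),$([NX3+](=[OX1])[OX1-])]", "checkmol_base")
#' @export
functional_group <- function(group_id, name, smarts, category,
                             specificity = "not_applicable",
                             ls_parent = NA_character_, notes = "") {
  stopifnot(is.character(group_id), length(group_id) == 1L, nzchar(group_id))
  if (!category %in% .efg_categories)
    stop("unknown category '", category, "' for group '", group_id, "'")
  if (!specificity %in% .efg_specificities)
    stop("unknown specificity '", specificity, "' for group '", group_id, "'")
  df <- data.frame(group_id = group_id, name = name, smarts = smarts,
                   category = category, specificity = specificity,
                   ls_parent = if (is.na(ls_parent) || !nzchar(ls_parent)) NA_character_ else ls_parent,
                   notes = notes, stringsAsFactors = FALSE)
  class(df) <- c("efg_registry", "data.frame")
  df
}

as_registry <- function(df) {
  stopifnot(all(.registry_columns %in% names(df)))
  df <- as.data.frame(df)[, .registry_columns]
  rownames(df) <- NULL
  df$ls_parent[!is.na(df$ls_parent) & !nzchar(df$ls_parent)] <- NA_character_
  class(df) <- c("efg_registry", "data.frame")
  df
}

#' Test whether a SMARTS pattern compiles under the matching engine
#'
#' @param smarts character vector of SMARTS strings.
#' @return logical vector; `FALSE` where the engine rejects the pattern.
#' @export
smarts_compiles <- function(smarts) {
  probe <- .probe_molecule()
  vapply(smarts, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    !inherits(try(ChemmineOB::smartsSearch_OB(probe, s, uniqueMatches = TRUE),
                  silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

# one-atom OBMol kept for pattern compilation checks
.probe_molecule <- function() {
  if (is.null(.efg_env$probe))
    .efg_env$probe <- ChemmineOB::forEachMol("SMI", "C probe\n", identity)
  .efg_env$probe
}

# structural integrity checks shared by load_registry() and the shipped build.
# Throws on first violation; `origin` names the offending source in messages.
assert_registry <- function(reg, origin = "registry") {
  dup <- reg$group_id[duplicated(reg$group_id)]
  if (length(dup))
    stop(origin, ": duplicate group_id: ", paste(unique(dup), collapse = ", "))
  dupn <- reg$name[duplicated(reg$name)]
  if (length(dupn))
    stop(origin, ": duplicate name: ", paste(unique(dupn), collapse = ", "))
  bad <- !reg$category %in% .efg_categories
  if (any(bad))
    stop(origin, ": unknown category for: ", paste(reg$group_id[bad], collapse = ", "))
  bad <- !reg$specificity %in% .efg_specificities
  if (any(bad))
    stop(origin, ": unknown specificity for: ", paste(reg$group_id[bad], collapse = ", "))
  bad <- reg$category == "periodic_group" & reg$specificity != "not_applicable"
  if (any(bad))
    stop(origin, ": periodic_group entries must have specificity not_applicable: ",
         paste(reg$group_id[bad], collapse = ", "))
  # HS entries must reference an existing LS parent; the HS->LS graph is a
  # one-level forest, so a parent must itself be parentless.
  hs <- reg[reg$specificity == "HS", , drop = FALSE]
  if (any(is.na(hs$ls_parent)))
    stop(origin, ": HS entry without ls_parent: ",
         paste(hs$group_id[is.na(hs$ls_parent)], collapse = ", "))
  missing <- setdiff(hs$ls_parent, reg$group_id)
  if (length(missing))
    stop(origin, ": dangling ls_parent reference(s): ",
         paste(missing, collapse = ", "))
  parent_spec <- reg$specificity[match(hs$ls_parent, reg$group_id)]
  if (any(parent_spec != "LS"))
    stop(origin, ": ls_parent of ", paste(hs$group_id[parent_spec != "LS"], collapse = ", "),
         " is not an LS entry")
  ok <- smarts_compiles(reg$smarts)
  if (!all(ok))
    stop(origin, ": SMARTS failed to compile for: ",
         paste(reg$group_id[!ok], collapse = ", "))
  invisible(reg)
}

#' Load a functional-group registry from a file
#'
#' Reads a UTF-8 tab-separated registry file with columns `group_id`, `name`,
#' `smarts`, `category`, `specificity`, `ls_parent`, `notes`. Lines starting
#' with `#` are comments (the `#` triple-bond symbol inside SMARTS is
#' untouched). All structural invariants are enforced: unique ids and names,
#' valid category/specificity values, every SMARTS compiling, and every HS
#' entry pointing at an existing LS parent. Any violation is an error naming
#' the offending entry.
#'
#' @param path path to the registry file.
#' @return an `efg_registry` data.frame in file order.
#' @seealso [efg_registry()] for the shipped registry, [validate_registry()]
#'   for a non-throwing report.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("registry file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!identical(header, .registry_columns))
    stop("registry schema violation in ", path, ": expected columns ",
         paste(.registry_columns, collapse = ", "))
  fields <- fields[-1]
  n_bad <- which(lengths(fields) < 5L | lengths(fields) > 7L)
  if (length(n_bad))
    stop("registry schema violation in ", path, ": wrong field count on data line(s) ",
         paste(head(n_bad, 5), collapse = ", "))
  rows <- lapply(fields, function(f) c(f, rep("", 7L - length(f))))
  reg <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(reg) <- .registry_columns
  reg <- as_registry(reg)
  assert_registry(reg, origin = path)
  reg
}

#' Write a registry to a tab-separated file
#'
#' @param reg an `efg_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  out <- as.data.frame(reg)
  out$ls_parent[is.na(out$ls_parent)] <- ""
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# EFG functional-group registry (tab-separated; '#' lines are comments)", con)
  writeLines(paste(.registry_columns, collapse = "\t"), con)
  writeLines(do.call(paste, c(out[.registry_columns], sep = "\t")), con)
  invisible(path)
}

#' The shipped EFG registry
#'
#' Loads (and caches) the registry distributed with the package:
#' 583 patterns in total, of which 200 form the classical functional-group
#' base set, plus reactivity extensions, the HS/LS heterocycle taxonomy and
#' periodic-table element categories.
#'
#' @return an `efg_registry` data.frame with 583 rows.
#' @examples
#' \donttest{
#' reg <- efg_registry()
#' nrow(reg)
#' table(reg$category)
#' }
#' @export
efg_registry <- function() {
  if (is.null(.efg_env$registry)) {
    path <- system.file("extdata", "efg_registry.tsv", package = "efgtools",
                        mustWork = TRUE)
    .efg_env$registry <- load_registry(path)
  }
  .efg_env$registry
}

#' Summarize and validate a registry without throwing
#'
#' Computes per-category and per-specificity pattern counts and compiles every
#' SMARTS, collecting failures instead of raising them.
#'
#' @param groups an `efg_registry` (possibly empty).
#' @return a list of class `efg_registry_stats`: `total_count`,
#'   `per_category` (named integer vector), `per_specificity`,
#'   `invalid_entries` (data.frame of `group_id`, `error`).
#' @export
validate_registry <- function(groups) {
  if (nrow(groups) == 0L) {
    out <- list(total_count = 0L,
                per_category = integer(0), per_specificity = integer(0),
                invalid_entries = data.frame(group_id = character(0),
                                             error = character(0)))
    class(out) <- "efg_registry_stats"
    return(out)
  }
  probe <- .probe_molecule()
  errs <- vapply(seq_len(nrow(groups)), function(i) {
    r <- try(ChemmineOB::smartsSearch_OB(probe, groups$smarts[i], uniqueMatches = TRUE),
             silent = TRUE)
    if (inherits(r, "try-error")) trimws(conditionMessage(attr(r, "condition"))) else NA_character_
  }, character(1))
  bad <- !is.na(errs)
  out <- list(
    total_count = nrow(groups),
    per_category = vapply(split(groups$group_id, factor(groups$category, .efg_categories)),
                          length, integer(1)),
    per_specificity = vapply(split(groups$group_id, factor(groups$specificity, .efg_specificities)),
                             length, integer(1)),
    invalid_entries = data.frame(group_id = groups$group_id[bad],
                                 error = errs[bad], stringsAsFactors = FALSE))
  class(out) <- "efg_registry_stats"
  out
}

#' @export
print.efg_registry_stats <- function(x, ...) {
  cat("EFG registry:", x$total_count, "patterns\n")
  for (cc in names(x$per_category))
    cat(sprintf("  %-22s %d\n", cc, x$per_category[[cc]]))
  cat("specificity:",
      paste(sprintf("%s=%d", names(x$per_specificity), x$per_specificity), collapse = ", "),
      "\n")
  if (nrow(x$invalid_entries))
    cat("INVALID entries:", paste(x$invalid_entries$group_id, collapse = ", "), "\n")
  else cat("all SMARTS compile\n")
  invisible(x)
}

#' High-specificity children of a low-specificity group
#'
#' @param ls_group a single `group_id` string or one-row registry slice with
#'   `specificity == "LS"`.
#' @param groups the registry to search (default: shipped registry).
#' @return the HS registry rows whose `ls_parent` is `ls_group` (possibly
#'   zero rows), in registry order.
#' @export
hs_entries_of <- function(ls_group, groups = efg_registry()) {
  id <- if (is.character(ls_group) && length(ls_group) == 1L) ls_group
        else if (is.data.frame(ls_group) && nrow(ls_group) == 1L) ls_group$group_id
        else stop("ls_group must be a single group_id or one-row registry slice")
  i <- match(id, groups$group_id)
  if (is.na(i)) stop("group '", id, "' not found in registry")
  if (groups$specificity[i] != "LS")
    stop("group '", id, "' is not a low-specificity (LS) entry")
  as_registry(groups[!is.na(groups$ls_parent) & groups$ls_parent == id, , drop = FALSE])
}
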