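#' @title Structure input and aromaticity normalization
#' @description
#' Substructure counts must not depend on how a structure was drawn or which
#' aromaticity dialect a SMILES uses. Every molecule is therefore brought to
#' one canonical state before matching: the structure is first written as a
#' Kekulé representation (explicit alternating bond orders; a MOL block by
#' definition) and then re-aromatized under a single aromaticity model
#' (OpenBabel's perception), producing a canonical aromatic SMILES. Matching
#' always runs on this normalized form, never on the raw input.
#' @name efg-normalize
NULL

.ob_noopts <- function() data.frame(names = character(0), args = character(0))

# single-record OB conversion; returns NA_character_ on parse failure
.ob_convert1 <- function(from, to, text) {
  out <- suppressWarnings(try(
    ChemmineOB::convertFormat(from, to, text, options = .ob_noopts()),
    silent = TRUE))
  if (inherits(out, "try-error") || !nzchar(trimws(out))) return(NA_character_)
  out
}

# first token of an OB "SMILES\tid" output line
.ob_smiles_of <- function(out) strsplit(trimws(out), "[ \t]+")[[1]][1]

#' Construct a molecule collection from SMILES strings
#'
#' @param smiles character vector of SMILES (the empty string denotes an
#'   empty, atom-free molecule).
#' @param mol_id identifiers; auto-generated (`mol1`, `mol2`, ...) when
#'   `NULL`. Collisions are resolved by suffixing (`id_2`, `id_3`, ...) with
#'   a message.
#' @param source_file,source_index provenance annotations.
#' @return an `efg_molecules` data.frame with columns `mol_id`, `input`,
#'   `smiles` (normalized form, `NA` until [normalize_molecules()] is
#'   called), `normalized`, `source_file`, `source_index`.
#' @export
efg_molecules <- function(smiles, mol_id = NULL, source_file = NA_character_,
                          source_index = seq_along(smiles)) {
  if (is.null(mol_id)) mol_id <- paste0("mol", seq_along(smiles))
  mol_id <- as.character(mol_id)
  blank <- !nzchar(mol_id)
  mol_id[blank] <- paste0("mol", which(blank))
  if (anyDuplicated(mol_id)) {
    tab <- ave(seq_along(mol_id), mol_id, FUN = seq_along)
    clash <- tab > 1L
    message("duplicate mol_id resolved by suffixing: ",
            paste(unique(mol_id[clash]), collapse = ", "))
    mol_id[clash] <- paste0(mol_id[clash], "_", tab[clash])
  }
  df <- data.frame(mol_id = mol_id, input = as.character(smiles),
                   smiles = NA_character_, normalized = FALSE,
                   source_file = source_file,
                   source_index = as.integer(source_index),
                   stringsAsFactors = FALSE)
  class(df) <- c("efg_molecules", "data.frame")
  df
}

as_molecules <- function(df) {
  class(df) <- c("efg_molecules", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read a compound collection from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`SMILES id`, whitespace-separated;
#' the identifier is optional; blank lines and `#` comment lines are
#' ignored). SDF input is split on `$$$$` record terminators and identifiers
#' are taken from the title line when present. Records the chemistry engine
#' cannot parse are skipped and reported (line/record number); parsing
#' succeeds only if at least one record is readable. Returned records are
#' not yet normalized.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return an `efg_molecules` collection; the number of skipped records is
#'   available as `attr(x, "n_failed")`.
#' @export
parse_collection <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "smiles") .parse_smiles_file(path) else .parse_sdf_file(path)
}

.parse_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  smiles <- character(0); ids <- character(0); idx <- integer(0); failed <- 0L
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    out <- .ob_convert1("SMI", "SMI", paste0(tok[1], "\n"))
    if (is.na(out)) {
      failed <- failed + 1L
      message("skipping unparseable SMILES at ", path, " line ", i, ": ", tok[1])
      next
    }
    smiles <- c(smiles, tok[1])
    ids <- c(ids, if (length(tok) > 1L) tok[2] else "")
    idx <- c(idx, i)
  }
  if (!length(smiles))
    stop("empty set: no parseable records in ", path,
         " (", failed, " failures)")
  mols <- efg_molecules(smiles, mol_id = ids, source_file = path,
                        source_index = idx)
  attr(mols, "n_failed") <- failed
  mols
}

.parse_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  smiles <- character(0); ids <- character(0); idx <- integer(0); failed <- 0L
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    if (!any(nzchar(trimws(block)))) next
    txt <- paste(c(block, "$$$$"), collapse = "\n")
    out <- .ob_convert1("SDF", "SMI", txt)
    if (is.na(out)) {
      failed <- failed + 1L
      message("skipping unparseable SDF record ", r, " in ", path)
      next
    }
    title <- trimws(block[1])
    smiles <- c(smiles, .ob_smiles_of(out))
    ids <- c(ids, title)
    idx <- c(idx, r)
  }
  if (!length(smiles))
    stop("empty set: no parseable records in ", path, " (", failed, " failures)")
  mols <- efg_molecules(smiles, mol_id = ids, source_file = path,
                        source_index = idx)
  attr(mols, "n_failed") <- failed
  mols
}

# Kekulize-then-rearomatize one SMILES under the package's aromaticity model.
# A MOL block carries explicit bond orders (Kekulé by construction); reading
# it back and writing canonical SMILES applies OpenBabel aromatization.
.normalize_smiles1 <- function(smi) {
  if (!nzchar(smi)) return("")   # empty molecule stays empty
  kek <- .ob_convert1("SMI", "MOL", paste0(smi, " m\n"))
  if (is.na(kek)) return(NA_character_)
  out <- .ob_convert1("MOL", "CAN", kek)
  if (is.na(out)) return(NA_character_)
  .ob_smiles_of(out)
}

#' Normalize a molecule collection
#'
#' Applies the package's canonical aromaticity normalization (Kekulé
#' conversion followed by re-aromatization) to every record. The operation
#' is idempotent, preserves atom and fragment content, and guarantees that
#' two inputs denoting the same molecule in different aromaticity dialects
#' produce identical group profiles downstream.
#'
#' @param mols an `efg_molecules` collection (or a single SMILES string,
#'   which is wrapped automatically).
#' @param on_error `"stop"` (default) to fail on structures that cannot be
#'   Kekulized/re-aromatized, or `"drop"` to remove them with a message.
#' @return the collection with `smiles` filled and `normalized = TRUE`.
#' @export
normalize_molecules <- function(mols, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  if (is.character(mols)) mols <- efg_molecules(mols)
  todo <- !mols$normalized
  norm <- vapply(mols$input[todo], .normalize_smiles1, character(1),
                 USE.NAMES = FALSE)
  mols$smiles[todo] <- norm
  bad <- is.na(mols$smiles)
  if (any(bad)) {
    who <- paste(mols$mol_id[bad], collapse = ", ")
    if (on_error == "stop")
      stop("normalization failed (cannot Kekulize/re-aromatize): ", who)
    message("dropping ", sum(bad), " record(s) that failed normalization: ", who)
    mols <- mols[!bad, , drop = FALSE]
  }
  mols$normalized <- TRUE
  as_molecules(mols)
}

#' Write a collection as a SMILES file
#'
#' Writes `SMILES id` lines using the normalized canonical SMILES when
#' available, the raw input otherwise.
#'
#' @param mols an `efg_molecules` collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path) {
  smi <- ifelse(mols$normalized, mols$smiles, mols$input)
  writeLines(paste(smi, mols$mol_id), path)
  invisible(path)
}

#' @export
print.efg_molecules <- function(x, ...) {
  cat("efg_molecules:", nrow(x), "record(s);",
      sum(x$normalized), "normalized\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
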