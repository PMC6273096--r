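#' @title Systematic HS/LS heterocycle taxonomy
#' @description
#' Heterocycle groups are enumerated systematically by ring size (3-7),
#' aromaticity, and ring heteroatom count/identity (N, O, S). Two
#' specificity levels are generated:
#'
#' * LS (low specificity): element-generic positional classes. Ring carbons
#'   are plain aromatic/any carbons and heteroatom positions are "any
#'   (aromatic) atom except carbon"; ring fusion is tolerated, so indole
#'   matches the LS class of pyrrole.
#' * HS (high specificity): element-specific positional isomers with a
#'   no-fusion constraint -- every ring atom carries the SMARTS ring-bond-count
#'   primitive `x2` (exactly two ring bonds), which rejects fused and spiro
#'   ring atoms. Indole therefore does not match the HS pyrrole pattern.
#'
#' Positional isomers are equivalence classes of heteroatom placements under
#' the dihedral symmetry of the ring (rotation + reflection), e.g. the three
#' diazines pyridazine (1,2), pyrimidine (1,3) and pyrazine (1,4).
#' @name efg-heterocycles
NULL

# all rotations and reflections of a ring vector
.dihedral_images <- function(v) {
  m <- length(v)
  idx <- seq_len(m)
  out <- vector("list", 2L * m)
  for (s in 0:(m - 1L)) out[[s + 1L]] <- v[(idx + s - 1L) %% m + 1L]
  r <- rev(v)
  for (s in 0:(m - 1L)) out[[m + s + 1L]] <- r[(idx + s - 1L) %% m + 1L]
  out
}

.necklace_key <- function(v) paste(v, collapse = "")

# canonical representative: lexicographically smallest dihedral image
.canonical_necklace <- function(v) {
  imgs <- .dihedral_images(v)
  keys <- vapply(imgs, .necklace_key, character(1))
  imgs[[which.min(rank(keys, ties.method = "first"))]]
}

# locant-assigned representative: image with the lowest sorted heteroatom
# locants, ties broken by element priority O < S < N at the heteroatom
# positions in locant order (the replacement-nomenclature convention of
# giving the earliest-cited element the lowest locants)
.locant_image <- function(v) {
  prio <- c(C = 9L, O = 1L, S = 2L, N = 3L)
  imgs <- .dihedral_images(v)
  keys <- vapply(imgs, function(w) {
    locs <- which(w != "C")
    paste(sprintf("%02d", c(locs, prio[w[locs]])), collapse = "")
  }, character(1))
  imgs[[which.min(rank(keys, ties.method = "first"))]]
}

# distinct element necklaces of size m over {C,N,O,S} with h heteroatoms,
# subject to the registry's composition caps
.enumerate_element_rings <- function(m, h, aromatic) {
  stopifnot(h >= 1L, h <= m)
  pos_sets <- utils::combn(m, h, simplify = FALSE)
  elems <- c("N", "O", "S")
  assign_grid <- as.matrix(expand.grid(rep(list(elems), h),
                                       stringsAsFactors = FALSE))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ps in pos_sets) {
    for (i in seq_len(nrow(assign_grid))) {
      v <- rep("C", m)
      v[ps] <- assign_grid[i, ]
      nO <- sum(v == "O"); nS <- sum(v == "S")
      if (aromatic) {
        # aromatic rings: at most one O and one S; six-membered aromatics
        # are N-only (neutral pyrylium/thiopyrylium analogues are charged)
        if (nO > 1L || nS > 1L) next
        # fully heteroatomic 5-rings: only the all-nitrogen pentazole class
        if (h == 5L && nO + nS > 0L) next
        if (m == 6L && nO + nS > 0L) next
      } else {
        # saturated rings with three heteroatoms: at most two sulfurs
        if (h == 3L && nS > 2L) next
      }
      canon <- .canonical_necklace(v)
      key <- .necklace_key(canon)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- canon
      }
    }
  }
  # deterministic order: by position class, then element string
  ord <- order(vapply(out, function(v) .position_key(v), character(1)),
               vapply(out, .necklace_key, character(1)))
  out[ord]
}

# canonical locants of the heteroatom position class (element-blind)
.position_locants <- function(v) {
  mask <- ifelse(v == "C", "C", "X")
  which(.locant_image(mask) != "C")
}

.position_key <- function(v) paste(.position_locants(v), collapse = "")

# distinct heteroatom position classes (binary necklaces) for size m, h marked
.enumerate_position_classes <- function(m, h) {
  pos_sets <- utils::combn(m, h, simplify = FALSE)
  keys <- character(0)
  out <- list()
  for (ps in pos_sets) {
    v <- rep("C", m); v[ps] <- "X"
    locs <- which(.locant_image(v) != "C")
    key <- paste(locs, collapse = "")
    if (!key %in% keys) { keys <- c(keys, key); out[[length(out) + 1L]] <- locs }
  }
  out[order(keys)]
}

# ---- SMARTS construction ----------------------------------------------------

.hs_atom_smarts <- c(
  aromatic  = NA,  # filled per element below
  saturated = NA)

.ring_atom_expr <- function(elem, kind) {
  switch(kind,
    aromatic_hs = c(C = "[cx2]", N = "[nx2]", O = "[ox2]", S = "[sx2]")[[elem]],
    aromatic_ls = if (elem == "C") "c" else "[a;!#6]",
    saturated_hs = c(C = "[CX4x2]", N = "[NX3x2]", O = "[OX2x2]", S = "[SX2x2]")[[elem]],
    nonaromatic_ls = if (elem == "C") "[#6]" else "[!#6;!#1;!a]",
    stop("unknown ring pattern kind: ", kind))
}

#' Build a ring SMARTS pattern
#'
#' Constructs the SMARTS for one monocyclic heterocycle class. `kind`
#' selects the taxonomy level: element-specific HS patterns carry the `x2`
#' no-fusion primitive on every ring atom; element-generic LS patterns allow
#' fusion and any non-carbon (aromatic) heteroatom at the marked positions.
#'
#' @param ring character vector over `c("C","N","O","S")` giving the ring
#'   atoms in order (for LS kinds only the C / non-C distinction is used).
#' @param kind one of `"aromatic_hs"`, `"aromatic_ls"`, `"saturated_hs"`,
#'   `"nonaromatic_ls"`.
#' @return a SMARTS string.
#' @examples
#' build_ring_smarts(c("N", "C", "C", "C", "C"), "aromatic_hs")  # pyrrole, HS
#' build_ring_smarts(c("N", "C", "C", "C", "C"), "aromatic_ls")  # Fig-2-style LS
#' @export
build_ring_smarts <- function(ring, kind) {
  stopifnot(all(ring %in% c("C", "N", "O", "S")), length(ring) >= 3L)
  atoms <- vapply(ring, .ring_atom_expr, character(1), kind = kind)
  if (kind == "nonaromatic_ls") {
    # explicit "any" bonds so partially unsaturated rings match
    paste0(atoms[1L], "1", paste0("~", atoms[-1L], collapse = ""), "~1")
  } else {
    paste0(atoms[1L], "1", paste0(atoms[-1L], collapse = ""), "1")
  }
}

# ---- naming -----------------------------------------------------------------

.het_prefix <- c(O = "oxa", S = "thia", N = "aza")
.multiplier <- c("", "di", "tri", "tetra", "penta")

# condensed Hantzsch-Widman-style name for aromatic rings
# (locants in element citation order O,S,N; prefixes concatenated; suffix
# "ole" for 5-rings, "ine" for 6-rings, with elision of a trailing "a")
.aromatic_ring_name <- function(v) {
  w <- .locant_image(v)
  locs <- which(w != "C")
  parts <- character(0); all_locs <- integer(0)
  for (el in c("O", "S", "N")) {
    el_locs <- locs[w[locs] == el]
    if (!length(el_locs)) next
    all_locs <- c(all_locs, el_locs)
    parts <- c(parts, paste0(.multiplier[length(el_locs)], .het_prefix[[el]]))
  }
  prefix <- paste(parts, collapse = "")
  suffix <- if (length(v) == 5L) "ole" else "ine"
  prefix <- sub("a$", "", prefix)  # elision before vowel
  paste0(paste(all_locs, collapse = ","), "-", prefix, suffix)
}

# hyphenated replacement name for saturated rings,
# e.g. "1-oxa-4-azacyclohexane"
.saturated_ring_name <- function(v) {
  w <- .locant_image(v)
  locs <- which(w != "C")
  parts <- character(0)
  for (el in c("O", "S", "N")) {
    el_locs <- locs[w[locs] == el]
    if (!length(el_locs)) next
    parts <- c(parts, paste0(paste(el_locs, collapse = ","), "-",
                             .multiplier[length(el_locs)], .het_prefix[[el]]))
  }
  base <- c("cyclopropane", "cyclobutane", "cyclopentane", "cyclohexane",
            "cycloheptane")[length(v) - 2L]
  paste0(paste(parts, collapse = "-"), base)
}

.hs_group_id <- function(v, aromatic) {
  w <- .locant_image(v)
  locs <- which(w != "C")
  paste0("hs_", if (aromatic) "ar" else "st", length(v), "_",
         paste0(locs, tolower(w[locs]), collapse = ""))
}

# trivial names for well-known rings, keyed by systematic group_id
.trivial_ring_names <- c(
  hs_ar5_1n = "Pyrrole", hs_ar5_1o = "Furan", hs_ar5_1s = "Thiophene",
  hs_ar5_1n2n = "Pyrazole", hs_ar5_1n3n = "Imidazole",
  hs_ar5_1o2n = "Isoxazole", hs_ar5_1o3n = "Oxazole",
  hs_ar5_1s2n = "Isothiazole", hs_ar5_1s3n = "Thiazole",
  hs_ar5_1n2n3n = "1,2,3-triazole", hs_ar5_1n2n4n = "1,2,4-triazole",
  hs_ar5_1n2n3n4n = "Tetrazole", hs_ar5_1n2n3n4n5n = "Pentazole",
  hs_ar6_1n = "Pyridine", hs_ar6_1n2n = "Pyridazine",
  hs_ar6_1n3n = "Pyrimidine", hs_ar6_1n4n = "Pyrazine",
  hs_st3_1n = "Aziridine", hs_st3_1o = "Oxirane", hs_st3_1s = "Thiirane",
  hs_st4_1n = "Azetidine", hs_st4_1o = "Oxetane", hs_st4_1s = "Thietane",
  hs_st5_1n = "Pyrrolidine", hs_st5_1o = "Oxolane (THF)", hs_st5_1s = "Thiolane",
  hs_st6_1n = "Piperidine", hs_st6_1o = "Oxane", hs_st6_1s = "Thiane",
  hs_st7_1n = "Azepane", hs_st7_1o = "Oxepane", hs_st7_1s = "Thiepane",
  hs_st6_1n4n = "Piperazine", hs_st6_1o4n = "Morpholine",
  hs_st6_1s4n = "Thiomorpholine", hs_st6_1o4o = "1,4-dioxane",
  hs_st6_1o3o = "1,3-dioxane", hs_st5_1o3o = "1,3-dioxolane",
  hs_st5_1n2n = "Pyrazolidine", hs_st5_1n3n = "Imidazolidine")

# ---- registry assembly ------------------------------------------------------

# LS entry for one (family, size, position-class)
.ls_entry <- function(fam, m, locs) {
  h <- length(locs)
  aromatic <- fam == "ar"
  v <- rep("C", m); v[locs] <- "X"
  kind <- if (aromatic) "aromatic_ls" else "nonaromatic_ls"
  smarts <- build_ring_smarts(ifelse(v == "C", "C", "N"), kind)  # element-blind
  id <- paste0("ls_", fam, m, "_h", h,
               if (h >= 2L) paste0("_", paste(locs, collapse = "")) else "")
  label <- paste0(if (aromatic) "Aromatic " else "Non-aromatic ", m,
                  "-membered heterocycle, ", h,
                  if (h == 1L) " ring heteroatom" else
                    paste0(" ring heteroatoms (", paste(locs, collapse = ","), ")"),
                  " (LS)")
  functional_group(id, label, smarts, category = "heterocycle",
                   specificity = "LS", notes = "")
}

# HS entry for one element necklace
.hs_entry <- function(v, aromatic) {
  m <- length(v)
  w <- .locant_image(v)
  kind <- if (aromatic) "aromatic_hs" else "saturated_hs"
  smarts <- build_ring_smarts(w, kind)
  id <- .hs_group_id(v, aromatic)
  sysname <- if (aromatic) .aromatic_ring_name(v) else .saturated_ring_name(v)
  trivial <- .trivial_ring_names[id]
  nm <- if (!is.na(trivial)) paste0(trivial, " (HS)")
        else paste0(sysname, " (HS)")
  locs <- .position_locants(v)
  parent <- paste0("ls_", if (aromatic) "ar" else "na", m, "_h", length(locs),
                   if (length(locs) >= 2L) paste0("_", paste(locs, collapse = "")) else "")
  functional_group(id, nm, smarts, category = "heterocycle",
                   specificity = "HS", ls_parent = parent,
                   notes = if (!is.na(trivial)) sysname else "")
}

# full systematic heterocycle block of the shipped registry (353 entries)
heterocycle_registry <- function() {
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  # aromatic 5- and 6-membered rings: azoles up to pentazole (all classes
  # with an experimentally known all-nitrogen parent), azines up to tetrazine
  for (m in c(5L, 6L)) {
    hmax <- if (m == 5L) 5L else 4L
    for (h in seq_len(hmax)) {
      for (locs in .enumerate_position_classes(m, h))
        add(.ls_entry("ar", m, locs))
    }
    for (h in seq_len(hmax)) {
      for (v in .enumerate_element_rings(m, h, aromatic = TRUE))
        add(.hs_entry(v, aromatic = TRUE))
    }
  }
  # non-aromatic LS classes and saturated HS isomers, ring sizes 3-7
  for (m in 3:7) {
    for (h in 1:3) {
      if (h > m - 1L) next
      for (locs in .enumerate_position_classes(m, h))
        add(.ls_entry("na", m, locs))
    }
    for (h in 1:3) {
      if (h > m - 1L) next
      for (v in .enumerate_element_rings(m, h, aromatic = FALSE))
        add(.hs_entry(v, aromatic = FALSE))
    }
  }
  as_registry(do.call(rbind, rows))
}
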