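#' @title Periodic-table category patterns
#' @description
#' Element-category groups match any molecule containing at least one atom of
#' a listed element, independent of charge, valence or aromaticity. They are
#' encoded as a disjunction of atomic-number primitives (`[#7,#15,...]`),
#' which SMARTS engines match regardless of the atom's aromatic flag or
#' charge, so Kekulé and aromatized forms of the same structure always give
#' identical results.
#' @name efg-periodic
NULL

# symbol -> atomic number, Z = position in this vector
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

atomic_number <- function(symbols) {
  z <- match(symbols, .element_symbols)
  if (anyNA(z))
    stop("unknown element symbol(s): ", paste(symbols[is.na(z)], collapse = ", "))
  z
}

# named element sets behind the shipped periodic_group registry entries
periodic_category_elements <- function() {
  groups18 <- list(
    alkali_metals         = c("Li", "Na", "K", "Rb", "Cs", "Fr"),
    alkaline_earth_metals = c("Be", "Mg", "Ca", "Sr", "Ba", "Ra"),
    boron_group           = c("B", "Al", "Ga", "In", "Tl", "Nh"),
    carbon_group          = c("C", "Si", "Ge", "Sn", "Pb", "Fl"),
    pnictogens            = c("N", "P", "As", "Sb", "Bi", "Mc"),
    chalcogens            = c("O", "S", "Se", "Te", "Po", "Lv"),
    halogens              = c("F", "Cl", "Br", "I", "At", "Ts"),
    noble_gases           = c("He", "Ne", "Ar", "Kr", "Xe", "Rn", "Og"))
  lanth <- .element_symbols[57:71]
  actin <- .element_symbols[89:103]
  trans <- .element_symbols[c(21:30, 39:48, 72:80, 104:112)]
  post_transition <- c("Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi", "Po")
  metalloids <- c("B", "Si", "Ge", "As", "Sb", "Te")
  nonmetals <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Se", "Br", "I")
  metals <- setdiff(.element_symbols,
                    c(nonmetals, metalloids, groups18$noble_gases,
                      "At", "Ts", "Og"))
  c(groups18,
    list(transition_metals = trans, lanthanides = lanth, actinides = actin,
         post_transition_metals = post_transition, metalloids = metalloids,
         nonmetals = nonmetals, metals = metals))
}

#' Build an element-category pattern
#'
#' Constructs a `periodic_group` registry entry whose SMARTS matches any atom
#' of any of the listed elements, in any charge, valence or aromaticity
#' state. Occurrence counts from such a pattern equal the number of atoms of
#' the listed elements in the molecule.
#'
#' @param element_symbols non-empty character vector of element symbols.
#' @param label human-readable group name.
#' @param group_id registry identifier (default: derived from `label`).
#' @return a one-row `efg_registry`.
#' @examples
#' build_periodic_group_pattern(c("N", "P", "As", "Sb", "Bi"), "Pnictogens")
#' @export
build_periodic_group_pattern <- function(element_symbols, label,
                                         group_id = paste0("pt_", gsub("[^a-z0-9]+", "_", tolower(label)))) {
  if (!length(element_symbols)) stop("element_symbols must be non-empty")
  z <- atomic_number(element_symbols)
  smarts <- paste0("[", paste0("#", sort(unique(z)), collapse = ","), "]")
  functional_group(group_id, label, smarts, category = "periodic_group",
                   specificity = "not_applicable",
                   notes = paste("elements:", paste(element_symbols, collapse = " ")))
}

# the 15 shipped periodic-table categories
periodic_group_registry <- function() {
  cats <- periodic_category_elements()
  labels <- c(alkali_metals = "Alkali metals (group 1)",
              alkaline_earth_metals = "Alkaline earth metals (group 2)",
              boron_group = "Boron group elements (group 13)",
              carbon_group = "Carbon group elements (group 14)",
              pnictogens = "Pnictogens (group 15)",
              chalcogens = "Chalcogens (group 16)",
              halogens = "Halogens (group 17)",
              noble_gases = "Noble gases (group 18)",
              transition_metals = "Transition metals",
              lanthanides = "Lanthanides",
              actinides = "Actinides",
              post_transition_metals = "Post-transition metals",
              metalloids = "Metalloids",
              nonmetals = "Reactive nonmetals",
              metals = "Metals (any)")
  rows <- lapply(names(cats), function(k)
    build_periodic_group_pattern(cats[[k]], labels[[k]], group_id = paste0("pt_", k)))
  as_registry(do.call(rbind, rows))
}
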