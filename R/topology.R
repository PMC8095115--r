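#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom utils read.table write.table head tail
NULL

# Atomic masses (u) for the elements that occur in biomolecular systems.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971
)

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common force-field histidine/protonation variants
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP"
)

.categories <- c("protein_backbone", "protein_sidechain", "ligand", "water", "other")

#' Atomic mass of an element
#'
#' Looks up the mass of one or more element symbols in the built-in table.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in atomic mass units.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         "; supply masses explicitly or extend the element table")
  }
  unname(m)
}

#' Infer element symbols from PDB-style atom names
#'
#' Strips leading digits (as in `1HB`) and maps two-letter element prefixes
#' (`CL`, `BR`, ...) where unambiguous; otherwise the first letter is used.
#'
#' @param atom_name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9 ]+", "", trimws(atom_name)))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  # two-letter symbols that cannot be confused with amino-acid atom names
  # (CA/CD/... are carbons; NA would clash with backbone N variants)
  unambig <- c("CL", "BR", "MG", "ZN", "FE", "MN", "CU", "SE")
  hit <- two %in% unambig & nchar(nm) == 2
  el[hit] <- two[hit]
  el
}

#' Atom-category classification rules
#'
#' The rule set used to assign each atom to exactly one of the categories
#' `protein_backbone`, `protein_sidechain`, `ligand`, `water`, `other`.
#'
#' @param water_residues residue names treated as water.
#' @param ligand_residues residue names treated as ligand.
#' @param protein_residues residue names treated as protein (defaults to the
#'   20 standard amino acids plus common histidine variants).
#' @param backbone_atoms atom names forming the protein backbone.
#' @return an object of class `classify_rules`.
#' @export
classify_rules <- function(water_residues = c("HOH", "WAT", "TIP3", "SOL"),
                           ligand_residues = character(),
                           protein_residues = .standard_aa,
                           backbone_atoms = c("N", "CA", "C", "O")) {
  structure(list(water_residues = toupper(water_residues),
                 ligand_residues = toupper(ligand_residues),
                 protein_residues = toupper(protein_residues),
                 backbone_atoms = toupper(backbone_atoms)),
            class = "classify_rules")
}

#' Assign atom categories under a rule set
#'
#' @param atoms data frame with columns `residue_name`, `atom_name`,
#'   `is_hydrogen`.
#' @param rules a [classify_rules()] object.
#' @return character vector of categories; unknown residues are mapped to
#'   `other` with one warning listing them.
#' @export
assign_categories <- function(atoms, rules = classify_rules()) {
  stopifnot(inherits(rules, "classify_rules"))
  res <- toupper(atoms$residue_name)
  nm <- toupper(atoms$atom_name)
  cat <- rep("other", nrow(atoms))
  cat[res %in% rules$water_residues] <- "water"
  cat[res %in% rules$ligand_residues] <- "ligand"
  is_prot <- res %in% rules$protein_residues
  cat[is_prot] <- ifelse(nm[is_prot] %in% rules$backbone_atoms & !atoms$is_hydrogen[is_prot],
                         "protein_backbone", "protein_sidechain")
  unknown <- unique(atoms$residue_name[cat == "other"])
  if (length(unknown) > 0) {
    warning("residue name(s) not covered by classification rules, ",
            "recorded as category 'other': ", paste(unknown, collapse = ", "))
  }
  cat
}

#' Construct a topology table
#'
#' A topology is the static per-atom metadata shared by every frame of an
#' ensemble: identity, residue, subunit (chain), mass and category. Atom
#' order is fixed for the life of an ensemble.
#'
#' @param atoms data frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_seq`, `residue_name`, `subunit_id`, and optionally `mass`,
#'   `category`, `is_hydrogen`. Missing masses are filled from the element
#'   table; missing categories are assigned from `rules`.
#' @param rules a [classify_rules()] object used when `category` is absent.
#' @return data frame of class `topology`.
#' @export
topology <- function(atoms, rules = classify_rules()) {
  req <- c("atom_id", "atom_name", "element", "residue_seq", "residue_name",
           "subunit_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stop("topology: missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_seq <- as.integer(atoms$residue_seq)
  atoms$subunit_id <- as.character(atoms$subunit_id)
  if (anyDuplicated(atoms$atom_id)) stop("topology: atom_id values must be unique")
  if (any(atoms$element == "" | is.na(atoms$element))) stop("topology: element must be nonempty")
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- toupper(atoms$element) == "H"
  if (any(atoms$is_hydrogen != (toupper(atoms$element) == "H")))
    stop("topology: is_hydrogen inconsistent with element")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass) | atoms$mass <= 0)) stop("topology: mass must be > 0")
  if (is.null(atoms$category)) atoms$category <- assign_categories(atoms, rules)
  if (!all(atoms$category %in% .categories))
    stop("topology: invalid category value(s): ",
         paste(setdiff(unique(atoms$category), .categories), collapse = ", "))
  # every (subunit, residue_seq) pair maps to exactly one residue_name
  key <- paste(atoms$subunit_id, atoms$residue_seq)
  nn <- tapply(atoms$residue_name, key, function(x) length(unique(x)))
  if (any(nn > 1)) {
    stop("topology: (subunit, residue_seq) pair(s) with conflicting residue names: ",
         paste(names(nn)[nn > 1], collapse = "; "))
  }
  rownames(atoms) <- NULL
  class(atoms) <- c("topology", "data.frame")
  atoms
}

#' Distinct subunit identifiers of a topology, in order of appearance
#' @param top a `topology`.
#' @return character vector.
#' @export
subunit_ids <- function(top) unique(top$subunit_id)

#' Select atom indices from a topology
#'
#' @param top a `topology`.
#' @param subunit,residue_seq,atom_name,category optional filters (vectors).
#' @param heavy_only drop hydrogens (default `FALSE`).
#' @return integer vector of row indices into the topology.
#' @export
select_atoms <- function(top, subunit = NULL, residue_seq = NULL,
                         atom_name = NULL, category = NULL,
                         heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(subunit)) keep <- keep & top$subunit_id %in% subunit
  if (!is.null(residue_seq)) keep <- keep & top$residue_seq %in% residue_seq
  if (!is.null(atom_name)) keep <- keep & top$atom_name %in% atom_name
  if (!is.null(category)) keep <- keep & top$category %in% category
  if (heavy_only) keep <- keep & !top$is_hydrogen
  which(keep)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d subunit(s) [%s], categories: %s\n",
              nrow(x), length(subunit_ids(x)),
              paste(subunit_ids(x), collapse = ","),
              paste(sprintf("%s=%d", names(table(x$category)), table(x$category)),
                    collapse = " ")))
  invisible(x)
}
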