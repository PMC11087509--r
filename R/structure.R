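#' Atomic structure model
#'
#' A `structure_model` is an ordered set of atoms (one conformer). Atom order
#' is stable and index-addressable; two models are topology-compatible when
#' they have the same number of atoms and identical (atom_name, residue_index)
#' sequences.
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_index`, `chain_id`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @param label free-text conformer label (e.g. "I", "II", "III").
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "") {
  req <- c("atom_name", "element", "residue_name", "residue_index",
           "chain_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  atoms$residue_index <- as.integer(atoms$residue_index)
  rownames(atoms) <- NULL
  structure(list(label = as.character(label), atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$residue_index))))
  invisible(x)
}

#' Coordinates of a structure model
#' @param model a [structure_model()].
#' @return numeric matrix n_atoms x 3 (Angstrom).
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#' @param model a [structure_model()].
#' @param xyz numeric matrix n_atoms x 3.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(model$atoms) || ncol(xyz) != 3L)
    stop("coordinate matrix must be n_atoms x 3")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Topology compatibility of two models
#' @param a,b [structure_model()] objects.
#' @return logical; TRUE when atom counts and (atom_name, residue_index)
#'   sequences match.
#' @export
topology_compatible <- function(a, b) {
  nrow(a$atoms) == nrow(b$atoms) &&
    all(a$atoms$atom_name == b$atoms$atom_name) &&
    all(a$atoms$residue_index == b$atoms$residue_index)
}

# Elements whose symbols have two letters and appear in biomolecular PDBs;
# used for element inference from atom names.
.two_letter_elements <- c("NA", "MG", "CL", "CA", "MN", "FE", "CO", "NI",
                          "CU", "ZN", "SE", "BR", "MO", "CD", "HG")

.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12,
                     P = 15, S = 16, CL = 17, K = 19, CA. = 20, MN = 25,
                     FE = 26, CO = 27, NI = 28, CU = 29, ZN = 30, SE = 34,
                     BR = 35)

#' Atomic number lookup
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of atomic numbers; unknown elements error.
#' @export
atomic_number <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."   # avoid clash with R's NA when indexing by name
  key[key == "CA"] <- "CA."
  z <- .atomic_numbers[key]
  if (any(is.na(z)))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  as.integer(z)
}

#' Infer an element symbol from an atom name
#'
#' Strategy used when the PDB element column is blank: strip digits and
#' primes, then match a curated two-letter element list before falling back
#' to the first alphabetic character. Atom names like `"CA"` in an amino-acid
#' residue mean the alpha carbon, so the two-letter match is only accepted
#' when the name has no following characters typical of biopolymer naming.
#'
#' @param atom_name character vector of PDB atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    s <- gsub("[^A-Za-z]", "", toupper(trimws(nm)))
    if (nchar(s) == 0L) stop("cannot infer element from atom name '", nm, "'")
    two <- substr(s, 1, 2)
    # heuristics: 'CA'/'CD'... inside residues are carbons; accept a
    # two-letter element only when the whole cleaned name is that symbol and
    # it is not a common biopolymer carbon/nitrogen name
    if (nchar(s) == 2L && two %in% .two_letter_elements &&
        !(two %in% c("CA", "CD", "CE", "CG", "CB", "CZ", "CH", "ND", "NE",
                     "NZ", "NH", "OD", "OE", "OG", "OH", "SD", "SG"))) {
      return(two)
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Heavy-atom (non-hydrogen) indicator
#' @param model a [structure_model()].
#' @return logical vector, one per atom; TRUE for non-hydrogen atoms.
#' @export
is_heavy <- function(model) {
  toupper(trimws(model$atoms$element)) != "H"
}
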