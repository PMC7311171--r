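#' Atom-table structure container
#'
#' A `structure_model` is a light hierarchical container for macromolecular
#' coordinates: one row per atom with element, atom name, Cartesian position
#' (Angstrom), author residue numbering (number + insertion code), residue
#' name, chain id and a HETATM flag. It is the common currency of all
#' geometric stages (membrane placement, orientation search, clash counting).
#'
#' @param atoms data.frame with columns `element`, `name`, `x`, `y`, `z`,
#'   `resno`, `insert`, `resid`, `chain`, `het`. Missing `insert` defaults to
#'   `""`, missing `het` to `FALSE`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  needed <- c("element", "name", "x", "y", "z", "resno", "resid", "chain")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  atoms$heavy <- atoms$element != "H" & atoms$element != "D"
  atoms$standard_aa <- atoms$resid %in% standard_aa3()
  atoms <- atoms[, c("element", "name", "x", "y", "z", "resno", "insert",
                     "resid", "chain", "het", "heavy", "standard_aa")]
  structure(list(atoms = atoms), class = "structure_model")
}

#' The 20 standard three-letter amino-acid codes
#' @return Character vector of length 20.
#' @export
standard_aa3 <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), n_residues(x), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param model a `structure_model`
#' @return integer
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Number of residues (unique chain/resno/insert triples)
#' @param model a `structure_model`
#' @return integer
#' @export
n_residues <- function(model) {
  a <- model$atoms
  nrow(unique(a[, c("chain", "resno", "insert")]))
}

#' Coordinate matrix of a structure
#'
#' @param model a `structure_model`
#' @param heavy_only keep only heavy (non-hydrogen) atoms
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom)
#' @export
coords <- function(model, heavy_only = FALSE) {
  a <- model$atoms
  if (heavy_only) a <- a[a$heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' C-alpha coordinates of a structure, in residue order
#'
#' @param model a `structure_model`
#' @param chain optional chain id filter
#' @return numeric matrix of CA positions with rownames `chain:resno:insert`
#' @export
ca_coords <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[a$name == "CA" & !a$het, , drop = FALSE]
  a <- a[order(a$chain, a$resno, a$insert), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, a$insert, sep = ":")
  m
}

#' Apply a rigid transform to a structure
#' @param model a `structure_model`
#' @param transform a `rigid_transform`
#' @return transformed `structure_model`
#' @export
transform_structure <- function(model, transform) {
  xyz <- apply_transform(transform, coords(model))
  out <- model
  out$atoms$x <- xyz[, 1]
  out$atoms$y <- xyz[, 2]
  out$atoms$z <- xyz[, 3]
  out
}

#' One-residue-per-row summary table
#'
#' @param model a `structure_model`
#' @return data.frame with chain, resno, insert, resid, ordered by chain then
#'   author number then insertion code (insertion codes sort after their base
#'   number, the standard PDB convention).
#' @export
residue_table <- function(model) {
  a <- model$atoms
  r <- unique(a[, c("chain", "resno", "insert", "resid")])
  r <- r[order(r$chain, r$resno, r$insert), , drop = FALSE]
  rownames(r) <- NULL
  r
}
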