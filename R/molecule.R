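#' Build a molecule from an atoms table
#'
#' A molecule is a light S3 container around two tibbles: one row per atom
#' and one row per bond. Atom typing columns (`pair_type`, flags, charge,
#' radius) start unset and are filled by [assign_types()].
#'
#' @param atoms data frame with columns `serial` (unique positive integer),
#'   `element` (symbol, e.g. "C"), `x`, `y`, `z` (Angstrom). Optional typing
#'   columns are preserved.
#' @param bonds data frame with columns `from`, `to` (atom indices, 1-based
#'   row positions in `atoms`) and `order` (1, 2, 3 or 4 = aromatic). May be
#'   empty.
#' @param name molecule identifier.
#' @return An object of class `iec_molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, name = "mol") {
  atoms <- as_tibble(atoms)
  required <- c("serial", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(atoms$serial) > 0) abort("atom serials must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  for (col in c("partial_charge", "vdw_radius")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  for (col in c("is_hydrophobic", "is_hbond_donor", "is_hbond_acceptor", "is_metal")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA
  }
  if (!"pair_type" %in% names(atoms)) atoms$pair_type <- NA_character_
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- as_tibble(bonds)
    stopifnot(all(c("from", "to") %in% names(bonds)))
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    n <- nrow(atoms)
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n)) {
      abort("bond indices out of range")
    }
    if (any(bonds$from == bonds$to)) abort("self-bonds are not allowed")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "iec_molecule")
}

#' @export
print.iec_molecule <- function(x, ...) {
  typed <- if (all(!is.na(x$atoms$pair_type))) "typed" else "untyped"
  cat(sprintf("<iec_molecule> %s: %d atoms, %d bonds (%s)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), typed))
  invisible(x)
}

#' Pair a receptor and a ligand into a complex
#'
#' @param receptor,ligand `iec_molecule` objects. The two atom sets must be
#'   disjoint (enforced on serial/coordinate identity).
#' @return An object of class `iec_complex`.
#' @export
plcomplex <- function(receptor, ligand) {
  stopifnot(inherits(receptor, "iec_molecule"), inherits(ligand, "iec_molecule"))
  key <- function(m) paste(round(m$atoms$x, 6), round(m$atoms$y, 6), round(m$atoms$z, 6))
  if (length(intersect(key(receptor), key(ligand))) > 0) {
    abort("receptor and ligand atom sets must be disjoint (shared coordinates found)")
  }
  structure(list(receptor = receptor, ligand = ligand), class = "iec_complex")
}

#' @export
print.iec_complex <- function(x, ...) {
  cat(sprintf("<iec_complex> receptor %s (%d atoms) / ligand %s (%d atoms)\n",
              x$receptor$name, nrow(x$receptor$atoms),
              x$ligand$name, nrow(x$ligand$atoms)))
  invisible(x)
}

is_typed <- function(mol) {
  !any(is.na(mol$atoms$pair_type)) && !any(is.na(mol$atoms$vdw_radius))
}

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# Heavy atoms + polar hydrogens take part in pairwise terms; nonpolar
# hydrogens are ignored (united-heavy-atom convention).
interacting_idx <- function(mol) {
  which(mol$atoms$pair_type != "H")
}
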