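#' Parse a receptor structure from PDB text or file
#'
#' Reads ATOM/HETATM records into an untyped [molecule()]. Water residues
#' (HOH/WAT) are dropped; alternate locations other than blank or "A" are
#' discarded; insertion codes are kept; HETATM metals are retained.
#' Coordinates are in Angstrom, as stored (no re-centering).
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or more than one element is treated as
#'   text).
#' @param name molecule identifier (defaults to the file name or "receptor").
#' @return An `iec_molecule`; call [assign_types()] before computing terms.
#' @export
parse_receptor <- function(pdb_source, name = NULL) {
  src <- resolve_text_source(pdb_source)
  lines <- src$lines
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort("no ATOM/HETATM records found")
  # validate coordinate fields up front so errors can name the line
  for (i in which(rec)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (any(is.na(coords))) {
      abort(sprintf("malformed coordinate fields at line %d", i))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0) abort("empty structure after water removal")
  element <- trimws(at$elesy)
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- element_from_atom_name(at$elety[bad])
  element <- normalize_element(element)
  atoms <- tibble(
    serial = as.integer(at$eleno),
    element = element,
    x = at$x, y = at$y, z = at$z,
    atom_name = trimws(at$elety),
    residue = at$resid,
    resno = at$resno
  )
  if (anyDuplicated(atoms$serial) > 0) atoms$serial <- seq_len(nrow(atoms))
  molecule(atoms, bonds = NULL,
           name = name %||% src$name %||% "receptor")
}

#' Parse docked ligand poses from SDF or Mol2
#'
#' @param source path or text of an SDF or Mol2 file with explicit
#'   connectivity. Each record becomes one molecule, in file order, named
#'   from the record title.
#' @param format `"sdf"` or `"mol2"`.
#' @return List of `iec_molecule`. Records with zero atoms are skipped with
#'   a warning; their indices are recorded in the `skipped` attribute.
#' @export
parse_ligand <- function(source, format = c("sdf", "mol2")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0("unsupported format: ",
                                                      source_format_token(format))))
  if (format == "sdf") parse_sdf(source) else parse_mol2(source)
}

source_format_token <- function(x) if (is.character(x)) x[1] else "<?>"

parse_sdf <- function(source) {
  src <- resolve_text_source(source)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(src$lines, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  # records are usable when they carry atoms; bond-less molecules are legal
  ok <- vapply(seq_along(sdfs), function(i) {
    ab <- tryCatch(ChemmineR::atomblock(sdfs[[i]]), error = function(e) NULL)
    !is.null(ab) && is.matrix(ab) && nrow(ab) > 0 &&
      !all(rownames(ab) == "R_NA")
  }, logical(1))
  skipped <- which(!ok)
  if (length(skipped) > 0) {
    warn(sprintf("skipping %d record(s) with no atoms: index %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  ids <- ChemmineR::sdfid(sdfs)
  mols <- vector("list", sum(ok))
  j <- 0
  for (i in which(ok)) {
    j <- j + 1
    ab <- ChemmineR::atomblock(sdfs[[i]])
    bb <- tryCatch(ChemmineR::bondblock(sdfs[[i]]), error = function(e) NULL)
    element <- normalize_element(sub("_.*$", "", rownames(ab)))
    atoms <- tibble(serial = seq_len(nrow(ab)), element = element,
                    x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]))
    usable_bonds <- !is.null(bb) && is.matrix(bb) && nrow(bb) > 0 &&
      ncol(bb) >= 3 && !anyNA(bb[, 1:2])
    bonds <- if (!usable_bonds) NULL else
      tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
    nm <- ids[i]
    if (is.na(nm) || nm == "") nm <- sprintf("mol_%d", i)
    mols[[j]] <- molecule(atoms, bonds, name = nm)
  }
  attr(mols, "skipped") <- skipped
  mols
}

parse_mol2 <- function(source) {
  src <- resolve_text_source(source)
  lines <- src$lines
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) abort("no @<TRIPOS>MOLECULE record found")
  ends <- c(starts[-1] - 1, length(lines))
  mols <- list()
  skipped <- integer()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    tf <- tempfile(fileext = ".mol2")
    writeLines(chunk, tf)
    m2 <- tryCatch(bio3d::read.mol2(tf), error = function(e) NULL)
    unlink(tf)
    if (is.null(m2) || nrow(m2$atom) == 0) {
      skipped <- c(skipped, k)
      warn(sprintf("skipping mol2 record %d with no atoms", k))
      next
    }
    at <- m2$atom
    element <- normalize_element(sub("\\..*$", "", at$elety))
    atoms <- tibble(serial = as.integer(at$eleno), element = element,
                    x = at$x, y = at$y, z = at$z)
    if ("charge" %in% names(at) && !all(is.na(at$charge)) &&
        any(at$charge != 0)) {
      atoms$partial_charge <- at$charge
    }
    bonds <- NULL
    if (!is.null(m2$bond) && nrow(m2$bond) > 0) {
      ord <- m2$bond$type
      ord_int <- suppressWarnings(as.integer(ord))
      ord_int[toupper(ord) == "AR"] <- 4L
      ord_int[toupper(ord) == "AM"] <- 1L
      ord_int[is.na(ord_int)] <- 1L
      bonds <- tibble(from = as.integer(m2$bond$origin),
                      to = as.integer(m2$bond$target), order = ord_int)
    }
    nm <- trimws(chunk[2])
    if (is.na(nm) || nm == "") nm <- sprintf("mol_%d", k)
    mols[[length(mols) + 1]] <- molecule(atoms, bonds, name = nm)
  }
  attr(mols, "skipped") <- skipped
  mols
}

resolve_text_source <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    list(lines = readLines(x, warn = FALSE), name = sub("\\.[^.]*$", "", basename(x)))
  } else {
    list(lines = unlist(strsplit(x, "\n", fixed = TRUE)), name = NULL)
  }
}

element_from_atom_name <- function(atom_name) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  metals <- toupper(metal_elements())
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    out[i] <- if (two[i] %in% metals) two[i] else substr(nm[i], 1, 1)
  }
  out
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
}
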