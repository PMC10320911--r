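#' Assign atom types, flags, radii and partial charges
#'
#' Maps every atom onto the fixed AutoDock-style heavy-atom alphabet
#' (`C`, `A` aromatic carbon, `N`/`NA`, `O`/`OA`, `S`/`SA`, `P`, halogens,
#' `HD` polar hydrogen, `MET` any metal), sets the hydrophobic /
#' donor / acceptor / metal flags, attaches per-type van der Waals radii,
#' and computes Gasteiger (PEOE) partial charges when the molecule carries
#' connectivity. Nonpolar hydrogens receive the ignored type `"H"` and take
#' no part in pairwise terms.
#'
#' Structures without explicit bonds (PDB receptors) first get connectivity
#' inferred from covalent radii. Typing is independent of atom input order.
#'
#' @param mol an `iec_molecule`.
#' @param recharge recompute charges even if `partial_charge` is already set.
#' @param infer_bonds infer connectivity by covalent-distance criterion when
#'   the molecule has atoms but no bonds.
#' @return The molecule with all typing columns filled.
#' @export
assign_types <- function(mol, recharge = FALSE, infer_bonds = TRUE) {
  stopifnot(inherits(mol, "iec_molecule"))
  atoms <- mol$atoms
  n <- nrow(atoms)
  if (n == 0) abort("empty molecule")
  bonds <- mol$bonds
  if (nrow(bonds) == 0 && infer_bonds && n > 1) {
    bonds <- infer_bonds_by_distance(atoms)
  }
  nb <- neighbor_list(n, bonds)
  el <- atoms$element
  known <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", metal_elements())
  unknown <- setdiff(unique(el), known)
  if (length(unknown) > 0) {
    warn(paste0("unknown element(s) mapped to generic type C: ",
                paste(unknown, collapse = ", ")))
  }

  ring_atom <- ring_membership(n, bonds)
  has_double <- per_atom_bond_order(n, bonds, 2L)
  has_arom <- per_atom_bond_order(n, bonds, 4L)

  pair_type <- character(n)
  hydrophobic <- logical(n)
  donor <- logical(n)
  acceptor <- logical(n)
  metal <- logical(n)

  bonded_h <- vapply(seq_len(n), function(i) sum(el[nb[[i]]] == "H"), integer(1))
  heavy_nb <- vapply(seq_len(n), function(i) sum(el[nb[[i]]] != "H"), integer(1))

  for (i in seq_len(n)) {
    e <- el[i]
    if (e %in% metal_elements()) {
      pair_type[i] <- "MET"; metal[i] <- TRUE
    } else if (e == "H") {
      heavy <- nb[[i]][el[nb[[i]]] != "H"]
      polar <- length(heavy) > 0 && any(el[heavy] %in% c("N", "O", "S"))
      pair_type[i] <- if (polar) "HD" else "H"
    } else if (e == "C" || !(e %in% known)) {
      aromatic <- has_arom[i] || (ring_atom[i] && has_double[i])
      pair_type[i] <- if (aromatic) "A" else "C"
      nbe <- el[nb[[i]]]
      hydrophobic[i] <- length(nbe) == 0 || all(nbe %in% c("C", "H"))
    } else if (e == "N") {
      donor[i] <- bonded_h[i] > 0
      acceptor[i] <- bonded_h[i] == 0
      pair_type[i] <- if (acceptor[i]) "NA" else "N"
    } else if (e == "O") {
      acceptor[i] <- TRUE
      donor[i] <- bonded_h[i] > 0
      pair_type[i] <- "OA"
    } else if (e == "S") {
      donor[i] <- bonded_h[i] > 0
      acceptor[i] <- bonded_h[i] == 0 && heavy_nb[i] <= 2
      pair_type[i] <- if (acceptor[i]) "SA" else "S"
    } else if (e == "P") {
      pair_type[i] <- "P"
    } else {
      pair_type[i] <- e  # F, Cl, Br, I
      hydrophobic[i] <- e %in% c("F", "Cl", "Br", "I")
    }
  }
  # invariant: a metal is never a donor or acceptor
  donor[metal] <- FALSE
  acceptor[metal] <- FALSE

  params <- atom_type_params()
  radius <- params$vdw_radius[match(pair_type, params$pair_type)]
  radius[is.na(radius)] <- 1.9

  atoms$pair_type <- pair_type
  atoms$is_hydrophobic <- hydrophobic
  atoms$is_hbond_donor <- donor
  atoms$is_hbond_acceptor <- acceptor
  atoms$is_metal <- metal
  atoms$vdw_radius <- radius

  need_charge <- recharge | is.na(atoms$partial_charge)
  if (any(need_charge)) {
    q <- if (nrow(bonds) > 0) gasteiger_charges(el, bonds) else rep(0, n)
    atoms$partial_charge[need_charge] <- q[need_charge]
  }

  mol$atoms <- atoms
  mol$bonds <- bonds
  mol
}

infer_bonds_by_distance <- function(atoms, slack = 0.45) {
  rc <- covalent_radii()
  r <- rc[atoms$element]
  r[is.na(r)] <- 0.77
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thresh <- outer(r, r, "+") + slack
  hit <- which(d < thresh & upper.tri(d) & d > 0.4, arr.ind = TRUE)
  tibble(from = as.integer(hit[, 1]), to = as.integer(hit[, 2]),
         order = rep(1L, nrow(hit)))
}

neighbor_list <- function(n, bonds) {
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$from[k]; j <- bonds$to[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# atoms incident to at least one cycle edge (non-bridge)
ring_membership <- function(n, bonds) {
  out <- rep(FALSE, n)
  if (nrow(bonds) == 0) return(out)
  g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  idx <- unique(c(bonds$from[cyc_edges], bonds$to[cyc_edges]))
  out[idx] <- TRUE
  out
}

per_atom_bond_order <- function(n, bonds, ord) {
  out <- rep(FALSE, n)
  if (nrow(bonds) == 0) return(out)
  sel <- bonds$order == ord
  out[unique(c(bonds$from[sel], bonds$to[sel]))] <- TRUE
  out
}

# ---- Gasteiger-Marsili PEOE partial charges -------------------------------

gasteiger_params <- function() {
  # columns a, b, c of the electronegativity polynomial per (element, hyb)
  list(
    "H"     = c(7.17, 6.24, -0.56),
    "C.sp3" = c(7.98, 9.18, 1.88),
    "C.sp2" = c(8.79, 9.32, 1.51),
    "C.sp"  = c(10.39, 9.45, 0.73),
    "N.sp3" = c(11.54, 10.82, 1.36),
    "N.sp2" = c(12.87, 11.15, 0.85),
    "N.sp"  = c(15.68, 11.70, -0.27),
    "O.sp3" = c(14.18, 12.92, 1.39),
    "O.sp2" = c(17.07, 13.79, 0.47),
    "F"     = c(14.66, 13.85, 2.31),
    "Cl"    = c(11.00, 9.69, 1.35),
    "Br"    = c(10.08, 8.47, 1.16),
    "I"     = c(9.90, 7.96, 0.96),
    "S"     = c(10.14, 9.13, 1.38),
    "P"     = c(8.90, 8.24, 0.96)
  )
}

hybridization <- function(el, bonds, n) {
  hyb <- rep("sp3", n)
  if (nrow(bonds) == 0) return(hyb)
  for (i in seq_len(n)) {
    sel <- bonds$from == i | bonds$to == i
    ords <- bonds$order[sel]
    if (any(ords == 3L) || sum(ords == 2L) >= 2) hyb[i] <- "sp"
    else if (any(ords %in% c(2L, 4L))) hyb[i] <- "sp2"
  }
  hyb
}

#' Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity with the
#' classical polynomial coefficients, damping factor 1/2 per iteration,
#' 8 iterations, neutral formal charges. Atoms with no parameters (metals,
#' exotic elements) are held at zero charge.
#'
#' @param elements character vector of element symbols.
#' @param bonds bond tibble with `from`, `to`, `order`.
#' @return Numeric vector of partial charges (elementary charge units).
#' @export
gasteiger_charges <- function(elements, bonds, n_iter = 8) {
  n <- length(elements)
  hyb <- hybridization(elements, bonds, n)
  key <- ifelse(elements %in% c("C", "N", "O"),
                paste(elements, hyb, sep = "."), elements)
  pars <- gasteiger_params()
  abc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    p <- pars[[key[i]]]
    if (!is.null(p)) abc[i, ] <- p
  }
  active <- !is.na(abc[, 1])
  q <- rep(0, n)
  if (nrow(bonds) == 0) return(q)
  # cation electronegativity (denominator); H is special-cased classically
  chi_plus <- rowSums(abc)
  chi_plus[elements == "H"] <- 20.02
  for (iter in seq_len(n_iter)) {
    chi <- abc[, 1] + abc[, 2] * q + abc[, 3] * q^2
    damp <- 0.5^iter
    dq <- rep(0, n)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$from[k]; j <- bonds$to[k]
      if (!active[i] || !active[j]) next
      if (chi[j] > chi[i]) {
        t <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else if (chi[i] > chi[j]) {
        t <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  q
}
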