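#' Enumerate receptor-ligand atom contacts within a cutoff
#'
#' Returns every receptor-ligand atom pair with interatomic distance
#' `r <= cutoff` (closed boundary), with the surface distance
#' `d = r - R_i - R_j` and the typing columns of both partners, ordered by
#' receptor atom index then ligand atom index. Nonpolar hydrogens (pair
#' type `"H"`) never enter; polar hydrogens (`HD`) do.
#'
#' @param cplx an `iec_complex` whose molecules have been through
#'   [assign_types()].
#' @param cutoff positive distance cutoff in Angstrom.
#' @return Tibble with one row per contact: `ri`, `li` (atom row indices),
#'   `r_type`, `l_type`, `distance`, `surface_distance`, flag and charge
#'   columns for both partners.
#' @export
contacts <- function(cplx, cutoff = kernel_params()$cutoff) {
  stopifnot(inherits(cplx, "iec_complex"), cutoff > 0)
  if (!is_typed(cplx$receptor) || !is_typed(cplx$ligand)) {
    abort("molecules are untyped; run assign_types() first")
  }
  ra <- cplx$receptor$atoms
  la <- cplx$ligand$atoms
  ri_all <- interacting_idx(cplx$receptor)
  li_all <- interacting_idx(cplx$ligand)
  if (length(ri_all) == 0 || length(li_all) == 0) {
    return(empty_contacts())
  }
  rxyz <- as.matrix(ra[ri_all, c("x", "y", "z")])
  lxyz <- as.matrix(la[li_all, c("x", "y", "z")])
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_contacts())
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  ri <- ri_all[hit[, 1]]
  li <- li_all[hit[, 2]]
  r <- sqrt(d2[hit])
  tibble(
    ri = ri, li = li,
    receptor_serial = ra$serial[ri], ligand_serial = la$serial[li],
    r_type = ra$pair_type[ri], l_type = la$pair_type[li],
    distance = r,
    surface_distance = r - ra$vdw_radius[ri] - la$vdw_radius[li],
    r_hydrophobic = ra$is_hydrophobic[ri], l_hydrophobic = la$is_hydrophobic[li],
    r_donor = ra$is_hbond_donor[ri], l_donor = la$is_hbond_donor[li],
    r_acceptor = ra$is_hbond_acceptor[ri], l_acceptor = la$is_hbond_acceptor[li],
    r_metal = ra$is_metal[ri], l_metal = la$is_metal[li],
    r_charge = ra$partial_charge[ri], l_charge = la$partial_charge[li]
  )
}

empty_contacts <- function() {
  tibble(
    ri = integer(), li = integer(),
    receptor_serial = integer(), ligand_serial = integer(),
    r_type = character(), l_type = character(),
    distance = numeric(), surface_distance = numeric(),
    r_hydrophobic = logical(), l_hydrophobic = logical(),
    r_donor = logical(), l_donor = logical(),
    r_acceptor = logical(), l_acceptor = logical(),
    r_metal = logical(), l_metal = logical(),
    r_charge = numeric(), l_charge = numeric()
  )
}
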