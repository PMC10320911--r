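#' Atom-type parameter table
#'
#' Per-type van der Waals radii (X-Score/Vina-style), Lennard-Jones well
#' depths and pairwise desolvation parameters for the fixed heavy-atom
#' typing alphabet. Bundled as a plain CSV under `extdata` so the values
#' are auditable and editable.
#'
#' @return A tibble with columns `pair_type`, `vdw_radius` (Angstrom),
#'   `lj_epsilon` (kcal/mol), `solv_par`.
#' @export
#' @examples
#' atom_type_params()
atom_type_params <- function() {
  path <- system.file("extdata", "atom_type_params.csv", package = "iecscore")
  # na.strings = NULL: the acceptor-nitrogen type is literally "NA"
  tbl <- as_tibble(read.csv(path, stringsAsFactors = FALSE, na.strings = NULL))
  tbl$pair_type <- as.character(tbl$pair_type)
  tbl
}

#' Pair-kernel parameters
#'
#' Reads the serialized kernel configuration: the global interaction cutoff,
#' the Vina-style steric triple (two Gaussians plus quadratic repulsion with
#' the published default weights), piecewise-linear H-bond and hydrophobic
#' kernels on surface distance, the Coulomb model with distance-dependent
#' dielectric, Gaussian pair desolvation width, hydrogen-bond geometric
#' criteria and the contact-shell radii of the atom-type pair block.
#'
#' @param overrides optional named list merged over the defaults (one level
#'   deep), e.g. `list(cutoff = 6)`.
#' @return Nested list of kernel parameters.
#' @export
kernel_params <- function(overrides = NULL) {
  path <- system.file("extdata", "kernel_params.yaml", package = "iecscore")
  p <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  }
  stopifnot(p$cutoff > 0, p$desolvation$sigma > 0,
            p$hydrophobic_pl$full < p$hydrophobic_pl$zero,
            p$hbond_pl$full < p$hbond_pl$zero)
  p
}

# Fixed heavy-atom pair-type alphabet (AutoDock-style) plus the ignored
# nonpolar hydrogen type "H". MET covers any metal.
pair_type_alphabet <- function(include_nonpolar_h = FALSE) {
  types <- c("C", "A", "N", "NA", "O", "OA", "S", "SA", "P",
             "F", "Cl", "Br", "I", "HD", "MET")
  if (include_nonpolar_h) c(types, "H") else types
}

metal_elements <- function() {
  c("Zn", "Mg", "Mn", "Ca", "Fe", "Ni", "Cu", "Co", "Na", "K", "Cd", "Hg")
}

# Covalent radii used only for distance-based bond inference on structures
# that carry no explicit connectivity (PDB receptors).
covalent_radii <- function() {
  c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
    F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
    Zn = 1.22, Mg = 1.41, Mn = 1.39, Ca = 1.76, Fe = 1.32, Ni = 1.24,
    Cu = 1.32, Co = 1.26, Na = 1.66, K = 2.03, Cd = 1.44, Hg = 1.32)
}
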