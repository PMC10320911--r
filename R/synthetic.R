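#' Specification of a planted synthetic complex
#'
#' Describes a toy protein-ligand complex whose descriptor values are
#' computable in closed form: isolated interaction sites (pairwise more
#' than 8 Angstrom apart, so pair terms are exactly additive) planted on a
#' line, plus inert decoy atoms far from the interface.
#'
#' @param n_hydrophobic_contacts carbon-carbon contacts at surface
#'   distance 0 (kernel plateau).
#' @param n_hbonds linear N-H...O geometries (H...O 1.9 Angstrom).
#' @param n_clashes oxygen-oxygen pairs at surface distance -0.5.
#' @param charge_pairs data frame with columns `q_receptor`, `q_ligand`,
#'   `distance`: carbon pairs carrying the given partial charges.
#' @param n_decoy decoy ligand atoms placed far from every receptor atom.
#' @param n_scaffold inert receptor carbon-grid atoms far from all sites.
#' @param seed integer seed (kept for provenance; geometry is
#'   deterministic).
#' @return Object of class `iec_plant_spec`.
#' @export
plant_spec <- function(n_hydrophobic_contacts = 0, n_hbonds = 0, n_clashes = 0,
                       charge_pairs = NULL, n_decoy = 0, n_scaffold = 4,
                       seed = 1) {
  stopifnot(n_hydrophobic_contacts >= 0, n_hbonds >= 0, n_clashes >= 0,
            n_decoy >= 0, n_scaffold >= 0)
  if (!is.null(charge_pairs)) {
    charge_pairs <- as_tibble(charge_pairs)
    stopifnot(all(c("q_receptor", "q_ligand", "distance") %in% names(charge_pairs)),
              all(charge_pairs$distance > 0))
  }
  structure(list(n_hydrophobic_contacts = n_hydrophobic_contacts,
                 n_hbonds = n_hbonds, n_clashes = n_clashes,
                 charge_pairs = charge_pairs, n_decoy = n_decoy,
                 n_scaffold = n_scaffold, seed = as.integer(seed)),
            class = "iec_plant_spec")
}

# site spacing guaranteeing no cross-site pair within the 8 A cutoff
.site_spacing <- 25

#' Generate a planted complex and its ground-truth descriptor vector
#'
#' Builds the complex described by a [plant_spec()] and evaluates every
#' native descriptor from the planted geometry with an independent
#' single-pair evaluator (plain closed-form arithmetic, no shared code
#' with the production term calculators).
#'
#' @param spec an `iec_plant_spec`.
#' @return List with `complex` (typed `iec_complex`) and `truth` (named
#'   vector over the full smina + nnscore + aux schema).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "iec_plant_spec"))
  r_atoms <- list(); r_bonds <- list()
  l_atoms <- list()
  site <- 0
  add_r <- function(el, x, y, z, q = 0) {
    r_atoms[[length(r_atoms) + 1]] <<- list(element = el, x = x, y = y, z = z, q = q)
    length(r_atoms)
  }
  add_l <- function(el, x, y, z, q = 0) {
    l_atoms[[length(l_atoms) + 1]] <<- list(element = el, x = x, y = y, z = z, q = q)
    length(l_atoms)
  }

  for (k in seq_len(spec$n_hydrophobic_contacts)) {
    x0 <- site * .site_spacing; site <- site + 1
    add_r("C", x0, 0, 0)
    add_l("C", x0, 3.8, 0)          # r = R_C + R_C, surface distance 0
  }
  for (k in seq_len(spec$n_hbonds)) {
    x0 <- site * .site_spacing; site <- site + 1
    ni <- add_r("N", x0, 0, 0)
    hi <- add_r("H", x0, 1.0, 0)
    r_bonds[[length(r_bonds) + 1]] <- c(ni, hi)
    add_l("O", x0, 2.9, 0)          # H...O = 1.9, angle 180
  }
  for (k in seq_len(spec$n_clashes)) {
    x0 <- site * .site_spacing; site <- site + 1
    add_r("O", x0, 0, 0)
    add_l("O", x0, 2.9, 0)          # surface distance 2.9 - 3.4 = -0.5
  }
  cp <- spec$charge_pairs
  if (!is.null(cp)) {
    for (k in seq_len(nrow(cp))) {
      x0 <- site * .site_spacing; site <- site + 1
      add_r("C", x0, 0, 0, q = cp$q_receptor[k])
      add_l("C", x0, cp$distance[k], 0, q = cp$q_ligand[k])
    }
  }
  for (k in seq_len(spec$n_scaffold)) {
    add_r("C", (k - 1) * 5, 0, -60)
  }
  for (k in seq_len(spec$n_decoy)) {
    add_l("C", (k - 1) * 10, 60, 0)   # >8 A apart: no intra-ligand LJ either
  }
  if (length(l_atoms) == 0) add_l("C", 0, 60, 0)  # a ligand must exist
  if (length(r_atoms) == 0) add_r("C", 0, 0, -60)

  to_tbl <- function(lst) {
    tibble(serial = seq_along(lst),
           element = vapply(lst, `[[`, "", "element"),
           x = vapply(lst, `[[`, 0, "x"),
           y = vapply(lst, `[[`, 0, "y"),
           z = vapply(lst, `[[`, 0, "z"),
           partial_charge = vapply(lst, `[[`, 0, "q"))
  }
  rb <- if (length(r_bonds) > 0) {
    m <- do.call(rbind, r_bonds)
    tibble(from = m[, 1], to = m[, 2], order = 1L)
  } else NULL
  receptor <- assign_types(molecule(to_tbl(r_atoms), rb, name = "synthetic_receptor"),
                           infer_bonds = FALSE)
  ligand <- assign_types(molecule(to_tbl(l_atoms), NULL,
                                  name = sprintf("synthetic_ligand_%d", spec$seed)),
                         infer_bonds = FALSE)
  # planted charges are authoritative: assign_types only fills NAs, but the
  # receptor N-H site gets PEOE charges; reset to the planted values
  receptor$atoms$partial_charge <- vapply(r_atoms, `[[`, 0, "q")
  ligand$atoms$partial_charge <- vapply(l_atoms, `[[`, 0, "q")

  list(complex = plcomplex(receptor, ligand),
       truth = plant_truth(spec))
}

# ---- independent single-pair ground-truth evaluator -----------------------
# Closed-form arithmetic from the planted geometry; deliberately written
# without calling the production kernels.

plant_truth <- function(spec) {
  schema <- c(paste0("smina:", c("vdw", "hbond", "elec", "hydrophobic",
                                 "non_hydrophobic", "sol")),
              nn_schema(),
              paste0("aux:", c("entropy", "clash", "metal", "internal")))
  v <- setNames(numeric(length(schema)), schema)
  ap <- atom_type_params()
  p <- function(t, col) ap[[col]][ap$pair_type == t]
  vol <- function(t) 4 / 3 * pi * p(t, "vdw_radius")^3
  sol_pair <- function(t1, t2, r) {
    (p(t1, "solv_par") * vol(t2) + p(t2, "solv_par") * vol(t1)) *
      exp(-r^2 / (2 * 3.6^2))
  }
  steric <- function(d) {
    -0.035579 * exp(-(d / 0.5)^2) +
      -0.005156 * exp(-((d - 3) / 2)^2) +
      0.840245 * (if (d < 0) d^2 else 0)
  }
  lj <- function(t1, t2, r) {
    rmin <- p(t1, "vdw_radius") + p(t2, "vdw_radius")
    eps <- sqrt(p(t1, "lj_epsilon") * p(t2, "lj_epsilon"))
    eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }

  k <- spec$n_hydrophobic_contacts
  if (k > 0) {
    r <- 3.8; d <- 0
    v["smina:vdw"] <- v["smina:vdw"] + k * steric(d)
    v["smina:hydrophobic"] <- v["smina:hydrophobic"] + k * 1
    v["smina:sol"] <- v["smina:sol"] + k * sol_pair("C", "C", r)
    v["nn:vdw"] <- v["nn:vdw"] + k * lj("C", "C", r)
    v["nn:hydrophobic"] <- v["nn:hydrophobic"] + k * 1
    v["nn:pair_C_C_semi"] <- v["nn:pair_C_C_semi"] + k
  }
  k <- spec$n_hbonds
  if (k > 0) {
    r <- 2.9; d <- 2.9 - 1.8 - 1.7          # N...O heavy pair
    v["smina:vdw"] <- v["smina:vdw"] + k * steric(d)
    v["smina:hbond"] <- v["smina:hbond"] + k * (-d / 0.7)  # linear part of the kernel
    v["smina:non_hydrophobic"] <- v["smina:non_hydrophobic"] + k * 1
    v["smina:sol"] <- v["smina:sol"] + k * sol_pair("N", "OA", r)
    v["nn:vdw"] <- v["nn:vdw"] + k * lj("N", "OA", r)
    v["nn:hbond"] <- v["nn:hbond"] + k * 1
    v["nn:pair_N_OA_semi"] <- v["nn:pair_N_OA_semi"] + k
    v["nn:pair_HD_OA_close"] <- v["nn:pair_HD_OA_close"] + k
    v["aux:clash"] <- v["aux:clash"] + k * d^2
  }
  k <- spec$n_clashes
  if (k > 0) {
    r <- 2.9; d <- -0.5                      # O...O pair
    v["smina:vdw"] <- v["smina:vdw"] + k * steric(d)
    v["smina:non_hydrophobic"] <- v["smina:non_hydrophobic"] + k * 1
    v["smina:sol"] <- v["smina:sol"] + k * sol_pair("OA", "OA", r)
    v["nn:vdw"] <- v["nn:vdw"] + k * lj("OA", "OA", r)
    v["nn:pair_OA_OA_semi"] <- v["nn:pair_OA_OA_semi"] + k
    v["aux:clash"] <- v["aux:clash"] + k * d^2
  }
  cp <- spec$charge_pairs
  if (!is.null(cp)) {
    for (i in seq_len(nrow(cp))) {
      r <- cp$distance[i]; d <- r - 3.8
      if (r > 8) next
      qq <- cp$q_receptor[i] * cp$q_ligand[i]
      v["smina:vdw"] <- v["smina:vdw"] + steric(d)
      v["smina:elec"] <- v["smina:elec"] + 332 * qq / (4 * r * r)
      v["smina:hydrophobic"] <- v["smina:hydrophobic"] +
        (if (d <= 0.5) 1 else if (d >= 1.5) 0 else (1.5 - d))
      v["smina:sol"] <- v["smina:sol"] + sol_pair("C", "C", r)
      v["nn:vdw"] <- v["nn:vdw"] + lj("C", "C", r)
      if (r <= 4) {
        v["nn:hydrophobic"] <- v["nn:hydrophobic"] + 1
        v["nn:elec_C_C"] <- v["nn:elec_C_C"] + 332 * qq / r
        if (r <= 2.5) v["nn:pair_C_C_close"] <- v["nn:pair_C_C_close"] + 1
        else v["nn:pair_C_C_semi"] <- v["nn:pair_C_C_semi"] + 1
      }
      if (d < 0) v["aux:clash"] <- v["aux:clash"] + d^2
    }
  }
  v
}

#' Specification of a labeled synthetic screening set
#'
#' @param n_actives,n_decoys class sizes.
#' @param n_features number of feature columns; columns are named after
#'   registry (scoring function, term) pairs so combination and ablation
#'   machinery applies to synthetic sets.
#' @param effect per-feature mean shift of the active class: a scalar
#'   applied to the first `n_informative` features, or a full vector of
#'   length `n_features`.
#' @param n_informative number of shifted features when `effect` is
#'   scalar.
#' @param covariance `NULL` for identity, or a symmetric positive-definite
#'   matrix.
#' @param seed integer seed.
#' @return Object of class `iec_class_spec`.
#' @export
class_spec <- function(n_actives = 200, n_decoys = 1800, n_features = 50,
                       effect = 2, n_informative = 5, covariance = NULL,
                       seed = 1) {
  stopifnot(n_actives > 0, n_decoys > 0, n_features > 0)
  if (length(effect) == 1) {
    effect <- c(rep(effect, min(n_informative, n_features)),
                rep(0, max(0, n_features - n_informative)))
  }
  stopifnot(length(effect) == n_features)
  if (!is.null(covariance)) {
    stopifnot(isSymmetric(unname(covariance)),
              all(eigen(covariance, only.values = TRUE)$values > 0))
  }
  structure(list(n_actives = n_actives, n_decoys = n_decoys,
                 n_features = n_features, effect = effect,
                 covariance = covariance, seed = as.integer(seed)),
            class = "iec_class_spec")
}

#' Generate a labeled synthetic screening feature set
#'
#' Decoys are drawn from a multivariate Gaussian at mean 0, actives at
#' mean `effect`, with shared covariance. Reproducible per seed.
#'
#' @param spec an `iec_class_spec`.
#' @return Tibble with `ligand`, feature columns, and binary `label`
#'   (1 = active).
#' @export
make_screening_set <- function(spec) {
  stopifnot(inherits(spec, "iec_class_spec"))
  set.seed(spec$seed)
  n <- spec$n_actives + spec$n_decoys
  p <- spec$n_features
  z <- matrix(rnorm(n * p), n, p)
  if (!is.null(spec$covariance)) z <- z %*% chol(spec$covariance)
  label <- c(rep(1L, spec$n_actives), rep(0L, spec$n_decoys))
  z <- z + outer(label, spec$effect)
  colnames(z) <- synthetic_feature_names(p)
  out <- dplyr::bind_cols(tibble(ligand = sprintf("lig_%05d", seq_len(n))),
                          as_tibble(z))
  out$label <- label
  # shuffle row order so class blocks are not contiguous
  out[sample.int(n), , drop = FALSE]
}

synthetic_feature_names <- function(p) {
  reg <- build_registry()
  base <- paste0(reg$scoring_function, ":", reg$term)
  if (p <= length(base)) base[seq_len(p)]
  else c(base, sprintf("extra:f%03d", seq_len(p - length(base))))
}

#' Write a complex to standard text fixtures
#'
#' Emits `receptor.pdb`, `ligand.sdf` and `types.csv` (a sidecar with the
#' assigned pair types, flags and partial charges, which plain PDB/SDF
#' cannot carry). Byte-deterministic for a given complex.
#'
#' @param cplx an `iec_complex`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cplx, dir) {
  stopifnot(inherits(cplx, "iec_complex"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb <- file.path(dir, "receptor.pdb")
  sdf <- file.path(dir, "ligand.sdf")
  sidecar <- file.path(dir, "types.csv")
  write_pdb_atoms(cplx$receptor, pdb)
  write_sdf_mol(cplx$ligand, sdf)
  side <- dplyr::bind_rows(
    dplyr::mutate(cplx$receptor$atoms, molecule = "receptor"),
    dplyr::mutate(cplx$ligand$atoms, molecule = "ligand"))
  side <- side[, c("molecule", "serial", "element", "pair_type", "partial_charge",
                   "vdw_radius", "is_hydrophobic", "is_hbond_donor",
                   "is_hbond_acceptor", "is_metal")]
  utils::write.csv(side, sidecar, row.names = FALSE, quote = FALSE)
  invisible(c(pdb = pdb, sdf = sdf, types = sidecar))
}

write_pdb_atoms <- function(mol, path) {
  at <- mol$atoms
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    name <- sprintf("%-4s", substr(paste0(el, i %% 10), 1, 4))
    lines[i] <- sprintf("%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        "HETATM", at$serial[i], name, "LIG", "A", 1,
                        at$x[i], at$y[i], at$z[i], 1.0, 0.0, toupper(el))
  }
  writeLines(c(lines, "END"), path)
}

write_sdf_mol <- function(mol, path) {
  at <- mol$atoms
  bd <- mol$bonds
  lines <- c(mol$name, "  iecscore", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(bd)))
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              at$x[i], at$y[i], at$z[i], at$element[i]))
  }
  for (k in seq_len(nrow(bd))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", bd$from[k], bd$to[k], bd$order[k]))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
}

#' Read back a fixture written by [write_fixture()]
#'
#' Parses the PDB/SDF pair and restores the sidecar typing (pair types,
#' flags, planted charges), yielding a complex equivalent to the one
#' written.
#'
#' @param dir fixture directory.
#' @return An `iec_complex`.
#' @export
read_fixture <- function(dir) {
  rec <- parse_receptor(file.path(dir, "receptor.pdb"))
  lig <- parse_ligand(file.path(dir, "ligand.sdf"), "sdf")[[1]]
  side <- read.csv(file.path(dir, "types.csv"), stringsAsFactors = FALSE)
  apply_side <- function(mol, which) {
    s <- side[side$molecule == which, , drop = FALSE]
    s <- s[match(mol$atoms$serial, s$serial), , drop = FALSE]
    for (col in c("pair_type", "partial_charge", "vdw_radius", "is_hydrophobic",
                  "is_hbond_donor", "is_hbond_acceptor", "is_metal")) {
      mol$atoms[[col]] <- s[[col]]
    }
    # PDB carries no connectivity; donor-H bonds are needed for H-bond geometry
    if (nrow(mol$bonds) == 0 && nrow(mol$atoms) > 1) {
      mol$bonds <- infer_bonds_by_distance(mol$atoms)
    }
    mol
  }
  plcomplex(apply_side(rec, "receptor"), apply_side(lig, "ligand"))
}
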