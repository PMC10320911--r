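#' Smina-style six-term descriptor block
#'
#' Computes the six interaction energy components of the Smina/Vina family
#' over interface contacts within the global cutoff: the steric van der
#' Waals triple (two Gaussians plus quadratic repulsion on the surface
#' distance, default weights), a non-directional piecewise-linear H-bond
#' kernel over complementary donor-acceptor pairs, a Coulomb electrostatic
#' sum with distance-dependent dielectric, piecewise-linear hydrophobic and
#' non-hydrophobic contact terms, and a Gaussian pair desolvation term.
#' Steric, hydrophobic and desolvation sums run over heavy-atom pairs;
#' electrostatics includes polar hydrogens (they carry charge).
#'
#' @param cplx a typed `iec_complex`.
#' @param params kernel parameters, see [kernel_params()].
#' @return Named numeric vector with entries `smina:vdw`, `smina:hbond`,
#'   `smina:elec`, `smina:hydrophobic`, `smina:non_hydrophobic`, `smina:sol`.
#' @export
smina_terms <- function(cplx, params = kernel_params()) {
  ct <- prepared_contacts(cplx, params)
  heavy <- ct$r_type != "HD" & ct$l_type != "HD"
  h <- ct[heavy, , drop = FALSE]
  d <- h$surface_distance

  vdw <- sum(vina_steric(d, params))

  da <- (h$r_donor & h$l_acceptor) | (h$r_acceptor & h$l_donor)
  hb <- sum(piecewise_linear_kernel(d[da], params$hbond_pl$full, params$hbond_pl$zero))

  elec <- if (nrow(ct) == 0) 0 else
    coulomb_sum(ct, params, dielectric = "distance_dependent")

  phob <- h$r_hydrophobic & h$l_hydrophobic
  nonphob <- !h$r_hydrophobic & !h$l_hydrophobic
  k_phob <- piecewise_linear_kernel(d, params$hydrophobic_pl$full, params$hydrophobic_pl$zero)
  hydrophobic <- sum(k_phob[phob])
  non_hydrophobic <- sum(k_phob[nonphob])

  ap <- atom_type_params()
  si <- ap$solv_par[match(h$r_type, ap$pair_type)]
  sj <- ap$solv_par[match(h$l_type, ap$pair_type)]
  rad_i <- ap$vdw_radius[match(h$r_type, ap$pair_type)]
  rad_j <- ap$vdw_radius[match(h$l_type, ap$pair_type)]
  sol <- sum(desolvation_kernel(h$distance, si, type_volume(rad_i),
                                sj, type_volume(rad_j), params$desolvation$sigma))

  c("smina:vdw" = vdw, "smina:hbond" = hb, "smina:elec" = elec,
    "smina:hydrophobic" = hydrophobic, "smina:non_hydrophobic" = non_hydrophobic,
    "smina:sol" = sol)
}

#' Coulomb electrostatic sum over contacts
#'
#' \eqn{\sum 332 \, q_i q_j / (\epsilon(r) \, r)} in kcal/mol-like units;
#' opposite charges give negative energy. The dielectric model is either
#' `"distance_dependent"` (\eqn{\epsilon(r) = 4r}) or `"constant"`
#' (\eqn{\epsilon} from `params$elec$epsilon`).
#'
#' @param ct contact tibble from [contacts()].
#' @param params kernel parameters.
#' @param dielectric override of `params$elec$dielectric`.
#' @export
coulomb_sum <- function(ct, params = kernel_params(), dielectric = NULL) {
  if (nrow(ct) == 0) return(0)
  if (any(ct$distance == 0)) abort("overlapping atoms: r = 0 in a contact pair")
  sum(coulomb_kernel(ct$distance, ct$r_charge, ct$l_charge, params, dielectric))
}

#' Count interface hydrogen bonds
#'
#' Counts donor-H...acceptor triples across the protein-ligand interface
#' satisfying both a distance and an angle criterion: H...A within
#' `dist_cutoff`, donor-acceptor heavy distance within `da_max`, and
#' D-H...A angle at the hydrogen of at least `angle_cutoff` degrees. Both
#' directions (protein donor to ligand acceptor and vice versa) count.
#' Donors flagged without a resolvable polar hydrogen are skipped with a
#' warning.
#'
#' @param cplx typed `iec_complex` with polar hydrogens present.
#' @param dist_cutoff maximum H...acceptor distance (Angstrom).
#' @param angle_cutoff minimum D-H...A angle (degrees).
#' @param da_max maximum donor...acceptor heavy-atom distance (Angstrom).
#' @return Nonnegative integer count.
#' @export
hbond_count <- function(cplx, dist_cutoff = kernel_params()$hbond_geom$ha_max,
                        angle_cutoff = kernel_params()$hbond_geom$angle_min,
                        da_max = kernel_params()$hbond_geom$da_max) {
  stopifnot(inherits(cplx, "iec_complex"))
  n1 <- count_hbonds_directed(cplx$receptor, cplx$ligand, dist_cutoff, angle_cutoff, da_max)
  n2 <- count_hbonds_directed(cplx$ligand, cplx$receptor, dist_cutoff, angle_cutoff, da_max)
  n1 + n2
}

count_hbonds_directed <- function(donor_mol, acceptor_mol, ha_max, angle_min, da_max) {
  da <- donor_mol$atoms
  aa <- acceptor_mol$atoms
  donors <- which(da$is_hbond_donor)
  acceptors <- which(aa$is_hbond_acceptor)
  if (length(donors) == 0 || length(acceptors) == 0) return(0L)
  nb <- neighbor_list(nrow(da), donor_mol$bonds)
  count <- 0L
  for (di in donors) {
    hs <- nb[[di]][da$pair_type[nb[[di]]] == "HD"]
    if (length(hs) == 0) {
      warn(sprintf("donor atom %d has no polar hydrogen; skipped", da$serial[di]))
      next
    }
    dpos <- c(da$x[di], da$y[di], da$z[di])
    for (hi in hs) {
      hpos <- c(da$x[hi], da$y[hi], da$z[hi])
      for (ai in acceptors) {
        apos <- c(aa$x[ai], aa$y[ai], aa$z[ai])
        ha <- sqrt(sum((apos - hpos)^2))
        if (ha > ha_max) next
        if (sqrt(sum((apos - dpos)^2)) > da_max) next
        v1 <- dpos - hpos
        v2 <- apos - hpos
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        if (ang >= angle_min) count <- count + 1L
      }
    }
  }
  count
}

#' NNScore-2-style contact and electrostatics block
#'
#' The full fixed-schema feature vector: a Lennard-Jones 6-12 sum over
#' heavy-atom contacts, the geometric H-bond count, the hydrophobic
#' heavy-pair contact count within 4 Angstrom, per-atom-type-pair contact
#' counts in two shells (close, within 2.5 Angstrom; semi-close, 2.5-4.0),
#' and per-type-pair Coulomb sums within 4 Angstrom. Pair keys are
#' canonically ordered (`T1 <= T2` in C-locale); absent pairs are emitted
#' as 0 so the schema never varies.
#'
#' @inheritParams smina_terms
#' @return Named numeric vector (`nn:vdw`, `nn:hbond`, `nn:hydrophobic`,
#'   `nn:pair_<T1>_<T2>_close`, `nn:pair_<T1>_<T2>_semi`,
#'   `nn:elec_<T1>_<T2>`).
#' @export
nnscore_block <- function(cplx, params = kernel_params()) {
  ct <- prepared_contacts(cplx, params)
  keys <- nn_pair_keys()
  out <- setNames(numeric(length(nn_schema())), nn_schema())

  heavy <- ct[ct$r_type != "HD" & ct$l_type != "HD", , drop = FALSE]
  if (nrow(heavy) > 0) {
    rmin <- heavy_rmin(heavy)
    eps <- heavy_eps(heavy)
    out["nn:vdw"] <- sum(lj_kernel(heavy$distance, rmin, eps))
    phob <- heavy$r_hydrophobic & heavy$l_hydrophobic &
      heavy$distance <= params$nnscore$hydrophobic_max
    out["nn:hydrophobic"] <- sum(phob)
  }
  out["nn:hbond"] <- hbond_count(cplx, params$hbond_geom$ha_max,
                                 params$hbond_geom$angle_min,
                                 params$hbond_geom$da_max)

  if (nrow(ct) > 0) {
    key <- canonical_pair_key(ct$r_type, ct$l_type)
    close_sel <- ct$distance <= params$nnscore$close_max
    semi_sel <- ct$distance > params$nnscore$close_max &
      ct$distance <= params$nnscore$semi_max
    close_counts <- table(key[close_sel])
    semi_counts <- table(key[semi_sel])
    if (length(close_counts) > 0) {
      nm <- paste0("nn:pair_", names(close_counts), "_close")
      out[nm] <- out[nm] + as.numeric(close_counts)
    }
    if (length(semi_counts) > 0) {
      nm <- paste0("nn:pair_", names(semi_counts), "_semi")
      out[nm] <- out[nm] + as.numeric(semi_counts)
    }

    esel <- ct$distance <= params$nnscore$elec_max
    if (any(esel)) {
      ec <- ct[esel, , drop = FALSE]
      ekey <- canonical_pair_key(ec$r_type, ec$l_type)
      ev <- coulomb_kernel(ec$distance, ec$r_charge, ec$l_charge, params,
                           dielectric = "constant_unit")
      agg <- tapply(ev, ekey, sum)
      if (length(agg) > 0) {
        nm <- paste0("nn:elec_", names(agg))
        out[nm] <- out[nm] + as.numeric(agg)
      }
    }
  }
  out
}

heavy_rmin <- function(ct) {
  ap <- atom_type_params()
  ap$vdw_radius[match(ct$r_type, ap$pair_type)] +
    ap$vdw_radius[match(ct$l_type, ap$pair_type)]
}

heavy_eps <- function(ct) {
  ap <- atom_type_params()
  sqrt(ap$lj_epsilon[match(ct$r_type, ap$pair_type)] *
         ap$lj_epsilon[match(ct$l_type, ap$pair_type)])
}

canonical_pair_key <- function(t1, t2) {
  # rank against the radix-sorted alphabet so ordering is locale-independent
  types <- sort(pair_type_alphabet(), method = "radix")
  r1 <- match(t1, types)
  r2 <- match(t2, types)
  a <- ifelse(r1 <= r2, t1, t2)
  b <- ifelse(r1 <= r2, t2, t1)
  paste(a, b, sep = "_")
}

nn_pair_keys <- function() {
  types <- sort(pair_type_alphabet(), method = "radix")
  pairs <- character()
  for (i in seq_along(types)) {
    for (j in i:length(types)) {
      pairs <- c(pairs, paste(types[i], types[j], sep = "_"))
    }
  }
  pairs
}

nn_schema <- function() {
  keys <- nn_pair_keys()
  c("nn:vdw", "nn:hbond", "nn:hydrophobic",
    paste0("nn:pair_", keys, "_close"),
    paste0("nn:pair_", keys, "_semi"),
    paste0("nn:elec_", keys))
}

#' Ligand rotatable-bond (entropy) term
#'
#' Number of rotatable bonds: non-ring single bonds between heavy atoms
#' where each end bears at least one additional heavy neighbor; amide C-N
#' bonds are excluded. Only ligand flexibility is counted (the receptor is
#' treated as rigid).
#'
#' @param ligand an `iec_molecule` with bonds.
#' @return Nonnegative integer.
#' @export
entropy_term <- function(ligand) {
  stopifnot(inherits(ligand, "iec_molecule"))
  atoms <- ligand$atoms
  bonds <- ligand$bonds
  if (nrow(bonds) == 0) return(0L)
  n <- nrow(atoms)
  heavy <- atoms$element != "H"
  nb <- neighbor_list(n, bonds)
  in_ring_edge <- ring_edges(n, bonds)
  count <- 0L
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] != 1L || in_ring_edge[k]) next
    i <- bonds$from[k]; j <- bonds$to[k]
    if (!heavy[i] || !heavy[j]) next
    extra_i <- sum(heavy[setdiff(nb[[i]], j)])
    extra_j <- sum(heavy[setdiff(nb[[j]], i)])
    if (extra_i < 1 || extra_j < 1) next
    if (is_amide_cn(i, j, atoms, bonds, nb) || is_amide_cn(j, i, atoms, bonds, nb)) next
    count <- count + 1L
  }
  count
}

ring_edges <- function(n, bonds) {
  if (nrow(bonds) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  out <- rep(TRUE, nrow(bonds))
  out[as.integer(igraph::bridges(g))] <- FALSE
  out
}

is_amide_cn <- function(ci, ni, atoms, bonds, nb) {
  if (atoms$element[ci] != "C" || atoms$element[ni] != "N") return(FALSE)
  sel <- (bonds$from == ci | bonds$to == ci) & bonds$order == 2L
  if (!any(sel)) return(FALSE)
  partners <- ifelse(bonds$from[sel] == ci, bonds$to[sel], bonds$from[sel])
  any(atoms$element[partners] == "O")
}

#' Steric clash penalty
#'
#' Quadratic repulsion \eqn{\sum d^2} over heavy-atom interface contacts
#' with negative surface distance (interpenetrating vdW spheres); 0 when no
#' pair interpenetrates.
#'
#' @inheritParams smina_terms
#' @export
clash_term <- function(cplx, params = kernel_params()) {
  ct <- prepared_contacts(cplx, params, require_heavy_ligand = FALSE)
  h <- ct[ct$r_type != "HD" & ct$l_type != "HD", , drop = FALSE]
  sum(repulsion_kernel(h$surface_distance))
}

#' Metal coordination term
#'
#' Piecewise-linear attraction over (receptor metal, ligand acceptor)
#' pairs: 1 on the plateau (center distance within `params$metal$full`),
#' 0 beyond `params$metal$zero`, linear in between.
#'
#' @inheritParams smina_terms
#' @export
metal_term <- function(cplx, params = kernel_params()) {
  ct <- prepared_contacts(cplx, params, require_heavy_ligand = FALSE)
  sel <- ct$r_metal & ct$l_acceptor
  sum(piecewise_linear_kernel(ct$distance[sel], params$metal$full, params$metal$zero))
}

#' Ligand internal steric term
#'
#' Intramolecular Lennard-Jones sum over ligand heavy-atom pairs separated
#' by at least three bonds (1-4 and beyond, plus disconnected fragments)
#' within the global cutoff; a proxy for ligand torsional strain.
#'
#' @param ligand typed `iec_molecule`.
#' @param params kernel parameters.
#' @export
internal_term <- function(ligand, params = kernel_params()) {
  atoms <- ligand$atoms
  heavy <- which(atoms$pair_type != "HD" & atoms$pair_type != "H")
  if (length(heavy) < 2) return(0)
  n <- nrow(atoms)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ligand$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(ligand$bonds$from, ligand$bonds$to))
  }
  topo <- igraph::distances(g)
  ap <- atom_type_params()
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  total <- 0
  for (ii in seq_along(heavy)[-length(heavy)]) {
    for (jj in (ii + 1):length(heavy)) {
      i <- heavy[ii]; j <- heavy[jj]
      if (is.finite(topo[i, j]) && topo[i, j] < 3) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > params$cutoff || r == 0) next
      rmin <- ap$vdw_radius[match(atoms$pair_type[i], ap$pair_type)] +
        ap$vdw_radius[match(atoms$pair_type[j], ap$pair_type)]
      eps <- sqrt(ap$lj_epsilon[match(atoms$pair_type[i], ap$pair_type)] *
                    ap$lj_epsilon[match(atoms$pair_type[j], ap$pair_type)])
      total <- total + lj_kernel(r, rmin, eps)
    }
  }
  total
}

prepared_contacts <- function(cplx, params, require_heavy_ligand = TRUE) {
  stopifnot(inherits(cplx, "iec_complex"))
  if (require_heavy_ligand &&
      !any(!cplx$ligand$atoms$element %in% "H")) {
    abort("ligand has zero heavy atoms")
  }
  contacts(cplx, cutoff = params$cutoff)
}

#' Featurize complexes into a descriptor table
#'
#' One row per ligand; the column schema is fixed by the chosen blocks:
#' `smina` (six components), `nnscore` (full contact/electrostatics
#' vector) and `aux` (`aux:entropy` rotatable bonds, `aux:clash`,
#' `aux:metal`, `aux:internal`). Deterministic given the inputs.
#'
#' @param complexes a single `iec_complex` or list of them.
#' @param blocks character subset of `c("smina", "nnscore", "aux")`.
#' @param params kernel parameters.
#' @return Tibble with `ligand` identifier column first.
#' @export
featurize <- function(complexes, blocks = c("smina", "nnscore"),
                      params = kernel_params()) {
  blocks <- match.arg(blocks, c("smina", "nnscore", "aux"), several.ok = TRUE)
  if (inherits(complexes, "iec_complex")) complexes <- list(complexes)
  schema <- character()
  if ("smina" %in% blocks) {
    schema <- c(schema, paste0("smina:", c("vdw", "hbond", "elec", "hydrophobic",
                                           "non_hydrophobic", "sol")))
  }
  if ("nnscore" %in% blocks) schema <- c(schema, nn_schema())
  if ("aux" %in% blocks) {
    schema <- c(schema, paste0("aux:", c("entropy", "clash", "metal", "internal")))
  }
  if (length(complexes) == 0) {
    return(as_tibble(c(list(ligand = character()),
                       setNames(rep(list(numeric()), length(schema)), schema))))
  }
  rows <- purrr::map(complexes, function(cp) {
    v <- numeric()
    if ("smina" %in% blocks) v <- c(v, smina_terms(cp, params))
    if ("nnscore" %in% blocks) v <- c(v, nnscore_block(cp, params))
    if ("aux" %in% blocks) {
      v <- c(v, "aux:entropy" = as.numeric(entropy_term(cp$ligand)),
             "aux:clash" = clash_term(cp, params),
             "aux:metal" = metal_term(cp, params),
             "aux:internal" = internal_term(cp$ligand, params))
    }
    c(list(ligand = cp$ligand$name), as.list(v[schema]))
  })
  dplyr::bind_rows(rows)
}
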