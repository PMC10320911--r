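# Fixture builders and independent oracles shared across the suite.
# The oracles re-derive every quantity with plain double loops and inline
# formulas -- no calls into the production kernel/term code paths.

suppressPackageStartupMessages({
  library(tibble)
  library(dplyr)
})

type_table <- function() {
  read.csv(system.file("extdata", "atom_type_params.csv", package = "iecscore"),
           stringsAsFactors = FALSE, na.strings = NULL)
}

# scatter points with a minimum pairwise separation (docked heavy atoms
# are never closer than ~2 A; also keeps r^-12 terms numerically tame)
scatter_points <- function(n, center, spread, existing = NULL, min_sep = 2.2) {
  pts <- existing
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    cand <- center
    for (try in 1:200) {
      cand <- center + runif(3, -spread, spread)
      if (is.null(pts) ||
          min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep) break
      if (try == 200) spread <- spread * 1.3  # grow the box rather than spin
    }
    out[i, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

# a typed molecule with random heavy atoms (no hydrogens): flags derived
# from the type so typing is internally consistent
random_typed_molecule <- function(n, seed, center = c(0, 0, 0), spread = 5,
                                  name = "mol", charged = TRUE,
                                  avoid = NULL) {
  set.seed(seed)
  types <- c("C", "A", "N", "NA", "O", "OA", "S", "SA", "F", "Cl", "MET")
  tt <- type_table()
  pt <- sample(types, n, replace = TRUE)
  xyz <- scatter_points(n, center, spread, existing = avoid)
  atoms <- tibble(
    serial = seq_len(n),
    element = c(C = "C", A = "C", N = "N", "NA" = "N", O = "O", OA = "O",
                S = "S", SA = "S", F = "F", Cl = "Cl", MET = "Zn")[pt],
    x = xyz[, 1],
    y = xyz[, 2],
    z = xyz[, 3],
    partial_charge = if (charged) round(runif(n, -0.5, 0.5), 3) else 0,
    vdw_radius = tt$vdw_radius[match(pt, tt$pair_type)],
    is_hydrophobic = pt %in% c("C", "A", "F", "Cl"),
    is_hbond_donor = pt %in% "N",
    is_hbond_acceptor = pt %in% c("NA", "OA", "SA"),
    is_metal = pt == "MET",
    pair_type = pt
  )
  molecule(atoms, NULL, name = name)
}

random_typed_complex <- function(seed, n_rec = 60, n_lig = 15, gap = 4) {
  rec <- random_typed_molecule(n_rec, seed, center = c(0, 0, 0),
                               name = "rec")
  lig <- random_typed_molecule(n_lig, seed + 10000, center = c(gap, 0, 0),
                               spread = 3, name = "lig",
                               avoid = as.matrix(rec$atoms[, c("x", "y", "z")]))
  plcomplex(rec, lig)
}

# ---- brute-force oracles --------------------------------------------------

oracle_contact_pairs <- function(cplx, cutoff) {
  ra <- cplx$receptor$atoms
  la <- cplx$ligand$atoms
  out <- NULL
  for (i in seq_len(nrow(ra))) {
    if (ra$pair_type[i] == "H") next
    for (j in seq_len(nrow(la))) {
      if (la$pair_type[j] == "H") next
      r <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (r <= cutoff) out <- rbind(out, c(i, j, r))
    }
  }
  out
}

# independent recomputation of the native pairwise descriptor sums
oracle_pair_terms <- function(cplx, cutoff = 8) {
  tt <- type_table()
  P <- function(t, col) tt[[col]][match(t, tt$pair_type)]
  ra <- cplx$receptor$atoms
  la <- cplx$ligand$atoms
  acc <- c("smina:vdw" = 0, "smina:hbond" = 0, "smina:elec" = 0,
           "smina:hydrophobic" = 0, "smina:non_hydrophobic" = 0,
           "smina:sol" = 0, "nn:vdw" = 0, "nn:hydrophobic" = 0,
           "aux:clash" = 0, "aux:metal" = 0)
  pair_counts <- list()
  elec_sums <- list()
  for (i in seq_len(nrow(ra))) {
    ti <- ra$pair_type[i]
    if (ti == "H") next
    for (j in seq_len(nrow(la))) {
      tj <- la$pair_type[j]
      if (tj == "H") next
      r <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (r > cutoff) next
      d <- r - ra$vdw_radius[i] - la$vdw_radius[j]
      if (ti != "HD" && tj != "HD") {
        acc["smina:vdw"] <- acc["smina:vdw"] +
          (-0.035579) * exp(-(d / 0.5)^2) +
          (-0.005156) * exp(-((d - 3) / 2)^2) +
          0.840245 * (if (d < 0) d^2 else 0)
        if ((ra$is_hbond_donor[i] && la$is_hbond_acceptor[j]) ||
            (ra$is_hbond_acceptor[i] && la$is_hbond_donor[j])) {
          acc["smina:hbond"] <- acc["smina:hbond"] +
            (if (d <= -0.7) 1 else if (d >= 0) 0 else -d / 0.7)
        }
        phk <- if (d <= 0.5) 1 else if (d >= 1.5) 0 else (1.5 - d)
        if (ra$is_hydrophobic[i] && la$is_hydrophobic[j]) {
          acc["smina:hydrophobic"] <- acc["smina:hydrophobic"] + phk
          if (r <= 4) acc["nn:hydrophobic"] <- acc["nn:hydrophobic"] + 1
        }
        if (!ra$is_hydrophobic[i] && !la$is_hydrophobic[j]) {
          acc["smina:non_hydrophobic"] <- acc["smina:non_hydrophobic"] + phk
        }
        vol <- function(t) 4 / 3 * pi * P(t, "vdw_radius")^3
        acc["smina:sol"] <- acc["smina:sol"] +
          (P(ti, "solv_par") * vol(tj) + P(tj, "solv_par") * vol(ti)) *
          exp(-r^2 / (2 * 3.6^2))
        rmin <- P(ti, "vdw_radius") + P(tj, "vdw_radius")
        eps <- sqrt(P(ti, "lj_epsilon") * P(tj, "lj_epsilon"))
        acc["nn:vdw"] <- acc["nn:vdw"] + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
        if (d < 0) acc["aux:clash"] <- acc["aux:clash"] + d^2
      }
      acc["smina:elec"] <- acc["smina:elec"] +
        332 * ra$partial_charge[i] * la$partial_charge[j] / (4 * r * r)
      if (ra$is_metal[i] && la$is_hbond_acceptor[j]) {
        acc["aux:metal"] <- acc["aux:metal"] +
          (if (r <= 2.2) 1 else if (r >= 4.0) 0 else (4.0 - r) / 1.8)
      }
      key <- paste(sort(c(ti, tj), method = "radix"), collapse = "_")
      if (r <= 2.5) {
        k <- paste0("nn:pair_", key, "_close")
        pair_counts[[k]] <- (pair_counts[[k]] %||% 0) + 1
      } else if (r <= 4.0) {
        k <- paste0("nn:pair_", key, "_semi")
        pair_counts[[k]] <- (pair_counts[[k]] %||% 0) + 1
      }
      if (r <= 4.0) {
        k <- paste0("nn:elec_", key)
        elec_sums[[k]] <- (elec_sums[[k]] %||% 0) +
          332 * ra$partial_charge[i] * la$partial_charge[j] / r
      }
    }
  }
  c(acc, unlist(pair_counts), unlist(elec_sums))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply one rigid rotation + translation to every atom of a complex
transform_complex <- function(cplx, angles = c(0.3, -0.7, 1.1),
                              shift = c(5, -3, 2)) {
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  R <- rot(angles)
  move <- function(mol) {
    xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
    mol$atoms$x <- xyz[, 1] + shift[1]
    mol$atoms$y <- xyz[, 2] + shift[2]
    mol$atoms$z <- xyz[, 3] + shift[3]
    mol
  }
  plcomplex(move(cplx$receptor), move(cplx$ligand))
}

# minimal two-atom typed complex at an exact separation
two_atom_complex <- function(r, t_rec = "C", t_lig = "C",
                             q_rec = 0, q_lig = 0) {
  tt <- type_table()
  mk <- function(t, x, q, nm) {
    el <- c(C = "C", A = "C", N = "N", "NA" = "N", O = "O", OA = "O",
            S = "S", SA = "S", F = "F", Cl = "Cl", Br = "Br", I = "I",
            MET = "Zn", HD = "H", P = "P")[t]
    molecule(tibble(
      serial = 1L, element = unname(el), x = x, y = 0, z = 0,
      partial_charge = q,
      vdw_radius = tt$vdw_radius[match(t, tt$pair_type)],
      is_hydrophobic = t %in% c("C", "A", "F", "Cl", "Br", "I"),
      is_hbond_donor = FALSE,
      is_hbond_acceptor = t %in% c("NA", "OA", "SA"),
      is_metal = t == "MET", pair_type = t), NULL, nm)
  }
  plcomplex(mk(t_rec, 0, q_rec, "rec"), mk(t_lig, r, q_lig, "lig"))
}
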