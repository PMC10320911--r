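# Pair kernels shared by the descriptor blocks. All take the surface
# distance d (Angstrom) or the center distance r and return per-pair values;
# summation over contacts happens in the term calculators.

gauss_kernel <- function(d, offset, width) {
  exp(-((d - offset) / width)^2)
}

repulsion_kernel <- function(d) {
  ifelse(d < 0, d^2, 0)
}

# 1 on the plateau (d <= full), 0 beyond `zero`, linear in between
piecewise_linear_kernel <- function(d, full, zero) {
  ifelse(d <= full, 1, ifelse(d >= zero, 0, (zero - d) / (zero - full)))
}

# Vina steric triple with default weights
vina_steric <- function(d, p) {
  p$vina$gauss1$weight * gauss_kernel(d, p$vina$gauss1$offset, p$vina$gauss1$width) +
    p$vina$gauss2$weight * gauss_kernel(d, p$vina$gauss2$offset, p$vina$gauss2$width) +
    p$vina$repulsion$weight * repulsion_kernel(d)
}

# Lennard-Jones 6-12 with pair minimum at R_i + R_j
lj_kernel <- function(r, rmin, eps) {
  sr6 <- (rmin / r)^6
  eps * (sr6^2 - 2 * sr6)
}

# Coulomb per-pair energy; eps_model "distance_dependent" uses eps(r) = 4r
coulomb_kernel <- function(r, qi, qj, p, dielectric = NULL) {
  dielectric <- dielectric %||% p$elec$dielectric
  eps <- if (identical(dielectric, "distance_dependent")) 4 * r
  else if (identical(dielectric, "constant_unit")) 1
  else p$elec$epsilon
  p$elec$constant * qi * qj / (eps * r)
}

# AutoDock4-style Gaussian pair desolvation; S are per-type solvation
# parameters, V fragmental volumes derived from the vdW radii
desolvation_kernel <- function(r, si, vi, sj, vj, sigma) {
  (si * vj + sj * vi) * exp(-r^2 / (2 * sigma^2))
}

type_volume <- function(radius) 4 / 3 * pi * radius^3
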