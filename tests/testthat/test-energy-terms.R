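test_that("all pairwise terms vanish beyond the 8 A interface cutoff", {
  far <- two_atom_complex(9.5)
  expect_true(all(smina_terms(far) == 0))
  nn <- suppressWarnings(nnscore_block(far))
  expect_true(all(nn == 0))
  made <- make_complex(plant_spec(n_decoy = 5, n_scaffold = 3, seed = 1))
  ft <- suppressWarnings(featurize(made$complex,
                                   blocks = c("smina", "nnscore", "aux")))
  expect_true(all(unlist(ft[1, -1]) == 0))
})

test_that("a ligand with no heavy atoms is rejected", {
  rec <- assign_types(molecule(tibble(serial = 1L, element = "C",
                                      x = 0, y = 0, z = 0)))
  hlig <- assign_types(molecule(tibble(serial = 1L, element = "H",
                                       x = 3, y = 0, z = 0)))
  expect_error(smina_terms(plcomplex(rec, hlig)), "zero heavy atoms")
})

test_that("single-pair kernel values match hand evaluation", {
  # hydrophobic C-C at surface distance 0: plateau of the piecewise kernel
  cc <- two_atom_complex(3.8)
  st <- smina_terms(cc)
  expect_equal(unname(st["smina:hydrophobic"]), 1.0)
  expect_equal(unname(st["smina:hbond"]), 0)
  expect_equal(unname(st["smina:vdw"]),
               -0.035579 - 0.005156 * exp(-2.25))
  # planted k pure hydrophobic contacts at d = 0
  for (k in c(1, 3, 7)) {
    made <- make_complex(plant_spec(n_hydrophobic_contacts = k, seed = k))
    st <- smina_terms(made$complex)
    expect_equal(unname(st["smina:hydrophobic"]), k)
  }
})

test_that("coulomb sum follows the formula with its sign convention", {
  none <- contacts(two_atom_complex(3, q_rec = 0, q_lig = 0), 8)
  expect_equal(coulomb_sum(none), 0)
  # direct evaluation: q_i = q_j = 1, r = 3.32, constant eps = 4
  ct <- contacts(two_atom_complex(3.32, q_rec = 1, q_lig = 1), 8)
  p <- kernel_params(list(elec = list(constant = 332, dielectric = "constant",
                                      epsilon = 4)))
  expect_equal(coulomb_sum(ct, p), 25.0)
  # antisymmetry under ligand charge negation
  a <- coulomb_sum(contacts(two_atom_complex(3.1, q_rec = 0.4, q_lig = 0.3), 8))
  b <- coulomb_sum(contacts(two_atom_complex(3.1, q_rec = 0.4, q_lig = -0.3), 8))
  expect_identical(a, -b)
  expect_lt(coulomb_sum(contacts(two_atom_complex(3, q_rec = 1, q_lig = -1), 8)), 0)
  bad <- contacts(two_atom_complex(3), 8)
  bad$distance <- 0
  expect_error(coulomb_sum(bad), "overlapping")
})

hbond_fixture <- function(angle_deg = 180, ha = 1.9) {
  # receptor N-H donor; ligand O placed at the given D-H...A angle
  a <- (180 - angle_deg) * pi / 180
  rec <- assign_types(molecule(
    tibble(serial = 1:2, element = c("N", "H"), x = c(0, 1), y = 0, z = 0),
    tibble(from = 1, to = 2, order = 1L)), infer_bonds = FALSE)
  lig <- assign_types(molecule(
    tibble(serial = 1L, element = "O",
           x = 1 + ha * cos(a), y = ha * sin(a), z = 0)), infer_bonds = FALSE)
  plcomplex(rec, lig)
}

test_that("hydrogen-bond counting enforces distance and angle criteria", {
  expect_equal(hbond_count(two_atom_complex(3)), 0L)
  expect_equal(hbond_count(hbond_fixture(180)), 1L)
  expect_equal(hbond_count(hbond_fixture(90), angle_cutoff = 120), 0L)
  expect_equal(hbond_count(hbond_fixture(180, ha = 2.7)), 0L)   # too far
  expect_equal(hbond_count(hbond_fixture(125)), 1L)             # inside both
  # a flagged donor with no polar hydrogen is skipped with a warning
  rec <- assign_types(molecule(tibble(serial = 1L, element = "N",
                                      x = 0, y = 0, z = 0)))
  rec$atoms$is_hbond_donor <- TRUE
  lig <- assign_types(molecule(tibble(serial = 1L, element = "O",
                                      x = 2.9, y = 0, z = 0)))
  expect_warning(n <- hbond_count(plcomplex(rec, lig)), "no polar hydrogen")
  expect_equal(n, 0L)
})

test_that("NNScore-style shells classify planted contacts", {
  # one ligand OA 2.4 A from one receptor N: a close contact, not semi
  cc <- two_atom_complex(2.4, t_rec = "N", t_lig = "OA")
  nn <- suppressWarnings(nnscore_block(cc))
  expect_equal(unname(nn["nn:pair_N_OA_close"]), 1)
  expect_equal(unname(nn["nn:pair_N_OA_semi"]), 0)
  # at 3.0 A the same pair is semi-close
  nn2 <- suppressWarnings(nnscore_block(two_atom_complex(3.0, t_rec = "N",
                                                         t_lig = "OA")))
  expect_equal(unname(nn2["nn:pair_N_OA_close"]), 0)
  expect_equal(unname(nn2["nn:pair_N_OA_semi"]), 1)
  # fixed schema: every emitted name present even when zero
  expect_true(all(c("nn:vdw", "nn:hbond", "nn:hydrophobic",
                    "nn:pair_C_C_close", "nn:elec_A_OA") %in% names(nn)))
})

test_that("every summed term matches the brute-force double loop", {
  for (seed in c(2, 5, 9, 14, 23)) {
    cplx <- random_typed_complex(seed, n_rec = 20, n_lig = 8)
    st <- smina_terms(cplx)
    nn <- suppressWarnings(nnscore_block(cplx))
    prod <- c(st, nn,
              "aux:clash" = clash_term(cplx), "aux:metal" = metal_term(cplx))
    oracle <- oracle_pair_terms(cplx)
    expect_lt(max(abs(prod[names(oracle)] - oracle)), 1e-9)
    # nn entries absent from the oracle must all be zero
    extra <- setdiff(names(nn)[nn != 0], c(names(oracle), "nn:hbond"))
    expect_length(extra, 0)
  }
})

test_that("terms are invariant under rigid rotation and translation", {
  cplx <- random_typed_complex(31, n_rec = 25, n_lig = 10)
  moved <- transform_complex(cplx)
  v1 <- c(smina_terms(cplx), suppressWarnings(nnscore_block(cplx)),
          clash_term(cplx), metal_term(cplx))
  v2 <- c(smina_terms(moved), suppressWarnings(nnscore_block(moved)),
          clash_term(moved), metal_term(moved))
  expect_lt(max(abs(v1 - v2)), 1e-9)
})

test_that("pairwise terms are additive over disjoint ligand fragments", {
  made <- make_complex(plant_spec(n_hydrophobic_contacts = 3, n_hbonds = 2,
                                  n_clashes = 1, seed = 6))
  cplx <- made$complex
  lig <- cplx$ligand
  n <- nrow(lig$atoms)
  idx1 <- seq_len(floor(n / 2)); idx2 <- setdiff(seq_len(n), idx1)
  frag <- function(idx) {
    at <- lig$atoms[idx, ]
    molecule(at, NULL, name = "frag")
  }
  whole <- c(smina_terms(cplx), suppressWarnings(nnscore_block(cplx)))
  f1 <- plcomplex(cplx$receptor, frag(idx1))
  f2 <- plcomplex(cplx$receptor, frag(idx2))
  parts <- c(smina_terms(f1), suppressWarnings(nnscore_block(f1))) +
    c(smina_terms(f2), suppressWarnings(nnscore_block(f2)))
  expect_lt(max(abs(whole - parts)), 1e-9)
})

test_that("rotatable-bond counting handles rings and amides", {
  butane <- molecule(tibble(serial = 1:4, element = "C",
                            x = c(0, 1.5, 3, 4.5), y = 0, z = 0),
                     tibble(from = 1:3, to = 2:4, order = 1L))
  expect_equal(entropy_term(butane), 1L)
  ring6 <- function(off = 0) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    tibble(serial = 1:6, element = "C", x = 1.4 * cos(ang) + off,
           y = 1.4 * sin(ang), z = 0)
  }
  kek <- tibble(from = 1:6, to = c(2:6, 1), order = rep(c(2L, 1L), 3))
  expect_equal(entropy_term(molecule(ring6(), kek)), 0L)
  at <- rbind(ring6(0), ring6(10)); at$serial <- 1:12
  bb <- rbind(kek, dplyr::mutate(kek, from = from + 6, to = to + 6),
              tibble(from = 1L, to = 7L, order = 1L))
  expect_equal(entropy_term(molecule(at, bb)), 1L)
  # N-ethylpropanamide skeleton C-C-C(=O)-N-C-C: the two internal single
  # bonds C2-C3 and N5-C6 rotate; the amide C3-N5 is excluded; terminal
  # bonds lack a second heavy neighbor on one end
  amide <- molecule(
    tibble(serial = 1:7, element = c("C", "C", "C", "O", "N", "C", "C"),
           x = c(0, 1.5, 3, 3.6, 3.6, 5.1, 6.6),
           y = c(0, 0, 0, 1.1, -1.1, -1.1, -1.1), z = 0),
    tibble(from = c(1, 2, 3, 3, 5, 6), to = c(2, 3, 4, 5, 6, 7),
           order = c(1L, 1L, 2L, 1L, 1L, 1L)))
  expect_equal(entropy_term(amide), 2L)
  expect_equal(entropy_term(molecule(tibble(serial = 1L, element = "C",
                                            x = 0, y = 0, z = 0))), 0L)
})

test_that("clash term is quadratic, zero without interpenetration", {
  expect_equal(clash_term(two_atom_complex(4.0)), 0)
  expect_equal(clash_term(two_atom_complex(3.3)), 0.25)   # d = -0.5
  prev <- -Inf
  for (r in c(3.7, 3.3, 2.9, 2.5)) {
    val <- clash_term(two_atom_complex(r))
    expect_gte(val, prev)
    prev <- val
  }
})

test_that("metal term is a plateau kernel, additive over pairs", {
  expect_equal(metal_term(two_atom_complex(2.0)), 0)      # no metals
  one <- two_atom_complex(2.0, t_rec = "MET", t_lig = "OA")
  expect_equal(metal_term(one), 1.0)
  # two identical, isolated metal sites: exactly twice the single pair
  tt <- type_table()
  mk2 <- function(el, t, xs, acc) {
    molecule(tibble(serial = 1:2, element = el, x = xs, y = 0, z = 0,
                    partial_charge = 0,
                    vdw_radius = tt$vdw_radius[match(t, tt$pair_type)],
                    is_hydrophobic = FALSE, is_hbond_donor = FALSE,
                    is_hbond_acceptor = acc, is_metal = !acc, pair_type = t))
  }
  two <- plcomplex(mk2("Zn", "MET", c(0, 30), FALSE),
                   mk2("O", "OA", c(2, 32), TRUE))
  expect_equal(metal_term(two), 2.0)
  mid <- metal_term(two_atom_complex(3.1, t_rec = "MET", t_lig = "OA"))
  expect_equal(mid, (4.0 - 3.1) / 1.8)
})

test_that("external term tables ingest with prefixing and validation", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ligand = c("a", "b", "c"), gauss1 = 1:3,
                       gauss2 = c(0.1, 0.2, 0.3), rep = 0, hyd = -1),
            tf, row.names = FALSE)
  ft <- ingest_external_terms(tf, "vina")
  expect_equal(dim(ft), c(3, 5))
  expect_equal(names(ft), c("ligand", "vina:gauss1", "vina:gauss2",
                            "vina:rep", "vina:hyd"))
  expect_equal(ft$ligand, c("a", "b", "c"))

  dup <- data.frame(ligand = c("a", "a"), t1 = 1:2)
  expect_error(ingest_external_terms(dup, "x"), "duplicate ligand")
  bad <- data.frame(ligand = c("a", "b"), t1 = c("1.5", "oops"))
  expect_error(ingest_external_terms(bad, "x"), "row 2, column 't1'")

  # merging two ingested tables reproduces a hand-joined reference
  t2 <- data.frame(ligand = c("b", "a", "c"), sc = c(5, 4, 6))
  merged <- merge_feature_tables(ft, ingest_external_terms(t2, "dock"))
  expect_equal(merged$`dock:sc`, c(4, 5, 6))
  expect_equal(merged$`vina:gauss1`, 1:3)
})

test_that("featurize emits fixed schemas deterministically", {
  made <- make_complex(plant_spec(n_hydrophobic_contacts = 2, seed = 3))
  sm <- featurize(made$complex, blocks = "smina")
  expect_equal(ncol(sm), 7)  # ligand id + the six Smina components
  expect_equal(names(sm)[1], "ligand")

  empty <- featurize(list(), blocks = "smina")
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 7)

  two <- suppressWarnings(
    featurize(list(made$complex, made$complex), blocks = c("smina", "nnscore")))
  expect_equal(unlist(two[1, -1]), unlist(two[2, -1]))
})

test_that("gasteiger charges are conserved and match reference signs", {
  # ethanol heavy-atom pattern: C-C-O-H
  el <- c("C", "C", "O", "H", "H", "H", "H", "H", "H")
  bonds <- tibble(from = c(1, 2, 3, 1, 1, 1, 2, 2),
                  to = c(2, 3, 4, 5, 6, 7, 8, 9),
                  order = 1L)
  q <- gasteiger_charges(el, bonds)
  expect_lt(abs(sum(q)), 1e-9)            # neutral molecule stays neutral
  expect_lt(q[3], -0.3)                   # hydroxyl oxygen strongly negative
  expect_gt(q[4], 0.15)                   # hydroxyl hydrogen positive
  expect_gt(q[2], q[1])                   # alpha carbon more positive
})
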