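test_that("registry reconstructs the scoring-function taxonomy", {
  reg <- build_registry()
  expect_equal(dplyr::n_distinct(reg$scoring_function), 15)
  expect_equal(dplyr::n_distinct(reg$group), 12)
  expect_equal(reg$group[reg$scoring_function == "Smina" & reg$term == "hbond"],
               "hbond")
  expect_equal(sum(reg$scoring_function == "Smina"), 6)
  expect_equal(sum(reg$scoring_function == "NNScore"), 5)
  expect_equal(sum(reg$scoring_function == "Glide XP"), 7)
  # every entry maps to exactly one group
  expect_false(any(duplicated(reg[, c("scoring_function", "term")])))
  expect_setequal(unique(reg$group),
                  c("vdw", "hbond", "elec", "hydrophobic", "sol", "entropy",
                    "knowledge", "clash", "metal", "internal",
                    "non_hydrophobic", "nn_pair"))
})

test_that("formula enumeration is the exact cartesian product", {
  specs <- enumerate_formula()
  expect_equal(nrow(specs), 288)
  expect_false(any(duplicated(specs[, -1])))
  # brute-force product oracle over the option sets
  opts <- combination_options("formula")
  expect_equal(nrow(specs), prod(vapply(opts, length, integer(1))))
  manual <- expand.grid(rev(lapply(opts, sort)), stringsAsFactors = FALSE)
  expect_equal(nrow(manual), nrow(specs))
  # every varied group covered exactly once per spec
  expect_true(all(varied_groups() %in% names(specs)))
  # deterministic lexicographic order
  expect_identical(specs, enumerate_formula())
  expect_true(all(specs$vdw[1:96] == sort(opts$vdw, method = "radix")[1]))
})

test_that("tree-based rows give 24 + 12 = 36 combinations", {
  ts <- enumerate_tree("sum")
  tm <- enumerate_tree("mean")
  expect_equal(nrow(ts), 24)
  expect_equal(nrow(tm), 12)
  expect_equal(nrow(ts) + nrow(tm), 36)
  expect_equal(nrow(enumerate_formula()) + nrow(ts) + nrow(tm), 324)
  for (sp in list(ts, tm)) {
    expect_false(any(duplicated(sp[, -1])))
  }
  # singleton options collapse to exactly one combination
  single <- lapply(varied_groups(), function(g) "Smina")
  names(single) <- varied_groups()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(single, tmp)
  expect_equal(nrow(enumerate_formula(combination_options(tmp))), 1)
  # empty option set errors
  bad <- single; bad$vdw <- list()
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, tmp2)
  expect_error(combination_options(tmp2), "empty option set")
})

test_that("arbitrary option-set sizes multiply out", {
  sfs <- c("Smina", "Vina", "X-score", "Autodock", "NNScore")
  set.seed(3)
  for (rep in 1:5) {
    sizes <- sample(1:4, 6, replace = TRUE)
    opts <- lapply(sizes, function(k) sample(sfs, k))
    names(opts) <- varied_groups()
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(opts, tmp)
    specs <- enumerate_formula(combination_options(tmp))
    expect_equal(nrow(specs),
                 prod(vapply(opts, function(x) length(unique(x)), integer(1))))
    unlink(tmp)
  }
})

test_that("feature columns resolve to registry cells", {
  info <- column_info(c("smina:vdw", "smina:hbond", "nn:pair_C_OA_close",
                        "nn:elec_C_C", "nn:vdw", "aux:entropy",
                        "vina:hydrophobic", "mystery"))
  expect_equal(info$scoring_function[1], "Smina")
  expect_equal(info$group[1:2], c("vdw", "hbond"))
  expect_equal(info$group[3], "nn_pair")
  expect_equal(info$group[4], "elec")       # NNScore electrostatics
  expect_equal(info$group[5], "vdw")
  expect_equal(info$group[6], "entropy")
  expect_equal(info$scoring_function[7], "Vina")
  expect_true(is.na(info$group[8]))
})

test_that("tree importance favours separating features", {
  set.seed(10)
  n <- 300
  tbl <- tibble(
    ligand = sprintf("l%03d", 1:n),
    `Smina:vdw` = c(rnorm(n / 2, 3), rnorm(n / 2, 0)),  # separates classes
    `Vina:vdw` = rnorm(n),                              # pure noise
    label = rep(c(1L, 0L), each = n / 2)
  )
  rep_sum <- tree_importance(tbl, mode = "sum", seed = 5)
  smina <- rep_sum$importance[rep_sum$scoring_function == "Smina"]
  vina <- rep_sum$importance[rep_sum$scoring_function == "Vina"]
  expect_gt(smina, vina * 2)
  # sum equals mean on single-term groups
  rep_mean <- tree_importance(tbl, mode = "mean", seed = 5)
  expect_equal(rep_sum$importance, rep_mean$importance)
  # option derivation keeps the winner
  opts <- options_from_importance(
    dplyr::bind_rows(rep_sum,
                     tibble(scoring_function = "Filler", group = setdiff(varied_groups(), "vdw"),
                            importance = 1, n_terms = 1, mode = "sum")))
  expect_equal(opts$vdw, "Smina")
})

test_that("duplicating a term approximately conserves summed group importance", {
  base_imp <- numeric(25); dup_imp <- numeric(25)
  for (s in 1:25) {
    set.seed(s)
    n <- 200
    signal <- c(rnorm(n / 2, 2), rnorm(n / 2, 0))
    tbl <- tibble(ligand = as.character(1:n),
                  `Smina:vdw` = signal,
                  `Vina:vdw` = rnorm(n),
                  label = rep(c(1L, 0L), each = n / 2))
    r1 <- tree_importance(tbl, mode = "sum", seed = s, num_trees = 300)
    base_imp[s] <- r1$importance[r1$scoring_function == "Smina"]
    tbl2 <- dplyr::mutate(tbl, `Smina:hydrophobic` = signal)
    r2 <- tree_importance(tbl2, mode = "sum", seed = s, num_trees = 300)
    dup_imp[s] <- sum(r2$importance[r2$scoring_function == "Smina"])
  }
  expect_lt(abs(mean(dup_imp) - mean(base_imp)) / mean(base_imp), 0.10)
})

test_that("assembly projects the chosen scoring functions plus defaults", {
  # synthetic source with one column per registry cell
  reg <- build_registry()
  cols <- paste0(reg$scoring_function, ":", reg$term)
  src <- as_tibble(setNames(as.list(seq_along(cols)), cols))
  src <- dplyr::bind_cols(tibble(ligand = "m1"), src)

  all_smina <- setNames(as.list(rep("Smina", 6)), varied_groups())
  # Smina block only: choosing Smina everywhere over a Smina-only source
  smina_src <- src[, c("ligand", cols[reg$scoring_function == "Smina"])]
  out <- assemble(smina_src, all_smina)
  expect_equal(ncol(out) - 1, 6)

  # a registry-defined cell missing from the source is an error
  no_gold <- src[, setdiff(names(src), "Goldscore:vdw")]
  gold_spec <- all_smina; gold_spec$vdw <- "Goldscore"
  expect_error(assemble(no_gold, gold_spec), "Goldscore, vdw")

  # the final combined spec: Smina + NNScore per varied group; the entropy
  # choice names an SF without an entropy term and contributes nothing
  two_sf <- list(vdw = c("NNScore", "Smina"), hbond = c("NNScore", "Smina"),
                 elec = c("NNScore", "Smina"),
                 hydrophobic = c("NNScore", "Smina"),
                 entropy = "Smina", clash = "Smina")
  out2 <- assemble(src, two_sf)
  expect_true(all(c("Smina:vdw", "NNScore:vdw", "Smina:hbond") %in% names(out2)))
  expect_false(any(c("Vina:entropy", "Chemscore:clash") %in% names(out2)))

  spec5 <- list(vdw = c("NNScore", "Smina"), hbond = c("NNScore", "Smina"),
                elec = c("NNScore", "Smina"),
                hydrophobic = c("NNScore", "Smina"),
                entropy = "Vina", clash = "ASP")
  out5 <- assemble(src, spec5)
  picked <- setdiff(names(out5), "ligand")
  expect_true(all(c("Smina:vdw", "NNScore:vdw", "Smina:hbond", "NNScore:nn_elec",
                    "Smina:elec", "Vina:entropy", "ASP:clash") %in% picked))
  expect_false("Goldscore:vdw" %in% picked)
  # defaults: non-varied groups all retained
  expect_true(all(c("Smina:sol", "NNScore:nn_pair", "DSX:pair",
                    "ASP:internal", "Chemscore:metal") %in% picked))
  # output schema never invents columns; idempotent
  expect_true(all(picked %in% names(src)))
  expect_identical(assemble(out5, spec5), out5)
})

test_that("group ablation removes exactly that group's columns", {
  reg <- build_registry()
  cols <- paste0(reg$scoring_function, ":", reg$term)
  src <- as_tibble(setNames(as.list(seq_along(cols)), cols))
  src <- dplyr::bind_cols(tibble(ligand = "m1"), src)
  ab <- ablate(src, "vdw")
  n_vdw <- sum(reg$group == "vdw")
  expect_equal(ncol(src) - ncol(ab), n_vdw)
  expect_identical(ablate(ab, "vdw"), ab)
  left <- src
  for (g in unique(reg$group)) left <- ablate(left, g)
  expect_equal(names(left), "ligand")
})
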