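#' Build the energy-term registry
#'
#' The taxonomy of (scoring function, term) pairs and their physicochemical
#' interaction groups: 15 classical scoring functions whose energy
#' components fall into 12 groups (van der Waals, H-bond, electrostatic,
#' hydrophobic, solvation, entropy, knowledge-based, clash, metal,
#' internal, non-hydrophobic, atom-pair counts). Shipped as a plain CSV
#' under `extdata` so the taxonomy is data, not code.
#'
#' @return Tibble with columns `scoring_function`, `term`, `group`.
#' @export
#' @examples
#' reg <- build_registry()
#' dplyr::n_distinct(reg$scoring_function)  # 15
#' dplyr::n_distinct(reg$group)             # 12
build_registry <- function() {
  path <- system.file("extdata", "term_registry.csv", package = "iecscore")
  reg <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(!any(duplicated(reg[, c("scoring_function", "term")])))
  reg
}

#' The six varied interaction groups
#'
#' The frequently used interaction types over which feature combinations
#' vary; all other groups are retained in default during assembly.
#' @export
varied_groups <- function() {
  c("vdw", "hbond", "elec", "hydrophobic", "entropy", "clash")
}

#' Load an option table for a combination strategy
#'
#' Reads the bundled option configuration: for each varied interaction
#' group, the ordered set of scoring functions eligible to supply that
#' group under the given strategy row.
#'
#' @param row one of `"formula"`, `"tree_sum"`, `"tree_mean"`, or a path to
#'   a YAML file with the same layout.
#' @return Named list of character vectors, one per varied group.
#' @export
combination_options <- function(row = c("formula", "tree_sum", "tree_mean")) {
  if (length(row) == 1 && file.exists(row)) {
    opts <- yaml::read_yaml(row)
  } else {
    row <- match.arg(row)
    path <- system.file("extdata", "combination_options.yaml", package = "iecscore")
    opts <- yaml::read_yaml(path)[[row]]
  }
  missing_g <- setdiff(varied_groups(), names(opts))
  if (length(missing_g) > 0) {
    abort(paste0("option table lacks group(s): ", paste(missing_g, collapse = ", ")))
  }
  opts <- opts[varied_groups()]
  lens <- vapply(opts, length, integer(1))
  if (any(lens == 0)) {
    abort(paste0("empty option set for group(s): ",
                 paste(names(opts)[lens == 0], collapse = ", ")))
  }
  lapply(opts, as.character)
}

enumerate_combinations <- function(options) {
  opts <- lapply(options[varied_groups()], function(x) sort(x, method = "radix"))
  grid <- tidyr::expand_grid(!!!opts)
  grid <- dplyr::distinct(grid)
  dplyr::bind_cols(tibble(spec_id = sprintf("comb_%03d", seq_len(nrow(grid)))), grid)
}

#' Enumerate formula-based feature combinations
#'
#' Cartesian product over the six varied interaction groups of the formula
#' option row: one scoring function chosen per group, deterministic
#' lexicographic order (group order, then scoring-function name), no
#' duplicates.
#'
#' @param options option table from [combination_options()].
#' @return Tibble of combination specs (one row each; columns `spec_id`
#'   plus one column per varied group).
#' @export
enumerate_formula <- function(options = combination_options("formula")) {
  enumerate_combinations(options)
}

#' Enumerate tree-importance-based feature combinations
#'
#' Cartesian product over the option row of the given tree strategy. The
#' option rows already embody the retention rule: when terms from distinct
#' scoring functions yield similar importance for one interaction, all are
#' retained as options.
#'
#' @param mode `"sum"` or `"mean"` aggregation row.
#' @param options optional explicit option table; defaults to the bundled
#'   row for `mode`.
#' @return Tibble of combination specs.
#' @export
enumerate_tree <- function(mode = c("sum", "mean"), options = NULL) {
  mode <- match.arg(mode)
  if (is.null(options)) {
    options <- combination_options(paste0("tree_", mode))
  }
  enumerate_combinations(options)
}

# ---- column resolution -----------------------------------------------------

sf_aliases <- function() {
  c(smina = "Smina", nn = "NNScore", nnscore = "NNScore", aux = "aux")
}

normalize_sf <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Resolve feature columns to (scoring function, term, group)
#'
#' Maps column names of the form `"<sf>:<term>"` onto the registry. The
#' native blocks use the aliases `smina` (Smina), `nn` (NNScore) and `aux`
#' (auxiliary single terms whose group equals the term name); NNScore
#' pair-count columns (`pair_*`) map to the atom-pair group and
#' `elec_*` columns to the electrostatic group.
#'
#' @param cols character vector of column names.
#' @param registry registry tibble from [build_registry()].
#' @return Tibble with `column`, `scoring_function`, `term`, `group`
#'   (NA where unresolvable).
#' @export
column_info <- function(cols, registry = build_registry()) {
  sf_raw <- ifelse(grepl(":", cols, fixed = TRUE), sub(":.*$", "", cols), NA)
  term <- ifelse(grepl(":", cols, fixed = TRUE), sub("^[^:]*:", "", cols), NA)
  alias <- sf_aliases()
  sf <- character(length(cols))
  group <- character(length(cols))
  reg_norm <- normalize_sf(registry$scoring_function)
  for (i in seq_along(cols)) {
    s <- sf_raw[i]
    if (is.na(s)) { sf[i] <- NA; group[i] <- NA; next }
    s_resolved <- if (tolower(s) %in% names(alias)) alias[[tolower(s)]] else {
      hit <- which(reg_norm == normalize_sf(s))
      if (length(hit) > 0) registry$scoring_function[hit[1]] else s
    }
    sf[i] <- s_resolved
    tm <- term[i]
    if (identical(s_resolved, "aux")) {
      group[i] <- tm
      next
    }
    if (identical(s_resolved, "NNScore")) {
      if (grepl("^pair_", tm)) tm <- "nn_pair"
      else if (grepl("^elec", tm)) tm <- "nn_elec"
    }
    hit <- which(registry$scoring_function == s_resolved & registry$term == tm)
    group[i] <- if (length(hit) > 0) registry$group[hit[1]] else NA_character_
  }
  tibble(column = cols, scoring_function = sf, term = term, group = group)
}

#' Random-forest importance aggregated by (scoring function, group)
#'
#' Fits a probability random forest to the labeled feature table and
#' aggregates the per-column impurity importance within each
#' (scoring function, interaction group) cell by sum or mean — the two
#' tree-based selection modes.
#'
#' @param features tibble with `ligand`, feature columns and a binary
#'   `label` column.
#' @param registry registry tibble.
#' @param mode `"sum"` or `"mean"`.
#' @param seed integer seed (forest is deterministic given it).
#' @param num_trees number of trees.
#' @return Tibble `scoring_function`, `group`, `importance`, `n_terms`,
#'   `mode`, sorted by group then decreasing importance.
#' @export
tree_importance <- function(features, registry = build_registry(),
                            mode = c("sum", "mean"), seed = 1,
                            num_trees = 500) {
  mode <- match.arg(mode)
  assert_labeled(features)
  cols <- feature_columns(features)
  x <- as.data.frame(features[, cols, drop = FALSE], check.names = FALSE)
  colnames(x) <- paste0("f", seq_along(cols))  # ranger dislikes ':' in names
  y <- factor(features$label)
  fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                        importance = "impurity", num.trees = num_trees,
                        seed = as.integer(seed), num.threads = 1)
  imp <- setNames(as.numeric(fit$variable.importance), cols)
  info <- column_info(cols, registry)
  info$importance <- imp[info$column]
  agg <- info |>
    dplyr::filter(!is.na(.data$group), !is.na(.data$scoring_function)) |>
    dplyr::group_by(.data$scoring_function, .data$group) |>
    dplyr::summarise(
      importance = if (mode == "sum") sum(.data$importance) else mean(.data$importance),
      n_terms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$group, dplyr::desc(.data$importance))
  agg$mode <- mode
  agg
}

#' Derive an option table from an importance report
#'
#' For each varied group keeps the scoring function with the highest
#' aggregated importance, together with any others whose importance lies
#' within `tol` relative difference of the best (ties are all retained).
#'
#' @param report tibble from [tree_importance()].
#' @param tol relative similarity threshold for retaining ties.
#' @return Named list of character vectors per varied group.
#' @export
options_from_importance <- function(report, tol = 0.01) {
  out <- list()
  for (g in varied_groups()) {
    sub <- report[report$group == g, , drop = FALSE]
    if (nrow(sub) == 0) abort(paste0("no importance entries for group ", g))
    best <- max(sub$importance)
    keep <- sub$scoring_function[sub$importance >= best * (1 - tol)]
    out[[g]] <- sort(keep, method = "radix")
  }
  out
}

#' Assemble the feature table of one combination spec
#'
#' Projects, for each varied interaction group, all term columns of the
#' scoring function(s) chosen for that group, plus the columns of every
#' non-varied group (retained in default). `ligand` and `label` columns
#' are carried through; column order is deterministic.
#'
#' @param source feature table containing the required columns.
#' @param spec a one-row spec tibble from the `enumerate_*` functions, or a
#'   named list mapping each varied group to one or more scoring-function
#'   names.
#' @param registry registry tibble.
#' @return Projected tibble.
#' @export
assemble <- function(source, spec, registry = build_registry()) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- as.list(spec[, intersect(varied_groups(), names(spec)), drop = FALSE])
    spec <- lapply(spec, function(v) unlist(strsplit(as.character(v), "\\+")))
  }
  missing_g <- setdiff(varied_groups(), names(spec))
  if (length(missing_g) > 0) {
    abort(paste0("spec lacks group(s): ", paste(missing_g, collapse = ", ")))
  }
  cols <- feature_columns(source)
  info <- column_info(cols, registry)
  keep <- character()
  for (g in varied_groups()) {
    for (sf in spec[[g]]) {
      hit <- info$column[!is.na(info$group) & info$group == g &
                           info$scoring_function == sf]
      if (length(hit) == 0) {
        # an SF that simply has no term of this group contributes nothing;
        # an SF that should (per the registry) but is absent is an error
        in_registry <- any(registry$scoring_function == sf &
                             registry$group == g)
        if (in_registry) {
          abort(sprintf("source table lacks columns for (%s, %s)", sf, g))
        }
        next
      }
      keep <- c(keep, sort(hit, method = "radix"))
    }
  }
  fixed <- info$column[!is.na(info$group) & !(info$group %in% varied_groups())]
  keep <- c(keep, fixed[order(match(fixed, cols))])
  keep <- unique(keep)
  id_cols <- intersect(c("ligand", "label"), names(source))
  source[, c(id_cols, keep), drop = FALSE]
}

#' Remove all columns of one interaction group
#'
#' Group ablation for sensitivity experiments: drops every feature column
#' mapped to the named interaction group, leaving everything else
#' untouched. Idempotent.
#'
#' @param source feature table.
#' @param group interaction group name.
#' @param registry registry tibble.
#' @export
ablate <- function(source, group, registry = build_registry()) {
  stopifnot(is.character(group), length(group) == 1)
  info <- column_info(feature_columns(source), registry)
  drop <- info$column[!is.na(info$group) & info$group == group]
  source[, setdiff(names(source), drop), drop = FALSE]
}
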