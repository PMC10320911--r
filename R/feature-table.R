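#' Ingest an externally computed energy-term table
#'
#' Adapter for per-ligand term tables produced by third-party scoring
#' functions. Reads a delimited text table (CSV or TSV, autodetected from
#' the header line) whose first column — or a column named `ligand` — holds
#' the ligand identifier, and prefixes every term column as
#' `"<sf_name>:<term>"`. Row order is preserved.
#'
#' @param table path to a delimited file, or a data frame.
#' @param sf_name scoring-function name used as the column prefix.
#' @return Tibble with `ligand` first and prefixed numeric term columns.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(ligand = c("a", "b"), gauss = c(1, 2), rep = c(0, 1)),
#'           tf, row.names = FALSE)
#' ingest_external_terms(tf, "vina")
ingest_external_terms <- function(table, sf_name) {
  stopifnot(is.character(sf_name), length(sf_name) == 1, nzchar(sf_name))
  if (is.character(table)) {
    header <- readLines(table, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- read.csv(table, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    df <- as.data.frame(table, check.names = FALSE)
  }
  if (nrow(df) == 0) abort("external term table has no rows")
  id_col <- if ("ligand" %in% names(df)) "ligand" else names(df)[1]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicate ligand identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  terms <- setdiff(names(df), id_col)
  if (length(terms) == 0) abort("no term columns found")
  for (cn in terms) {
    vals <- df[[cn]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at row %d, column '%s'", bad[1], cn))
    }
    if (any(is.na(num))) {
      abort(sprintf("missing value at row %d, column '%s'", which(is.na(num))[1], cn))
    }
    df[[cn]] <- num
  }
  out <- as_tibble(df[, c(id_col, terms), drop = FALSE])
  names(out) <- c("ligand", paste0(sf_name, ":", terms))
  out
}

#' Join feature tables on the ligand identifier
#'
#' @param ... tibbles with a `ligand` column (as produced by [featurize()]
#'   or [ingest_external_terms()]).
#' @return Inner-joined tibble.
#' @export
merge_feature_tables <- function(...) {
  tables <- list(...)
  stopifnot(length(tables) >= 1)
  purrr::reduce(tables, function(a, b) dplyr::inner_join(a, b, by = "ligand"))
}

feature_columns <- function(tbl) {
  setdiff(names(tbl), c("ligand", "label"))
}

assert_labeled <- function(tbl) {
  if (!"label" %in% names(tbl)) abort("feature table has no 'label' column")
  if (length(unique(tbl$label)) < 2) abort("labels contain a single class")
  invisible(tbl)
}
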