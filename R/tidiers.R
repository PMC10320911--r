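#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a tuning trace
#'
#' @param x an `iec_tune` object.
#' @param ... unused.
#' @return The candidate-by-candidate trace tibble (`step`,
#'   hyperparameters, `cv_f1`).
#' @method tidy iec_tune
#' @export
tidy.iec_tune <- function(x, ...) x$trace

#' @method glance iec_tune
#' @export
glance.iec_tune <- function(x, ...) {
  dplyr::bind_cols(tibble(algorithm = x$algorithm, steps = nrow(x$trace),
                          folds = x$folds, search = x$search,
                          best_cv_f1 = x$best_score),
                   as_tibble(x$best))
}

#' Tidy a trained scorer
#'
#' One row per kept feature with its training standardization statistics.
#'
#' @param x an `iec_scorer`.
#' @param ... unused.
#' @method tidy iec_scorer
#' @export
tidy.iec_scorer <- function(x, ...) {
  tibble(feature = x$preprocess$features,
         center = unname(x$preprocess$center),
         scale = unname(x$preprocess$scale))
}

#' @method glance iec_scorer
#' @export
glance.iec_scorer <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_features = length(x$preprocess$features),
         n_train = x$n_train, seed = x$seed)
}

#' @method tidy iec_report
#' @export
tidy.iec_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "f1", value = x$f1),
    tibble(metric = "roc_auc", value = x$roc_auc),
    tibble(metric = paste0("ef_", names(x$ef)),
           value = unlist(x$ef, use.names = FALSE))
  )
}

#' @method glance iec_pipeline
#' @export
glance.iec_pipeline <- function(x, ...) {
  dplyr::bind_cols(glance(x$scorer),
                   tibble(f1 = x$report$f1, roc_auc = x$report$roc_auc))
}
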