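#' Build a ranked screening result
#'
#' @param data data frame with one row per ligand.
#' @param score,label column names holding the predicted score and the
#'   binary activity label (1/TRUE = active).
#' @param id optional identifier column.
#' @return Tibble of class `iec_screen` with `ligand`, `score`, `label`
#'   and `rank` (descending score, ties broken by input order — stable and
#'   deterministic).
#' @export
screen_result <- function(data, score = "score", label = "label", id = "ligand") {
  df <- as.data.frame(data, check.names = FALSE)
  stopifnot(score %in% names(df), label %in% names(df))
  lab <- as.integer(as.logical(df[[label]]))
  if (any(is.na(lab))) abort("labels must be binary (0/1 or logical)")
  out <- tibble(
    ligand = if (id %in% names(df)) as.character(df[[id]]) else
      sprintf("lig_%d", seq_len(nrow(df))),
    score = as.numeric(df[[score]]),
    label = lab
  )
  if (any(!is.finite(out$score))) abort("scores must be finite")
  out$rank <- order(order(-out$score, seq_len(nrow(out))))
  class(out) <- c("iec_screen", class(out))
  out
}

#' Confusion counts at a score threshold
#'
#' @param result `iec_screen` tibble (or any tibble with `score`, `label`).
#' @param threshold scores `>= threshold` predict active.
#' @return Named list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(result, threshold = 0.5) {
  pred <- result$score >= threshold
  act <- result$label == 1
  list(tp = sum(pred & act), fp = sum(pred & !act),
       tn = sum(!pred & !act), fn = sum(!pred & act))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; degenerate
#' denominators yield 0 with a warning.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0 || tp + fn == 0) {
    warn("F1 undefined (no predicted or no actual positives); returning 0")
    return(0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @rdname f1_score
#' @export
precision_score <- function(counts) {
  if (counts$tp + counts$fp == 0) return(0)
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname f1_score
#' @export
recall_score <- function(counts) {
  if (counts$tp + counts$fn == 0) return(0)
  counts$tp / (counts$tp + counts$fn)
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a uniformly drawn active outscores a uniformly drawn
#' decoy, counting ties as one half — the exact area under the ROC curve.
#' Computed from midranks, so it matches the O(n^2) pairwise count to
#' machine precision.
#'
#' @param result `iec_screen` tibble (or tibble with `score`, `label`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(result) {
  act <- result$label == 1
  n_a <- sum(act); n_d <- sum(!act)
  if (n_a == 0 || n_d == 0) abort("both classes must be present for ROC AUC")
  r <- rank(result$score, ties.method = "average")
  (sum(r[act]) - n_a * (n_a + 1) / 2) / (n_a * n_d)
}

#' Enrichment factor at a screening fraction
#'
#' `EF = (a/s) / (A/N)` with `s = ceiling(fraction * N)` top-ranked
#' molecules, `a` the actives among them, `A` all actives, `N` all
#' molecules. Ties at the cut are resolved by the stable rank of
#' [screen_result()].
#'
#' @param result `iec_screen` tibble.
#' @param fraction top fraction in `(0, 1]` (0.01 = the one-percent level).
#' @return Nonnegative real; 1 is the random expectation.
#' @export
enrichment_factor <- function(result, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(result)
  n_act <- sum(result$label == 1)
  if (n_act == 0) abort("no actives in the screened set")
  s <- ceiling(fraction * n)
  if (!"rank" %in% names(result)) result <- screen_result(result)
  top <- result$label[result$rank <= s]
  a <- sum(top == 1)
  (a / s) / (n_act / n)
}

#' Full screening-power report
#'
#' F1 at the probability threshold, ROC AUC, and enrichment factors at the
#' requested fractions, as a JSON-serializable list.
#'
#' @param scores numeric predicted scores (probabilities).
#' @param labels binary activity labels.
#' @param threshold F1 classification threshold.
#' @param fractions enrichment-factor fractions.
#' @return Object of class `iec_report`: list with `f1`, `roc_auc`, `ef`
#'   (named by fraction), `n`, `n_actives`.
#' @export
evaluate_screen <- function(scores, labels, threshold = 0.5, fractions = 0.01) {
  res <- screen_result(tibble(score = scores, label = labels))
  ef <- lapply(fractions, function(f) enrichment_factor(res, f))
  names(ef) <- vapply(fractions, function(f) as.character(f), "")
  out <- list(
    f1 = f1_score(confusion_counts(res, threshold)),
    roc_auc = roc_auc(res),
    ef = ef,
    n = nrow(res),
    n_actives = sum(res$label == 1)
  )
  class(out) <- "iec_report"
  out
}

#' @export
print.iec_report <- function(x, ...) {
  cat(sprintf("screening report: n = %d (%d actives)\n", x$n, x$n_actives))
  cat(sprintf("  F1      = %.4f\n  ROC AUC = %.4f\n", x$f1, x$roc_auc))
  for (f in names(x$ef)) cat(sprintf("  EF@%s  = %.3f\n", f, x$ef[[f]]))
  invisible(x)
}
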