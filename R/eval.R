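# Span-level nested-NER scoring: exact-match (type + both boundaries)
# confusion counts pooled across nesting levels, per-class and micro
# precision/recall/F1, and macro F1 over the eight classes.

#' Exact-match confusion counts per entity type
#'
#' A prediction counts as a true positive only when its entity type and
#' both character boundaries equal a gold span's; all nesting levels are
#' pooled. Both sets are deduplicated on (`etype`, `start`, `end`) first.
#'
#' @param gold,pred Span tibbles in the same coordinate frame.
#' @return A tibble with one row per entity type: `etype`, `tp`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(gold, pred) {
  gold <- dedup_spans(gold)
  pred <- dedup_spans(pred)
  gk <- span_key(gold)
  pk <- span_key(pred)
  purrr::map_dfr(entity_types(), function(ty) {
    g <- gk[gold$etype == ty]
    p <- pk[pred$etype == ty]
    tibble::tibble(etype = ty,
                   tp = sum(p %in% g),
                   fp = sum(!p %in% g),
                   fn = sum(!g %in% p))
  })
}

prf <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  list(precision = p, recall = r, f1 = f)
}

#' Score confusion counts into an evaluation report
#'
#' Computes precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and their
#' harmonic mean F1 per class and micro-averaged (pooled counts), plus the
#' macro F1: the unweighted arithmetic mean of the per-class F1 values over
#' all eight classes, including zero-F1 classes. Any zero denominator
#' yields 0 for that metric.
#'
#' @param counts A tibble from [confusion_counts()].
#' @return An `eval_report`: list with `per_class` tibble, `micro` one-row
#'   tibble, `macro_f1` and `n_classes`.
#' @export
score <- function(counts) {
  per <- prf(counts$tp, counts$fp, counts$fn)
  per_class <- dplyr::bind_cols(counts, tibble::as_tibble(per))
  mic <- prf(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  micro <- tibble::tibble(tp = sum(counts$tp), fp = sum(counts$fp),
                          fn = sum(counts$fn),
                          precision = mic$precision, recall = mic$recall,
                          f1 = mic$f1)
  structure(list(per_class = per_class, micro = micro,
                 macro_f1 = mean(per_class$f1),
                 n_classes = nrow(per_class)),
            class = "eval_report")
}

#' Evaluate predicted spans against gold spans
#'
#' Convenience wrapper: `score(confusion_counts(gold, pred))`.
#'
#' @param gold,pred Span tibbles in the same coordinate frame.
#' @return An `eval_report`.
#' @export
evaluate_spans <- function(gold, pred) {
  score(confusion_counts(gold, pred))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> span-level exact match, ", x$n_classes, " classes\n",
      sep = "")
  print(format_eval_table(x))
  invisible(x)
}

#' Per-class rows of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-class tibble (`etype`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`).
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble with micro precision/recall/F1 and macro F1.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(precision = x$micro$precision, recall = x$micro$recall,
                 f1 = x$micro$f1, macro_f1 = x$macro_f1,
                 n_classes = x$n_classes)
}

#' Format an evaluation report as a percentage table
#'
#' Renders micro precision, recall, F1 and macro F1 as percentages to two
#' decimals — the conventional reporting layout for this task.
#'
#' @param x An `eval_report`.
#' @return A one-row tibble of formatted strings.
#' @export
format_eval_table <- function(x) {
  pc <- function(v) sprintf("%.2f", 100 * v)
  tibble::tibble(`Precision (%)` = pc(x$micro$precision),
                 `Recall (%)` = pc(x$micro$recall),
                 `F1 Score (%)` = pc(x$micro$f1),
                 `Macro F1 Score (%)` = pc(x$macro_f1))
}

#' Write an evaluation report as JSON
#'
#' @param x An `eval_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(list(per_class = x$per_class, micro = x$micro,
                            macro_f1 = x$macro_f1, n_classes = x$n_classes),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
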