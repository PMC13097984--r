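# ggplot2 views of tag tallies, training curves and evaluation reports.

#' Plot BIO tag frequencies
#'
#' Bar chart of `B-`/`I-` label counts from [tabulate_tags()], pooled over
#' layers or faceted per nesting layer. The outside label is never shown.
#'
#' @param tally A tibble from [tabulate_tags()].
#' @param per_layer Facet by nesting layer instead of pooling.
#' @return A ggplot object.
#' @export
plot_tag_distribution <- function(tally, per_layer = FALSE) {
  if (!per_layer) {
    tally <- dplyr::summarise(dplyr::group_by(tally, .data$label),
                              n = sum(.data$n), .groups = "drop")
  }
  p <- ggplot2::ggplot(tally,
                       ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                    y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "named entity tag", y = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if (per_layer) {
    p <- p + ggplot2::facet_wrap(~layer,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training and validation loss curves
#'
#' @param object A trained `multilayer_ner_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multilayer_ner_model <- function(object, ...) {
  hist <- tidy(object)
  long <- tidyr::pivot_longer(hist, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  long <- long[!is.na(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "summed per-head cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-class F1 bars of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  pc <- tidy(object)
  ggplot2::ggplot(pc, ggplot2::aes(x = stats::reorder(.data$etype,
                                                      -.data$f1),
                                   y = .data$f1)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = object$macro_f1, linetype = 2) +
    ggplot2::labs(x = "entity type", y = "span-level F1",
                  subtitle = sprintf("macro F1 = %.3f", object$macro_f1)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
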