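# ggplot2 views of the package's result types.

#' Plot a spectrum as a stick plot
#'
#' @param object A one-row spectrum tibble (or a peaks data frame).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_spectrum <- function(object, ...) {
  peaks <- if (is.data.frame(object) && "peaks" %in% names(object)) {
    object$peaks[[1]]
  } else {
    as_tibble(object)
  }
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                      y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @describeIn train_cnn Training-log curve (loss and binary accuracy by
#'   epoch) of a trained model.
#' @param object A trained `cnn_model`.
#' @exportS3Method ggplot2::autoplot
autoplot.cnn_model <- function(object, ...) {
  log <- object$training_log
  if (is.null(log)) abort("Model has no training log yet.")
  long <- tidyr::pivot_longer(log, c("loss", "binary_accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_annotation Top-k accuracy curves under both
#'   denominators.
#' @param object An `eval_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$k, .data$accuracy,
                               colour = .data$denominator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "rank depth k", y = "top-k accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn train_cnn Tidy the per-epoch training log.
#' @param x A trained `cnn_model`.
#' @param ... Unused.
#' @export
tidy.cnn_model <- function(x, ...) {
  x$training_log %||% tibble(epoch = integer(), loss = numeric(),
                             binary_accuracy = numeric())
}

#' @describeIn train_cnn One-row model summary.
#' @export
glance.cnn_model <- function(x, ...) {
  log <- x$training_log
  tibble(
    input_length = x$cfg$input_length,
    n_layers = length(x$layers),
    n_parameters = sum(vapply(x$layers, function(l)
      length(l$W) + length(l$b), numeric(1))),
    trained = x$trained,
    final_loss = if (!is.null(log)) log$loss[nrow(log)] else NA_real_,
    final_binary_accuracy = if (!is.null(log)) log$binary_accuracy[nrow(log)] else NA_real_
  )
}

#' @describeIn fit_strategy Per-member training summaries of a bundle.
#' @param x A `model_bundle`.
#' @param ... Unused.
#' @export
tidy.model_bundle <- function(x, ...) {
  bind_rows(lapply(names(x$members), function(key) {
    g <- glance(x$members[[key]])
    g$member <- key
    g
  }))
}
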