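#' Tidy a trained or built model: the per-layer summary
#'
#' One row per layer with its output shape and parameter counts - the
#' model's architecture table.
#'
#' @param x An `hb_model`.
#' @param ... Unused.
#' @return A tibble: `layer`, `name`, `kernel`, `filters`, `stride`,
#'   `shape`, `trainable`, `non_trainable`.
#' @method tidy hb_model
#' @export
tidy.hb_model <- function(x, ...) {
  sh <- architecture_shapes(x$arch)
  pc <- count_parameters(x$arch)
  dplyr::bind_cols(
    x$arch[, c("layer", "name", "kernel", "filters", "stride")],
    sh[, "shape"], pc[, c("trainable", "non_trainable")]
  )
}

#' One-row model summary
#'
#' @param x An `hb_model`.
#' @param ... Unused.
#' @return A tibble with parameter totals, training status, loss kind and
#'   final training loss.
#' @method glance hb_model
#' @export
glance.hb_model <- function(x, ...) {
  pc <- count_parameters(x$arch)
  tibble(
    n_trainable = sum(pc$trainable),
    n_non_trainable = sum(pc$non_trainable),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    loss_kind = if (is.null(x$loss_config)) NA_character_ else
      x$loss_config$kind,
    n_train_records = length(x$train_records)
  )
}

#' Tidy an evaluation: per-class metrics
#'
#' @param x An `hb_eval`.
#' @param ... Unused.
#' @return The per-class metric tibble (percentages, unrounded).
#' @method tidy hb_eval
#' @export
tidy.hb_eval <- function(x, ...) x$metrics$per_class

#' One-row evaluation summary
#'
#' @param x An `hb_eval`.
#' @param ... Unused.
#' @return A tibble with the macro-averaged metrics, overall (trace)
#'   accuracy and beat counts.
#' @method glance hb_eval
#' @export
glance.hb_eval <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::rename_with(x$metrics$macro, ~ paste0("macro_", .x)),
    tibble(overall_accuracy_pct = x$metrics$overall_accuracy_pct,
           n_beats = x$metrics$n_beats, n_correct = x$metrics$n_correct)
  )
}

#' Tidy a confusion matrix into long counts
#'
#' @param x An `hb_confusion`.
#' @param ... Unused.
#' @return A tibble `truth`, `predicted`, `n`.
#' @method tidy hb_confusion
#' @export
tidy.hb_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)))
  names(df) <- c("truth", "predicted", "n")
  as_tibble(df)
}

#' Plot the training loss history
#'
#' @param object A trained `hb_model`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch (log-scaled loss axis).
#' @method autoplot hb_model
#' @export
autoplot.hb_model <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history yet.")
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "training loss history") +
    ggplot2::theme_minimal()
}

#' Plot a confusion heatmap for an evaluation
#'
#' @param object An `hb_eval` or `hb_confusion`.
#' @param ... Unused.
#' @return A ggplot heatmap with counts annotated.
#' @method autoplot hb_eval
#' @export
autoplot.hb_eval <- function(object, ...) autoplot(object$confusion)

#' @rdname autoplot.hb_eval
#' @method autoplot hb_confusion
#' @export
autoplot.hb_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = format(.data$n, big.mark = ",")),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(aami_classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 trans = "log1p", guide = "none") +
    ggplot2::labs(x = "predicted class", y = "ground truth") +
    ggplot2::theme_minimal()
}
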