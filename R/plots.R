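# ggplot2 views of the pipeline's result objects.

#' Plot a confusion matrix as a heat map
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot object (true class on the vertical axis, counts
#'   printed in each cell).
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(object$class_labels))
  df$predicted <- factor(df$predicted, levels = object$class_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot the selection criterion trajectory
#'
#' @param object An [sfs_select()] result.
#' @param ... Unused.
#' @return A ggplot of the cross-validated deviance against the number of
#'   accepted features (step 0 is the intercept-only model).
#' @method autoplot sfs_result
#' @export
autoplot.sfs_result <- function(object, ...) {
  df <- tibble::tibble(
    n_features = seq_along(object$criterion_trajectory) - 1,
    criterion = object$criterion_trajectory
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "features accepted", y = "CV deviance criterion") +
    ggplot2::theme_minimal()
}

#' Plot the hidden-size sweep
#'
#' @param object A [sweep_structures()] result.
#' @param ... Unused.
#' @return A ggplot of overall CCR against hidden-layer size; the chosen
#'   structure is highlighted.
#' @method autoplot mlp_sweep
#' @export
autoplot.mlp_sweep <- function(object, ...) {
  df <- object$records
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hidden_size,
                                   y = .data$overall_ccr)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$hidden_size == object$chosen_hidden_size, ],
                        colour = "#d7301f", size = 3) +
    ggplot2::labs(x = "hidden-layer size",
                  y = "overall correct classification rate (%)") +
    ggplot2::theme_minimal()
}

#' Plot the training curves of a fitted network
#'
#' @param object A [train_mlp()] model.
#' @param ... Unused.
#' @return A ggplot of train and validation MSE per epoch; the best epoch
#'   (validation minimum used for early stopping) is marked.
#' @method autoplot mlp_model
#' @export
autoplot.mlp_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch",
                            names_to = "series", values_to = "mse")
  p <- ggplot2::ggplot(df[!is.na(df$mse), ],
                       ggplot2::aes(x = .data$epoch, y = .data$mse,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL) +
    ggplot2::theme_minimal()
  if (object$best_epoch > 0 && is.finite(object$best_validation_error)) {
    p <- p + ggplot2::geom_vline(xintercept = object$best_epoch,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
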