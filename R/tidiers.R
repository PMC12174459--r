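#' @exportS3Method generics::tidy
tidy.mogat_fit <- function(x, ...) {
  tidyr::pivot_longer(x$log, -"epoch", names_to = "component",
                      values_to = "loss")
}

#' @exportS3Method generics::glance
glance.mogat_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), , drop = FALSE]
  dplyr::bind_cols(
    tibble::tibble(n_views = length(x$view_names),
                   n_samples = length(x$sample_ids),
                   n_train = length(x$train_ids),
                   n_classes = x$label_info$C,
                   epochs = nrow(x$log)),
    last[, setdiff(names(last), "epoch"), drop = FALSE])
}

#' Plot training loss curves
#'
#' One line per loss component (each omics branch, the fusion head, and the
#' total) over epochs.
#'
#' @param object A `mogat_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mogat_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$loss), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the metric distribution across repeated splits
#'
#' @param object A `mogat_experiment`.
#' @param ... Unused.
#' @return A ggplot object (one boxplot per metric).
#' @exportS3Method ggplot2::autoplot
autoplot.mogat_experiment <- function(object, ...) {
  d <- tidyr::pivot_longer(object$repeats,
                           c("accuracy", "recall_weighted", "f1_weighted",
                             "f1_macro"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out value") +
    ggplot2::theme_minimal()
}

#' Plot top biomarkers by importance
#'
#' @param object A `mogat_importance` table.
#' @param k Features shown per view.
#' @param ... Unused.
#' @return A ggplot object, one facet per omics view.
#' @exportS3Method ggplot2::autoplot
autoplot.mogat_importance <- function(object, k = 10, ...) {
  d <- top_biomarkers(object, k = k)
  d$feature <- stats::reorder(d$feature, d$importance)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~view_name, scales = "free_y") +
    ggplot2::labs(x = "importance (held-out F1 drop)", y = NULL) +
    ggplot2::theme_minimal()
}
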