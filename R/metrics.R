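#' Multiclass classification metrics
#'
#' Computes the four headline metrics and the per-class breakdown from a
#' confusion matrix. Accuracy is the fraction of correct predictions
#' (confusion-matrix trace over total); weighted recall averages per-class
#' recall with class supports as weights (and therefore equals accuracy for
#' single-label multiclass predictions -- an algebraic identity); per-class
#' `F1_i` is the harmonic mean of precision and recall (0 when both vanish);
#' macro F1 is the unweighted mean of `F1_i` over all `C` classes (absent
#' classes contribute 0); weighted F1 uses supports as weights.
#'
#' @param truth True class codes (0-based integers) or labels.
#' @param estimate Predicted class codes or labels, same length.
#' @param class_names Optional class name vector; codes index into it. When
#'   `truth`/`estimate` are labels, defaults to their sorted union.
#' @return A `metrics_report`: list with `accuracy`, `recall_weighted`,
#'   `f1_weighted`, `f1_macro`, `per_class` (tibble), and `confusion`
#'   (C x C matrix, rows = truth).
#' @export
compute_metrics <- function(truth, estimate, class_names = NULL) {
  if (length(truth) == 0) abort("empty input")
  if (length(truth) != length(estimate)) abort("length mismatch")
  if (is.numeric(truth)) {
    if (is.null(class_names)) {
      C <- max(truth, estimate) + 1L
      class_names <- as.character(seq_len(C) - 1L)
    }
    t_codes <- as.integer(truth); e_codes <- as.integer(estimate)
  } else {
    if (is.null(class_names)) {
      class_names <- sort(unique(c(as.character(truth), as.character(estimate))))
    }
    t_codes <- match(as.character(truth), class_names) - 1L
    e_codes <- match(as.character(estimate), class_names) - 1L
  }
  C <- length(class_names)
  if (anyNA(t_codes) || anyNA(e_codes) ||
      any(t_codes < 0) || any(t_codes >= C) ||
      any(e_codes < 0) || any(e_codes >= C)) {
    abort("class codes out of range")
  }
  conf <- matrix(0L, C, C, dimnames = list(truth = class_names,
                                           estimate = class_names))
  for (i in seq_along(t_codes)) {
    conf[t_codes[i] + 1L, e_codes[i] + 1L] <-
      conf[t_codes[i] + 1L, e_codes[i] + 1L] + 1L
  }
  total <- sum(conf)
  tp <- unname(diag(conf))
  support <- unname(rowSums(conf))
  predicted <- unname(colSums(conf))
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  per_class <- tibble::tibble(class = class_names, precision = precision,
                              recall = recall, f1 = f1,
                              support = as.integer(support))
  structure(list(
    accuracy = sum(tp) / total,
    recall_weighted = sum(w * recall),
    f1_weighted = sum(w * f1),
    f1_macro = mean(f1),
    per_class = per_class,
    confusion = conf), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report: ACC %.4f | Recall_w %.4f | F1_w %.4f | F1_macro %.4f>\n",
    x$accuracy, x$recall_weighted, x$f1_weighted, x$f1_macro))
  print(x$per_class)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, recall_weighted = x$recall_weighted,
                 f1_weighted = x$f1_weighted, f1_macro = x$f1_macro,
                 n = sum(x$confusion))
}

#' Write metrics to JSON
#'
#' @param x A `metrics_report` or `mogat_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  obj <- if (inherits(x, "metrics_report")) {
    list(summary = as.list(glance(x)), per_class = x$per_class)
  } else if (inherits(x, "mogat_experiment")) {
    list(summary = as.list(glance(x)), repeats = tidy(x))
  } else {
    abort("x must be a metrics_report or mogat_experiment")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
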