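#' Run the full repeated-split evaluation protocol
#'
#' For each of `num_repeats` repeats: draw a stratified `train_fraction`
#' split (repeat r uses seed `seed + r`), fit the preprocessing on the
#' training samples only (filter, correlation-based selection, min-max
#' normalization), build the patient graphs over all samples, train the
#' model jointly, and score the held-out samples. View-subset and no-fusion
#' ablations are driven by `config$views` and `config$use_vcdn`.
#'
#' @param views Named list of raw [omics_view()] objects (they are aligned
#'   with the labels internally).
#' @param labels Label tibble.
#' @param config A [mogat_config()].
#' @param mapping Optional CpG-to-gene table (see [preprocess_views()]).
#' @return A `mogat_experiment`: per-repeat metric tibble, the individual
#'   `metrics_report`s, summary means/sds, the config echo and seeds used.
#' @export
run_experiment <- function(views, labels, config = mogat_config(),
                           mapping = NULL) {
  if (!is.null(config$views)) {
    missing <- setdiff(config$views, names(views))
    if (length(missing) > 0) {
      abort(sprintf("unknown view(s) in config: %s",
                    paste(missing, collapse = ", ")))
    }
    views <- views[config$views]
  }
  al <- align_views(views, labels)
  views <- al$views
  labels <- al$labels

  seeds <- config$seed + seq_len(config$num_repeats)
  reports <- vector("list", config$num_repeats)
  rows <- vector("list", config$num_repeats)
  for (r in seq_len(config$num_repeats)) {
    res <- tryCatch({
      sp <- split_stratified(labels, config$train_fraction, seed = seeds[r])
      pp <- preprocess_views(views, labels, train_ids = sp$train_ids,
                             config = config, mapping = mapping)
      rcfg <- config
      rcfg$seed <- seeds[r]
      fit <- mogat_fit(pp$views, labels, train_ids = sp$train_ids,
                       config = rcfg, feature_universe = pp$universe)
      preds <- predict(fit)
      test <- preds$sample_id %in% sp$test_ids
      compute_metrics(labels$label[match(preds$sample_id[test],
                                         labels$sample_id)],
                      as.character(preds$.pred_class[test]),
                      class_names = fit$label_info$class_names)
    }, error = function(e) {
      abort(sprintf("repeat %d failed: %s", r, conditionMessage(e)))
    })
    reports[[r]] <- res
    rows[[r]] <- dplyr::bind_cols(tibble::tibble(repeat_id = r), glance(res))
  }
  repeats <- dplyr::bind_rows(rows)
  metric_cols <- c("accuracy", "recall_weighted", "f1_weighted", "f1_macro")
  summary <- tidyr::pivot_longer(repeats, dplyr::all_of(metric_cols),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = sd(.data$value), .groups = "drop")
  structure(list(repeats = repeats, reports = reports, summary = summary,
                 config = config, seeds = seeds,
                 view_names = names(views)),
            class = "mogat_experiment")
}

#' @export
print.mogat_experiment <- function(x, ...) {
  cat(sprintf("<mogat_experiment: views [%s], %d repeat(s), vcdn=%s>\n",
              paste(x$view_names, collapse = ", "), nrow(x$repeats),
              x$config$use_vcdn))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mogat_experiment <- function(x, ...) x$repeats

#' @exportS3Method generics::glance
glance.mogat_experiment <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(num_repeats = nrow(x$repeats),
                                  train_fraction = x$config$train_fraction,
                                  use_vcdn = x$config$use_vcdn,
                                  views = paste(x$view_names, collapse = "+")),
                   wide)
}

#' All non-empty view combinations
#'
#' Enumerates the 2^m - 1 omics combinations used by the ablation study
#' (three views give seven combinations).
#'
#' @param view_names Character vector of available view names.
#' @return List of character vectors, singletons first.
#' @export
view_combinations <- function(view_names) {
  m <- length(view_names)
  combos <- list()
  for (k in seq_len(m)) {
    cs <- utils::combn(view_names, k, simplify = FALSE)
    combos <- c(combos, cs)
  }
  combos
}

#' Binarize a staged cohort into adjacent stage pairs
#'
#' For stages S1..SK (ordered by factor levels if the label is a factor,
#' lexicographically otherwise, which orders Roman-numeral stages I..V
#' correctly) returns the K-1 datasets restricted to each adjacent pair --
#' the binary tasks used to isolate transition-specific biomarkers.
#'
#' @param labels Label tibble.
#' @return Named list (`"I_vs_II"`, ...) of label tibbles, each containing
#'   only its two stages.
#' @export
stage_pair_datasets <- function(labels) {
  li <- label_info(labels)
  if (li$C < 2) abort("need at least two stages")
  out <- list()
  for (t in seq_len(li$C - 1)) {
    pair <- li$class_names[c(t, t + 1)]
    sub <- labels[as.character(labels$label) %in% pair, , drop = FALSE]
    sub$label <- as.character(sub$label)
    out[[paste(pair, collapse = "_vs_")]] <- sub
  }
  out
}
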