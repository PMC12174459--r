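#' Rank input features by masking importance
#'
#' The primary importance definition is model-agnostic ablation: a feature's
#' importance is the drop in weighted F1 on the held-out samples when its
#' column is replaced by zeros (the post-min-max floor, so masked inputs stay
#' in-domain) while the trained parameters and the patient graph stay fixed.
#' Features that were not selected into the model never enter the network
#' and score exactly 0. A gradient-times-input score is available as an
#' alternative (`method = "gradient"`): the mean over held-out samples of
#' `|x_ij * dL/dx_ij|`, with the cross-entropy taken on the held-out nodes.
#'
#' @param fit A `mogat_fit` with a non-empty held-out set.
#' @param method `"masking"` (default) or `"gradient"`.
#' @param repeats Number of evaluation repeats averaged per feature.
#' @return A tibble of class `mogat_importance` with columns `view_name`,
#'   `feature`, `importance`, `rank` (1..p within each view, descending
#'   importance, ties broken by feature name). Attributes: `baseline`
#'   (held-out weighted F1), `method`, `task`.
#' @export
masking_importance <- function(fit, method = c("masking", "gradient"),
                               repeats = 1) {
  stopifnot(inherits(fit, "mogat_fit"))
  method <- match.arg(method)
  test_ids <- fit$test_ids
  if (length(test_ids) == 0) abort("fit has no held-out samples")
  test_idx <- match(test_ids, fit$sample_ids)
  truth <- as.character(fit$labels$label[test_idx])
  cls <- fit$label_info$class_names

  test_f1 <- function(final_probs) {
    est <- cls[max.col(final_probs[test_idx, , drop = FALSE],
                       ties.method = "first")]
    compute_metrics(truth, est, class_names = cls)$f1_weighted
  }
  baseline <- test_f1(forward_probs(fit)$final)

  grad_score <- NULL
  if (method == "gradient") {
    cfg <- fit$config
    lg <- cpp_loss_grad(unname(fit$X),
                        lapply(fit$csrs, `[[`, "ei"),
                        lapply(fit$csrs, `[[`, "ej"),
                        lapply(fit$csrs, `[[`, "ptr"),
                        fit$label_info$codes[match(fit$sample_ids,
                                                   fit$labels$sample_id)],
                        test_idx - 1L, fit$params, fit$label_info$C,
                        cfg$num_heads, cfg$hidden_dims, cfg$leaky_slope,
                        cfg$delta, fit$use_fusion, cfg$use_layernorm)
    grad_score <- lapply(seq_along(fit$X), function(v) {
      gi <- abs(fit$X[[v]] * lg$grads$X[[v]])
      colMeans(gi[test_idx, , drop = FALSE])
    })
    names(grad_score) <- fit$view_names
  }

  rows <- list()
  for (nm in fit$view_names) {
    universe <- fit$feature_universe[[nm]]
    selected <- colnames(fit$X[[nm]])
    imp <- setNames(rep(0, length(universe)), universe)
    if (method == "masking") {
      for (f in intersect(universe, selected)) {
        drops <- numeric(repeats)
        for (r in seq_len(repeats)) {
          X2 <- fit$X
          X2[[nm]][, f] <- 0
          drops[r] <- baseline - test_f1(forward_probs(fit, X = X2)$final)
        }
        imp[f] <- mean(drops)
      }
    } else {
      hit <- intersect(universe, selected)
      imp[hit] <- grad_score[[nm]][hit]
    }
    ord <- order(-imp, names(imp))
    rows[[nm]] <- tibble::tibble(view_name = nm,
                                 feature = names(imp)[ord],
                                 importance = unname(imp[ord]),
                                 rank = seq_along(imp))
  }
  structure(dplyr::bind_rows(rows), baseline = baseline, method = method,
            task = paste(fit$label_info$class_names, collapse = "/"),
            class = c("mogat_importance", class(tibble::tibble())))
}

#' Top-ranked biomarkers per view
#'
#' @param importance A `mogat_importance` table.
#' @param k Number of features to report per view; clipped (with a warning)
#'   when a view has fewer features.
#' @return Tibble of the top `k` rows per view, in rank order.
#' @export
top_biomarkers <- function(importance, k = 3) {
  stopifnot(k >= 0)
  if (k == 0) return(importance[0, , drop = FALSE])
  out <- dplyr::group_by(importance, .data$view_name)
  sizes <- dplyr::summarise(out, n = dplyr::n())
  if (any(sizes$n < k)) {
    warn(sprintf("k = %d exceeds the feature count of some view; clipping", k))
  }
  dplyr::ungroup(dplyr::slice_min(out, .data$rank, n = k, with_ties = FALSE))
}

#' Stage-pair biomarker discovery
#'
#' Converts the multi-stage task into the adjacent-pair binary tasks from
#' [stage_pair_datasets()], then runs the full pipeline per pair -- stratified
#' split, train-fitted preprocessing, joint training, masking importance on
#' the held-out samples -- and returns one importance table per stage pair.
#'
#' @param views Named list of raw [omics_view()] objects.
#' @param labels Label tibble with orderable stage names.
#' @param config A [mogat_config()].
#' @param method Importance method, see [masking_importance()].
#' @return Named list of `mogat_importance` tables, one per adjacent pair.
#' @export
stage_pair_biomarkers <- function(views, labels, config = mogat_config(),
                                  method = "masking") {
  pairs <- stage_pair_datasets(labels)
  out <- list()
  for (task in names(pairs)) {
    pl <- pairs[[task]]
    al <- align_views(views, pl)
    sp <- split_stratified(al$labels, config$train_fraction,
                           seed = config$seed)
    pp <- preprocess_views(al$views, al$labels, train_ids = sp$train_ids,
                           config = config)
    fit <- mogat_fit(pp$views, al$labels, train_ids = sp$train_ids,
                     config = config, feature_universe = pp$universe)
    imp <- masking_importance(fit, method = method)
    attr(imp, "task") <- task
    out[[task]] <- imp
  }
  out
}
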