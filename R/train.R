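#' Stratified train/test split
#'
#' Randomly assigns `train_fraction` of each class to training (rounded per
#' class, always leaving at least one sample on each side), so small classes
#' cannot vanish from either partition.
#'
#' @param labels Label tibble.
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with character vectors `train_ids` and `test_ids`.
#' @export
split_stratified <- function(labels, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(labels$label)
  if (any(counts < 2)) {
    abort(sprintf("class '%s' has fewer than 2 samples",
                  names(counts)[counts < 2][1]))
  }
  set.seed(as.integer(seed))
  # largest-remainder allocation: per-class counts sum to round(f * n)
  # whenever the per-class floors leave room, so the overall train size hits
  # the nominal fraction exactly up to stratification rounding
  classes <- sort(unique(as.character(labels$label)))
  n_c <- vapply(classes, function(cl) sum(labels$label == cl), integer(1))
  target <- train_fraction * n_c
  k_c <- floor(target)
  rem <- round(train_fraction * nrow(labels)) - sum(k_c)
  if (rem > 0) {
    extra <- order(-(target - k_c), classes)[seq_len(min(rem, length(classes)))]
    k_c[extra] <- k_c[extra] + 1
  }
  k_c <- pmax(1, pmin(k_c, n_c - 1))
  train_ids <- character(0)
  for (i in seq_along(classes)) {
    ids <- labels$sample_id[labels$label == classes[i]]
    train_ids <- c(train_ids, sample(ids, k_c[i]))
  }
  train_ids <- sort(train_ids)
  list(train_ids = train_ids,
       test_ids = sort(setdiff(labels$sample_id, train_ids)))
}

#' Mean cross-entropy of predicted class probabilities
#'
#' `-log p[true]` per sample (probability floored at 1e-12 for finiteness),
#' averaged over samples.
#'
#' @param probs Probability matrix (n x C) or a single probability vector.
#' @param true_class 0-based class codes (length n, or 1).
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(probs, true_class) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  true_class <- as.integer(true_class)
  if (any(true_class < 0) || any(true_class >= ncol(probs))) {
    abort("invalid class code")
  }
  p <- probs[cbind(seq_len(nrow(probs)), true_class + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Total training loss
#'
#' `sum(branch losses) + delta * fusion loss`: each omics branch keeps its
#' own supervision signal, and `delta` trades it off against the fused
#' classifier's loss.
#'
#' @param branch_losses Numeric vector of per-branch cross-entropies.
#' @param fusion_loss Fusion cross-entropy (scalar).
#' @param delta Nonnegative trade-off weight (default 1).
#' @return Scalar total loss.
#' @export
total_loss <- function(branch_losses, fusion_loss, delta = 1) {
  if (any(branch_losses < 0) || fusion_loss < 0) {
    abort("cross-entropy losses cannot be negative")
  }
  stopifnot(delta >= 0)
  sum(branch_losses) + delta * fusion_loss
}

#' Jointly train the multi-omics graph attention model
#'
#' Builds one cosine-similarity patient graph per view, initializes every
#' weight matrix with Xavier-uniform draws, and optimizes all branches plus
#' the fusion head together with Adam, minimizing
#' `sum(branch CE) + delta * fusion CE` on the training nodes only. The
#' forward pass is transductive: all samples (training and held-out) sit in
#' the graph, but only training nodes contribute loss.
#'
#' Views must be aligned, preprocessed (see [preprocess_views()]) and on a
#' common \[0, 1\] scale. With a single view, or `use_vcdn = FALSE`, the
#' fusion head is dropped and prediction averages the branch distributions.
#'
#' @param views Named list of aligned, normalized [omics_view()] objects.
#' @param labels Aligned label tibble.
#' @param train_ids Sample ids used for the loss; `NULL` trains on all.
#' @param config A [mogat_config()].
#' @param feature_universe Optional per-view character list of the full
#'   pre-selection feature names (kept for biomarker reporting).
#' @return A `mogat_fit` object holding the trained parameters, the graphs,
#'   the training log, and everything needed to predict.
#' @export
mogat_fit <- function(views, labels, train_ids = NULL,
                      config = mogat_config(), feature_universe = NULL) {
  stopifnot(length(views) >= 1)
  if (is.null(names(views)) || any(names(views) == "")) {
    abort("views must be a named list")
  }
  ids <- views[[1]]$sample_id
  for (v in views) {
    if (!identical(v$sample_id, ids)) abort("views are not aligned; run align_views()")
  }
  if (!identical(labels$sample_id, ids)) {
    abort("labels are not aligned with the views")
  }
  li <- label_info(labels)
  if (is.null(train_ids)) train_ids <- ids
  tr_idx <- match(train_ids, ids)
  if (anyNA(tr_idx)) abort("train_ids contains unknown sample ids")

  m <- length(views)
  use_fusion <- config$use_vcdn && m >= 2
  X <- lapply(views, view_matrix)
  graphs <- lapply(views, build_patient_graph, avg_degree = config$avg_degree)
  csrs <- lapply(graphs, function(g) graph_csr(g$adjacency))

  set.seed(config$seed)
  params <- init_model_params(vapply(X, ncol, integer(1)), li$C, config,
                              use_fusion)
  res <- cpp_train(
    unname(X),
    lapply(csrs, `[[`, "ei"), lapply(csrs, `[[`, "ej"),
    lapply(csrs, `[[`, "ptr"),
    li$codes, tr_idx - 1L, params, li$C, config$num_heads,
    config$hidden_dims, config$leaky_slope, config$delta, use_fusion,
    config$use_layernorm, config$learning_rate, config$num_epochs,
    config$dropout, config$seed)

  log <- res$log
  colnames(log) <- c(paste0("branch_", names(views)), "fusion", "total")
  log_tbl <- tibble::as_tibble(log)
  log_tbl <- tibble::add_column(log_tbl, epoch = seq_len(nrow(log_tbl)),
                                .before = 1)

  structure(list(
    params = res$params, config = config, view_names = names(views),
    X = X, graphs = graphs, csrs = csrs,
    sample_ids = ids, labels = labels, label_info = li,
    train_ids = sort(train_ids),
    test_ids = sort(setdiff(ids, train_ids)),
    feature_universe = feature_universe %||%
      lapply(views, feature_names),
    use_fusion = use_fusion, log = log_tbl),
    class = "mogat_fit")
}

#' @export
print.mogat_fit <- function(x, ...) {
  cat(sprintf("<mogat_fit: %d view(s) [%s], %d samples (%d train), %d classes>\n",
              length(x$view_names), paste(x$view_names, collapse = ", "),
              length(x$sample_ids), length(x$train_ids), x$label_info$C))
  if (nrow(x$log) > 0) {
    cat(sprintf("  final total loss: %.4f (epoch %d)\n",
                x$log$total[nrow(x$log)], nrow(x$log)))
  }
  cat(sprintf("  fusion: %s\n", if (x$use_fusion) "cross-omics tensor head"
              else "bypassed (branch average)"))
  invisible(x)
}

# Forward pass with arbitrary view matrices / graphs (shared by predict and
# masking importance). Returns list(branch = list of prob matrices,
# final = prob matrix).
forward_probs <- function(fit, X = NULL, csrs = NULL) {
  X <- X %||% fit$X
  csrs <- csrs %||% fit$csrs
  cfg <- fit$config
  out <- cpp_forward(unname(X),
                     lapply(csrs, `[[`, "ei"), lapply(csrs, `[[`, "ej"),
                     lapply(csrs, `[[`, "ptr"),
                     fit$params, fit$label_info$C, cfg$num_heads,
                     cfg$hidden_dims, cfg$leaky_slope,
                     fit$use_fusion, cfg$use_layernorm)
  branch <- out$branch_probs
  names(branch) <- fit$view_names
  final <- if (fit$use_fusion) out$fused else Reduce(`+`, branch) / length(branch)
  list(branch = branch, final = final)
}

#' Predict stage classes from a trained model
#'
#' In transductive mode (the default) all samples were already nodes of the
#' training-time graph, and prediction is a forward pass over it. In
#' inductive mode, `newdata` samples are attached to the *training* nodes by
#' cosine similarity -- each new sample links to its `round(avg_degree)` most
#' similar training samples -- without rebuilding or retraining anything, and
#' a forward pass over training + new nodes scores them.
#'
#' With several views and `use_vcdn = TRUE` the fused head's distribution is
#' returned; otherwise the branch distributions are averaged. The predicted
#' class is the argmax, ties broken toward the lowest class code.
#'
#' @param object A `mogat_fit`.
#' @param newdata For inductive mode: a named list of [omics_view()] objects
#'   with the same views and features as training, on the same \[0, 1\]
#'   scale. Ignored (must be `NULL`) in transductive mode.
#' @param mode `"transductive"` or `"inductive"`.
#' @param type `"prob"` for a tibble of probabilities and classes (default),
#'   `"branch"` to also return each branch's probability matrix.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `.pred_class`, and one `.pred_<class>`
#'   probability column per class (attribute `branch_probs` when
#'   `type = "branch"`).
#' @export
predict.mogat_fit <- function(object, newdata = NULL,
                              mode = c("transductive", "inductive"),
                              type = c("prob", "branch"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (mode == "transductive") {
    if (!is.null(newdata)) {
      abort("transductive prediction scores the fitted samples; use mode = 'inductive' for new data")
    }
    fp <- forward_probs(object)
    ids <- object$sample_ids
  } else {
    if (is.null(newdata)) abort("inductive mode needs newdata")
    if (!setequal(names(newdata), object$view_names)) {
      abort("newdata views differ from the training views")
    }
    ids <- newdata[[object$view_names[1]]]$sample_id
    tr <- object$train_ids
    X <- list(); csrs <- list()
    for (nm in object$view_names) {
      new_m <- view_matrix(newdata[[nm]])
      if (!identical(colnames(new_m), colnames(object$X[[nm]]))) {
        abort(sprintf("feature mismatch in view '%s'", nm))
      }
      train_m <- object$X[[nm]][tr, , drop = FALSE]
      gi <- match(tr, object$graphs[[nm]]$sample_ids)
      train_adj <- object$graphs[[nm]]$adjacency[gi, gi, drop = FALSE]
      adj <- attach_to_graph(train_adj, train_m, new_m,
                             object$config$avg_degree)
      X[[nm]] <- rbind(train_m, new_m)
      csrs[[nm]] <- graph_csr(adj)
    }
    fp <- forward_probs(object, X = X, csrs = csrs)
    keep <- length(tr) + seq_along(ids)
    fp$final <- fp$final[keep, , drop = FALSE]
    fp$branch <- lapply(fp$branch, function(b) b[keep, , drop = FALSE])
  }
  cls <- object$label_info$class_names
  probs <- fp$final
  colnames(probs) <- paste0(".pred_", cls)
  pred <- cls[max.col(fp$final, ties.method = "first")]
  out <- tibble::tibble(sample_id = ids,
                        .pred_class = factor(pred, levels = cls))
  out <- dplyr::bind_cols(out, tibble::as_tibble(probs))
  if (type == "branch") attr(out, "branch_probs") <- fp$branch
  out
}
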