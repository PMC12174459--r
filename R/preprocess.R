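#' Drop low-quality features and impute the rest
#'
#' Removes features whose zero fraction or missing fraction (computed on the
#' statistics samples, by default all rows) exceeds the thresholds, then
#' imputes any remaining missing entries with the feature median of the
#' statistics samples. Dropped features are reported on stderr.
#'
#' @param view An [omics_view()] (missing entries as `NA`).
#' @param max_zero_fraction,max_missing_fraction Thresholds in \[0, 1\].
#' @param stats_ids Sample ids used to compute the fractions and medians
#'   (training samples, to avoid test leakage); `NULL` for all samples.
#' @return The filtered, imputed `omics_view`.
#' @export
filter_low_quality <- function(view, max_zero_fraction = 0.2,
                               max_missing_fraction = 0.2, stats_ids = NULL) {
  m <- view_matrix(view)
  rows <- if (is.null(stats_ids)) seq_len(nrow(m)) else {
    idx <- match(stats_ids, rownames(m))
    if (anyNA(idx)) abort("stats_ids contains unknown sample ids")
    idx
  }
  sub <- m[rows, , drop = FALSE]
  zero_frac <- colMeans(sub == 0, na.rm = TRUE)
  zero_frac[is.nan(zero_frac)] <- 0   # all-missing columns
  miss_frac <- colMeans(is.na(sub))
  keep <- zero_frac <= max_zero_fraction & miss_frac <= max_missing_fraction
  if (!any(keep)) {
    abort("all features dropped; raise max_zero_fraction / max_missing_fraction")
  }
  if (any(!keep)) {
    inform(sprintf("filter_low_quality ('%s'): dropped %d of %d features",
                   view_name(view), sum(!keep), ncol(m)))
  }
  m <- m[, keep, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    if (anyNA(m[, j])) {
      med <- median(m[rows, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      m[is.na(m[, j]), j] <- med
    }
  }
  view_from_matrix(m, view_name(view))
}

#' Min-max normalize features to \[0, 1\]
#'
#' Per-feature `(x - min) / (max - min)` using statistics from the training
#' view, applied to `view` and clipped to \[0, 1\] so unseen samples cannot
#' escape the training range. Constant features map to 0. Normalizing per
#' feature (not per sample) preserves the cross-sample comparability that the
#' cosine-similarity patient graph relies on.
#'
#' @param view The `omics_view` to transform.
#' @param train An `omics_view` supplying min/max statistics; defaults to
#'   `view` itself. Must have the same feature set.
#' @return The normalized `omics_view`; every entry lies in \[0, 1\].
#' @export
normalize_minmax <- function(view, train = NULL) {
  m <- view_matrix(view)
  tm <- if (is.null(train)) m else view_matrix(train)
  if (!identical(colnames(m), colnames(tm))) {
    abort("feature set mismatch between view and training view")
  }
  mins <- apply(tm, 2, min)
  maxs <- apply(tm, 2, max)
  rng <- maxs - mins
  out <- sweep(m, 2, mins, "-")
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], "/")
  out[, !pos] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  view_from_matrix(out, view_name(view))
}

#' Correlation-based feature selection
#'
#' Scores each feature by its strongest one-vs-rest association with any
#' class: `score = max_c | cor(feature, 1{y = c}) |`. Zero-variance features
#' (undefined correlation) score 0. The top
#' `k = min(ceiling(feature_fraction * p), feature_cap)` features are kept,
#' sorted by descending score with ties broken by feature name. Scores are
#' computed on the training samples only.
#'
#' @param view An `omics_view` aligned with `labels`.
#' @param labels Label tibble covering the view's samples.
#' @param feature_fraction Fraction of features to keep (default 0.25).
#' @param feature_cap Hard cap on kept features per view (default 5000).
#' @param train_ids Sample ids to score on; `NULL` for all.
#' @return A tibble of class `mogat_selection` with columns `view_name`,
#'   `feature`, `score`, `rank`, `kept`, ordered by rank.
#' @export
cfs_select <- function(view, labels, feature_fraction = 0.25,
                       feature_cap = 5000, train_ids = NULL) {
  stopifnot(feature_fraction > 0, feature_fraction <= 1, feature_cap >= 1)
  m <- view_matrix(view)
  li <- label_info(labels)
  codes <- li$codes[match(rownames(m), labels$sample_id)]
  if (anyNA(codes)) abort("view contains samples absent from the labels")
  if (!is.null(train_ids)) {
    idx <- match(train_ids, rownames(m))
    if (anyNA(idx)) abort("train_ids contains unknown sample ids")
    m <- m[idx, , drop = FALSE]
    codes <- codes[idx]
  }
  if (nrow(m) < 3) abort("need at least 3 samples to compute correlations")
  if (length(unique(codes)) < 2) abort("need >= 2 classes present")
  # one-vs-rest indicators, n x C
  ind <- vapply(0:(li$C - 1), function(cc) as.numeric(codes == cc),
                numeric(nrow(m)))
  suppressWarnings(cm <- abs(cor(m, ind)))
  score <- apply(cm, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  score[is.na(score)] <- 0
  p <- ncol(m)
  k <- min(ceiling(feature_fraction * p), feature_cap)
  ord <- order(-score, colnames(m))
  out <- tibble::tibble(
    view_name = view_name(view),
    feature = colnames(m)[ord],
    score = unname(score[ord]),
    rank = seq_len(p),
    kept = seq_len(p) <= k)
  structure(out, k = as.integer(k),
            class = c("mogat_selection", class(tibble::tibble())))
}

#' Restrict a view to the features kept by a selection
#'
#' @param view The `omics_view` the selection was computed from.
#' @param selection A `mogat_selection` from [cfs_select()].
#' @return The reduced `omics_view`, features in selection (rank) order.
#' @export
apply_selection <- function(view, selection) {
  kept <- selection$feature[selection$kept]
  missing <- setdiff(kept, feature_names(view))
  if (length(missing) > 0) {
    abort(sprintf("selected feature '%s' absent from view", missing[1]))
  }
  m <- view_matrix(view)[, kept, drop = FALSE]
  view_from_matrix(m, view_name(view))
}

#' Rename methylation features by their adjacent gene
#'
#' CpG-site identifiers are replaced with gene names from a mapping table so
#' nomenclature is consistent across views; unmapped features are dropped.
#' When several CpG sites map to the same gene, the site with the highest
#' variance is kept and the collision is reported.
#'
#' @param view An `omics_view` with CpG-site feature names.
#' @param mapping Two-column table (`feature`, `gene`), see [read_mapping()].
#' @return The renamed `omics_view`.
#' @export
rename_methylation_features <- function(view, mapping) {
  mapping <- tibble::as_tibble(mapping)
  names(mapping)[1:2] <- c("feature", "gene")
  if (nrow(mapping) == 0) abort("mapping table is empty")
  m <- view_matrix(view)
  hit <- intersect(colnames(m), mapping$feature)
  if (length(hit) == 0) abort("mapping covers none of the view's features")
  dropped <- setdiff(colnames(m), hit)
  if (length(dropped) > 0) {
    inform(sprintf("rename_methylation_features: dropped %d unmapped feature(s)",
                   length(dropped)))
  }
  m <- m[, hit, drop = FALSE]
  genes <- mapping$gene[match(colnames(m), mapping$feature)]
  vars <- apply(m, 2, var)
  keep <- rep(TRUE, ncol(m))
  for (g in unique(genes[duplicated(genes)])) {
    grp <- which(genes == g)
    winner <- grp[order(-vars[grp], colnames(m)[grp])][1]
    keep[setdiff(grp, winner)] <- FALSE
    inform(sprintf("collision on gene '%s': kept '%s' (highest variance)",
                   g, colnames(m)[winner]))
  }
  m <- m[, keep, drop = FALSE]
  colnames(m) <- genes[keep]
  view_from_matrix(m, view_name(view))
}

#' Run the full per-view preprocessing pipeline
#'
#' Fixed order: low-quality filter, correlation-based selection, min-max
#' normalization -- each fitted on the training samples only and applied to
#' all samples, so no test information leaks into the transformations.
#'
#' @param views Named list of aligned [omics_view()] objects.
#' @param labels Aligned label tibble.
#' @param train_ids Training sample ids; `NULL` fits on all samples.
#' @param config A [mogat_config()].
#' @param mapping Optional CpG-to-gene table applied to views named "meth"
#'   or "methylation" before filtering.
#' @return List with `views` (processed), `selections` (per-view
#'   `mogat_selection`), and `universe` (per-view pre-selection feature
#'   names).
#' @export
preprocess_views <- function(views, labels, train_ids = NULL,
                             config = mogat_config(), mapping = NULL) {
  out <- list(views = list(), selections = list(), universe = list())
  for (nm in names(views)) {
    v <- views[[nm]]
    if (!is.null(mapping) && nm %in% c("meth", "methylation")) {
      v <- rename_methylation_features(v, mapping)
    }
    v <- filter_low_quality(v, config$max_zero_fraction,
                            config$max_missing_fraction, stats_ids = train_ids)
    out$universe[[nm]] <- feature_names(v)
    sel <- cfs_select(v, labels, config$feature_fraction, config$feature_cap,
                      train_ids = train_ids)
    v <- apply_selection(v, sel)
    train_view <- if (is.null(train_ids)) NULL else {
      view_from_matrix(view_matrix(v)[train_ids, , drop = FALSE], nm)
    }
    v <- normalize_minmax(v, train = train_view)
    out$views[[nm]] <- v
    out$selections[[nm]] <- sel
  }
  out
}
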