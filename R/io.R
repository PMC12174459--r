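#' Construct an omics view
#'
#' An omics view is one molecular modality (e.g. mRNA expression, miRNA
#' expression, DNA methylation beta-values) measured over a common set of
#' samples. It is stored as a tibble whose first column is `sample_id` and
#' whose remaining columns are numeric features; the view name travels along
#' as an attribute. Missing measurements are kept as `NA` so that
#' [filter_low_quality()] can drop or impute them explicitly.
#'
#' @param x A data frame with a `sample_id` column (or a first column that
#'   will be treated as the sample identifier) and numeric feature columns.
#' @param view_name Label for the modality, e.g. `"mRNA"`.
#' @return A tibble of class `omics_view`.
#' @export
omics_view <- function(x, view_name) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2) {
    abort("an omics view needs a sample-id column plus at least one feature")
  }
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    dup <- x$sample_id[duplicated(x$sample_id)][1]
    abort(sprintf("duplicate sample id '%s' in view '%s'", dup, view_name))
  }
  feats <- names(x)[-1]
  if (anyDuplicated(feats)) {
    dup <- feats[duplicated(feats)][1]
    abort(sprintf("duplicate feature name '%s' in view '%s'", dup, view_name))
  }
  for (f in feats) {
    if (!is.numeric(x[[f]])) {
      abort(sprintf("feature '%s' in view '%s' is not numeric", f, view_name))
    }
  }
  structure(x, view_name = as.character(view_name),
            class = c("omics_view", class(tibble::tibble())))
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics view '%s': %d samples x %d features>\n",
              view_name(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' View accessors
#'
#' @param view An `omics_view`.
#' @return `view_name()` the modality label; `feature_names()` the ordered
#'   feature names; `view_matrix()` the numeric sample-by-feature matrix with
#'   sample ids as row names.
#' @export
view_name <- function(view) attr(view, "view_name") %||% "view"

#' @rdname view_name
#' @export
feature_names <- function(view) setdiff(names(view), "sample_id")

#' @rdname view_name
#' @export
view_matrix <- function(view) {
  m <- as.matrix(view[, setdiff(names(view), "sample_id"), drop = FALSE])
  rownames(m) <- view$sample_id
  m
}

# inverse of view_matrix()
view_from_matrix <- function(m, view_name) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- tibble::add_column(df, sample_id = rownames(m), .before = 1)
  omics_view(df, view_name)
}

#' Read an omics feature table
#'
#' Expects a delimited table whose header row holds feature names and whose
#' first column holds sample identifiers; every other cell must parse as a
#' real number or be empty. Empty cells are recorded as missing (`NA`), not
#' imputed -- preprocessing decides their fate. A duplicated sample id or
#' feature name, or a non-numeric cell, is an error naming the offender.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param view_name Modality label attached to the result.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return An [omics_view()].
#' @export
read_omics_view <- function(path, view_name, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # read the header ourselves: readr silently de-duplicates column names,
  # but a duplicated feature name must be a hard error
  hdr <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  if (length(hdr) < 2) abort("expected a sample-id column plus feature columns")
  feats <- hdr[-1]
  if (anyDuplicated(feats)) {
    abort(sprintf("duplicated feature name '%s' in %s",
                  feats[duplicated(feats)][1], path))
  }
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE, skip = 1,
                           col_types = readr::cols(
                             .default = readr::col_character()),
                           progress = FALSE, na = character())
  if (ncol(raw) != length(hdr)) {
    abort(sprintf("header has %d columns but rows have %d in %s",
                  length(hdr), ncol(raw), path))
  }
  names(raw) <- hdr
  out <- raw[, 1]
  for (j in seq_along(feats)) {
    x <- raw[[j + 1]]
    blank <- is.na(x) | x == "" | x == "NA"
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!blank & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    x[bad[1]], bad[1], feats[j], path))
    }
    num[blank] <- NA_real_
    out[[feats[j]]] <- num
  }
  omics_view(out, view_name)
}

#' Write an omics view to CSV
#'
#' Missing entries are written as empty cells, so write/read round-trips
#' preserve the missingness pattern.
#'
#' @param view An [omics_view()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omics_view <- function(view, path) {
  readr::write_csv(tibble::as_tibble(view), path, na = "")
  invisible(path)
}

#' Read a sample-to-stage label table
#'
#' A two-column table `sample_id,label`. Class names are the sorted distinct
#' labels and integer class codes are assigned in that order, so the coding is
#' deterministic under any row shuffling of the input.
#'
#' @param path Path to a two-column CSV.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) != 2) abort("label table must have exactly two columns")
  names(x) <- c("sample_id", "label")
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("duplicate sample id '%s' in label table",
                  x$sample_id[duplicated(x$sample_id)][1]))
  }
  validate_labels(x)
  x
}

#' @rdname read_labels
#' @param labels A label tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels[, c("sample_id", "label")], path)
  invisible(path)
}

validate_labels <- function(labels) {
  if (nrow(labels) == 0) abort("label table is empty")
  if (length(unique(labels$label)) < 2) {
    abort("C must be >= 2: need at least two distinct class labels")
  }
  invisible(labels)
}

# Deterministic label coding: class names sorted, codes 0..C-1 in that order.
# Honors factor level order when the label column is a factor.
label_info <- function(labels) {
  if (is.factor(labels$label)) {
    class_names <- levels(droplevels(labels$label))
  } else {
    class_names <- sort(unique(as.character(labels$label)))
  }
  codes <- match(as.character(labels$label), class_names) - 1L
  list(class_names = class_names, codes = codes, C = length(class_names))
}

#' Restrict views and labels to their common samples
#'
#' Mirrors the exclusion of samples that are inconsistent or incomplete
#' across omics datasets: only samples present in every view *and* in the
#' label table are kept, in lexicographic sample-id order so the result does
#' not depend on input row order. Dropped ids are reported on stderr.
#'
#' @param views Named list of [omics_view()] objects.
#' @param labels Label tibble (see [read_labels()]).
#' @return A list with elements `views`, `labels` and `dropped`.
#' @export
align_views <- function(views, labels) {
  stopifnot(length(views) >= 1)
  id_sets <- c(lapply(views, function(v) v$sample_id), list(labels$sample_id))
  keep <- sort(Reduce(intersect, id_sets))
  if (length(keep) == 0) abort("no samples shared by every view and the labels")
  all_ids <- sort(unique(unlist(id_sets)))
  dropped <- setdiff(all_ids, keep)
  if (length(dropped) > 0) {
    inform(sprintf("align_views: dropped %d sample(s): %s", length(dropped),
                   paste(head(dropped, 10), collapse = ", ")))
  }
  views <- lapply(views, function(v) {
    out <- v[match(keep, v$sample_id), , drop = FALSE]
    structure(out, view_name = view_name(v),
              class = c("omics_view", class(tibble::tibble())))
  })
  labels <- labels[match(keep, labels$sample_id), , drop = FALSE]
  list(views = views, labels = labels, dropped = dropped)
}

#' Read a CpG-site-to-gene mapping table
#'
#' Two-column TSV used by [rename_methylation_features()]; the first column
#' holds CpG identifiers (e.g. "cg00000108"), the second the adjacent gene
#' name the site is renamed to.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `feature` and `gene`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) != 2) abort("mapping table must have exactly two columns")
  names(x) <- c("feature", "gene")
  x
}
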