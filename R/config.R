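#' Run configuration
#'
#' Holds every tunable of the pipeline. Defaults: 200 epochs, learning rate 0.008, 32 attention heads,
#' hidden dimension 16, a 128-unit fusion layer, loss trade-off `delta = 1`,
#' and the 70/30 split repeated 10 times.
#'
#' @param num_epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param num_heads Attention heads on the first (concatenating) graph
#'   attention layer; the second layer uses a single head.
#' @param hidden_dims Width of the fully connected reduction and the per-head
#'   attention output dimension.
#' @param vcdn_features Width of the first fusion layer applied to the
#'   flattened cross-omics tensor.
#' @param delta Weight of the fusion cross-entropy in the total loss.
#' @param train_fraction Fraction of samples assigned to training in each
#'   stratified split.
#' @param num_repeats Number of independent train/test splits.
#' @param avg_degree Target mean off-diagonal degree of the patient graph.
#' @param feature_cap Hard cap on features kept per view by selection.
#' @param feature_fraction Fraction of (post-filter) features kept per view.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param views Optional character vector restricting which views are used.
#' @param use_vcdn If `FALSE`, the cross-omics fusion head is bypassed and
#'   the final prediction is the average of the branch distributions.
#' @param dropout Dropout rate inside the fully connected reduction.
#' @param use_layernorm Apply per-sample feature normalization after each
#'   fully connected layer.
#' @param leaky_slope Negative slope of every LeakyReLU.
#' @param max_zero_fraction,max_missing_fraction Low-quality feature filter
#'   thresholds (see [filter_low_quality()]).
#' @param mode `"transductive"` (graph over train+test, losses on train
#'   nodes only) or `"inductive"` (test samples attached to the training
#'   graph at prediction time).
#' @return A `mogat_config` list.
#' @export
mogat_config <- function(num_epochs = 200,
                         learning_rate = 0.008,
                         num_heads = 32,
                         hidden_dims = 16,
                         vcdn_features = 128,
                         delta = 1,
                         train_fraction = 0.7,
                         num_repeats = 10,
                         avg_degree = 10,
                         feature_cap = 5000,
                         feature_fraction = 0.25,
                         seed = 42L,
                         views = NULL,
                         use_vcdn = TRUE,
                         dropout = 0.5,
                         use_layernorm = TRUE,
                         leaky_slope = 0.2,
                         max_zero_fraction = 0.2,
                         max_missing_fraction = 0.2,
                         mode = c("transductive", "inductive")) {
  cfg <- list(
    num_epochs = as.integer(num_epochs), learning_rate = learning_rate,
    num_heads = as.integer(num_heads), hidden_dims = as.integer(hidden_dims),
    vcdn_features = as.integer(vcdn_features), delta = delta,
    train_fraction = train_fraction, num_repeats = as.integer(num_repeats),
    avg_degree = avg_degree, feature_cap = as.integer(feature_cap),
    feature_fraction = feature_fraction, seed = as.integer(seed),
    views = views, use_vcdn = isTRUE(use_vcdn), dropout = dropout,
    use_layernorm = isTRUE(use_layernorm), leaky_slope = leaky_slope,
    max_zero_fraction = max_zero_fraction,
    max_missing_fraction = max_missing_fraction,
    mode = match.arg(mode))
  validate_config(cfg)
  structure(cfg, class = "mogat_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$num_epochs >= 0, cfg$learning_rate >= 0, cfg$num_heads >= 1,
    cfg$hidden_dims >= 1, cfg$vcdn_features >= 1, cfg$delta >= 0,
    cfg$train_fraction > 0, cfg$train_fraction < 1, cfg$num_repeats >= 1,
    cfg$avg_degree > 0, cfg$feature_cap >= 1,
    cfg$feature_fraction > 0, cfg$feature_fraction <= 1,
    cfg$dropout >= 0, cfg$dropout < 1,
    cfg$max_zero_fraction >= 0, cfg$max_zero_fraction <= 1,
    cfg$max_missing_fraction >= 0, cfg$max_missing_fraction <= 1)
  if (abs(cfg$seed) > 2^30) abort("seed must stay below 2^30")
  invisible(cfg)
}

#' @export
print.mogat_config <- function(x, ...) {
  cat("<mogat_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) {
    cat(sprintf("  %-20s %s\n", nm, paste(flat[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path Path to a YAML file whose keys mirror [mogat_config()]
#'   arguments.
#' @return A `mogat_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mogat_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(mogat_config, vals)
}
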