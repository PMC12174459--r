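#' Default view layout for the synthetic generator
#'
#' Three modalities of differing dimensionality: two unbounded expression-like
#' views and one methylation-like view squashed into (0,1). `p` is the total
#' feature count, `s` how many of them carry planted class signal.
#'
#' @param p,s Integer vectors of length 3 (mRNA, miRNA, methylation).
#' @return Named list of per-view specifications.
#' @export
default_view_specs <- function(p = c(50L, 40L, 50L), s = c(10L, 10L, 10L)) {
  list(
    mRNA  = list(p = p[1], s = s[1], kind = "expression"),
    miRNA = list(p = p[2], s = s[2], kind = "expression"),
    meth  = list(p = p[3], s = s[3], kind = "methylation"))
}

#' Generate a seeded synthetic multi-omics dataset with planted structure
#'
#' Emulates, at desk scale, the statistical shape of a normalized multi-omics
#' stage-classification dataset: several views of differing dimensionality,
#' per-class mean-shifted informative features, view-specific Gaussian noise,
#' and a bounded methylation-like view. Because the planted features are
#' known, every downstream stage (selection, classification, fusion,
#' biomarker ranking) can be validated against ground truth.
#'
#' For an informative feature j of an expression-like view, samples of class
#' `c` are drawn `Normal(c * effect * d_j, noise_sd)` with a fixed random sign
#' `d_j` in {-1, +1}; non-informative features are `Normal(0, noise_sd)`.
#' Methylation-like views push the same construction through the logistic
#' function so values resemble beta-values, strictly inside (0,1).
#'
#' With `shared_latent = TRUE` the class is split into a coarse and a fine
#' partition: view 1's informative features depend only on
#' `c mod ceiling(C/2)`, view 2's only on `c %/% ceiling(C/2)`, and any
#' further view carries no class signal. No single view can then identify the
#' class; combining views 1 and 2 recovers it exactly -- the regime in which
#' label-space fusion provably beats any single branch.
#'
#' `pair_boundary = t` plants one extra step feature in view 1 whose mean
#' jumps by `pair_effect` between classes below and from `t` (0-based), so it
#' separates exactly one adjacent stage pair.
#'
#' Labels are balanced across `C` stages named "I", "II", ... Each view draws
#' from its own seeded substream, so adding a view never perturbs the draws
#' of earlier views.
#'
#' @param n Sample count.
#' @param C Number of stage classes (2..5).
#' @param view_specs Named list as produced by [default_view_specs()]; use
#'   fewer entries for fewer views.
#' @param effect Per-class mean shift of informative features.
#' @param noise_sd Noise standard deviation (> 0).
#' @param shared_latent Plant complementary cross-view signal (see Details).
#' @param pair_boundary Optional 0-based class index where the planted step
#'   feature jumps; `NULL` for none.
#' @param pair_effect Step size of the pair-specific feature.
#' @param seed Integer seed; identical seeds give bitwise-identical data.
#' @return A list of class `mogat_sim`: `views` (named list of
#'   [omics_view()]), `labels` (tibble), and `truth` (per view, the planted
#'   informative feature names, their signs, and the pair feature if any).
#' @export
simulate_multiomics <- function(n = 300, C = 3,
                                view_specs = default_view_specs(),
                                effect = 3, noise_sd = 1,
                                shared_latent = FALSE,
                                pair_boundary = NULL, pair_effect = 6,
                                seed = 1L) {
  stopifnot(n >= C, C >= 2, C <= 5, effect >= 0, noise_sd > 0,
            length(view_specs) >= 1)
  for (vs in view_specs) if (vs$s > vs$p) abort("spec error: s > p in a view")
  if (!is.null(pair_boundary)) {
    stopifnot(pair_boundary >= 1, pair_boundary <= C - 1)
  }
  seed <- as.integer(seed)
  if (abs(seed) > 2^30) abort("seed must stay below 2^30")

  stage_names <- c("I", "II", "III", "IV", "V")[seq_len(C)]
  codes <- rep_len(0:(C - 1), n)
  ids <- sprintf("S%04d", seq_len(n))
  labels <- tibble::tibble(sample_id = ids, label = stage_names[codes + 1L])

  g_coarse <- ceiling(C / 2)
  views <- list()
  truth <- list()
  for (vi in seq_along(view_specs)) {
    vs <- view_specs[[vi]]
    vname <- names(view_specs)[vi]
    # independent substream per view
    set.seed((abs(seed) %% 1000000L) * 1000L + vi)
    p <- vs$p; s <- vs$s
    d <- sample(c(-1, 1), p, replace = TRUE)
    inf_idx <- sort(sample.int(p, s))
    eff_class <- if (!shared_latent) codes
      else if (vi == 1L) codes %% g_coarse
      else if (vi == 2L) codes %/% g_coarse
      else rep(0L, n)
    M <- matrix(rnorm(n * p, 0, noise_sd), n, p)
    for (j in inf_idx) M[, j] <- M[, j] + eff_class * effect * d[j]
    fnames <- sprintf("%s_f%04d", vname, seq_len(p))
    pair_name <- NULL
    if (!is.null(pair_boundary) && vi == 1L) {
      pair_name <- sprintf("%s_pair%02d", vname, pair_boundary)
      M <- cbind(M, rnorm(n, 0, noise_sd) + pair_effect * (codes >= pair_boundary))
      fnames <- c(fnames, pair_name)
    }
    if (identical(vs$kind, "methylation")) M <- plogis(M)
    colnames(M) <- fnames
    rownames(M) <- ids
    views[[vname]] <- view_from_matrix(M, vname)
    truth[[vname]] <- list(informative = fnames[inf_idx],
                           sign = d[inf_idx], pair = pair_name)
  }
  structure(list(views = views, labels = labels, truth = truth,
                 spec = list(n = n, C = C, effect = effect,
                             noise_sd = noise_sd,
                             shared_latent = shared_latent,
                             pair_boundary = pair_boundary,
                             pair_effect = pair_effect, seed = seed)),
            class = "mogat_sim")
}

#' @export
print.mogat_sim <- function(x, ...) {
  cat(sprintf("<mogat_sim: %d samples, %d classes, %d view(s)>\n",
              x$spec$n, x$spec$C, length(x$views)))
  for (nm in names(x$views)) {
    cat(sprintf("  %s: %d features (%d informative)\n", nm,
                ncol(x$views[[nm]]) - 1L, length(x$truth[[nm]]$informative)))
  }
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One CSV per view, a `labels.csv`, and a `truth.json` listing the planted
#' informative features -- everything [read_omics_view()] and [read_labels()]
#' can read back.
#'
#' @param sim A `mogat_sim` from [simulate_multiomics()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "mogat_sim"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  for (nm in names(sim$views)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_omics_view(sim$views[[nm]], p)
    paths[nm] <- p
  }
  lp <- file.path(out_dir, "labels.csv")
  write_labels(sim$labels, lp)
  paths["labels"] <- lp
  tp <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, pretty = TRUE)
  paths["truth"] <- tp
  invisible(paths)
}
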