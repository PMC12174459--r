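test_that("masking importance is zero for features the model cannot see", {
  s <- fit_small(config = tiny_config(num_epochs = 15))
  fit <- s$fit
  # a feature whose first-layer incoming weights are exactly zero
  seen <- colnames(fit$X$mRNA)[1]
  fit$params$views[[1]]$W1[1, ] <- 0
  imp <- masking_importance(fit)
  expect_s3_class(imp, "mogat_importance")
  expect_equal(imp$importance[imp$feature == seen], 0)

  # features dropped by selection never enter the network
  universe <- fit$feature_universe$mRNA
  absent <- setdiff(universe, colnames(fit$X$mRNA))
  expect_true(all(imp$importance[imp$feature %in% absent] == 0))

  # within each view ranks are 1..p with descending importance
  for (nm in unique(imp$view_name)) {
    sub <- imp[imp$view_name == nm, ]
    expect_equal(sub$rank, seq_len(nrow(sub)))
    expect_true(all(diff(sub$importance) <= 1e-12))
  }
})

test_that("tabulated importances equal directly evaluated performance drops", {
  s <- fit_small(config = tiny_config(num_epochs = 15))
  fit <- s$fit
  imp <- masking_importance(fit)
  baseline <- attr(imp, "baseline")
  cls <- fit$label_info$class_names
  test_idx <- match(fit$test_ids, fit$sample_ids)
  truth <- as.character(fit$labels$label[test_idx])
  eval_masked <- function(zero_cols) {
    X2 <- fit$X
    X2$mRNA[, zero_cols] <- 0
    probs <- mogat:::forward_probs(fit, X = X2)$final
    est <- cls[max.col(probs[test_idx, , drop = FALSE], ties.method = "first")]
    compute_metrics(truth, est, class_names = cls)$f1_weighted
  }
  # per-feature: the table stores exactly the directly evaluated drop
  for (f in colnames(fit$X$mRNA)[1:2]) {
    expect_equal(imp$importance[imp$feature == f], baseline - eval_masked(f),
                 tolerance = 1e-12)
  }
  # masking the whole view at once: importance of the view-level super
  # feature is baseline minus the all-masked score, directly evaluated
  all_drop <- baseline - eval_masked(colnames(fit$X$mRNA))
  expect_true(is.finite(all_drop))
  expect_gte(baseline, 0)
})

test_that("importance is keyed by feature name, not column position", {
  s <- fit_small(config = tiny_config(num_epochs = 15))
  imp1 <- masking_importance(s$fit)
  fit2 <- s$fit
  fit2$feature_universe <- lapply(fit2$feature_universe, rev)
  imp2 <- masking_importance(fit2)
  j1 <- dplyr::arrange(imp1, .data$view_name, .data$feature)
  j2 <- dplyr::arrange(imp2, .data$view_name, .data$feature)
  expect_equal(j1$importance, j2$importance, tolerance = 1e-12)
})

test_that("a dominant planted feature ranks first in most seeds", {
  ranks <- vapply(1:10, function(s) {
    sim <- simulate_multiomics(
      n = 90, C = 2,
      view_specs = list(v1 = list(p = 20L, s = 1L, kind = "expression"),
                        v2 = list(p = 15L, s = 0L, kind = "expression")),
      effect = 5, noise_sd = 1, seed = 400 + s)
    cfg <- tiny_config(num_epochs = 40, seed = 500 + s)
    sp <- split_stratified(sim$labels, 0.7, seed = 600 + s)
    pp <- preprocess_views(sim$views, sim$labels, train_ids = sp$train_ids,
                           config = cfg)
    fit <- mogat_fit(pp$views, sim$labels, train_ids = sp$train_ids,
                     config = cfg, feature_universe = pp$universe)
    imp <- masking_importance(fit)
    imp$rank[imp$feature == sim$truth$v1$informative]
  }, numeric(1))
  expect_gte(sum(ranks == 1), 8)
})

test_that("top_biomarkers formats per-view shortlists", {
  imp <- structure(tibble::tibble(
    view_name = rep(c("a", "b", "c"), each = 4),
    feature = paste0("f", 1:12),
    importance = rep(c(0.4, 0.3, 0.2, 0.1), 3),
    rank = rep(1:4, 3)),
    class = c("mogat_importance", class(tibble::tibble())))
  expect_equal(nrow(top_biomarkers(imp, k = 3)), 9)
  expect_equal(nrow(top_biomarkers(imp, k = 0)), 0)
  expect_warning(top_biomarkers(imp, k = 5), "clipping")

  # ties broken name-lexicographically at ranking time
  s <- fit_small(config = tiny_config(num_epochs = 5))
  imp2 <- masking_importance(s$fit)
  zero <- imp2[imp2$importance == 0 & imp2$view_name == "mRNA", ]
  expect_equal(zero$feature, sort(zero$feature))
})

test_that("stage-pair pipelines produce one table per adjacent pair", {
  sim <- small_sim(n = 48, C = 4, p = c(16L, 12L, 12L), s = c(4L, 4L, 4L))
  cfg <- tiny_config(num_epochs = 10)
  suppressMessages(tabs <- stage_pair_biomarkers(sim$views, sim$labels,
                                                 config = cfg))
  expect_equal(names(tabs), c("I_vs_II", "II_vs_III", "III_vs_IV"))
  for (t in tabs) expect_s3_class(t, "mogat_importance")

  sim3 <- small_sim(n = 36, C = 3, p = c(16L, 12L, 12L), s = c(4L, 4L, 4L))
  suppressMessages(tabs3 <- stage_pair_biomarkers(sim3$views, sim3$labels,
                                                  config = cfg))
  expect_length(tabs3, 2)
})

test_that("the gradient-times-input alternative scores selected features", {
  s <- fit_small(config = tiny_config(num_epochs = 15))
  imp <- masking_importance(s$fit, method = "gradient")
  expect_equal(attr(imp, "method"), "gradient")
  expect_true(all(imp$importance >= 0))
  absent <- setdiff(s$fit$feature_universe$mRNA, colnames(s$fit$X$mRNA))
  expect_true(all(imp$importance[imp$feature %in% absent] == 0))
  sel <- imp$importance[imp$view_name == "mRNA" &
                          imp$feature %in% colnames(s$fit$X$mRNA)]
  expect_gt(max(sel), 0)
})
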