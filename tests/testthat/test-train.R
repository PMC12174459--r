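test_that("stratified splits have the right size, strata and determinism", {
  lab <- tibble::tibble(sample_id = sprintf("s%03d", 1:100),
                        label = rep(c("I", "II", "III", "IV"), 25))
  sp <- split_stratified(lab, 0.7, seed = 5)
  expect_length(sp$train_ids, 70)
  expect_length(sp$test_ids, 30)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), lab$sample_id)

  sp2 <- split_stratified(lab, 0.7, seed = 5)
  expect_identical(sp, sp2)

  # class proportions in train within one sample of the global proportions
  for (cl in unique(lab$label)) {
    n_cl <- sum(lab$label == cl)
    got <- sum(lab$label[lab$sample_id %in% sp$train_ids] == cl)
    expect_lte(abs(got - 0.7 * n_cl), 1)
  }

  bad <- tibble::tibble(sample_id = c("a", "b", "c"),
                        label = c("I", "I", "II"))
  expect_error(split_stratified(bad, 0.7, 1), "fewer than 2")
})

test_that("analytic gradients match finite differences at a generic point", {
  set.seed(4)
  n <- 7; C <- 2
  Xs <- list(matrix(runif(n * 4), n, 4), matrix(runif(n * 3), n, 3))
  for (v in 1:2) {
    rownames(Xs[[v]]) <- sprintf("s%02d", 1:n)
    colnames(Xs[[v]]) <- paste0("f", 1:ncol(Xs[[v]]))
  }
  cfg <- mogat_config(num_heads = 2, hidden_dims = 3, vcdn_features = 5,
                      dropout = 0, seed = 5, avg_degree = 3)
  graphs <- lapply(Xs, function(x) {
    build_patient_graph(mogat:::view_from_matrix(x, "v"), avg_degree = 3)
  })
  csrs <- lapply(graphs, function(g) mogat:::graph_csr(g$adjacency))
  set.seed(2)
  params <- mogat:::init_model_params(c(4L, 3L), C, cfg, TRUE)
  # move biases off 0 so no ReLU sits exactly at its kink
  for (v in 1:2) for (nm in c("b1", "b2", "b3", "Ob")) {
    params$views[[v]][[nm]][] <- rnorm(length(params$views[[v]][[nm]]), 0, 0.3)
  }
  y <- rep(0:1, length.out = n); tr <- 0:4
  loss_grad <- function(p) {
    mogat:::cpp_loss_grad(Xs, lapply(csrs, `[[`, "ei"),
                          lapply(csrs, `[[`, "ej"), lapply(csrs, `[[`, "ptr"),
                          y, tr, p, C, 2L, 3L, 0.2, 1.0, TRUE, TRUE)
  }
  lg <- loss_grad(params)
  expect_equal(lg$total, sum(lg$branch_losses) + lg$fusion_loss,
               tolerance = 1e-12)
  eps <- 1e-6
  check <- function(get, set) {
    g <- get(lg$grads)
    for (k in sample(seq_along(g), min(6, length(g)))) {
      p2 <- set(params, k, eps)
      num <- (loss_grad(p2)$total - lg$total) / eps
      expect_equal(g[k], num, tolerance = 5e-4)
    }
  }
  set.seed(10)
  for (v in 1:2) for (nm in names(params$views[[v]])) {
    check(function(gr) gr$views[[v]][[nm]],
          function(p, k, e) { p$views[[v]][[nm]][k] <- p$views[[v]][[nm]][k] + e; p })
  }
  for (nm in names(params$fusion)) {
    check(function(gr) gr$fusion[[nm]],
          function(p, k, e) { p$fusion[[nm]][k] <- p$fusion[[nm]][k] + e; p })
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  sim <- small_sim(n = 24)
  cfg <- tiny_config(learning_rate = 0, num_epochs = 5)
  sp <- split_stratified(sim$labels, 0.7, seed = 1)
  pp <- preprocess_views(sim$views, sim$labels, train_ids = sp$train_ids,
                         config = cfg)
  fit <- mogat_fit(pp$views, sim$labels, train_ids = sp$train_ids, config = cfg)
  set.seed(cfg$seed)
  init <- mogat:::init_model_params(
    vapply(fit$X, ncol, integer(1)), fit$label_info$C, cfg, TRUE)
  expect_equal(fit$params$views[[1]]$W1, init$views[[1]]$W1, tolerance = 1e-14)
  expect_equal(fit$params$fusion$W1, init$fusion$W1, tolerance = 1e-14)
})

test_that("training is bitwise reproducible and reduces the loss on signal", {
  s1 <- fit_small(config = tiny_config(dropout = 0.5))
  s2 <- fit_small(config = tiny_config(dropout = 0.5))
  expect_identical(s1$fit$log, s2$fit$log)
  expect_identical(s1$fit$params$views[[1]]$G1W, s2$fit$params$views[[1]]$G1W)
  p1 <- predict(s1$fit); p2 <- predict(s2$fit)
  expect_identical(p1, p2)

  # optimization sanity over several seeds
  improved <- vapply(1:5, function(s) {
    r <- fit_small(sim = small_sim(n = 45, seed = 30 + s),
                   config = tiny_config(seed = 50 + s))
    r$fit$log$total[nrow(r$fit$log)] < r$fit$log$total[1]
  }, logical(1))
  expect_true(all(improved))
})

test_that("prediction follows the fusion/averaging and tie-break rules", {
  s <- fit_small()
  pr <- predict(s$fit, type = "branch")
  probs <- as.matrix(pr[, grep("^\\.pred_[^c]", names(pr))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  cls <- s$fit$label_info$class_names
  expect_equal(as.character(pr$.pred_class),
               cls[max.col(probs, ties.method = "first")])

  # no-fusion ablation: final probabilities are the branch average
  cfg <- tiny_config(use_vcdn = FALSE)
  s2 <- fit_small(config = cfg)
  pr2 <- predict(s2$fit, type = "branch")
  branch <- attr(pr2, "branch_probs")
  avg <- Reduce(`+`, branch) / length(branch)
  got <- as.matrix(pr2[, grep("^\\.pred_[^c]", names(pr2))])
  expect_equal(unname(got), unname(avg), tolerance = 1e-12)

  # single view: branch passthrough
  sim <- small_sim(n = 30)
  sp <- split_stratified(sim$labels, 0.7, seed = 2)
  pp <- preprocess_views(sim$views["mRNA"], sim$labels,
                         train_ids = sp$train_ids, config = cfg)
  f1 <- mogat_fit(pp$views, sim$labels, train_ids = sp$train_ids, config = cfg)
  pr3 <- predict(f1, type = "branch")
  expect_equal(unname(as.matrix(pr3[, grep("^\\.pred_[^c]", names(pr3))])),
               unname(attr(pr3, "branch_probs")[[1]]), tolerance = 1e-12)
})

test_that("inductive attachment reproduces transductive scores when graphs coincide", {
  sim <- small_sim(n = 20, p = c(10L, 8L, 8L), s = c(4L, 4L, 4L))
  # fully connected graphs: transductive and inductive neighborhoods coincide
  cfg <- tiny_config(avg_degree = 19, num_epochs = 15)
  test_id <- sim$labels$sample_id[20]
  train_ids <- setdiff(sim$labels$sample_id, test_id)
  pp <- preprocess_views(sim$views, sim$labels, train_ids = train_ids,
                         config = cfg)
  fit <- mogat_fit(pp$views, sim$labels, train_ids = train_ids, config = cfg,
                   feature_universe = pp$universe)
  trans <- predict(fit)
  newdata <- lapply(pp$views, function(v) {
    mogat:::view_from_matrix(view_matrix(v)[test_id, , drop = FALSE],
                             view_name(v))
  })
  ind <- predict(fit, newdata = newdata, mode = "inductive")
  pcols <- grep("^\\.pred_[^c]", names(trans))
  expect_equal(as.numeric(ind[1, pcols]),
               as.numeric(trans[trans$sample_id == test_id, pcols]),
               tolerance = 1e-9)
})
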